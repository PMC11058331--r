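test_that("manifest validation reports all offenders with row numbers", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(3, "A", master_seed = 2, size = 32, dir = dir)
  mpath <- file.path(dir, "manifest.csv")
  expect_silent(m <- load_manifest(mpath))

  # break one mask reference
  m2 <- utils::read.csv(mpath)
  m2$mask_path[2] <- "nonexistent_mask.png"
  p2 <- file.path(dir, "broken.csv")
  utils::write.csv(m2, p2, row.names = FALSE)
  expect_error(load_manifest(p2), "row 2.*nonexistent_mask")

  # split leak across cases
  m3 <- utils::read.csv(mpath)
  m3$split <- "train"
  m3$split[m3$case_id == m3$case_id[1]][1] <- "val"
  p3 <- file.path(dir, "leak.csv")
  utils::write.csv(m3, p3, row.names = FALSE)
  expect_error(load_manifest(p3), "multiple splits")

  expect_error(load_manifest(file.path(dir, "absent.csv")), "no such file")
  p4 <- file.path(dir, "cols.csv")
  utils::write.csv(data.frame(path = "a"), p4, row.names = FALSE)
  expect_error(load_manifest(p4), "missing columns")
})

test_that("load_image rescales, resizes and keeps masks strictly binary", {
  dir <- withr::local_tempdir()
  set.seed(41)
  img <- matrix(stats::runif(32 * 32), 32, 32)
  msk <- rand_mask(32, p = 0.3)
  ip <- file.path(dir, "img.png"); mp <- file.path(dir, "msk.png")
  png::writePNG(img, ip); png::writePNG(msk, mp)
  rec <- list(path = ip, mask_path = mp, case_id = "c", modality = "m1",
              domain = "A")
  same <- load_image(rec, target_size = 32)          # no-op resize
  expect_lt(max(abs(same$pixels - img)), 1 / 255)    # 8-bit quantization only
  expect_identical(same$mask, msk * 1)
  up <- load_image(rec, target_size = 64)
  expect_equal(dim(up$pixels), c(64, 64))
  expect_true(all(up$mask %in% c(0, 1)))
  expect_true(all(up$pixels >= 0 & up$pixels <= 1))
  expect_error(load_image(list(path = "a.tif", mask_path = mp, case_id = "c",
                               modality = "m", domain = "A")), "unsupported")
})

test_that("checkerboard mask area is roughly preserved by nearest resize", {
  # 2x2-block checkerboard: a period-2 pattern under an exact 2x decimation
  # would alias to a constant, which tests nothing
  cb <- outer(1:8, 1:8, function(i, j) (ceiling(i / 2) + ceiling(j / 2)) %% 2)
  down <- resize_nearest(cb, 4, 4)
  expect_true(all(down %in% c(0, 1)))
  ratio <- sum(down) / sum(cb)                       # expect ~0.25 of pixels
  expect_gte(ratio, 0.25 * 0.5)
  expect_lte(ratio, 0.25 * 2)
})

test_that("split_cases is case-disjoint, seeded and unbiased", {
  manifest <- data.frame(
    path = "p", mask_path = "q",
    case_id = rep(sprintf("c%02d", 1:10), each = 3),
    domain = "A", modality = rep(c("m1", "m2", "m3"), 10))
  s <- split_cases(manifest, 0.8, seed = 1)
  tab <- table(unique(s[, c("case_id", "split")])$split)
  expect_equal(unname(tab["train"]), 8L)
  expect_equal(unname(tab["val"]), 2L)
  expect_identical(split_cases(manifest, 0.8, seed = 1), s)
  # each case should fall in val ~20% of the time across seeds
  val_count <- setNames(numeric(10), sprintf("c%02d", 1:10))
  for (sd in 1:200) {
    ss <- split_cases(manifest, 0.8, seed = sd)
    v <- unique(ss$case_id[ss$split == "val"])
    val_count[v] <- val_count[v] + 1
  }
  expect_true(all(val_count / 200 >= 0.1 & val_count / 200 <= 0.3))
  expect_error(split_cases(manifest[manifest$case_id == "c01", ], 0.8, 1),
               "at least 2")
})

test_that("streams shuffle reproducibly and honour the lambda endpoint", {
  imgs <- phantom_images(3, "A", seed = 71, size = 32)
  st0 <- make_streams(imgs, seed = 3, lambda_range = c(0, 0))
  ep <- st0$epoch(1)
  for (k in seq_along(ep$original)) {
    expect_lt(max(abs(ep$mixed[[k]]$image - ep$original[[k]]$pixels)), 1e-6)
    expect_identical(ep$mixed[[k]]$mask, ep$original[[k]]$mask)
    expect_identical(ep$mixed[[k]]$case_id, ep$original[[k]]$case_id)
  }
  st1 <- make_streams(imgs, seed = 3)
  e1 <- st1$epoch(5)
  e2 <- st1$epoch(5)
  expect_identical(vapply(e1$original, `[[`, character(1), "modality_id"),
                   vapply(e2$original, `[[`, character(1), "modality_id"))
  expect_identical(vapply(e1$mixed, `[[`, numeric(1), "lam"),
                   vapply(e2$mixed, `[[`, numeric(1), "lam"))
})

test_that("donor modalities are drawn uniformly from the case's siblings", {
  set.seed(81)
  base <- matrix(stats::runif(256), 16, 16)
  msk <- rand_mask(16)
  imgs <- lapply(c("m1", "m2", "m3"), function(m) {
    modality_image(matrix(stats::runif(256), 16, 16), msk, "c1", m)
  })
  st <- make_streams(imgs, seed = 4)
  donors <- character(0)
  for (e in 1:700) {
    ep <- st$epoch(e)
    src <- vapply(ep$mixed, `[[`, character(1), "source_modality")
    donors <- c(donors, ep$mixed[[which(src == "m1")]]$donor_modality)
  }
  freq <- table(donors) / length(donors)
  expect_setequal(names(freq), c("m2", "m3"))
  expect_true(all(abs(freq - 0.5) < 0.06))  # 700 draws, 3 sigma ~ 0.057
})

test_that("single-modality cases stay in the original stream with a warning", {
  imgs <- phantom_images(2, "A", seed = 91, size = 32)
  lone <- modality_image(matrix(0.5, 32, 32), matrix(0, 32, 32), "solo", "m1")
  expect_warning(st <- make_streams(c(imgs, list(lone)), seed = 1),
                 "no donor")
  ep <- st$epoch(1)
  solo_pos <- which(vapply(ep$original, `[[`, character(1), "case_id") == "solo")
  expect_null(ep$mixed[[solo_pos]])
  expect_equal(sum(vapply(ep$mixed, is.null, logical(1))), 1L)
})
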