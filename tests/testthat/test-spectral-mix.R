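test_that("decompose agrees with the brute-force DFT oracle on small grids", {
  set.seed(11)
  for (dims in list(c(2, 2), c(3, 5), c(4, 4), c(8, 8), c(8, 6))) {
    x <- rand_img(dims[1], dims[2])
    z <- dft_oracle(x)
    sp <- decompose_image(x)
    expect_lt(max(abs(sp$amplitude - Mod(z))), 1e-9)
    # compare phase through the complex value (phase of ~0 amplitude is noise)
    expect_lt(max(abs(sp$amplitude * exp(1i * sp$phase) - z)), 1e-9)
  }
})

test_that("a constant image has a DC-only spectrum", {
  n <- 6
  sp <- decompose_image(matrix(3.5, n, n))
  expect_equal(sp$amplitude[1, 1], 3.5 * n^2, tolerance = 1e-12)
  expect_lt(max(sp$amplitude[-1]), 1e-9)
  expect_equal(sp$phase[1, 1], 0)
})

test_that("compose inverts decompose for arbitrary shapes", {
  set.seed(12)
  for (dims in list(c(5, 7), c(8, 8), c(16, 12), c(33, 17), c(64, 64))) {
    x <- rand_img(dims[1], dims[2])
    sp <- decompose_image(x)
    expect_lt(max(abs(compose(sp$amplitude, sp$phase) - x)), 1e-6)
    expect_true(all(sp$amplitude >= 0))
    expect_true(all(sp$phase > -pi - 1e-12 & sp$phase <= pi + 1e-12))
  }
})

test_that("decompose validates its input", {
  bad <- matrix(c(1, NaN, 2, 3), 2, 2)
  expect_error(decompose_image(bad, slice_id = "caseX/m2"), "caseX/m2")
  expect_error(decompose_image(matrix(1)), "2x2")
  expect_error(decompose_image(1:4), "matrix")
})

test_that("mix_amplitude is an exact convex combination with validated inputs", {
  a <- matrix(2, 4, 4); b <- matrix(4, 4, 4)
  expect_identical(mix_amplitude(a, b, 0), a)
  expect_identical(mix_amplitude(a, b, 1), b)
  expect_equal(mix_amplitude(a, b, 0.5), matrix(3, 4, 4))
  expect_error(mix_amplitude(a, matrix(1, 3, 3), 0.5), "shape")
  expect_error(mix_amplitude(a, b, 1.2), "lam")
  expect_error(mix_amplitude(a, b, -0.1), "lam")
})

test_that("Hermitian symmetry survives amplitude mixing (real reconstruction)", {
  set.seed(13)
  x1 <- rand_img(8); x2 <- rand_img(8)
  s1 <- decompose_image(x1); s2 <- decompose_image(x2)
  am <- mix_amplitude(s1$amplitude, s2$amplitude, 0.37)
  expect_lt(compose_residual(am, s1$phase), 1e-6)
  # amplitude symmetric / phase antisymmetric under frequency negation
  neg <- function(m) m[c(1, nrow(m):2), c(1, ncol(m):2)]
  expect_lt(max(abs(s1$amplitude - neg(s1$amplitude))), 1e-9)
  wrap <- function(p) atan2(sin(p), cos(p))
  expect_lt(max(abs(wrap(s1$phase + neg(s1$phase)))), 1e-6)
})

test_that("mix_images endpoint and self-mix identities hold through the pipeline", {
  p <- tiny_pair()
  m0 <- mix_images(p$src, p$donor, 0)
  expect_lt(max(abs(m0$image - p$src$pixels)), 1e-6)
  expect_identical(m0$mask, p$src$mask)
  # donor forced to the same pixels under a different modality id
  clone <- modality_image(p$src$pixels, p$src$mask, "c1", "m9")
  m7 <- mix_images(p$src, clone, 0.7)
  expect_lt(max(abs(m7$image - p$src$pixels)), 1e-6)
})

test_that("the mixed image's amplitude is the analytic convex combination", {
  p <- tiny_pair(size = 32)
  lam <- 0.5
  ms <- mix_images(p$src, p$donor, lam, clip = FALSE)
  a_mixed <- decompose_image(ms$image)$amplitude
  a_expect <- mix_amplitude(decompose_image(p$src$pixels)$amplitude,
                            decompose_image(p$donor$pixels)$amplitude, lam)
  expect_lt(max(abs(a_mixed - a_expect)), 1e-5)
  expect_equal(ms$lam, lam)
  expect_identical(ms$source_modality, "m1")
  expect_identical(ms$donor_modality, "m2")
})

test_that("mix_images rejects invalid pairs and clips to [0, 1]", {
  p <- tiny_pair()
  same_mod <- modality_image(p$donor$pixels, p$donor$mask, "c1", "m1")
  expect_error(mix_images(p$src, same_mod, 0.5), "distinct")
  small <- modality_image(rand_img(8), rand_mask(8), "c1", "m2")
  expect_error(mix_images(p$src, small, 0.5), "shape")
  ms <- mix_images(p$src, p$donor, 0.8)
  expect_true(all(ms$image >= 0 & ms$image <= 1))
})

test_that("sample_lambda is uniform, seeded, and honours degenerate ranges", {
  set.seed(5); a <- sample_lambda(50)
  set.seed(5); b <- sample_lambda(50)
  expect_identical(a, b)
  set.seed(6); draws <- sample_lambda(10000)
  expect_true(all(draws >= 0 & draws <= 1))
  expect_gt(mean(draws), 0.48)
  expect_lt(mean(draws), 0.52)
  expect_identical(sample_lambda(5, c(0.3, 0.3)), rep(0.3, 5))
  expect_error(sample_lambda(1, c(0.5, 0.2)), "range")
  expect_error(sample_lambda(1, c(-0.1, 1)), "range")
})
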