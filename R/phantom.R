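# Synthetic multi-modal, two-domain head-slice phantom.
#
# Each case is a layered 2D "anatomy": background, an elliptical head,
# 2-4 internal structures and one irregular tumour blob. The three
# modalities (m1/m2/m3) render the SAME tissue map through different
# piecewise intensity transfer curves — qualitatively structure-bright,
# fluid-bright, and rim-enhanced-tumour — so they share geometry (one mask
# fits all three) but differ in contrast, which is exactly what the
# amplitude-mixing augmentation needs. The two domains A and B differ only
# in appearance (transfer curves, bias-field amplitude, noise level), never
# in geometry, so a generalization gap between them is a pure style shift.

tissue_classes <- c(bg = 1L, head = 2L, struct_a = 3L, struct_b = 4L, tumour = 5L)

#' Domain appearance parameters
#'
#' Per-modality tissue-to-intensity transfer curves plus bias-field
#' amplitude, noise level and per-case contrast jitter for one simulated
#' "hospital". Domain `A` (the training/source analogue) and domain `B`
#' (the unseen analogue) are distinct by construction: their transfer
#' curves differ by at least 0.05 somewhere (asserted).
#'
#' @param domain `"A"` or `"B"`.
#' @return Object of class `domain_params`: `curves` (5 tissue classes x 3
#'   modalities), `rim_value` (modality-3 tumour-rim intensity),
#'   `bias_amp`, `noise_sd`, `jitter`.
#' @export
domain_params <- function(domain = c("A", "B")) {
  domain <- match.arg(domain)
  curves_a <- cbind(
    m1 = c(0.05, 0.60, 0.78, 0.40, 0.47),
    m2 = c(0.05, 0.32, 0.22, 0.80, 0.72),
    m3 = c(0.05, 0.58, 0.72, 0.45, 0.52))
  curves_b <- cbind(
    m1 = c(0.12, 0.72, 0.85, 0.55, 0.60),
    m2 = c(0.10, 0.45, 0.33, 0.88, 0.80),
    m3 = c(0.12, 0.70, 0.82, 0.58, 0.66))
  rownames(curves_a) <- rownames(curves_b) <- names(tissue_classes)
  stopifnot(max(abs(curves_a - curves_b)) >= 0.05) # domains measurably apart
  p <- if (domain == "A") {
    list(curves = curves_a, rim_value = 0.88, bias_amp = 0.08,
         noise_sd = 0.02, jitter = 0.03)
  } else {
    list(curves = curves_b, rim_value = 0.95, bias_amp = 0.15,
         noise_sd = 0.035, jitter = 0.04)
  }
  p$domain <- domain
  structure(p, class = "domain_params")
}

# one-pixel binary erosion (4-neighbourhood)
binary_erode <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- m
  out <- p[2:(h + 1), 2:(w + 1)] *
    p[1:h, 2:(w + 1)] * p[3:(h + 2), 2:(w + 1)] *
    p[2:(h + 1), 1:w] * p[2:(h + 1), 3:(w + 2)]
  out
}

ellipse_mask <- function(size, cx, cy, ra, rb, phi) {
  x <- matrix(seq_len(size), size, size) - cx          # row coordinate
  y <- matrix(seq_len(size), size, size, byrow = TRUE) - cy
  u <- x * cos(phi) + y * sin(phi)
  v <- -x * sin(phi) + y * cos(phi)
  ((u / ra)^2 + (v / rb)^2 <= 1) * 1
}

# irregular blob: ellipse radius modulated by low-order angular harmonics
blob_mask <- function(size, cx, cy, r0, amps, phases) {
  x <- matrix(seq_len(size), size, size) - cx
  y <- matrix(seq_len(size), size, size, byrow = TRUE) - cy
  ang <- atan2(y, x)
  r <- r0 * (1 + Reduce(`+`, Map(function(j, a, p) a * cos(j * ang + p),
                                 seq_along(amps) + 1L, amps, phases)))
  (sqrt(x^2 + y^2) <= r) * 1
}

smooth_field <- function(size) {
  f <- matrix(0, size, size)
  x <- matrix(seq_len(size), size, size)
  y <- t(x)
  for (k in 1:3) {
    cx <- stats::runif(1, 0.2, 0.8) * size
    cy <- stats::runif(1, 0.2, 0.8) * size
    s <- stats::runif(1, 0.35, 0.6) * size
    a <- stats::runif(1, -1, 1)
    f <- f + a * exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))
  }
  f / max(abs(f))
}

#' Generate one phantom case
#'
#' Builds the shared tissue geometry from `geometry_seed` (head ellipse,
#' 2-4 internal structures, one tumour blob of 1-8% of the head area, all
#' placement by bounded rejection sampling), then renders the three
#' modality images from `appearance_seed` (jittered transfer curves, the
#' modality-3 tumour rim, a smooth multiplicative bias field, additive
#' Gaussian noise, clipping to `[0, 1]`). Identical seeds give bit-identical
#' cases.
#'
#' @param case_id Identifier.
#' @param domain `"A"` or `"B"` (selects [domain_params()] unless `params`
#'   is given).
#' @param size Image side length (must suit the model depth downstream).
#' @param geometry_seed,appearance_seed Integer seeds.
#' @param params Optional [domain_params()] override.
#' @return Object of class `phantom_case`: `case_id`, `domain_id`, `images`
#'   (named list m1/m2/m3 of matrices in `[0, 1]`), `mask`, `head` (the
#'   anatomy region the tumour is contained in), seeds.
#' @export
generate_case <- function(case_id, domain = "A", size = 96L,
                          geometry_seed = 1L, appearance_seed = 1L,
                          params = NULL) {
  if (is.null(params)) params <- domain_params(domain)
  set.seed(geometry_seed)
  cx <- size / 2 + stats::runif(1, -0.03, 0.03) * size
  cy <- size / 2 + stats::runif(1, -0.03, 0.03) * size
  ra <- stats::runif(1, 0.28, 0.36) * size
  rb <- stats::runif(1, 0.28, 0.36) * size
  phi <- stats::runif(1, 0, pi)
  head <- ellipse_mask(size, cx, cy, ra, rb, phi)
  tissue <- matrix(tissue_classes["bg"], size, size)
  tissue[head == 1] <- tissue_classes["head"]

  inner <- binary_erode(binary_erode(head))
  nstruct <- sample(2:4, 1)
  for (s in seq_len(nstruct)) {
    for (try in 1:20) {
      scx <- stats::runif(1, 0.2, 0.8) * size
      scy <- stats::runif(1, 0.2, 0.8) * size
      if (inner[round(scx), round(scy)] == 1) break
    }
    sm <- ellipse_mask(size, scx, scy, stats::runif(1, 0.05, 0.11) * size,
                       stats::runif(1, 0.05, 0.11) * size,
                       stats::runif(1, 0, pi)) * head
    cls <- if (s %% 2 == 1) tissue_classes["struct_a"] else tissue_classes["struct_b"]
    tissue[sm == 1] <- cls
  }

  head_area <- sum(head)
  tumour <- NULL
  for (try in 1:50) {
    tcx <- stats::runif(1, 0.25, 0.75) * size
    tcy <- stats::runif(1, 0.25, 0.75) * size
    if (inner[round(tcx), round(tcy)] != 1) next
    frac <- stats::runif(1, 0.015, 0.07)
    r0 <- sqrt(frac * head_area / pi)
    tm <- blob_mask(size, tcx, tcy, r0,
                    amps = stats::runif(3, -0.15, 0.15),
                    phases = stats::runif(3, 0, 2 * pi))
    area <- sum(tm)
    ok <- area >= 8 && all(head[tm == 1] == 1) &&
      area / head_area >= 0.01 && area / head_area <= 0.08
    if (ok) { tumour <- tm; break }
  }
  if (is.null(tumour)) stop("generate_case: infeasible tumour geometry for case ", case_id)
  tissue[tumour == 1] <- tissue_classes["tumour"]
  rim <- tumour - binary_erode(tumour)

  set.seed(appearance_seed)
  images <- list()
  for (mod in colnames(params$curves)) {
    curve <- params$curves[, mod] + stats::runif(5, -params$jitter, params$jitter)
    img <- matrix(curve[tissue], size, size)
    if (mod == "m3") {
      img[rim == 1] <- params$rim_value + stats::runif(1, -params$jitter, params$jitter)
    }
    img <- img * (1 + params$bias_amp * smooth_field(size))
    img <- img + stats::rnorm(size * size, sd = params$noise_sd)
    images[[mod]] <- pmin(pmax(img, 0), 1)
  }
  structure(list(case_id = as.character(case_id), domain_id = params$domain,
                 images = images, mask = tumour, head = head,
                 geometry_seed = geometry_seed,
                 appearance_seed = appearance_seed),
            class = "phantom_case")
}

#' Generate a phantom dataset
#'
#' Generates `n_cases` independent cases of one domain, deterministically
#' from `master_seed`. If `dir` is given, writes each modality image and
#' the mask as 8-bit grayscale PNGs plus a `manifest.csv`
#' (`path,mask_path,case_id,domain,modality`).
#'
#' @param n_cases Number of cases (`>= 1`).
#' @param domain `"A"` or `"B"`.
#' @param master_seed Integer; per-case seeds are derived from it.
#' @param size Image side length.
#' @param dir Optional output directory.
#' @param prefix Case-id prefix (defaults to the domain id).
#' @return List with `cases` (list of [generate_case()] results) and
#'   `manifest` (`data.frame`; paths are `NA` when nothing was written).
#' @export
generate_dataset <- function(n_cases, domain = "A", master_seed = 1L,
                             size = 96L, dir = NULL, prefix = domain) {
  stopifnot(n_cases >= 1)
  cases <- vector("list", n_cases)
  rows <- list()
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    dir <- normalizePath(dir)  # manifests must resolve from any cwd
  }
  for (i in seq_len(n_cases)) {
    cid <- sprintf("%s%03d", prefix, i)
    cs <- generate_case(cid, domain = domain, size = size,
                        geometry_seed = derive_seed(master_seed, 2L * i),
                        appearance_seed = derive_seed(master_seed, 2L * i + 1L))
    cases[[i]] <- cs
    mask_path <- NA_character_
    if (!is.null(dir)) {
      mask_path <- file.path(dir, paste0(cid, "_mask.png"))
      png::writePNG(cs$mask, mask_path)
    }
    for (mod in names(cs$images)) {
      img_path <- NA_character_
      if (!is.null(dir)) {
        img_path <- file.path(dir, paste0(cid, "_", mod, ".png"))
        png::writePNG(cs$images[[mod]], img_path)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        path = img_path, mask_path = mask_path, case_id = cid,
        domain = domain, modality = mod)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) write_manifest(manifest, file.path(dir, "manifest.csv"))
  list(cases = cases, manifest = manifest)
}

#' Flatten phantom cases into modality images
#'
#' @param cases List of [generate_case()] results.
#' @return List of [modality_image()] objects (3 per case).
#' @export
as_modality_images <- function(cases) {
  out <- list()
  for (cs in cases) {
    for (mod in names(cs$images)) {
      out[[length(out) + 1L]] <- modality_image(
        cs$images[[mod]], cs$mask, cs$case_id, mod, cs$domain_id)
    }
  }
  out
}
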