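#' A single modality slice with its mask
#'
#' The atomic data unit: one real-valued 2D slice of one modality of one
#' case, intensities in `[0, 1]`, with a co-registered binary lesion mask.
#'
#' @param pixels Numeric matrix in `[0, 1]`.
#' @param mask Binary matrix (`0`/`1`) of the same shape.
#' @param case_id,modality_id,domain_id Identifiers; modalities of one case
#'   are expected to share geometry (the mask is valid for all of them).
#' @param source_path Optional originating file path.
#' @return Object of class `modality_image`.
#' @export
modality_image <- function(pixels, mask, case_id, modality_id,
                           domain_id = "A", source_path = NA_character_) {
  if (!is.matrix(pixels) || !is.matrix(mask) ||
      !identical(dim(pixels), dim(mask))) {
    stop("modality_image: pixels and mask must be matrices of the same shape")
  }
  if (any(pixels < 0 | pixels > 1)) {
    stop("modality_image: pixel intensities must lie in [0, 1]")
  }
  if (!all(mask %in% c(0, 1))) stop("modality_image: mask must be binary")
  structure(list(pixels = pixels, mask = mask, case_id = as.character(case_id),
                 modality_id = as.character(modality_id),
                 domain_id = as.character(domain_id),
                 source_path = source_path),
            class = "modality_image")
}

manifest_columns <- c("path", "mask_path", "case_id", "domain", "modality")

#' Load and validate a dataset manifest
#'
#' The manifest is a UTF-8 CSV with header columns
#' `path,mask_path,case_id,domain,modality` (an optional `split` column is
#' validated for case-disjointness). All validation failures — missing
#' columns, missing files with their row numbers, split leaks — are
#' collected and reported in one error.
#'
#' @param path Manifest CSV path.
#' @param check_files Verify that every referenced file exists.
#' @return `data.frame` manifest; relative paths are resolved against the
#'   manifest's directory.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("load_manifest: no such file: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  errs <- character()
  missing_cols <- setdiff(manifest_columns, names(m))
  if (length(missing_cols)) {
    stop("load_manifest: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  m$path <- resolve(m$path)
  m$mask_path <- resolve(m$mask_path)
  if (check_files) {
    for (i in seq_len(nrow(m))) {
      if (!file.exists(m$path[i])) {
        errs <- c(errs, sprintf("row %d: missing image file %s", i, m$path[i]))
      }
      if (!file.exists(m$mask_path[i])) {
        errs <- c(errs, sprintf("row %d: missing mask file %s", i, m$mask_path[i]))
      }
    }
  }
  if ("split" %in% names(m)) {
    leaks <- names(which(vapply(split(m$split, m$case_id),
                                function(s) length(unique(s)) > 1L, logical(1))))
    if (length(leaks)) {
      errs <- c(errs, paste("cases present in multiple splits:",
                            paste(leaks, collapse = ", ")))
    }
  }
  if (length(errs)) {
    stop("load_manifest: invalid manifest:\n  ", paste(errs, collapse = "\n  "))
  }
  m
}

# bilinear interpolation matrix mapping `src` samples onto `dst` samples
interp_matrix <- function(dst, src) {
  pos <- ((seq_len(dst) - 0.5) * src / dst) - 0.5
  pos <- pmin(pmax(pos, 0), src - 1)
  lo <- floor(pos)
  w <- pos - lo
  M <- matrix(0, dst, src)
  for (i in seq_len(dst)) {
    l <- lo[i] + 1
    h <- min(l + 1, src)
    M[i, l] <- M[i, l] + (1 - w[i])
    M[i, h] <- M[i, h] + w[i]
  }
  M
}

#' Resize a grayscale image (bilinear)
#' @param img Numeric matrix.
#' @param h,w Target height and width.
#' @return Resized matrix.
#' @export
resize_bilinear <- function(img, h, w) {
  if (nrow(img) == h && ncol(img) == w) return(img)
  interp_matrix(h, nrow(img)) %*% img %*% t(interp_matrix(w, ncol(img)))
}

#' Resize a mask (nearest neighbour, stays binary)
#' @inheritParams resize_bilinear
#' @export
resize_nearest <- function(img, h, w) {
  if (nrow(img) == h && ncol(img) == w) return(img)
  ri <- pmin(floor((seq_len(h) - 0.5) * nrow(img) / h) + 1, nrow(img))
  ci <- pmin(floor((seq_len(w) - 0.5) * ncol(img) / w) + 1, ncol(img))
  img[ri, ci, drop = FALSE]
}

read_gray <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("load_image: unsupported image format: ", path)
  )
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  img
}

#' Load one manifest record as a modality image
#'
#' Reads an 8/16-bit grayscale PNG or JPEG slice and its mask, rescales
#' intensities to `[0, 1]`, and resizes to `target_size` (bilinear for the
#' image, nearest-neighbour for the mask, which is then re-binarized at
#' 0.5).
#'
#' @param record One manifest row (`data.frame` row or named list).
#' @param target_size Optional side length (or `c(h, w)`); `NULL` keeps the
#'   stored size.
#' @return A [modality_image()].
#' @export
load_image <- function(record, target_size = NULL) {
  img <- tryCatch(read_gray(record$path),
                  error = function(e) stop("load_image: cannot decode ",
                                           record$path, ": ", conditionMessage(e)))
  msk <- tryCatch(read_gray(record$mask_path),
                  error = function(e) stop("load_image: cannot decode ",
                                           record$mask_path, ": ", conditionMessage(e)))
  if (!is.null(target_size)) {
    if (length(target_size) == 1L) target_size <- c(target_size, target_size)
    img <- resize_bilinear(img, target_size[1], target_size[2])
    msk <- resize_nearest(msk, target_size[1], target_size[2])
  }
  img <- pmin(pmax(img, 0), 1)
  msk <- (msk > 0.5) * 1
  modality_image(img, msk, record$case_id, record$modality, record$domain,
                 source_path = record$path)
}

#' Load every (filtered) manifest record
#'
#' @param manifest A [load_manifest()] result.
#' @param target_size Passed to [load_image()].
#' @param split Optional split filter (requires a `split` column).
#' @param domain Optional domain filter.
#' @return List of [modality_image()] objects.
#' @export
load_dataset <- function(manifest, target_size = NULL, split = NULL,
                         domain = NULL) {
  if (!is.null(split)) manifest <- manifest[manifest$split %in% split, , drop = FALSE]
  if (!is.null(domain)) manifest <- manifest[manifest$domain %in% domain, , drop = FALSE]
  lapply(seq_len(nrow(manifest)),
         function(i) load_image(manifest[i, ], target_size))
}

#' Case-level train/validation split
#'
#' Randomly assigns whole cases (never individual slices) to `train` or
#' `val`, so no case leaks across splits. Reproducible under `seed`.
#'
#' @param manifest Manifest `data.frame`.
#' @param train_fraction Fraction of cases assigned to training (default
#'   0.8).
#' @param seed Integer seed.
#' @return Manifest with a `split` column.
#' @export
split_cases <- function(manifest, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  cases <- unique(manifest$case_id)
  if (length(cases) < 2L) stop("split_cases: need at least 2 cases")
  set.seed(seed)
  n_train <- max(1L, min(length(cases) - 1L,
                         round(train_fraction * length(cases))))
  tr <- sample(cases, n_train)
  manifest$split <- ifelse(manifest$case_id %in% tr, "train", "val")
  manifest
}

#' Build the original and mixed training streams
#'
#' Returns a stream object whose `epoch(e)` method yields the epoch's
#' reproducibly shuffled original items (`D_init`) and, when mixing is on,
#' a parallel list of [mix_images()] samples (`D_mix`): for each original
#' item a donor modality is drawn uniformly from the *other* modalities of
#' the same case and a fresh mixing ratio is drawn from `lambda_range`.
#' Items whose case has a single modality get a `NULL` mixed entry (they
#' contribute to the original stream only; a warning is emitted once).
#'
#' @param images List of [modality_image()] objects.
#' @param seed Integer seed; shuffling and mixing use independent derived
#'   streams, so `mix = FALSE` leaves the shuffle order unchanged.
#' @param lambda_range Mixing-ratio range, see [sample_lambda()].
#' @param mix Build the mixed stream at all.
#' @return List with `n` (number of items) and `epoch(e)`.
#' @export
make_streams <- function(images, seed = 1L, lambda_range = c(0, 1),
                         mix = TRUE) {
  n <- length(images)
  by_case <- split(seq_len(n), vapply(images, `[[`, character(1), "case_id"))
  donors <- lapply(seq_len(n), function(i) {
    sibs <- setdiff(by_case[[images[[i]]$case_id]], i)
    sibs[vapply(sibs, function(j) {
      !identical(images[[j]]$modality_id, images[[i]]$modality_id)
    }, logical(1))]
  })
  if (mix && any(lengths(donors) == 0L)) {
    warning("make_streams: ", sum(lengths(donors) == 0L),
            " item(s) have no donor modality; original stream only")
  }
  list(
    n = n,
    epoch = function(epoch) {
      set.seed(derive_seed(seed, 2L * epoch))
      ord <- sample.int(n)
      orig <- images[ord]
      mixed <- NULL
      if (mix) {
        set.seed(derive_seed(seed, 2L * epoch + 1L))
        mixed <- lapply(ord, function(i) {
          if (!length(donors[[i]])) return(NULL)
          j <- donors[[i]][sample.int(length(donors[[i]]), 1L)]
          mix_images(images[[i]], images[[j]],
                     sample_lambda(1L, lambda_range))
        })
      }
      list(original = orig, mixed = mixed)
    }
  )
}

#' Write a manifest CSV
#' @param manifest Manifest `data.frame`.
#' @param path Output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
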