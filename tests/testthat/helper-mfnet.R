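# Shared fixtures and independent oracles, built in code at test time.

# brute-force O(n^4) double-loop DFT: the independent oracle for decompose
dft_oracle <- function(x) {
  H <- nrow(x); W <- ncol(x)
  z <- matrix(0i, H, W)
  for (u in 0:(H - 1)) {
    for (v in 0:(W - 1)) {
      acc <- 0i
      for (h in 0:(H - 1)) {
        for (w in 0:(W - 1)) {
          acc <- acc + x[h + 1, w + 1] *
            exp(-2i * pi * (u * h / H + v * w / W))
        }
      }
      z[u + 1, v + 1] <- acc
    }
  }
  z
}

rand_img <- function(h, w = h) matrix(stats::runif(h * w), h, w)

rand_mask <- function(h, w = h, p = 0.3) {
  matrix(as.numeric(stats::rbinom(h * w, 1, p)), h, w)
}

# two co-registered "modalities" of one synthetic case
tiny_pair <- function(size = 16, seed = 42) {
  set.seed(seed)
  base <- rand_img(size)
  mask <- rand_mask(size, p = 0.2)
  list(
    src = modality_image(base, mask, "c1", "m1"),
    donor = modality_image(pmin(pmax(base * 0.5 + rand_img(size) * 0.5, 0), 1),
                           mask, "c1", "m2")
  )
}

# small in-memory phantom training set (cached per test run)
.phantom_cache <- new.env(parent = emptyenv())
phantom_images <- function(n_cases, domain = "A", seed = 7, size = 32) {
  key <- paste(n_cases, domain, seed, size, sep = "_")
  if (is.null(.phantom_cache[[key]])) {
    .phantom_cache[[key]] <- as_modality_images(
      generate_dataset(n_cases, domain, master_seed = seed, size = size)$cases)
  }
  .phantom_cache[[key]]
}
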