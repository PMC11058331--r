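#' U-Net model configuration
#'
#' Classic 2-conv-per-stage encoder/decoder with batch normalization,
#' 2x2 max pooling, bilinear upsampling and skip connections; a final 1x1
#' convolution plus sigmoid yields a per-pixel foreground probability.
#' Input spatial size must be divisible by `2^depth`.
#'
#' Two profiles are used throughout the package: the CPU-friendly desk
#' scale (`base_channels = 16`, `depth = 3`, 96x96 inputs) and the full
#' scale (`base_channels = 64`, `depth = 4`, 512x512 inputs).
#'
#' @param in_channels Input channels (1 for grayscale slices).
#' @param base_channels Width of the first encoder stage; doubles per stage.
#' @param depth Number of down-sampling stages.
#' @return Object of class `unet_config`.
#' @export
unet_config <- function(in_channels = 1L, base_channels = 16L, depth = 3L) {
  stopifnot(in_channels >= 1L, base_channels >= 1L, depth >= 1L)
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), out_channels = 1L),
            class = "unet_config")
}

# stage plan: list of (name, cin, cout) for every conv block
unet_plan <- function(cfg) {
  ch <- cfg$base_channels * 2L^(0:cfg$depth) # enc widths + bottleneck
  plan <- list()
  cin <- cfg$in_channels
  for (s in seq_len(cfg$depth)) {
    plan[[paste0("enc", s)]] <- c(cin, ch[s])
    cin <- ch[s]
  }
  plan[["bot"]] <- c(cin, ch[cfg$depth + 1L])
  up <- ch[cfg$depth + 1L]
  for (s in rev(seq_len(cfg$depth))) {
    plan[[paste0("dec", s)]] <- c(up + ch[s], ch[s])
    up <- ch[s]
  }
  plan
}

he_conv <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

#' Build a U-Net with reproducible initialization
#'
#' Convolution weights use He-normal initialization, biases start at zero,
#' batch-norm scale/shift at 1/0. The same `seed` always yields
#' bit-identical initial parameters.
#'
#' @param config A [unet_config()].
#' @param seed Integer seed governing initialization.
#' @return Object of class `unet_model`: `params` (ordered named list of
#'   arrays), `state` (batch-norm running statistics), `config`.
#' @export
build_unet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  set.seed(seed)
  params <- list()
  state <- list()
  for (nm in names(unet_plan(config))) {
    io <- unet_plan(config)[[nm]]
    cin <- io[1]; cout <- io[2]
    params[[paste0(nm, ".conv1.w")]] <- he_conv(3L, cin, cout)
    params[[paste0(nm, ".conv1.b")]] <- numeric(cout)
    params[[paste0(nm, ".bn1.g")]] <- rep(1, cout)
    params[[paste0(nm, ".bn1.b")]] <- numeric(cout)
    params[[paste0(nm, ".conv2.w")]] <- he_conv(3L, cout, cout)
    params[[paste0(nm, ".conv2.b")]] <- numeric(cout)
    params[[paste0(nm, ".bn2.g")]] <- rep(1, cout)
    params[[paste0(nm, ".bn2.b")]] <- numeric(cout)
    state[[paste0(nm, ".bn1")]] <- list(mean = numeric(cout), var = rep(1, cout))
    state[[paste0(nm, ".bn2")]] <- list(mean = numeric(cout), var = rep(1, cout))
  }
  params[["out.w"]] <- he_conv(1L, config$base_channels, 1L)
  params[["out.b"]] <- numeric(1L)
  structure(list(params = params, state = state, config = config),
            class = "unet_model")
}

#' Number of trainable parameters
#' @param model A [build_unet()] model.
#' @return Integer count.
#' @export
n_params <- function(model) length(flatten_params(model$params))

#' Flatten / restore a parameter list
#'
#' The optimizer and the meta-gradient operate on a flat double vector;
#' these two helpers map between that vector and the named array list.
#'
#' @param params Named list of numeric arrays.
#' @return `flatten_params`: numeric vector.
#' @export
flatten_params <- function(params) unlist(params, use.names = FALSE)

#' @rdname flatten_params
#' @param theta Flat numeric vector from [flatten_params()].
#' @param template Parameter list providing names and dims.
#' @export
unflatten_params <- function(theta, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    v <- theta[(pos + 1L):(pos + n)]
    dim(v) <- dim(template[[nm]])
    out[[nm]] <- v
    pos <- pos + n
  }
  stopifnot(pos == length(theta))
  out
}

# ---- layer primitives (R side) ----

bn_fwd <- function(x, g, b, run, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    st <- bn_stats_cpp(x)
    mu <- st$mean
    v <- st$var
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * v
  } else {
    mu <- run$mean
    v <- run$var
  }
  ap <- bn_apply_cpp(x, g, b, mu, v, eps)
  list(y = ap$y,
       cache = list(xhat = ap$xhat, ivar = ap$ivar, g = g, train = train),
       run = run)
}

bn_bwd <- function(cache, gy) {
  bn_bwd_cpp(cache$xhat, cache$ivar, cache$g, gy, cache$train)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  y
}

block_fwd <- function(params, prefix, x, state, train) {
  c1 <- conv2d_fwd(x, params[[paste0(prefix, ".conv1.w")]],
                   params[[paste0(prefix, ".conv1.b")]])
  b1 <- bn_fwd(c1, params[[paste0(prefix, ".bn1.g")]],
               params[[paste0(prefix, ".bn1.b")]],
               state[[paste0(prefix, ".bn1")]], train)
  state[[paste0(prefix, ".bn1")]] <- b1$run
  r1 <- pmax(b1$y, 0)
  c2 <- conv2d_fwd(r1, params[[paste0(prefix, ".conv2.w")]],
                   params[[paste0(prefix, ".conv2.b")]])
  b2 <- bn_fwd(c2, params[[paste0(prefix, ".bn2.g")]],
               params[[paste0(prefix, ".bn2.b")]],
               state[[paste0(prefix, ".bn2")]], train)
  state[[paste0(prefix, ".bn2")]] <- b2$run
  r2 <- pmax(b2$y, 0)
  list(y = r2, state = state,
       cache = list(x = x, bn1 = b1$cache, m1 = b1$y > 0, r1 = r1,
                    bn2 = b2$cache, m2 = b2$y > 0))
}

block_bwd <- function(params, prefix, cache, gy, grads) {
  gy <- gy * cache$m2
  bb2 <- bn_bwd(cache$bn2, gy)
  grads[[paste0(prefix, ".bn2.g")]] <- bb2$gg
  grads[[paste0(prefix, ".bn2.b")]] <- bb2$gb
  cb2 <- conv2d_bwd(cache$r1, params[[paste0(prefix, ".conv2.w")]], bb2$gx)
  grads[[paste0(prefix, ".conv2.w")]] <- cb2$gw
  grads[[paste0(prefix, ".conv2.b")]] <- cb2$gb
  g1 <- cb2$gx * cache$m1
  bb1 <- bn_bwd(cache$bn1, g1)
  grads[[paste0(prefix, ".bn1.g")]] <- bb1$gg
  grads[[paste0(prefix, ".bn1.b")]] <- bb1$gb
  cb1 <- conv2d_bwd(cache$x, params[[paste0(prefix, ".conv1.w")]], bb1$gx)
  grads[[paste0(prefix, ".conv1.w")]] <- cb1$gw
  grads[[paste0(prefix, ".conv1.b")]] <- cb1$gb
  list(gx = cb1$gx, grads = grads)
}

# ---- full network ----

unet_forward <- function(params, x, state, config, train = FALSE) {
  d <- dim(x)
  if (is.null(d) || length(d) != 4L) stop("unet_forward: input must be (H,W,C,N)")
  if (d[1] %% 2L^config$depth != 0L || d[2] %% 2L^config$depth != 0L) {
    stop("unet_forward: spatial size must be divisible by 2^depth")
  }
  if (d[3] != config$in_channels) stop("unet_forward: wrong channel count")
  cache <- list(enc = vector("list", config$depth),
                pool = vector("list", config$depth),
                dec = vector("list", config$depth))
  h <- x
  skips <- vector("list", config$depth)
  for (s in seq_len(config$depth)) {
    bf <- block_fwd(params, paste0("enc", s), h, state, train)
    state <- bf$state
    cache$enc[[s]] <- bf$cache
    skips[[s]] <- bf$y
    mp <- maxpool2_fwd(bf$y)
    cache$pool[[s]] <- list(idx = mp$idx, xdim = dim(bf$y))
    h <- mp$y
  }
  bf <- block_fwd(params, "bot", h, state, train)
  state <- bf$state
  cache$bot <- bf$cache
  h <- bf$y
  for (s in rev(seq_len(config$depth))) {
    up <- upsample2_fwd(h)
    cat_in <- concat_ch(up, skips[[s]])
    bf <- block_fwd(params, paste0("dec", s), cat_in, state, train)
    state <- bf$state
    cache$dec[[s]] <- list(block = bf$cache, updim = dim(h),
                           nch_up = dim(up)[3], nch_skip = dim(skips[[s]])[3])
    h <- bf$y
  }
  logits <- conv2d_fwd(h, params[["out.w"]], params[["out.b"]])
  prob <- 1 / (1 + exp(-logits))
  cache$last <- h
  cache$prob <- prob
  list(prob = prob, cache = cache, state = state)
}

unet_backward <- function(params, cache, dlogits, config) {
  grads <- list()
  cb <- conv2d_bwd(cache$last, params[["out.w"]], dlogits)
  grads[["out.w"]] <- cb$gw
  grads[["out.b"]] <- cb$gb
  gy <- cb$gx
  gskip <- vector("list", config$depth)
  for (s in seq_len(config$depth)) {
    dc <- cache$dec[[s]]
    bb <- block_bwd(params, paste0("dec", s), dc$block, gy, grads)
    grads <- bb$grads
    gcat <- bb$gx
    gup <- gcat[, , seq_len(dc$nch_up), , drop = FALSE]
    gskip[[s]] <- gcat[, , dc$nch_up + seq_len(dc$nch_skip), , drop = FALSE]
    gy <- upsample2_bwd(gup, dc$updim)
  }
  bb <- block_bwd(params, "bot", cache$bot, gy, grads)
  grads <- bb$grads
  gy <- bb$gx
  for (s in rev(seq_len(config$depth))) {
    gpool <- maxpool2_bwd(cache$pool[[s]]$idx, gy, cache$pool[[s]]$xdim)
    gpool <- gpool + gskip[[s]]
    bb <- block_bwd(params, paste0("enc", s), cache$enc[[s]], gpool, grads)
    grads <- bb$grads
    gy <- bb$gx
  }
  grads
}

#' Forward pass producing per-pixel probabilities
#'
#' Runs the network in evaluation mode (batch norm uses running statistics,
#' so each sample's output is independent of the rest of the batch).
#'
#' @param model A [build_unet()] model.
#' @param x Input batch: `(H, W, C, N)` array, or a single `H x W` matrix.
#' @return `(H, W, 1, N)` array of probabilities in `[0, 1]`.
#' @export
predict_unet <- function(model, x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  unet_forward(model$params, x, model$state, model$config, train = FALSE)$prob
}

# Mean per-sample soft-Dice loss over a batch, with gradient w.r.t. a flat
# parameter vector. `task` carries the template/state; `update_state`
# controls whether batch-norm running stats advance (the mixed-batch pass
# of the meta objective does not advance them).
unet_loss_and_grad <- function(theta, batch, task, train = TRUE,
                               update_state = TRUE, want_grad = TRUE,
                               eps = 1e-6) {
  params <- unflatten_params(theta, task$template)
  fw <- unet_forward(params, batch$x, task$state_env$state, task$config,
                     train = train)
  if (train && update_state) task$state_env$state <- fw$state
  d <- dim(fw$prob)
  nb <- d[4]
  loss <- 0
  dprob <- array(0, dim = d)
  for (n in seq_len(nb)) {
    p <- fw$prob[, , 1L, n]
    g <- batch$y[, , 1L, n]
    loss <- loss + dice_loss(p, g, eps = eps) / nb
    if (want_grad) dprob[, , 1L, n] <- dice_loss_grad(p, g, eps = eps) / nb
  }
  if (!want_grad) return(list(loss = loss))
  dlogits <- dprob * fw$prob * (1 - fw$prob)
  grads <- unet_backward(params, fw$cache, dlogits, task$config)
  list(loss = loss, grad = flatten_params(grads[names(task$template)]))
}

#' Wrap a U-Net model as a trainable task
#'
#' Produces the loss-and-gradient interface consumed by the meta-learning
#' trainer: a list with `loss_and_grad(theta, batch, ...)`, the flat initial
#' parameter vector `theta0`, and a mutable environment holding batch-norm
#' running statistics.
#'
#' @param model A [build_unet()] model.
#' @return Object of class `unet_task`.
#' @export
unet_task <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  env <- new.env(parent = emptyenv())
  env$state <- model$state
  task <- list(template = model$params, config = model$config, state_env = env)
  task$loss_and_grad <- function(theta, batch, train = TRUE,
                                 update_state = TRUE, want_grad = TRUE) {
    unet_loss_and_grad(theta, batch, task, train = train,
                       update_state = update_state, want_grad = want_grad)
  }
  task$theta0 <- flatten_params(model$params)
  class(task) <- "unet_task"
  task
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the parameters, batch-norm running statistics and the
#' architecture config, so a loaded checkpoint is immediately usable with
#' [predict_unet()].
#'
#' @param model A [build_unet()] model (possibly trained).
#' @param path File path.
#' @return `load_checkpoint` returns the restored `unet_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "unet_model"))
  m
}
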