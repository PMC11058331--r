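# Deterministic sub-seed derivation (all derived seeds stay below 2^31).
derive_seed <- function(seed, salt) {
  as.integer((as.double(seed) %% 65536 * 30269 + as.double(salt) * 1013 + 7) %%
               2147483629)
}

#' Training configuration
#'
#' All hyperparameters of the two-task meta-learning objective
#' `L = alpha * L_init + beta * L_mix` and its SGD optimizer.
#'
#' Defaults follow the published training recipe where one is stated
#' (momentum 0.9, weight decay 5e-4, batch size 4, 30 epochs, polynomial
#' LR decay) and the field's conventions where not (poly power 0.9, base
#' LR 0.01, `alpha = beta = 1`, inner LR `gamma` equal to the base LR,
#' first-order meta-gradient).
#'
#' @param alpha,beta Positive trade-off weights of the original-data and
#'   mixed-data loss terms. `beta = 0` is the plain-ERM limit.
#' @param inner_lr Inner-loop step size `gamma` of the one-step adaptation
#'   `theta_hat = theta - gamma * grad(L_init)`.
#' @param base_lr,poly_power Polynomial schedule
#'   `lr(t) = base_lr * (1 - t/T)^poly_power` over all optimizer steps.
#' @param momentum,weight_decay Outer SGD hyperparameters (the inner update
#'   is plain gradient descent).
#' @param batch_size Images per optimizer step.
#' @param epochs Training epochs.
#' @param seeds Integer vector; one full run per seed, results averaged.
#' @param second_order If `TRUE`, back-propagate through the inner update
#'   (Hessian-vector term); default is the first-order approximation.
#' @param lambda_range Range the mixing ratio is drawn from, per sample.
#' @param val_every Validation period in epochs (`NA` history entries in
#'   between).
#' @return Object of class `train_config`.
#' @export
train_config <- function(alpha = 1, beta = 1, inner_lr = 0.01,
                         base_lr = 0.01, poly_power = 0.9,
                         momentum = 0.9, weight_decay = 5e-4,
                         batch_size = 4L, epochs = 30L,
                         seeds = c(1L, 2L, 3L), second_order = FALSE,
                         lambda_range = c(0, 1), val_every = 1L) {
  stopifnot(alpha >= 0, beta >= 0, inner_lr >= 0, base_lr > 0,
            poly_power > 0, momentum >= 0, momentum < 1, weight_decay >= 0,
            batch_size >= 1, epochs >= 1, length(seeds) >= 1)
  structure(list(alpha = alpha, beta = beta, inner_lr = inner_lr,
                 base_lr = base_lr, poly_power = poly_power,
                 momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seeds = as.integer(seeds),
                 second_order = isTRUE(second_order),
                 lambda_range = lambda_range,
                 val_every = as.integer(val_every)),
            class = "train_config")
}

#' Polynomial learning-rate schedule
#'
#' `base_lr * (1 - step/total_steps)^power`: equals `base_lr` at step 0 and
#' decays to 0 at `total_steps`. Steps beyond the schedule are clamped to 0
#' with a warning.
#'
#' @param step Current optimizer step (0-based).
#' @param total_steps Total scheduled steps.
#' @param base_lr Initial learning rate.
#' @param power Decay exponent.
#' @return Learning rate.
#' @export
poly_lr <- function(step, total_steps, base_lr, power = 0.9) {
  stopifnot(step >= 0, total_steps >= 1)
  if (step > total_steps) {
    warning("poly_lr: step beyond schedule, clamping learning rate to 0")
    return(0)
  }
  base_lr * (1 - step / total_steps)^power
}

#' One-step inner adaptation
#'
#' `theta_hat = theta - gamma * grad(L(theta))` on a batch of original
#' (unmixed) data. `theta` itself is not modified.
#'
#' @param task A task object exposing `loss_and_grad(theta, batch, ...)`
#'   (see [unet_task()] and [quadratic_task()]).
#' @param theta Flat parameter vector.
#' @param batch Original-data batch in the task's format.
#' @param gamma Inner step size, `>= 0`.
#' @return List with `theta_hat`, `loss` (the loss at `theta`) and `grad`.
#' @export
inner_update <- function(task, theta, batch, gamma) {
  stopifnot(gamma >= 0)
  g <- task$loss_and_grad(theta, batch, update_state = FALSE)
  if (!all(is.finite(g$grad)) || !is.finite(g$loss)) {
    stop("inner_update: non-finite loss or gradient (training divergence)")
  }
  list(theta_hat = theta - gamma * g$grad, loss = g$loss, grad = g$grad)
}

# Hessian-vector product H(theta) v by central differences of the analytic
# gradient; exact for quadratics, O(h^2) otherwise.
hvp_fd <- function(task, theta, batch, v, eps_scale = 1e-3) {
  vn <- sqrt(sum(v^2))
  if (vn == 0) return(v)
  h <- eps_scale * (1 + sqrt(sum(theta^2))) / vn
  gp <- task$loss_and_grad(theta + h * v, batch, update_state = FALSE)$grad
  gm <- task$loss_and_grad(theta - h * v, batch, update_state = FALSE)$grad
  (gp - gm) / (2 * h)
}

#' Two-task meta objective
#'
#' `L = alpha * L_init(theta) + beta * L_mix(theta_hat)` where `theta_hat`
#' is the one-step [inner_update()] on the original batch and `L_mix` is
#' evaluated on the amplitude-mixed batch. No state is mutated.
#'
#' @inheritParams inner_update
#' @param orig_batch,mixed_batch Batches of original and mixed samples.
#' @param config A [train_config()] (uses `alpha`, `beta`, `inner_lr`).
#' @return List `loss`, `l_init`, `l_mix`, `theta_hat`.
#' @export
meta_objective <- function(task, theta, orig_batch, mixed_batch, config) {
  iu <- inner_update(task, theta, orig_batch, config$inner_lr)
  lm <- task$loss_and_grad(iu$theta_hat, mixed_batch, update_state = FALSE,
                           want_grad = FALSE)
  list(loss = config$alpha * iu$loss + config$beta * lm$loss,
       l_init = iu$loss, l_mix = lm$loss, theta_hat = iu$theta_hat)
}

#' Meta-gradient of the two-task objective
#'
#' First-order mode treats `theta_hat` as constant, giving
#' `alpha * g_init(theta) + beta * g_mix(theta_hat)`. Second-order mode adds
#' the chain-rule term through the inner update,
#' `beta * (-gamma) * H_init(theta) g_mix(theta_hat)`, with the
#' Hessian-vector product evaluated by central differences of the analytic
#' gradient.
#'
#' @inheritParams meta_objective
#' @param update_state If `TRUE`, the original-batch forward pass advances
#'   the task's internal state (batch-norm running statistics); the mixed
#'   pass never does.
#' @return List `grad`, `loss`, `l_init`, `l_mix`.
#' @export
meta_grad <- function(task, theta, orig_batch, mixed_batch, config,
                      update_state = FALSE) {
  gi <- task$loss_and_grad(theta, orig_batch, update_state = update_state)
  if (!all(is.finite(gi$grad))) {
    stop("meta_grad: non-finite gradient on original batch")
  }
  if (config$beta == 0) {
    return(list(grad = config$alpha * gi$grad,
                loss = config$alpha * gi$loss,
                l_init = gi$loss, l_mix = NA_real_))
  }
  theta_hat <- theta - config$inner_lr * gi$grad
  gm <- task$loss_and_grad(theta_hat, mixed_batch, update_state = FALSE)
  g_mix <- gm$grad
  if (config$second_order) {
    hv <- hvp_fd(task, theta, orig_batch, g_mix)
    g_mix <- g_mix - config$inner_lr * hv
  }
  list(grad = config$alpha * gi$grad + config$beta * g_mix,
       loss = config$alpha * gi$loss + config$beta * gm$loss,
       l_init = gi$loss, l_mix = gm$loss)
}

# PyTorch-convention SGD with momentum and (coupled) weight decay.
sgd_step <- function(theta, grad, vel, lr, momentum, weight_decay) {
  g <- grad + weight_decay * theta
  vel <- momentum * vel + g
  list(theta = theta - lr * vel, vel = vel)
}

#' Scalar quadratic toy task
#'
#' `L(theta) = (theta - target)^2` with analytic gradient — the oracle used
#' to validate the meta-gradient in both first- and second-order modes
#' against closed forms.
#'
#' @param theta0 Initial parameter.
#' @return A task object; batches are lists with a `target` element.
#' @export
quadratic_task <- function(theta0 = 1) {
  list(
    theta0 = theta0,
    loss_and_grad = function(theta, batch, train = TRUE, update_state = TRUE,
                             want_grad = TRUE) {
      l <- sum((theta - batch$target)^2)
      if (!want_grad) return(list(loss = l))
      list(loss = l, grad = 2 * (theta - batch$target))
    }
  )
}

# stack modality/mixed items into (H,W,1,B) image and mask arrays
items_to_batch <- function(items) {
  imgs <- lapply(items, function(it) if (inherits(it, "mixed_sample")) it$image else it$pixels)
  masks <- lapply(items, function(it) it$mask)
  h <- nrow(imgs[[1]]); w <- ncol(imgs[[1]]); b <- length(imgs)
  list(x = array(unlist(imgs, use.names = FALSE), dim = c(h, w, 1L, b)),
       y = array(unlist(masks, use.names = FALSE), dim = c(h, w, 1L, b)))
}

run_one_seed <- function(train_images, config, model_config, seed,
                         val_images = NULL, erm = FALSE, verbose = FALSE) {
  model <- build_unet(model_config, seed)
  task <- unet_task(model)
  theta <- task$theta0
  vel <- numeric(length(theta))
  mix_on <- !erm && config$beta > 0
  streams <- make_streams(train_images, seed = seed,
                          lambda_range = config$lambda_range, mix = mix_on)
  if (streams$n == 0L) stop("run_one_seed: empty training dataset")
  steps_per_epoch <- ceiling(streams$n / config$batch_size)
  total_steps <- config$epochs * steps_per_epoch
  step <- 0L
  step_lr <- numeric(total_steps)
  hist <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ep <- streams$epoch(epoch)
    li <- lm <- lt <- numeric(steps_per_epoch)
    lr0 <- NA_real_
    for (bi in seq_len(steps_per_epoch)) {
      sel <- ((bi - 1L) * config$batch_size + 1L):min(bi * config$batch_size, streams$n)
      lr <- poly_lr(step, total_steps, config$base_lr, config$poly_power)
      if (bi == 1L) lr0 <- lr
      orig <- items_to_batch(ep$original[sel])
      if (erm) {
        g <- task$loss_and_grad(theta, orig, update_state = TRUE)
        if (!all(is.finite(g$grad))) {
          stop(sprintf("training divergence at epoch %d step %d", epoch, bi))
        }
        li[bi] <- g$loss; lm[bi] <- NA_real_; lt[bi] <- g$loss
        grad <- g$grad
      } else {
        mixed <- NULL
        if (mix_on) {
          mitems <- Filter(Negate(is.null), ep$mixed[sel])
          if (length(mitems)) mixed <- items_to_batch(mitems)
        }
        mg <- meta_grad(task, theta, orig,
                        if (is.null(mixed)) orig else mixed,
                        config, update_state = TRUE)
        if (!all(is.finite(mg$grad))) {
          stop(sprintf("training divergence at epoch %d step %d", epoch, bi))
        }
        li[bi] <- mg$l_init; lm[bi] <- mg$l_mix; lt[bi] <- mg$loss
        grad <- mg$grad
      }
      up <- sgd_step(theta, grad, vel, lr, config$momentum, config$weight_decay)
      theta <- up$theta; vel <- up$vel
      step <- step + 1L
      step_lr[step] <- lr
    }
    val_dice <- NA_real_
    if (!is.null(val_images) && (epoch %% config$val_every == 0L ||
                                 epoch == config$epochs)) {
      model$params <- unflatten_params(theta, task$template)
      model$state <- task$state_env$state
      val_dice <- evaluate_model(model, val_images)$dice_mean
    }
    hist[[epoch]] <- data.frame(
      epoch = epoch, l_init = mean(li), l_mix = mean(lm), loss = mean(lt),
      lr = lr0, val_dice = val_dice)
    if (verbose) {
      message(sprintf("[seed %d] epoch %3d  L_init %.4f  L_mix %s  val %s",
                      seed, epoch, mean(li),
                      ifelse(is.na(mean(lm)), "--", sprintf("%.4f", mean(lm))),
                      ifelse(is.na(val_dice), "--", sprintf("%.4f", val_dice))))
    }
  }
  model$params <- unflatten_params(theta, task$template)
  model$state <- task$state_env$state
  list(model = model, history = do.call(rbind, hist), step_lr = step_lr,
       seed = seed, total_steps = total_steps)
}

#' Train the meta-learning segmentation model
#'
#' Runs one full training per seed: each optimizer step takes a batch from
#' the original stream, builds its amplitude-mixed counterpart on the fly,
#' computes the meta-gradient of `alpha * L_init + beta * L_mix` and applies
#' SGD with momentum, weight decay and the polynomial schedule. With
#' `beta = 0` the mixed stream is skipped entirely and training reduces to
#' plain Dice-loss ERM.
#'
#' @param train_images List of [modality_image()] objects (the training
#'   split).
#' @param config A [train_config()].
#' @param model_config A [unet_config()].
#' @param val_images Optional validation images for per-epoch Dice.
#' @param verbose Print per-epoch progress.
#' @return Object of class `train_result`: per-seed `runs` (each with
#'   `model`, `history`, `step_lr`), the configs, and `val_dice_mean`
#'   averaged over seeds (if validation data was given).
#' @export
train_mfnet <- function(train_images, config = train_config(),
                        model_config = unet_config(), val_images = NULL,
                        verbose = FALSE) {
  if (!length(train_images)) stop("train_mfnet: empty dataset")
  runs <- lapply(config$seeds, function(s) {
    run_one_seed(train_images, config, model_config, s,
                 val_images = val_images, erm = FALSE, verbose = verbose)
  })
  vd <- vapply(runs, function(r) r$history$val_dice[config$epochs], numeric(1))
  structure(list(runs = runs, config = config, model_config = model_config,
                 val_dice_mean = if (is.null(val_images)) NA_real_ else mean(vd)),
            class = "train_result")
}

#' Plain ERM baseline trainer
#'
#' Independent implementation of standard Dice-loss training (no mixing,
#' no inner update) with the same data order, initialization and optimizer
#' as [train_mfnet()]. Serves as the comparison baseline and as the oracle
#' for the `beta = 0` reduction of the meta objective.
#'
#' @inheritParams train_mfnet
#' @return A `train_result` (the `l_mix` history column is `NA`).
#' @export
train_erm <- function(train_images, config = train_config(beta = 0),
                      model_config = unet_config(), val_images = NULL,
                      verbose = FALSE) {
  if (!length(train_images)) stop("train_erm: empty dataset")
  runs <- lapply(config$seeds, function(s) {
    run_one_seed(train_images, config, model_config, s,
                 val_images = val_images, erm = TRUE, verbose = verbose)
  })
  vd <- vapply(runs, function(r) r$history$val_dice[config$epochs], numeric(1))
  structure(list(runs = runs, config = config, model_config = model_config,
                 val_dice_mean = if (is.null(val_images)) NA_real_ else mean(vd)),
            class = "train_result")
}

#' Evaluate a model on a set of slices
#'
#' Eval-mode forward pass, binarization at `threshold`, per-image Dice and
#' IoU, aggregated with [aggregate_metrics()].
#'
#' @param model A `unet_model`.
#' @param images List of [modality_image()] objects.
#' @param threshold Probability binarization threshold.
#' @param chunk Images per forward pass (eval mode is per-sample
#'   independent; batching only affects speed).
#' @return A `metrics_report`.
#' @export
evaluate_model <- function(model, images, threshold = 0.5, chunk = 8L) {
  if (!length(images)) stop("evaluate_model: empty image list")
  rows <- vector("list", length(images))
  idx <- split(seq_along(images), ceiling(seq_along(images) / chunk))
  for (grp in idx) {
    b <- items_to_batch(images[grp])
    prob <- unet_forward(model$params, b$x, model$state, model$config,
                         train = FALSE)$prob
    for (j in seq_along(grp)) {
      pm <- (prob[, , 1L, j] >= threshold) * 1
      gm <- b$y[, , 1L, j]
      it <- images[[grp[j]]]
      rows[[grp[j]]] <- data.frame(
        case_id = it$case_id, modality_id = it$modality_id,
        dice = dice_coefficient(pm, gm), iou = iou(pm, gm))
    }
  }
  aggregate_metrics(do.call(rbind, rows))
}

#' Evaluate every seed of a training result
#'
#' @param result A [train_mfnet()] / [train_erm()] result.
#' @param images Evaluation images.
#' @param threshold Binarization threshold.
#' @return List with per-seed `reports`, `dice_mean` and `miou` averaged
#'   over seeds.
#' @export
evaluate_runs <- function(result, images, threshold = 0.5) {
  reports <- lapply(result$runs, function(r) {
    evaluate_model(r$model, images, threshold = threshold)
  })
  list(reports = reports,
       dice_mean = mean(vapply(reports, `[[`, numeric(1), "dice_mean")),
       miou = mean(vapply(reports, `[[`, numeric(1), "miou")),
       dice_by_seed = vapply(reports, `[[`, numeric(1), "dice_mean"))
}
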