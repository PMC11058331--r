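toy_batches <- function() list(orig = list(target = 0), mixed = list(target = 0))

test_that("poly_lr follows the schedule and clamps past the end", {
  expect_equal(poly_lr(0, 100, 0.01, 0.9), 0.01)
  expect_equal(poly_lr(100, 100, 0.01, 0.9), 0)
  expect_equal(poly_lr(50, 100, 0.01, 0.9), 0.01 * 0.5^0.9)
  expect_warning(lr <- poly_lr(101, 100, 0.01, 0.9), "clamping")
  expect_equal(lr, 0)
})

test_that("inner_update applies one plain gradient step", {
  qt <- quadratic_task()
  b <- list(target = 0)
  expect_equal(inner_update(qt, 1, b, 0)$theta_hat, 1)           # zero step
  expect_equal(inner_update(qt, 1, b, 0.1)$theta_hat, 0.8)       # 1 - 0.1*2*1
  # step length is linear in gamma
  d1 <- abs(inner_update(qt, 1, b, 0.05)$theta_hat - 1)
  d2 <- abs(inner_update(qt, 1, b, 0.10)$theta_hat - 1)
  expect_equal(d2, 2 * d1)
})

test_that("meta objective and gradients match the scalar closed forms", {
  qt <- quadratic_task()
  tb <- toy_batches()
  cfg1 <- train_config(alpha = 1, beta = 1, inner_lr = 0.1)
  mo <- meta_objective(qt, 1, tb$orig, tb$mixed, cfg1)
  expect_equal(mo$loss, 1.64, tolerance = 1e-9)     # 1^2 + 0.8^2
  expect_equal(mo$l_init, 1)
  expect_equal(mo$l_mix, 0.64, tolerance = 1e-9)
  expect_equal(mo$theta_hat, 0.8)

  g1 <- meta_grad(qt, 1, tb$orig, tb$mixed, cfg1)
  expect_equal(g1$grad, 3.6, tolerance = 1e-6)      # 2*theta + 2*theta_hat

  cfg2 <- train_config(alpha = 1, beta = 1, inner_lr = 0.1, second_order = TRUE)
  g2 <- meta_grad(qt, 1, tb$orig, tb$mixed, cfg2)
  expect_equal(g2$grad, 3.28, tolerance = 1e-6)     # 2*theta + 2*theta_hat*(1-2*gamma)

  # independent check: central finite differences of the full objective
  h <- 1e-5
  fd <- (meta_objective(qt, 1 + h, tb$orig, tb$mixed, cfg1)$loss -
         meta_objective(qt, 1 - h, tb$orig, tb$mixed, cfg1)$loss) / (2 * h)
  expect_equal(fd, 3.28, tolerance = 1e-5)

  # ERM limit: alpha=1, beta=0 reduces to the plain loss and gradient
  cfg0 <- train_config(alpha = 1, beta = 0, inner_lr = 0.1)
  g0 <- meta_grad(qt, 1, tb$orig, tb$mixed, cfg0)
  expect_equal(g0$loss, 1)
  expect_equal(g0$grad, 2)
  expect_true(is.na(g0$l_mix))
})

test_that("one SGD step on the toy moves theta by lr * meta-gradient", {
  qt <- quadratic_task()
  tb <- toy_batches()
  cfg <- train_config(alpha = 1, beta = 1, inner_lr = 0.1, momentum = 0,
                      weight_decay = 0)
  mg <- meta_grad(qt, 1, tb$orig, tb$mixed, cfg)
  up <- mfnet:::sgd_step(1, mg$grad, 0, lr = 0.01, momentum = 0,
                         weight_decay = 0)
  expect_equal(up$theta, 1 - 0.01 * 3.6, tolerance = 1e-9)
})

test_that("beta = 0 meta-training is bit-identical to the plain ERM loop", {
  imgs <- phantom_images(4, "A", seed = 51, size = 32)
  mc <- unet_config(base_channels = 4, depth = 2)
  cfg <- train_config(alpha = 1, beta = 0, epochs = 2, seeds = 1L,
                      batch_size = 4)
  a <- train_mfnet(imgs, cfg, mc)
  b <- train_erm(imgs, cfg, mc)
  expect_identical(a$runs[[1]]$history$l_init, b$runs[[1]]$history$l_init)
  expect_identical(a$runs[[1]]$history$loss, b$runs[[1]]$history$loss)
  expect_identical(flatten_params(a$runs[[1]]$model$params),
                   flatten_params(b$runs[[1]]$model$params))
})

test_that("training is reproducible and records the exact LR schedule", {
  imgs <- phantom_images(4, "A", seed = 51, size = 32)
  mc <- unet_config(base_channels = 4, depth = 2)
  cfg <- train_config(epochs = 2, seeds = 1L, batch_size = 4)
  r1 <- train_mfnet(imgs, cfg, mc)
  r2 <- train_mfnet(imgs, cfg, mc)
  expect_identical(flatten_params(r1$runs[[1]]$model$params),
                   flatten_params(r2$runs[[1]]$model$params))
  expect_identical(r1$runs[[1]]$history, r2$runs[[1]]$history)
  run <- r1$runs[[1]]
  expected_lr <- vapply(seq_along(run$step_lr) - 1L, function(t) {
    poly_lr(t, run$total_steps, cfg$base_lr, cfg$poly_power)
  }, numeric(1))
  expect_identical(run$step_lr, expected_lr)
})

test_that("bookkeeping: steps, seeds and averaged validation", {
  imgs <- phantom_images(4, "A", seed = 51, size = 32)[1:4]  # 4 slices
  mc <- unet_config(base_channels = 4, depth = 2)
  cfg <- train_config(epochs = 1, seeds = 1L, batch_size = 4)
  # the 4-slice subset leaves one case with a single modality; the resulting
  # "no donor" warning is expected behaviour (tested in test-data-io.R)
  r <- suppressWarnings(train_mfnet(imgs, cfg, mc))
  expect_equal(r$runs[[1]]$total_steps, 1L)
  expect_equal(length(r$runs[[1]]$step_lr), 1L)
  expect_equal(nrow(r$runs[[1]]$history), 1L)

  cfg3 <- train_config(epochs = 1, seeds = c(1L, 2L, 3L), batch_size = 4)
  val <- phantom_images(2, "A", seed = 77, size = 32)
  r3 <- suppressWarnings(train_mfnet(imgs, cfg3, mc, val_images = val))
  expect_equal(length(r3$runs), 3L)
  per_seed <- vapply(r3$runs, function(x) x$history$val_dice[1], numeric(1))
  expect_equal(r3$val_dice_mean, mean(per_seed))
})

test_that("loss decreases over a short phantom run on most seeds", {
  imgs <- phantom_images(8, "A", seed = 61, size = 32)
  mc <- unet_config(base_channels = 4, depth = 2)
  cfg <- train_config(epochs = 8, seeds = c(1L, 2L, 3L), batch_size = 4)
  r <- train_mfnet(imgs, cfg, mc)
  improved <- vapply(r$runs, function(run) {
    run$history$l_init[cfg$epochs] < run$history$l_init[1]
  }, logical(1))
  expect_gte(sum(improved), 2L)
})

test_that("train_config validates its fields", {
  expect_error(train_config(base_lr = 0))
  expect_error(train_config(momentum = 1))
  expect_error(train_config(epochs = 0))
  expect_error(train_config(seeds = integer(0)))
  expect_error(train_mfnet(list(), train_config()), "empty")
})
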