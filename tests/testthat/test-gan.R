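# Tiny architecture used throughout: 24 px images (the smallest the patch
# discriminator supports), narrow nets. Keeps each pass in the millisecond
# range.
tiny_gan_config <- function(...) {
  gan_config("test", image_size = 24L, ngf = 8L, ndf = 8L, unet_base = 4L,
             n_res = 3L, ...)
}

rand_img <- function(n = 24L) array(stats::runif(n * n * 3), c(n, n, 3))
rand_hm <- function(n = 24L) matrix(stats::runif(n * n), n, n)

test_that("heatmap BCE matches its closed forms", {
  p <- matrix(0.5, 8, 8)
  expect_equal(heatmap_bce(p, matrix(0, 8, 8)), log(2), tolerance = 1e-12)
  expect_equal(heatmap_bce(p, matrix(1, 8, 8)), log(2), tolerance = 1e-12)
  # soft targets: -(0.5 log 0.5 + 0.5 log 0.5) = log 2 as well
  expect_equal(heatmap_bce(p, matrix(0.5, 8, 8)), log(2), tolerance = 1e-12)
  expect_equal(log(2), 0.69315, tolerance = 1e-5)

  # over constant predictions, BCE is minimised at pred = target
  for (t in c(0.2, 0.5, 0.73)) {
    tgt <- matrix(t, 4, 4)
    grid_vals <- seq(0.01, 0.99, by = 0.01)
    losses <- vapply(grid_vals, function(pv)
      heatmap_bce(matrix(pv, 4, 4), tgt), numeric(1))
    expect_equal(grid_vals[which.min(losses)], t, tolerance = 0.011)
  }
  expect_error(heatmap_bce(matrix(0.5, 2, 2), matrix(0.5, 3, 3)), "shape")
})

test_that("cycle loss is mean absolute error", {
  x <- array(stats::runif(48), c(4, 4, 3))
  expect_equal(cycle_loss(x, x), 0)
  expect_equal(cycle_loss(x, x + 0.5), 0.5, tolerance = 1e-12)
  y <- array(stats::runif(48), c(4, 4, 3))
  # elementwise oracle
  expect_equal(cycle_loss(x, y), sum(abs(x - y)) / length(x),
               tolerance = 1e-6)
  expect_error(cycle_loss(x, array(0, c(4, 4, 2))), "shape")
})

test_that("least-squares adversarial losses match hand values", {
  adv <- adversarial_losses(matrix(1, 3, 3), matrix(0, 3, 3))
  expect_equal(adv$d_term, 0)
  expect_equal(adv$g_term, 1)
  expect_equal(adversarial_losses(matrix(1, 3, 3), matrix(1, 3, 3))$g_term, 0)
  expect_equal(adversarial_losses(matrix(0.5, 2, 2),
                                  matrix(0.5, 2, 2))$d_term, 0.25)
})

test_that("model construction honours the architecture contracts", {
  cfg <- tiny_gan_config(seed = 4L)
  m1 <- build_models(cfg)
  m2 <- build_models(cfg)
  ns <- asNamespace("wheatsyn")

  # lightweight contract: each support UNet under 1/4 of a generator
  expect_lt(ns$nn_param_count(m1$U_r), ns$nn_param_count(m1$G_s2r) / 4)

  # seeded determinism of initialisation
  expect_identical(ns$modelset_state(m1), ns$modelset_state(m2))

  # generator forward: shape preserved, range squashed to [-1, 1]
  x <- array(0, c(24, 24, 3))
  y <- ns$nn_fwd(m1$G_s2r, x)$y
  expect_equal(dim(y), c(24, 24, 3))
  expect_true(all(y >= -1 & y <= 1))

  # support net emits one channel squashed to (0, 1)
  p <- predict_heatmap(m1, rand_img(), "r")
  expect_equal(dim(p), c(24, 24))
  expect_true(all(p > 0 & p < 1))

  expect_error(gan_config("test", image_size = 30L), "divisible")
})

test_that("layer gradients agree with finite differences", {
  ns <- asNamespace("wheatsyn")
  set.seed(6)
  mod <- ns$nn_seq(ns$nn_conv(2L, 3L, 3L, stride = 2L), ns$nn_inorm(3L),
                   ns$nn_lrelu(), ns$nn_up2(), ns$nn_conv(3L, 2L, 3L),
                   ns$nn_tanh())
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  tgt <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  loss_now <- function() {
    y <- ns$nn_fwd(mod, x)$y
    0.5 * sum((y - tgt)^2)
  }
  out <- ns$nn_fwd(mod, x)
  ns$nn_zero_grad(mod)
  gx <- ns$nn_bwd(mod, out$cache, out$y - tgt)
  eps <- 1e-6
  for (i in sample(length(x), 4)) {
    x0 <- x[i]
    x[i] <- x0 + eps; lp <- loss_now()
    x[i] <- x0 - eps; lm <- loss_now()
    x[i] <- x0
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(gx[i] - fd), 1e-5 * max(1, abs(fd)))
  }
  for (p in ns$nn_params(mod)) {
    w <- get(p$par, envir = p$env)
    g <- get(p$grad, envir = p$env)
    i <- sample(length(w), 1)
    w0 <- w[i]
    w[i] <- w0 + eps; assign(p$par, w, envir = p$env); lp <- loss_now()
    w[i] <- w0 - eps; assign(p$par, w, envir = p$env); lm <- loss_now()
    w[i] <- w0; assign(p$par, w, envir = p$env)
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(g[i] - fd), 1e-5 * max(1, abs(fd)))
  }
})

test_that("the support-UNet BCE gradient is exact", {
  ns <- asNamespace("wheatsyn")
  set.seed(7)
  un <- ns$nn_unet(4L)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  tgt <- matrix(runif(64), 8, 8)
  fw <- ns$nn_fwd(un, x)
  p <- 1 / (1 + exp(-fw$y[, , 1]))
  ns$nn_zero_grad(un)
  gx <- ns$nn_bwd(un, fw$cache, array((p - tgt) / length(tgt), dim(fw$y)))
  bce_now <- function() {
    z <- ns$nn_fwd(un, x)$y[, , 1]
    heatmap_bce(1 / (1 + exp(-z)), tgt)
  }
  eps <- 1e-6
  for (i in sample(length(x), 4)) {
    x0 <- x[i]
    x[i] <- x0 + eps; lp <- bce_now()
    x[i] <- x0 - eps; lm <- bce_now()
    x[i] <- x0
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(gx[i] - fd), 1e-6 * max(1, abs(fd)))
  }
})

test_that("a training step is deterministic and reports a consistent total", {
  cfg <- tiny_gan_config(seed = 9L)
  set.seed(1)
  si <- rand_img(); ri <- rand_img(); sh <- rand_hm(); rh <- rand_hm()
  run_once <- function() {
    m <- build_models(cfg)
    opts <- make_optimizers(m)
    set.seed(2)
    train_step(train_batch(si, ri, sh, rh), m, opts)
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(r1, r2)

  expect_equal(r1$total_g,
               r1$adv_g_s2r + r1$adv_g_r2s +
                 cfg$lambda_cycle * (r1$cycle_s + r1$cycle_r) +
                 cfg$lambda_identity * r1$identity +
                 cfg$lambda_heatmap * (r1$heatmap_s + r1$heatmap_r),
               tolerance = 1e-12)
})

test_that("plain mode shares all non-heatmap computations at step 0", {
  set.seed(3)
  si <- rand_img(); ri <- rand_img(); sh <- rand_hm(); rh <- rand_hm()
  step0 <- function(lh) {
    cfg <- tiny_gan_config(seed = 11L, lambda_heatmap = lh)
    m <- build_models(cfg)
    opts <- make_optimizers(m)
    set.seed(4)
    train_step(train_batch(si, ri, sh, rh), m, opts)
  }
  plain <- step0(0)
  supported <- step0(1)
  for (comp in c("adv_g_s2r", "adv_g_r2s", "cycle_s", "cycle_r", "identity",
                 "heatmap_s", "heatmap_r"))
    expect_identical(plain[[comp]], supported[[comp]])
  # the heatmap terms are excluded from the plain total
  expect_equal(plain$total_g,
               supported$total_g - (supported$heatmap_s + supported$heatmap_r),
               tolerance = 1e-12)
})

test_that("training bookkeeping: zero epochs is a no-op, steps are counted", {
  ns <- asNamespace("wheatsyn")
  cfg <- tiny_gan_config(seed = 13L, epochs = 0L)
  set.seed(5)
  dom <- function(tag) {
    imgs <- list(rand_img(), rand_img())
    names(imgs) <- paste0(tag, 1:2)
    hms <- list(rand_hm(), rand_hm())
    names(hms) <- names(imgs)
    list(images = imgs, heatmaps = hms)
  }
  src <- dom("s"); tgt <- dom("t")
  res0 <- train_gan(src, tgt, cfg)
  expect_identical(ns$modelset_state(res0$models),
                   ns$modelset_state(build_models(cfg)))
  expect_equal(nrow(res0$history), 0)

  cfg2 <- tiny_gan_config(seed = 13L, epochs = 2L)
  res2 <- train_gan(src, tgt, cfg2)
  expect_equal(nrow(res2$history), 2 * 2)  # epochs * max(n_s, n_t)
  expect_true(all(is.finite(res2$history$total_g)))

  expect_error(train_gan(list(images = list(), heatmaps = list()), tgt, cfg2),
               "non-empty")
})

test_that("translation preserves count, size and determinism", {
  cfg <- tiny_gan_config(seed = 15L)
  m <- build_models(cfg)
  set.seed(6)
  imgs <- list(a = rand_img(), b = rand_img(), c = rand_img())
  out1 <- translate_images(m, imgs, "s2r")
  out2 <- translate_images(m, imgs, "s2r")
  expect_identical(names(out1), names(imgs))
  expect_identical(out1, out2)
  for (y in out1) {
    expect_equal(dim(y), c(24, 24, 3))
    expect_true(all(y >= 0 & y <= 1))
  }
  expect_error(translate_images(m, imgs, "sideways"))
})

test_that("checkpoints are self-describing and restore exactly", {
  ns <- asNamespace("wheatsyn")
  cfg <- tiny_gan_config(seed = 17L)
  m <- build_models(cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_modelset(m, path)
  m2 <- load_modelset(path)
  expect_identical(ns$modelset_state(m), ns$modelset_state(m2))
  expect_equal(m2$config$image_size, 24L)
})
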