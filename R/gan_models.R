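# Model set for the heatmap-supported unpaired translator: two generators
# (synthetic->real, real->synthetic), two patch discriminators, and two
# lightweight UNet heatmap-regression support networks that read each
# generator's output and are trained jointly with it.

#' Training configuration for the translation networks
#'
#' Two profiles bundle the standard settings: `"paper"` (400 px images, 100
#' epochs, 9 residual blocks, full-width networks — the published operating
#' point) and `"test"` (64 px, 2 epochs, narrow networks — a desk-scale
#' profile for CPU smoke runs). Any field can be overridden.
#'
#' @param profile `"paper"` or `"test"`.
#' @param image_size square image side in pixels; must be divisible by 4.
#' @param lr Adam learning rate (default 2e-4); each generator shares one
#'   optimiser and learning rate with its support UNet.
#' @param epochs training epochs.
#' @param batch_size pairs per optimiser step (the canonical unpaired recipe
#'   uses 1, the only supported value).
#' @param lambda_cycle,lambda_identity,lambda_heatmap loss weights; setting
#'   `lambda_heatmap = 0` gives the plain (unsupported) translator used as a
#'   baseline.
#' @param pool_size replay-pool capacity for discriminator updates.
#' @param seed RNG seed for initialisation and training order.
#' @param ngf,ndf,unet_base channel widths of generator, discriminator and
#'   UNet; defaults depend on the profile.
#' @param n_res residual blocks in the generator (9 at 400 px, 6 at <= 128).
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(profile = c("test", "paper"),
                       image_size = NULL, lr = 2e-4, epochs = NULL,
                       batch_size = 1L, lambda_cycle = 10,
                       lambda_identity = 5, lambda_heatmap = 1,
                       pool_size = 50L, seed = 1L,
                       ngf = NULL, ndf = NULL, unet_base = NULL,
                       n_res = NULL) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    image_size <- image_size %||% 400L
    epochs <- epochs %||% 100L
    ngf <- ngf %||% 32L
    ndf <- ndf %||% 64L
    unet_base <- unet_base %||% 16L
  } else {
    image_size <- image_size %||% 64L
    epochs <- epochs %||% 2L
    ngf <- ngf %||% 12L
    ndf <- ndf %||% 16L
    unet_base <- unet_base %||% 8L
  }
  n_res <- n_res %||% (if (image_size <= 128L) 6L else 9L)
  if (image_size %% 4L != 0L) stopf("image_size must be divisible by 4")
  if (image_size < 24L)
    stopf("image_size must be >= 24 (the patch discriminator has five conv levels)")
  if (lr <= 0) stopf("lr must be > 0")
  if (batch_size != 1L)
    stopf("only batch_size = 1 is supported (the canonical unpaired recipe)")
  if (lambda_cycle < 0 || lambda_identity < 0 || lambda_heatmap < 0)
    stopf("loss weights must be >= 0")
  structure(
    list(profile = profile, image_size = as.integer(image_size), lr = lr,
         epochs = as.integer(epochs), batch_size = 1L,
         lambda_cycle = lambda_cycle, lambda_identity = lambda_identity,
         lambda_heatmap = lambda_heatmap, pool_size = as.integer(pool_size),
         seed = as.integer(seed), ngf = as.integer(ngf),
         ndf = as.integer(ndf), unet_base = as.integer(unet_base),
         n_res = as.integer(n_res)),
    class = "gan_config")
}

# generator: 2-downsample conv encoder, n_res residual blocks, decoder with
# nearest-upsample convs, tanh output in [-1, 1]
make_generator <- function(ngf, n_res) {
  mods <- list(
    nn_conv(3L, ngf, 7L), nn_inorm(ngf), nn_relu(),
    nn_conv(ngf, 2L * ngf, 3L, stride = 2L), nn_inorm(2L * ngf), nn_relu(),
    nn_conv(2L * ngf, 4L * ngf, 3L, stride = 2L), nn_inorm(4L * ngf),
    nn_relu())
  for (i in seq_len(n_res)) mods <- c(mods, list(nn_res(4L * ngf)))
  mods <- c(mods, list(
    nn_up2(), nn_conv(4L * ngf, 2L * ngf, 3L), nn_inorm(2L * ngf), nn_relu(),
    nn_up2(), nn_conv(2L * ngf, ngf, 3L), nn_inorm(ngf), nn_relu(),
    nn_conv(ngf, 3L, 7L), nn_tanh()))
  nn_seq(mods)
}

# 70x70-receptive-field patch discriminator (4x4 kernels, strides 2,2,2,1,1)
make_discriminator <- function(ndf) {
  nn_seq(
    nn_conv(3L, ndf, 4L, stride = 2L, pad = 1L), nn_lrelu(),
    nn_conv(ndf, 2L * ndf, 4L, stride = 2L, pad = 1L), nn_inorm(2L * ndf),
    nn_lrelu(),
    nn_conv(2L * ndf, 4L * ndf, 4L, stride = 2L, pad = 1L),
    nn_inorm(4L * ndf), nn_lrelu(),
    nn_conv(4L * ndf, 4L * ndf, 4L, stride = 1L, pad = 1L),
    nn_inorm(4L * ndf), nn_lrelu(),
    nn_conv(4L * ndf, 1L, 4L, stride = 1L, pad = 1L))
}

## ---- lightweight UNet heatmap regressor -----------------------------------

nn_unet <- function(base = 8L, cin = 3L) {
  u <- as.integer(base)
  new_module("unet", "nn_unet", list(
    u = u,
    e1 = nn_seq(nn_conv(cin, u, 3L), nn_inorm(u), nn_relu()),
    d1 = nn_seq(nn_conv(u, 2L * u, 3L, stride = 2L), nn_inorm(2L * u),
                nn_relu()),
    e2 = nn_seq(nn_conv(2L * u, 2L * u, 3L), nn_inorm(2L * u), nn_relu()),
    d2 = nn_seq(nn_conv(2L * u, 4L * u, 3L, stride = 2L), nn_inorm(4L * u),
                nn_relu()),
    e3 = nn_seq(nn_conv(4L * u, 4L * u, 3L), nn_inorm(4L * u), nn_relu()),
    u2 = nn_seq(nn_up2(), nn_conv(4L * u, 2L * u, 3L), nn_inorm(2L * u),
                nn_relu()),
    dec2 = nn_seq(nn_conv(4L * u, 2L * u, 3L), nn_inorm(2L * u), nn_relu()),
    u1 = nn_seq(nn_up2(), nn_conv(2L * u, u, 3L), nn_inorm(u), nn_relu()),
    dec1 = nn_seq(nn_conv(2L * u, u, 3L), nn_inorm(u), nn_relu()),
    out = nn_conv(u, 1L, 3L)))
}

# returns heatmap *logits* (1 channel); the sigmoid lives in the loss / the
# prediction helper so BCE backprop stays numerically exact
#' @export
nn_fwd.nn_unet <- function(m, x) {
  a1 <- nn_fwd(m$e1, x)
  h1 <- nn_fwd(m$d1, a1$y)
  a2 <- nn_fwd(m$e2, h1$y)
  h2 <- nn_fwd(m$d2, a2$y)
  a3 <- nn_fwd(m$e3, h2$y)
  b2 <- nn_fwd(m$u2, a3$y)
  c2 <- nn_fwd(m$dec2, cat_channels(b2$y, a2$y))
  b1 <- nn_fwd(m$u1, c2$y)
  c1 <- nn_fwd(m$dec1, cat_channels(b1$y, a1$y))
  z <- nn_fwd(m$out, c1$y)
  list(y = z$y,
       cache = list(a1 = a1, h1 = h1, a2 = a2, h2 = h2, a3 = a3, b2 = b2,
                    c2 = c2, b1 = b1, c1 = c1, z = z))
}

#' @export
nn_bwd.nn_unet <- function(m, cache, gy) {
  u <- m$u
  g_c1 <- nn_bwd(m$out, cache$z$cache, gy)
  g_cat1 <- nn_bwd(m$dec1, cache$c1$cache, g_c1)
  sp1 <- split_channels(g_cat1, u)
  g_c2 <- nn_bwd(m$u1, cache$b1$cache, sp1[[1]])
  g_cat2 <- nn_bwd(m$dec2, cache$c2$cache, g_c2)
  sp2 <- split_channels(g_cat2, 2L * u)
  g_a3 <- nn_bwd(m$u2, cache$b2$cache, sp2[[1]])
  g_h2 <- nn_bwd(m$e3, cache$a3$cache, g_a3)
  g_a2 <- nn_bwd(m$d2, cache$h2$cache, g_h2) + sp2[[2]]
  g_h1 <- nn_bwd(m$e2, cache$a2$cache, g_a2)
  g_a1 <- nn_bwd(m$d1, cache$h1$cache, g_h1) + sp1[[2]]
  nn_bwd(m$e1, cache$a1$cache, g_a1)
}

#' @export
nn_params.nn_unet <- function(m) {
  do.call(c, lapply(list(m$e1, m$d1, m$e2, m$d2, m$e3, m$u2, m$dec2, m$u1,
                         m$dec1, m$out), nn_params))
}

#' Build the full model set
#'
#' Deterministic given `config$seed`. The support UNets are "lightweight" by
#' contract: each has fewer than a quarter of a generator's parameters.
#'
#' @param config a [gan_config()].
#' @return A `model_set`: generators `G_s2r`, `G_r2s`, discriminators `D_r`,
#'   `D_s`, heatmap networks `U_r` (reads `G_s2r` output), `U_s` (reads
#'   `G_r2s` output), and the config.
#' @export
build_models <- function(config) {
  stopifnot(inherits(config, "gan_config"))
  with_seed(config$seed, {
    ms <- list(
      G_s2r = make_generator(config$ngf, config$n_res),
      G_r2s = make_generator(config$ngf, config$n_res),
      D_r = make_discriminator(config$ndf),
      D_s = make_discriminator(config$ndf),
      U_r = nn_unet(config$unet_base),
      U_s = nn_unet(config$unet_base),
      config = config)
    class(ms) <- "model_set"
    g_n <- nn_param_count(ms$G_s2r)
    u_n <- nn_param_count(ms$U_r)
    if (u_n >= g_n / 4)
      stopf("support UNet (%d params) is not lightweight relative to the generator (%d)",
            u_n, g_n)
    ms
  })
}

## ---- parameter (de)serialisation ------------------------------------------

modelset_state <- function(models) {
  grab <- function(m) lapply(nn_params(m), function(p) get(p$par, envir = p$env))
  list(G_s2r = grab(models$G_s2r), G_r2s = grab(models$G_r2s),
       D_r = grab(models$D_r), D_s = grab(models$D_s),
       U_r = grab(models$U_r), U_s = grab(models$U_s),
       config = models$config)
}

modelset_restore <- function(state) {
  models <- build_models(state$config)
  put <- function(m, vals) {
    ps <- nn_params(m)
    stopifnot(length(ps) == length(vals))
    for (i in seq_along(ps))
      assign(ps[[i]]$par, vals[[i]], envir = ps[[i]]$env)
  }
  for (nm in c("G_s2r", "G_r2s", "D_r", "D_s", "U_r", "U_s"))
    put(models[[nm]], state[[nm]])
  models
}

#' Save / load a model set checkpoint
#'
#' Checkpoints are self-describing: the config is embedded, and loading
#' rebuilds the architecture before restoring parameters.
#'
#' @param models a `model_set`.
#' @param path checkpoint file (RDS).
#' @export
save_modelset <- function(models, path) {
  saveRDS(modelset_state(models), path)
  invisible(path)
}

#' @rdname save_modelset
#' @export
load_modelset <- function(path) modelset_restore(readRDS(path))
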