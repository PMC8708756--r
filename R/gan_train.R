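# Training loop for the heatmap-supported translator.
#
# Per step: translate one source image and one target image to the other's
# domain, reconstruct both cycles, predict a heatmap from each translated
# image with the support UNets, and take one shared Adam step per direction
# ({G_s2r, U_r} and {G_r2s, U_s}); then update each discriminator from the
# replay pool. The support networks never see ground truth for the
# translated image other than the *source* image's own heatmap — this is the
# mechanism that penalises translations which move, add or delete heads.

#' One training example pair
#'
#' @param si source (synthetic) image, `n x n x 3` in `[0, 1]`.
#' @param ri target (real-style) image, same shape.
#' @param sh,rh their Gaussian heatmaps (`n x n` matrices in `[0, 1]`).
#' @return An object of class `train_batch` (images converted to `[-1, 1]`).
#' @export
train_batch <- function(si, ri, sh, rh) {
  d <- dim(si)
  if (!identical(d, dim(ri)) || d[1] != d[2])
    stopf("si and ri must be square images of equal size")
  if (!identical(dim(sh), d[1:2]) || !identical(dim(rh), d[1:2]))
    stopf("heatmap dimensions must match the images")
  if (min(sh) < 0 || max(sh) > 1 || min(rh) < 0 || max(rh) > 1)
    stopf("heatmaps must lie in [0, 1]")
  structure(list(si = 2 * si - 1, ri = 2 * ri - 1, sh = sh, rh = rh),
            class = "train_batch")
}

# replay pool of previously generated fakes (environment with reference
# semantics); query() pushes the new fake and, with probability 1/2 once
# full, returns (and replaces) a stored one
pool_new <- function(capacity) {
  p <- new.env(parent = emptyenv())
  p$capacity <- capacity
  p$items <- list()
  p
}

pool_query <- function(pool, fake) {
  if (pool$capacity <= 0L) return(fake)
  if (length(pool$items) < pool$capacity) {
    pool$items[[length(pool$items) + 1L]] <- fake
    return(fake)
  }
  if (stats::runif(1) > 0.5) {
    i <- sample.int(length(pool$items), 1L)
    out <- pool$items[[i]]
    pool$items[[i]] <- fake
    out
  } else {
    fake
  }
}

#' Create the shared optimisers
#'
#' One Adam instance jointly holds each generator and its support UNet
#' (shared optimiser and learning rate); the discriminators get their own.
#'
#' @param models a `model_set`.
#' @return List of optimisers plus the two replay pools.
#' @export
make_optimizers <- function(models) {
  cfg <- models$config
  list(opt_s2r = adam_new(list(models$G_s2r, models$U_r), lr = cfg$lr),
       opt_r2s = adam_new(list(models$G_r2s, models$U_s), lr = cfg$lr),
       opt_d_r = adam_new(list(models$D_r), lr = cfg$lr),
       opt_d_s = adam_new(list(models$D_s), lr = cfg$lr),
       pool_r = pool_new(cfg$pool_size),
       pool_s = pool_new(cfg$pool_size))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' One optimisation step
#'
#' Runs the full forward pass, backpropagates the generator objective
#' (adversarial + cycle + optional identity + weighted heatmap BCE), steps
#' the two shared generator/UNet optimisers, then updates both
#' discriminators from their replay pools. With `lambda_heatmap = 0` the
#' heatmap terms contribute nothing to the generators (the plain-translator
#' baseline) while the UNets still train on their own BCE.
#'
#' @param batch a [train_batch()].
#' @param models a `model_set` from [build_models()].
#' @param optimizers from [make_optimizers()].
#' @param config the [gan_config()] (defaults to the model set's).
#' @return A `loss_report` list: `adv_g_s2r`, `adv_g_r2s`, `d_r`, `d_s`,
#'   `cycle_s`, `cycle_r`, `identity`, `heatmap_s`, `heatmap_r`, `total_g`.
#' @export
train_step <- function(batch, models, optimizers, config = models$config) {
  stopifnot(inherits(batch, "train_batch"))
  if (dim(batch$si)[1] != config$image_size)
    stopf("batch size %d does not match config image_size %d",
          dim(batch$si)[1], config$image_size)
  lc <- config$lambda_cycle
  li <- config$lambda_identity
  lh <- config$lambda_heatmap

  for (m in list(models$G_s2r, models$G_r2s, models$U_r, models$U_s,
                 models$D_r, models$D_s))
    nn_zero_grad(m)

  ## ---- forward -------------------------------------------------------
  f_r <- nn_fwd(models$G_s2r, batch$si) # fake real
  f_s <- nn_fwd(models$G_r2s, batch$ri) # fake synthetic
  c_s <- nn_fwd(models$G_r2s, f_r$y)    # cycle back to synthetic
  c_r <- nn_fwd(models$G_s2r, f_s$y)    # cycle back to real
  u_r <- nn_fwd(models$U_r, f_r$y)      # heatmap logits for fake real
  u_s <- nn_fwd(models$U_s, f_s$y)
  p_s <- sigmoid(u_r$y[, , 1])
  p_r <- sigmoid(u_s$y[, , 1])
  d_fr <- nn_fwd(models$D_r, f_r$y)
  d_fs <- nn_fwd(models$D_s, f_s$y)

  loss_cycle_s <- cycle_loss(batch$si, c_s$y)
  loss_cycle_r <- cycle_loss(batch$ri, c_r$y)
  loss_hm_s <- heatmap_bce(p_s, batch$sh)
  loss_hm_r <- heatmap_bce(p_r, batch$rh)
  adv_g_s2r <- mean((d_fr$y - 1)^2)
  adv_g_r2s <- mean((d_fs$y - 1)^2)
  loss_idt <- 0
  if (li > 0) {
    i_r <- nn_fwd(models$G_s2r, batch$ri)
    i_s <- nn_fwd(models$G_r2s, batch$si)
    loss_idt <- cycle_loss(batch$ri, i_r$y) + cycle_loss(batch$si, i_s$y)
  }
  total_g <- adv_g_s2r + adv_g_r2s + lc * (loss_cycle_s + loss_cycle_r) +
    li * loss_idt + lh * (loss_hm_s + loss_hm_r)
  if (!is.finite(total_g)) stopf("training diverged: non-finite loss")

  ## ---- generator backward --------------------------------------------
  n_img <- length(batch$si)
  n_hm <- length(batch$sh)

  # grad wrt fake_r: adversarial + cycle-through-G_r2s + weighted heatmap
  g_adv_fr <- nn_bwd(models$D_r, d_fr$cache,
                     2 * (d_fr$y - 1) / length(d_fr$y))
  g_cyc_fr <- nn_bwd(models$G_r2s, c_s$cache,
                     lc * sign(c_s$y - batch$si) / n_img)
  gz_s <- array((p_s - batch$sh) / n_hm, dim(u_r$y))
  g_hm_fr <- nn_bwd(models$U_r, u_r$cache, gz_s)
  nn_bwd(models$G_s2r, f_r$cache, g_adv_fr + g_cyc_fr + lh * g_hm_fr)

  # grad wrt fake_s, symmetric
  g_adv_fs <- nn_bwd(models$D_s, d_fs$cache,
                     2 * (d_fs$y - 1) / length(d_fs$y))
  g_cyc_fs <- nn_bwd(models$G_s2r, c_r$cache,
                     lc * sign(c_r$y - batch$ri) / n_img)
  gz_r <- array((p_r - batch$rh) / n_hm, dim(u_s$y))
  g_hm_fs <- nn_bwd(models$U_s, u_s$cache, gz_r)
  nn_bwd(models$G_r2s, f_s$cache, g_adv_fs + g_cyc_fs + lh * g_hm_fs)

  if (li > 0) {
    nn_bwd(models$G_s2r, i_r$cache, li * sign(i_r$y - batch$ri) / n_img)
    nn_bwd(models$G_r2s, i_s$cache, li * sign(i_s$y - batch$si) / n_img)
  }

  adam_step(optimizers$opt_s2r)
  adam_step(optimizers$opt_r2s)

  ## ---- discriminator updates (replay pool) ---------------------------
  upd_d <- function(D, opt, pool, real, fake) {
    nn_zero_grad(D)
    fake_p <- pool_query(pool, fake)
    d_real <- nn_fwd(D, real)
    d_fake <- nn_fwd(D, fake_p)
    adv <- adversarial_losses(d_real$y, d_fake$y)
    nn_bwd(D, d_real$cache, (d_real$y - 1) / length(d_real$y))
    nn_bwd(D, d_fake$cache, d_fake$y / length(d_fake$y))
    adam_step(opt)
    adv$d_term
  }
  loss_d_r <- upd_d(models$D_r, optimizers$opt_d_r, optimizers$pool_r,
                    batch$ri, f_r$y)
  loss_d_s <- upd_d(models$D_s, optimizers$opt_d_s, optimizers$pool_s,
                    batch$si, f_s$y)

  structure(
    list(adv_g_s2r = adv_g_s2r, adv_g_r2s = adv_g_r2s,
         d_r = loss_d_r, d_s = loss_d_s,
         cycle_s = loss_cycle_s, cycle_r = loss_cycle_r,
         identity = loss_idt, heatmap_s = loss_hm_s, heatmap_r = loss_hm_r,
         total_g = total_g),
    class = "loss_report")
}

#' Train the translator on two unpaired image sets
#'
#' Iterates `epochs` passes of `max(n_source, n_target)` steps; source and
#' target orders are shuffled independently each epoch (seeded from the
#' config), with the smaller set recycled. Optionally checkpoints each epoch.
#'
#' @param source list with `images` (named list of `[0,1]` arrays) and
#'   `heatmaps` (named list aligned by id).
#' @param target same structure for the target domain.
#' @param config a [gan_config()].
#' @param models optionally, a pre-built `model_set` to continue training.
#' @param checkpoint_dir if non-`NULL`, epoch checkpoints and a loss-history
#'   CSV are written there.
#' @param verbose print a line per epoch.
#' @return List: `models` (trained `model_set`), `history` (data frame of
#'   per-step loss components).
#' @export
train_gan <- function(source, target, config = gan_config(),
                      models = NULL, checkpoint_dir = NULL, verbose = FALSE) {
  if (!length(source$images) || !length(target$images))
    stopf("both domains must be non-empty")
  if (length(source$images) != length(source$heatmaps) ||
      length(target$images) != length(target$heatmaps))
    stopf("each image needs a heatmap")
  models <- models %||% build_models(config)
  opts <- make_optimizers(models)
  n_s <- length(source$images)
  n_t <- length(target$images)
  steps_per_epoch <- max(n_s, n_t)
  history <- list()
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord_s <- sample(rep_len(sample.int(n_s), steps_per_epoch))
      ord_t <- sample(rep_len(sample.int(n_t), steps_per_epoch))
      for (st in seq_len(steps_per_epoch)) {
        b <- train_batch(source$images[[ord_s[st]]],
                         target$images[[ord_t[st]]],
                         source$heatmaps[[ord_s[st]]],
                         target$heatmaps[[ord_t[st]]])
        rep_ <- train_step(b, models, opts, config)
        history[[length(history) + 1L]] <-
          c(epoch = ep, step = st, unlist(unclass(rep_)))
      }
      if (verbose) {
        last <- history[[length(history)]]
        message(sprintf("epoch %d/%d  total_g %.4f", ep, config$epochs,
                        last[["total_g"]]))
      }
      if (!is.null(checkpoint_dir)) {
        dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        save_modelset(models,
                      file.path(checkpoint_dir, sprintf("epoch_%03d.rds", ep)))
      }
    }
  })
  history <- as.data.frame(do.call(rbind, history))
  if (!is.null(checkpoint_dir))
    utils::write.csv(history, file.path(checkpoint_dir, "history.csv"),
                     row.names = FALSE)
  list(models = models, history = history)
}

#' Translate images between domains
#'
#' Annotations are never modified by translation: translated images keep the
#' boxes of their source image.
#'
#' @param models a trained `model_set`.
#' @param images named list of `[0, 1]` image arrays.
#' @param direction `"s2r"` (synthetic to real) or `"r2s"`.
#' @return Named list of translated `[0, 1]` arrays, same ids and sizes.
#' @export
translate_images <- function(models, images, direction = c("s2r", "r2s")) {
  direction <- match.arg(direction)
  g <- if (direction == "s2r") models$G_s2r else models$G_r2s
  lapply(images, function(img) {
    if (dim(img)[1] != models$config$image_size)
      stopf("image size %d does not match model image_size %d",
            dim(img)[1], models$config$image_size)
    y <- nn_fwd(g, 2 * img - 1)$y
    clamp((y + 1) / 2, 0, 1)
  })
}

#' Predict a heatmap with a support network
#'
#' @param models a `model_set`.
#' @param image `[0, 1]` image array.
#' @param which `"r"`: the network reading synthetic-to-real output;
#'   `"s"`: the one reading real-to-synthetic output.
#' @return Heatmap matrix in `(0, 1)`.
#' @export
predict_heatmap <- function(models, image, which = c("r", "s")) {
  which <- match.arg(which)
  u <- if (which == "r") models$U_r else models$U_s
  sigmoid(nn_fwd(u, 2 * image - 1)$y[, , 1])
}
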