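# Loss functions of the translation objective. All take plain arrays and
# return scalars; the training step wires up their analytic gradients.

#' Binary cross-entropy between a predicted and a target heatmap
#'
#' Mean over pixels of `-(t*log(p) + (1-t)*log(1-p))`, with `p` clamped to
#' `[eps, 1-eps]`. Targets are soft Gaussians in `[0, 1]`; BCE is
#' well-defined for non-binary targets and is minimised (over a constant
#' prediction) at `p = t`.
#'
#' @param pred predicted heatmap, values in `(0, 1)`.
#' @param target target heatmap in `[0, 1]`, same shape.
#' @param eps clamp floor (default 1e-7).
#' @return Scalar loss.
#' @export
heatmap_bce <- function(pred, target, eps = 1e-7) {
  if (!identical(dim(pred), dim(target)))
    stopf("pred and target shapes differ")
  p <- clamp(pred, eps, 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Cycle-consistency loss
#'
#' Mean absolute difference between an image and its reconstruction after a
#' round trip through both generators.
#'
#' @param x original tensor.
#' @param x_rec reconstruction, same shape.
#' @return Scalar mean absolute error.
#' @export
cycle_loss <- function(x, x_rec) {
  if (!identical(dim(x), dim(x_rec))) stopf("shape mismatch")
  mean(abs(x - x_rec))
}

#' Least-squares adversarial losses
#'
#' The LSGAN objective: the discriminator drives real outputs toward 1 and
#' fake outputs toward 0 (`d_term = mean((d_real - 1)^2)/2 +
#' mean(d_fake^2)/2`); the generator drives fake outputs toward 1
#' (`g_term = mean((d_fake - 1)^2)`).
#'
#' @param d_real_out discriminator output on real inputs.
#' @param d_fake_out discriminator output on generated inputs.
#' @return List with `g_term` and `d_term`.
#' @export
adversarial_losses <- function(d_real_out, d_fake_out) {
  if (!all(is.finite(d_real_out)) || !all(is.finite(d_fake_out)))
    stopf("non-finite discriminator outputs")
  list(g_term = mean((d_fake_out - 1)^2),
       d_term = 0.5 * mean((d_real_out - 1)^2) + 0.5 * mean(d_fake_out^2))
}
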