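# Minimal convolutional-network framework with manual backpropagation.
#
# Tensors are plain R arrays of dim (H, W, C). Modules are environments
# holding parameters (`w`, `b`, `gamma`, ...) and their gradient accumulators
# (`gw`, `gb`, ...). Forward passes return the output together with an
# explicit cache, so a module can appear several times in one computation
# (both generators are traversed twice per cycle-consistent step):
#
#   out <- nn_fwd(m, x)      # list(y = ..., cache = ...)
#   gx  <- nn_bwd(m, out$cache, gy)   # accumulates parameter gradients
#
# Convolutions call into the compiled im2col+GEMM kernels.

new_module <- function(type, class, fields = list()) {
  m <- new.env(parent = emptyenv())
  m$type <- type
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = m)
  class(m) <- c(class, "nn_module")
  m
}

#' @keywords internal
nn_fwd <- function(m, x) UseMethod("nn_fwd")
#' @keywords internal
nn_bwd <- function(m, cache, gy) UseMethod("nn_bwd")
# list of list(env, par, grad) descriptors for every learnable parameter
nn_params <- function(m) UseMethod("nn_params")
#' @export
nn_params.default <- function(m) list()

nn_zero_grad <- function(m) {
  for (p in nn_params(m)) {
    g <- get(p$grad, envir = p$env)
    assign(p$grad, g * 0, envir = p$env)
  }
  invisible(m)
}

nn_param_count <- function(m) {
  sum(vapply(nn_params(m), function(p) length(get(p$par, envir = p$env)),
             numeric(1)))
}

## ---- convolution ----------------------------------------------------------

nn_conv <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                    init_sd = 0.02) {
  w <- matrix(stats::rnorm(k * k * cin * cout, sd = init_sd),
              k * k * cin, cout)
  new_module("conv", "nn_conv", list(
    cin = cin, cout = cout, k = as.integer(k), stride = as.integer(stride),
    pad = as.integer(pad), w = w, b = numeric(cout),
    gw = w * 0, gb = numeric(cout)))
}

#' @export
nn_fwd.nn_conv <- function(m, x) {
  y <- cpp_conv2d_fwd(x, m$w, m$b, m$k, m$k, m$stride, m$pad)
  list(y = y, cache = x)
}

#' @export
nn_bwd.nn_conv <- function(m, cache, gy) {
  g <- cpp_conv2d_bwd(cache, m$w, gy, m$k, m$k, m$stride, m$pad)
  m$gw <- m$gw + g$gw
  m$gb <- m$gb + as.numeric(g$gb)
  g$gx
}

#' @export
nn_params.nn_conv <- function(m) {
  list(list(env = m, par = "w", grad = "gw"),
       list(env = m, par = "b", grad = "gb"))
}

## ---- instance normalisation ----------------------------------------------

nn_inorm <- function(c, eps = 1e-5) {
  new_module("inorm", "nn_inorm", list(
    c = c, eps = eps, gamma = rep(1, c), beta = numeric(c),
    ggamma = numeric(c), gbeta = numeric(c)))
}

#' @export
nn_fwd.nn_inorm <- function(m, x) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  v <- colMeans(xc^2)
  inv_sd <- 1 / sqrt(v + m$eps)
  xhat <- sweep(xc, 2L, inv_sd, `*`)
  y <- sweep(sweep(xhat, 2L, m$gamma, `*`), 2L, m$beta, `+`)
  list(y = array(y, d), cache = list(xhat = xhat, inv_sd = inv_sd, d = d))
}

#' @export
nn_bwd.nn_inorm <- function(m, cache, gy) {
  d <- cache$d
  n <- d[1] * d[2]
  gym <- matrix(gy, n, d[3])
  xhat <- cache$xhat
  m$gbeta <- m$gbeta + colSums(gym)
  m$ggamma <- m$ggamma + colSums(gym * xhat)
  gxhat <- sweep(gym, 2L, m$gamma, `*`)
  s1 <- colMeans(gxhat)
  s2 <- colMeans(gxhat * xhat)
  gx <- sweep(gxhat, 2L, s1) - sweep(xhat, 2L, s2, `*`)
  gx <- sweep(gx, 2L, cache$inv_sd, `*`)
  array(gx, d)
}

#' @export
nn_params.nn_inorm <- function(m) {
  list(list(env = m, par = "gamma", grad = "ggamma"),
       list(env = m, par = "beta", grad = "gbeta"))
}

## ---- pointwise activations ------------------------------------------------

nn_relu <- function() new_module("relu", "nn_relu")
#' @export
nn_fwd.nn_relu <- function(m, x) {
  y <- pmax(x, 0)
  list(y = y, cache = x > 0)
}
#' @export
nn_bwd.nn_relu <- function(m, cache, gy) gy * cache

nn_lrelu <- function(slope = 0.2) new_module("lrelu", "nn_lrelu",
                                             list(slope = slope))
#' @export
nn_fwd.nn_lrelu <- function(m, x) {
  pos <- x > 0
  list(y = ifelse(pos, x, m$slope * x), cache = pos)
}
#' @export
nn_bwd.nn_lrelu <- function(m, cache, gy) ifelse(cache, gy, m$slope * gy)

nn_tanh <- function() new_module("tanh", "nn_tanh")
#' @export
nn_fwd.nn_tanh <- function(m, x) {
  y <- tanh(x)
  list(y = y, cache = y)
}
#' @export
nn_bwd.nn_tanh <- function(m, cache, gy) gy * (1 - cache^2)

## ---- nearest-neighbour x2 upsampling --------------------------------------

nn_up2 <- function() new_module("up2", "nn_up2")
#' @export
nn_fwd.nn_up2 <- function(m, x) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
         drop = FALSE]
  list(y = y, cache = d)
}
#' @export
nn_bwd.nn_up2 <- function(m, cache, gy) {
  h <- cache[1]
  w <- cache[2]
  oi <- seq(1L, 2L * h, by = 2L)
  oj <- seq(1L, 2L * w, by = 2L)
  gy[oi, oj, , drop = FALSE] + gy[oi + 1L, oj, , drop = FALSE] +
    gy[oi, oj + 1L, , drop = FALSE] + gy[oi + 1L, oj + 1L, , drop = FALSE]
}

## ---- sequential container -------------------------------------------------

nn_seq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) &&
      !inherits(mods[[1]], "nn_module"))
    mods <- mods[[1]]
  new_module("seq", "nn_seq", list(mods = mods))
}

#' @export
nn_fwd.nn_seq <- function(m, x) {
  caches <- vector("list", length(m$mods))
  for (i in seq_along(m$mods)) {
    out <- nn_fwd(m$mods[[i]], x)
    x <- out$y
    caches[[i]] <- out$cache
  }
  list(y = x, cache = caches)
}

#' @export
nn_bwd.nn_seq <- function(m, cache, gy) {
  for (i in rev(seq_along(m$mods)))
    gy <- nn_bwd(m$mods[[i]], cache[[i]], gy)
  gy
}

#' @export
nn_params.nn_seq <- function(m)
  do.call(c, lapply(m$mods, nn_params))

## ---- residual block -------------------------------------------------------

nn_res <- function(c) {
  body <- nn_seq(nn_conv(c, c, 3L), nn_inorm(c), nn_relu(),
                 nn_conv(c, c, 3L), nn_inorm(c))
  new_module("res", "nn_res", list(body = body))
}

#' @export
nn_fwd.nn_res <- function(m, x) {
  out <- nn_fwd(m$body, x)
  list(y = x + out$y, cache = out$cache)
}

#' @export
nn_bwd.nn_res <- function(m, cache, gy) {
  gy + nn_bwd(m$body, cache, gy)
}

#' @export
nn_params.nn_res <- function(m) nn_params(m$body)

## ---- channel concatenation (used by the UNet skips) -----------------------

cat_channels <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3]))
  y[, , seq_len(da[3])] <- a
  y[, , da[3] + seq_len(db[3])] <- b
  y
}

split_channels <- function(g, c1) {
  d <- dim(g)
  list(g[, , seq_len(c1), drop = FALSE],
       g[, , (c1 + 1L):d[3], drop = FALSE])
}

## ---- Adam optimiser -------------------------------------------------------

#' Adam optimiser over one or more modules
#'
#' One optimiser instance may jointly hold several modules — the translation
#' setup shares a single optimiser between each generator and its heatmap
#' support network.
#'
#' @param modules list of `nn_module`s.
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps numerical fuzz.
#' @return An optimiser environment.
#' @keywords internal
adam_new <- function(modules, lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                     eps = 1e-8) {
  params <- do.call(c, lapply(modules, nn_params))
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr
  opt$beta1 <- beta1
  opt$beta2 <- beta2
  opt$eps <- eps
  opt$t <- 0L
  opt$m <- lapply(params, function(p) get(p$par, envir = p$env) * 0)
  opt$v <- lapply(params, function(p) get(p$par, envir = p$env) * 0)
  opt
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- get(p$grad, envir = p$env)
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g^2
    step <- opt$lr * (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
    assign(p$par, get(p$par, envir = p$env) - step, envir = p$env)
  }
  invisible(opt)
}
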