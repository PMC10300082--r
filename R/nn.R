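# Minimal neural-network engine used by the UNet-RCAN restoration model.
#
# Activations travel as a list(v, sp): `v` is an (Npix x C) matrix whose rows
# enumerate spatial positions in column-major order over the spatial dims
# `sp` (2D: c(y, x); 3D: c(y, x, z)).  Convolutions are evaluated as im2col
# followed by one BLAS matrix multiplication, which is what makes training
# feasible without a deep-learning framework.  Every layer is an environment
# holding its parameters, gradients and forward cache; modules compose these
# with explicit backward code (batch size 1 throughout, as in training).

nn_act <- function(v, sp) list(v = v, sp = sp)

nn_param <- function(dims, fan_in = NULL) {
  p <- new.env(parent = emptyenv())
  n <- prod(dims)
  if (is.null(fan_in)) {
    p$v <- array(0, dims)
  } else {
    limit <- sqrt(6 / fan_in)  # He-uniform
    p$v <- array(stats::runif(n, -limit, limit), dims)
  }
  p$g <- array(0, dims)
  p
}

nn_module <- function(class, pars = list(), subs = list()) {
  m <- new.env(parent = emptyenv())
  m$pars <- pars
  m$subs <- subs
  class(m) <- c(class, "nn_module")
  m
}

nn_collect_params <- function(mod) {
  out <- mod$pars
  for (s in mod$subs) out <- c(out, nn_collect_params(s))
  out
}

nn_count_params <- function(mod) {
  sum(vapply(nn_collect_params(mod), function(p) length(p$v), numeric(1)))
}

nn_zero_grad <- function(mod) {
  for (p in nn_collect_params(mod)) p$g[] <- 0
  invisible(mod)
}

nn_get_state <- function(mod) lapply(nn_collect_params(mod), function(p) p$v)

nn_set_state <- function(mod, state) {
  ps <- nn_collect_params(mod)
  stopifnot(length(ps) == length(state))
  for (i in seq_along(ps)) ps[[i]]$v <- state[[i]]
  invisible(mod)
}

# ---- spatial index caches ----------------------------------------------

# Linear (column-major) index of coordinates inside a grid of dims `dd`.
# coords: list of integer vectors, one per axis; expanded as a full grid.
grid_linear_index <- function(coords, dd) {
  strides <- cumprod(c(1, dd[-length(dd)]))
  g <- as.matrix(expand.grid(coords, KEEP.OUT.ATTRS = FALSE))
  as.integer(1 + (g - 1) %*% strides)
}

# Index map for a same-padded k^d convolution: for output grid `sp` returns
# list(inner = rows of original pixels inside the padded grid,
#      idx   = Npix x k^d matrix of padded-grid rows per kernel offset,
#      spp   = padded dims)
conv_index_map <- function(sp, k) {
  p <- (k - 1L) %/% 2L
  spp <- sp + 2L * p
  inner <- grid_linear_index(lapply(sp, function(n) seq_len(n) + p), spp)
  offs <- as.matrix(expand.grid(rep(list(0:(k - 1L)), length(sp)),
                                KEEP.OUT.ATTRS = FALSE))
  idx <- matrix(0L, prod(sp), nrow(offs))
  for (j in seq_len(nrow(offs))) {
    idx[, j] <- grid_linear_index(
      lapply(seq_along(sp), function(ax) seq_len(sp[ax]) + offs[j, ax]), spp)
  }
  list(inner = inner, idx = idx, spp = spp)
}

# Cache index maps on a module keyed by spatial shape.
nn_shape_cache <- function(mod, sp, maker) {
  key <- paste(sp, collapse = "x")
  if (is.null(mod$cache_idx)) mod$cache_idx <- list()
  hit <- mod$cache_idx[[key]]
  if (is.null(hit)) {
    hit <- maker(sp)
    mod$cache_idx[[key]] <- hit
  }
  hit
}

im2col <- function(v, sp, k, map) {
  C <- ncol(v)
  np <- prod(map$spp)
  vp <- matrix(0, np, C)
  vp[map$inner, ] <- v
  kk <- ncol(map$idx)
  out <- matrix(0, nrow(v), kk * C)
  for (j in seq_len(kk)) {
    out[, ((j - 1L) * C + 1L):(j * C)] <- vp[map$idx[, j], , drop = FALSE]
  }
  out
}

col2im <- function(dxc, sp, C, map) {
  np <- prod(map$spp)
  dvp <- matrix(0, np, C)
  kk <- ncol(map$idx)
  for (j in seq_len(kk)) {
    rows <- map$idx[, j]
    dvp[rows, ] <- dvp[rows, , drop = FALSE] +
      dxc[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
  }
  dvp[map$inner, , drop = FALSE]
}

# ---- primitive layers ---------------------------------------------------

nn_conv <- function(cin, cout, k = 3L, dims = 2L) {
  kk <- as.integer(k)^dims
  m <- nn_module("nn_conv",
                 pars = list(W = nn_param(c(kk * cin, cout), fan_in = kk * cin),
                             b = nn_param(cout)))
  m$cin <- cin; m$cout <- cout; m$k <- as.integer(k); m$dims <- dims
  m
}

nn_forward.nn_conv <- function(mod, x) {
  if (mod$k == 1L) {
    mod$xc <- x$v
  } else {
    map <- nn_shape_cache(mod, x$sp, function(sp) conv_index_map(sp, mod$k))
    mod$xc <- im2col(x$v, x$sp, mod$k, map)
  }
  mod$sp <- x$sp
  y <- mod$xc %*% mod$pars$W$v
  y <- sweep(y, 2L, mod$pars$b$v, `+`)
  nn_act(y, x$sp)
}

nn_backward.nn_conv <- function(mod, dy) {
  mod$pars$W$g <- mod$pars$W$g + crossprod(mod$xc, dy$v)
  mod$pars$b$g <- mod$pars$b$g + colSums(dy$v)
  dxc <- tcrossprod(dy$v, mod$pars$W$v)
  if (mod$k == 1L) return(nn_act(dxc, mod$sp))
  map <- nn_shape_cache(mod, mod$sp, function(sp) conv_index_map(sp, mod$k))
  nn_act(col2im(dxc, mod$sp, mod$cin, map), mod$sp)
}

nn_lrelu <- function(slope = 0.3) {
  m <- nn_module("nn_lrelu")
  m$slope <- slope
  m
}

nn_forward.nn_lrelu <- function(mod, x) {
  f <- ifelse(x$v > 0, 1, mod$slope)
  mod$f <- f
  nn_act(x$v * f, x$sp)
}

nn_backward.nn_lrelu <- function(mod, dy) nn_act(dy$v * mod$f, dy$sp)

nn_maxpool <- function(dims = 2L) {
  m <- nn_module("nn_maxpool")
  m$dims <- dims
  m
}

pool_index_map <- function(sp) {
  spo <- sp %/% 2L
  offs <- as.matrix(expand.grid(rep(list(0:1), length(sp)),
                                KEEP.OUT.ATTRS = FALSE))
  idx <- matrix(0L, prod(spo), nrow(offs))
  for (j in seq_len(nrow(offs))) {
    idx[, j] <- grid_linear_index(
      lapply(seq_along(sp), function(ax) 2L * (seq_len(spo[ax]) - 1L) + 1L + offs[j, ax]),
      sp)
  }
  list(idx = idx, spo = spo)
}

nn_forward.nn_maxpool <- function(mod, x) {
  if (any(x$sp %% 2L != 0L)) {
    stop("max-pooling requires even spatial dimensions; pad the input ",
         "(got ", paste(x$sp, collapse = "x"), ")", call. = FALSE)
  }
  map <- nn_shape_cache(mod, x$sp, pool_index_map)
  C <- ncol(x$v)
  n <- nrow(map$idx)
  best <- matrix(-Inf, n, C)
  argo <- matrix(1L, n, C)
  for (j in seq_len(ncol(map$idx))) {
    cand <- x$v[map$idx[, j], , drop = FALSE]
    upd <- cand > best
    best[upd] <- cand[upd]
    argo[upd] <- j
  }
  mod$sp_in <- x$sp
  mod$argo <- argo
  mod$Cin <- C
  nn_act(best, map$spo)
}

nn_backward.nn_maxpool <- function(mod, dy) {
  map <- nn_shape_cache(mod, mod$sp_in, pool_index_map)
  dv <- matrix(0, prod(mod$sp_in), mod$Cin)
  for (j in seq_len(ncol(map$idx))) {
    sel <- mod$argo == j
    if (!any(sel)) next
    tmp <- matrix(0, nrow(dy$v), ncol(dy$v))
    tmp[sel] <- dy$v[sel]
    rows <- map$idx[, j]
    dv[rows, ] <- dv[rows, , drop = FALSE] + tmp
  }
  nn_act(dv, mod$sp_in)
}

# Transposed convolution, kernel 2, stride 2 (used for decoder upsampling).
nn_convT <- function(cin, cout, dims = 2L) {
  no <- 2L^dims
  m <- nn_module("nn_convT",
                 pars = c(stats::setNames(
                   lapply(seq_len(no), function(j) nn_param(c(cin, cout), fan_in = cin)),
                   paste0("W", seq_len(no))),
                   list(b = nn_param(cout))))
  m$cin <- cin; m$cout <- cout; m$dims <- dims; m$no <- no
  m
}

upsample_index_map <- function(sp) {
  spo <- 2L * sp
  offs <- as.matrix(expand.grid(rep(list(0:1), length(sp)),
                                KEEP.OUT.ATTRS = FALSE))
  idx <- matrix(0L, prod(sp), nrow(offs))
  for (j in seq_len(nrow(offs))) {
    idx[, j] <- grid_linear_index(
      lapply(seq_along(sp), function(ax) 2L * (seq_len(sp[ax]) - 1L) + 1L + offs[j, ax]),
      spo)
  }
  list(idx = idx, spo = spo)
}

nn_forward.nn_convT <- function(mod, x) {
  map <- nn_shape_cache(mod, x$sp, upsample_index_map)
  y <- matrix(0, prod(map$spo), mod$cout)
  for (j in seq_len(mod$no)) {
    y[map$idx[, j], ] <- x$v %*% mod$pars[[paste0("W", j)]]$v
  }
  y <- sweep(y, 2L, mod$pars$b$v, `+`)
  mod$xv <- x$v
  mod$sp_in <- x$sp
  nn_act(y, map$spo)
}

nn_backward.nn_convT <- function(mod, dy) {
  map <- nn_shape_cache(mod, mod$sp_in, upsample_index_map)
  dx <- matrix(0, nrow(mod$xv), mod$cin)
  mod$pars$b$g <- mod$pars$b$g + colSums(dy$v)
  for (j in seq_len(mod$no)) {
    dyj <- dy$v[map$idx[, j], , drop = FALSE]
    pj <- mod$pars[[paste0("W", j)]]
    pj$g <- pj$g + crossprod(mod$xv, dyj)
    dx <- dx + tcrossprod(dyj, pj$v)
  }
  nn_act(dx, mod$sp_in)
}

nn_sequential <- function(...) {
  m <- nn_module("nn_sequential", subs = list(...))
  m
}

nn_forward.nn_sequential <- function(mod, x) {
  for (s in mod$subs) x <- nn_forward(s, x)
  x
}

nn_backward.nn_sequential <- function(mod, dy) {
  for (s in rev(mod$subs)) dy <- nn_backward(s, dy)
  dy
}

nn_forward <- function(mod, x) UseMethod("nn_forward")
nn_backward <- function(mod, dy) UseMethod("nn_backward")

# ---- composite blocks ---------------------------------------------------

# Residual convolution block: conv3 -> LeakyReLU -> conv3, with a 1x1
# convolution refining the skip path before the addition.
nn_rcb <- function(cin, cout, dims = 2L, slope = 0.3) {
  m <- nn_module("nn_rcb", subs = list(
    branch = nn_sequential(nn_conv(cin, cout, 3L, dims),
                           nn_lrelu(slope),
                           nn_conv(cout, cout, 3L, dims)),
    skip = nn_conv(cin, cout, 1L, dims)))
  m
}

nn_forward.nn_rcb <- function(mod, x) {
  b <- nn_forward(mod$subs$branch, x)
  s <- nn_forward(mod$subs$skip, x)
  nn_act(b$v + s$v, x$sp)
}

nn_backward.nn_rcb <- function(mod, dy) {
  db <- nn_backward(mod$subs$branch, dy)
  ds <- nn_backward(mod$subs$skip, dy)
  nn_act(db$v + ds$v, dy$sp)
}

# Residual channel attention block.  The convolution block output u is
# rescaled per channel by a sigmoid gate computed from globally pooled
# features (squeeze to `reduction` filters, LeakyReLU, expand, sigmoid),
# then added to the block input: y = x + u * g(u).
nn_cab <- function(channels, reduction = 4L, dims = 2L, slope = 0.3) {
  m <- nn_module("nn_cab",
                 pars = list(
                   Wd = nn_param(c(channels, reduction), fan_in = channels),
                   bd = nn_param(reduction),
                   Wu = nn_param(c(reduction, channels), fan_in = reduction),
                   bu = nn_param(channels)),
                 subs = list(
                   block = nn_sequential(nn_conv(channels, channels, 3L, dims),
                                         nn_lrelu(slope),
                                         nn_conv(channels, channels, 3L, dims))))
  m$slope <- slope
  m
}

nn_forward.nn_cab <- function(mod, x) {
  u <- nn_forward(mod$subs$block, x)
  npix <- nrow(u$v)
  mvec <- colMeans(u$v)                               # global average pooling
  a <- drop(mvec %*% mod$pars$Wd$v) + mod$pars$bd$v   # channel down-scaling
  f <- ifelse(a > 0, 1, mod$slope)
  h <- a * f
  z <- drop(h %*% mod$pars$Wu$v) + mod$pars$bu$v      # channel up-scaling
  g <- 1 / (1 + exp(-z))                              # sigmoid gate
  y <- x$v + u$v * rep(g, each = npix)
  mod$cache <- list(x = x, u = u, mvec = mvec, f = f, h = h, g = g, npix = npix)
  nn_act(y, x$sp)
}

nn_backward.nn_cab <- function(mod, dy) {
  cc <- mod$cache
  du_direct <- dy$v * rep(cc$g, each = cc$npix)
  dg <- colSums(dy$v * cc$u$v)
  dz <- dg * cc$g * (1 - cc$g)
  mod$pars$Wu$g <- mod$pars$Wu$g + outer(cc$h, dz)
  mod$pars$bu$g <- mod$pars$bu$g + dz
  dh <- drop(mod$pars$Wu$v %*% dz)
  da <- dh * cc$f
  mod$pars$Wd$g <- mod$pars$Wd$g + outer(cc$mvec, da)
  mod$pars$bd$g <- mod$pars$bd$g + da
  dm <- drop(mod$pars$Wd$v %*% da)
  du <- du_direct + matrix(dm / cc$npix, cc$npix, length(dm), byrow = TRUE)
  dxb <- nn_backward(mod$subs$block, nn_act(du, cc$u$sp))
  nn_act(dy$v + dxb$v, dy$sp)
}

# Residual group: n CABs followed by a convolution, wrapped by a short skip.
nn_rg <- function(channels, n_cab, reduction = 4L, dims = 2L, slope = 0.3) {
  cabs <- lapply(seq_len(n_cab), function(i) nn_cab(channels, reduction, dims, slope))
  m <- nn_module("nn_rg", subs = list(
    trunk = do.call(nn_sequential, c(cabs, list(nn_conv(channels, channels, 3L, dims))))))
  m
}

nn_forward.nn_rg <- function(mod, x) {
  t <- nn_forward(mod$subs$trunk, x)
  nn_act(x$v + t$v, x$sp)
}

nn_backward.nn_rg <- function(mod, dy) {
  dt <- nn_backward(mod$subs$trunk, dy)
  nn_act(dy$v + dt$v, dy$sp)
}
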