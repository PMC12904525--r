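# Minimal neural-network layer library: convolution (via the compiled
# im2col kernels), depthwise convolution, activations, nearest-neighbor
# up/down sampling, global average pooling, dense layers, and an Adam
# optimizer over nested parameter lists. Every op exposes an explicit
# forward (returning a cache) and backward (returning input and parameter
# gradients); network architectures compose these by hand.

as_cube <- function(x) {
  if (length(dim(x)) == 2L) array(x, dim = c(dim(x), 1L)) else x
}

# ---- parameter initialization -------------------------------------------

he_conv <- function(k, cin, cout, zero = FALSE) {
  fan_in <- k * k * cin
  w <- if (zero) matrix(0, k * k * cin, cout) else
    matrix(rnorm(k * k * cin * cout, 0, sqrt(2 / fan_in)), k * k * cin, cout)
  list(w = w, b = numeric(cout), k = k, cin = cin, cout = cout)
}

he_dense <- function(nin, nout, zero = FALSE) {
  w <- if (zero) matrix(0, nin, nout) else
    matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  list(w = w, b = numeric(nout))
}

dw_identity <- function(k, C) {
  w <- matrix(0, k * k, C)
  center <- (k %/% 2) + (k %/% 2) * k + 1  # ki + kj*k + 1 at kernel center
  w[center, ] <- 1
  list(w = w, b = numeric(C), k = k, C = C)
}

dw_random <- function(k, C, sd = 0.2) {
  p <- dw_identity(k, C)
  p$w <- p$w + matrix(rnorm(k * k * C, 0, sd), k * k, C)
  p
}

# ---- conv / depthwise ----------------------------------------------------

conv_fwd <- function(p, x, stride = 1L, pad = NULL) {
  x <- as_cube(x)
  if (is.null(pad)) pad <- p$k %/% 2
  r <- cpp_conv2d_fwd(x, p$w, p$b, p$k, p$k, as.integer(stride),
                      as.integer(pad))
  list(y = r$y, xc = r$xc, din = dim(x), stride = as.integer(stride),
       pad = as.integer(pad))
}

conv_bwd <- function(p, cache, dy) {
  d <- cache$din
  r <- cpp_conv2d_bwd(cache$xc, p$w, as_cube(dy), d[1], d[2], d[3],
                      p$k, p$k, cache$stride, cache$pad)
  list(dx = r$dx, grads = list(w = r$dw, b = as.numeric(r$db)))
}

dwconv_fwd <- function(p, x, pad = NULL) {
  x <- as_cube(x)
  if (is.null(pad)) pad <- p$k %/% 2
  y <- cpp_dwconv2d_fwd(x, p$w, p$b, p$k, p$k, as.integer(pad))
  list(y = y, x = x, pad = as.integer(pad))
}

dwconv_bwd <- function(p, cache, dy) {
  r <- cpp_dwconv2d_bwd(cache$x, p$w, as_cube(dy), p$k, p$k, cache$pad)
  list(dx = r$dx, grads = list(w = r$dw, b = as.numeric(r$db)))
}

# ---- activations ---------------------------------------------------------

relu_fwd <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_bwd <- function(cache, dy) dy * cache$mask

lrelu_fwd <- function(x, alpha = 0.2) {
  list(y = ifelse(x > 0, x, alpha * x), mask = x > 0, alpha = alpha)
}
lrelu_bwd <- function(cache, dy) dy * ifelse(cache$mask, 1, cache$alpha)

sigmoid_fwd <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y)
}
sigmoid_bwd <- function(cache, dy) dy * cache$y * (1 - cache$y)

softplus_fwd <- function(x) list(y = softplus(x), x = x)
softplus_bwd <- function(cache, dy) dy * sigmoid(cache$x)

# ---- resampling ----------------------------------------------------------

upsample2_fwd <- function(x) {
  x <- as_cube(x)
  d <- dim(x)
  y <- array(0, dim = c(2 * d[1], 2 * d[2], d[3]))
  r <- rep(seq_len(d[1]), each = 2)
  c <- rep(seq_len(d[2]), each = 2)
  for (ch in seq_len(d[3])) y[, , ch] <- x[r, c, ch]
  list(y = y, din = d)
}

upsample2_bwd <- function(cache, dy) {
  dy <- as_cube(dy)
  d <- cache$din
  dx <- array(0, dim = d)
  r1 <- seq(1, 2 * d[1], 2); c1 <- seq(1, 2 * d[2], 2)
  for (ch in seq_len(d[3])) {
    dx[, , ch] <- dy[r1, c1, ch] + dy[r1 + 1, c1, ch] +
      dy[r1, c1 + 1, ch] + dy[r1 + 1, c1 + 1, ch]
  }
  dx
}

# ---- pooling / dense -----------------------------------------------------

gap_fwd <- function(x) {
  x <- as_cube(x)
  d <- dim(x)
  list(y = apply(x, 3, mean), din = d)
}

gap_bwd <- function(cache, dv) {
  d <- cache$din
  dx <- array(0, dim = d)
  for (ch in seq_len(d[3])) dx[, , ch] <- dv[ch] / (d[1] * d[2])
  dx
}

dense_fwd <- function(p, v) list(y = as.numeric(crossprod(p$w, v) + p$b),
                                 v = v)
dense_bwd <- function(p, cache, dy) {
  list(dx = as.numeric(p$w %*% dy),
       grads = list(w = outer(cache$v, dy), b = dy))
}

# ---- channel concat ------------------------------------------------------

concat_c <- function(a, b) {
  a <- as_cube(a); b <- as_cube(b)
  out <- array(0, dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

split_c <- function(dy, c1) {
  dy <- as_cube(dy)
  list(a = dy[, , seq_len(c1), drop = FALSE],
       b = dy[, , -seq_len(c1), drop = FALSE])
}

# ---- squeeze-and-excitation block ---------------------------------------

se_new <- function(C, reduction = 8) {
  mid <- max(1L, C %/% reduction)
  list(d1 = he_dense(C, mid), d2 = he_dense(mid, C))
}

se_fwd <- function(p, x) {
  x <- as_cube(x)
  g1 <- gap_fwd(x)
  z1 <- dense_fwd(p$d1, g1$y)
  r1 <- relu_fwd(z1$y)
  z2 <- dense_fwd(p$d2, r1$y)
  s2 <- sigmoid_fwd(z2$y)
  gates <- s2$y
  y <- x
  for (ch in seq_len(dim(x)[3])) y[, , ch] <- x[, , ch] * gates[ch]
  list(y = y, x = x, g1 = g1, z1 = z1, r1 = r1, z2 = z2, s2 = s2,
       gates = gates)
}

se_bwd <- function(p, cache, dy) {
  dy <- as_cube(dy)
  x <- cache$x
  C <- dim(x)[3]
  dx <- dy
  dgate <- numeric(C)
  for (ch in seq_len(C)) {
    dx[, , ch] <- dy[, , ch] * cache$gates[ch]
    dgate[ch] <- sum(dy[, , ch] * x[, , ch])
  }
  dz2 <- sigmoid_bwd(cache$s2, dgate)
  b2 <- dense_bwd(p$d2, cache$z2, dz2)
  dr1 <- relu_bwd(cache$r1, b2$dx)
  b1 <- dense_bwd(p$d1, cache$z1, dr1)
  dx <- dx + gap_bwd(cache$g1, b1$dx)
  list(dx = dx, grads = list(d1 = b1$grads, d2 = b2$grads))
}

# ---- Adam over nested parameter lists -----------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(t) tree_map(f, t)) else f(tree)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else {
    f(a, b)
  }
}

# Zero-filled gradient tree matching numeric leaves of a parameter tree
# (non-numeric leaves, e.g. integer shape fields, map to NULL and are
# skipped by the optimizer).
numeric_leaf <- function(x) is.numeric(x) && !is.integer(x)

adam_new <- function(params) {
  list(m = tree_map(function(x) if (numeric_leaf(x)) x * 0 else NULL, params),
       v = tree_map(function(x) if (numeric_leaf(x)) x * 0 else NULL, params),
       t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (!numeric_leaf(p) || is.null(g)) {
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      nm <- names(p)
      for (i in seq_along(p)) {
        # match gradient subtrees by name where available (gradient lists
        # may omit or reorder parameter entries)
        gi <- if (!is.null(nm) && !is.null(names(g)) && nzchar(nm[i])) {
          g[[nm[i]]]
        } else if (i <= length(g)) g[[i]] else NULL
        if (is.null(gi)) next
        r <- walk(p[[i]], gi, m[[i]], v[[i]])
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      upd(p, g, m, v)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

# Accumulate two gradient trees (b may have NULL leaves).
tree_add <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.null(a)) return(b)
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- tree_add(a[[i]], b[[i]])
    a
  } else {
    a + b
  }
}
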