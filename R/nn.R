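# Internal mini neural-network engine.
#
# Activations are (B*H*W) x C matrices in NHWC-flattened layout (row index
# b*H*W + y*W + x, 0-based); convolutions are im2col (Rcpp) + GEMM through
# BLAS. Each forward returns the activation plus a cache consumed by the
# matching backward.

# tensorflow-style 'same' padding: output ceil(in/s), asymmetric pad
same_pad <- function(in_size, k, s) {
  out <- ceiling(in_size / s)
  pad <- max((out - 1L) * s + k - in_size, 0L)
  list(before = pad %/% 2L, after = pad - pad %/% 2L, out = as.integer(out))
}

conv_out_geom <- function(h, w, k, s, padding) {
  if (padding == "same") {
    ph <- same_pad(h, k, s); pw <- same_pad(w, k, s)
    list(ho = ph$out, wo = pw$out, pt = ph$before, pl = pw$before)
  } else {
    list(ho = as.integer((h - k) %/% s + 1L), wo = as.integer((w - k) %/% s + 1L),
         pt = 0L, pl = 0L)
  }
}

# A conv with very few output kernels (the stem) takes a direct path: the
# im2col buffer would be far larger than the input and the GEMM is tiny.
# `cols` lets callers share one im2col between convs over the same input
# with identical geometry (a residual branch and its projection shortcut).
conv_fw <- function(X, B, h, w, Wmat, k, s, padding, cols = NULL,
                    need_dx = TRUE) {
  g <- conv_out_geom(h, w, k, s, padding)
  if (is.null(cols) && ncol(Wmat) <= 4L && !need_dx) {
    out <- nn_conv_direct_fw(X, Wmat, B, h, w, k, k, s, s,
                             g$pt, g$pl, g$ho, g$wo)
    return(list(out = out, ho = g$ho, wo = g$wo,
                cache = list(direct = TRUE, X = X, Wmat = Wmat, B = B,
                             h = h, w = w, cin = ncol(X), k = k, s = s, g = g)))
  }
  if (is.null(cols))
    cols <- nn_im2col(X, B, h, w, k, k, s, s, g$pt, g$pl, g$ho, g$wo)
  out <- cols %*% Wmat
  list(out = out, ho = g$ho, wo = g$wo,
       cache = list(direct = FALSE, cols = cols, Wmat = Wmat, B = B, h = h,
                    w = w, cin = ncol(X), k = k, s = s, g = g))
}

conv_bw <- function(dY, cache, need_dx = TRUE) {
  if (isTRUE(cache$direct)) {
    dW <- nn_conv_direct_dw(cache$X, dY, cache$B, cache$h, cache$w,
                            cache$k, cache$k, cache$s, cache$s,
                            cache$g$pt, cache$g$pl, cache$g$ho, cache$g$wo)
    return(list(dX = NULL, dW = dW))
  }
  dW <- crossprod(cache$cols, dY)
  dX <- NULL
  if (need_dx) {
    dcols <- dY %*% t(cache$Wmat)
    dX <- nn_col2im(dcols, cache$B, cache$h, cache$w, cache$cin,
                    cache$k, cache$k, cache$s, cache$s,
                    cache$g$pt, cache$g$pl, cache$g$ho, cache$g$wo)
  }
  list(dX = dX, dW = dW)
}

bn_fw <- function(X, gamma, beta, run_mean, run_var, training,
                  momentum = 0.9, eps = 1e-5) {
  if (training) {
    st <- bn_stats(X)
    mu <- st$mu; v <- st$var
    new_mean <- momentum * run_mean + (1 - momentum) * mu
    new_var <- momentum * run_var + (1 - momentum) * v
  } else {
    mu <- run_mean; v <- run_var
    new_mean <- run_mean; new_var <- run_var
  }
  inv_std <- 1 / sqrt(v + eps)
  ap <- bn_apply(X, mu, inv_std, gamma, beta)
  list(out = ap$out, run_mean = new_mean, run_var = new_var,
       cache = list(xhat = ap$xhat, inv_std = inv_std, gamma = gamma))
}

bn_bw <- function(dY, cache) {
  bn_backward(dY, cache$xhat, cache$inv_std, cache$gamma)
}

relu_fw <- function(X) {
  out <- X * (X > 0)
  list(out = out, cache = X > 0)
}

relu_bw <- function(dY, cache) dY * cache

# squash applied row-wise with cache for the backward Jacobian
squash_rows_fw <- function(S) {
  n2 <- rowSums(S^2)
  n <- sqrt(n2)
  g <- ifelse(n > 1e-12, n / (1 + n2), 0)
  list(out = S * g, cache = list(S = S, n = n, n2 = n2, g = g))
}

squash_rows_bw <- function(dV, cache) {
  n <- cache$n; n2 <- cache$n2; g <- cache$g; S <- cache$S
  gp <- (1 - n2) / (1 + n2)^2
  coef <- ifelse(n > 1e-12, gp / n, 0)
  dV * g + S * (coef * rowSums(S * dV))
}
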