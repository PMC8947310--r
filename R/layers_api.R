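# Single-image layer operations. These expose the network's building blocks
# on plain H x W x C arrays; the training engine uses the batched internals
# in nn.R / model.R directly.

default_conv_weights <- function(cin, k, m, seed, bn = TRUE) {
  with_local_seed(derive_seed(seed, 23L), {
    w <- list(W = matrix(rnorm(m * m * cin * k, sd = sqrt(2 / (m * m * cin))),
                         m * m * cin, k))
    if (bn) { w$g <- rep(1, k); w$b <- rep(0, k) }
    w
  })
}

run_conv_bn_relu <- function(x, w, k, m, s, padding, relu, training = TRUE) {
  h <- dim(x)[1]; wd <- dim(x)[2]
  cf <- conv_fw(img_to_rows(x), 1L, h, wd, w$W, m, s, padding)
  bf <- bn_fw(cf$out, w$g, w$b, rep(0, k), rep(1, k), training)
  out <- if (relu) relu_fw(bf$out)$out else bf$out
  rows_to_img(out, cf$ho, cf$wo)
}

#' Conv-BN-ReLU forward pass on one image
#'
#' A convolution ('same' padding, no bias), batch normalization, then ReLU.
#' Output spatial size is `ceiling(input / stride)`.
#'
#' @param x Input array H x W x C.
#' @param kernels Number of convolution kernels k.
#' @param kernel_size Kernel side m (default 3).
#' @param stride Stride s (default 1).
#' @param weights Optional list with `W` (an `(m*m*C) x k` matrix), `g`,
#'   `b` (batch-norm scale/shift); seeded He-normal defaults otherwise.
#' @param seed Seed for default weights.
#' @return Array `ceil(H/s) x ceil(W/s) x k`, elementwise nonnegative.
#' @export
conv_bn_relu_forward <- function(x, kernels, kernel_size = 3, stride = 1,
                                 weights = NULL, seed = 1L) {
  stopifnot(length(dim(x)) == 3L)
  if (is.null(weights))
    weights <- default_conv_weights(dim(x)[3], kernels, kernel_size, seed)
  if (nrow(weights$W) != kernel_size^2 * dim(x)[3])
    abort("weight shape does not match the input channels.",
          class = "tonguecaps_dimension_error")
  run_conv_bn_relu(x, weights, kernels, kernel_size, stride, "same", TRUE)
}

#' Residual block forward pass on one image
#'
#' The branch is Conv-BN-ReLU followed by Conv-BN; the result is added to a
#' shortcut copy of the input — the identity for variant `"a"` (which
#' therefore requires unchanged channels and stride 1), a convolved
#' projection (stride `s`, `kernels` kernels, Conv-BN) for variant `"b"` —
#' and passed through a final ReLU. With `use_shortcuts = FALSE` the
#' shortcut is dropped and the block reduces to its branch (the
#' shortcut-ablated form).
#'
#' @param x Input array H x W x C.
#' @param variant `"a"` (identity shortcut) or `"b"` (projection shortcut).
#' @param kernels Output channels k.
#' @param kernel_size Kernel side (default 3).
#' @param stride Stride of the first branch conv and the projection.
#' @param use_shortcuts Keep the shortcut connection (default TRUE).
#' @param weights Optional list of lists `c1`, `c2`, `sc`, each as in
#'   [conv_bn_relu_forward()].
#' @param seed Seed for default weights.
#' @return Array `ceil(H/s) x ceil(W/s) x kernels`.
#' @export
residual_forward <- function(x, variant = c("a", "b"), kernels,
                             kernel_size = 3, stride = 1,
                             use_shortcuts = TRUE, weights = NULL, seed = 1L) {
  variant <- match.arg(variant)
  cin <- dim(x)[3]
  if (variant == "a" && (cin != kernels || stride != 1))
    abort("variant a requires unchanged channels and stride 1.",
          class = "tonguecaps_config_error")
  if (is.null(weights)) {
    weights <- list(
      c1 = default_conv_weights(cin, kernels, kernel_size, derive_seed(seed, 1L)),
      c2 = default_conv_weights(kernels, kernels, kernel_size, derive_seed(seed, 2L)),
      sc = default_conv_weights(cin, kernels, kernel_size, derive_seed(seed, 3L)))
  }
  br <- run_conv_bn_relu(x, weights$c1, kernels, kernel_size, stride, "same", TRUE)
  br <- run_conv_bn_relu(br, weights$c2, kernels, kernel_size, 1L, "same", FALSE)
  if (use_shortcuts) {
    sc <- if (variant == "a") x
          else run_conv_bn_relu(x, weights$sc, kernels, kernel_size, stride,
                                "same", FALSE)
    br <- br + sc
  }
  br * (br > 0)
}

#' Primary Caps forward pass on one feature map
#'
#' Applies `units` independent groups of `kernels` 3x3 stride-1 'valid'
#' convolutions, flattens each group's `(H-2) x (W-2) x kernels` map into
#' one vector, and squashes each vector, yielding `units` primary capsules.
#'
#' @param features Input array H x W x C with `H, W >=` `kernel_size`.
#' @param units Number of capsule units (default 8).
#' @param kernels Kernels per unit (default 32).
#' @param kernel_size Kernel side (default 3).
#' @param weights Optional `(kernel_size^2 * C) x (units*kernels)` matrix.
#' @param seed Seed for default weights.
#' @return Matrix `units x ((H-2)*(W-2)*kernels)` of squashed capsule
#'   vectors (rows), every row norm `< 1`.
#' @export
primary_caps_forward <- function(features, units = 8, kernels = 32,
                                 kernel_size = 3, weights = NULL, seed = 1L) {
  h <- dim(features)[1]; w <- dim(features)[2]; cin <- dim(features)[3]
  if (h < kernel_size || w < kernel_size)
    abort("spatial size smaller than the kernel.",
          class = "tonguecaps_dimension_error")
  if (is.null(weights))
    weights <- default_conv_weights(cin, units * kernels, kernel_size, seed,
                                    bn = FALSE)$W
  cf <- conv_fw(img_to_rows(features), 1L, h, w, weights,
                kernel_size, 1L, "valid")
  d <- cf$ho * cf$wo * kernels
  U <- matrix(0, units, d)
  for (u in seq_len(units)) {
    cols_u <- (u - 1L) * kernels + seq_len(kernels)
    U[u, ] <- cf$out[, cols_u]
  }
  squash_rows_fw(U)$out
}

#' Class Caps forward pass
#'
#' Transforms the primary capsules into per-class prediction vectors
#' ([predict_vectors()]) and couples them by dynamic routing
#' ([dynamic_routing()]).
#'
#' @param primary Matrix `N_in x D_in` of primary capsule vectors (rows).
#' @param num_classes Number of class capsules (default 5).
#' @param capsule_dim Dimension of each class capsule (default 16).
#' @param r Routing iterations (default 3).
#' @param weights Optional `N_in x num_classes x D_in x capsule_dim` array.
#' @param seed Seed for default weights.
#' @return List with `v` (matrix `num_classes x capsule_dim`), `lengths`,
#'   and the routing `state`.
#' @export
class_caps_forward <- function(primary, num_classes = 5, capsule_dim = 16,
                               r = 3, weights = NULL, seed = 1L) {
  if (!is.matrix(primary)) primary <- matrix(primary, nrow = 1)
  n_in <- nrow(primary); d_in <- ncol(primary)
  if (is.null(weights)) {
    lim <- sqrt(6 / (d_in + capsule_dim))
    weights <- with_local_seed(derive_seed(seed, 29L),
      array(runif(n_in * num_classes * d_in * capsule_dim, -lim, lim),
            dim = c(n_in, num_classes, d_in, capsule_dim)))
  }
  u_hat <- predict_vectors(primary, weights)
  rt <- dynamic_routing(u_hat, r)
  list(v = rt$v, lengths = capsule_lengths(rt$v), state = rt$state)
}
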