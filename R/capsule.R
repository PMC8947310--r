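#' Squash nonlinearity
#'
#' Compresses a vector's length into `[0, 1)` while preserving its
#' direction: `v = (|s|^2 / (1 + |s|^2)) * s / |s|`. The zero vector maps
#' to the zero vector.
#'
#' @param s Numeric vector, or a matrix whose rows are squashed
#'   independently.
#' @return Object of the same shape.
#' @export
#' @examples
#' sqrt(sum(squash(c(1, 0))^2)) # 0.5
#' sqrt(sum(squash(c(3, 0))^2)) # 0.9
squash <- function(s) {
  if (is.matrix(s)) {
    n2 <- rowSums(s^2)
    scale <- ifelse(n2 > 0, n2 / (1 + n2) / sqrt(n2), 0)
    return(s * scale)
  }
  n2 <- sum(s^2)
  if (n2 == 0) return(s * 0)
  s * (n2 / (1 + n2) / sqrt(n2))
}

#' Prediction vectors from capsule outputs
#'
#' Computes the prediction each input capsule i makes for each output
#' capsule j: `u_hat[j|i] = W[i,j] %*% u[i]` — one transform matrix per
#' (input, output) capsule pair.
#'
#' @param u Matrix `N_in x D_in` of input capsule vectors (rows).
#' @param W Array `N_in x N_out x D_in x D_out` of transform matrices.
#' @return Array `N_in x N_out x D_out` of prediction vectors.
#' @export
predict_vectors <- function(u, W) {
  if (!is.matrix(u)) u <- matrix(u, nrow = 1)
  dW <- dim(W)
  if (length(dW) != 4L || dW[1] != nrow(u) || dW[3] != ncol(u))
    abort("`W` must be N_in x N_out x D_in x D_out matching `u`.",
          class = "tonguecaps_dimension_error")
  n_in <- dW[1]; n_out <- dW[2]; d_out <- dW[4]
  u_hat <- array(0, dim = c(n_in, n_out, d_out))
  for (i in seq_len(n_in)) {
    for (j in seq_len(n_out)) {
      u_hat[i, j, ] <- u[i, ] %*% W[i, j, , ]
    }
  }
  u_hat
}

#' Coupling coefficients from routing logits
#'
#' Softmax of the logits over the output capsules, per input capsule:
#' `c[i, j] = exp(b[i, j]) / sum_j exp(b[i, j])`.
#'
#' @param b Matrix `N_in x N_out` of routing logits.
#' @return Matrix of couplings; each row is nonnegative and sums to 1.
#' @export
#' @examples
#' coupling_from_logits(matrix(0, 2, 3)) # uniform 1/3
coupling_from_logits <- function(b) {
  if (!is.matrix(b)) b <- matrix(b, nrow = 1)
  e <- exp(b - apply(b, 1, max)) # shift-invariant, overflow-safe
  e / rowSums(e)
}

#' Dynamic routing by agreement
#'
#' Iteratively couples input capsules to output capsules. Logits start at
#' zero; each iteration computes couplings by [coupling_from_logits()],
#' forms the weighted sums `s_j = sum_i c_ij u_hat[j|i]`, squashes them into
#' output vectors `v_j`, and (on all but the last iteration) reinforces the
#' logits by the agreement `b_ij <- b_ij + u_hat[j|i] . v_j`.
#'
#' @param u_hat Array `N_in x N_out x D_out` of prediction vectors.
#' @param r Number of routing iterations (>= 1, default 3).
#' @return List with `v` (matrix `N_out x D_out` of output capsules) and
#'   `state` (list with final `b`, `c`, `s`, and `iterations`).
#' @export
dynamic_routing <- function(u_hat, r = 3L) {
  if (r < 1) abort("`r` must be >= 1.", class = "tonguecaps_invalid_parameter")
  d <- dim(u_hat)
  if (length(d) != 3L)
    abort("`u_hat` must be N_in x N_out x D_out.",
          class = "tonguecaps_dimension_error")
  n_in <- d[1]; n_out <- d[2]; d_out <- d[3]
  b <- matrix(0, n_in, n_out)
  cc <- coupling_from_logits(b)
  s <- matrix(0, n_out, d_out)
  v <- matrix(0, n_out, d_out)
  for (it in seq_len(r)) {
    cc <- coupling_from_logits(b)
    for (j in seq_len(n_out)) {
      uh_j <- matrix(u_hat[, j, ], nrow = n_in)
      s[j, ] <- colSums(uh_j * cc[, j])
      v[j, ] <- squash(s[j, ])
    }
    if (it < r) {
      for (j in seq_len(n_out)) {
        uh_j <- matrix(u_hat[, j, ], nrow = n_in)
        b[, j] <- b[, j] + drop(uh_j %*% v[j, ])
      }
    }
  }
  list(v = v, state = list(b = b, c = cc, s = s, iterations = r))
}

#' Lengths of capsule output vectors
#'
#' Euclidean norm of each capsule vector; the length encodes the
#' probability that the class entity is present.
#'
#' @param v Matrix `N x D` of capsule vectors (rows), or a single vector.
#' @return Numeric vector of `N` norms.
#' @export
#' @examples
#' capsule_lengths(rbind(c(3, 4), c(0, 0))) # 5, 0
capsule_lengths <- function(v) {
  if (!is.matrix(v)) v <- matrix(v, nrow = 1)
  sqrt(rowSums(v^2))
}

#' Classify by maximum capsule length
#'
#' Returns the index of the longest capsule; ties are broken towards the
#' lowest index.
#'
#' @param lengths Numeric vector of capsule lengths (>= 1 element).
#' @return Integer index in `1..length(lengths)`.
#' @export
classify_lengths <- function(lengths) {
  if (length(lengths) < 1)
    abort("`lengths` must be non-empty.", class = "tonguecaps_invalid_input")
  which.max(lengths)
}

#' Margin-loss parameters
#'
#' @param m_plus Margin for the present class (default 0.9).
#' @param m_minus Margin for absent classes (default 0.1).
#' @param lambda Down-weight for absent-class terms (default 0.5).
#' @return A named list.
#' @export
margin_loss_params <- function(m_plus = 0.9, m_minus = 0.1, lambda = 0.5) {
  stopifnot(0 < m_minus, m_minus < m_plus, m_plus < 1, lambda > 0)
  list(m_plus = m_plus, m_minus = m_minus, lambda = lambda)
}

#' Margin loss for capsule classification
#'
#' Per-class hinge-squared loss summed over the classes:
#' `L = sum_k T_k max(0, m+ - |v_k|)^2 +
#'      lambda (1 - T_k) max(0, |v_k| - m-)^2`.
#' It is zero exactly when the correct class capsule is at least `m+` long
#' and every other capsule is at most `m-` long.
#'
#' @param lengths Capsule lengths, one per class.
#' @param target One-hot numeric vector of the same cardinality.
#' @param params See [margin_loss_params()].
#' @return Nonnegative scalar loss.
#' @export
#' @examples
#' margin_loss(c(0.9, 0.1, 0.1), c(1, 0, 0)) # 0
margin_loss <- function(lengths, target, params = margin_loss_params()) {
  if (length(lengths) != length(target))
    abort("`lengths` and `target` must have the same cardinality.",
          class = "tonguecaps_dimension_error")
  pos <- pmax(0, params$m_plus - lengths)^2
  neg <- pmax(0, lengths - params$m_minus)^2
  sum(target * pos + params$lambda * (1 - target) * neg)
}
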