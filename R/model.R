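#' TongueCaps architecture specification
#'
#' Builds the declarative layer list of the TongueCaps network: a 7x7
#' Conv-BN-ReLU stem, 3x3 max-pooling (stride 2), six residual blocks in
#' three channel stages, a Primary Caps layer (8 units of 32-kernel 3x3
#' 'valid' convolutions, outputs squashed into 8 capsules), and a Class Caps
#' layer routed by agreement, finished by a vector-length head. Stage three
#' changes the channel count at stride 1, so its first block carries a
#' projection (convolved) shortcut; blocks that preserve their input shape
#' use identity shortcuts (variant a).
#'
#' @param input_size Input image side length (images are `side x side x 3`
#'   after [resize_pad()]), default 128.
#' @param in_channels Input channels, default 3.
#' @param stem_kernels Kernels in the stem convolution, default 3.
#' @param stage_channels Channels of the three residual stages, default
#'   `c(64, 128, 256)`.
#' @param num_classes Number of output classes (default 5).
#' @param class_capsule_dim Dimension of each class capsule (default 16).
#' @param routing_iterations Dynamic-routing iterations (default 3).
#' @param primary_units Primary Caps units (default 8).
#' @param primary_kernels Kernels per Primary Caps unit (default 32).
#' @param use_shortcuts Keep the residual shortcut connections. Setting
#'   `FALSE` gives the shortcut-ablated twin (a plain convolutional stack in
#'   front of the capsule layers) with identical shape trace.
#' @return A `tonguecaps_spec` object.
#' @export
#' @examples
#' spec <- tonguecaps_spec()
#' trace_shapes(spec)
tonguecaps_spec <- function(input_size = 128, in_channels = 3,
                            stem_kernels = 3, stage_channels = c(64, 128, 256),
                            num_classes = 5, class_capsule_dim = 16,
                            routing_iterations = 3, primary_units = 8,
                            primary_kernels = 32, use_shortcuts = TRUE) {
  st <- as.integer(stage_channels)
  layers <- tibble::tribble(
    ~name,      ~kind,          ~kernels,     ~kernel_size, ~stride, ~units,        ~padding,
    "stem",     "conv_bn_relu", as.integer(stem_kernels), 7L, 1L,    NA_integer_,   "same",
    "pool",     "maxpool",      NA_integer_,  3L,           2L,      NA_integer_,   "same",
    "res_b1",   "residual_b",   st[1],        3L,           2L,      NA_integer_,   "same",
    "res_a1",   "residual_a",   st[1],        3L,           1L,      NA_integer_,   "same",
    "res_b2",   "residual_b",   st[2],        3L,           2L,      NA_integer_,   "same",
    "res_a2",   "residual_a",   st[2],        3L,           1L,      NA_integer_,   "same",
    "res_b3",   "residual_b",   st[3],        3L,           1L,      NA_integer_,   "same",
    "res_a3",   "residual_a",   st[3],        3L,           1L,      NA_integer_,   "same",
    "primary",  "primary_caps", as.integer(primary_kernels), 3L, 1L, as.integer(primary_units), "valid",
    "caps",     "class_caps",   NA_integer_,  NA_integer_,  NA_integer_, as.integer(num_classes), NA_character_,
    "length",   "length_head",  NA_integer_,  NA_integer_,  NA_integer_, NA_integer_, NA_character_
  )
  structure(list(layers = layers,
                 input_shape = c(as.integer(input_size), as.integer(input_size),
                                 as.integer(in_channels)),
                 num_classes = as.integer(num_classes),
                 class_capsule_dim = as.integer(class_capsule_dim),
                 routing_iterations = as.integer(routing_iterations),
                 use_shortcuts = isTRUE(use_shortcuts)),
            class = "tonguecaps_spec")
}

#' @export
print.tonguecaps_spec <- function(x, ...) {
  cat(sprintf("<tonguecaps_spec> input %dx%dx%d, %d classes, shortcuts %s\n",
              x$input_shape[1], x$input_shape[2], x$input_shape[3],
              x$num_classes, if (x$use_shortcuts) "on" else "off"))
  print(trace_shapes(x))
  invisible(x)
}

#' Propagate output shapes through an architecture
#'
#' Symbolic shape propagation, without instantiating any weights. Feature
#' maps are `H x W x C`; capsule layers report `count x dimension`.
#'
#' @param spec A [tonguecaps_spec()].
#' @return Tibble with columns `layer`, `kind`, `out_h`, `out_w`, `out_c`,
#'   `caps_n`, `caps_d`, `shape` (a compact string like `"32x32x64"` or
#'   `"8x6272"`).
#' @export
trace_shapes <- function(spec) {
  stopifnot(inherits(spec, "tonguecaps_spec"))
  h <- spec$input_shape[1]; w <- spec$input_shape[2]; c <- spec$input_shape[3]
  caps_n <- NA_integer_; caps_d <- NA_integer_
  rows <- purrr::pmap(spec$layers, function(name, kind, kernels, kernel_size,
                                            stride, units, padding) {
    if (kind %in% c("conv_bn_relu", "maxpool", "residual_a", "residual_b")) {
      g <- conv_out_geom(h, w, kernel_size, stride, padding)
      if (kind == "residual_a") {
        if (kernels != c)
          abort(sprintf("identity-shortcut block `%s` cannot change channels %d -> %d",
                        name, c, kernels),
                class = "tonguecaps_config_error")
        if (stride != 1L)
          abort(sprintf("identity-shortcut block `%s` requires stride 1", name),
                class = "tonguecaps_config_error")
      }
      h <<- g$ho; w <<- g$wo
      if (kind != "maxpool") c <<- kernels
      tibble::tibble(layer = name, kind = kind, out_h = h, out_w = w, out_c = c,
                     caps_n = NA_integer_, caps_d = NA_integer_,
                     shape = sprintf("%dx%dx%d", h, w, c))
    } else if (kind == "primary_caps") {
      if (h < kernel_size || w < kernel_size)
        abort("Primary Caps input smaller than its kernel.",
              class = "tonguecaps_dimension_error")
      g <- conv_out_geom(h, w, kernel_size, stride, padding)
      caps_n <<- units
      caps_d <<- g$ho * g$wo * kernels
      h <<- g$ho; w <<- g$wo; c <<- units * kernels
      tibble::tibble(layer = name, kind = kind, out_h = NA_integer_,
                     out_w = NA_integer_, out_c = NA_integer_,
                     caps_n = caps_n, caps_d = caps_d,
                     shape = sprintf("%dx%d", caps_n, caps_d))
    } else if (kind == "class_caps") {
      caps_n <<- units
      caps_d <<- spec$class_capsule_dim
      tibble::tibble(layer = name, kind = kind, out_h = NA_integer_,
                     out_w = NA_integer_, out_c = NA_integer_,
                     caps_n = caps_n, caps_d = caps_d,
                     shape = sprintf("%dx%d", caps_n, caps_d))
    } else { # length_head
      tibble::tibble(layer = name, kind = kind, out_h = NA_integer_,
                     out_w = NA_integer_, out_c = NA_integer_,
                     caps_n = spec$num_classes, caps_d = 1L,
                     shape = sprintf("%d", spec$num_classes))
    }
  })
  dplyr::bind_rows(rows)
}

# shared walk over the conv stack collecting per-layer geometry used by
# build/count/flops; returns tibble of primitive conv descriptors
conv_plan <- function(spec) {
  tr <- trace_shapes(spec)
  h <- spec$input_shape[1]; w <- spec$input_shape[2]; cin <- spec$input_shape[3]
  out <- list()
  for (i in seq_len(nrow(spec$layers))) {
    L <- spec$layers[i, ]
    if (L$kind == "conv_bn_relu") {
      out[[length(out) + 1]] <- tibble::tibble(
        name = paste0(L$name, ".c1"), layer = L$name, cin = cin, k = L$kernels,
        m = L$kernel_size, s = L$stride, padding = L$padding,
        in_h = h, in_w = w, bn = TRUE)
    } else if (L$kind %in% c("residual_a", "residual_b")) {
      out[[length(out) + 1]] <- tibble::tibble(
        name = paste0(L$name, ".c1"), layer = L$name, cin = cin, k = L$kernels,
        m = L$kernel_size, s = L$stride, padding = L$padding,
        in_h = h, in_w = w, bn = TRUE)
      g <- conv_out_geom(h, w, L$kernel_size, L$stride, L$padding)
      out[[length(out) + 1]] <- tibble::tibble(
        name = paste0(L$name, ".c2"), layer = L$name, cin = L$kernels,
        k = L$kernels, m = L$kernel_size, s = 1L, padding = L$padding,
        in_h = g$ho, in_w = g$wo, bn = TRUE)
      if (L$kind == "residual_b" && spec$use_shortcuts) {
        out[[length(out) + 1]] <- tibble::tibble(
          name = paste0(L$name, ".sc"), layer = L$name, cin = cin,
          k = L$kernels, m = L$kernel_size, s = L$stride, padding = L$padding,
          in_h = h, in_w = w, bn = TRUE)
      }
    } else if (L$kind == "primary_caps") {
      out[[length(out) + 1]] <- tibble::tibble(
        name = "primary.c1", layer = L$name, cin = cin,
        k = L$units * L$kernels, m = L$kernel_size, s = L$stride,
        padding = L$padding, in_h = h, in_w = w, bn = FALSE)
    }
    if (!is.na(tr$out_h[i])) { h <- tr$out_h[i]; w <- tr$out_w[i]; cin <- tr$out_c[i] }
    else if (tr$kind[i] == "primary_caps") {
      g <- conv_out_geom(h, w, L$kernel_size, L$stride, L$padding)
      h <- g$ho; w <- g$wo; cin <- L$units * L$kernels
    }
  }
  dplyr::bind_rows(out)
}

caps_dims <- function(spec) {
  tr <- trace_shapes(spec)
  pc <- tr[tr$kind == "primary_caps", ]
  list(n_in = pc$caps_n, d_in = pc$caps_d,
       n_out = spec$num_classes, d_out = spec$class_capsule_dim)
}

#' Count trainable parameters of an architecture
#'
#' Analytic per-layer counts: a convolution contributes
#' `kernels * m^2 * C_in` weights (no bias — every conv except Primary Caps
#' is followed by batch norm, whose shift makes a bias redundant; Primary
#' Caps is kept bias-free for symmetry) plus `2 * kernels` batch-norm
#' scale/shift parameters where batch norm is present; the Class Caps layer
#' contributes one `D_in x D_out` matrix per (input capsule, class) pair.
#' The total equals the instantiated model's trainable-weight count exactly.
#'
#' @param spec A [tonguecaps_spec()].
#' @return Total parameter count (numeric scalar) with a `by_layer`
#'   attribute tibble.
#' @export
count_parameters <- function(spec) {
  plan <- conv_plan(spec)
  conv_counts <- plan$k * plan$m^2 * plan$cin + ifelse(plan$bn, 2 * plan$k, 0)
  cd <- caps_dims(spec)
  caps_count <- cd$n_in * cd$n_out * cd$d_in * cd$d_out
  by_layer <- dplyr::bind_rows(
    tibble::tibble(name = plan$name, params = conv_counts),
    tibble::tibble(name = "caps.W", params = caps_count))
  total <- sum(by_layer$params)
  attr(total, "by_layer") <- by_layer
  total
}

#' Estimate multiply-accumulate FLOPs of an architecture
#'
#' Analytic per-sample compute estimate under a documented convention: one
#' multiply-accumulate counts as one FLOP; convolutions contribute
#' `Ho * Wo * m^2 * C_in * kernels`, the Class Caps transform contributes
#' `N_in * N_out * D_in * D_out`, and each routing iteration adds the
#' weighted-sum work `N_in * N_out * D_out`. Elementwise work (batch norm,
#' ReLU, pooling, shortcut additions, squash) is excluded. `convention =
#' "madd2"` doubles the multiply-accumulate terms (multiply and add counted
#' separately).
#'
#' @param spec A [tonguecaps_spec()].
#' @param convention `"mac"` (default) or `"madd2"`.
#' @return Total FLOPs (numeric scalar) with a `by_layer` attribute tibble.
#' @export
estimate_flops <- function(spec, convention = c("mac", "madd2")) {
  convention <- match.arg(convention)
  plan <- conv_plan(spec)
  geom <- purrr::pmap(plan, function(in_h, in_w, m, s, padding, ...)
    conv_out_geom(in_h, in_w, m, s, padding))
  ho <- vapply(geom, `[[`, integer(1), "ho")
  wo <- vapply(geom, `[[`, integer(1), "wo")
  conv_macs <- as.numeric(ho) * wo * plan$m^2 * plan$cin * plan$k
  cd <- caps_dims(spec)
  caps_macs <- cd$n_in * cd$n_out * cd$d_in * cd$d_out +
    spec$routing_iterations * cd$n_in * cd$n_out * cd$d_out
  mult <- if (convention == "madd2") 2 else 1
  by_layer <- dplyr::bind_rows(
    tibble::tibble(name = plan$name, flops = mult * conv_macs),
    tibble::tibble(name = "caps", flops = mult * caps_macs))
  total <- sum(by_layer$flops)
  attr(total, "by_layer") <- by_layer
  total
}

#' Instantiate a TongueCaps model with seeded weights
#'
#' Convolution weights use He-normal initialization, batch-norm scales start
#' at 1 and shifts at 0, and the Class Caps transform matrices use
#' Glorot-uniform initialization. The same seed always produces identical
#' weights.
#'
#' @param spec A [tonguecaps_spec()].
#' @param seed Integer seed.
#' @return A `tonguecaps_model` (weights, batch-norm running statistics,
#'   and the layer plan).
#' @export
build_model <- function(spec, seed = 1L) {
  plan <- conv_plan(spec)
  cd <- caps_dims(spec)
  params <- list(); state <- list()
  with_local_seed(derive_seed(seed, 17L), {
    for (i in seq_len(nrow(plan))) {
      p <- plan[i, ]
      fan_in <- p$m^2 * p$cin
      params[[paste0(p$name, ".W")]] <-
        matrix(rnorm(fan_in * p$k, sd = sqrt(2 / fan_in)), fan_in, p$k)
      if (p$bn) {
        params[[paste0(p$name, ".g")]] <- rep(1, p$k)
        params[[paste0(p$name, ".b")]] <- rep(0, p$k)
        state[[paste0(p$name, ".rm")]] <- rep(0, p$k)
        state[[paste0(p$name, ".rv")]] <- rep(1, p$k)
      }
    }
    lim <- sqrt(6 / (cd$d_in + cd$d_out))
    for (u in seq_len(cd$n_in)) {
      params[[paste0("caps.W", u)]] <-
        matrix(runif(cd$d_in * cd$n_out * cd$d_out, -lim, lim),
               cd$d_in, cd$n_out * cd$d_out)
    }
  })
  structure(list(spec = spec, params = params, state = state,
                 plan = plan, caps = cd, seed = as.integer(seed)),
            class = "tonguecaps_model")
}

#' @export
print.tonguecaps_model <- function(x, ...) {
  cat(sprintf("<tonguecaps_model> %s parameters, seed %d\n",
              format(sum(vapply(x$params, length, numeric(1))), big.mark = ","),
              x$seed))
  invisible(x)
}

# ---- image <-> activation-row layout -------------------------------------

img_to_rows <- function(img) {
  d <- dim(img)
  matrix(aperm(img, c(2, 1, 3)), nrow = d[1] * d[2])
}

rows_to_img <- function(rows, h, w) {
  aperm(array(rows, dim = c(w, h, ncol(rows))), c(2, 1, 3))
}

stack_images <- function(imgs) do.call(rbind, lapply(imgs, img_to_rows))

# ---- full network forward / backward -------------------------------------

conv_bn_relu_block_fw <- function(X, B, h, w, nm, params, state, training,
                                  k, m, s, padding, relu = TRUE,
                                  cols = NULL, need_dx = TRUE) {
  cf <- conv_fw(X, B, h, w, params[[paste0(nm, ".W")]], m, s, padding,
                cols = cols, need_dx = need_dx)
  bf <- bn_fw(cf$out, params[[paste0(nm, ".g")]], params[[paste0(nm, ".b")]],
              state[[paste0(nm, ".rm")]], state[[paste0(nm, ".rv")]], training)
  state[[paste0(nm, ".rm")]] <- bf$run_mean
  state[[paste0(nm, ".rv")]] <- bf$run_var
  if (relu) {
    rf <- relu_fw(bf$out)
    out <- rf$out; rc <- rf$cache
  } else {
    out <- bf$out; rc <- NULL
  }
  list(out = out, ho = cf$ho, wo = cf$wo, state = state,
       cache = list(conv = cf$cache, bn = bf$cache, relu = rc, nm = nm))
}

conv_bn_relu_block_bw <- function(dY, cache, grads, need_dx = TRUE) {
  if (!is.null(cache$relu)) dY <- relu_bw(dY, cache$relu)
  bb <- bn_bw(dY, cache$bn)
  grads[[paste0(cache$nm, ".g")]] <- bb$dgamma
  grads[[paste0(cache$nm, ".b")]] <- bb$dbeta
  cb <- conv_bw(bb$dX, cache$conv, need_dx = need_dx)
  grads[[paste0(cache$nm, ".W")]] <- cb$dW
  list(dX = cb$dX, grads = grads)
}

model_forward <- function(model, X, B, training = FALSE) {
  spec <- model$spec
  params <- model$params
  state <- model$state
  cd <- model$caps
  layers <- spec$layers
  h <- spec$input_shape[1]; w <- spec$input_shape[2]
  caches <- vector("list", nrow(layers))
  v <- NULL; lengths <- NULL
  for (i in seq_len(nrow(layers))) {
    L <- layers[i, ]
    if (L$kind == "conv_bn_relu") {
      f <- conv_bn_relu_block_fw(X, B, h, w, paste0(L$name, ".c1"),
                                 params, state, training,
                                 L$kernels, L$kernel_size, L$stride, L$padding,
                                 need_dx = (i != 1L))
      X <- f$out; h <- f$ho; w <- f$wo; state <- f$state
      caches[[i]] <- list(kind = L$kind, block = f$cache)
    } else if (L$kind == "maxpool") {
      g <- conv_out_geom(h, w, L$kernel_size, L$stride, L$padding)
      mp <- nn_maxpool_fw(X, B, h, w, L$kernel_size, L$kernel_size,
                          L$stride, L$stride, g$pt, g$pl, g$ho, g$wo)
      caches[[i]] <- list(kind = L$kind, idx = mp$idx, n_in = nrow(X))
      X <- mp$out; h <- g$ho; w <- g$wo
    } else if (L$kind %in% c("residual_a", "residual_b")) {
      shared_cols <- NULL
      if (spec$use_shortcuts && L$kind == "residual_b") {
        g <- conv_out_geom(h, w, L$kernel_size, L$stride, L$padding)
        shared_cols <- nn_im2col(X, B, h, w, L$kernel_size, L$kernel_size,
                                 L$stride, L$stride, g$pt, g$pl, g$ho, g$wo)
      }
      f1 <- conv_bn_relu_block_fw(X, B, h, w, paste0(L$name, ".c1"),
                                  params, state, training,
                                  L$kernels, L$kernel_size, L$stride, L$padding,
                                  cols = shared_cols)
      state <- f1$state
      f2 <- conv_bn_relu_block_fw(f1$out, B, f1$ho, f1$wo, paste0(L$name, ".c2"),
                                  params, state, training,
                                  L$kernels, L$kernel_size, 1L, L$padding,
                                  relu = FALSE)
      state <- f2$state
      sc_cache <- NULL
      if (spec$use_shortcuts) {
        if (L$kind == "residual_a") {
          total <- f2$out + X
        } else {
          fs <- conv_bn_relu_block_fw(X, B, h, w, paste0(L$name, ".sc"),
                                      params, state, training,
                                      L$kernels, L$kernel_size, L$stride,
                                      L$padding, relu = FALSE,
                                      cols = shared_cols)
          state <- fs$state
          sc_cache <- fs$cache
          total <- f2$out + fs$out
        }
      } else {
        total <- f2$out
      }
      rf <- relu_fw(total)
      caches[[i]] <- list(kind = L$kind, b1 = f1$cache, b2 = f2$cache,
                          sc = sc_cache, relu = rf$cache)
      X <- rf$out; h <- f1$ho; w <- f1$wo
    } else if (L$kind == "primary_caps") {
      cf <- conv_fw(X, B, h, w, params[["primary.c1.W"]],
                    L$kernel_size, L$stride, L$padding)
      ho <- cf$ho; wo <- cf$wo
      d_in <- ho * wo * L$kernels
      # group columns into units, flatten each unit's map into one vector
      Um <- matrix(0, B * cd$n_in, d_in)
      for (b in seq_len(B)) {
        rows_b <- (b - 1L) * ho * wo + seq_len(ho * wo)
        for (u in seq_len(cd$n_in)) {
          cols_u <- (u - 1L) * L$kernels + seq_len(L$kernels)
          Um[(b - 1L) * cd$n_in + u, ] <- cf$out[rows_b, cols_u]
        }
      }
      sq <- squash_rows_fw(Um)
      caches[[i]] <- list(kind = L$kind, conv = cf$cache, squash = sq$cache,
                          ho = ho, wo = wo, kern = L$kernels)
      X <- sq$out # (B*n_in) x d_in, squashed primary capsules
    } else if (L$kind == "class_caps") {
      # prediction vectors per unit, then per-sample dynamic routing
      uhat <- array(0, dim = c(B, cd$n_in, cd$n_out * cd$d_out))
      Ul <- vector("list", cd$n_in)
      for (u in seq_len(cd$n_in)) {
        Uu <- X[(seq_len(B) - 1L) * cd$n_in + u, , drop = FALSE]
        Ul[[u]] <- Uu
        uhat[, u, ] <- Uu %*% params[[paste0("caps.W", u)]]
      }
      v <- array(0, dim = c(B, cd$n_out, cd$d_out))
      couplings <- array(0, dim = c(B, cd$n_in, cd$n_out))
      s_sums <- array(0, dim = c(B, cd$n_out, cd$d_out))
      for (b in seq_len(B)) {
        uh <- array(uhat[b, , ], dim = c(cd$n_in, cd$n_out, cd$d_out))
        rt <- dynamic_routing(uh, spec$routing_iterations)
        v[b, , ] <- rt$v
        couplings[b, , ] <- rt$state$c
        s_sums[b, , ] <- rt$state$s
      }
      caches[[i]] <- list(kind = L$kind, U = Ul, c = couplings, s = s_sums)
    } else if (L$kind == "length_head") {
      lengths <- sqrt(apply(v^2, c(1, 2), sum))
      caches[[i]] <- list(kind = L$kind, v = v, lengths = lengths)
    }
  }
  list(lengths = lengths, v = v, caches = caches, state = state)
}

model_backward <- function(model, fw, dlengths) {
  spec <- model$spec
  cd <- model$caps
  layers <- spec$layers
  grads <- list()
  dX <- NULL
  for (i in rev(seq_len(nrow(layers)))) {
    L <- layers[i, ]
    cache <- fw$caches[[i]]
    if (L$kind == "length_head") {
      v <- cache$v; len <- cache$lengths
      dv <- array(0, dim = dim(v))
      safe <- ifelse(len > 1e-12, 1 / len, 0)
      for (j in seq_len(dim(v)[2]))
        dv[, j, ] <- v[, j, ] * (dlengths[, j] * safe[, j])
      dX <- dv
    } else if (L$kind == "class_caps") {
      B <- dim(dX)[1]
      duhat <- array(0, dim = c(B, cd$n_in, cd$n_out * cd$d_out))
      for (b in seq_len(B)) {
        s_b <- matrix(cache$s[b, , ], cd$n_out, cd$d_out)
        n2 <- rowSums(s_b^2); n <- sqrt(n2)
        sq_cache <- list(S = s_b, n = n, n2 = n2,
                         g = ifelse(n > 1e-12, n / (1 + n2), 0))
        ds_b <- squash_rows_bw(matrix(dX[b, , ], cd$n_out, cd$d_out), sq_cache)
        cc <- matrix(cache$c[b, , ], cd$n_in, cd$n_out)
        for (u in seq_len(cd$n_in)) {
          # column (j, d) of the prediction layout is j + (d-1)*n_out, i.e.
          # the column-major flattening of the n_out x d_out matrix
          duhat[b, u, ] <- as.vector(ds_b * cc[u, ])
        }
      }
      dU <- matrix(0, B * cd$n_in, ncol(cache$U[[1]]))
      for (u in seq_len(cd$n_in)) {
        dUu_hat <- matrix(duhat[, u, ], B, cd$n_out * cd$d_out)
        grads[[paste0("caps.W", u)]] <- crossprod(cache$U[[u]], dUu_hat)
        dU[(seq_len(B) - 1L) * cd$n_in + u, ] <-
          dUu_hat %*% t(model$params[[paste0("caps.W", u)]])
      }
      dX <- dU
    } else if (L$kind == "primary_caps") {
      dUm <- squash_rows_bw(dX, cache$squash)
      B <- nrow(dUm) / cd$n_in
      ho <- cache$ho; wo <- cache$wo; kern <- cache$kern
      dConv <- matrix(0, B * ho * wo, cd$n_in * kern)
      for (b in seq_len(B)) {
        rows_b <- (b - 1L) * ho * wo + seq_len(ho * wo)
        for (u in seq_len(cd$n_in)) {
          cols_u <- (u - 1L) * kern + seq_len(kern)
          dConv[rows_b, cols_u] <-
            matrix(dUm[(b - 1L) * cd$n_in + u, ], ho * wo, kern)
        }
      }
      cb <- conv_bw(dConv, cache$conv)
      grads[["primary.c1.W"]] <- cb$dW
      dX <- cb$dX
    } else if (L$kind %in% c("residual_a", "residual_b")) {
      dTotal <- relu_bw(dX, cache$relu)
      b2 <- conv_bn_relu_block_bw(dTotal, cache$b2, grads)
      grads <- b2$grads
      b1 <- conv_bn_relu_block_bw(b2$dX, cache$b1, grads)
      grads <- b1$grads
      dX <- b1$dX
      if (spec$use_shortcuts) {
        if (L$kind == "residual_a") {
          dX <- dX + dTotal
        } else {
          sb <- conv_bn_relu_block_bw(dTotal, cache$sc, grads)
          grads <- sb$grads
          dX <- dX + sb$dX
        }
      }
    } else if (L$kind == "maxpool") {
      dX <- nn_maxpool_bw(dX, cache$idx, cache$n_in)
    } else if (L$kind == "conv_bn_relu") {
      b <- conv_bn_relu_block_bw(dX, cache$block, grads, need_dx = (i != 1L))
      grads <- b$grads
      dX <- b$dX
    }
  }
  grads
}

# margin loss (batch mean) and its gradient w.r.t. the lengths matrix
margin_loss_batch <- function(lengths, targets, params = margin_loss_params()) {
  pos <- pmax(0, params$m_plus - lengths)
  neg <- pmax(0, lengths - params$m_minus)
  per_sample <- rowSums(targets * pos^2 + params$lambda * (1 - targets) * neg^2)
  B <- nrow(lengths)
  dlengths <- (-2 * targets * pos + 2 * params$lambda * (1 - targets) * neg) / B
  list(loss = mean(per_sample), dlengths = dlengths)
}

#' Class-capsule lengths for a batch of images
#'
#' Runs the full forward pass in inference mode (batch-norm running
#' statistics) and returns one capsule length per class per image.
#'
#' @param model A [build_model()] result.
#' @param imgs List of H x W x C input arrays (preprocessed model inputs,
#'   e.g. HSV in `[0, 1]`), all matching the spec's input shape.
#' @return Matrix `length(imgs) x num_classes` of capsule lengths in
#'   `[0, 1)`.
#' @export
model_lengths <- function(model, imgs) {
  X <- stack_images(imgs)
  model_forward(model, X, length(imgs), training = FALSE)$lengths
}
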