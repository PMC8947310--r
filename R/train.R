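#' Reference per-class split counts of the clinical composition
#'
#' The fixed per-class train/validation/test counts used throughout the
#' package's examples: the composition of the 1371-image clinical dataset
#' the architecture was developed on. These exact counts are not the result
#' of any single rounding rule applied to an 8:2 ratio, so they ship as a
#' literal override table; ratio-based splitting is the general path.
#'
#' @return Tibble with columns `label`, `train`, `val`, `test`.
#' @export
tongue_split_counts <- function() {
  tibble::tribble(
    ~label,        ~train, ~val, ~test,
    "light_red",   244L,   62L,  76L,
    "red",         200L,   50L,  62L,
    "deep_red",    66L,    17L,  21L,
    "light_white", 196L,   49L,  59L,
    "cyan",        172L,   43L,  54L
  )
}

#' Stratified train/validation/test split
#'
#' Partitions a manifest per class by a seeded shuffle. Either ratios or an
#' exact per-class count table drive the partition; the result is disjoint
#' and exhaustive within every class.
#'
#' @param manifest Data frame with `path` and `label` columns.
#' @param ratios Named numeric `c(train=, val=, test=)` summing to 1; the
#'   train and val counts are rounded half-up, test takes the remainder.
#'   Default `c(train = 0.8, val = 0, test = 0.2)`.
#' @param counts Optional override tibble (`label`, `train`, `val`, `test`)
#'   with exact counts per class, e.g. [tongue_split_counts()]; when given,
#'   `ratios` is ignored and the per-class counts must sum to the class
#'   totals.
#' @param seed Integer seed for the shuffles.
#' @return The manifest as a tibble with an added `split` column
#'   (`"train"`, `"val"`, `"test"`).
#' @export
split_dataset <- function(manifest, ratios = c(train = 0.8, val = 0, test = 0.2),
                          counts = NULL, seed = 1L) {
  manifest <- tibble::as_tibble(manifest)
  pieces <- split(manifest, manifest$label)
  out <- purrr::imap(pieces, function(df, label) {
    n <- nrow(df)
    if (!is.null(counts)) {
      row <- counts[counts$label == label, ]
      if (nrow(row) != 1L)
        abort(paste0("no split counts for class ", label),
              class = "tonguecaps_config_error")
      n_tr <- row$train; n_va <- row$val; n_te <- row$test
      if (n_tr + n_va + n_te != n)
        abort(sprintf("split counts for %s (%d) do not sum to the class total (%d)",
                      label, n_tr + n_va + n_te, n),
              class = "tonguecaps_config_error")
    } else {
      n_tr <- as.integer(round_half_up(n * ratios[["train"]]))
      n_va <- as.integer(round_half_up(n * ratios[["val"]]))
      if (n_tr + n_va > n)
        abort("split ratios exceed the class total.",
              class = "tonguecaps_config_error")
      n_te <- n - n_tr - n_va
    }
    ord <- with_local_seed(derive_seed(seed, match(label, names(pieces))),
                           sample.int(n))
    df <- df[ord, ]
    df$split <- rep(c("train", "val", "test"), times = c(n_tr, n_va, n_te))
    df
  })
  dplyr::bind_rows(out)
}

#' Hyperparameter grid
#'
#' The default grid spans learning rates 0.1 / 0.001 / 0.0001, SGD and Adam,
#' and batch sizes 8 / 16 / 32 / 64 / 128 — 30 combinations.
#'
#' @param learning_rates,optimizers,batch_sizes Grid axes (nonempty).
#' @return Tibble with one row per combination, in deterministic order.
#' @export
hyper_grid <- function(learning_rates = c(0.1, 0.001, 0.0001),
                       optimizers = c("sgd", "adam"),
                       batch_sizes = c(8L, 16L, 32L, 64L, 128L)) {
  if (!length(learning_rates) || !length(optimizers) || !length(batch_sizes))
    abort("empty grid axis.", class = "tonguecaps_config_error")
  tidyr::expand_grid(lr = learning_rates, optimizer = optimizers,
                     batch_size = as.integer(batch_sizes))
}

#' Grid search with k-fold cross-validation
#'
#' Evaluates every grid point by k-fold cross-validation on the training
#' pool and returns the configuration with the highest mean validation
#' accuracy. Ties break deterministically towards the smaller learning
#' rate, SGD before Adam, then the smaller batch size.
#'
#' @param n Size of the training pool (folds partition `1..n`).
#' @param trainer Function `(config, train_idx, val_idx) -> accuracy`;
#'   `config` is a one-row tibble with `lr`, `optimizer`, `batch_size`.
#' @param grid A [hyper_grid()] tibble.
#' @param folds Number of folds (>= 2, default 5).
#' @param seed Seed for the fold assignment.
#' @return List with `best` (one-row tibble) and `results` (grid plus
#'   `mean_accuracy`).
#' @export
grid_search_cv <- function(n, trainer, grid = hyper_grid(), folds = 5L,
                           seed = 1L) {
  if (nrow(grid) == 0) abort("empty grid.", class = "tonguecaps_config_error")
  if (folds < 2) abort("`folds` must be >= 2.", class = "tonguecaps_config_error")
  fold_id <- with_local_seed(derive_seed(seed, 3L),
                             sample(rep_len(seq_len(folds), n)))
  accs <- purrr::map_dbl(seq_len(nrow(grid)), function(g) {
    cfg <- grid[g, ]
    mean(purrr::map_dbl(seq_len(folds), function(f) {
      trainer(cfg, which(fold_id != f), which(fold_id == f))
    }))
  })
  results <- dplyr::mutate(grid, mean_accuracy = accs)
  ranked <- dplyr::arrange(results, dplyr::desc(.data$mean_accuracy),
                           .data$lr, match(.data$optimizer, c("sgd", "adam")),
                           .data$batch_size)
  list(best = ranked[1, c("lr", "optimizer", "batch_size")], results = results)
}

#' Load a manifest's images as model inputs
#'
#' Reads every image, optionally jitters its brightness (the factors are
#' cycled across images, in manifest order), letterboxes it to
#' `side x side`, and converts to HSV in `[0, 1]` — the network's input
#' representation.
#'
#' @param manifest Tibble with `path` and `label` columns.
#' @param side Input side length.
#' @param hsv Convert to HSV (default TRUE).
#' @param brightness Optional vector of power-law factors in `[0.25, 4]`
#'   applied cyclically before resizing (e.g. `c(0.5, 1, 1.5)` for a
#'   mixed-brightness test set); `NULL` leaves images unchanged.
#' @param labels Class levels; defaults to [tongue_classes()] restricted to
#'   the labels present.
#' @return List with `x` (list of arrays), `y` (integer class ids), and
#'   `labels` (the level set).
#' @export
load_tongue_inputs <- function(manifest, side = 64, hsv = TRUE,
                               brightness = NULL, labels = NULL) {
  manifest <- tibble::as_tibble(manifest)
  if (is.null(labels))
    labels <- intersect(tongue_classes(), unique(manifest$label))
  x <- purrr::imap(manifest$path, function(p, i) {
    img <- read_image(p)
    if (!is.null(brightness))
      img <- adjust_brightness(img, brightness[(i - 1L) %% length(brightness) + 1L])
    img <- resize_pad(img, side)
    if (hsv) rgb_to_hsv(img) else img / 255
  })
  list(x = x, y = match(manifest$label, labels), labels = labels)
}

make_optimizer <- function(kind = c("sgd", "adam"), lr) {
  kind <- match.arg(kind)
  list(kind = kind, lr = lr, t = 0L, m = list(), v = list(),
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

optimizer_step <- function(opt, params, grads) {
  if (opt$kind == "sgd") {
    for (nm in names(grads)) params[[nm]] <- params[[nm]] - opt$lr * grads[[nm]]
    return(list(opt = opt, params = params))
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(opt$m[[nm]])) { opt$m[[nm]] <- g * 0; opt$v[[nm]] <- g * 0 }
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(opt = opt, params = params)
}

batch_loss <- function(model, xr, y, num_classes, batch_size = 32L) {
  n <- length(xr)
  total <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- model_forward(model, do.call(rbind, xr[idx]), length(idx),
                        training = FALSE)
    tg <- matrix(0, length(idx), num_classes)
    tg[cbind(seq_along(idx), y[idx])] <- 1
    total <- total + margin_loss_batch(fw$lengths, tg)$loss * length(idx)
  }
  total / n
}

#' Train a TongueCaps model by margin loss
#'
#' Mini-batch training of the capsule network on preprocessed inputs,
#' minimizing the batch-mean margin loss. Fully seeded: weight
#' initialization and the per-epoch data order derive from `seed`, so the
#' same inputs and configuration reproduce the same fit bit for bit.
#' Training aborts with a diagnostic if the loss turns non-finite.
#'
#' @param x List of input arrays (see [load_tongue_inputs()]).
#' @param y Integer class ids in `1..num_classes`.
#' @param spec A [tonguecaps_spec()]; its input shape must match `x`.
#' @param epochs Number of epochs (default 12).
#' @param batch_size Mini-batch size (default 16).
#' @param lr Learning rate (default 0.001).
#' @param optimizer `"adam"` (default) or `"sgd"`.
#' @param val_x,val_y Optional validation inputs; validation loss is logged
#'   per epoch when given.
#' @param seed Integer seed.
#' @param labels Optional class level names carried into the fit.
#' @param verbose Print per-epoch losses.
#' @return A `tonguecaps_fit`: the trained model, a `history` tibble
#'   (`epoch`, `train_loss`, `val_loss`), and the training configuration.
#' @export
train_tonguecaps <- function(x, y, spec, epochs = 12L, batch_size = 16L,
                             lr = 0.001, optimizer = "adam",
                             val_x = NULL, val_y = NULL, seed = 1L,
                             labels = NULL, verbose = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  xr <- lapply(x, img_to_rows)          # convert once, reuse every epoch
  val_xr <- if (!is.null(val_x)) lapply(val_x, img_to_rows)
  model <- build_model(spec, seed = seed)
  opt <- make_optimizer(optimizer, lr)
  k <- spec$num_classes
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- with_local_seed(derive_seed(seed, 1000L + ep), sample(length(x)))
    ep_loss <- 0; n_seen <- 0
    for (start in seq(1L, length(ord), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, length(ord))]
      X <- do.call(rbind, xr[idx])
      fw <- model_forward(model, X, length(idx), training = TRUE)
      model$state <- fw$state
      tg <- matrix(0, length(idx), k)
      tg[cbind(seq_along(idx), y[idx])] <- 1
      ml <- margin_loss_batch(fw$lengths, tg)
      if (!is.finite(ml$loss))
        abort(sprintf("training diverged at epoch %d (loss %s)", ep, ml$loss),
              class = "tonguecaps_divergence")
      grads <- model_backward(model, fw, ml$dlengths)
      step <- optimizer_step(opt, model$params, grads)
      opt <- step$opt
      model$params <- step$params
      ep_loss <- ep_loss + ml$loss * length(idx)
      n_seen <- n_seen + length(idx)
    }
    val_loss <- if (!is.null(val_x))
      batch_loss(model, val_xr, val_y, k) else NA_real_
    history[[ep]] <- tibble::tibble(epoch = ep, train_loss = ep_loss / n_seen,
                                    val_loss = val_loss)
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %s", ep, ep_loss / n_seen,
                      ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss))))
  }
  structure(list(model = model, history = dplyr::bind_rows(history),
                 config = list(epochs = epochs, batch_size = batch_size,
                               lr = lr, optimizer = optimizer, seed = seed),
                 labels = labels),
            class = "tonguecaps_fit")
}

#' @export
print.tonguecaps_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf("<tonguecaps_fit> %d epochs (%s, lr %g, batch %d); final train loss %.4f\n",
              x$config$epochs, x$config$optimizer, x$config$lr,
              x$config$batch_size, h$train_loss))
  invisible(x)
}

#' Predict classes or capsule lengths
#'
#' @param object A `tonguecaps_fit`.
#' @param x List of input arrays.
#' @param type `"class"` (default) for maximum-length labels, `"lengths"`
#'   for the raw per-class capsule lengths.
#' @param batch_size Evaluation batch size.
#' @param ... Unused.
#' @return Integer class ids (or a character vector when the fit carries
#'   labels), or a lengths matrix.
#' @export
predict.tonguecaps_fit <- function(object, x, type = c("class", "lengths"),
                                   batch_size = 32L, ...) {
  type <- match.arg(type)
  n <- length(x)
  xr <- lapply(x, img_to_rows)
  lens <- matrix(0, n, object$model$spec$num_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    lens[idx, ] <- model_forward(object$model, do.call(rbind, xr[idx]),
                                 length(idx), training = FALSE)$lengths
  }
  if (type == "lengths") return(lens)
  cls <- apply(lens, 1, classify_lengths)
  if (!is.null(object$labels)) object$labels[cls] else cls
}
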