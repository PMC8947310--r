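tiny_spec <- function(...) {
  tonguecaps_spec(input_size = 32, stage_channels = c(4, 6, 8),
                  class_capsule_dim = 4, ...)
}

tiny_data <- function(n_per_class = 4, seed = 21, side = 32) {
  man <- local_synth_manifest(setNames(rep(n_per_class, 5), tongue_classes()),
                              seed = seed, size = c(40, 34),
                              env = parent.frame())
  load_tongue_inputs(man, side = side)
}

test_that("split_dataset reproduces the reference clinical division exactly", {
  totals <- c(light_red = 382, red = 312, deep_red = 104, light_white = 304,
              cyan = 269)
  man <- dplyr::bind_rows(purrr::imap(totals, function(n, lab)
    tibble::tibble(path = sprintf("%s_%04d.png", lab, seq_len(n)), label = lab)))
  sp <- split_dataset(man, counts = tongue_split_counts(), seed = 1)
  got <- as.data.frame(table(sp$label, sp$split))
  ref <- tongue_split_counts()
  for (lab in names(totals)) {
    expect_equal(sum(sp$label == lab & sp$split == "train"),
                 ref$train[ref$label == lab])
    expect_equal(sum(sp$label == lab & sp$split == "val"),
                 ref$val[ref$label == lab])
    expect_equal(sum(sp$label == lab & sp$split == "test"),
                 ref$test[ref$label == lab])
  }
  # partition is disjoint and exhaustive
  expect_setequal(sp$path, man$path)
  expect_equal(anyDuplicated(sp$path), 0L)
})

test_that("ratio splits round half-up and are seed-deterministic", {
  man <- tibble::tibble(path = sprintf("p%02d", 1:10), label = "red")
  sp <- split_dataset(man, ratios = c(train = 0.8, val = 0, test = 0.2), seed = 3)
  expect_equal(sum(sp$split == "train"), 8)
  expect_equal(sum(sp$split == "test"), 2)
  sp2 <- split_dataset(man, ratios = c(train = 0.8, val = 0, test = 0.2), seed = 3)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(man, ratios = c(train = 0.8, val = 0, test = 0.2), seed = 4)
  expect_false(identical(sp$split[order(sp$path)], sp3$split[order(sp3$path)]))
  bad <- tongue_split_counts(); bad$train[1] <- bad$train[1] + 1L
  totals <- c(light_red = 382, red = 312, deep_red = 104, light_white = 304,
              cyan = 269)
  manb <- dplyr::bind_rows(purrr::imap(totals, function(n, lab)
    tibble::tibble(path = sprintf("%s_%04d.png", lab, seq_len(n)), label = lab)))
  expect_error(split_dataset(manb, counts = bad),
               class = "tonguecaps_config_error")
})

test_that("the default hyperparameter grid spans 30 combinations", {
  g <- hyper_grid()
  expect_equal(nrow(g), 30)
  expect_equal(nrow(dplyr::distinct(g)), 30)
})

test_that("grid search recovers a planted optimum and breaks ties deterministically", {
  # accuracy is a known function peaking at lr = 0.001, adam, batch 32
  trainer <- function(cfg, train_idx, val_idx) {
    1 - abs(log10(cfg$lr) + 3) / 10 +
      0.05 * (cfg$optimizer == "adam") - 0.001 * abs(cfg$batch_size - 32)
  }
  out <- grid_search_cv(50, trainer, folds = 5, seed = 2)
  expect_equal(out$best$lr, 0.001)
  expect_equal(out$best$optimizer, "adam")
  expect_equal(out$best$batch_size, 32L)
  expect_equal(nrow(out$results), 30)
  # single-point grid returns that point
  g1 <- hyper_grid(0.05, "sgd", 16)
  expect_equal(grid_search_cv(10, trainer, grid = g1, folds = 2)$best$lr, 0.05)
  # constant accuracy: smallest lr, sgd first, smallest batch
  flat <- grid_search_cv(20, function(cfg, a, b) 0.5, folds = 2)
  expect_equal(flat$best$lr, 1e-4)
  expect_equal(flat$best$optimizer, "sgd")
  expect_equal(flat$best$batch_size, 8L)
  # folds partition the pool
  expect_error(grid_search_cv(10, trainer, folds = 1),
               class = "tonguecaps_config_error")
})

test_that("training logs per-epoch losses and lr = 0 leaves weights untouched", {
  d <- tiny_data()
  fit0 <- train_tonguecaps(d$x[1:10], d$y[1:10], tiny_spec(), epochs = 1,
                           batch_size = 5, lr = 0, optimizer = "sgd", seed = 5,
                           val_x = d$x[11:14], val_y = d$y[11:14])
  expect_equal(nrow(fit0$history), 1)
  expect_true(is.finite(fit0$history$val_loss))
  ref <- build_model(tiny_spec(), seed = 5)
  for (nm in names(ref$params))
    expect_equal(fit0$model$params[[nm]], ref$params[[nm]])
})

test_that("training reduces the margin loss and is bit-reproducible", {
  d <- tiny_data(6)
  run <- function() train_tonguecaps(d$x, d$y, tiny_spec(), epochs = 4,
                                     batch_size = 10, lr = 0.002, seed = 7,
                                     labels = d$labels)
  fit <- run()
  expect_lt(fit$history$train_loss[4], fit$history$train_loss[1])
  fit2 <- run()
  expect_identical(fit$history, fit2$history)
  expect_identical(predict(fit, d$x[1:5]), predict(fit2, d$x[1:5]))
  cm <- evaluate_tonguecaps(fit, d$x, d$y)
  expect_equal(sum(cm), length(d$x))
})

test_that("confusion matrices count (truth, prediction) pairs exactly", {
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"),
                         labels = c("a", "b"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2,
                                   dimnames = list(truth = c("a", "b"),
                                                   pred = c("a", "b"))))
  perfect <- confusion_matrix(1:5, 1:5, labels = 1:5)
  expect_equal(unclass(perfect), diag(1L, 5),  ignore_attr = TRUE)
  constant <- confusion_matrix(rep(1:5, 2), rep(3L, 10), labels = 1:5)
  expect_true(all(unclass(constant)[, -3] == 0))
  expect_error(confusion_matrix(integer(0), integer(0)),
               class = "tonguecaps_invalid_input")
})

test_that("one-vs-rest metrics match the binary-collapse formulas", {
  cm <- confusion_matrix(1:3, 1:3, labels = 1:3)
  for (c in 1:3) {
    m <- one_vs_rest_metrics(cm, c)
    expect_equal(c(m$accuracy, m$sensitivity, m$specificity), c(1, 1, 1))
  }
  cm2 <- structure(matrix(c(8L, 1L, 2L, 9L), 2, 2,
                          dimnames = list(truth = 1:2, pred = 1:2)),
                   class = "confusion_matrix")
  m0 <- one_vs_rest_metrics(cm2, 1)
  expect_equal(m0$accuracy, 0.85)
  expect_equal(m0$sensitivity, 0.8)
  expect_equal(m0$specificity, 0.9)
})

test_that("metric identities hold on random confusion matrices", {
  withr::with_seed(11, {
    for (i in 1:200) {
      k <- sample(2:6, 1)
      cm <- structure(matrix(rpois(k * k, 4), k, k,
                             dimnames = list(truth = 1:k, pred = 1:k)),
                      class = "confusion_matrix")
      if (sum(cm) == 0) next
      n <- sum(cm)
      cls <- sample(k, 1)
      m <- suppressWarnings(one_vs_rest_metrics(cm, cls))
      expect_equal(m$tp + m$fn, sum(cm[cls, ]))
      expect_equal(m$tp + m$fp, sum(cm[, cls]))
      expect_equal(m$tp + m$fn + m$fp + m$tn, n)
      expect_equal(m$accuracy,
                   (n - sum(cm[cls, ]) - sum(cm[, cls]) + 2 * cm[cls, cls]) / n)
    }
  })
})

test_that("absent classes yield NaN sensitivity and are excluded from the macro mean", {
  cm <- structure(matrix(c(5L, 0L, 3L, 0L, 0L, 0L, 1L, 0L, 6L), 3, 3,
                         byrow = TRUE,
                         dimnames = list(truth = 1:3, pred = 1:3)),
                  class = "confusion_matrix")
  expect_warning(m2 <- one_vs_rest_metrics(cm, 2), "undefined")
  expect_true(is.nan(m2$sensitivity))
  per <- suppressWarnings(
    dplyr::bind_rows(lapply(1:3, function(c) one_vs_rest_metrics(cm, c))))
  macro <- macro_average(per)
  expect_equal(macro$sensitivity,
               mean(per$sensitivity[!is.nan(per$sensitivity)]))
  expect_equal(macro_average(tibble::tibble(accuracy = c(1, 0.5),
                                            sensitivity = c(1, 0.5),
                                            specificity = c(1, 0.5)))$accuracy,
               0.75)
  all_nan <- tibble::tibble(accuracy = NaN, sensitivity = NaN, specificity = NaN)
  expect_error(macro_average(all_nan), class = "tonguecaps_invalid_input")
})

test_that("tidiers and autoplot produce well-formed summaries", {
  d <- tiny_data()
  fit <- train_tonguecaps(d$x[1:10], d$y[1:10], tiny_spec(), epochs = 2,
                          batch_size = 5, lr = 0.001, seed = 9,
                          val_x = d$x[11:14], val_y = d$y[11:14],
                          labels = d$labels)
  td <- tidy(fit)
  expect_equal(nrow(td), 4) # 2 epochs x train/val
  expect_named(td, c("epoch", "set", "loss"))
  gl <- glance(fit)
  expect_equal(gl$epochs, 2)
  expect_equal(gl$n_parameters,
               sum(vapply(fit$model$params, length, numeric(1))))
  cm <- evaluate_tonguecaps(fit, d$x, d$y)
  expect_equal(sum(tidy(cm)$n), length(d$x))
  expect_equal(glance(cm)$n, length(d$x))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(cm), "ggplot")
})
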