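reduced_spec <- function(...) {
  tonguecaps_spec(input_size = 64, stage_channels = c(32, 64, 128), ...)
}

test_that("the default architecture trace reproduces the published output shapes", {
  tr <- trace_shapes(tonguecaps_spec())
  expect_equal(tr$shape[1:9],
               c("128x128x3", "64x64x3", "32x32x64", "32x32x64", "16x16x128",
                 "16x16x128", "16x16x256", "16x16x256", "8x6272"))
  expect_equal(tr$shape[10], "5x16")
  # shortcut ablation leaves the trace untouched
  expect_equal(trace_shapes(tonguecaps_spec(use_shortcuts = FALSE)), tr)
})

test_that("identity-shortcut blocks reject channel changes", {
  bad <- tonguecaps_spec()
  bad$layers$kernels[bad$layers$name == "res_a1"] <- 99L
  expect_error(trace_shapes(bad), class = "tonguecaps_config_error")
  x <- array(1, dim = c(8, 8, 4))
  expect_error(residual_forward(x, "a", kernels = 8),
               class = "tonguecaps_config_error")
})

test_that("conv-bn-relu keeps 'same' geometry and nonnegativity", {
  x <- array(runif(128 * 128 * 3), dim = c(128, 128, 3))
  out <- conv_bn_relu_forward(x, kernels = 3, kernel_size = 7, stride = 1)
  expect_equal(dim(out), c(128, 128, 3))
  out2 <- conv_bn_relu_forward(array(1, dim = c(16, 16, 2)), kernels = 5,
                               stride = 2)
  expect_equal(dim(out2), c(8, 8, 5))
  expect_true(all(out >= 0) && all(out2 >= 0))
  zero <- conv_bn_relu_forward(array(0, dim = c(12, 12, 3)), kernels = 4)
  expect_true(all(zero == 0))
})

test_that("residual blocks compute F(x) + shortcut with a final ReLU", {
  x <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  out_b <- residual_forward(x, "b", kernels = 64, stride = 2)
  expect_equal(dim(out_b), c(32, 32, 64))
  xa <- array(runif(16 * 16 * 8, -1, 1), dim = c(16, 16, 8))
  out_a <- residual_forward(xa, "a", kernels = 8)
  expect_equal(dim(out_a), c(16, 16, 8))
  # zeroed branch weights reduce variant a to ReLU(x)
  zw <- function(cin, k, m = 3) list(W = matrix(0, m * m * cin, k),
                                     g = rep(1, k), b = rep(0, k))
  out0 <- residual_forward(xa, "a", kernels = 8,
                           weights = list(c1 = zw(8, 8), c2 = zw(8, 8)))
  expect_equal(out0, xa * (xa > 0))
  # without the shortcut the zero-branch block collapses to zero
  out_ns <- residual_forward(xa, "a", kernels = 8, use_shortcuts = FALSE,
                             weights = list(c1 = zw(8, 8), c2 = zw(8, 8)))
  expect_true(all(out_ns == 0))
})

test_that("Primary Caps flattens unit maps into squashed capsule vectors", {
  f <- array(runif(16 * 16 * 256, -0.5, 0.5), dim = c(16, 16, 256))
  caps <- primary_caps_forward(f)
  expect_equal(dim(caps), c(8, 14 * 14 * 32)) # 8 x 6272
  expect_true(all(capsule_lengths(caps) < 1))
  small <- primary_caps_forward(array(runif(3 * 3 * 4), dim = c(3, 3, 4)))
  expect_equal(dim(small), c(8, 32))
  expect_error(primary_caps_forward(array(0, dim = c(2, 2, 4))),
               class = "tonguecaps_dimension_error")
})

test_that("Class Caps routes primary capsules into one capsule per class", {
  withr::with_seed(10, primary <- matrix(rnorm(8 * 50, sd = 0.3), 8, 50))
  out <- class_caps_forward(primary, num_classes = 5, capsule_dim = 16)
  expect_equal(dim(out$v), c(5, 16))
  expect_true(all(out$lengths >= 0 & out$lengths < 1))
  zero <- class_caps_forward(matrix(0, 8, 50))
  expect_true(all(zero$v == 0))
  expect_equal(zero$state$c, matrix(0.2, 8, 5))
})

test_that("analytic parameter counts equal the instantiated weight counts", {
  for (spec in list(tonguecaps_spec(),
                    reduced_spec(),
                    reduced_spec(use_shortcuts = FALSE))) {
    n_analytic <- as.numeric(count_parameters(spec))
    model <- build_model(spec, seed = 2)
    expect_equal(n_analytic, sum(vapply(model$params, length, numeric(1))))
  }
  # a lone 7x7 conv over 3 channels with batch norm: 3*49*3 + 2*3
  by_layer <- attr(count_parameters(tonguecaps_spec()), "by_layer")
  expect_equal(by_layer$params[by_layer$name == "stem.c1"], 447)
})

test_that("FLOP estimates scale linearly in kernel count", {
  f1 <- attr(estimate_flops(tonguecaps_spec(stem_kernels = 3)), "by_layer")
  f2 <- attr(estimate_flops(tonguecaps_spec(stem_kernels = 6)), "by_layer")
  expect_equal(f2$flops[f2$name == "stem.c1"],
               2 * f1$flops[f1$name == "stem.c1"])
  expect_equal(as.numeric(estimate_flops(tonguecaps_spec(), "madd2")),
               2 * as.numeric(estimate_flops(tonguecaps_spec())))
})

test_that("a forward pass returns per-class capsule lengths in [0, 1)", {
  spec <- tonguecaps_spec() # full 128x128 network
  model <- build_model(spec, seed = 4)
  imgs <- list(rgb_to_hsv(resize_pad(render_tongue("red", 1, c(128, 96)), 128)),
               array(runif(128 * 128 * 3), dim = c(128, 128, 3)))
  lens <- model_lengths(model, imgs)
  expect_equal(dim(lens), c(2, 5))
  expect_true(all(lens >= 0 & lens < 1))
})

test_that("the shortcut flag is wired: ablated twin differs, trace does not", {
  spec <- reduced_spec(routing_iterations = 2)
  spec_ab <- reduced_spec(routing_iterations = 2, use_shortcuts = FALSE)
  m <- build_model(spec, seed = 6)
  m_ab <- build_model(spec_ab, seed = 6)
  # copy every shared (non-shortcut) weight into the ablated twin
  for (nm in names(m_ab$params)) m_ab$params[[nm]] <- m$params[[nm]]
  img <- list(array(runif(64 * 64 * 3), dim = c(64, 64, 3)))
  expect_false(isTRUE(all.equal(model_lengths(m, img),
                                model_lengths(m_ab, img))))
  expect_equal(trace_shapes(spec_ab), trace_shapes(spec))
})
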