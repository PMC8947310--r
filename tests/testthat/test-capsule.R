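test_that("squash matches its closed form and preserves direction", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  v1 <- squash(c(1, 0))
  expect_equal(sqrt(sum(v1^2)), 0.5)
  v3 <- squash(c(0, 3))
  expect_equal(sqrt(sum(v3^2)), 0.9)
  withr::with_seed(4, {
    norms <- sort(runif(50, 0, 10))
    out_norms <- vapply(norms, function(n) sqrt(sum(squash(c(n, 0))^2)), 0)
    expect_true(all(diff(out_norms) > 0)) # strictly increasing in |s|
    expect_true(all(out_norms < 1))
    for (i in 1:10) {
      s <- rnorm(4)
      v <- squash(s)
      cosine <- sum(s * v) / sqrt(sum(s^2) * sum(v^2))
      expect_equal(cosine, 1)
    }
  })
})

test_that("predict_vectors applies one transform matrix per capsule pair", {
  u <- rbind(c(1, 2), c(3, 4))
  W_id <- array(0, dim = c(2, 3, 2, 2))
  for (i in 1:2) for (j in 1:3) W_id[i, j, , ] <- diag(2)
  uh <- predict_vectors(u, W_id)
  for (j in 1:3) expect_equal(uh[, j, ], u)
  expect_equal(predict_vectors(u * 0, W_id), array(0, dim = c(2, 3, 2)))
  W <- array(0, dim = c(1, 1, 2, 2))
  W[1, 1, , ] <- rbind(c(1, 0), c(0, 2))
  expect_equal(as.numeric(predict_vectors(matrix(c(1, 2), 1), W)), c(1, 4))
  expect_error(predict_vectors(u, array(0, dim = c(2, 3, 5, 2))),
               class = "tonguecaps_dimension_error")
})

test_that("coupling softmax is row-normalized, uniform at zero, shift-invariant", {
  cc <- coupling_from_logits(matrix(0, 2, 4))
  expect_equal(cc, matrix(0.25, 2, 4))
  c2 <- coupling_from_logits(matrix(c(log(2), 0), 1, 2))
  expect_equal(as.numeric(c2), c(2 / 3, 1 / 3))
  withr::with_seed(5, {
    b <- matrix(rnorm(12), 3, 4)
    expect_equal(rowSums(coupling_from_logits(b)), rep(1, 3), tolerance = 1e-12)
    expect_equal(coupling_from_logits(b + 7), coupling_from_logits(b))
  })
})

test_that("dynamic routing reduces to closed forms in degenerate cases", {
  withr::with_seed(6, u_hat <- array(rnorm(4 * 1 * 3), dim = c(4, 1, 3)))
  for (r in 1:3) {
    out <- dynamic_routing(u_hat, r)
    expect_equal(out$v[1, ], squash(colSums(u_hat[, 1, ])))
  }
  withr::with_seed(7, uh2 <- array(rnorm(3 * 4 * 2), dim = c(3, 4, 2)))
  one <- dynamic_routing(uh2, 1) # uniform couplings 1/J after one pass
  for (j in 1:4)
    expect_equal(one$v[j, ], squash(colSums(uh2[, j, ]) / 4))
  expect_error(dynamic_routing(uh2, 0), class = "tonguecaps_invalid_parameter")
})

test_that("dynamic routing matches the straight-line oracle on 200 random instances", {
  withr::with_seed(8, {
    worst <- 0
    for (case in 1:200) {
      n_in <- sample(1:8, 1); n_out <- sample(1:4, 1)
      d <- sample(1:4, 1); r <- sample(1:3, 1)
      u_hat <- array(rnorm(n_in * n_out * d, sd = 2), dim = c(n_in, n_out, d))
      got <- dynamic_routing(u_hat, r)$v
      want <- routing_oracle(u_hat, r)
      worst <- max(worst, max(abs(got - want)))
    }
    expect_lt(worst, 1e-9)
  })
})

test_that("agreement routing upweights the capsule the inputs agree on", {
  # two inputs agree on capsule 1 and oppose each other on capsule 2
  u_hat <- array(0, dim = c(2, 2, 2))
  u_hat[1, 1, ] <- c(1, 0); u_hat[2, 1, ] <- c(1, 0)
  u_hat[1, 2, ] <- c(0, 1); u_hat[2, 2, ] <- c(0, -1)
  out <- dynamic_routing(u_hat, 2)
  expect_true(all(out$state$c[, 1] > 0.5))
  expect_equal(rowSums(out$state$c), c(1, 1), tolerance = 1e-12)
})

test_that("capsule lengths and argmax classification behave", {
  expect_equal(capsule_lengths(rbind(c(1, 0, 0), c(3, 4, 0), c(0, 0, 0))),
               c(1, 5, 0))
  expect_equal(classify_lengths(c(0.1, 0.9, 0.2, 0.05, 0.3)), 2L)
  expect_equal(classify_lengths(rep(0.4, 5)), 1L) # ties break low
  expect_equal(classify_lengths(c(0.2, 0.2, 0.8, 0.1, 0.1)), 3L)
  expect_error(classify_lengths(numeric(0)), class = "tonguecaps_invalid_input")
})

test_that("margin loss matches its closed forms and vanishes exactly at the margins", {
  expect_equal(margin_loss(c(0.9, 0.1, 0.1), c(1, 0, 0)), 0)
  expect_equal(margin_loss(c(0, 0.1, 0.1), c(1, 0, 0)), 0.81)
  # one wrong class at 0.6, everything else at its margin: 0.5 * 0.5^2
  expect_equal(margin_loss(c(0.9, 0.6, 0.1), c(1, 0, 0)), 0.125)
  expect_error(margin_loss(c(0.5, 0.5), c(1, 0, 0)),
               class = "tonguecaps_dimension_error")
  withr::with_seed(9, {
    for (i in 1:50) {
      len <- runif(5)
      tgt <- as.numeric(seq_len(5) == sample(5, 1))
      l <- margin_loss(len, tgt)
      expect_gte(l, 0)
      zero_iff <- len[tgt == 1] >= 0.9 && all(len[tgt == 0] <= 0.1)
      expect_equal(l == 0, zero_iff)
    }
  })
})
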