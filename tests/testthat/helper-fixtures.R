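# shared fixtures and independent oracles, built in code

# a small asymmetric, non-uniform RGB test image
fixture_image <- function(h = 20, w = 14, seed = 99) {
  withr::with_seed(seed, {
    img <- array(runif(h * w * 3, 10, 245), dim = c(h, w, 3))
    img[1:3, 1:3, ] <- 250 # break symmetry
    round(img)
  })
}

# straight-line reference implementation of routing by agreement, written
# independently of the package internals (explicit loops, own softmax)
routing_oracle <- function(u_hat, r) {
  n_in <- dim(u_hat)[1]; n_out <- dim(u_hat)[2]; d <- dim(u_hat)[3]
  b <- matrix(0, n_in, n_out)
  v <- matrix(0, n_out, d)
  for (it in seq_len(r)) {
    cc <- matrix(0, n_in, n_out)
    for (i in seq_len(n_in)) {
      e <- exp(b[i, ])
      cc[i, ] <- e / sum(e)
    }
    for (j in seq_len(n_out)) {
      s <- rep(0, d)
      for (i in seq_len(n_in)) s <- s + cc[i, j] * u_hat[i, j, ]
      n2 <- sum(s * s)
      v[j, ] <- if (n2 > 0) (n2 / (1 + n2)) * s / sqrt(n2) else rep(0, d)
    }
    if (it < r) {
      for (i in seq_len(n_in))
        for (j in seq_len(n_out))
          b[i, j] <- b[i, j] + sum(u_hat[i, j, ] * v[j, ])
    }
  }
  v
}

# a synthetic manifest written once per test run
local_synth_manifest <- function(counts, seed = 7, size = c(60, 45),
                                 env = parent.frame()) {
  td <- withr::local_tempdir(.local_envir = env)
  cfg <- synthetic_config(counts = counts, image_size = size, seed = seed)
  generate_dataset(cfg, td)
}
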