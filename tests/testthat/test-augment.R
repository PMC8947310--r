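test_that("rotations are exact array permutations", {
  img <- fixture_image(10, 6)
  r90 <- transform_spec("rot90")
  r180 <- transform_spec("rot180")
  # counter-clockwise quarter turn on a 2x2 pattern [[a,b],[c,d]] -> [[b,d],[a,c]]
  pat <- array(c(1, 3, 2, 4), dim = c(2, 2, 1))
  pat3 <- array(rep(pat, 3), dim = c(2, 2, 3))
  got <- apply_transform(pat3, r90)
  expect_equal(got[, , 1], matrix(c(2, 1, 4, 3), 2, 2))
  # group property: two quarter turns are a half turn
  expect_equal(apply_transform(apply_transform(img, r90), r90),
               apply_transform(img, r180))
  # half turn twice is the identity
  expect_equal(apply_transform(apply_transform(img, r180), r180), img)
})

test_that("shifts move content towards +x/+y, clip, and fill with black", {
  img <- fixture_image(20, 10)
  expect_equal(apply_transform(img, transform_spec("hshift", 0)), img)
  sh <- apply_transform(img, transform_spec("hshift", 0.2)) # 2 of 10 columns
  expect_true(all(sh[, 1:2, ] == 0))
  expect_equal(sh[, 3:10, ], img[, 1:8, ])
  sv <- apply_transform(img, transform_spec("vshift", 0.1)) # 2 of 20 rows
  expect_true(all(sv[1:2, , ] == 0))
  expect_equal(sv[3:20, , ], img[1:18, , ])
})

test_that("brightness transform delegates to the power law and composition nests once", {
  img <- fixture_image()
  t <- transform_spec("brightness", 0.5)
  expect_equal(apply_transform(img, t), adjust_brightness(img, 0.5))
  comp <- transform_spec("rot90", compose_with = transform_spec("brightness", 1.5))
  expect_equal(apply_transform(img, comp),
               adjust_brightness(apply_transform(img, transform_spec("rot90")), 1.5))
  expect_error(transform_spec("rot90", compose_with = comp),
               class = "tonguecaps_invalid_plan")
})

test_that("enumerate_plan yields the canonical ordered pool", {
  expect_equal(format(enumerate_plan(1)[[1]]), "identity")
  p7 <- enumerate_plan(7)
  expect_equal(vapply(p7, format, character(1)),
               c("identity", "rot90", "rot180", "hshift+0.1", "vshift+0.1",
                 "brightness0.5", "brightness1.5"))
  p14 <- enumerate_plan(14)
  nms <- vapply(p14, format, character(1))
  expect_equal(nms[1:7], vapply(p7, format, character(1)))
  expect_equal(anyDuplicated(nms), 0L)
  expect_equal(nms[8], "rot90_brightness0.5") # composites follow the singles
  expect_error(enumerate_plan(1000), class = "tonguecaps_capacity_error")
})

test_that("balance_dataset reproduces the balanced training counts", {
  n_cls <- c(light_red = 244, red = 200, deep_red = 66, light_white = 196,
             cyan = 172)
  man <- dplyr::bind_rows(purrr::imap(n_cls, function(n, lab)
    tibble::tibble(path = sprintf("%s_%03d.png", lab, seq_len(n)), label = lab)))
  aug <- balance_dataset(man) # default multipliers, no image IO
  got <- table(aug$label)[tongue_classes()]
  expect_equal(as.integer(got), c(976L, 1000L, 924L, 980L, 1032L))
  expect_equal(nrow(aug), 4912L)
  # count conservation under arbitrary multipliers
  mult <- c(light_red = 2L, red = 3L, deep_red = 7L, light_white = 1L, cyan = 5L)
  aug2 <- balance_dataset(man, multipliers = mult)
  expect_equal(nrow(aug2), sum(n_cls * mult))
  # all multipliers 1 keeps the manifest unchanged
  ones <- setNames(rep(1L, 5), tongue_classes())
  expect_equal(balance_dataset(man, multipliers = ones)$path, man$path)
  expect_error(balance_dataset(man, multipliers = mult[-1]),
               class = "tonguecaps_config_error")
})

test_that("one source image with m = 3 yields identity, rot90, rot180", {
  man <- tibble::tibble(path = "img.png", label = "red")
  aug <- balance_dataset(man, multipliers = c(red = 3L))
  expect_equal(aug$transform, c("identity", "rot90", "rot180"))
  expect_equal(aug$source, rep("img.png", 3))
})

test_that("written augmentations are pairwise distinct and bit-reproducible", {
  man <- local_synth_manifest(c(deep_red = 1))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  aug1 <- balance_dataset(man, multipliers = c(deep_red = 14L), out_dir = out1)
  aug2 <- balance_dataset(man, multipliers = c(deep_red = 14L), out_dir = out2)
  expect_equal(nrow(aug1), 14)
  pix <- lapply(aug1$path, function(p) as.numeric(read_image(p)))
  for (i in 1:13) for (j in (i + 1):14)
    expect_false(isTRUE(all.equal(pix[[i]], pix[[j]])))
  expect_identical(unname(tools::md5sum(aug1$path)),
                   unname(tools::md5sum(aug2$path)))
})
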