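#' Default class-conditional color palette for synthetic tongues
#'
#' One row per tongue-color class giving the hue/saturation/value box the
#' base tongue color is drawn from, plus the coating speckle density and
#' coating color. The five boxes are pairwise disjoint in (H, S, V), which
#' is what makes the generated classes separable. The values follow the
#' usual clinical descriptions qualitatively — light white is desaturated
#' and bright, light red / red / deep red sit near hue 0 with increasing
#' saturation and decreasing value, cyan sits at hue ~0.5 — but they are
#' configuration, not claims about clinical color ranges.
#'
#' @return Tibble with columns `label`, `h_lo`, `h_hi`, `s_lo`, `s_hi`,
#'   `v_lo`, `v_hi`, `coating_density`, `coat_h`, `coat_s`, `coat_v`.
#' @export
default_palette <- function() {
  tibble::tribble(
    ~label,         ~h_lo, ~h_hi, ~s_lo, ~s_hi, ~v_lo, ~v_hi, ~coating_density, ~coat_h, ~coat_s, ~coat_v,
    "light_red",     0.00,  0.03,  0.35,  0.55,  0.80,  0.95,  0.06,            0.12,    0.15,    0.92,
    "red",           0.00,  0.03,  0.60,  0.85,  0.55,  0.75,  0.04,            0.12,    0.20,    0.85,
    "deep_red",      0.95,  0.99,  0.70,  0.95,  0.30,  0.45,  0.03,            0.10,    0.25,    0.70,
    "light_white",   0.03,  0.08,  0.05,  0.20,  0.85,  0.98,  0.08,            0.14,    0.08,    0.96,
    "cyan",          0.45,  0.55,  0.30,  0.60,  0.50,  0.80,  0.05,            0.40,    0.10,    0.85
  )
}

palette_centers <- function(palette = default_palette()) {
  dplyr::transmute(palette,
    label = .data$label,
    h = (.data$h_lo + .data$h_hi) / 2,
    s = (.data$s_lo + .data$s_hi) / 2,
    v = (.data$v_lo + .data$v_hi) / 2)
}

# deterministic sub-seed from a base seed and stream indices (stays < 2^31)
derive_seed <- function(seed, a, b = 0L) {
  (as.double(seed) * 7919 + a * 104729 + b * 131) %% 2147483629
}

hsv_to_rgb255 <- function(h, s, v) {
  grDevices::col2rgb(grDevices::hsv(pmin(pmax(h, 0), 1),
                                    pmin(pmax(s, 0), 1),
                                    pmin(pmax(v, 0), 1)))
}

#' Render one synthetic tongue image
#'
#' Draws an ellipse-like tongue blob on an exactly-black background. The
#' base color is sampled uniformly from the class's palette box, shaded by a
#' smooth multiplicative radial gradient on the value channel, and speckled
#' with coating spots at the class's density. Identical `(label, seed, size)`
#' give bit-identical images.
#'
#' @param label One of [tongue_classes()].
#' @param seed Integer seed for this image.
#' @param size `c(H, W)` in pixels, both >= 32.
#' @param palette Palette tibble, see [default_palette()].
#' @return RGB array H x W x 3 in 0-255, with logical attributes `mask`
#'   (tongue pixels) and `coating` (coating-speckle pixels).
#' @export
#' @examples
#' img <- render_tongue("cyan", seed = 1, size = c(48, 40))
#' range(img)
render_tongue <- function(label, seed, size = c(120, 90),
                          palette = default_palette()) {
  if (!label %in% palette$label)
    abort(paste0("Unknown label: ", label), class = "tonguecaps_invalid_label")
  h_px <- as.integer(size[1]); w_px <- as.integer(size[2])
  if (h_px < 32L || w_px < 32L)
    abort("size must be at least 32 x 32.", class = "tonguecaps_invalid_input")
  row <- palette[palette$label == label, ]
  with_local_seed(derive_seed(seed, match(label, palette$label)), {
    cy <- h_px * runif(1, 0.45, 0.55)
    cx <- w_px * runif(1, 0.45, 0.55)
    ry <- h_px * runif(1, 0.32, 0.42)
    rx <- w_px * runif(1, 0.30, 0.40)
    yy <- matrix(seq_len(h_px), h_px, w_px)
    xx <- matrix(seq_len(w_px), h_px, w_px, byrow = TRUE)
    # slightly pointed towards the tip (larger exponent above centre)
    d2 <- ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2
    mask <- d2 <= 1
    base_h <- runif(1, row$h_lo, row$h_hi)
    base_s <- runif(1, row$s_lo, row$s_hi)
    base_v <- runif(1, row$v_lo, row$v_hi)
    # multiplicative shading: darker rim, mild low-frequency ripple
    shade <- 1 - 0.22 * d2 +
      0.04 * sin(2 * pi * yy / h_px * runif(1, 1, 3) + runif(1, 0, 2 * pi))
    v_px <- pmin(pmax(base_v * shade, 0.12), 1)
    s_px <- pmin(pmax(base_s * (1 + 0.05 * (d2 - 0.5)), 0), 1)
    # coating speckles: small disks of the coating color inside the mask
    coating <- matrix(FALSE, h_px, w_px)
    area <- sum(mask)
    n_spots <- as.integer(round(row$coating_density * area / 9))
    if (n_spots > 0) {
      ys <- runif(n_spots, cy - 0.7 * ry, cy + 0.7 * ry)
      xs <- runif(n_spots, cx - 0.7 * rx, cx + 0.7 * rx)
      rs <- runif(n_spots, 1, 2.2)
      for (k in seq_len(n_spots)) {
        spot <- (yy - ys[k])^2 + (xx - xs[k])^2 <= rs[k]^2
        coating <- coating | (spot & mask)
      }
    }
    hch <- matrix(base_h, h_px, w_px)
    sch <- s_px
    vch <- v_px
    hch[coating] <- row$coat_h
    sch[coating] <- row$coat_s
    vch[coating] <- row$coat_v
    rgb <- hsv_to_rgb255(hch[mask], sch[mask], vch[mask])
    img <- array(0, dim = c(h_px, w_px, 3L))
    for (c in 1:3) {
      ch <- matrix(0, h_px, w_px)
      ch[mask] <- rgb[c, ]
      img[, , c] <- ch
    }
    # background must stay exactly black, tongue pixels strictly positive
    img[, , 3][mask & img[, , 1] + img[, , 2] + img[, , 3] == 0] <- 1
    attr(img, "mask") <- mask
    attr(img, "coating") <- coating
    img
  })
}

#' Configuration for a synthetic tongue dataset
#'
#' @param counts Named (or unnamed, canonical order) integer vector of
#'   per-class image counts. Defaults to the clinical dataset composition
#'   (382, 312, 104, 304, 269).
#' @param image_size `c(H, W)` nominal size; each image's actual size is
#'   jittered by +/-10 percent (seeded) to emulate the variable acquisition
#'   sizes. Minimum 32.
#' @param seed Integer master seed.
#' @param palette Palette tibble ([default_palette()]).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(counts = c(382L, 312L, 104L, 304L, 269L),
                             image_size = c(120, 90), seed = 1L,
                             palette = default_palette()) {
  if (is.null(names(counts))) names(counts) <- tongue_classes()[seq_along(counts)]
  if (any(counts < 0)) abort("counts must be >= 0.", class = "tonguecaps_config_error")
  if (any(image_size < 32)) abort("image_size must be >= 32.",
                                  class = "tonguecaps_config_error")
  structure(list(counts = counts, image_size = as.integer(image_size),
                 seed = as.integer(seed), palette = palette),
            class = "synthetic_config")
}

#' Generate a labeled synthetic tongue dataset
#'
#' Renders `counts[label]` images per class and writes them as PNG under
#' `out_dir`, returning the manifest. Generation is a pure function of the
#' configuration: the same config always yields byte-identical images and
#' an identical manifest.
#'
#' @param cfg A [synthetic_config()].
#' @param out_dir Output directory, created if needed.
#' @return Manifest tibble with columns `path`, `label`.
#' @export
generate_dataset <- function(cfg, out_dir) {
  if (!inherits(cfg, "synthetic_config"))
    abort("`cfg` must be a synthetic_config.", class = "tonguecaps_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::imap(cfg$counts, function(n, label) {
    if (n == 0) return(NULL)
    li <- match(label, names(cfg$counts))
    paths <- vapply(seq_len(n), function(i) {
      jit <- with_local_seed(derive_seed(cfg$seed, li, i), runif(2, 0.9, 1.1))
      sz <- pmax(as.integer(round(cfg$image_size * jit)), 32L)
      img <- render_tongue(label, seed = derive_seed(cfg$seed, li * 1000 + i),
                           size = sz, palette = cfg$palette)
      dest <- file.path(out_dir, sprintf("%s_%04d.png", label, i))
      write_image(img, dest)
      dest
    }, character(1))
    tibble::tibble(path = paths, label = label)
  })
  dplyr::bind_rows(rows)
}

#' Nearest-palette-center color probe
#'
#' A deliberately simple separability guard for the generator: each image is
#' classified by the nearest class-palette center (Euclidean in H/S/V with
#' circular hue distance) of its mean color over the tongue mask (all
#' non-black pixels). Returns the fraction classified correctly.
#'
#' @param manifest Manifest tibble with `path` and `label` columns, at least
#'   one row.
#' @param palette Palette tibble the centers are taken from.
#' @return Accuracy in `[0, 1]`.
#' @export
hue_probe <- function(manifest, palette = default_palette()) {
  manifest <- tibble::as_tibble(manifest)
  if (nrow(manifest) == 0)
    abort("empty manifest.", class = "tonguecaps_invalid_input")
  centers <- palette_centers(palette)
  pred <- purrr::map_chr(manifest$path, function(p) {
    img <- read_image(p)
    mask <- img[, , 1] + img[, , 2] + img[, , 3] > 0
    hsv <- rgb_to_hsv(img)
    mh <- mean(hsv[, , 1][mask]); ms <- mean(hsv[, , 2][mask]); mv <- mean(hsv[, , 3][mask])
    dh <- abs(centers$h - mh); dh <- pmin(dh, 1 - dh)
    d <- (2 * dh)^2 + (centers$s - ms)^2 + (centers$v - mv)^2
    centers$label[which.min(d)]
  })
  mean(pred == manifest$label)
}
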