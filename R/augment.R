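#' Describe a single augmentation transform
#'
#' A transform is one of the four augmentation families used to expand the
#' training set — rotation (90 or 180 degrees, counter-clockwise), horizontal
#' or vertical shift, power-law brightness change — plus the identity.
#' Transforms may be composed once (`compose_with`), giving composition depth
#' at most 2; composites are only needed for classes whose multiplier exceeds
#' the pool of single transforms.
#'
#' @param kind One of `"identity"`, `"rot90"`, `"rot180"`, `"hshift"`,
#'   `"vshift"`, `"brightness"`.
#' @param param Shift fraction of the axis (in `(0, 0.25]`) or brightness
#'   factor k; ignored for identity/rotations.
#' @param compose_with Optional second `transform_spec` applied after this
#'   one; must itself be uncomposed.
#' @return A `transform_spec` object.
#' @export
transform_spec <- function(kind, param = NA_real_, compose_with = NULL) {
  kinds <- c("identity", "rot90", "rot180", "hshift", "vshift", "brightness")
  if (!kind %in% kinds)
    abort(paste0("Unknown transform kind: ", kind), class = "tonguecaps_config_error")
  if (kind %in% c("hshift", "vshift") &&
      (is.na(param) || param < 0 || param > 0.25))
    abort("Shift fraction must lie in [0, 0.25].", class = "tonguecaps_config_error")
  if (!is.null(compose_with)) {
    if (!inherits(compose_with, "transform_spec"))
      abort("`compose_with` must be a transform_spec.", class = "tonguecaps_config_error")
    if (!is.null(compose_with$compose_with))
      abort("Composition depth is limited to 2.", class = "tonguecaps_invalid_plan")
  }
  structure(list(kind = kind, param = param, compose_with = compose_with),
            class = "transform_spec")
}

#' @export
format.transform_spec <- function(x, ...) {
  base <- switch(x$kind,
    identity = "identity",
    rot90 = "rot90",
    rot180 = "rot180",
    hshift = sprintf("hshift%+g", x$param),
    vshift = sprintf("vshift%+g", x$param),
    brightness = sprintf("brightness%g", x$param))
  if (!is.null(x$compose_with))
    base <- paste0(base, "_", format(x$compose_with))
  base
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("<transform_spec>", format(x), "\n")
  invisible(x)
}

rot90_ccw <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  out <- array(0, dim = c(w, h, dim(img)[3]))
  for (c in seq_len(dim(img)[3])) out[, , c] <- t(img[, , c])[w:1, , drop = FALSE]
  out
}

shift_image <- function(img, frac, axis) {
  h <- dim(img)[1]; w <- dim(img)[2]
  out <- array(0, dim = dim(img))
  if (axis == "x") {
    px <- as.integer(round_half_up(abs(frac) * w))
    if (px == 0) return(img)
    if (px >= w) return(out)
    if (frac > 0) out[, (px + 1):w, ] <- img[, 1:(w - px), ]
    else out[, 1:(w - px), ] <- img[, (px + 1):w, ]
  } else {
    px <- as.integer(round_half_up(abs(frac) * h))
    if (px == 0) return(img)
    if (px >= h) return(out)
    if (frac > 0) out[(px + 1):h, , ] <- img[1:(h - px), , ]
    else out[1:(h - px), , ] <- img[(px + 1):h, , ]
  }
  out
}

#' Apply an augmentation transform to an image
#'
#' Rotations are exact array permutations (counter-clockwise); shifts move
#' the content by `round(param * axis length)` pixels towards positive x
#' (right) or y (down), filling vacated pixels with black and clipping
#' content at the border; brightness delegates to [adjust_brightness()].
#' A composed spec applies the base transform first, then `compose_with`.
#'
#' @param img RGB array (H x W x 3, values 0-255).
#' @param t A [transform_spec()].
#' @return The transformed RGB array.
#' @export
#' @examples
#' img <- array(runif(12, 0, 255), dim = c(2, 2, 3))
#' all.equal(apply_transform(apply_transform(img, transform_spec("rot90")),
#'                           transform_spec("rot90")),
#'           apply_transform(img, transform_spec("rot180")))
apply_transform <- function(img, t) {
  validate_rgb_image(img)
  if (!inherits(t, "transform_spec"))
    abort("`t` must be a transform_spec.", class = "tonguecaps_config_error")
  out <- switch(t$kind,
    identity = img,
    rot90 = rot90_ccw(img),
    rot180 = rot90_ccw(rot90_ccw(img)),
    hshift = shift_image(img, t$param, "x"),
    vshift = shift_image(img, t$param, "y"),
    brightness = adjust_brightness(img, t$param))
  if (!is.null(t$compose_with)) out <- apply_transform(out, t$compose_with)
  out
}

# the canonical ordered pool of transforms; singles first, then composites
transform_pool <- function(shift = 0.1, brightness = c(0.5, 1.5)) {
  singles <- list(
    transform_spec("identity"),
    transform_spec("rot90"),
    transform_spec("rot180"),
    transform_spec("hshift", shift),
    transform_spec("vshift", shift),
    transform_spec("brightness", brightness[1]),
    transform_spec("brightness", brightness[2]))
  geoms <- singles[2:5]
  brights <- singles[6:7]
  geo_bright <- purrr::flatten(purrr::map(geoms, function(g)
    purrr::map(brights, function(b)
      transform_spec(g$kind, g$param, compose_with = b))))
  geo_geo <- list()
  for (i in seq_along(geoms)) {
    for (j in seq_along(geoms)) {
      if (i == j) next
      # rot180 o rot90 duplicates rot90 o rot180 pixel-for-pixel; keep one
      if (geoms[[i]]$kind == "rot180" && geoms[[j]]$kind == "rot90") next
      geo_geo <- c(geo_geo, list(
        transform_spec(geoms[[i]]$kind, geoms[[i]]$param,
                       compose_with = geoms[[j]])))
    }
  }
  c(singles, geo_bright, geo_geo)
}

#' Enumerate the first m transforms of the canonical augmentation pool
#'
#' The canonical order is: identity, rot90, rot180, hshift(+0.1),
#' vshift(+0.1), brightness(0.5), brightness(1.5), then composites —
#' geometric-then-brightness pairs, then geometric-then-geometric pairs — in
#' lexicographic order of the single-transform list. All returned specs are
#' pairwise distinct, and the first is always the identity, so the original
#' image is retained in every augmentation plan.
#'
#' @param m Number of transforms required (>= 1).
#' @param shift Shift fraction used by the shift transforms (default 0.1).
#' @param brightness The two brightness factors (default `c(0.5, 1.5)`).
#' @return List of `m` [transform_spec()] objects.
#' @export
#' @examples
#' length(enumerate_plan(7))
enumerate_plan <- function(m, shift = 0.1, brightness = c(0.5, 1.5)) {
  if (m < 1) abort("`m` must be >= 1.", class = "tonguecaps_config_error")
  pool <- transform_pool(shift, brightness)
  if (m > length(pool))
    abort(sprintf("Requested %d transforms but the pool holds %d.",
                  m, length(pool)),
          class = "tonguecaps_capacity_error")
  pool[seq_len(m)]
}

#' Default per-class augmentation multipliers
#'
#' The multipliers that balance the clinical training-set composition: each
#' class is expanded to (original count) x multiplier variants, the original
#' image included.
#'
#' @return Named integer vector over [tongue_classes()].
#' @export
default_multipliers <- function() {
  c(light_red = 4L, red = 5L, deep_red = 14L, light_white = 5L, cyan = 6L)
}

#' Expand a manifest so the classes are balanced
#'
#' For every source image of class with multiplier m, applies the first m
#' transforms of the canonical pool ([enumerate_plan()]) and writes each
#' variant as a PNG under `out_dir`. The expansion is fully deterministic:
#' re-running with the same inputs is bit-identical.
#'
#' @param manifest Data frame with columns `path`, `label` (and optionally
#'   `split`, carried through).
#' @param multipliers Named vector label -> positive integer m; defaults to
#'   [default_multipliers()].
#' @param out_dir Directory for augmented images; `NULL` returns the
#'   augmented manifest without writing images (paths refer to the source,
#'   and the `transform` column says which transform to apply on load).
#' @param shift,brightness Passed to [enumerate_plan()].
#' @return Tibble with one row per augmented image: `path`, `label`,
#'   `source`, `transform` (canonical name), plus any carried columns.
#' @export
balance_dataset <- function(manifest, multipliers = default_multipliers(),
                            out_dir = NULL, shift = 0.1,
                            brightness = c(0.5, 1.5)) {
  manifest <- tibble::as_tibble(manifest)
  if (!all(c("path", "label") %in% names(manifest)))
    abort("manifest needs `path` and `label` columns.",
          class = "tonguecaps_config_error")
  labs <- unique(manifest$label)
  missing <- setdiff(labs, names(multipliers))
  if (length(missing))
    abort(paste0("No multiplier for class(es): ", paste(missing, collapse = ", ")),
          class = "tonguecaps_config_error")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plans <- lapply(setNames(labs, labs), function(l)
    enumerate_plan(multipliers[[l]], shift, brightness))
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    rec <- manifest[i, ]
    plan <- plans[[rec$label]]
    names_t <- vapply(plan, format, character(1))
    stem <- tools::file_path_sans_ext(basename(rec$path))
    img <- if (is.null(out_dir)) NULL else read_image(rec$path)
    paths <- vapply(seq_along(plan), function(j) {
      if (is.null(out_dir)) return(rec$path)
      dest <- file.path(out_dir, paste0(stem, "__", names_t[j], ".png"))
      write_image(apply_transform(img, plan[[j]]), dest)
      dest
    }, character(1))
    out <- rec[rep(1L, length(plan)), ]
    out$path <- paths
    out$source <- rec$path
    out$transform <- names_t
    out
  })
  dplyr::bind_rows(rows)
}

#' Read / write manifest CSV files
#'
#' A manifest is a CSV with columns `path,label` and optionally `split` and
#' the augmentation provenance columns (`source`, `transform`).
#'
#' @param path CSV file path.
#' @return `read_manifest()` returns a tibble.
#' @export
read_manifest <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_manifest
#' @param manifest Data frame to write.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(tibble::as_tibble(manifest), path)
  invisible(path)
}
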