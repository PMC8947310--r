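#' Validate an RGB tongue image array
#'
#' Images flow through the package as plain numeric arrays of shape
#' H x W x 3 with 8-bit intensities in `[0, 255]`.
#'
#' @param img Numeric array, H x W x 3, values in `[0, 255]`.
#' @return The validated array, invisibly unchanged.
#' @export
validate_rgb_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    abort("`img` must be an H x W x 3 array.", class = "tonguecaps_invalid_input")
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    abort("`img` has a zero-sized dimension.", class = "tonguecaps_invalid_input")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    abort("`img` values must lie in [0, 255].", class = "tonguecaps_invalid_input")
  invisible(img)
}

#' Letterbox an image to a fixed square with black padding
#'
#' Scales the image so its longest side equals `side` (aspect ratio
#' preserved, bilinear interpolation), then pads the short side with black
#' pixels to a `side` x `side` square. The scaled content is centred along
#' the padded axis; when the number of padding pixels is odd the extra pixel
#' goes to the bottom/right. The scaled short side is rounded half-up.
#'
#' @param img RGB array (H x W x 3, values 0-255).
#' @param side Target side length L (integer >= 2).
#' @return An RGB array of shape `side` x `side` x 3.
#' @export
#' @examples
#' img <- array(runif(60 * 30 * 3, 0, 255), dim = c(60, 30, 3))
#' out <- resize_pad(img, 32)
#' dim(out)
resize_pad <- function(img, side) {
  validate_rgb_image(img)
  side <- as.integer(side)
  if (side < 2L)
    abort("`side` must be at least 2.", class = "tonguecaps_invalid_input")
  h <- dim(img)[1]; w <- dim(img)[2]
  long <- max(h, w)
  new_h <- if (h == long) side else as.integer(round_half_up(h * side / long))
  new_w <- if (w == long) side else as.integer(round_half_up(w * side / long))
  new_h <- max(new_h, 1L); new_w <- max(new_w, 1L)
  scaled <-
    if (new_h == h && new_w == w) img
    else resize_bilinear(as.numeric(img), h, w, 3L, new_h, new_w)
  out <- array(0, dim = c(side, side, 3L))
  top <- (side - new_h) %/% 2L
  left <- (side - new_w) %/% 2L
  out[top + seq_len(new_h), left + seq_len(new_w), ] <- scaled
  out
}

#' Convert an RGB image to HSV
#'
#' Standard hexcone conversion via [grDevices::rgb2hsv()]. All three output
#' channels are scaled to `[0, 1]`; a full hue circle is 1.0.
#'
#' @param img RGB array (H x W x 3, values 0-255).
#' @return Numeric array H x W x 3 with hue, saturation, value in `[0, 1]`.
#' @export
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' rgb_to_hsv(px) # pure red: H = 0, S = 1, V = 1
rgb_to_hsv <- function(img) {
  validate_rgb_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  m <- rbind(as.numeric(img[, , 1]), as.numeric(img[, , 2]), as.numeric(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  array(c(hsv[1, ], hsv[2, ], hsv[3, ]), dim = c(h, w, 3L))
}

#' Power-law brightness adjustment
#'
#' Maps every 8-bit channel value by `I' = (I/255)^k * 255`, rounded half-up
#' back to an integer. Factors `k < 1` brighten the image, `k > 1` darken it;
#' `k` must lie in `[0.25, 4]`.
#'
#' @param img RGB array (H x W x 3, values 0-255).
#' @param k Adjustment factor in `[0.25, 4]`.
#' @return Adjusted RGB array, same shape, integer-valued in 0-255.
#' @export
#' @examples
#' img <- array(64, dim = c(2, 2, 3))
#' adjust_brightness(img, 0.5)[1, 1, 1] # 128
adjust_brightness <- function(img, k) {
  validate_rgb_image(img)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0.25 || k > 4)
    abort("`k` must be a single value in [0.25, 4].",
          class = "tonguecaps_invalid_parameter")
  out <- round_half_up((img / 255)^k * 255)
  array(out, dim = dim(img))
}

#' Read an image file as an RGB array
#'
#' PNG files are read with the png package; JPEG files with EBImage when it
#' is installed. Gray and RGBA inputs are expanded/flattened to three
#' channels. Values are returned on the 0-255 scale.
#'
#' @param path File path (.png, .jpg, .jpeg).
#' @return RGB array H x W x 3 in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      abort("Reading JPEG requires the EBImage package.",
            class = "tonguecaps_io_error")
    eb <- EBImage::readImage(path)
    px <- aperm(EBImage::imageData(EBImage::Image(eb, colormode = "Color")),
                c(2, 1, 3))
  } else {
    abort(paste0("Unsupported image format: ", ext),
          class = "tonguecaps_io_error")
  }
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  round_half_up(px * 255)
}

#' Write an RGB array to a PNG file
#'
#' @param img RGB array (H x W x 3, values 0-255).
#' @param path Output path (.png).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  validate_rgb_image(img)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' Preprocess a manifest of images to model input size
#'
#' Applies [resize_pad()] and optionally [rgb_to_hsv()] to every image of a
#' manifest and writes the results as PNG to `out_dir` (HSV arrays are
#' written with the three channels stored as the PNG's RGB planes).
#'
#' @param manifest Data frame with at least a `path` column; `label` and
#'   `split` columns are carried through when present.
#' @param out_dir Output directory (created if needed).
#' @param side Target square side, default 128.
#' @param hsv Convert to HSV after resizing (default FALSE).
#' @return The manifest as a tibble with `path` pointing at the outputs.
#' @export
preprocess_manifest <- function(manifest, out_dir, side = 128, hsv = FALSE) {
  manifest <- tibble::as_tibble(manifest)
  if (!"path" %in% names(manifest))
    abort("manifest needs a `path` column.", class = "tonguecaps_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out_paths <- purrr::map_chr(manifest$path, function(p) {
    img <- resize_pad(read_image(p), side)
    dest <- file.path(out_dir, paste0(tools::file_path_sans_ext(basename(p)), ".png"))
    if (hsv) {
      png::writePNG(rgb_to_hsv(img), target = dest)
    } else {
      write_image(img, dest)
    }
    dest
  })
  dplyr::mutate(manifest, path = out_paths)
}
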