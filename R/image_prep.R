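#' Construct and read raw fundus images
#'
#' A raw image is an `H x W x 3` array of integer intensities in
#' `[0, 255]`. [read_raw_image()] and [write_raw_image()] go through
#' EBImage (PNG and JPEG).
#'
#' @param pixels An `H x W x 3` numeric array with values in `[0, 255]`.
#' @return An object of class `dr_raw_image` (the array, validated).
#' @export
#' @examples
#' img <- raw_image(array(128, c(32, 40, 3)))
#' dim(img)
raw_image <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  }
  if (dim(pixels)[1] < 10 || dim(pixels)[2] < 10) {
    stop("image must be at least 10 x 10 pixels", call. = FALSE)
  }
  if (any(pixels < 0) || any(pixels > 255)) {
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  }
  structure(pixels, class = "dr_raw_image")
}

#' @rdname raw_image
#' @param path File path (`.png`, `.jpg`/`.jpeg`).
#' @export
read_raw_image <- function(path) {
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  raw_image(round(255 * aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3))))
}

#' @rdname raw_image
#' @param img A `dr_raw_image`.
#' @export
write_raw_image <- function(img, path) {
  a <- aperm(unclass(img) / 255, c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Configuration of the image normalisation chain
#'
#' @param crop_fraction Fraction of each linear dimension retained by the
#'   centred crop that removes the circular-mask rim (default 0.90).
#' @param out_size Output side length in pixels (default 299, the input
#'   size of Inception-style networks).
#' @param blur_scale Width of the local-average kernel as a fraction of the
#'   output width; the Gaussian sigma is `blur_scale * out_size`
#'   (default 1/30).
#' @param gray_level Intensity added after local-average subtraction so
#'   the output is centred on mid-gray (default 128, i.e. 50% gray).
#' @param gain Multiplier on the residual `in - local_average`; 1 is plain
#'   subtraction (default); 4 is the classic fundus-enhancement setting.
#' @param interpolation Resize interpolation: `"bilinear"` (default) or
#'   `"nearest"`.
#' @return An object of class `dr_prep_config`.
#' @export
prep_config <- function(crop_fraction = 0.90, out_size = 299L,
                        blur_scale = 1 / 30, gray_level = 128L, gain = 1,
                        interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (crop_fraction <= 0 || crop_fraction > 1) {
    stop("`crop_fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (out_size < 8) stop("`out_size` must be >= 8", call. = FALSE)
  if (blur_scale <= 0) stop("`blur_scale` must be positive", call. = FALSE)
  structure(list(crop_fraction = crop_fraction, out_size = as.integer(out_size),
                 blur_scale = blur_scale, gray_level = as.integer(gray_level),
                 gain = gain, interpolation = interpolation),
            class = "dr_prep_config")
}

#' Normalise a fundus photograph for classification
#'
#' The pipeline, in order: centred crop retaining `crop_fraction` of each
#' linear dimension (floor of the product), resize to
#' `out_size x out_size`, per-channel subtraction of a Gaussian-smoothed
#' local average colour, addition of `gray_level`, and clamping to
#' `[0, 255]`. A constant-colour input therefore maps exactly to
#' `gray_level` everywhere, and adding a constant offset to all input
#' pixels leaves the (pre-clamp) output unchanged because the local
#' average absorbs it.
#'
#' @param img A [raw_image()].
#' @param cfg A [prep_config()].
#' @return A `dr_raw_image` of dimension `out_size x out_size x 3`.
#' @export
#' @examples
#' img <- raw_image(array(77, c(40, 40, 3)))
#' out <- preprocess(img, prep_config(out_size = 32))
#' unique(as.vector(out))  # 128: local average of a constant is the constant
preprocess <- function(img, cfg = prep_config()) {
  stopifnot(inherits(img, "dr_raw_image"), inherits(cfg, "dr_prep_config"))
  a <- unclass(img)
  h <- dim(a)[1]
  w <- dim(a)[2]

  # 1. centred crop
  h2 <- max(1L, floor(cfg$crop_fraction * h))
  w2 <- max(1L, floor(cfg$crop_fraction * w))
  top <- floor((h - h2) / 2)
  left <- floor((w - w2) / 2)
  a <- a[top + seq_len(h2), left + seq_len(w2), , drop = FALSE]

  # 2. resize (EBImage works in x = width, y = height order)
  eb <- EBImage::Image(aperm(a / 255, c(2, 1, 3)), colormode = "Color")
  eb <- EBImage::resize(eb, w = cfg$out_size, h = cfg$out_size,
                        filter = if (cfg$interpolation == "bilinear")
                          "bilinear" else "none")

  # 3. local-average subtraction, mapped to gray
  sigma <- cfg$blur_scale * cfg$out_size
  support <- 2 * ceiling(3 * sigma) + 1
  if (support > cfg$out_size) {
    stop("local-average kernel support (", support,
         " px) exceeds the output size; reduce `blur_scale`", call. = FALSE)
  }
  blur <- EBImage::gblur(eb, sigma = sigma)
  out <- 255 * cfg$gain * (EBImage::imageData(eb) - EBImage::imageData(blur)) +
    cfg$gray_level
  out <- round(pmin(pmax(out, 0), 255))
  raw_image(aperm(out, c(2, 1, 3)))
}

#' @rdname preprocess
#' @param in_dir,out_dir Directories for batch processing; every `.png`,
#'   `.jpg` or `.jpeg` file in `in_dir` is normalised and written under the
#'   same name in `out_dir`.
#' @return `preprocess_dir()` returns the output paths invisibly.
#' @export
preprocess_dir <- function(in_dir, out_dir, cfg = prep_config()) {
  files <- list.files(in_dir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out <- character(length(files))
  for (i in seq_along(files)) {
    img <- read_raw_image(file.path(in_dir, files[i]))
    out[i] <- file.path(out_dir, files[i])
    write_raw_image(preprocess(img, cfg), out[i])
  }
  invisible(out)
}
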