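#' @useDynLib angiopath, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Construct a raster image
#'
#' An 8-bit raster image stored as an integer array of dimension
#' \code{height x width} (single channel) or \code{height x width x 3}.
#' Pixel coordinates used throughout the package are 0-based,
#' \code{(x = column, y = row)}, origin top-left.
#'
#' @param pixels Numeric or integer matrix/array, values in \code{[0, 255]}.
#' @param colour_model One of \code{"RGB"}, \code{"HSV"}, \code{"GREY"}.
#' @return A \code{raster_image} object.
#' @export
raster_image <- function(pixels, colour_model = c("RGB", "HSV", "GREY")) {
  colour_model <- match.arg(colour_model)
  px <- round(pixels)
  if (any(px < 0 | px > 255)) stop("pixel values must lie in [0, 255]")
  nch <- if (length(dim(px)) == 3L) dim(px)[3L] else 1L
  if (colour_model == "GREY" && nch != 1L)
    stop("GREY images must have a single channel")
  if (colour_model != "GREY" && nch != 3L)
    stop(colour_model, " images must have 3 channels")
  storage.mode(px) <- "integer"
  structure(px, class = "raster_image", colour_model = colour_model)
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image %s %d x %d px>\n", attr(x, "colour_model"),
              image_width(x), image_height(x)))
  invisible(x)
}

#' @rdname raster_image
#' @param img A \code{raster_image} or \code{binary_mask}.
#' @export
image_width <- function(img) ncol(as_matrix(img, 1L))

#' @rdname raster_image
#' @export
image_height <- function(img) nrow(as_matrix(img, 1L))

#' @rdname raster_image
#' @export
colour_model <- function(img) attr(img, "colour_model")

# first-channel matrix view, used for dimension queries
as_matrix <- function(img, ch = 1L) {
  if (length(dim(img)) == 3L) img[, , ch] else unclass(img)
}

#' Construct a binary mask
#'
#' A single-channel image over \{0, 255\}; 255 is foreground.
#'
#' @param pixels Matrix whose entries are all 0 or 255 (logical matrices are
#'   mapped to 0/255).
#' @return A \code{binary_mask} object (integer matrix).
#' @export
binary_mask <- function(pixels) {
  if (is.logical(pixels)) {
    px <- matrix(ifelse(pixels, 255L, 0L), nrow(pixels), ncol(pixels))
  } else {
    px <- pixels
    if (!all(px %in% c(0, 255))) stop("binary mask pixels must be 0 or 255")
  }
  px <- unclass(px)
  attributes(px) <- list(dim = dim(px))
  storage.mode(px) <- "integer"
  structure(px, class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %d x %d px, %d fg px>\n", ncol(x), nrow(x),
              sum(unclass(x) != 0L)))
  invisible(x)
}

mask_matrix <- function(m) {
  x <- unclass(m)
  attributes(x) <- list(dim = dim(x))
  storage.mode(x) <- "integer"
  x
}

# trusted constructor for masks produced by the package's own C ops
new_mask <- function(px) structure(px, class = "binary_mask")

#' Physical pixel calibration
#'
#' @param microns_per_pixel Isotropic pixel pitch in micrometres per pixel;
#'   0.25 is a typical 40x brightfield scanner value.
#' @return A \code{calibration} object.
#' @export
calibration <- function(microns_per_pixel = 0.25) {
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0)
    stop("microns_per_pixel must be > 0")
  structure(list(microns_per_pixel = microns_per_pixel), class = "calibration")
}

#' Read an image file as an 8-bit RGB raster
#'
#' Supports TIFF, PNG and JPEG. Greyscale files are replicated to three
#' channels; an alpha channel, if present, is dropped. 16-bit TIFFs are
#' rejected unless \code{allow_16bit = TRUE}, in which case they are linearly
#' rescaled to 8 bits.
#'
#' @param path Path to the image file.
#' @param allow_16bit Rescale 16-bit TIFF input instead of failing.
#' @return A 3-channel RGB \code{raster_image}.
#' @export
load_image <- function(path, allow_16bit = FALSE) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(switch(ext,
    tif = , tiff = tiff::readTIFF(path, info = TRUE),
    png = png::readPNG(path),
    jpg = , jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '", ext, "' for ", path)
  ), error = function(e) stop("failed to read image ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  if (ext %in% c("tif", "tiff")) {
    bits <- attr(arr, "bits.per.sample")
    if (!is.null(bits) && any(bits > 8) && !allow_16bit)
      stop("16-bit TIFF not supported (set allow_16bit = TRUE to rescale): ",
           path)
  }
  arr <- round(arr * 255) # readers return [0, 1]
  if (length(dim(arr)) == 2L) {
    arr <- array(arr, dim = c(dim(arr), 3L)) # grey -> R = G = B
  } else if (dim(arr)[3L] > 3L) {
    arr <- arr[, , 1:3, drop = FALSE] # drop alpha
  } else if (dim(arr)[3L] == 2L) {
    arr <- array(arr[, , 1L], dim = c(dim(arr)[1:2], 3L)) # grey + alpha
  }
  raster_image(arr, "RGB")
}

#' Write an image or mask as TIFF
#'
#' @param img A \code{raster_image} or \code{binary_mask}.
#' @param path Output path (TIFF).
#' @export
write_image <- function(img, path) {
  arr <- if (inherits(img, "binary_mask")) mask_matrix(img) else {
    x <- unclass(img)
    attributes(x) <- list(dim = dim(x))
    x
  }
  tiff::writeTIFF(arr / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Convert an RGB raster to HSV
#'
#' Uses the 8-bit half-degree convention: H in \code{[0, 179]} (hue degrees
#' halved), S and V in \code{[0, 255]}. Under this convention the DAB-brown
#' staining of vessel endothelium falls at low hue (H below about 20) and
#' moderate-to-high saturation.
#'
#' @param img An RGB \code{raster_image}.
#' @return An HSV \code{raster_image} of the same dimensions.
#' @export
rgb_to_hsv <- function(img) {
  if (!inherits(img, "raster_image") || colour_model(img) != "RGB")
    stop("rgb_to_hsv expects an RGB raster_image")
  r <- img[, , 1L]; g <- img[, , 2L]; b <- img[, , 3L]
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  delta <- v - mn
  s <- ifelse(v == 0L, 0, 255 * delta / v)
  h6 <- ifelse(delta == 0, 0,
        ifelse(v == r, (g - b) / delta,
        ifelse(v == g, 2 + (b - r) / delta,
                       4 + (r - g) / delta)))
  h <- (h6 * 30) %% 180 # 60 deg per sextant, halved for 8-bit storage
  out <- array(0, dim = dim(unclass(img)))
  out[, , 1L] <- floor(h + 0.5) %% 180
  out[, , 2L] <- floor(s + 0.5)
  out[, , 3L] <- v
  raster_image(out, "HSV")
}

#' Extract one channel as a grey raster
#'
#' @param img A \code{raster_image}.
#' @param channel 1-based channel index (1..3 for RGB/HSV, 1 for grey).
#' @return A single-channel GREY \code{raster_image}.
#' @export
extract_channel <- function(img, channel) {
  nch <- if (length(dim(img)) == 3L) dim(img)[3L] else 1L
  if (channel < 1L || channel > nch)
    stop("channel index ", channel, " out of range for a ", nch,
         "-channel image")
  raster_image(as_matrix(img, as.integer(channel)), "GREY")
}
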