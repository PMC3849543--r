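#' HSV stage configuration
#'
#' Parameters of the colour-based segmentation of closed vessels. Defaults
#' are the published operating point: S/H thresholds 30/20, erosion 2 and
#' dilation 4 iterations, and the small-object filter that discards
#' macrophage-sized blobs (contours kept only if they have more than
#' \code{min_contour_points} boundary points and a bounding box strictly
#' larger than \code{min_bbox_px} in both width and height).
#'
#' \code{filter_combinator = "and"} is the default: under \code{"or"} any
#' blob with more than 6 boundary points survives, which defeats the filter's
#' stated purpose of removing macrophages; \code{"or"} is retained as an
#' option (see the methods vignette).
#'
#' @param s_threshold Saturation threshold (0-255).
#' @param h_threshold Hue threshold (0-179, half-degree units).
#' @param erode_iters,dilate_iters Morphological cleanup iterations.
#' @param min_contour_points Strict lower bound on boundary point count.
#' @param min_bbox_px Strict lower bound on bbox width and height, px.
#' @param edge_mode Contour source for tracing.
#' @param filter_combinator How the two size conditions combine.
#' @return An \code{hsv_config} object.
#' @export
hsv_config <- function(s_threshold = 30, h_threshold = 20,
                       erode_iters = 2L, dilate_iters = 4L,
                       min_contour_points = 6L, min_bbox_px = 20,
                       edge_mode = c("threshold", "canny"),
                       filter_combinator = c("and", "or")) {
  cfg <- list(s_threshold = s_threshold, h_threshold = h_threshold,
              erode_iters = as.integer(erode_iters),
              dilate_iters = as.integer(dilate_iters),
              min_contour_points = as.integer(min_contour_points),
              min_bbox_px = min_bbox_px,
              edge_mode = match.arg(edge_mode),
              filter_combinator = match.arg(filter_combinator))
  stopifnot(cfg$s_threshold >= 0, cfg$s_threshold <= 255,
            cfg$h_threshold >= 0, cfg$h_threshold <= 179,
            cfg$erode_iters >= 0, cfg$dilate_iters >= 0,
            cfg$min_contour_points >= 0, cfg$min_bbox_px >= 0)
  structure(cfg, class = "hsv_config")
}

#' Segment DAB-brown pixels in HSV space
#'
#' The brown endothelial stain is isolated by combining the saturation and
#' hue planes: NOT( OR( threshold(S, s_threshold, inverted),
#' threshold(H, h_threshold) ) ). Low-saturation background (pale tissue,
#' lumens) fires the inverted S branch; high-hue colour (haematoxylin-blue
#' nuclei) fires the H branch; the complement of their union is the
#' saturated, low-hue brown foreground.
#'
#' @param img RGB \code{raster_image}.
#' @param cfg \code{hsv_config}.
#' @return A \code{binary_mask} with 255 = brown-stained pixels.
#' @export
segment_brown_mask <- function(img, cfg = hsv_config()) {
  hsv <- rgb_to_hsv(img)
  s_low <- threshold(extract_channel(hsv, 2L), cfg$s_threshold, inverted = TRUE)
  h_high <- threshold(extract_channel(hsv, 1L), cfg$h_threshold, inverted = FALSE)
  logical_not(logical_or(s_low, h_high))
}

#' Morphological cleanup of the brown mask
#'
#' Erosion (\code{erode_iters}) removes small artefacts, then dilation
#' (\code{dilate_iters}) rejoins nearby endothelial fragments.
#'
#' @param mask A \code{binary_mask}.
#' @param cfg \code{hsv_config}.
#' @return A \code{binary_mask}.
#' @export
cleanup <- function(mask, cfg = hsv_config()) {
  morph(morph(mask, "erode", cfg$erode_iters), "dilate", cfg$dilate_iters)
}

#' Trace and filter vessel contours from a cleaned mask
#'
#' Contours are traced with hole hierarchy; each outer contour is paired
#' with its largest-area hole as the lumen. The small-object filter then
#' removes macrophage-sized blobs (see \code{\link{hsv_config}}).
#'
#' @param mask Cleaned \code{binary_mask} (or grey image when
#'   \code{cfg$edge_mode = "canny"}).
#' @param cfg \code{hsv_config}.
#' @return A list of \code{vessel_contour} objects (fields \code{outer},
#'   \code{inner}, \code{source}, \code{bbox}).
#' @export
extract_vessels <- function(mask, cfg = hsv_config()) {
  contours <- find_contours(mask, edge_mode = cfg$edge_mode)
  vessels <- pair_lumens(contours, source = "hsv")
  Filter(function(v) keep_vessel(v, cfg), vessels)
}

# pair each outer contour with its largest hole; shared by both stages
pair_lumens <- function(contours, source) {
  outer_idx <- which(!vapply(contours, `[[`, TRUE, "is_hole"))
  lapply(outer_idx, function(i) {
    holes <- which(vapply(contours, function(ct)
      isTRUE(ct$is_hole) && identical(ct$parent, i), TRUE))
    inner <- NULL
    if (length(holes)) {
      areas <- vapply(holes, function(j) contour_area(contours[[j]]$points), 0)
      inner <- contours[[holes[which.max(areas)]]]$points
    }
    vessel_contour(contours[[i]]$points, inner, source)
  })
}

#' @rdname extract_vessels
#' @param outer n x 2 matrix, outer boundary points.
#' @param inner Optional m x 2 matrix, lumen boundary points.
#' @param source \code{"hsv"} or \code{"radial"}.
#' @export
vessel_contour <- function(outer, inner = NULL, source = c("hsv", "radial")) {
  structure(list(outer = outer, inner = inner, source = match.arg(source),
                 bbox = contour_bbox(outer)),
            class = "vessel_contour")
}

#' @export
print.vessel_contour <- function(x, ...) {
  cat(sprintf("<vessel_contour %s, %d boundary pts%s, bbox %dx%d>\n",
              x$source, nrow(x$outer),
              if (is.null(x$inner)) "" else sprintf(" + lumen (%d pts)",
                                                    nrow(x$inner)),
              round(x$bbox["w"]), round(x$bbox["h"])))
  invisible(x)
}

keep_vessel <- function(v, cfg) {
  npts <- nrow(v$outer) > cfg$min_contour_points
  big <- v$bbox["w"] > cfg$min_bbox_px && v$bbox["h"] > cfg$min_bbox_px
  if (cfg$filter_combinator == "and") npts && big else npts || big
}
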