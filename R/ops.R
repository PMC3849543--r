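#' Binary thresholding
#'
#' Strict comparison: with \code{inverted = FALSE} a pixel maps to 255 iff
#' \code{pixel > t}; with \code{inverted = TRUE} iff \code{pixel <= t}.
#'
#' @param img Single-channel \code{raster_image} (or plain matrix).
#' @param t Threshold in \code{[0, 255]} (clamped).
#' @param inverted Invert the comparison.
#' @return A \code{binary_mask}.
#' @export
threshold <- function(img, t, inverted = FALSE) {
  if (inherits(img, "raster_image") && length(dim(img)) == 3L)
    stop("threshold expects a single-channel image")
  m <- as_matrix(img)
  t <- min(max(t, 0), 255)
  binary_mask(if (inverted) m <= t else m > t)
}

#' Pixelwise mask logic
#'
#' @param a,b \code{binary_mask}s of equal dimensions.
#' @return A \code{binary_mask}.
#' @export
logical_or <- function(a, b) {
  ma <- mask_matrix(a); mb <- mask_matrix(b)
  if (!identical(dim(ma), dim(mb)))
    stop("mask dimensions differ: ", paste(dim(ma), collapse = "x"), " vs ",
         paste(dim(mb), collapse = "x"))
  binary_mask(ma != 0L | mb != 0L)
}

#' @rdname logical_or
#' @export
logical_not <- function(a) binary_mask(mask_matrix(a) == 0L)

#' Binary morphology with a 3x3 square structuring element
#'
#' \code{iterations} successive applications of a 3x3 (8-connected) erosion
#' or dilation; 0 iterations is the identity. Pixels outside the image are
#' treated as background, so erosion strips the image border.
#'
#' @param mask A \code{binary_mask}.
#' @param op \code{"erode"} or \code{"dilate"}.
#' @param iterations Non-negative iteration count.
#' @return A \code{binary_mask}.
#' @export
morph <- function(mask, op = c("erode", "dilate"), iterations = 1L) {
  op <- match.arg(op)
  if (iterations < 0) stop("iterations must be >= 0")
  if (iterations == 0) return(new_mask(mask_matrix(mask)))
  new_mask(cpp_morph(mask_matrix(mask), op == "dilate",
                     as.integer(iterations)))
}

#' Fill small enclosed holes
#'
#' Every 4-connected background component fully enclosed by foreground whose
#' area is strictly smaller than \code{max_hole_px} is set to foreground.
#' Background touching the image border is never filled.
#'
#' @param mask A \code{binary_mask}.
#' @param max_hole_px Strict upper bound on hole area, in pixels.
#' @return A \code{binary_mask}.
#' @export
fill_small_holes <- function(mask, max_hole_px) {
  if (max_hole_px < 0) stop("max_hole_px must be >= 0")
  new_mask(cpp_fill_holes(mask_matrix(mask), as.numeric(max_hole_px)))
}

#' Trace object contours with hole hierarchy
#'
#' Border-following trace of every 8-connected foreground component (one
#' outer contour each) and every enclosed 4-connected background component
#' (hole contours, carrying the index of their enclosing outer contour).
#' Outer contours are oriented counter-clockwise in the Cartesian (y-up)
#' frame, holes clockwise.
#'
#' With \code{edge_mode = "canny"} the input is a grey image; a gradient-
#' magnitude edge map (Sobel kernels, hysteresis thresholds \code{canny_low}/
#' \code{canny_high}) is binarised first and its components traced.
#'
#' @param mask A \code{binary_mask} (\code{edge_mode = "threshold"}) or a
#'   grey \code{raster_image} (\code{edge_mode = "canny"}).
#' @param edge_mode Contour source: a binary mask or a Canny-style edge map.
#' @param canny_low,canny_high Hysteresis thresholds for the edge map.
#' @return A list of contours, each a list with \code{points} (n x 2 integer
#'   matrix of 0-based x,y), \code{is_hole}, and \code{parent} (1-based index
#'   into the returned list, \code{NA} for outer contours).
#' @export
find_contours <- function(mask, edge_mode = c("threshold", "canny"),
                          canny_low = 50, canny_high = 150) {
  edge_mode <- match.arg(edge_mode)
  if (edge_mode == "canny") {
    mask <- canny_edges(mask, canny_low, canny_high)
  } else if (!inherits(mask, "binary_mask")) {
    stop("find_contours with edge_mode='threshold' expects a binary_mask")
  }
  cpp_trace_contours(mask_matrix(mask))
}

# Minimal Canny-style edge detector: Sobel gradient magnitude + hysteresis.
# Kept simple; stage (a) uses the threshold path by default.
canny_edges <- function(img, low, high) {
  m <- as_matrix(img)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  sh <- function(dr, dc) pad[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  mag <- sqrt(gx^2 + gy^2) / 4
  strong <- binary_mask(mag > high)
  weak <- binary_mask(mag > low)
  # keep weak components that contain at least one strong pixel
  lab <- cpp_label(mask_matrix(weak), 8L)
  keep <- sort(unique(lab[mask_matrix(strong) != 0L]))
  keep <- keep[keep != 0L]
  binary_mask(matrix(lab %in% keep, nrow(lab), ncol(lab)))
}

# ---- contour utilities ------------------------------------------------------

#' Contour geometry helpers
#'
#' \code{contour_signed_area} is the shoelace area on raw image coordinates
#' (positive for outer contours under this package's orientation convention);
#' \code{contour_area} its absolute value; \code{contour_perimeter} the summed
#' Euclidean edge length of the closed polygon; \code{contour_bbox} the tight
#' axis-aligned bounding box as \code{c(x, y, w, h)}; \code{contour_centroid}
#' the polygon (area) centroid, falling back to the vertex mean for
#' degenerate polygons.
#'
#' @param points n x 2 matrix of (x, y) vertices of a closed polygon.
#' @name contour_geometry
NULL

#' @rdname contour_geometry
#' @export
contour_signed_area <- function(points) {
  x <- points[, 1L]; y <- points[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' @rdname contour_geometry
#' @export
contour_area <- function(points) abs(contour_signed_area(points))

#' @rdname contour_geometry
#' @export
contour_perimeter <- function(points) {
  d <- points - points[c(2:nrow(points), 1L), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

#' @rdname contour_geometry
#' @export
contour_bbox <- function(points) {
  c(x = min(points[, 1L]), y = min(points[, 2L]),
    w = diff(range(points[, 1L])) + 1, h = diff(range(points[, 2L])) + 1)
}

#' @rdname contour_geometry
#' @export
contour_centroid <- function(points) {
  x <- points[, 1L]; y <- points[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < 1e-9) return(c(mean(x), mean(y)))
  c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * a)
}

#' Rasterise a closed contour to a filled mask
#'
#' Draws the contour's pixel chain onto an empty mask and fills every
#' enclosed background region, yielding the solid region bounded by the
#' contour.
#'
#' @param points n x 2 matrix of 0-based (x, y) pixel coordinates forming an
#'   8-connected closed chain.
#' @param width,height Output mask dimensions.
#' @return A \code{binary_mask}.
#' @export
rasterise_contour <- function(points, width, height) {
  m <- matrix(FALSE, height, width)
  px <- round(points)
  keep <- px[, 1L] >= 0 & px[, 1L] < width & px[, 2L] >= 0 & px[, 2L] < height
  px <- px[keep, , drop = FALSE]
  m[cbind(px[, 2L] + 1L, px[, 1L] + 1L)] <- TRUE
  fill_small_holes(binary_mask(m), width * height + 1)
}

#' Simplify a closed contour (Ramer-Douglas-Peucker)
#'
#' Removes staircase quantisation noise from pixel chains before shape
#' measurement: vertices are dropped while the polygon stays within
#' \code{tol} px of the original. Exact on true polygons (a square chain
#' collapses to its 4 corners), and debiases the ~5\% Euclidean length
#' overestimate of 8-connected digital curves. \code{tol = 0} is the
#' identity.
#'
#' @param points n x 2 matrix of closed-polygon vertices.
#' @param tol Maximum deviation, px.
#' @return An m x 2 matrix, m <= n.
#' @export
simplify_contour <- function(points, tol = 0.8) {
  n <- nrow(points)
  if (tol <= 0 || n < 5L) return(points)
  # split the cycle at the vertex farthest from vertex 1
  d0 <- rowSums((points - matrix(points[1L, ], n, 2L, byrow = TRUE))^2)
  s <- which.max(d0)
  p <- rbind(points[s:n, , drop = FALSE], points[1:s, , drop = FALSE])
  keep <- logical(nrow(p))
  keep[c(1L, nrow(p))] <- TRUE
  stack <- list(c(1L, nrow(p)))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1L]; j <- seg[2L]
    if (j - i < 2L) next
    a <- p[i, ]; b <- p[j, ]
    ab <- b - a
    len <- sqrt(sum(ab^2))
    idx <- (i + 1L):(j - 1L)
    d <- if (len == 0)
      sqrt(rowSums((p[idx, , drop = FALSE] -
                      matrix(a, length(idx), 2L, byrow = TRUE))^2))
    else
      abs((p[idx, 1L] - a[1L]) * ab[2L] - (p[idx, 2L] - a[2L]) * ab[1L]) / len
    m <- which.max(d)
    if (d[m] > tol) {
      k <- idx[m]
      keep[k] <- TRUE
      stack <- c(stack, list(c(i, k), c(k, j)))
    }
  }
  out <- p[keep, , drop = FALSE]
  out[-nrow(out), , drop = FALSE] # drop duplicated closing vertex
}
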