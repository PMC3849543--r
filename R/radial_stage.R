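#' Radial stage configuration
#'
#' Parameters of the lumen-probing stage that detects and closes open
#' vessels. Defaults follow the published pipeline: green-channel threshold
#' 236 to extract bright lumens, erosion 3 / dilation 2, filling of enclosed
#' holes smaller than 400 px, and a second 1-iteration erosion that widens
#' the gap between lumen boundary and membrane before probing.
#'
#' Probing walks outward from every lumen boundary point along its normal,
#' sampling offsets \code{probe_min_px..probe_max_px}; a lumen is a valid
#' vessel when the fraction of boundary points whose probe hits brown
#' membrane reaches a size-adjusted threshold: \code{small_ratio} for
#' contours with fewer than \code{small_contour_points} points (small lumens
#' are more artefact-prone), \code{base_ratio} otherwise.
#'
#' @param green_threshold Green-channel threshold (0-255).
#' @param erode_iters,dilate_iters,second_erode_iters Morphology iterations.
#' @param max_hole_px Strict upper bound for hole filling, px.
#' @param probe_min_px,probe_max_px Probe offset range along the normal, px.
#' @param base_ratio Membrane-hit ratio required of large lumens.
#' @param small_contour_points Boundary size below which a lumen is "small".
#' @param small_ratio Ratio required of small lumens.
#' @return A \code{radial_config} object.
#' @export
radial_config <- function(green_threshold = 236, erode_iters = 3L,
                          dilate_iters = 2L, max_hole_px = 400,
                          second_erode_iters = 1L, probe_min_px = 2L,
                          probe_max_px = 30L, base_ratio = 0.60,
                          small_contour_points = 100L, small_ratio = 0.80) {
  cfg <- list(green_threshold = green_threshold,
              erode_iters = as.integer(erode_iters),
              dilate_iters = as.integer(dilate_iters),
              max_hole_px = max_hole_px,
              second_erode_iters = as.integer(second_erode_iters),
              probe_min_px = as.integer(probe_min_px),
              probe_max_px = as.integer(probe_max_px),
              base_ratio = base_ratio,
              small_contour_points = as.integer(small_contour_points),
              small_ratio = small_ratio)
  stopifnot(cfg$green_threshold >= 0, cfg$green_threshold <= 255,
            cfg$probe_min_px < cfg$probe_max_px,
            cfg$base_ratio >= 0, cfg$base_ratio <= cfg$small_ratio,
            cfg$small_ratio <= 1)
  structure(cfg, class = "radial_config")
}

#' Extract candidate vascular lumens
#'
#' Green channel -> strict threshold (> \code{green_threshold}) -> erode
#' \code{erode_iters} -> dilate \code{dilate_iters} -> fill holes smaller
#' than \code{max_hole_px} -> second erosion. Outer contours of the
#' surviving bright regions are the lumen candidates. With the default
#' iteration counts the traced boundary sits a net 2 px inside the true
#' lumen boundary.
#'
#' @param img RGB \code{raster_image}.
#' @param cfg \code{radial_config}.
#' @return A list of contours (as from \code{\link{find_contours}}, outer
#'   contours only).
#' @export
extract_lumen_candidates <- function(img, cfg = radial_config()) {
  g <- extract_channel(img, 2L)
  m <- threshold(g, cfg$green_threshold, inverted = FALSE)
  m <- morph(m, "erode", cfg$erode_iters)
  m <- morph(m, "dilate", cfg$dilate_iters)
  m <- fill_small_holes(m, cfg$max_hole_px)
  m <- morph(m, "erode", cfg$second_erode_iters)
  Filter(function(ct) !ct$is_hole, find_contours(m))
}

#' Outward boundary normal at a contour point
#'
#' The tangent is a cyclic central difference between points \code{i - k}
#' and \code{i + k}; the normal is the tangent rotated 90 degrees, oriented
#' away from the contour interior using the polygon's winding, and scaled to
#' unit length. A degenerate (zero) tangent falls back to a widened window.
#'
#' @param points n x 2 matrix of closed-contour vertices.
#' @param i 1-based point index.
#' @param k Half-window in contour points.
#' @return Unit 2-vector (x, y).
#' @export
boundary_normal <- function(points, i, k = 2L) {
  n <- nrow(points)
  sa <- contour_signed_area(points)
  kk <- k
  repeat {
    ip <- ((i - 1 + kk) %% n) + 1L
    im <- ((i - 1 - kk) %% n) + 1L
    tg <- points[ip, ] - points[im, ]
    if (any(tg != 0) || kk >= n) break
    kk <- kk + 1L # coincident points: widen the window
  }
  len <- sqrt(sum(tg^2))
  if (len == 0) return(c(0, 0))
  tg <- tg / len
  # positive raw shoelace area = outer orientation; outward = (ty, -tx)
  if (sa >= 0) c(tg[2L], -tg[1L]) else c(-tg[2L], tg[1L])
}

contour_normals <- function(points, k = 2L) {
  t(vapply(seq_len(nrow(points)), function(i) boundary_normal(points, i, k),
           numeric(2L)))
}

#' Membrane hit ratio of a lumen candidate
#'
#' Fraction of boundary points whose outward normal probe (integer offsets
#' \code{probe_min_px..probe_max_px}) finds at least one membrane pixel.
#' Samples outside the image are misses.
#'
#' @param points Lumen contour vertices (n x 2).
#' @param membrane Brown-stain \code{binary_mask} from
#'   \code{\link{segment_brown_mask}} (the raw, pre-cleanup mask).
#' @param cfg \code{radial_config}.
#' @return Fraction in \code{[0, 1]}.
#' @export
membrane_hit_ratio <- function(points, membrane, cfg = radial_config()) {
  if (nrow(points) == 0L) return(0)
  normals <- contour_normals(points)
  hits <- cpp_probe_hits(apply_int(points), normals, mask_matrix(membrane),
                         cfg$probe_min_px, cfg$probe_max_px)
  mean(hits)
}

apply_int <- function(m) {
  m <- round(m)
  storage.mode(m) <- "integer"
  m
}

#' Validate lumen candidates and emit closed vessels
#'
#' A candidate is valid when its membrane hit ratio reaches the
#' size-adjusted threshold. Each valid lumen is compensated for the net
#' erosion of the extraction pipeline (\code{erode_iters - dilate_iters +
#' second_erode_iters} px of dilation on its filled region), re-traced, and
#' emitted as a closed \code{vessel_contour} with \code{source = "radial"}
#' and the original lumen boundary as its inner contour. The stage-(a)
#' small-object filter is applied last.
#'
#' @param candidates List of lumen contours
#'   (from \code{\link{extract_lumen_candidates}}).
#' @param membrane Raw brown mask (see \code{\link{membrane_hit_ratio}}).
#' @param cfg \code{radial_config}.
#' @param size_filter \code{hsv_config} providing the small-object filter.
#' @return A list of \code{vessel_contour} objects.
#' @export
validate_and_close <- function(candidates, membrane, cfg = radial_config(),
                               size_filter = hsv_config()) {
  comp <- cfg$erode_iters - cfg$dilate_iters + cfg$second_erode_iters
  out <- list()
  for (cand in candidates) {
    pts <- if (is.list(cand)) cand$points else cand
    ratio <- membrane_hit_ratio(pts, membrane, cfg)
    thr <- if (nrow(pts) < cfg$small_contour_points) cfg$small_ratio
           else cfg$base_ratio
    if (ratio < thr) next
    # rasterise, compensate and re-trace inside a local window
    pad <- comp + 2L
    x0 <- min(pts[, 1L]) - pad; y0 <- min(pts[, 2L]) - pad
    local <- cbind(pts[, 1L] - x0, pts[, 2L] - y0)
    region <- rasterise_contour(local, max(local[, 1L]) + pad + 1L,
                                max(local[, 2L]) + pad + 1L)
    if (comp > 0) region <- morph(region, "dilate", comp)
    traced <- Filter(function(ct) !ct$is_hole, find_contours(region))
    if (!length(traced)) next
    areas <- vapply(traced, function(ct) contour_area(ct$points), 0)
    outer <- traced[[which.max(areas)]]$points
    outer <- cbind(outer[, 1L] + x0, outer[, 2L] + y0)
    v <- vessel_contour(outer, inner = pts, source = "radial")
    v$hit_ratio <- ratio
    if (keep_vessel(v, size_filter)) out <- c(out, list(v))
  }
  out
}
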