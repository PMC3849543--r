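#' Synthetic TMA scene specification
#'
#' Describes an IHC-like synthetic image: DAB-brown annular vessels (closed,
#' or open with an arc of the ring erased) with bright near-white lumens on
#' a pale pink tissue background, plus small solid brown blobs emulating
#' macrophages. Defaults are chosen so that, by construction, vessel rings
#' satisfy the brown HSV gate (H <= 20, S > 30), lumens exceed the green
#' threshold 236, the background fails both, vessel bounding boxes exceed
#' 20 px, and distractors stay below the size filter.
#'
#' @param width,height Image size, px.
#' @param n_closed,n_open,n_distractors Object counts.
#' @param radius_range Outer vessel radius range, px.
#' @param ring_thickness_range Ring (membrane) thickness range, px.
#' @param gap_fraction_range Fraction of circumference erased for open
#'   vessels, in (0, 0.5].
#' @param distractor_diameter_range Distractor diameter range, px (<= 15).
#' @param noise_sigma Gaussian pixel noise SD, grey levels.
#' @param seed Integer seed; scenes are bit-reproducible per seed.
#' @param palette Named list of RGB triplets: \code{background},
#'   \code{vessel}, \code{lumen}.
#' @return A \code{scene_spec} object.
#' @export
scene_spec <- function(width = 1024L, height = 1024L, n_closed = 10L,
                       n_open = 10L, n_distractors = 15L,
                       radius_range = c(16, 36),
                       ring_thickness_range = c(6, 10),
                       gap_fraction_range = c(0.05, 0.3),
                       distractor_diameter_range = c(6, 15),
                       noise_sigma = 2, seed = 1L,
                       palette = list(background = c(232, 213, 218),
                                      vessel = c(150, 90, 40),
                                      lumen = c(252, 252, 252))) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_closed = as.integer(n_closed), n_open = as.integer(n_open),
               n_distractors = as.integer(n_distractors),
               radius_range = radius_range,
               ring_thickness_range = ring_thickness_range,
               gap_fraction_range = gap_fraction_range,
               distractor_diameter_range = distractor_diameter_range,
               noise_sigma = noise_sigma, seed = as.integer(seed),
               palette = palette)
  stopifnot(spec$width >= 1, spec$height >= 1,
            spec$n_closed >= 0, spec$n_open >= 0, spec$n_distractors >= 0,
            all(spec$gap_fraction_range > 0),
            all(spec$gap_fraction_range <= 0.5),
            spec$distractor_diameter_range[2] <= 15)
  structure(spec, class = "scene_spec")
}

# run code under a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

#' Generate a synthetic IHC scene with ground truth
#'
#' Objects are placed by rejection sampling without outer-boundary overlap
#' and fully inside the image; generation is deterministic for a fixed seed.
#'
#' @param spec A \code{scene_spec}.
#' @return A list: \code{image} (RGB \code{raster_image}) and \code{truth},
#'   a data.frame of ground-truth objects with columns \code{kind}
#'   (\code{closed_vessel}/\code{open_vessel}/\code{distractor}), \code{cx},
#'   \code{cy}, \code{outer_radius}, \code{lumen_radius}, \code{gap_start_deg},
#'   \code{gap_extent_deg}.
#' @export
generate_scene <- function(spec = scene_spec()) {
  with_seed(spec$seed, {
    w <- spec$width; h <- spec$height
    truth <- place_objects(spec)
    img <- draw_scene(spec, truth)
    list(image = img, truth = truth)
  })
}

place_objects <- function(spec) {
  kinds <- c(rep("closed_vessel", spec$n_closed),
             rep("open_vessel", spec$n_open),
             rep("distractor", spec$n_distractors))
  n <- length(kinds)
  out <- data.frame(kind = kinds, cx = NA_real_, cy = NA_real_,
                    outer_radius = NA_real_, lumen_radius = NA_real_,
                    gap_start_deg = NA_real_, gap_extent_deg = NA_real_,
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  for (i in seq_len(n)) {
    if (kinds[i] == "distractor") {
      r <- stats::runif(1, spec$distractor_diameter_range[1],
                        spec$distractor_diameter_range[2]) / 2
      lum <- NA_real_
    } else {
      r <- stats::runif(1, spec$radius_range[1], spec$radius_range[2])
      th <- stats::runif(1, spec$ring_thickness_range[1],
                         spec$ring_thickness_range[2])
      lum <- max(r - th, 3)
    }
    placed <- FALSE
    for (try in seq_len(500L)) {
      margin <- r + 3
      cx <- stats::runif(1, margin, spec$width - 1 - margin)
      cy <- stats::runif(1, margin, spec$height - 1 - margin)
      prev <- out[seq_len(i - 1L), , drop = FALSE]
      prev <- prev[!is.na(prev$cx), , drop = FALSE]
      if (!nrow(prev) ||
          all(sqrt((prev$cx - cx)^2 + (prev$cy - cy)^2) >
              prev$outer_radius + r + 6)) {
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place object ", i, " of ", n,
           ": scene too crowded for rejection sampling")
    out$cx[i] <- round(cx); out$cy[i] <- round(cy)
    out$outer_radius[i] <- round(r)
    out$lumen_radius[i] <- if (is.na(lum)) NA_real_ else round(lum)
    if (kinds[i] == "open_vessel") {
      gapf <- stats::runif(1, spec$gap_fraction_range[1],
                           spec$gap_fraction_range[2])
      out$gap_start_deg[i] <- round(stats::runif(1, 0, 360), 1)
      out$gap_extent_deg[i] <- round(360 * gapf, 1)
    }
  }
  out
}

draw_scene <- function(spec, truth) {
  w <- spec$width; h <- spec$height
  pal <- spec$palette
  ch <- function(v) matrix(v, h, w)
  img <- array(0, dim = c(h, w, 3L))
  for (k in 1:3) img[, , k] <- ch(pal$background[k])
  for (i in seq_len(nrow(truth))) {
    o <- truth[i, ]
    r <- o$outer_radius
    x0 <- max(0, o$cx - r - 1); x1 <- min(w - 1, o$cx + r + 1)
    y0 <- max(0, o$cy - r - 1); y1 <- min(h - 1, o$cy + r + 1)
    xs <- x0:x1; ys <- y0:y1
    dx <- outer(rep(1, length(ys)), xs - o$cx)
    dy <- outer(ys - o$cy, rep(1, length(xs)))
    d <- sqrt(dx^2 + dy^2)
    rows <- ys + 1L; cols <- xs + 1L
    if (o$kind == "distractor") {
      sel <- d <= r
      for (k in 1:3) {
        plane <- img[rows, cols, k]
        plane[sel] <- pal$vessel[k]
        img[rows, cols, k] <- plane
      }
    } else {
      ring <- d <= r & d >= o$lumen_radius
      if (o$kind == "open_vessel") {
        ang <- (atan2(dy, dx) * 180 / pi) %% 360
        rel <- (ang - o$gap_start_deg) %% 360
        ring <- ring & !(rel < o$gap_extent_deg)
      }
      lum <- d < o$lumen_radius
      for (k in 1:3) {
        plane <- img[rows, cols, k]
        plane[ring] <- pal$vessel[k]
        plane[lum] <- pal$lumen[k]
        img[rows, cols, k] <- plane
      }
    }
  }
  if (spec$noise_sigma > 0) {
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sigma),
                       dim = dim(img))
    img <- pmin(pmax(img, 0), 255)
  }
  raster_image(round(img), "RGB")
}

#' Score detections against ground truth
#'
#' Greedy nearest-centroid matching: candidate (detection, truth) pairs with
#' centroid distance within \code{match_radius} (per-object truth outer
#' radius by default) are assigned in order of increasing distance, each
#' detection and truth object at most once. TP = vessels matched, FN =
#' vessels unmatched, FP = detections matched to a distractor or to nothing,
#' TN = distractors matched by no detection. Matching is invariant to the
#' order of the detection list.
#'
#' @param detected List of \code{vessel_contour}s.
#' @param truth Ground-truth data.frame (see \code{\link{generate_scene}}).
#' @param match_radius Matching radius, px; \code{NULL} = each truth
#'   object's outer radius.
#' @return A list with \code{sensitivity}, \code{specificity}, and the
#'   confusion counts \code{tp}, \code{fn}, \code{fp}, \code{tn}.
#' @export
score_detections <- function(detected, truth, match_radius = NULL) {
  nv <- sum(truth$kind != "distractor")
  nd <- sum(truth$kind == "distractor")
  if (!length(detected) && !nrow(truth))
    return(list(sensitivity = 1, specificity = 1, tp = 0L, fn = 0L,
                fp = 0L, tn = 0L))
  cents <- if (length(detected))
    t(vapply(detected, function(v) contour_centroid(v$outer), numeric(2L)))
  else matrix(0, 0L, 2L)
  radii <- if (is.null(match_radius)) truth$outer_radius
           else rep(match_radius, nrow(truth))
  pairs <- NULL
  if (length(detected) && nrow(truth)) {
    dmat <- outer(cents[, 1L], truth$cx, "-")^2 +
            outer(cents[, 2L], truth$cy, "-")^2
    dmat <- sqrt(dmat)
    ok <- which(dmat <= matrix(radii, nrow(dmat), ncol(dmat), byrow = TRUE),
                arr.ind = TRUE)
    if (nrow(ok)) {
      pairs <- data.frame(det = ok[, 1L], tru = ok[, 2L],
                          dist = dmat[ok])
      # deterministic order independent of detection-list permutation
      pairs <- pairs[order(pairs$dist, pairs$tru, cents[pairs$det, 1L],
                           cents[pairs$det, 2L]), , drop = FALSE]
    }
  }
  det_used <- logical(length(detected))
  tru_used <- logical(nrow(truth))
  if (!is.null(pairs)) {
    for (j in seq_len(nrow(pairs))) {
      d <- pairs$det[j]; t <- pairs$tru[j]
      if (!det_used[d] && !tru_used[t]) {
        det_used[d] <- TRUE
        tru_used[t] <- TRUE
      }
    }
  }
  is_vessel <- truth$kind != "distractor"
  tp <- sum(tru_used & is_vessel)
  fn <- sum(!tru_used & is_vessel)
  tn <- sum(!tru_used & !is_vessel)
  fp <- sum(tru_used & !is_vessel) + sum(!det_used)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else 1,
       specificity = if (tn + fp > 0) tn / (tn + fp) else 1,
       tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Write a ground-truth table as JSON
#'
#' @param truth Ground-truth data.frame.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
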