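#' Pipeline run configuration
#'
#' Bundles the two stage configurations, calibration, and output options.
#'
#' @param mode Which stages to run: \code{"both"} (default), \code{"hsv"},
#'   or \code{"radial"}.
#' @param hsv An \code{hsv_config}.
#' @param radial A \code{radial_config}.
#' @param cal A \code{calibration}.
#' @param out_dir Output directory, or \code{NULL} to skip file output.
#' @param overlay Write the contour overlay TIFF.
#' @param xlsx Request XLSX output (unsupported; errors).
#' @param dedup_iou Bounding-box IoU above which an HSV and a radial vessel
#'   are considered duplicates (the HSV one is kept).
#' @return A \code{run_config} object.
#' @export
run_config <- function(mode = c("both", "hsv", "radial"),
                       hsv = hsv_config(), radial = radial_config(),
                       cal = calibration(), out_dir = NULL, overlay = FALSE,
                       xlsx = FALSE, dedup_iou = 0.5) {
  structure(list(mode = match.arg(mode), hsv = hsv, radial = radial,
                 cal = cal, out_dir = out_dir, overlay = overlay,
                 xlsx = xlsx, dedup_iou = dedup_iou),
            class = "run_config")
}

#' Run the two-stage vessel segmentation pipeline on one image
#'
#' Stage (a) segments brown-stained closed vessels in HSV space; stage (b)
#' detects bright lumens and validates them by radial membrane probing,
#' using stage (a)'s raw brown mask as membrane evidence. Overlapping
#' detections from the two stages (bbox IoU > \code{dedup_iou}) are merged,
#' keeping the HSV one. Each surviving vessel is measured and an image-level
#' density report computed. When \code{cfg$out_dir} is set, the measurement
#' CSV, density CSV, run-metadata JSON and (optionally) the contour overlay
#' TIFF are written there.
#'
#' @param img RGB \code{raster_image}, or a file path readable by
#'   \code{\link{load_image}}.
#' @param cfg A \code{run_config}.
#' @param drop_ids Optional vessel ids to exclude from outputs (manual
#'   curation of wrong segmentations).
#' @return Invisibly, a list: \code{vessels} (list of
#'   \code{vessel_contour}), \code{records} (morphometry data.frame),
#'   \code{density} (one-row data.frame).
#' @export
run_pipeline <- function(img, cfg = run_config(), drop_ids = NULL) {
  if (is.character(img)) img <- load_image(img)
  membrane <- segment_brown_mask(img, cfg$hsv)
  vessels <- list()
  if (cfg$mode %in% c("both", "hsv")) {
    cleaned <- cleanup(membrane, cfg$hsv)
    vessels <- extract_vessels(cleaned, cfg$hsv)
  }
  if (cfg$mode %in% c("both", "radial")) {
    cands <- extract_lumen_candidates(img, cfg$radial)
    radial <- validate_and_close(cands, membrane, cfg$radial, cfg$hsv)
    vessels <- dedupe_vessels(vessels, radial, cfg$dedup_iou)
  }
  records <- measure_all(vessels, cfg$cal)
  if (!is.null(drop_ids) && nrow(records)) {
    keep <- !(records$vessel_id %in% drop_ids)
    records <- records[keep, , drop = FALSE]
    vessels <- vessels[keep]
  }
  density <- vascular_density(records, img, cfg$cal)
  if (!is.null(cfg$out_dir))
    write_outputs(img, vessels, records, density, cfg)
  invisible(list(vessels = vessels, records = records, density = density))
}

measure_all <- function(vessels, cal) {
  if (!length(vessels)) {
    rec <- measure_vessel(vessel_contour(rbind(c(0, 0), c(1, 0), c(1, 1))),
                          cal)
    return(rec[0, , drop = FALSE])
  }
  do.call(rbind, lapply(seq_along(vessels), function(i)
    measure_vessel(vessels[[i]], cal, vessel_id = i)))
}

bbox_iou <- function(a, b) {
  inter <- bbox_intersection(a, b)
  union <- a["w"] * a["h"] + b["w"] * b["h"] - inter
  unname(if (union > 0) inter / union else 0)
}

bbox_intersection <- function(a, b) {
  ix <- max(0, min(a["x"] + a["w"], b["x"] + b["w"]) - max(a["x"], b["x"]))
  iy <- max(0, min(a["y"] + a["h"], b["y"] + b["h"]) - max(a["y"], b["y"]))
  unname(ix * iy)
}

# Keep all HSV vessels; add radial vessels that do not duplicate one.
# Duplication is judged by intersection over the smaller box: a radial
# vessel is typically the closed lumen nested inside the HSV ring detection
# of the same vessel, and nested boxes have low IoU but high containment.
# This subsumes the IoU criterion (IoM >= IoU), so no two emitted vessels
# ever have bbox IoU above the cut.
dedupe_vessels <- function(hsv_vessels, radial_vessels, iou_cut) {
  keep <- Filter(function(rv)
    !any(vapply(hsv_vessels, function(hv) {
      iom <- bbox_intersection(hv$bbox, rv$bbox) /
        min(hv$bbox["w"] * hv$bbox["h"], rv$bbox["w"] * rv$bbox["h"])
      iom > iou_cut
    }, TRUE)),
    radial_vessels)
  c(hsv_vessels, keep)
}

write_outputs <- function(img, vessels, records, density, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(cfg$out_dir)) stop("cannot create output dir: ", cfg$out_dir)
  write_measurements(records, file.path(cfg$out_dir, "measurements.csv"),
                     xlsx = cfg$xlsx)
  utils::write.csv(density, file.path(cfg$out_dir, "density.csv"),
                   row.names = FALSE)
  meta <- list(mode = cfg$mode, hsv = unclass(cfg$hsv),
               radial = unclass(cfg$radial),
               microns_per_pixel = cfg$cal$microns_per_pixel,
               dedup_iou = cfg$dedup_iou, n_vessels = length(vessels))
  jsonlite::write_json(meta, file.path(cfg$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  if (isTRUE(cfg$overlay))
    write_image(render_overlay(img, vessels),
                file.path(cfg$out_dir, "overlay.tiff"))
  invisible(NULL)
}

#' Render vessel contours onto an image
#'
#' Returns a copy of the image with each vessel's outer contour stroked
#' 1 px wide (red for HSV detections, blue for radial) and inner (lumen)
#' contours dashed. No pixels outside the stroked contours are altered.
#'
#' @param img RGB \code{raster_image}.
#' @param vessels List of \code{vessel_contour}s.
#' @param colours Named list of RGB triplets for the two sources.
#' @return An RGB \code{raster_image}.
#' @export
render_overlay <- function(img, vessels,
                           colours = list(hsv = c(255, 0, 0),
                                          radial = c(0, 0, 255))) {
  out <- unclass(img)
  attributes(out) <- list(dim = dim(unclass(img)))
  h <- dim(out)[1L]; w <- dim(out)[2L]
  stroke <- function(pts, col) {
    px <- round(pts)
    ok <- px[, 1L] >= 0 & px[, 1L] < w & px[, 2L] >= 0 & px[, 2L] < h
    px <- px[ok, , drop = FALSE]
    for (k in 1:3) {
      plane <- out[, , k]
      plane[cbind(px[, 2L] + 1L, px[, 1L] + 1L)] <- col[k]
      out[, , k] <<- plane
    }
  }
  for (v in vessels) {
    col <- colours[[v$source]]
    stroke(v$outer, col)
    if (!is.null(v$inner)) {
      idx <- seq_len(nrow(v$inner))
      stroke(v$inner[idx %% 4L < 2L, , drop = FALSE], col) # dashed
    }
  }
  raster_image(out, "RGB")
}

#' Pooled detection scores over a batch of synthetic scenes
#'
#' Generates one scene per seed, runs the full two-stage pipeline with the
#' given configuration, scores detections against the scene's ground truth,
#' and pools the confusion counts across scenes. This is the synthetic
#' analogue of a sensitivity/specificity evaluation on annotated TMA cores.
#'
#' @param seeds Integer vector of scene seeds.
#' @param spec_fn Function mapping a seed to a \code{scene_spec}; the
#'   default draws 10-50 vessels (split evenly between closed and open) and
#'   10-30 distractors per 1024 x 1024 scene.
#' @param cfg A \code{run_config}.
#' @return A list: pooled \code{sensitivity} and \code{specificity}
#'   (fractions), the pooled confusion counts, and \code{n_vessels} /
#'   \code{n_distractors} totals.
#' @export
pooled_detection_scores <- function(seeds, spec_fn = default_scene_for_seed,
                                    cfg = run_config()) {
  tp <- fn <- fp <- tn <- nd <- 0L
  for (s in seeds) {
    scene <- generate_scene(spec_fn(s))
    res <- run_pipeline(scene$image, cfg)
    sc <- score_detections(res$vessels, scene$truth)
    tp <- tp + sc$tp; fn <- fn + sc$fn; fp <- fp + sc$fp; tn <- tn + sc$tn
    nd <- nd + sum(scene$truth$kind == "distractor")
  }
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else 1,
       specificity = if (tn + fp > 0) tn / (tn + fp) else 1,
       tp = tp, fn = fn, fp = fp, tn = tn,
       n_vessels = tp + fn, n_distractors = nd)
}

#' @rdname pooled_detection_scores
#' @param seed Scene seed.
#' @export
default_scene_for_seed <- function(seed) {
  counts <- with_seed(as.integer((as.numeric(seed) * 7919) %% 2147483647), {
    n_vessels <- sample(10:50, 1L)
    n_open <- sample(0:n_vessels, 1L)
    c(n_vessels - n_open, n_open, sample(10:30, 1L))
  })
  scene_spec(width = 1024L, height = 1024L, n_closed = counts[1L],
             n_open = counts[2L], n_distractors = counts[3L], seed = seed)
}
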