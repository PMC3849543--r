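# Shared fixtures and independent oracles, all built in code at test time.

# disc mask: pixels whose centre lies within r + 0.5 of (c0, c0)
# (half-pixel coverage, so the traced boundary straddles radius r)
disc_mask <- function(r, pad = 4L, centre = NULL) {
  n <- 2L * (r + pad) + 1L
  c0 <- if (is.null(centre)) r + pad else centre
  binary_mask(outer(0:(n - 1L), 0:(n - 1L),
                    function(y, x) sqrt((x - c0)^2 + (y - c0)^2) <= r + 0.5))
}

# annulus mask with given outer/inner radii
annulus_mask <- function(r_out, r_in, pad = 4L) {
  n <- 2L * (r_out + pad) + 1L
  c0 <- r_out + pad
  d <- outer(0:(n - 1L), 0:(n - 1L),
             function(y, x) sqrt((x - c0)^2 + (y - c0)^2))
  binary_mask(d <= r_out + 0.5 & d >= r_in - 0.5)
}

# closed 8-connected square chain with side `s`, corner at (x0, y0)
square_chain <- function(s, x0 = 0, y0 = 0) {
  pts <- rbind(cbind(0:s, 0), cbind(s, 1:s), cbind((s - 1):0, s),
               cbind(0, (s - 1):1))
  cbind(pts[, 1] + x0, pts[, 2] + y0)
}

# star polygon r(theta) = r * (1 + depth * cos(spikes * theta))
star_polygon <- function(r = 60, depth = 0.2, spikes = 8L, n = 720L,
                         centre = c(100, 100)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  rad <- r * (1 + depth * cos(spikes * th))
  cbind(centre[1] + rad * cos(th), centre[2] + rad * sin(th))
}

# brute-force 3x3 min/max filter oracle (outside the image = background)
oracle_morph <- function(mask, op, iterations = 1L) {
  m <- mask_int(mask)
  nr <- nrow(m); nc <- ncol(m)
  for (it in seq_len(iterations)) {
    out <- matrix(0L, nr, nc)
    for (r in seq_len(nr)) {
      for (c in seq_len(nc)) {
        vals <- integer(0)
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; cc <- c + dc
          vals <- c(vals, if (rr >= 1 && cc >= 1 && rr <= nr && cc <= nc)
            m[rr, cc] else 0L)
        }
        out[r, c] <- if (op == "dilate") max(vals) else min(vals)
      }
    }
    m <- out
  }
  m
}

# flood-fill connected-component count oracle (BFS, chosen connectivity)
oracle_component_count <- function(mask, connectivity = 8L) {
  m <- mask_int(mask)
  nr <- nrow(m); nc <- ncol(m)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  count <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (m[r0, c0] == 0L || seen[r0, c0]) next
    count <- count + 1L
    queue <- matrix(c(r0, c0), 1L)
    seen[r0, c0] <- TRUE
    while (nrow(queue)) {
      p <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        rr <- p[1L] + offs[k, 1L]; cc <- p[2L] + offs[k, 2L]
        if (rr >= 1 && cc >= 1 && rr <= nr && cc <= nc &&
            m[rr, cc] != 0L && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  count
}

mask_int <- function(mask) {
  x <- unclass(mask)
  attributes(x) <- list(dim = dim(x))
  storage.mode(x) <- "integer"
  x
}

# random small binary mask, reproducible
random_mask <- function(nr = 16L, nc = 16L, p = 0.4) {
  binary_mask(matrix(stats::runif(nr * nc) < p, nr, nc))
}

# RGB image of constant colour
flat_rgb <- function(col, w = 8L, h = 8L) {
  a <- array(0, c(h, w, 3L))
  for (k in 1:3) a[, , k] <- col[k]
  raster_image(a, "RGB")
}

# synthetic lumen + membrane-arc scene: bright disc (lumen) of radius r_lum,
# membrane arc of angular fraction `frac` at radius r_lum..r_lum+thick,
# centred in a dark image; returns the RGB image and the membrane mask
arc_scene <- function(r_lum = 30, thick = 6, frac = 1.0, size = 101L,
                      arc_start = 0) {
  c0 <- (size - 1) / 2
  d <- outer(0:(size - 1L), 0:(size - 1L),
             function(y, x) sqrt((x - c0)^2 + (y - c0)^2))
  ang <- outer(0:(size - 1L), 0:(size - 1L),
               function(y, x) (atan2(y - c0, x - c0) * 180 / pi) %% 360)
  img <- array(0, c(size, size, 3L))
  for (k in 1:3) img[, , k] <- 80 # dark tissue
  lum <- d <= r_lum + 0.5
  arc <- d > r_lum + 0.5 & d <= r_lum + thick &
    ((ang - arc_start) %% 360) < 360 * frac
  brown <- c(150, 90, 40)
  for (k in 1:3) {
    plane <- img[, , k]
    plane[lum] <- 252
    plane[arc] <- brown[k]
    img[, , k] <- plane
  }
  list(image = raster_image(round(img), "RGB"),
       membrane = binary_mask(arc), lumen_mask = binary_mask(lum),
       centre = c(c0, c0), r_lum = r_lum)
}
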