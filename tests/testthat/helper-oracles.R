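# Independent oracles used across the suite. They deliberately share no
# code with the package internals: distances are computed by an O(points x
# edges) loop in plain R, and Wilcoxon p-values by full enumeration.

# random star-shaped (hence simple) polygon around a centre
rand_polygon <- function(n_vert = 12, cx = 500, cy = 500,
                         rmin = 100, rmax = 350) {
  th <- sort(runif(n_vert, 0, 2 * pi))
  r <- runif(n_vert, rmin, rmax)
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# signed distance of points to closed rings: per-edge minimum plus
# even-odd ray cast, all in R
oracle_signed_distance <- function(px, py, rings) {
  n <- length(px)
  best <- rep(Inf, n)
  cross <- integer(n)
  for (ring in rings) {
    nv <- nrow(ring)
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1L else i + 1L
      x1 <- ring[i, 1]; y1 <- ring[i, 2]
      x2 <- ring[j, 1]; y2 <- ring[j, 2]
      dx <- x2 - x1; dy <- y2 - y1
      L2 <- dx * dx + dy * dy
      t <- if (L2 > 0) pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2)) else 0
      d2 <- (px - x1 - t * dx)^2 + (py - y1 - t * dy)^2
      best <- pmin(best, d2)
      hit <- (y1 <= py & y2 > py) | (y2 <= py & y1 > py)
      if (any(hit)) {
        xint <- x1 + (py[hit] - y1) / dy * dx
        cross[hit] <- cross[hit] + (xint > px[hit])
      }
    }
  }
  sqrt(best) * ifelse(cross %% 2 == 1, -1, 1)
}

oracle_region <- function(d, band) {
  ifelse(d < 0, "TC", ifelse(d < band, "TF", "PT"))
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
enum_signed_rank_p <- function(a, b) {
  d <- (a - b)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# exact two-sided rank-sum p by enumerating all C(m+n, m) group assignments
enum_rank_sum_p <- function(a, b) {
  m <- length(a)
  pool <- c(a, b)
  rk <- rank(pool)
  u_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(length(pool), m)
  u_all <- apply(combs, 2, function(idx) sum(rk[idx]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# small random sample map for I/O and quantification tests
rand_sample_map <- function(n_cells = 30, n_rois = 2, panel = crc_panel(),
                            patient_id = "Pt", lesion_type = "primary") {
  rois <- data.frame(
    roi_id = paste0("r", seq_len(n_rois)),
    xmin = 0, ymin = 0, xmax = 500, ymax = 400,
    area_mm2 = runif(n_rois, 0.05, 0.2), stringsAsFactors = FALSE)
  cells <- data.frame(
    cell_id = sprintf("c%d", seq_len(n_cells)),
    roi_id = rois$roi_id[sample.int(n_rois, n_cells, replace = TRUE)],
    x = runif(n_cells, 0, 500), y = runif(n_cells, 0, 400),
    compartment = sample(c("tumor", "stroma"), n_cells, replace = TRUE),
    stringsAsFactors = FALSE)
  for (m in panel) cells[[m]] <- sample(c(TRUE, FALSE), n_cells, replace = TRUE)
  sample_map(patient_id, lesion_type, "les1", panel, rois, cells)
}

# stroma-only point sample over one square ROI
make_point_sample <- function(pts, roi_side = 2000) {
  cells <- data.frame(cell_id = sprintf("c%d", seq_len(nrow(pts))), roi_id = "r1",
                      x = pts[, 1], y = pts[, 2], compartment = "stroma",
                      stringsAsFactors = FALSE)
  for (m in crc_panel()) cells[[m]] <- FALSE
  rois <- data.frame(roi_id = "r1", xmin = 0, ymin = 0, xmax = roi_side,
                     ymax = roi_side, area_mm2 = roi_side^2 / 1e6,
                     stringsAsFactors = FALSE)
  sample_map("Pt", "primary", "les1", crc_panel(), rois, cells)
}

# hand-built square boundary, for exact-distance scenarios
square_boundary <- function(side = 100) {
  structure(list(rings = list(cbind(c(0, side, side, 0), c(0, 0, side, side))),
                 grid_resolution = 5, closing_radius = 0),
            class = "tumor_boundary")
}

# tiny synthetic config used where full study scale is not needed
tiny_config <- function(seed = 1, n_patients = 2, ...) {
  synth_config(seed = seed, n_patients = n_patients, rois_min = 2,
               rois_max = 2, ...)
}
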