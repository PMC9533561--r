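# Tumor-boundary estimation and TC / TF / PT region assignment.
#
# The boundary of each ROI's tumor mask is estimated from the positions of
# tumor-compartment cells: occupancy is rasterized on a grid, closed
# morphologically (disc structuring element), holes are filled and the 0.5
# iso-contour of the mask is extracted as one or more polygons. Cells and
# tissue area are then banded by signed Euclidean distance to the polygon
# set: tumor center (TC) inside the mask, invasive front (TF) within
# band_width (150 um) outside it, peritumor (PT) at or beyond band_width.

#' Estimate the tumor boundary of one ROI
#'
#' @param cells Cell table of a single ROI (needs `x`, `y`, `compartment`).
#' @param roi One-row ROI descriptor (`xmin`, `ymin`, `xmax`, `ymax`).
#' @param grid_resolution Raster cell size in micrometres (default 5).
#' @param closing_radius Radius of the morphological closing disc in
#'   micrometres (default 30, about two cell diameters); bridges gaps
#'   between neighbouring tumor cells so the mask is solid.
#' @return Object of class `tumor_boundary`: a list of polygon rings
#'   (2-column matrices in micrometres) plus the grid resolution used.
#' @export
estimate_boundary <- function(cells, roi, grid_resolution = 5, closing_radius = 30) {
  tum <- cells[cells$compartment == "tumor", , drop = FALSE]
  if (!nrow(tum))
    stop("no tumor region: ROI has no tumor-compartment cells", call. = FALSE)
  w <- roi$xmax - roi$xmin
  h <- roi$ymax - roi$ymin
  nx <- max(2L, as.integer(ceiling(w / grid_resolution)))
  ny <- max(2L, as.integer(ceiling(h / grid_resolution)))
  px <- w / nx
  py <- h / ny
  ix <- pmin(nx, pmax(1L, as.integer(floor((tum$x - roi$xmin) / px)) + 1L))
  iy <- pmin(ny, pmax(1L, as.integer(floor((tum$y - roi$ymin) / py)) + 1L))
  occ <- matrix(0, nx, ny)
  occ[cbind(ix, iy)] <- 1

  rpx <- max(1L, as.integer(round(closing_radius / ((px + py) / 2))))
  brush <- EBImage::makeBrush(2L * rpx + 1L, shape = "disc")
  mask <- EBImage::fillHull(EBImage::closing(EBImage::Image(occ), brush))
  mask <- as.matrix(EBImage::imageData(mask))

  # pad with a zero frame so every contour is a closed ring
  zp <- matrix(0, nx + 2L, ny + 2L)
  zp[2:(nx + 1L), 2:(ny + 1L)] <- mask
  xc <- roi$xmin + (seq_len(nx + 2L) - 1.5) * px
  yc <- roi$ymin + (seq_len(ny + 2L) - 1.5) * py
  cl <- contourLines(x = xc, y = yc, z = zp, levels = 0.5)
  rings <- lapply(cl, function(g) cbind(g$x, g$y))
  rings <- Filter(function(r) nrow(r) >= 3 && abs(ring_area(r)) > 0, rings)
  if (!length(rings))
    stop("no tumor region: mask vanished during boundary extraction", call. = FALSE)
  structure(list(rings = rings, grid_resolution = grid_resolution,
                 closing_radius = closing_radius),
            class = "tumor_boundary")
}

ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

#' Total enclosed area of a boundary, in square micrometres
#' @param boundary A `tumor_boundary`.
#' @return Area in um^2 (sum of absolute ring areas).
#' @export
boundary_area_um2 <- function(boundary) {
  sum(vapply(boundary$rings, function(r) abs(ring_area(r)), 0))
}

#' @export
print.tumor_boundary <- function(x, ...) {
  cat(sprintf("<tumor_boundary> %d polygon(s), area %.3f mm2, grid %g um\n",
              length(x$rings), boundary_area_um2(x) / 1e6, x$grid_resolution))
  invisible(x)
}

#' Signed distance from points to a tumor boundary
#'
#' Exact Euclidean distance to the nearest polygon edge, negative inside a
#' polygon (even-odd rule) and positive outside. Vectorized over points.
#'
#' @param x,y Point coordinates in micrometres.
#' @param boundary A `tumor_boundary`, or any list with a `rings` element.
#' @return Numeric vector of signed distances in micrometres.
#' @export
distance_to_boundary <- function(x, y, boundary) {
  stopifnot(length(x) == length(y))
  if (!length(x)) return(numeric(0))
  signed_distance_cpp(as.numeric(x), as.numeric(y), boundary$rings)
}

#' Estimate boundaries for every ROI of a sample
#'
#' @param sample A [sample_map()].
#' @param grid_resolution,closing_radius Passed to [estimate_boundary()].
#' @param no_tumor_policy What to do with an ROI that contains no
#'   tumor-compartment cell: `"error"` (default; such fields cannot be
#'   banded and silently mislabelling them would mask the problem) or
#'   `"all_pt"`, which marks the ROI so all its cells and area are PT.
#' @return Named list (by `roi_id`) of `tumor_boundary` objects; ROIs under
#'   the `"all_pt"` policy carry `NA`.
#' @export
estimate_boundaries <- function(sample, grid_resolution = 5, closing_radius = 30,
                                no_tumor_policy = c("error", "all_pt")) {
  no_tumor_policy <- match.arg(no_tumor_policy)
  out <- setNames(vector("list", nrow(sample$rois)), sample$rois$roi_id)
  for (i in seq_len(nrow(sample$rois))) {
    id <- sample$rois$roi_id[i]
    cc <- sample$cells[sample$cells$roi_id == id, , drop = FALSE]
    b <- tryCatch(
      estimate_boundary(cc, sample$rois[i, ], grid_resolution, closing_radius),
      error = function(e) {
        if (no_tumor_policy == "all_pt" && grepl("no tumor region", conditionMessage(e)))
          NA else stop(e)
      })
    out[[id]] <- b
  }
  out
}

region_from_distance <- function(d, band_width) {
  ifelse(d < 0, "TC", ifelse(d < band_width, "TF", "PT"))
}

#' Partition cells and tissue area into TC / TF / PT
#'
#' Applies the distance-band rule per ROI: a cell is TC when its signed
#' distance to the tumor boundary is negative (inside the mask), TF when the
#' distance is at least 0 but less than `band_width`, and PT when the
#' distance is at or beyond `band_width` — honouring the convention that the
#' invasive front is the band of tissue less than 150 um from the tumor and
#' the peritumor begins at exactly 150 um. Region tissue areas are obtained
#' by classifying a raster of pixel centres over each ROI rectangle at
#' `grid_resolution` and converting to mm^2; by construction the three
#' region areas of an ROI sum exactly to the ROI rectangle area.
#'
#' @param sample A [sample_map()].
#' @param boundaries Named list from [estimate_boundaries()] (an `NA` entry
#'   means "no tumor region, everything PT").
#' @param band_width Band width in micrometres, default 150.
#' @param grid_resolution Raster cell size for area computation (um).
#' @return Object of class `region_partition`: per-cell table
#'   (`cell_id`, `roi_id`, `region`, `distance_um`), per-ROI area table and
#'   pooled `areas_mm2` for TC/TF/PT.
#' @export
assign_regions <- function(sample, boundaries, band_width = 150,
                           grid_resolution = 5) {
  stopifnot(band_width >= 0)
  miss <- setdiff(sample$rois$roi_id, names(boundaries))
  if (length(miss))
    stop("no boundary supplied for ROI ", miss[1], call. = FALSE)

  cell_rows <- vector("list", nrow(sample$rois))
  area_rows <- vector("list", nrow(sample$rois))
  for (i in seq_len(nrow(sample$rois))) {
    roi <- sample$rois[i, ]
    id <- roi$roi_id
    b <- boundaries[[id]]
    cc <- sample$cells[sample$cells$roi_id == id, , drop = FALSE]
    if (nrow(cc)) {
      inside <- cc$x >= roi$xmin & cc$x <= roi$xmax &
                cc$y >= roi$ymin & cc$y <= roi$ymax
      if (any(!inside))
        stop("cell outside its ROI rectangle: ", cc$cell_id[which(!inside)[1]],
             call. = FALSE)
    }
    w <- roi$xmax - roi$xmin
    h <- roi$ymax - roi$ymin
    nx <- max(1L, as.integer(ceiling(w / grid_resolution)))
    ny <- max(1L, as.integer(ceiling(h / grid_resolution)))
    pix_mm2 <- (w / nx) * (h / ny) / 1e6
    if (identical(b, NA) || (length(b) == 1 && is.na(b[1]))) {
      d <- rep(Inf, nrow(cc))
      areas <- c(TC = 0, TF = 0, PT = nx * ny * pix_mm2)
    } else {
      d <- distance_to_boundary(cc$x, cc$y, b)
      cnt <- region_counts_cpp(b$rings, roi$xmin, roi$ymin,
                               w / nx, h / ny, nx, ny, band_width)
      areas <- c(TC = cnt[1], TF = cnt[2], PT = cnt[3]) * pix_mm2
    }
    cell_rows[[i]] <- data.frame(
      cell_id = cc$cell_id, roi_id = id,
      region = if (nrow(cc)) region_from_distance(d, band_width) else character(0),
      distance_um = d, stringsAsFactors = FALSE)
    area_rows[[i]] <- data.frame(roi_id = id, TC = areas[["TC"]],
                                 TF = areas[["TF"]], PT = areas[["PT"]],
                                 stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cell_rows)
  areas <- do.call(rbind, area_rows)
  structure(list(cells = cells, roi_areas = areas,
                 areas_mm2 = c(TC = sum(areas$TC), TF = sum(areas$TF),
                               PT = sum(areas$PT)),
                 band_width = band_width),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  tab <- table(factor(x$cells$region, levels = REGIONS))
  cat(sprintf("<region_partition> band %g um; cells TC/TF/PT = %d/%d/%d; areas (mm2) %.3f/%.3f/%.3f\n",
              x$band_width, tab["TC"], tab["TF"], tab["PT"],
              x$areas_mm2["TC"], x$areas_mm2["TF"], x$areas_mm2["PT"]))
  invisible(x)
}

#' Export a boundary as GeoJSON text
#'
#' @param boundary A `tumor_boundary`.
#' @param path Optional path; when given the text is written there.
#' @return GeoJSON MultiPolygon string, invisibly when `path` is given.
#' @export
boundary_to_geojson <- function(boundary, path = NULL) {
  rings <- lapply(boundary$rings, function(r) {
    r2 <- rbind(r, r[1, , drop = FALSE])  # GeoJSON rings are explicitly closed
    list(lapply(seq_len(nrow(r2)), function(i) c(r2[i, 1], r2[i, 2])))
  })
  txt <- jsonlite::toJSON(
    list(type = "MultiPolygon", coordinates = rings),
    auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
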