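# Density quantification and CD68/CD163 macrophage subtyping.
#
# Densities are reported in cells/mm^2 of regional tissue area. Counts and
# areas are pooled across the 3-5 ROIs of a lesion (sum of counts divided by
# sum of areas), which keeps the estimate unbiased when ROI areas differ; a
# per-ROI-mean alternative is available for sensitivity analysis.

#' Define a cell phenotype by marker positivity
#'
#' @param name Phenotype label used in output tables.
#' @param positive Markers that must be positive.
#' @param negative Markers that must be negative.
#' @return Object of class `phenotype_def`.
#' @export
phenotype_def <- function(name, positive, negative = character()) {
  positive <- as.character(positive); negative <- as.character(negative)
  if (!length(c(positive, negative)))
    stop("phenotype must name at least one marker", call. = FALSE)
  overlap <- intersect(positive, negative)
  if (length(overlap))
    stop("marker(s) required both positive and negative: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  structure(list(name = name, positive = positive, negative = negative),
            class = "phenotype_def")
}

#' Single-marker phenotypes for a panel
#'
#' One phenotype per marker, positive for that marker with no constraint on
#' any other (a CD8 cell is CD8-positive regardless of co-expression).
#'
#' @param panel Marker names; default [crc_panel()].
#' @return List of [phenotype_def()]s named by marker.
#' @export
single_marker_phenotypes <- function(panel = crc_panel()) {
  setNames(lapply(panel, function(m) phenotype_def(m, m)), panel)
}

#' The three CD68/CD163 macrophage colocalization subtypes
#'
#' CD68+CD163+ (double-positive), CD68+CD163- (CD68 single-positive) and
#' CD68-CD163+ (CD163 single-positive). Double-negative cells belong to no
#' subtype; the three subtypes plus the double-negatives partition any cell
#' set exactly.
#'
#' @return Named list of three [phenotype_def()]s.
#' @export
macrophage_phenotypes <- function() {
  list(
    `CD68+CD163+` = phenotype_def("CD68+CD163+", c("CD68", "CD163")),
    `CD68+CD163-` = phenotype_def("CD68+CD163-", "CD68", "CD163"),
    `CD68-CD163+` = phenotype_def("CD68-CD163+", "CD163", "CD68"))
}

#' Test cells against a phenotype definition
#'
#' @param cells Cell table with one logical column per marker.
#' @param def A [phenotype_def()].
#' @return Logical vector, one element per cell.
#' @export
match_phenotype <- function(cells, def) {
  miss <- setdiff(c(def$positive, def$negative), names(cells))
  if (length(miss))
    stop("unknown marker in phenotype '", def$name, "': ",
         paste(miss, collapse = ", "), call. = FALSE)
  ok <- rep(TRUE, nrow(cells))
  for (m in def$positive) ok <- ok & cells[[m]]
  for (m in def$negative) ok <- ok & !cells[[m]]
  ok
}

#' Per-region phenotype densities for one lesion
#'
#' For every region (TC, TF, PT, plus the pooled ALL = TC + TF used by the
#' non-regional primary-vs-metastasis comparison) and every phenotype:
#' count of matching cells pooled across ROIs, pooled tissue area, and
#' density = count / area in cells/mm^2. A region with zero tissue area
#' yields a missing density (a lesion where the peritumor could not be
#' delineated simply drops out of PT statistics), and a zero-area region
#' containing cells raises an integrity error.
#'
#' @param sample A [sample_map()].
#' @param partition The [assign_regions()] output for `sample`.
#' @param defs List of [phenotype_def()]s; default the 12 single-marker
#'   phenotypes of the sample's panel.
#' @param pooling `"pooled"` (sum counts / sum areas, default) or
#'   `"roi_mean"` (mean of per-ROI densities).
#' @return Data frame: `patient_id`, `lesion_type`, `region`, `phenotype`,
#'   `count`, `area_mm2`, `density`.
#' @export
compute_densities <- function(sample, partition,
                              defs = single_marker_phenotypes(sample$panel),
                              pooling = c("pooled", "roi_mean")) {
  pooling <- match.arg(pooling)
  stopifnot(inherits(partition, "region_partition"))
  if (!setequal(partition$cells$cell_id, sample$cells$cell_id))
    stop("partition does not cover the sample", call. = FALSE)
  reg <- partition$cells$region[match(sample$cells$cell_id, partition$cells$cell_id)]
  roi <- sample$cells$roi_id
  out <- list()
  for (def in defs) {
    hit <- match_phenotype(sample$cells, def)
    for (rg in c(REGIONS, "ALL")) {
      in_rg <- if (rg == "ALL") reg %in% c("TC", "TF") else reg == rg
      if (pooling == "pooled") {
        n <- sum(hit & in_rg)
        a <- if (rg == "ALL") sum(partition$areas_mm2[c("TC", "TF")])
             else partition$areas_mm2[[rg]]
        if (a == 0 && n > 0)
          stop("integrity error: region ", rg, " has cells but zero area",
               call. = FALSE)
        n_out <- n
        dens <- if (a > 0) n / a else NA_real_
      } else {
        ra <- partition$roi_areas
        dens_i <- vapply(seq_len(nrow(ra)), function(i) {
          ai <- if (rg == "ALL") ra$TC[i] + ra$TF[i] else ra[[rg]][i]
          ni <- sum(hit & in_rg & roi == ra$roi_id[i])
          if (ai == 0 && ni > 0)
            stop("integrity error: region ", rg, " has cells but zero area",
                 call. = FALSE)
          if (ai > 0) ni / ai else NA_real_
        }, 0)
        n_out <- sum(hit & in_rg)
        a <- if (rg == "ALL") sum(ra$TC + ra$TF) else sum(ra[[rg]])
        dens <- if (all(is.na(dens_i))) NA_real_ else mean(dens_i, na.rm = TRUE)
      }
      out[[length(out) + 1L]] <- data.frame(
        patient_id = sample$patient_id, lesion_type = sample$lesion_type,
        region = rg, phenotype = def$name, count = n_out, area_mm2 = a,
        density = dens, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' CD68/CD163 macrophage subtype profile of one lesion
#'
#' Applies the three colocalization subtypes of [macrophage_phenotypes()]
#' per region via [compute_densities()].
#'
#' @inheritParams compute_densities
#' @return Density data frame restricted to the three subtypes.
#' @export
macrophage_profile <- function(sample, partition, pooling = "pooled") {
  miss <- setdiff(c("CD68", "CD163"), sample$panel)
  if (length(miss))
    stop("panel lacks marker(s) required for macrophage subtyping: ",
         paste(miss, collapse = ", "), call. = FALSE)
  compute_densities(sample, partition, macrophage_phenotypes(), pooling)
}

#' Median macrophage-subtype density matrix across a cohort
#'
#' Rows are (lesion type, region) strata, columns the three subtypes; each
#' entry is the across-patient median density, the quantity displayed as a
#' subtype distribution heatmap.
#'
#' @param profiles Row-bound [macrophage_profile()] output for a cohort.
#' @param regions Regions to include (default TC, TF, PT).
#' @return Numeric matrix with dimnames.
#' @export
subtype_heatmap_matrix <- function(profiles, regions = REGIONS) {
  stopifnot(nrow(profiles) >= 1)
  subtypes <- names(macrophage_phenotypes())
  rows <- as.vector(outer(LESION_TYPES, regions, paste, sep = "."))
  m <- matrix(NA_real_, length(rows), length(subtypes),
              dimnames = list(rows, subtypes))
  for (lt in LESION_TYPES) for (rg in regions) for (st in subtypes) {
    v <- profiles$density[profiles$lesion_type == lt & profiles$region == rg &
                          profiles$phenotype == st]
    if (length(v)) m[paste(lt, rg, sep = "."), st] <- median(v, na.rm = TRUE)
  }
  m
}
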