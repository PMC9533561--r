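# Immunophenotype classification from regional CD8 density.
#
# Following the inflamed / excluded / desert concept, a lesion is called
# immune-inflamed when CD8+ cells infiltrate the tumor center, immune-
# excluded when they accumulate at the invasive front without entering the
# center, and immune-desert when both regions are depleted. The published
# accounts of this scheme give no numeric cutoff, so the rule here is an
# explicit density threshold (cells/mm^2), reported with every call; the
# default threshold is the cohort median CD8 density in the tumor center,
# which keeps the rule unit-free and data-adaptive.

#' Classify a lesion's immunophenotype from regional CD8 densities
#'
#' Rule: inflamed when `d_tc >= threshold`; excluded when `d_tc < threshold`
#' and `d_tf >= threshold`; desert when both are below threshold. Raising
#' the threshold can only move a lesion along inflamed -> excluded ->
#' desert, never backward.
#'
#' @param d_tc CD8 density in the tumor center (cells/mm^2), vectorized.
#' @param d_tf CD8 density in the invasive front (cells/mm^2).
#' @param threshold Positive density cutoff (cells/mm^2).
#' @return Character vector with values `"inflamed"`, `"excluded"`,
#'   `"desert"`.
#' @export
classify_immunotype <- function(d_tc, d_tf, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0)
    stop("threshold must be a single positive density", call. = FALSE)
  if (any(d_tc < 0, na.rm = TRUE) || any(d_tf < 0, na.rm = TRUE))
    stop("densities must be non-negative", call. = FALSE)
  if (any(is.na(d_tc)))
    stop("missing tumor-center density: lesion unclassifiable", call. = FALSE)
  need_tf <- d_tc < threshold
  if (any(need_tf & is.na(d_tf)))
    stop("missing invasive-front density with sub-threshold center: ",
         "lesion unclassifiable", call. = FALSE)
  ifelse(!need_tf, "inflamed", ifelse(d_tf >= threshold, "excluded", "desert"))
}

#' Immunotype calls for a whole cohort
#'
#' Extracts per-lesion CD8 densities in TC and TF from a cohort density
#' table and classifies every lesion (primary and metastasis independently).
#' Lesions that cannot be classified (missing required density) get an `NA`
#' label with a warning rather than failing the cohort.
#'
#' @param densities Row-bound [compute_densities()] output.
#' @param threshold Density cutoff; default the cohort median CD8 TC
#'   density over all lesions.
#' @param marker Infiltration marker, default `"CD8"`.
#' @return Data frame: `patient_id`, `lesion_type`, `label`, `d_tc`,
#'   `d_tf`, `threshold`.
#' @export
immunotype_calls <- function(densities, threshold = NULL, marker = "CD8") {
  d <- densities[densities$phenotype == marker, ]
  if (!nrow(d)) stop("no '", marker, "' densities in table", call. = FALSE)
  key <- unique(d[, c("patient_id", "lesion_type")])
  pick <- function(i, rg) {
    v <- d$density[d$patient_id == key$patient_id[i] &
                   d$lesion_type == key$lesion_type[i] & d$region == rg]
    if (length(v)) v[1] else NA_real_
  }
  d_tc <- vapply(seq_len(nrow(key)), pick, 0, rg = "TC")
  d_tf <- vapply(seq_len(nrow(key)), pick, 0, rg = "TF")
  if (is.null(threshold)) {
    threshold <- median(d_tc, na.rm = TRUE)
    if (!is.finite(threshold) || threshold <= 0)
      stop("cannot derive a positive median threshold; supply one", call. = FALSE)
  }
  label <- vapply(seq_len(nrow(key)), function(i) {
    tryCatch(classify_immunotype(d_tc[i], d_tf[i], threshold),
             error = function(e) {
               warning("lesion ", key$patient_id[i], "/", key$lesion_type[i],
                       " unclassifiable: ", conditionMessage(e), call. = FALSE)
               NA_character_
             })
  }, "")
  data.frame(patient_id = key$patient_id, lesion_type = key$lesion_type,
             label = label, d_tc = d_tc, d_tf = d_tf, threshold = threshold,
             stringsAsFactors = FALSE)
}

#' Compare a marker's density across immunotype groups
#'
#' Pairwise rank-sum comparisons of one marker's density in one region
#' between the immunotype groups, run separately for primaries and
#' metastases. A pair with an empty group is reported with missing
#' statistic and p.
#'
#' @param densities Cohort density table.
#' @param calls [immunotype_calls()] output.
#' @param marker Marker to compare (e.g. `"CD163"`).
#' @param region Region in which to compare (e.g. `"TF"`).
#' @param alpha Significance level.
#' @return Data frame, one row per (lesion type, group pair).
#' @export
compare_marker_across_immunotypes <- function(densities, calls, marker,
                                              region, alpha = 0.05) {
  labs <- c("inflamed", "excluded", "desert")
  pairs <- utils::combn(labs, 2, simplify = FALSE)
  rows <- list()
  for (lt in LESION_TYPES) {
    cl <- calls[calls$lesion_type == lt & !is.na(calls$label), ]
    for (pr in pairs) {
      va <- density_vec(densities, cl$patient_id[cl$label == pr[1]],
                        lt, region, marker)
      vb <- density_vec(densities, cl$patient_id[cl$label == pr[2]],
                        lt, region, marker)
      res <- rank_sum_test(va, vb, alpha)
      rows[[length(rows) + 1L]] <- result_row(
        "immunotype", marker, paste0(region, " ", pr[1], "_vs_", pr[2]),
        lt, res, pr[1], pr[2])
    }
  }
  do.call(rbind, rows)
}
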