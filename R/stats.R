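# Wilcoxon comparison battery.
#
# Paired contrasts (region vs region within a lesion type; primary vs
# metastasis within patients) use the signed-rank test; independent
# clinical subgroups use the rank-sum (Mann-Whitney) test. Small untied
# samples get the exact null distribution, larger or tied samples the
# tie-corrected normal approximation with continuity correction. p-values
# are two-sided and reported raw (an optional Benjamini-Hochberg column can
# be added for sensitivity).

new_test_result <- function(test, statistic, n_effective, p, method,
                            a, b, alpha) {
  structure(list(
    test = test, statistic = unname(statistic), n_effective = n_effective,
    p_two_sided = unname(p), method = method,
    summary_a = group_summary(a), summary_b = group_summary(b),
    alpha = alpha,
    significant = !is.na(p) && p < alpha), class = "test_result")
}

group_summary <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return(c(mean = NA_real_, sd = NA_real_, median = NA_real_))
  c(mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_, median = median(v))
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s (%s): statistic = %g, n = %d, p = %.4g%s\n",
              x$test, x$method, x$statistic, x$n_effective, x$p_two_sided,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Pairs with a missing member and pairs with zero difference are dropped
#' (`n_effective` counts the remaining pairs). With `n_effective <= 25` and
#' no tied absolute differences the two-sided p-value is exact (equivalent
#' to enumerating all 2^n sign assignments); otherwise the tie-corrected
#' normal approximation with continuity correction is used. All differences
#' zero gives p = 1 with `n_effective = 0`.
#'
#' @param a,b Equal-length paired numeric vectors.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return A `test_result` (statistic W = sum of positive-difference ranks).
#' @export
signed_rank_test <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b))
    stop("paired vectors must have equal length", call. = FALSE)
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (!length(a)) {
    return(new_test_result("signed_rank", NA_real_, 0L, NA_real_, "exact",
                           a, b, alpha))
  }
  d <- a - b
  dz <- d[d != 0]
  n_eff <- length(dz)
  if (n_eff == 0L)
    return(new_test_result("signed_rank", 0, 0L, 1, "exact", a, b, alpha))
  ties <- anyDuplicated(abs(dz)) > 0
  exact <- n_eff <= 25 && !ties
  wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                     exact = exact, correct = TRUE))
  new_test_result("signed_rank", wt$statistic, n_eff, min(1, wt$p.value),
                  if (exact) "exact" else "normal_approx", a, b, alpha)
}

#' Wilcoxon rank-sum (Mann-Whitney U) test for independent samples
#'
#' With `m + n <= 20` and no ties in the pooled sample the two-sided
#' p-value is exact (equivalent to enumerating all C(m+n, m) group
#' assignments); otherwise the tie-corrected normal approximation with
#' continuity correction is used. An empty group gives a missing result.
#'
#' @param a,b Numeric vectors for the two groups.
#' @param alpha Significance level for the `significant` flag.
#' @return A `test_result` (statistic U for group `a`).
#' @export
rank_sum_test <- function(a, b, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    return(new_test_result("rank_sum", NA_real_, length(a) + length(b),
                           NA_real_, "exact", a, b, alpha))
  pool <- c(a, b)
  if (all(pool == pool[1]))  # degenerate: a single tied value, no evidence
    return(new_test_result("rank_sum", length(a) * length(b) / 2,
                           length(pool), 1, "exact", a, b, alpha))
  ties <- anyDuplicated(pool) > 0
  exact <- length(pool) <= 20 && !ties
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
  new_test_result("rank_sum", wt$statistic, length(a) + length(b),
                  min(1, wt$p.value),
                  if (exact) "exact" else "normal_approx", a, b, alpha)
}

result_row <- function(family, marker, stratum, lesion_type, res,
                       group_a, group_b) {
  data.frame(
    family = family, marker = marker, stratum = stratum,
    lesion_type = lesion_type, test = res$test, method = res$method,
    n = res$n_effective, statistic = res$statistic, p = res$p_two_sided,
    significant = res$significant,
    group_a = group_a, group_b = group_b,
    mean_a = res$summary_a[["mean"]], sd_a = res$summary_a[["sd"]],
    median_a = res$summary_a[["median"]],
    mean_b = res$summary_b[["mean"]], sd_b = res$summary_b[["sd"]],
    median_b = res$summary_b[["median"]],
    stringsAsFactors = FALSE)
}

# density lookup: per-patient vector for one marker / region / lesion type,
# ordered by `patients`
density_vec <- function(densities, patients, lesion_type, region, marker) {
  d <- densities[densities$lesion_type == lesion_type &
                 densities$region == region &
                 densities$phenotype == marker, ]
  d$density[match(patients, d$patient_id)]
}

#' Run the full comparison battery over a cohort density table
#'
#' Four families of two-sided Wilcoxon comparisons, each per marker:
#' \describe{
#'   \item{general}{primary vs metastasis on the pooled TC+TF (`ALL`)
#'     density, paired on patient (signed-rank).}
#'   \item{region_contrast}{TF vs TC and PT vs TF within each lesion type,
#'     paired on patient (signed-rank).}
#'   \item{cross_lesion}{primary vs metastasis within each of TC, TF, PT,
#'     paired on patient (signed-rank).}
#'   \item{subgroup}{clinical subgroups — single vs multiple liver
#'     metastases, and metastasis diameter < 3 vs >= 3 cm — compared within
#'     each lesion type on the `ALL` density (rank-sum), when `clinical`
#'     is supplied.}
#' }
#' Patients missing one member of a pair are dropped from that pair
#' (pairwise deletion); a stratum with no complete pair yields a row with
#' missing statistic and p.
#'
#' @param densities Row-bound [compute_densities()] output for the cohort
#'   (optionally including macrophage-subtype phenotypes).
#' @param clinical Optional clinical table ([read_clinical_table()] format).
#' @param markers Phenotypes to test; default all in `densities`.
#' @param alpha Significance level (default 0.05).
#' @param fdr Add a Benjamini-Hochberg adjusted column `p_adj`?
#' @return Tidy data frame, one row per (family, marker, stratum).
#' @export
run_comparison_battery <- function(densities, clinical = NULL, markers = NULL,
                                   alpha = 0.05, fdr = FALSE) {
  markers <- markers %||% unique(densities$phenotype)
  patients <- unique(densities$patient_id)
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r

  for (mk in markers) {
    # (i) general: primary vs metastasis, pooled TC+TF
    va <- density_vec(densities, patients, "primary", "ALL", mk)
    vb <- density_vec(densities, patients, "metastasis", "ALL", mk)
    add(result_row("general", mk, "ALL primary_vs_metastasis", "both",
                   signed_rank_test(va, vb, alpha), "primary", "metastasis"))
    # (ii) region contrasts within lesion type
    for (lt in LESION_TYPES) {
      for (ct in list(c("TF", "TC"), c("PT", "TF"))) {
        va <- density_vec(densities, patients, lt, ct[1], mk)
        vb <- density_vec(densities, patients, lt, ct[2], mk)
        add(result_row("region_contrast", mk,
                       paste0(ct[1], "_vs_", ct[2]), lt,
                       signed_rank_test(va, vb, alpha), ct[1], ct[2]))
      }
    }
    # (iii) primary vs metastasis within region
    for (rg in REGIONS) {
      va <- density_vec(densities, patients, "primary", rg, mk)
      vb <- density_vec(densities, patients, "metastasis", rg, mk)
      add(result_row("cross_lesion", mk,
                     paste0(rg, " primary_vs_metastasis"), rg,
                     signed_rank_test(va, vb, alpha), "primary", "metastasis"))
    }
    # (iv) clinical subgroups, unpaired, on pooled TC+TF density
    if (!is.null(clinical)) {
      grp <- list(
        n_metastases_1_vs_gt1 = list(
          a = clinical$patient_id[clinical$n_liver_metastases == 1],
          b = clinical$patient_id[clinical$n_liver_metastases > 1],
          la = "n=1", lb = "n>1"),
        diameter_lt3_vs_ge3 = list(
          a = clinical$patient_id[clinical$max_metastasis_diameter_cm < 3],
          b = clinical$patient_id[clinical$max_metastasis_diameter_cm >= 3],
          la = "<3cm", lb = ">=3cm"))
      for (gn in names(grp)) for (lt in LESION_TYPES) {
        va <- density_vec(densities, grp[[gn]]$a, lt, "ALL", mk)
        vb <- density_vec(densities, grp[[gn]]$b, lt, "ALL", mk)
        add(result_row("subgroup", mk, gn, lt,
                       rank_sum_test(va, vb, alpha),
                       grp[[gn]]$la, grp[[gn]]$lb))
      }
    }
  }
  out <- do.call(rbind, rows)
  if (fdr) out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
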