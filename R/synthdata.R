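# Synthetic paired-cohort generator.
#
# Emulates the study design the pipeline targets: 17 patients, each with
# one primary lesion and 1+ liver metastases, 3-5 ROIs of 1000x1000 um per
# lesion. Each ROI holds a disc-shaped tumor whose true geometry defines
# TC / TF / PT zones; tumor-compartment cells fill the disc at a fixed
# cellularity, and every immune phenotype is an independent Poisson process
# with a region- and lesion-type-specific intensity (cells/mm^2).
# Macrophages are one process whose cells draw a CD68/CD163 joint state
# (CD68+CD163+, CD68+CD163-, CD68-CD163+) from per-region probabilities, so
# the subtype composition is controlled explicitly. Ground truth (true
# regions, true intensities, regimes) is returned alongside the cohort and
# written as a sidecar, never inside the cell tables.

MAC_STATES <- c("CD68+CD163+", "CD68+CD163-", "CD68-CD163+")
NONMAC_MARKERS <- setdiff(crc_panel(), c("CD68", "CD163"))

# Default per-marker regional intensities (cells/mm^2) for the ten
# non-macrophage markers. They encode the qualitative effect directions of
# the emulated study: invasive front 3x tumor center for the front-enriched
# markers (CD8, Foxp3, CD20, CD11c, PDL1, VEGFR2), the reverse gradient for
# CD66b and Ki67, and metastasis peritumor above primary peritumor for the
# markers enriched around liver metastases.
default_intensities <- function() {
  tab <- rbind(
    # marker     prim TC, TF, PT   met TC, TF, PT
    CD8    = c(50, 150,  50,   75, 150, 100),
    Foxp3  = c(10,  30,  10,   15,  45,  40),
    CD20   = c(20,  60,  20,   20,  60,  55),
    CD11c  = c(15,  45,  15,   30,  45,  25),
    PDL1   = c(30,  90,  30,   60,  90,  75),
    VEGFR2 = c(10,  30,  10,   10,  30,  25),
    IFNg   = c( 8,   8,   3,   16,  16,  14),
    CD66b  = c(90,  45,  15,   45,  25,   8),
    Ki67   = c(120, 60,  20,  100,  50,  35),
    CD56   = c(45,  30,  10,   18,  18,   6))
  data.frame(
    marker = rep(rownames(tab), each = 6),
    lesion_type = rep(rep(LESION_TYPES, each = 3), nrow(tab)),
    region = rep(REGIONS, 2 * nrow(tab)),
    lambda = as.vector(t(tab)),
    stringsAsFactors = FALSE)
}

# Macrophage process: total intensity per (lesion type, region) and the
# joint CD68/CD163 state probabilities. Metastases shift mass towards the
# CD68-CD163+ subtype; the metastasis peritumor carries 3x the primary
# peritumor's CD68-CD163+ intensity.
default_macrophage <- function() {
  list(
    lambda = data.frame(
      lesion_type = rep(LESION_TYPES, each = 3),
      region = rep(REGIONS, 2),
      lambda = c(60, 180, 60, 75, 150, 105),
      stringsAsFactors = FALSE),
    joint = data.frame(
      lesion_type = rep(LESION_TYPES, each = 3),
      region = rep(REGIONS, 2),
      p_pp = c(0.30, 0.30, 0.25, 0.30, 0.24, 0.38),
      p_pm = c(0.50, 0.50, 0.50, 0.40, 0.48, 0.19),
      p_mp = c(0.20, 0.20, 0.25, 0.30, 0.28, 0.43),
      stringsAsFactors = FALSE))
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the target study design: 17 patients with one primary
#' and one-to-several metastatic lesions, 3-5 fields of 1000x1000 um per
#' lesion, disc tumors of radius 250-330 um, tumor cellularity 2000
#' cells/mm^2 and a 150 um invasive-front band. Identical seed and
#' configuration give a bit-identical cohort.
#'
#' @param seed Integer RNG seed.
#' @param n_patients Number of patients (default 17).
#' @param rois_min,rois_max Range of ROIs per lesion (default 3-5).
#' @param roi_width,roi_height ROI dimensions in micrometres.
#' @param tumor_radius Length-2 range of disc radii in micrometres.
#' @param tumor_cell_density Tumor-compartment cellularity (cells/mm^2).
#' @param band_width Invasive-front band width in micrometres.
#' @param intensities Data frame (`marker`, `lesion_type`, `region`,
#'   `lambda`) for the ten non-macrophage markers; cells/mm^2.
#' @param macrophage List with `lambda` (total macrophage intensity per
#'   lesion type and region) and `joint` (probabilities `p_pp`, `p_pm`,
#'   `p_mp` of the CD68/CD163 states, each row summing to 1).
#' @param patient_effect_sd Log-normal sdlog of the per-patient, per-marker
#'   intensity multiplier (mean-1 log-normal; shared across a patient's two
#'   lesions, so paired contrasts benefit from within-patient correlation).
#' @param immunotype_mix Optional list(`p` = named probabilities over
#'   inflamed/excluded/desert, `ref` = reference CD8 density in cells/mm^2).
#'   When set, each lesion draws a regime and its CD8 TC/TF intensities are
#'   overridden: inflamed 10x`ref` in both, excluded 0.1x in TC and 10x in
#'   TF, desert 0.1x in both.
#' @param clinical_model List: `p_n_mets` (probabilities of 1, 2, ... liver
#'   metastases), `diameter_meanlog`, `diameter_sdlog`, `diameter_range`
#'   (cm) for the maximum metastasis diameter.
#' @param max_cells_per_roi Resource guard (error if an ROI would exceed it).
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_patients = 17L,
                         rois_min = 3L, rois_max = 5L,
                         roi_width = 1000, roi_height = 1000,
                         tumor_radius = c(250, 330),
                         tumor_cell_density = 2000,
                         band_width = 150,
                         intensities = default_intensities(),
                         macrophage = default_macrophage(),
                         patient_effect_sd = 0.3,
                         immunotype_mix = NULL,
                         clinical_model = list(
                           p_n_mets = c(10, 3, 2, 2) / 17,
                           diameter_meanlog = log(3),
                           diameter_sdlog = 0.6,
                           diameter_range = c(0.5, 9)),
                         max_cells_per_roi = 1e6) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1, cfg$rois_min >= 1,
            cfg$rois_max >= cfg$rois_min,
            cfg$roi_width > 0, cfg$roi_height > 0,
            length(cfg$tumor_radius) == 2, all(cfg$tumor_radius > 0),
            cfg$tumor_cell_density >= 0, cfg$band_width >= 0)
  if (any(cfg$intensities$lambda < 0))
    stop("intensities must be non-negative", call. = FALSE)
  if (any(cfg$macrophage$lambda$lambda < 0))
    stop("macrophage intensities must be non-negative", call. = FALSE)
  ps <- cfg$macrophage$joint
  if (any(abs(ps$p_pp + ps$p_pm + ps$p_mp - 1) > 1e-8))
    stop("macrophage joint probabilities must sum to 1", call. = FALSE)
  fit <- cfg$tumor_radius[2] + cfg$band_width
  if (fit > min(cfg$roi_width, cfg$roi_height) / 2)
    stop("tumor radius + band width must fit inside the ROI", call. = FALSE)
  cfg
}

lam_lookup <- function(tab, lesion_type, region, marker = NULL) {
  sel <- tab$lesion_type == lesion_type & tab$region == region
  if (!is.null(marker)) sel <- sel & tab$marker == marker
  tab$lambda[sel]
}

# uniform points in disc / annulus / rectangle-minus-disc
runif_disc <- function(n, cx, cy, r0, r1) {
  r <- sqrt(runif(n, r0^2, r1^2))
  th <- runif(n, 0, 2 * pi)
  cbind(cx + r * cos(th), cy + r * sin(th))
}
runif_outside <- function(n, w, h, cx, cy, rmin) {
  out <- matrix(0, 0, 2)
  frac <- max(1e-3, 1 - pi * rmin^2 / (w * h))
  while (nrow(out) < n) {
    m <- ceiling((n - nrow(out)) / frac) + 10L
    x <- runif(m, 0, w); y <- runif(m, 0, h)
    keep <- (x - cx)^2 + (y - cy)^2 >= rmin^2
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate one ROI of one lesion
#'
#' Places a disc tumor in the ROI, fills it with tumor-compartment cells and
#' draws every immune phenotype as a Poisson process on the true TC/TF/PT
#' zones. Consumes the current RNG stream (call inside a seeded context for
#' reproducibility).
#'
#' @param config A [synth_config()].
#' @param lesion_type `"primary"` or `"metastasis"`.
#' @param lam_markers Matrix `[marker, region]` of resolved intensities for
#'   the non-macrophage markers.
#' @param lam_mac Named vector of macrophage intensities per region.
#' @param joint_mac Matrix `[region, state]` of CD68/CD163 probabilities.
#' @param roi_id Identifier for the new ROI.
#' @return List: `cells` (cell table rows), `roi` (ROI descriptor row),
#'   `truth` (true region per cell plus disc centre/radius).
#' @export
simulate_roi <- function(config, lesion_type, lam_markers, lam_mac, joint_mac,
                         roi_id = "roi1") {
  w <- config$roi_width; h <- config$roi_height
  band <- config$band_width
  R <- runif(1, config$tumor_radius[1], config$tumor_radius[2])
  slack <- max(0, min(w, h) / 2 - (R + band))
  cx <- w / 2 + runif(1, -1, 1) * min(20, slack)
  cy <- h / 2 + runif(1, -1, 1) * min(20, slack)

  A <- c(TC = pi * R^2,
         TF = pi * ((R + band)^2 - R^2),
         PT = w * h - pi * (R + band)^2) / 1e6  # mm^2
  expect <- config$tumor_cell_density * A[["TC"]] +
    sum(lam_markers %*% A) + sum(lam_mac * A)
  if (expect > config$max_cells_per_roi)
    stop("intensities imply more than ", config$max_cells_per_roi,
         " cells per ROI", call. = FALSE)

  draw_in_region <- function(n, rg) {
    if (n == 0) return(matrix(0, 0, 2))
    switch(rg,
           TC = runif_disc(n, cx, cy, 0, R),
           TF = runif_disc(n, cx, cy, R, R + band),
           PT = runif_outside(n, w, h, cx, cy, R + band))
  }

  xs <- list(); ys <- list(); marker_of <- list(); state_of <- list()
  push <- function(pts, marker, state = NA_character_) {
    if (!nrow(pts)) return()
    k <- length(xs) + 1L
    xs[[k]] <<- pts[, 1]; ys[[k]] <<- pts[, 2]
    marker_of[[k]] <<- rep(marker, nrow(pts))
    state_of[[k]] <<- rep(state, nrow(pts))
  }

  push(runif_disc(rpois(1, config$tumor_cell_density * A[["TC"]]), cx, cy, 0, R),
       "_tumor")
  for (m in rownames(lam_markers)) for (rg in REGIONS)
    push(draw_in_region(rpois(1, lam_markers[m, rg] * A[[rg]]), rg), m)
  for (rg in REGIONS) {
    n <- rpois(1, lam_mac[[rg]] * A[[rg]])
    if (n > 0) {
      st <- sample(MAC_STATES, n, replace = TRUE, prob = joint_mac[rg, ])
      push(draw_in_region(n, rg), "_mac", NA)
      state_of[[length(state_of)]] <- st
    }
  }

  x <- unlist(xs) %||% numeric(0); y <- unlist(ys) %||% numeric(0)
  mk <- unlist(marker_of) %||% character(0)
  st <- unlist(state_of) %||% character(0)
  n <- length(x)
  d_center <- if (n) sqrt((x - cx)^2 + (y - cy)^2) - R else numeric(0)

  cells <- data.frame(
    cell_id = sprintf("%s_c%05d", roi_id, seq_len(n)),
    roi_id = rep(roi_id, n), x = x, y = y,
    compartment = ifelse(d_center < 0, "tumor", "stroma"),
    stringsAsFactors = FALSE)
  for (m in crc_panel()) cells[[m]] <- rep(FALSE, n)
  for (m in NONMAC_MARKERS) cells[[m]][mk == m] <- TRUE
  is_mac <- mk == "_mac"
  cells$CD68[is_mac & st %in% c("CD68+CD163+", "CD68+CD163-")] <- TRUE
  cells$CD163[is_mac & st %in% c("CD68+CD163+", "CD68-CD163+")] <- TRUE

  roi <- data.frame(roi_id = roi_id, xmin = 0, ymin = 0, xmax = w, ymax = h,
                    area_mm2 = w * h / 1e6, stringsAsFactors = FALSE)
  truth <- list(
    regions = data.frame(cell_id = cells$cell_id,
                         region = region_from_distance(d_center, band),
                         stringsAsFactors = FALSE),
    center = c(cx, cy), radius = R, areas_mm2 = A)
  list(cells = cells, roi = roi, truth = truth)
}

simulate_lesion <- function(config, patient_id, lesion_type, lesion_id,
                            lam_markers, lam_mac, joint_mac) {
  n_rois <- if (config$rois_max > config$rois_min)
    sample(config$rois_min:config$rois_max, 1) else config$rois_min
  parts <- lapply(seq_len(n_rois), function(i)
    simulate_roi(config, lesion_type, lam_markers, lam_mac, joint_mac,
                 roi_id = sprintf("roi%d", i)))
  cells <- do.call(rbind, lapply(parts, `[[`, "cells"))
  # cell ids are unique per ROI already; prefix keeps them unique per lesion
  s <- sample_map(patient_id, lesion_type, lesion_id, crc_panel(),
                  do.call(rbind, lapply(parts, `[[`, "roi")), cells)
  truth_regions <- do.call(rbind, lapply(parts, function(p) p$truth$regions))
  list(sample = s, truth = list(regions = truth_regions,
                                rois = lapply(parts, function(p)
                                  p$truth[c("center", "radius", "areas_mm2")])))
}

#' Resolved intensity tables for one lesion type
#'
#' Collects the configured intensities into the matrix/vector form consumed
#' by [simulate_roi()]: a `[marker, region]` matrix for the ten
#' non-macrophage markers, the macrophage intensity per region, and the
#' CD68/CD163 joint-state probability matrix.
#'
#' @param config A [synth_config()].
#' @param lesion_type `"primary"` or `"metastasis"`.
#' @return List with `markers`, `mac`, `joint`.
#' @export
lesion_intensity_tables <- function(config, lesion_type) {
  markers10 <- unique(config$intensities$marker)
  lam_markers <- t(vapply(markers10, function(m)
    setNames(vapply(REGIONS, function(rg)
      lam_lookup(config$intensities, lesion_type, rg, m), 0), REGIONS),
    numeric(3)))
  lam_mac <- setNames(vapply(REGIONS, function(rg)
    lam_lookup(config$macrophage$lambda, lesion_type, rg), 0), REGIONS)
  j <- config$macrophage$joint[config$macrophage$joint$lesion_type == lesion_type, ]
  jm <- as.matrix(j[, c("p_pp", "p_pm", "p_mp")])
  dimnames(jm) <- list(j$region, MAC_STATES)
  list(markers = lam_markers, mac = lam_mac, joint = jm[REGIONS, , drop = FALSE])
}

# CD68/CD163 marginal and subtype intensities implied by the macrophage model
implied_mac_lambda <- function(macrophage) {
  lam <- macrophage$lambda; j <- macrophage$joint
  k <- match(paste(lam$lesion_type, lam$region),
             paste(j$lesion_type, j$region))
  data.frame(
    marker = rep(c("CD68", "CD163", MAC_STATES), each = nrow(lam)),
    lesion_type = rep(lam$lesion_type, 5), region = rep(lam$region, 5),
    lambda = c(lam$lambda * (j$p_pp[k] + j$p_pm[k]),
               lam$lambda * (j$p_pp[k] + j$p_mp[k]),
               lam$lambda * j$p_pp[k],
               lam$lambda * j$p_pm[k],
               lam$lambda * j$p_mp[k]),
    stringsAsFactors = FALSE)
}

#' Simulate a full paired cohort
#'
#' Draws, per patient: a mean-1 log-normal intensity multiplier per marker
#' (shared by both lesions), clinical covariates (number of liver
#' metastases, maximum metastasis diameter), one primary lesion and
#' `n_liver_metastases` metastatic lesions (merged into one metastasis
#' sample per patient, mirroring how a cohort reports one metastasis value
#' per patient). Ground truth is returned for recovery tests and sidecar
#' export.
#'
#' @param config A [synth_config()].
#' @return Object of class `synth_cohort`: `samples` (list of
#'   [sample_map()]), `clinical` (data frame), `truth` (true regions and
#'   geometry per lesion, base and per-lesion intensities, regimes, config).
#' @export
simulate_cohort <- function(config = synth_config()) {
  validate_synth_config(config)
  set.seed(config$seed)
  markers10 <- unique(config$intensities$marker)
  tabs <- lapply(setNames(LESION_TYPES, LESION_TYPES),
                 function(lt) lesion_intensity_tables(config, lt))
  samples <- list(); truths <- list(); regimes <- list()
  clin <- data.frame()

  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    eff <- setNames(rlnorm(length(markers10) + 1,
                           meanlog = -config$patient_effect_sd^2 / 2,
                           sdlog = config$patient_effect_sd),
                    c(markers10, "_mac"))
    n_mets <- sample(seq_along(config$clinical_model$p_n_mets), 1,
                     prob = config$clinical_model$p_n_mets)
    dia <- exp(rnorm(1, config$clinical_model$diameter_meanlog,
                     config$clinical_model$diameter_sdlog))
    dia <- min(max(dia, config$clinical_model$diameter_range[1]),
               config$clinical_model$diameter_range[2])
    clin <- rbind(clin, data.frame(patient_id = pid, n_liver_metastases = n_mets,
                                   max_metastasis_diameter_cm = round(dia, 1),
                                   stringsAsFactors = FALSE))

    for (lt in LESION_TYPES) {
      lam_markers <- tabs[[lt]]$markers * eff[markers10]
      regime <- NA_character_
      if (!is.null(config$immunotype_mix)) {
        mix <- config$immunotype_mix
        regime <- sample(names(mix$p), 1, prob = mix$p)
        mult <- switch(regime,
                       inflamed = c(TC = 10, TF = 10),
                       excluded = c(TC = 0.1, TF = 10),
                       desert = c(TC = 0.1, TF = 0.1))
        lam_markers["CD8", c("TC", "TF")] <- mix$ref * mult
      }
      lam_mac <- tabs[[lt]]$mac * eff[["_mac"]]
      jm <- tabs[[lt]]$joint

      n_lesions <- if (lt == "primary") 1L else n_mets
      les <- lapply(seq_len(n_lesions), function(i)
        simulate_lesion(config, pid, lt, sprintf("%s%d", substr(lt, 1, 3), i),
                        lam_markers, lam_mac, jm))
      if (n_lesions == 1L) {
        s <- les[[1]]$sample
        tr_reg <- les[[1]]$truth$regions
        tr_reg$cell_id <- s$cells$cell_id
      } else {
        s <- merge_lesions(lapply(les, function(l) l$sample))
        tr_reg <- do.call(rbind, lapply(seq_along(les), function(i) {
          r <- les[[i]]$truth$regions
          r$cell_id <- paste(les[[i]]$sample$lesion_id, r$cell_id, sep = ".")
          r
        }))
      }
      key <- paste(pid, lt, sep = ".")
      samples[[key]] <- s
      truths[[key]] <- list(regions = tr_reg,
                            rois = unlist(lapply(les, function(l) l$truth$rois),
                                          recursive = FALSE),
                            lambda_markers = lam_markers,
                            lambda_mac = lam_mac, joint = jm)
      regimes[[key]] <- regime
    }
  }
  base_lambda <- rbind(config$intensities, implied_mac_lambda(config$macrophage))
  structure(list(
    samples = samples, clinical = clin,
    truth = list(per_lesion = truths,
                 base_lambda = base_lambda,
                 regimes = unlist(regimes),
                 config = config)),
    class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("<synth_cohort> %d patients, %d lesion samples, %d cells total\n",
              nrow(x$clinical), length(x$samples),
              sum(vapply(x$samples, function(s) nrow(s$cells), 0))))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' One cell table per lesion sample (`cells_<patient>_<lesion_type>.tsv`),
#' the clinical table, and ground-truth sidecars (`truth_regions.tsv`,
#' `truth_lambda.tsv`, `truth_regimes.tsv`) that the pipeline never reads.
#'
#' @param cohort A `synth_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(cohort$samples)) {
    s <- cohort$samples[[key]]
    write_cell_table(s, file.path(dir, sprintf("cells_%s_%s.tsv",
                                               s$patient_id, s$lesion_type)))
  }
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  tr <- do.call(rbind, lapply(names(cohort$truth$per_lesion), function(key) {
    r <- cohort$truth$per_lesion[[key]]$regions
    cbind(lesion = key, r, stringsAsFactors = FALSE)
  }))
  write.table(tr, file.path(dir, "truth_regions.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(cohort$truth$base_lambda, file.path(dir, "truth_lambda.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  rg <- cohort$truth$regimes
  write.table(data.frame(lesion = names(rg), regime = unname(rg)),
              file.path(dir, "truth_regimes.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Reads only the cell tables and clinical metadata (never the ground-truth
#' sidecars).
#'
#' @param dir Cohort directory.
#' @param panel Required marker panel; default [crc_panel()].
#' @return List with `samples` and `clinical`.
#' @export
read_cohort <- function(dir, panel = crc_panel()) {
  files <- sort(list.files(dir, pattern = "^cells_.*\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no cell tables found in ", dir, call. = FALSE)
  samples <- lapply(files, read_cell_table, panel = panel)
  names(samples) <- vapply(samples, function(s)
    paste(s$patient_id, s$lesion_type, sep = "."), "")
  clin_path <- file.path(dir, "clinical.tsv")
  clinical <- if (file.exists(clin_path)) read_clinical_table(clin_path) else NULL
  list(samples = samples, clinical = clinical)
}
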