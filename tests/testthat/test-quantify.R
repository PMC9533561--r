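# Phenotype matching, density pooling, macrophage subtyping.

# build a sample plus hand-made partition without invoking geometry
manual_partition <- function(sample, regions, roi_areas) {
  cells <- data.frame(cell_id = sample$cells$cell_id,
                      roi_id = sample$cells$roi_id,
                      region = regions, distance_um = NA_real_,
                      stringsAsFactors = FALSE)
  structure(list(cells = cells, roi_areas = roi_areas,
                 areas_mm2 = c(TC = sum(roi_areas$TC), TF = sum(roi_areas$TF),
                               PT = sum(roi_areas$PT)),
                 band_width = 150),
            class = "region_partition")
}

flat_sample <- function(df, panel = c("CD8", "CD68", "CD163")) {
  n <- nrow(df)
  rois <- data.frame(roi_id = unique(df$roi_id), xmin = 0, ymin = 0,
                     xmax = 1000, ymax = 1000, area_mm2 = 1,
                     stringsAsFactors = FALSE)
  cells <- data.frame(cell_id = paste0("c", seq_len(n)), roi_id = df$roi_id,
                      x = runif(n, 0, 1000), y = runif(n, 0, 1000),
                      compartment = "stroma", stringsAsFactors = FALSE)
  for (m in panel) cells[[m]] <- if (m %in% names(df)) df[[m]] else FALSE
  sample_map("Pt", "primary", "les1", panel, rois, cells)
}

test_that("phenotype definitions validate and match correctly", {
  expect_error(phenotype_def("bad", "CD8", "CD8"), "both positive and negative")
  expect_error(phenotype_def("empty", character()), "at least one marker")

  cells <- data.frame(CD68 = c(TRUE, FALSE, TRUE, FALSE),
                      CD163 = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(match_phenotype(cells, phenotype_def("x", "CD68", "CD163")),
               c(TRUE, FALSE, FALSE, FALSE))
  # the double-negative cell matches none of the three subtypes
  hits <- vapply(macrophage_phenotypes(), function(d) match_phenotype(cells, d)[2],
                 logical(1))
  expect_false(any(hits))
  expect_error(match_phenotype(cells, phenotype_def("y", "CD57")),
               "unknown marker")
})

test_that("density is count over pooled area, not the mean of ROI densities", {
  set.seed(3)
  df <- data.frame(roi_id = c(rep("r1", 3), "r2"),
                   CD8 = rep(TRUE, 4))
  s <- flat_sample(df)
  part <- manual_partition(
    s, regions = rep("TC", 4),
    roi_areas = data.frame(roi_id = c("r1", "r2"), TC = c(0.2, 0.3),
                           TF = 0, PT = 0, stringsAsFactors = FALSE))
  d <- compute_densities(s, part, defs = list(phenotype_def("CD8", "CD8")))
  tc <- d[d$region == "TC", ]
  expect_equal(tc$count, 4)
  expect_equal(tc$density, 4 / 0.5)  # pooled, not (15 + 3.33)/2
  roi_mean <- compute_densities(s, part, defs = list(phenotype_def("CD8", "CD8")),
                                pooling = "roi_mean")
  expect_equal(roi_mean$density[roi_mean$region == "TC"], (3 / 0.2 + 1 / 0.3) / 2)
})

test_that("simple density arithmetic and empty/zero-area regions", {
  set.seed(4)
  df <- data.frame(roi_id = rep("r1", 12), CD8 = TRUE)
  s <- flat_sample(df)
  part <- manual_partition(
    s, regions = rep("TF", 12),
    roi_areas = data.frame(roi_id = "r1", TC = 0.25, TF = 0.5, PT = 0,
                           stringsAsFactors = FALSE))
  d <- compute_densities(s, part, defs = list(phenotype_def("CD8", "CD8")))
  expect_equal(d$density[d$region == "TF"], 24)
  expect_equal(d$density[d$region == "TC"], 0)       # 0 cells, positive area
  expect_true(is.na(d$density[d$region == "PT"]))    # zero area -> missing
  expect_equal(d$count[d$region == "ALL"], 12)
  expect_equal(d$density[d$region == "ALL"], 12 / 0.75)

  # cells in a zero-area region is an integrity error
  bad <- manual_partition(
    s, regions = rep("PT", 12),
    roi_areas = data.frame(roi_id = "r1", TC = 0.5, TF = 0.5, PT = 0,
                           stringsAsFactors = FALSE))
  expect_error(compute_densities(s, bad, defs = list(phenotype_def("CD8", "CD8"))),
               "integrity error")
})

test_that("density is invariant under splitting an ROI in two", {
  set.seed(6)
  df <- data.frame(roi_id = rep("r1", 40), CD8 = sample(c(TRUE, FALSE), 40, TRUE))
  s <- flat_sample(df)
  one <- manual_partition(
    s, regions = rep("TC", 40),
    roi_areas = data.frame(roi_id = "r1", TC = 0.6, TF = 0, PT = 0,
                           stringsAsFactors = FALSE))
  d1 <- compute_densities(s, one, defs = list(phenotype_def("CD8", "CD8")))

  s2 <- s
  s2$cells$roi_id[1:20] <- "r2"
  s2$rois <- rbind(s2$rois, within(s2$rois, roi_id <- "r2"))
  two <- manual_partition(
    s2, regions = rep("TC", 40),
    roi_areas = data.frame(roi_id = c("r1", "r2"), TC = c(0.25, 0.35),
                           TF = 0, PT = 0, stringsAsFactors = FALSE))
  d2 <- compute_densities(s2, two, defs = list(phenotype_def("CD8", "CD8")))
  expect_equal(d1$density, d2$density)
})

test_that("macrophage subtypes partition the CD68/CD163-positive cells", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(20:120, 1)
    df <- data.frame(roi_id = "r1",
                     CD68 = sample(c(TRUE, FALSE), n, TRUE),
                     CD163 = sample(c(TRUE, FALSE), n, TRUE))
    s <- flat_sample(df)
    part <- manual_partition(
      s, regions = sample(c("TC", "TF", "PT"), n, TRUE),
      roi_areas = data.frame(roi_id = "r1", TC = 0.3, TF = 0.3, PT = 0.4,
                             stringsAsFactors = FALSE))
    prof <- macrophage_profile(s, part)
    reg <- part$cells$region
    for (rg in c("TC", "TF", "PT")) {
      in_rg <- reg == rg
      # brute-force per-cell tally
      expect_equal(prof$count[prof$region == rg & prof$phenotype == "CD68+CD163+"],
                   sum(df$CD68 & df$CD163 & in_rg))
      expect_equal(prof$count[prof$region == rg & prof$phenotype == "CD68+CD163-"],
                   sum(df$CD68 & !df$CD163 & in_rg))
      expect_equal(prof$count[prof$region == rg & prof$phenotype == "CD68-CD163+"],
                   sum(!df$CD68 & df$CD163 & in_rg))
      # partition identities
      dp <- prof$count[prof$region == rg & prof$phenotype == "CD68+CD163+"]
      sp <- prof$count[prof$region == rg & prof$phenotype == "CD68+CD163-"]
      sn <- prof$count[prof$region == rg & prof$phenotype == "CD68-CD163+"]
      expect_equal(dp + sp, sum(df$CD68 & in_rg))
      expect_equal(dp + sp + sn + sum(!df$CD68 & !df$CD163 & in_rg), sum(in_rg))
    }
  }
  s <- flat_sample(data.frame(roi_id = "r1", CD8 = TRUE), panel = c("CD8"))
  part <- manual_partition(s, "TC", data.frame(roi_id = "r1", TC = 1, TF = 0,
                                               PT = 0, stringsAsFactors = FALSE))
  expect_error(macrophage_profile(s, part), "CD68")
})

test_that("an exhaustive phenotype family conserves region cell counts", {
  set.seed(9)
  n <- 60
  df <- data.frame(roi_id = "r1", CD8 = sample(c(TRUE, FALSE), n, TRUE))
  s <- flat_sample(df, panel = "CD8")
  reg <- sample(c("TC", "TF", "PT"), n, TRUE)
  part <- manual_partition(s, reg,
                           data.frame(roi_id = "r1", TC = 0.3, TF = 0.3, PT = 0.4,
                                      stringsAsFactors = FALSE))
  fam <- list(phenotype_def("CD8+", "CD8"), phenotype_def("CD8-", character(), "CD8"))
  d <- compute_densities(s, part, defs = fam)
  for (rg in c("TC", "TF", "PT"))
    expect_equal(sum(d$count[d$region == rg]), sum(reg == rg))
})

test_that("the subtype heatmap is the across-patient median", {
  set.seed(10)
  mk_prof <- function(pid, dens) {
    data.frame(patient_id = pid, lesion_type = "primary", region = "TC",
               phenotype = "CD68+CD163+", count = 1, area_mm2 = 1,
               density = dens, stringsAsFactors = FALSE)
  }
  one <- mk_prof("P1", 7)
  expect_equal(subtype_heatmap_matrix(one)["primary.TC", "CD68+CD163+"], 7)
  two <- rbind(mk_prof("P1", 2), mk_prof("P2", 4))
  expect_equal(subtype_heatmap_matrix(two)["primary.TC", "CD68+CD163+"], 3)
})
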