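# Cell-table input/output and the in-memory cell data model.
#
# A sample_map holds all segmented cells of one lesion (primary or
# metastasis) of one patient: an ROI table (one row per 20x field with its
# bounding rectangle in micrometres and analyzed tissue area in mm^2) and a
# cell table (one row per cell with position, tumor/stroma compartment and
# one logical positivity column per panel marker).

#' Construct a sample map for one lesion
#'
#' @param patient_id Patient identifier.
#' @param lesion_type `"primary"` or `"metastasis"`.
#' @param lesion_id Lesion identifier, unique within patient.
#' @param panel Character vector of marker names (no duplicates). The
#'   standard panel is [crc_panel()]; extra markers are allowed.
#' @param rois Data frame with columns `roi_id`, `xmin`, `ymin`, `xmax`,
#'   `ymax` (micrometres) and `area_mm2` (analyzed tissue area, > 0).
#' @param cells Data frame with columns `cell_id`, `roi_id`, `x`, `y`
#'   (micrometres), `compartment` (`"tumor"`/`"stroma"`) and one logical
#'   column per panel marker.
#' @return A validated object of class `sample_map`.
#' @export
sample_map <- function(patient_id, lesion_type, lesion_id, panel, rois, cells) {
  obj <- structure(
    list(patient_id = as.character(patient_id),
         lesion_type = match.arg(lesion_type, LESION_TYPES),
         lesion_id = as.character(lesion_id),
         panel = as.character(panel),
         rois = as.data.frame(rois, stringsAsFactors = FALSE),
         cells = as.data.frame(cells, stringsAsFactors = FALSE)),
    class = "sample_map")
  validate_sample_map(obj)
}

#' @export
print.sample_map <- function(x, ...) {
  cat(sprintf("<sample_map> patient %s, %s lesion %s: %d ROIs, %d cells, %d markers\n",
              x$patient_id, x$lesion_type, x$lesion_id,
              nrow(x$rois), nrow(x$cells), length(x$panel)))
  invisible(x)
}

validate_sample_map <- function(s) {
  stopifnot(inherits(s, "sample_map"))
  if (anyDuplicated(s$panel))
    stop("panel contains duplicate marker names", call. = FALSE)
  need_roi <- c("roi_id", "xmin", "ymin", "xmax", "ymax", "area_mm2")
  miss <- setdiff(need_roi, names(s$rois))
  if (length(miss))
    stop("ROI table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(s$rois$roi_id))
    stop("duplicate roi_id in ROI table", call. = FALSE)
  if (any(!is.finite(s$rois$area_mm2)) || any(s$rois$area_mm2 <= 0))
    stop("ROI areas must be strictly positive", call. = FALSE)
  need_cell <- c("cell_id", "roi_id", "x", "y", "compartment")
  miss <- setdiff(need_cell, names(s$cells))
  if (length(miss))
    stop("cell table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(s$panel, names(s$cells))
  if (length(miss))
    stop("missing marker column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  cells <- s$cells
  if (nrow(cells)) {
    if (anyDuplicated(cells$cell_id))
      stop("duplicate cell_id within sample", call. = FALSE)
    bad <- which(!is.finite(cells$x) | !is.finite(cells$y))
    if (length(bad))
      stop("non-finite cell coordinate at row ", bad[1], call. = FALSE)
    bad <- which(!cells$compartment %in% COMPARTMENTS)
    if (length(bad))
      stop("unknown compartment value '", cells$compartment[bad[1]],
           "' at row ", bad[1], call. = FALSE)
    unknown <- setdiff(unique(cells$roi_id), s$rois$roi_id)
    if (length(unknown))
      stop("cell references undeclared ROI: ", unknown[1], call. = FALSE)
    idx <- match(cells$roi_id, s$rois$roi_id)
    inside <- cells$x >= s$rois$xmin[idx] & cells$x <= s$rois$xmax[idx] &
              cells$y >= s$rois$ymin[idx] & cells$y <= s$rois$ymax[idx]
    if (any(!inside))
      stop("cell outside its ROI bounding rectangle at row ", which(!inside)[1],
           call. = FALSE)
    for (m in s$panel) {
      v <- cells[[m]]
      if (!is.logical(v) || anyNA(v))
        stop("marker column '", m, "' must be logical with no missing values",
             call. = FALSE)
    }
  }
  s
}

sniff_sep <- function(header_line) {
  if (grepl("\t", header_line)) "\t" else ","
}

#' Read a segmented-cell table
#'
#' Reads a delimited cell table (comma- or tab-separated, auto-detected from
#' the header) in the dialect written by [write_cell_table()]: columns
#' `cell_id`, `roi_id`, `x_um`, `y_um`, `compartment` and one `<marker>_pos`
#' column (values 0/1) per panel marker. Metadata lines starting with `#!`
#' carry lesion identity, an optional coordinate scale (`um_per_unit`,
#' applied on load so in-memory coordinates are always micrometres) and the
#' per-ROI bounding rectangles and tissue areas. If no ROI metadata is
#' present, one ROI per distinct `roi_id` is inferred from the cell extent.
#'
#' @param path Path to the file.
#' @param panel Marker names that must be present; default [crc_panel()].
#' @return A [sample_map()].
#' @export
read_cell_table <- function(path, panel = crc_panel()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  meta_idx <- grep("^#!", lines)
  meta <- lines[meta_idx]
  body <- if (length(meta_idx)) lines[-meta_idx] else lines
  if (!length(body)) stop("empty cell table: ", path, call. = FALSE)

  kv <- function(tag) {
    ln <- grep(paste0("^#!", tag, "\\b"), meta, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^#!", tag, "[ \t]+"), "", ln[1])
  }
  patient_id <- kv("patient_id") %||% "unknown"
  lesion_type <- kv("lesion_type") %||% "primary"
  lesion_id <- kv("lesion_id") %||% "lesion1"
  scale <- as.numeric(kv("um_per_unit") %||% "1")

  sep <- sniff_sep(body[1])
  df <- read.delim(text = paste(body, collapse = "\n"), sep = sep,
                   stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  need <- c("cell_id", "roi_id", "x_um", "y_um", "compartment")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing mandatory column: ", paste(miss, collapse = ", "), call. = FALSE)
  mcols <- paste0(panel, "_pos")
  miss <- setdiff(mcols, names(df))
  if (length(miss))
    stop("missing marker column: ", paste(miss, collapse = ", "), call. = FALSE)

  x <- suppressWarnings(as.numeric(df$x_um))
  y <- suppressWarnings(as.numeric(df$y_um))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad))
    stop("non-numeric coordinate at data row ", bad[1], call. = FALSE)
  bad <- which(!df$compartment %in% COMPARTMENTS)
  if (length(bad))
    stop("unknown compartment value '", df$compartment[bad[1]],
         "' at data row ", bad[1], call. = FALSE)

  cells <- data.frame(cell_id = df$cell_id, roi_id = df$roi_id,
                      x = x * scale, y = y * scale,
                      compartment = df$compartment,
                      stringsAsFactors = FALSE)
  # carry extra non-panel marker columns through unchanged
  extra <- setdiff(grep("_pos$", names(df), value = TRUE), mcols)
  all_markers <- c(panel, sub("_pos$", "", extra))
  for (i in seq_along(all_markers)) {
    v <- df[[paste0(all_markers[i], "_pos")]]
    if (!all(v %in% c("0", "1")))
      stop("marker column '", all_markers[i], "_pos' must be 0/1", call. = FALSE)
    cells[[all_markers[i]]] <- v == "1"
  }

  roi_lines <- grep("^#!roi\t", meta, value = TRUE)
  if (length(roi_lines)) {
    parts <- strsplit(sub("^#!roi\t", "", roi_lines), "\t")
    rois <- data.frame(
      roi_id = vapply(parts, `[`, "", 1),
      xmin = as.numeric(vapply(parts, `[`, "", 2)) * scale,
      ymin = as.numeric(vapply(parts, `[`, "", 3)) * scale,
      xmax = as.numeric(vapply(parts, `[`, "", 4)) * scale,
      ymax = as.numeric(vapply(parts, `[`, "", 5)) * scale,
      area_mm2 = as.numeric(vapply(parts, `[`, "", 6)),
      stringsAsFactors = FALSE)
  } else {
    rois <- infer_rois(cells)
  }
  sample_map(patient_id, lesion_type, lesion_id, all_markers, rois, cells)
}

# fallback ROI table from the cell extent (area = bounding rectangle)
infer_rois <- function(cells) {
  ids <- unique(cells$roi_id)
  do.call(rbind, lapply(ids, function(id) {
    cc <- cells[cells$roi_id == id, ]
    w <- max(diff(range(cc$x)), 1); h <- max(diff(range(cc$y)), 1)
    data.frame(roi_id = id, xmin = min(cc$x), ymin = min(cc$y),
               xmax = min(cc$x) + w, ymax = min(cc$y) + h,
               area_mm2 = w * h / 1e6, stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

num17 <- function(v) sprintf("%.17g", v)

#' Write a segmented-cell table
#'
#' Writes the dialect read by [read_cell_table()]. Coordinates are written
#' with 17 significant digits so that a write/read round trip reproduces the
#' sample bit-exactly.
#'
#' @param sample A [sample_map()].
#' @param path Output path.
#' @param sep Field separator, tab by default.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(sample, path, sep = "\t") {
  validate_sample_map(sample)
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write: ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(c(
    paste0("#!patient_id\t", sample$patient_id),
    paste0("#!lesion_type\t", sample$lesion_type),
    paste0("#!lesion_id\t", sample$lesion_id),
    paste0("#!um_per_unit\t1"),
    sprintf("#!roi\t%s\t%s\t%s\t%s\t%s\t%s", sample$rois$roi_id,
            num17(sample$rois$xmin), num17(sample$rois$ymin),
            num17(sample$rois$xmax), num17(sample$rois$ymax),
            num17(sample$rois$area_mm2))), con)
  hdr <- c("cell_id", "roi_id", "x_um", "y_um", "compartment",
           paste0(sample$panel, "_pos"))
  writeLines(paste(hdr, collapse = sep), con)
  if (nrow(sample$cells)) {
    cols <- do.call(cbind, c(
      list(sample$cells$cell_id, sample$cells$roi_id,
           num17(sample$cells$x), num17(sample$cells$y),
           sample$cells$compartment),
      lapply(sample$panel, function(m) ifelse(sample$cells[[m]], "1", "0"))))
    writeLines(apply(cols, 1, paste, collapse = sep), con)
  }
  invisible(path)
}

#' Merge several lesions of one patient into a single sample map
#'
#' Used for patients with more than one metastatic lesion so they contribute
#' one pooled metastasis value to the paired analyses. ROI identifiers are
#' prefixed with their lesion of origin to stay unique; the merged tissue
#' area is the sum over lesions.
#'
#' @param samples List of [sample_map()] objects sharing patient, lesion
#'   type and panel.
#' @return A single merged [sample_map()].
#' @export
merge_lesions <- function(samples) {
  stopifnot(length(samples) >= 1)
  if (length(samples) == 1) return(samples[[1]])
  s1 <- samples[[1]]
  for (s in samples[-1]) {
    if (!identical(s$patient_id, s1$patient_id))
      stop("cannot merge lesions from different patients", call. = FALSE)
    if (!identical(s$lesion_type, s1$lesion_type))
      stop("cannot merge lesions of mixed lesion_type", call. = FALSE)
    if (!identical(s$panel, s1$panel))
      stop("cannot merge lesions with different panels", call. = FALSE)
  }
  pref <- function(s) {
    r <- s$rois; c <- s$cells
    r$roi_id <- paste(s$lesion_id, r$roi_id, sep = ".")
    if (nrow(c)) {
      c$roi_id <- paste(s$lesion_id, c$roi_id, sep = ".")
      c$cell_id <- paste(s$lesion_id, c$cell_id, sep = ".")
    }
    list(r = r, c = c)
  }
  parts <- lapply(samples, pref)
  sample_map(s1$patient_id, s1$lesion_type,
             paste0(s1$lesion_type, "_merged"),
             s1$panel,
             do.call(rbind, lapply(parts, `[[`, "r")),
             do.call(rbind, lapply(parts, `[[`, "c")))
}

#' Read per-patient clinical metadata
#'
#' Delimited text keyed by `patient_id` with `n_liver_metastases` (an
#' integer of at least 1) and `max_metastasis_diameter_cm` (positive real);
#' the two grouping variables of the clinical subgroup analyses.
#'
#' @param path Path to the file.
#' @return Data frame with the three columns.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  df <- read.delim(path, sep = sniff_sep(first), stringsAsFactors = FALSE)
  need <- c("patient_id", "n_liver_metastases", "max_metastasis_diameter_cm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$patient_id <- as.character(df$patient_id)
  if (any(df$n_liver_metastases < 1))
    stop("n_liver_metastases must be >= 1", call. = FALSE)
  if (any(df$max_metastasis_diameter_cm <= 0))
    stop("max_metastasis_diameter_cm must be positive", call. = FALSE)
  df
}

#' Write per-patient clinical metadata
#' @param clinical Data frame as returned by [read_clinical_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  write.table(clinical, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
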