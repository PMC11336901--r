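#' DSP experiment container
#'
#' Bundles a gene x ROI count matrix, the matched negative-probe x ROI
#' count matrix, and per-ROI metadata (patient of origin, stage-coordinate
#' ROI centers in micrometres, segment label) into a validated object.
#' ROIs (regions of interest) are the sample unit of a GeoMx-style digital
#' spatial profiling run; negative probes target no transcript and anchor
#' the limit of quantitation.
#'
#' @param counts non-negative integer matrix, genes in rows (unique
#'   symbols as rownames), ROIs in columns (unique ids as colnames).
#' @param negprobes non-negative integer matrix of negative-probe counts;
#'   columns must match `counts` exactly (same ids, same order).
#' @param rois data.frame with columns `roi_id`, `patient_id`, `x_um`,
#'   `y_um`, `segment`; one row per ROI column (any row order).
#' @return an object of class `DSPExperiment`: a list with elements
#'   `counts`, `negprobes`, `rois` (rows re-ordered to the column order
#'   of `counts`).
#' @examples
#' cts <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("r1", "r2")))
#' neg <- matrix(1, 2, 2, dimnames = list(c("n1", "n2"), c("r1", "r2")))
#' md <- data.frame(roi_id = c("r1", "r2"), patient_id = "p1",
#'                  x_um = c(0, 100), y_um = c(0, 0), segment = "tumor")
#' DSPExperiment(cts, neg, md)
#' @export
DSPExperiment <- function(counts, negprobes, rois) {
  check_expr_matrix(counts, "counts")
  check_expr_matrix(negprobes, "negprobes")
  check_that(all(is.finite(counts)) && all(counts >= 0),
             "counts must be finite and non-negative")
  check_that(all(counts == round(counts)), "counts must be integers")
  check_that(all(negprobes >= 0) && all(negprobes == round(negprobes)),
             "negative-probe counts must be non-negative integers")
  check_that(identical(colnames(counts), colnames(negprobes)),
             "counts and negprobes must share identical ROI columns")
  check_that(is.data.frame(rois), "rois must be a data.frame")
  need <- c("roi_id", "patient_id", "x_um", "y_um", "segment")
  miss <- setdiff(need, names(rois))
  check_that(length(miss) == 0, "rois lacks column(s): %s",
             paste(miss, collapse = ", "))
  rois$roi_id <- as.character(rois$roi_id)
  rois$patient_id <- as.character(rois$patient_id)
  absent <- setdiff(colnames(counts), rois$roi_id)
  check_that(length(absent) == 0, "ROI(s) missing from metadata: %s",
             paste(absent, collapse = ", "))
  check_that(!anyDuplicated(rois$roi_id), "duplicated roi_id in metadata")
  check_that(all(nzchar(rois$patient_id)), "patient_id must be non-empty")
  check_that(all(is.finite(rois$x_um)) && all(is.finite(rois$y_um)),
             "ROI coordinates must be finite")
  rois <- rois[match(colnames(counts), rois$roi_id), , drop = FALSE]
  rownames(rois) <- NULL
  structure(list(counts = counts, negprobes = negprobes, rois = rois),
            class = "DSPExperiment")
}

#' @export
print.DSPExperiment <- function(x, ...) {
  cat(sprintf(
    "DSPExperiment: %d genes x %d ROIs (%d negative probes, %d patients)\n",
    nrow(x$counts), ncol(x$counts), nrow(x$negprobes),
    length(unique(x$rois$patient_id))))
  invisible(x)
}

#' @export
dim.DSPExperiment <- function(x) dim(x$counts)

read_tsv_matrix <- function(path, what) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_that(ncol(df) >= 2, "%s: expected a feature column plus ROI columns", what)
  feats <- as.character(df[[1]])
  dup <- unique(feats[duplicated(feats)])
  check_that(length(dup) == 0, "%s: duplicated feature symbol(s): %s", what,
             paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  check_that(is.numeric(m), "%s: non-numeric entries", what)
  check_that(all(m == round(m)), "%s: non-integer count entries", what)
  storage.mode(m) <- "double"
  rownames(m) <- feats
  m
}

#' Load a DSP experiment from TSV files
#'
#' Reads the three tab-separated files produced by a DSP export (or by
#' [write_dsp_experiment()]): a gene count table and a negative-probe
#' count table, both with a leading feature-symbol column and one column
#' per ROI, and an ROI metadata table with columns `roi_id`, `patient_id`,
#' `x_um`, `y_um`, `segment`. Metadata rows are joined on `roi_id`, so
#' their order need not match the count columns.
#'
#' @param counts_path,negprobes_path,metadata_path file paths.
#' @return a [DSPExperiment()].
#' @export
load_dsp_experiment <- function(counts_path, negprobes_path, metadata_path) {
  for (p in c(counts_path, negprobes_path, metadata_path)) {
    check_that(file.exists(p), "file not found: %s", p)
  }
  counts <- read_tsv_matrix(counts_path, "counts")
  negprobes <- read_tsv_matrix(negprobes_path, "negprobes")
  md <- utils::read.delim(metadata_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  DSPExperiment(counts, negprobes, md)
}

#' Write a DSP experiment to TSV files
#'
#' Inverse of [load_dsp_experiment()]; round-trips counts exactly.
#'
#' @param exp a [DSPExperiment()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written (`counts`, `negprobes`, `metadata`).
#' @export
write_dsp_experiment <- function(exp, dir) {
  stopifnot(inherits(exp, "DSPExperiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(counts = file.path(dir, "counts.tsv"),
                negprobes = file.path(dir, "negprobes.tsv"),
                metadata = file.path(dir, "roi_metadata.tsv"))
  write_matrix <- function(m, label, path) {
    df <- data.frame(rownames(m), m, check.names = FALSE)
    names(df)[1] <- label
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_matrix(exp$counts, "gene", paths$counts)
  write_matrix(exp$negprobes, "probe", paths$negprobes)
  utils::write.table(exp$rois, paths$metadata, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Within-patient spatial physical distances
#'
#' Euclidean distance in micrometres between the centers of every
#' unordered pair of ROIs that belong to the same patient; cross-patient
#' pairs are never formed (distance across tissue cores is meaningless).
#' Patients with a single ROI contribute no rows.
#'
#' @param rois data.frame with columns `roi_id`, `patient_id`, `x_um`,
#'   `y_um` (e.g. the `rois` element of a [DSPExperiment()]).
#' @return data.frame with columns `patient_id`, `roi_a`, `roi_b`,
#'   `spd_um`, one row per within-patient pair.
#' @examples
#' md <- data.frame(roi_id = c("r1", "r2"), patient_id = "p1",
#'                  x_um = c(0, 3), y_um = c(0, 4), segment = "tumor")
#' spd_matrix(md)  # 3-4-5 triangle: 5 um
#' @export
spd_matrix <- function(rois) {
  check_that(is.data.frame(rois) &&
               all(c("roi_id", "patient_id", "x_um", "y_um") %in% names(rois)),
             "rois must contain roi_id, patient_id, x_um, y_um")
  out <- lapply(split(rois, rois$patient_id), function(r) {
    n <- nrow(r)
    if (n < 2) return(NULL)
    idx <- utils::combn(n, 2)
    data.frame(
      patient_id = r$patient_id[1],
      roi_a = as.character(r$roi_id[idx[1, ]]),
      roi_b = as.character(r$roi_id[idx[2, ]]),
      spd_um = sqrt((r$x_um[idx[1, ]] - r$x_um[idx[2, ]])^2 +
                    (r$y_um[idx[1, ]] - r$y_um[idx[2, ]])^2),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), roi_a = character(),
                      roi_b = character(), spd_um = numeric())
  }
  rownames(out) <- NULL
  out
}
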