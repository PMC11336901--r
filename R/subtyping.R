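.sclc_tfs <- c(`SCLC-A` = "ASCL1", `SCLC-N` = "NEUROD1",
               `SCLC-P` = "POU2F3", `SCLC-Y` = "YAP1")

#' Call SCLC transcriptional subtype per ROI
#'
#' Assigns each ROI the subtype of its maximally expressed lineage
#' transcription factor among ASCL1, NEUROD1, POU2F3 and YAP1 (on the
#' normalized log2 matrix). Exact ties are broken by the fixed priority
#' ASCL1 > NEUROD1 > POU2F3 > YAP1 and flagged. With `zscore = TRUE` the
#' four TF rows are z-scored across ROIs first, so TFs with different
#' baseline expression compete on a common scale.
#'
#' @param matrix normalized log2 gene x ROI matrix containing all four
#'   TF rows.
#' @param tf_genes named character vector mapping the four subtype labels
#'   to gene symbols (override for non-default symbol sets).
#' @param zscore compare TFs on per-TF cohort z-scores instead of raw
#'   log2 values.
#' @return data.frame with `roi_id`, the four TF expression values,
#'   `label`, `tie_flag`.
#' @export
call_transcriptional_subtype <- function(matrix, tf_genes = .sclc_tfs,
                                         zscore = FALSE) {
  check_expr_matrix(matrix, "matrix")
  miss <- setdiff(tf_genes, rownames(matrix))
  check_that(length(miss) == 0, "missing transcription factor gene(s): %s",
             paste(miss, collapse = ", "))
  tf <- matrix[tf_genes, , drop = FALSE]
  if (zscore) {
    tf <- t(scale(t(tf)))
    tf[is.nan(tf)] <- 0
  }
  ## which.max returns the first maximum, i.e. the fixed priority order
  win <- apply(tf, 2, which.max)
  tie <- apply(tf, 2, function(v) sum(v == max(v)) > 1)
  out <- data.frame(roi_id = colnames(matrix),
                    t(matrix[tf_genes, , drop = FALSE]),
                    label = names(tf_genes)[win],
                    tie_flag = tie,
                    stringsAsFactors = FALSE)
  names(out)[2:5] <- tf_genes
  rownames(out) <- NULL
  out
}

#' Neuroendocrine (NE) score per ROI
#'
#' Correlates each ROI's expression over the NE gene panel with an NE
#' and a non-NE reference centroid (Pearson); the NE score is
#' `(corr_ne - corr_nonne) / 2`, in `[-1, 1]`, and the ROI is classed
#' NE-high when the score is positive. ROIs whose panel vector is
#' constant have no defined correlation and get `NA` with class
#' `"undefined"`.
#'
#' @param matrix normalized log2 gene x ROI matrix.
#' @param centroids list with named numeric vectors `ne` and `non_ne`
#'   over the panel genes (e.g. [simulate_ne_centroids()]).
#' @param ne_panel character vector of panel genes; defaults to the
#'   genes of the `ne` centroid. At least 3 panel genes must be present
#'   in the matrix.
#' @return data.frame with `roi_id`, `corr_ne`, `corr_nonne`,
#'   `ne_score`, `ne_class`.
#' @export
compute_ne_score <- function(matrix, centroids,
                             ne_panel = names(centroids$ne)) {
  check_expr_matrix(matrix, "matrix")
  check_that(is.list(centroids) && all(c("ne", "non_ne") %in% names(centroids)),
             "centroids must contain 'ne' and 'non_ne' vectors")
  panel <- intersect(ne_panel, rownames(matrix))
  check_that(length(panel) >= 3,
             "need >= 3 NE panel genes in the matrix (found %d)",
             length(panel))
  miss <- setdiff(panel, names(centroids$ne))
  check_that(length(miss) == 0, "centroids do not cover panel gene(s): %s",
             paste(miss, collapse = ", "))
  ne <- centroids$ne[panel]
  non_ne <- centroids$non_ne[panel]
  res <- lapply(colnames(matrix), function(j) {
    v <- matrix[panel, j]
    if (stats::sd(v) == 0 || stats::sd(ne) == 0 || stats::sd(non_ne) == 0) {
      return(data.frame(roi_id = j, corr_ne = NA_real_,
                        corr_nonne = NA_real_, ne_score = NA_real_,
                        ne_class = "undefined", stringsAsFactors = FALSE))
    }
    r1 <- stats::cor(v, ne)
    r2 <- stats::cor(v, non_ne)
    s <- (r1 - r2) / 2
    data.frame(roi_id = j, corr_ne = r1, corr_nonne = r2, ne_score = s,
               ne_class = if (s > 0) "high" else "low",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Class counts and printed-style percentages
#'
#' Tabulates a label vector into counts and percentages
#' (`100 * count / total`, rounded half-up to one decimal, the rounding
#' convention of printed clinical tables), ordered by descending count.
#'
#' @param labels non-empty character vector (or factor) of class labels.
#' @return data.frame with `class`, `count`, `percentage`.
#' @examples
#' summarize_subtype_distribution(rep(c("SCLC-A", "SCLC-N", "SCLC-P"),
#'                                    c(39, 25, 15)))
#' @export
summarize_subtype_distribution <- function(labels) {
  check_that(length(labels) > 0, "empty label list")
  tab <- sort(table(as.character(labels)), decreasing = TRUE)
  data.frame(class = names(tab),
             count = as.integer(tab),
             percentage = round_half_up(100 * as.integer(tab) / length(labels), 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-patient subtype concordance
#'
#' For each patient, the modal subtype over its ROIs (modal ties broken
#' by the lexicographically smallest label, flagged), the fraction of
#' ROIs matching it, and a purity flag. The cohort-level concordance is
#' the fraction of all ROIs matching their own patient's modal label.
#'
#' @param labels named character vector, ROI -> subtype label.
#' @param patients named character vector, ROI -> patient id (every ROI
#'   in `labels` must be mapped).
#' @return list with `patients` (data.frame `patient_id`,
#'   `majority_label`, `concordance`, `purity`, `modal_tie`) and
#'   `cohort_concordance`.
#' @export
patient_subtype_concordance <- function(labels, patients) {
  check_that(!is.null(names(labels)), "labels must be named by ROI")
  miss <- setdiff(names(labels), names(patients))
  check_that(length(miss) == 0, "ROI(s) without patient mapping: %s",
             paste(miss, collapse = ", "))
  pat <- patients[names(labels)]
  per <- lapply(split(labels, pat), function(l) {
    tab <- table(l)
    top <- max(tab)
    winners <- sort(names(tab)[tab == top])
    maj <- winners[1]
    data.frame(majority_label = maj,
               concordance = unname(tab[maj]) / length(l),
               purity = if (length(tab) == 1) "pure" else "mixed",
               modal_tie = length(winners) > 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  out <- data.frame(patient_id = names(per), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  modal <- stats::setNames(out$majority_label, out$patient_id)
  list(patients = out,
       cohort_concordance = mean(labels == modal[pat]))
}
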