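#' Per-ROI heterogeneity (DEPTH-style deviation) scores
#'
#' For each gene g, expression is z-scored across ROIs
#' (`z_gj = (x_gj - mean_g) / sd_g`; genes with zero SD contribute z = 0).
#' The deviating score of gene g in ROI j is `z_gj^2`, and the ROI's
#' heterogeneity score is the sample standard deviation of its deviating
#' scores over genes. A tumor-only cohort has no normal reference, so
#' z-scores are taken against the cohort of ROIs supplied in `matrix`;
#' pass a within-patient submatrix to change the reference scope.
#'
#' @param matrix normalized log-scale gene x ROI matrix with >= 2 ROIs.
#'   A single-gene matrix is degenerate: the SD over one deviating score
#'   is taken as 0.
#' @return list with `depth` (named per-ROI score, >= 0) and
#'   `zmatrix_summary` (data.frame of the per-gene mean and SD used for
#'   z-scoring).
#' @export
depth_scores <- function(matrix) {
  check_expr_matrix(matrix, "matrix")
  check_that(ncol(matrix) >= 2, "DEPTH undefined for a single ROI")
  mu <- rowMeans(matrix)
  sd_g <- apply(matrix, 1, stats::sd)
  z <- (matrix - mu) / ifelse(sd_g == 0, 1, sd_g)
  z[sd_g == 0, ] <- 0
  d <- z^2
  depth <- if (nrow(matrix) == 1) {
    stats::setNames(rep(0, ncol(matrix)), colnames(matrix))
  } else {
    apply(d, 2, stats::sd)
  }
  list(depth = depth,
       zmatrix_summary = data.frame(gene = rownames(matrix), mean = mu,
                                    sd = sd_g, row.names = NULL))
}

#' Within-patient inter-ROI concordance (C-score) table
#'
#' The C-score of an ROI pair is the Spearman correlation of the two
#' transcriptome vectors over all genes; it is computed for every
#' unordered pair of ROIs sharing a patient and joined with the pair's
#' spatial physical distance from [spd_matrix()]. Pairs in which either
#' profile is constant (rank correlation undefined) get `NA` and are
#' excluded from summaries.
#'
#' @param matrix normalized log-scale gene x ROI matrix.
#' @param rois ROI metadata data.frame (see [spd_matrix()]); only ROIs
#'   present in `matrix` are used.
#' @return data.frame with columns `patient_id`, `roi_a`, `roi_b`,
#'   `c_score`, `spd_um`.
#' @export
c_score_table <- function(matrix, rois) {
  check_expr_matrix(matrix, "matrix")
  rois <- rois[rois$roi_id %in% colnames(matrix), , drop = FALSE]
  pairs <- spd_matrix(rois)
  check_that(nrow(pairs) >= 1, "no patient contributes >= 2 ROIs")
  pairs$c_score <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- matrix[, pairs$roi_a[i]]
    b <- matrix[, pairs$roi_b[i]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b, method = "spearman")
  }, numeric(1))
  pairs[, c("patient_id", "roi_a", "roi_b", "c_score", "spd_um")]
}

#' Correlation between spatial distance and concordance
#'
#' Spearman correlation (with two-sided p-value) of the spatial physical
#' distance against the C-score over all within-patient ROI pairs — the
#' check that multi-region sampling distance does not by itself drive
#' transcriptional discordance.
#'
#' @param table output of [c_score_table()]; rows with `NA` C-score are
#'   dropped.
#' @return list with `rho`, `p`, and `n_pairs`.
#' @export
spd_cscore_correlation <- function(table) {
  check_that(all(c("c_score", "spd_um") %in% names(table)),
             "table must contain c_score and spd_um")
  tab <- table[stats::complete.cases(table[, c("c_score", "spd_um")]), ]
  check_that(nrow(tab) >= 3, "need >= 3 pairs for a correlation")
  check_that(stats::sd(tab$c_score) > 0 && stats::sd(tab$spd_um) > 0,
             "correlation undefined: a column has zero variance")
  ct <- suppressWarnings(
    stats::cor.test(tab$spd_um, tab$c_score, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n_pairs = nrow(tab))
}
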