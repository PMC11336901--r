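#' Negative-probe limit of quantitation (LOQ) filter
#'
#' For each ROI the LOQ is the geometric mean of its negative-probe
#' counts times the geometric standard deviation raised to `sd_exponent`
#' (default 2, the conventional GeoMx detection threshold). Geometric
#' statistics are taken on counts plus `offset` with natural logs and the
#' sample (n-1) SD. A gene is "detected" in an ROI when its count is at
#' least the ROI's LOQ; genes detected in fewer than `min_fraction_above`
#' of ROIs can be dropped. The default `min_fraction_above = 0` keeps
#' every gene, matching whole-transcriptome analyses that retain the full
#' panel downstream.
#'
#' @param exp a [DSPExperiment()] with at least two negative probes.
#' @param sd_exponent exponent applied to the geometric SD.
#' @param min_fraction_above fraction of ROIs in which a gene must reach
#'   the LOQ to be retained; 0 disables gene dropping.
#' @param offset count offset before geometric statistics; set to 0 to
#'   evaluate the bare formula (errors if any ROI has an all-zero probe
#'   column).
#' @return list with `loq` (named per-ROI LOQ), `detected` (logical gene
#'   x ROI matrix), `detect_fraction` (per-gene fraction of ROIs at or
#'   above LOQ), and `experiment` (the input with low-detection genes
#'   removed).
#' @export
loq_qc <- function(exp, sd_exponent = 2, min_fraction_above = 0,
                   offset = 0.5) {
  stopifnot(inherits(exp, "DSPExperiment"))
  check_that(nrow(exp$negprobes) >= 2,
             "LOQ needs >= 2 negative probes per ROI")
  check_that(min_fraction_above >= 0 && min_fraction_above <= 1,
             "min_fraction_above must be in [0, 1]")
  loq <- apply(exp$negprobes, 2, function(x) {
    g <- geom_stats(x, offset = offset)
    g$geomean * g$geosd^sd_exponent
  })
  detected <- sweep(exp$counts, 2, loq, `>=`)
  detect_fraction <- rowMeans(detected)
  keep <- detect_fraction >= min_fraction_above
  filtered <- exp
  filtered$counts <- exp$counts[keep, , drop = FALSE]
  list(loq = loq, detected = detected, detect_fraction = detect_fraction,
       experiment = filtered)
}

#' Q3 (upper-quartile) normalization
#'
#' Scales each ROI so that its 75th-percentile gene count (Q3, linear
#' interpolation over all genes, negative probes excluded) equals the
#' cohort anchor — the geometric mean of the per-ROI Q3 values. The
#' scale factor for ROI j is `geomean(Q3) / Q3_j`, so after normalization
#' every ROI has the same Q3 and inter-ROI comparisons are depth-free.
#'
#' @param exp a [DSPExperiment()], or a bare non-negative gene x ROI
#'   count matrix.
#' @return list with `q3` (per-ROI 75th percentile of the input),
#'   `scale_factor` (per-ROI multiplier), and `matrix` (normalized
#'   gene x ROI matrix, linear scale).
#' @export
q3_normalize <- function(exp) {
  m <- if (inherits(exp, "DSPExperiment")) exp$counts else exp
  check_expr_matrix(m, "counts")
  q3 <- col_q3(m)
  bad <- colnames(m)[q3 <= 0]
  check_that(length(bad) == 0,
             "ROI(s) with non-positive Q3 cannot be normalized: %s",
             paste(bad, collapse = ", "))
  anchor <- exp(mean(log(q3)))
  scale_factor <- anchor / q3
  out <- sweep(m, 2, scale_factor, `*`)
  list(q3 = q3, scale_factor = scale_factor, matrix = out)
}

#' Elementwise log2(x + 1) transform
#'
#' @param m non-negative numeric matrix (or vector).
#' @return `log2(m + 1)`, same shape.
#' @examples
#' log2_transform(c(0, 1, 7))  # 0, 1, 3
#' @export
log2_transform <- function(m) {
  check_that(all(m >= 0), "log2(x+1) transform requires non-negative values")
  log2(m + 1)
}

#' One-call QC + normalization front end
#'
#' Convenience wrapper running [loq_qc()], [q3_normalize()] and
#' [log2_transform()] in the standard order; returns the log2 Q3
#' matrix most downstream functions consume.
#'
#' @inheritParams loq_qc
#' @param log2 apply the log2(x+1) transform to the normalized matrix.
#' @return list with elements `loq`, `q3`, `scale_factor`, `matrix`.
#' @export
normalize_dsp <- function(exp, sd_exponent = 2, min_fraction_above = 0,
                          log2 = TRUE) {
  qc <- loq_qc(exp, sd_exponent = sd_exponent,
               min_fraction_above = min_fraction_above)
  norm <- q3_normalize(qc$experiment)
  mat <- if (log2) log2_transform(norm$matrix) else norm$matrix
  list(loq = qc$loq, q3 = norm$q3, scale_factor = norm$scale_factor,
       matrix = mat)
}
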