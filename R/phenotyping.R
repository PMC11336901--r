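#' Select highly variable genes from top principal components
#'
#' Ranks genes by their contribution to the leading eigenvectors of the
#' expression matrix: the score of gene g is the sum over the top
#' `n_components` principal components of (squared loading x component
#' variance), i.e. the part of the gene's variance captured by the
#' dominant expression axes. Ties are broken deterministically by gene
#' symbol.
#'
#' @param matrix normalized log-scale gene x ROI matrix.
#' @param n_top number of genes to return (default 200).
#' @param n_components number of leading components to sum over
#'   (default 10, capped at the matrix rank).
#' @return character vector of `n_top` gene symbols, highest score first.
#' @export
select_hvg <- function(matrix, n_top = 200, n_components = 10) {
  check_expr_matrix(matrix, "matrix")
  check_that(n_top >= 1 && n_top <= nrow(matrix),
             "n_top must be in [1, n_genes]")
  check_that(n_components >= 1, "n_components must be >= 1")
  ## PCA over ROIs: observations = ROIs, variables = genes
  pc <- stats::prcomp(t(matrix), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  lam <- pc$sdev[seq_len(k)]^2
  load2 <- pc$rotation[, seq_len(k), drop = FALSE]^2
  score <- as.vector(load2 %*% lam)
  ord <- order(-score, rownames(matrix))
  rownames(matrix)[ord[seq_len(n_top)]]
}

#' Ward clustering of ROIs on highly variable genes
#'
#' Standardizes each gene (zero mean, unit SD across ROIs; zero-variance
#' genes are dropped) and applies agglomerative hierarchical clustering
#' with Ward's criterion (`ward.D2`) on Euclidean distances, cut at `k`
#' clusters.
#'
#' @param matrix gene x ROI matrix restricted to the selected genes.
#' @param k number of clusters (default 3).
#' @return list with `cluster` (named integer vector over ROIs),
#'   `hclust` (the dendrogram object), and `linkage_summary` (merge
#'   heights).
#' @export
cluster_rois <- function(matrix, k = 3) {
  check_expr_matrix(matrix, "matrix")
  check_that(k >= 1 && k <= ncol(matrix), "k must be in [1, n_ROIs]")
  sd_g <- apply(matrix, 1, stats::sd)
  m <- matrix[sd_g > 0, , drop = FALSE]
  check_that(nrow(m) >= 1, "all genes constant: nothing to cluster on")
  zs <- t(scale(t(m)))
  hc <- stats::hclust(stats::dist(t(zs)), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  list(cluster = cl, hclust = hc, linkage_summary = hc$height)
}

#' Map ROI clusters to ITH phenotypes by heterogeneity ordering
#'
#' Orders clusters by their median per-ROI heterogeneity score: with
#' k = 3 the highest-median cluster becomes `h-ITH`, the middle `m-ITH`
#' and the lowest `l-ITH`; with k = 2 only `h-ITH`/`l-ITH` are assigned
#' (with a warning). Median ties are broken by mean score, then by
#' smallest cluster index, so the labeling is deterministic.
#'
#' @param cluster named integer vector, ROI -> cluster index.
#' @param depth named numeric vector of heterogeneity scores per ROI (the
#'   `depth` element of [depth_scores()]).
#' @return named character vector, ROI -> phenotype.
#' @export
label_ith_phenotypes <- function(cluster, depth) {
  check_that(!is.null(names(cluster)), "cluster must be named by ROI")
  miss <- setdiff(names(cluster), names(depth))
  check_that(length(miss) == 0, "no heterogeneity score for ROI(s): %s",
             paste(miss, collapse = ", "))
  ks <- sort(unique(cluster))
  check_that(length(ks) <= 3, "phenotype labeling defined for k <= 3 clusters")
  labels <- if (length(ks) == 3) c("h-ITH", "m-ITH", "l-ITH") else {
    if (length(ks) == 2) {
      warning("k = 2: assigning h-ITH/l-ITH only")
      c("h-ITH", "l-ITH")
    } else "h-ITH"
  }
  med <- vapply(ks, function(g) stats::median(depth[names(cluster)[cluster == g]]),
                numeric(1))
  avg <- vapply(ks, function(g) mean(depth[names(cluster)[cluster == g]]),
                numeric(1))
  ord <- ks[order(-med, -avg, ks)]
  map <- stats::setNames(labels, ord)
  stats::setNames(unname(map[as.character(cluster)]), names(cluster))
}

#' Deterministic 2-D embedding of ROI expression profiles
#'
#' Projects ROI profiles onto the first two principal components, for
#' visualization only (clustering and phenotype labels never consume
#' these coordinates). The embedding backend is deliberately pluggable;
#' the default PCA projection is exactly reproducible for any seed, and
#' the `perplexity`-style neighborhood check is kept so that
#' neighbor-based embeddings can be swapped in without an interface
#' change.
#'
#' @param matrix gene x ROI matrix.
#' @param seed integer seed (the PCA backend is deterministic regardless,
#'   but the seed is honored for stochastic backends).
#' @param perplexity neighborhood size parameter; must be < n_ROIs.
#' @return n_ROIs x 2 matrix of coordinates, rownames = ROI ids.
#' @export
embed_2d <- function(matrix, seed = 1L, perplexity = 10) {
  check_expr_matrix(matrix, "matrix")
  check_that(ncol(matrix) > perplexity,
             "too few ROIs (%d) for perplexity %s", ncol(matrix),
             format(perplexity))
  with_seed(seed, {
    pc <- stats::prcomp(t(matrix), center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(pc$x))
    out <- matrix(0, nrow = ncol(matrix), ncol = 2,
                  dimnames = list(colnames(matrix), c("dim1", "dim2")))
    out[, seq_len(k)] <- pc$x[, seq_len(k)]
    out
  })
}

#' End-to-end ITH phenotyping of a normalized experiment
#'
#' Convenience wrapper: select highly variable genes, Ward-cluster the
#' ROIs, score heterogeneity on the full matrix, and label clusters as
#' h/m/l-ITH.
#'
#' @param matrix normalized log-scale gene x ROI matrix.
#' @param n_hvg,n_components passed to [select_hvg()].
#' @param k number of clusters.
#' @return list with `hvg`, `cluster`, `depth`, `phenotype`.
#' @export
ith_phenotype_pipeline <- function(matrix, n_hvg = 200, n_components = 10,
                                   k = 3) {
  hvg <- select_hvg(matrix, n_top = min(n_hvg, nrow(matrix)),
                    n_components = n_components)
  cl <- cluster_rois(matrix[hvg, , drop = FALSE], k = k)
  dep <- depth_scores(matrix)
  list(hvg = hvg, cluster = cl$cluster, depth = dep$depth,
       phenotype = label_ith_phenotypes(cl$cluster, dep$depth))
}
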