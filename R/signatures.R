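#' One-vs-rest differential expression
#'
#' Tests every gene for differential expression between one ITH
#' phenotype and all remaining ROIs on the log2 matrix. `log2fc` is the
#' in-group mean minus the rest mean; p-values come from Welch's t-test
#' (default) or from an empirical-Bayes moderated t (`limma`). A gene
#' "passes" when the linear fold-change exceeds 1.5 in either direction
#' (|log2fc| > log2(1.5)) at p <= 0.05, the conventional spatial-DEG
#' filter; raw p is used (no multiplicity correction) unless
#' `adjust = TRUE` switches the pass rule to Benjamini-Hochberg adjusted
#' p-values.
#'
#' Degenerate genes with zero variance in both groups but unequal means
#' are kept with `p` set to the smallest representable double and
#' flagged in the `degenerate` column.
#'
#' @param matrix normalized log2 gene x ROI matrix.
#' @param phenotypes named character vector, ROI -> group label, covering
#'   the matrix columns.
#' @param contrast the label tested against the rest (both sides need
#'   >= 2 ROIs).
#' @param method `"welch"` or `"moderated"`.
#' @param fc_threshold linear fold-change threshold (default 1.5).
#' @param p_threshold p-value threshold (default 0.05).
#' @param adjust apply Benjamini-Hochberg and filter on adjusted p.
#' @return data.frame with `gene`, `contrast`, `log2fc`, `t`, `p`,
#'   (`p_adj` if `adjust`), `direction`, `passes`, `degenerate`.
#' @export
differential_expression <- function(matrix, phenotypes, contrast,
                                    method = c("welch", "moderated"),
                                    fc_threshold = 1.5, p_threshold = 0.05,
                                    adjust = FALSE) {
  method <- match.arg(method)
  check_expr_matrix(matrix, "matrix")
  miss <- setdiff(colnames(matrix), names(phenotypes))
  check_that(length(miss) == 0, "ROI(s) without phenotype: %s",
             paste(miss, collapse = ", "))
  grp <- phenotypes[colnames(matrix)] == contrast
  check_that(sum(grp) >= 2 && sum(!grp) >= 2,
             "both groups need >= 2 ROIs (in-group %d, rest %d)",
             sum(grp), sum(!grp))
  x <- matrix[, grp, drop = FALSE]
  y <- matrix[, !grp, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  log2fc <- m1 - m2
  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tstat <- ifelse(se2 > 0, log2fc / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
                 1)
    p <- 2 * stats::pt(-abs(tstat), df)
  } else {
    design <- stats::model.matrix(~ grp)
    fit <- limma::eBayes(limma::lmFit(matrix, design))
    tstat <- fit$t[, 2]
    p <- fit$p.value[, 2]
  }
  degenerate <- se_zero <- (v1 + v2) == 0 & log2fc != 0
  p[degenerate] <- .Machine$double.xmin
  tstat[degenerate] <- sign(log2fc[degenerate]) * Inf
  identical_gene <- (v1 + v2) == 0 & log2fc == 0
  p[identical_gene] <- 1
  out <- data.frame(gene = rownames(matrix), contrast = contrast,
                    log2fc = log2fc, t = tstat, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  p_pass <- p
  if (adjust) {
    out$p_adj <- stats::p.adjust(p, method = "BH")
    p_pass <- out$p_adj
  }
  out$direction <- ifelse(log2fc >= 0, "up", "down")
  out$passes <- abs(log2fc) > log2(fc_threshold) & p_pass <= p_threshold
  out$degenerate <- degenerate
  out
}

## vectorised Spearman rho + p for the columns of m against each other.
## p by the t-approximation for n >= 10, exact permutation
## distribution below (via cor.test).
spearman_pair <- function(a, b, exact_below = 10) {
  n <- length(a)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(c(rho = NA_real_, p = NA_real_))
  }
  rho <- stats::cor(a, b, method = "spearman")
  if (n < exact_below) {
    ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
    return(c(rho = rho, p = ct$p.value))
  }
  if (abs(rho) >= 1) return(c(rho = rho, p = 0))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  c(rho = rho, p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Spearman co-expression network over DEG sets
#'
#' Tests every unordered pair of the supplied genes for rank correlation
#' across ROIs; pairs with |rho| >= `rho_min` and p < `p_max` become
#' undirected edges. Genes left without any qualifying edge are dropped
#' from the node list. Constant genes cannot be rank-correlated; their
#' pairs are skipped with a warning.
#'
#' @param matrix normalized log2 gene x ROI matrix (>= 3 ROIs).
#' @param genes character vector of genes to wire (typically the union
#'   of per-phenotype DEG sets); must be present in the matrix.
#' @param rho_min minimum |Spearman rho| for an edge (default 0.6).
#' @param p_max p-value cutoff for an edge (default 0.01).
#' @param annotations optional named character vector gene -> phenotype
#'   of origin, carried onto the node table.
#' @return list with `nodes` (data.frame `gene`, `annotation`), `edges`
#'   (data.frame `gene_a`, `gene_b`, `rho`, `p`), and `n_tested`.
#' @export
build_coexpression_network <- function(matrix, genes, rho_min = 0.6,
                                       p_max = 0.01, annotations = NULL) {
  check_expr_matrix(matrix, "matrix")
  check_that(ncol(matrix) >= 3, "need >= 3 ROIs to correlate")
  genes <- unique(genes)
  miss <- setdiff(genes, rownames(matrix))
  check_that(length(miss) == 0, "gene(s) absent from matrix: %s",
             paste(utils::head(miss, 5), collapse = ", "))
  m <- matrix[genes, , drop = FALSE]
  const <- apply(m, 1, stats::sd) == 0
  if (any(const)) {
    warning(sprintf("skipping %d constant gene(s): %s", sum(const),
                    paste(utils::head(genes[const], 5), collapse = ", ")))
    m <- m[!const, , drop = FALSE]
    genes <- genes[!const]
  }
  check_that(length(genes) >= 2, "need >= 2 non-constant genes")
  n <- ncol(m)
  rk <- t(apply(m, 1, rank))
  ## Pearson on ranks == Spearman; vectorised across all pairs
  rho_mat <- suppressWarnings(stats::cor(t(rk)))
  idx <- which(upper.tri(rho_mat), arr.ind = TRUE)
  rho <- rho_mat[idx]
  if (n >= 10) {
    p <- ifelse(abs(rho) >= 1, 0,
                2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2))
  } else {
    p <- vapply(seq_len(nrow(idx)), function(i) {
      spearman_pair(m[idx[i, 1], ], m[idx[i, 2], ])[["p"]]
    }, numeric(1))
  }
  keep <- !is.na(rho) & abs(rho) >= rho_min & p < p_max
  edges <- data.frame(gene_a = genes[idx[keep, 1]],
                      gene_b = genes[idx[keep, 2]],
                      rho = rho[keep], p = p[keep],
                      stringsAsFactors = FALSE, row.names = NULL)
  connected <- sort(unique(c(edges$gene_a, edges$gene_b)))
  nodes <- data.frame(
    gene = connected,
    annotation = if (is.null(annotations)) rep(NA_character_, length(connected))
                 else unname(annotations[connected]),
    stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges, n_tested = nrow(idx))
}

#' Export a co-expression network as an igraph object
#'
#' @param network output of [build_coexpression_network()].
#' @return an `igraph` undirected graph with `rho`/`p` edge attributes
#'   and `annotation` vertex attribute (requires the igraph package).
#' @export
network_to_igraph <- function(network) {
  check_that(requireNamespace("igraph", quietly = TRUE),
             "the igraph package is required for graph export")
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Marker-module mean scores per ROI
#'
#' Scores each module (gene set) in each ROI as the unweighted mean of
#' the module genes' log2 expression — the marker-averaging principle of
#' MCP-counter-style microenvironment scoring. Module genes absent from
#' the matrix are dropped with a warning; a module with no gene present
#' is an error.
#'
#' @param matrix normalized log2 gene x ROI matrix.
#' @param modules named list of gene vectors (e.g. from [read_gmt()]).
#' @return data.frame with `roi_id`, `module`, `score`, `n_genes_used`.
#' @export
marker_module_score <- function(matrix, modules) {
  check_expr_matrix(matrix, "matrix")
  check_that(is.list(modules) && !is.null(names(modules)),
             "modules must be a named list of gene vectors")
  res <- lapply(names(modules), function(nm) {
    present <- intersect(modules[[nm]], rownames(matrix))
    check_that(length(present) > 0,
               "module '%s' has no gene present in the matrix", nm)
    if (length(present) < length(unique(modules[[nm]]))) {
      warning(sprintf("module '%s': %d of %d genes absent, scoring the rest",
                      nm, length(unique(modules[[nm]])) - length(present),
                      length(unique(modules[[nm]]))))
    }
    data.frame(roi_id = colnames(matrix), module = nm,
               score = colMeans(matrix[present, , drop = FALSE]),
               n_genes_used = length(present),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of the overlap between a query gene
#' list and each gene set, conditional on a stated universe. Sets are
#' silently intersected with the universe; the p-value is
#' `P(X >= overlap)` for X hypergeometric with the set/universe margins.
#' No multiple-testing correction by default (`adjust = TRUE` adds
#' Benjamini-Hochberg).
#'
#' @param query character vector of genes (must lie inside `universe`).
#' @param gene_sets named list of gene vectors.
#' @param universe character vector of all assayed genes.
#' @param adjust add a BH-adjusted p column.
#' @return data.frame with `set_name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p` (and `p_adj`), sorted by `p`.
#' @export
ora_enrichment <- function(query, gene_sets, universe, adjust = FALSE) {
  query <- unique(query)
  universe <- unique(universe)
  check_that(length(query) > 0, "empty query")
  check_that(length(universe) > 0, "empty universe")
  out <- setdiff(query, universe)
  check_that(length(out) == 0, "query gene(s) outside the universe: %s",
             paste(utils::head(out, 5), collapse = ", "))
  res <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(query, s))
    ## P(X >= k), X ~ Hypergeom(|set| white, |universe|-|set| black, draws=|query|)
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, length(s), length(universe) - length(s),
                    length(query), lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = length(s),
               query_size = length(query), universe_size = length(universe),
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (adjust) res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p), , drop = FALSE]
}
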