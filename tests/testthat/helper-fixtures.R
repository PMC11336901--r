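## Shared fixtures and independent oracles used across test files.

## small labelled gene x ROI matrix
toy_matrix <- function(nr, nc, values, genes = sprintf("g%02d", seq_len(nr)),
                       rois = sprintf("r%02d", seq_len(nc))) {
  matrix(values, nr, nc, dimnames = list(genes, rois))
}

## adjusted Rand index, computed from the contingency table (oracle
## implementation, independent of any clustering code under test)
ari <- function(a, b) {
  tab <- table(a, b)
  sc <- function(x) sum(choose(x, 2))
  sij <- sc(tab); si <- sc(rowSums(tab)); sj <- sc(colSums(tab))
  ex <- si * sj / choose(sum(tab), 2)
  (sij - ex) / ((si + sj) / 2 - ex)
}

## desk-scale simulation config for fast tests (overridable defaults)
desk_config <- function(...) {
  args <- list(n_patients = 20, n_genes = 500, n_negprobes = 50)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

## loop-written DEPTH oracle: explicit per-gene z-scores, squared
## deviating scores, per-ROI SD, no vectorised shortcuts
depth_oracle <- function(m) {
  z <- matrix(0, nrow(m), ncol(m))
  for (g in seq_len(nrow(m))) {
    mu <- mean(m[g, ]); s <- sd(m[g, ])
    if (s > 0) for (j in seq_len(ncol(m))) z[g, j] <- (m[g, j] - mu) / s
  }
  d <- z^2
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) out[j] <- sd(d[, j])
  names(out) <- colnames(m)
  out
}

## rank-then-Pearson Spearman oracle
spearman_oracle <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

## closed-form upper-tail hypergeometric summation oracle
hyper_tail_oracle <- function(overlap, set_size, query_size, universe_size) {
  ks <- overlap:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(universe_size - set_size, query_size - ks) /
        choose(universe_size, query_size))
}

## brute-force AUC: count positive/negative pairs, ties as 1/2
auc_oracle <- function(scores, pos) {
  s1 <- scores[pos]; s0 <- scores[!pos]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}
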