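grp_labels <- function(n1, n2) {
  setNames(rep(c("h-ITH", "rest"), c(n1, n2)), sprintf("r%02d", seq_len(n1 + n2)))
}

test_that("differential expression flags planted fold changes only", {
  set.seed(16)
  n1 <- 20; n2 <- 20
  m <- toy_matrix(30, n1 + n2, rnorm(30 * (n1 + n2), mean = 6, sd = 0.2))
  m[1, seq_len(n1)] <- m[1, seq_len(n1)] + 1     # planted log2fc = 1
  m[2, ] <- 4                                     # identical everywhere
  ph <- grp_labels(n1, n2)
  deg <- differential_expression(m, ph, "h-ITH")
  expect_true(deg$passes[1])
  expect_gt(deg$log2fc[1], 0.8)
  expect_equal(deg$log2fc[2], 0)
  expect_equal(deg$p[2], 1)
  expect_false(deg$passes[2])

  ## zero variance in both groups with unequal means: minimal p, flagged
  m2 <- m
  m2[3, ] <- rep(c(2, 9), c(n1, n2))
  deg2 <- differential_expression(m2, ph, "h-ITH")
  expect_true(deg2$degenerate[3])
  expect_equal(deg2$p[3], .Machine$double.xmin)
  expect_error(differential_expression(m[, 1:3], ph[1:3], "h-ITH"), ">= 2")
})

test_that("swapping the contrast negates fold changes and keeps p", {
  set.seed(17)
  m <- toy_matrix(25, 14, rnorm(350, 5))
  ph <- grp_labels(7, 7)
  a <- differential_expression(m, ph, "h-ITH")
  b <- differential_expression(m, ph, "rest")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("moderated and Welch tests agree on strong signals", {
  set.seed(18)
  m <- toy_matrix(40, 20, rnorm(800, 6, 0.3))
  m[1:5, 1:10] <- m[1:5, 1:10] + 2
  ph <- grp_labels(10, 10)
  w <- differential_expression(m, ph, "h-ITH")
  mo <- differential_expression(m, ph, "h-ITH", method = "moderated")
  expect_equal(w$log2fc, mo$log2fc, tolerance = 1e-9)
  expect_setequal(which(mo$passes), 1:5)
  expect_setequal(which(w$passes), 1:5)
})

test_that("network edges match a double-loop brute-force oracle", {
  set.seed(19)
  m <- toy_matrix(6, 12, rnorm(72))
  m[2, ] <- m[1, ] + rnorm(12, sd = 0.05)   # one strong pair
  net <- build_coexpression_network(m, rownames(m), rho_min = 0.5,
                                    p_max = 0.05)
  ## oracle: loop over all pairs with cor.test-equivalent t approximation
  edges <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    rho <- spearman_oracle(m[i, ], m[j, ])
    tt <- rho * sqrt((12 - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tt), 10)
    if (abs(rho) >= 0.5 && p < 0.05) {
      edges[[length(edges) + 1]] <- sprintf("g%02d-g%02d", i, j)
    }
  }
  expect_setequal(paste(net$edges$gene_a, net$edges$gene_b, sep = "-"),
                  unlist(edges))
  ## duplicated gene rows: perfect rank correlation, edge present
  dup <- rbind(m, g99 = m[1, ])
  net2 <- build_coexpression_network(dup, rownames(dup))
  expect_true(any((net2$edges$gene_a == "g01" & net2$edges$gene_b == "g99") |
                  (net2$edges$gene_a == "g99" & net2$edges$gene_b == "g01")))
  ## constant genes are skipped with a warning
  m3 <- m; m3[4, ] <- 7
  expect_warning(net3 <- build_coexpression_network(m3, rownames(m3)),
                 "constant")
  expect_false("g04" %in% c(net3$edges$gene_a, net3$edges$gene_b))
})

test_that("network construction is invariant to gene input order", {
  set.seed(20)
  m <- toy_matrix(10, 15, rnorm(150))
  m[5, ] <- m[3, ] * 1.2 + rnorm(15, sd = 0.1)
  a <- build_coexpression_network(m, rownames(m), rho_min = 0.4, p_max = 0.05)
  b <- build_coexpression_network(m, rev(rownames(m)), rho_min = 0.4,
                                  p_max = 0.05)
  key <- function(e) sort(paste(pmin(e$gene_a, e$gene_b),
                                pmax(e$gene_a, e$gene_b)))
  expect_identical(key(a$edges), key(b$edges))
})

test_that("networks export to igraph with attributes intact", {
  set.seed(21)
  m <- toy_matrix(5, 12, rnorm(60))
  m[2, ] <- m[1, ] + rnorm(12, sd = 0.05)
  net <- build_coexpression_network(m, rownames(m), rho_min = 0.5,
                                    p_max = 0.05,
                                    annotations = setNames(rep("h-ITH", 5),
                                                           rownames(m)))
  g <- network_to_igraph(net)
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_equal(sort(igraph::V(g)$name), net$nodes$gene)
  expect_equal(igraph::V(g)$annotation, net$nodes$annotation)
})

test_that("false-edge rate on independent noise matches the p threshold", {
  ## 20 independent genes, 30 ROIs: E[edges passing p < .01 with |rho| >= .46]
  ## ~ 190 * alpha where the rho cut is set at the p = .01 boundary so the
  ## p criterion governs
  n_seed <- 30
  counts <- vapply(seq_len(n_seed), function(s) {
    set.seed(s)
    m <- toy_matrix(20, 30, rnorm(600))
    net <- build_coexpression_network(m, rownames(m), rho_min = 0,
                                      p_max = 0.01)
    nrow(net$edges)
  }, numeric(1))
  expected <- 190 * 0.01
  binom_sd <- sqrt(190 * 0.01 * 0.99)
  expect_lt(abs(mean(counts) - expected), 3 * binom_sd / sqrt(n_seed) + 1)
})

test_that("module scores are marker means with the documented edge cases", {
  m <- toy_matrix(6, 4, as.numeric(1:24))
  ## single-gene module equals the gene itself
  s1 <- marker_module_score(m, list(one = "g03"))
  expect_equal(s1$score, unname(m["g03", ]))
  ## all-constant module returns the constant
  m2 <- m; m2[c(1, 2), ] <- 5
  s2 <- marker_module_score(m2, list(cc = c("g01", "g02")))
  expect_equal(s2$score, rep(5, 4))
  ## half-present module scores the present half with a warning
  expect_warning(s3 <- marker_module_score(m, list(hp = c("g01", "nope"))),
                 "absent")
  expect_equal(s3$score, unname(m["g01", ]))
  expect_equal(s3$n_genes_used, rep(1L, 4), ignore_attr = TRUE)
  expect_error(marker_module_score(m, list(bad = "missing")), "bad")
  ## linearity: score of the average ROI is the average of scores
  mod <- list(mm = c("g02", "g04", "g05"))
  avg <- cbind(m[, 1:2], r99 = rowMeans(m[, 1:2]))
  sc <- marker_module_score(avg, mod)
  expect_equal(sc$score[3], mean(sc$score[1:2]), tolerance = 1e-12)
})

test_that("over-representation p equals the hypergeometric tail", {
  universe <- sprintf("u%04d", 1:1000)
  set10 <- universe[1:10]
  got <- ora_enrichment(set10, list(s = set10), universe)
  expect_equal(got$p, hyper_tail_oracle(10, 10, 10, 1000), tolerance = 1e-12)
  ## zero overlap: p = 1
  got0 <- ora_enrichment(universe[11:20], list(s = set10), universe)
  expect_equal(got0$p, 1)
  ## sets are silently intersected with the universe
  gotx <- ora_enrichment(set10, list(s = c(set10, "alien")), universe)
  expect_equal(gotx$set_size, 10)
  ## monotone: p falls as overlap grows at fixed margins
  ps <- vapply(1:8, function(k) {
    ora_enrichment(c(universe[1:k], universe[500:(509 - k)]),
                   list(s = set10), universe)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(ora_enrichment(character(), list(s = set10), universe), "query")
  expect_error(ora_enrichment(c("alien"), list(s = set10), universe),
               "outside")
})

test_that("GMT files round-trip through the reader and writer", {
  sets <- list(alpha = structure(c("A", "B", "C"), description = "first"),
               beta = structure(c("D", "E"), description = "second"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(names(back), c("alpha", "beta"))
  expect_equal(as.character(back$alpha), c("A", "B", "C"))
  expect_equal(attr(back$beta, "description"), "second")
})
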