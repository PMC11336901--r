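make_toy_files <- function(dir, drop_roi = FALSE, dup_gene = FALSE,
                           non_integer = FALSE) {
  cts <- toy_matrix(3, 2, c(5, 10, 15, 20, 25, 30),
                    genes = c("A", "B", "C"), rois = c("r1", "r2"))
  if (dup_gene) rownames(cts) <- c("A", "A", "C")
  if (non_integer) cts[1, 1] <- 5.5
  neg <- toy_matrix(2, 2, c(1, 2, 3, 4), genes = c("n1", "n2"),
                    rois = c("r1", "r2"))
  md <- data.frame(roi_id = c("r2", "r1"), patient_id = "p1",
                   x_um = c(100, 0), y_um = 0, segment = "tumor")
  if (drop_roi) md <- md[md$roi_id != "r2", ]
  p <- list(counts = file.path(dir, "c.tsv"), neg = file.path(dir, "n.tsv"),
            md = file.path(dir, "m.tsv"))
  wr <- function(m, label, path) {
    df <- data.frame(rownames(m), m, check.names = FALSE)
    names(df)[1] <- label
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(cts, "gene", p$counts); wr(neg, "probe", p$neg)
  write.table(md, p$md, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

test_that("loader validates shape, joins metadata on roi_id, flags errors", {
  dir <- withr::local_tempdir()
  p <- make_toy_files(dir)
  exp <- load_dsp_experiment(p$counts, p$neg, p$md)
  expect_equal(dim(exp), c(3L, 2L))
  ## metadata arrived in the other order but is re-aligned to columns
  expect_equal(exp$rois$roi_id, c("r1", "r2"))

  p2 <- make_toy_files(withr::local_tempdir(), drop_roi = TRUE)
  expect_error(load_dsp_experiment(p2$counts, p2$neg, p2$md), "r2")
  p3 <- make_toy_files(withr::local_tempdir(), dup_gene = TRUE)
  expect_error(load_dsp_experiment(p3$counts, p3$neg, p3$md), "A")
  p4 <- make_toy_files(withr::local_tempdir(), non_integer = TRUE)
  expect_error(load_dsp_experiment(p4$counts, p4$neg, p4$md), "integer")
})

make_exp <- function(cts, neg) {
  md <- data.frame(roi_id = colnames(cts), patient_id = "p1",
                   x_um = seq_len(ncol(cts)), y_um = 0, segment = "tumor")
  DSPExperiment(cts, neg, md)
}

test_that("LOQ follows the geometric-statistics formula", {
  ## equal negprobes: geoSD = 1, LOQ = the probe value (bare formula)
  cts <- toy_matrix(3, 2, rep(50, 6))
  neg <- toy_matrix(3, 2, rep(8, 6), genes = c("n1", "n2", "n3"))
  qc <- loq_qc(make_exp(cts, neg), offset = 0)
  expect_equal(unname(qc$loq), c(8, 8), tolerance = 1e-12)

  ## {1, 100}: direct two-line evaluation of the formula as oracle
  neg2 <- toy_matrix(2, 2, c(1, 100, 1, 100), genes = c("n1", "n2"))
  qc2 <- loq_qc(make_exp(cts, neg2), offset = 0)
  lx <- log(c(1, 100))
  oracle <- exp(mean(lx)) * exp(sd(lx))^2
  expect_equal(unname(qc2$loq[1]), oracle, tolerance = 1e-12)

  ## scale equivariance: c times the probes => c times the LOQ
  neg3 <- toy_matrix(3, 2, c(3, 9, 27, 3 * 5, 9 * 5, 27 * 5),
                     genes = c("n1", "n2", "n3"))
  qc3 <- loq_qc(make_exp(cts, neg3), offset = 0)
  expect_equal(unname(qc3$loq[2] / qc3$loq[1]), 5, tolerance = 1e-12)
})

test_that("LOQ gene filtering honours min_fraction_above", {
  cts <- toy_matrix(4, 3, c(100, 1, 100, 1,
                            100, 1, 1, 1,
                            100, 1, 1, 1))
  neg <- toy_matrix(2, 3, rep(c(8, 8), 3), genes = c("n1", "n2"))
  ex <- make_exp(cts, neg)
  expect_equal(nrow(loq_qc(ex, min_fraction_above = 0)$experiment$counts), 4)
  kept <- loq_qc(ex, min_fraction_above = 0.99)$experiment$counts
  expect_equal(rownames(kept), "g01")  # detected in all three ROIs
  ## all-zero negprobes only work through the offset
  neg0 <- toy_matrix(2, 3, rep(0, 6), genes = c("n1", "n2"))
  expect_error(loq_qc(make_exp(cts, neg0), offset = 0), "offset")
  expect_silent(loq_qc(make_exp(cts, neg0)))
})

test_that("Q3 normalization equalizes upper quartiles and is idempotent", {
  ## identical columns: all factors 1
  cts <- toy_matrix(5, 3, rep(c(1, 4, 10, 20, 50), 3))
  nm <- q3_normalize(cts)
  expect_equal(unname(nm$scale_factor), rep(1, 3), tolerance = 1e-12)
  expect_equal(nm$matrix, cts)

  ## doubling a column halves its factor relative to the original
  cts2 <- cbind(cts[, 1:2], r03 = 2 * cts[, 1])
  nm2 <- q3_normalize(cts2)
  expect_equal(unname(nm2$scale_factor[3] / nm2$scale_factor[1]), 0.5,
               tolerance = 1e-12)

  ## random matrix: post-normalization Q3s all equal; re-running is a no-op
  set.seed(42)
  m <- toy_matrix(20, 5, sample(1:500, 100, replace = TRUE))
  nm3 <- q3_normalize(m)
  q3s <- apply(nm3$matrix, 2, quantile, probs = 0.75)
  expect_lt(diff(range(q3s)) / mean(q3s), 1e-9)
  again <- q3_normalize(nm3$matrix)
  expect_equal(unname(again$scale_factor), rep(1, 5), tolerance = 1e-9)

  zero <- toy_matrix(4, 2, c(0, 0, 0, 0, 1, 2, 3, 4))
  expect_error(q3_normalize(zero), "r01")
})

test_that("log2(x+1) transform and its domain check", {
  expect_equal(log2_transform(c(0, 1, 7)), c(0, 1, 3))
  expect_error(log2_transform(-1), "non-negative")
})

test_that("spatial distances are within-patient Euclidean distances", {
  md <- data.frame(roi_id = c("a", "b", "c", "d"),
                   patient_id = c("p1", "p1", "p1", "p2"),
                   x_um = c(0, 3, 1, 500), y_um = c(0, 4, 1, 500),
                   segment = "tumor")
  spd <- spd_matrix(md)
  expect_equal(nrow(spd), 3)  # p2 has one ROI: no pairs
  expect_equal(spd$spd_um[spd$roi_a == "a" & spd$roi_b == "b"], 5)
  ## identical coordinates give zero distance
  md2 <- data.frame(roi_id = c("a", "b"), patient_id = "p",
                    x_um = 1, y_um = 2, segment = "t")
  expect_equal(spd_matrix(md2)$spd_um, 0)
  ## triangle inequality over a random triple
  set.seed(1)
  md3 <- data.frame(roi_id = c("a", "b", "c"), patient_id = "p",
                    x_um = runif(3, 0, 100), y_um = runif(3, 0, 100),
                    segment = "t")
  d <- spd_matrix(md3)
  dd <- setNames(d$spd_um, paste0(d$roi_a, d$roi_b))
  expect_lte(dd["ab"], dd["ac"] + dd["bc"])
  expect_lte(dd["ac"], dd["ab"] + dd["bc"])
  expect_lte(dd["bc"], dd["ab"] + dd["ac"])
})
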