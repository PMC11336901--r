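test_that("generation is deterministic for a fixed config and seed", {
  cfg <- sim_config(n_patients = 4, n_genes = 200, n_negprobes = 20, seed = 7)
  a <- simulate_dsp_experiment(cfg)
  b <- simulate_dsp_experiment(cfg)
  expect_identical(a$experiment$counts, b$experiment$counts)
  expect_identical(a$experiment$negprobes, b$experiment$negprobes)
  expect_identical(a$experiment$rois, b$experiment$rois)
  expect_identical(a$truth, b$truth)
  ## byte-for-byte after serialization
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("ROI and patient bookkeeping matches the config", {
  cfg <- sim_config(n_patients = 2, roi_count_range = c(3, 3),
                    n_genes = 250, n_negprobes = 10, seed = 3)
  sim <- simulate_dsp_experiment(cfg)
  expect_equal(ncol(sim$experiment$counts), 6)
  expect_equal(length(unique(sim$experiment$rois$patient_id)), 2)
  expect_setequal(names(sim$truth$roi_phenotype),
                  colnames(sim$experiment$counts))
})

test_that("counts are non-negative integers and coordinates stay in the disc", {
  sim <- simulate_dsp_experiment(desk_config(seed = 5))
  cts <- sim$experiment$counts
  expect_true(all(cts >= 0))
  expect_true(all(cts == round(cts)))
  expect_true(all(sim$experiment$negprobes >= 0))
  spd <- spd_matrix(sim$experiment$rois)
  cfg_extent <- desk_config(seed = 5)$coord_extent_um
  expect_true(all(spd$spd_um > 0))
  expect_true(all(spd$spd_um <= 2 * cfg_extent))
})

test_that("planted dispersion strata order the empirical per-gene log2 SDs", {
  ## strong-contrast strata: the per-gene SD inside h-ROIs should exceed
  ## the SD inside l-ROIs for nearly all genes
  cfg <- sim_config(n_patients = 30, n_genes = 500, n_negprobes = 20,
                    phenotype_dispersions = c(h = 1.0, m = 0.5, l = 0.1),
                    seed = 13)
  sim <- simulate_dsp_experiment(cfg)
  lg <- log2_transform(sim$experiment$counts)
  ph <- sim$truth$roi_phenotype[colnames(lg)]
  expect_gte(sum(ph == "h"), 10)
  expect_gte(sum(ph == "l"), 10)
  sd_h <- apply(lg[, ph == "h", drop = FALSE], 1, sd)
  sd_l <- apply(lg[, ph == "l", drop = FALSE], 1, sd)
  expect_gte(mean(sd_h > sd_l), 0.90)
})

test_that("raising a subtype program's effect never lowers its markers", {
  base <- sim_config(n_patients = 10, n_genes = 300, n_negprobes = 10,
                     subtype_effect = 1, mixing_prob = 0, seed = 21)
  boosted <- sim_config(n_patients = 10, n_genes = 300, n_negprobes = 10,
                        subtype_effect = 3, mixing_prob = 0, seed = 21)
  a <- simulate_dsp_experiment(base)
  b <- simulate_dsp_experiment(boosted)
  ## same seed => same ROI structure; compare marker means in the ROIs of
  ## the most frequent planted subtype
  top <- names(sort(table(a$truth$roi_subtype), decreasing = TRUE))[1]
  in_a <- names(a$truth$roi_subtype)[a$truth$roi_subtype == top]
  markers <- base$subtype_programs[[top]]$genes
  expect_gte(mean(b$experiment$counts[markers, in_a]),
             mean(a$experiment$counts[markers, in_a]))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(mixing_prob = 1.5), "mixing_prob")
  expect_error(sim_config(roi_count_range = c(1, 5)), "roi_count_range")
  expect_error(sim_config(hazard_ratio = -1), "hazard_ratio")
  expect_error(sim_config(phenotype_dispersions = c(h = 0.2, m = 0.5, l = 0.1)),
               "phenotype_dispersions")
})

test_that("bulk cohort is reproducible and carries the planted separation", {
  cfg <- sim_config(n_genes = 300, n_negprobes = 10, seed = 2)
  a <- simulate_bulk_cohort(cfg, 50, seed = 9)
  b <- simulate_bulk_cohort(cfg, 50, seed = 9)
  expect_identical(a$expression, b$expression)
  expect_equal(ncol(a$expression), 50)
  ## risk-direction signature genes higher in HCs-like samples, the
  ## protective half lower
  lg <- log2_transform(a$expression)
  k <- ceiling(length(cfg$signature_module) / 2)
  up <- colMeans(lg[cfg$signature_module[seq_len(k)], ])
  dn <- colMeans(lg[cfg$signature_module[-seq_len(k)], ])
  cls <- a$truth$sample_class
  expect_gt(mean(up[cls == "HCs"]), mean(up[cls == "LCs"]))
  expect_lt(mean(dn[cls == "HCs"]), mean(dn[cls == "LCs"]))
  expect_error(simulate_bulk_cohort(cfg, 1), "n_samples")
})

test_that("a null signature effect leaves group means at noise level", {
  cfg0 <- sim_config(n_genes = 200, n_negprobes = 10, signature_effect = 0)
  ps <- vapply(1:100, function(s) {
    bc <- simulate_bulk_cohort(cfg0, 200, seed = s)
    lg <- log2_transform(bc$expression)
    sig <- colMeans(lg[cfg0$signature_module, ])
    stats::t.test(sig[bc$truth$sample_class == "HCs"],
                  sig[bc$truth$sample_class == "LCs"])$p.value
  }, numeric(1))
  expect_gte(mean(ps > 0.01), 0.95)
})

test_that("exponential survival respects the planted hazard ratio", {
  cls <- setNames(rep(c("HCs", "LCs"), each = 1000),
                  sprintf("P%04d", 1:2000))
  eq <- simulate_survival(cls, hazard_ratio = 1, censor_frac = 0, seed = 4)
  m_h <- median(eq$time[grepl("HCs", cls[eq$patient_id])])
  m_l <- median(eq$time[cls[eq$patient_id] == "LCs"])
  expect_gt(m_l / m_h, 0.8); expect_lt(m_l / m_h, 1.25)

  hr3 <- simulate_survival(cls, hazard_ratio = 3, censor_frac = 0, seed = 4)
  m_h <- median(hr3$time[cls[hr3$patient_id] == "HCs"])
  m_l <- median(hr3$time[cls[hr3$patient_id] == "LCs"])
  expect_gt(m_l / m_h, 2.5); expect_lt(m_l / m_h, 3.5)

  expect_true(all(eq$event == 1))
  cens <- simulate_survival(cls, hazard_ratio = 2, censor_frac = 0.4, seed = 4)
  expect_gt(mean(cens$event == 0), 0.3); expect_lt(mean(cens$event == 0), 0.5)
  expect_error(simulate_survival(cls, hazard_ratio = 0), "hazard_ratio")
})

test_that("written fixtures round-trip through the loader exactly", {
  cfg <- sim_config(n_patients = 3, n_genes = 250, n_negprobes = 8, seed = 17)
  sim <- simulate_dsp_experiment(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  back <- load_dsp_experiment(paths$counts, paths$negprobes, paths$metadata)
  expect_identical(back$counts, sim$experiment$counts)
  expect_identical(back$negprobes, sim$experiment$negprobes)
  expect_equal(back$rois$roi_id, sim$experiment$rois$roi_id)
})
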