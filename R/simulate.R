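#' Simulation configuration for synthetic DSP experiments
#'
#' Builds the configuration object consumed by [simulate_dsp_experiment()]
#' and [simulate_bulk_cohort()]. Defaults emulate the structure of a
#' multi-region SCLC DSP study at desk scale: 25 patients contributing
#' 2-9 tumor ROIs each (median 3), a 2,000-gene panel with 100 negative
#' probes, three planted ITH variance strata (h > m > l extra log2 noise),
#' per-patient dominant transcriptional subtype programs with occasional
#' intra-patient mixing, a 50-gene NE panel split into NE-up/NE-down
#' halves, an immune module boosted in m-ITH regions, a 10-gene signature
#' separating high-complex (HCs) from low-complex (LCs) sub-TME patients,
#' and exponential survival tied to that patient class.
#'
#' The gene universe is constructed deterministically: the four subtype
#' transcription factors (ASCL1, NEUROD1, POU2F3, YAP1), dedicated
#' subtype program markers, the NE panel (`NEP01..NEP50`), the immune
#' module (`IMM01..`), the signature module (`SIG01..`), three
#' phenotype-program blocks (`PHH../PHM../PHL..`), and anonymous filler
#' genes. All planted-effect gene sets are therefore subsets of the gene
#' list by construction; user-supplied overrides are validated.
#'
#' @param n_patients number of patients.
#' @param roi_count_range integer length-2 vector, min/max ROIs per
#'   patient (counts are drawn with a long-tailed distribution whose
#'   median is 3 under the default range).
#' @param n_genes,n_negprobes panel sizes.
#' @param phenotype_dispersions named numeric `c(h=, m=, l=)`: extra
#'   per-ROI per-gene noise SD on the log2 scale; must be strictly
#'   ordered h > m > l.
#' @param phenotype_effect log2 shift applied to each stratum's dedicated
#'   phenotype-program genes (what makes the strata transcript-defined
#'   clusters with their own differentially expressed genes).
#' @param subtype_effect log2 boost of a subtype's program genes (the TF
#'   itself plus its markers) in ROIs carrying that subtype.
#' @param mixing_prob probability that an ROI deviates from its patient's
#'   dominant subtype.
#' @param subtype_probs sampling weights for the patient dominant
#'   subtype, named `c(A=, N=, P=, Y=)`.
#' @param ne_effect log2 boost of NE-up genes in NE-high ROIs and of
#'   NE-down genes in NE-low ROIs.
#' @param immune_effect log2 boost of the immune module in m-ITH ROIs.
#' @param n_immune,n_signature,n_phenotype_program module sizes.
#' @param signature_effect log2 magnitude of the signature-module shift
#'   in ROIs (or bulk samples) from HCs patients; the first half of the
#'   module goes up and the second half down in HCs tumors (real risk
#'   signatures mix risk and protective genes). Set to 0 for a null
#'   cohort.
#' @param hcs_fraction fraction of patients planted as HCs.
#' @param hazard_ratio event-hazard ratio of HCs relative to LCs
#'   patients (> 1 means HCs die faster).
#' @param censor_frac target fraction of censored patients.
#' @param baseline_median_survival median survival of the LCs class, in
#'   months.
#' @param nb_dispersion negative-binomial size parameter of the count
#'   noise (smaller = more overdispersed).
#' @param coord_extent_um radius (micrometres) of the disc around each
#'   patient's core center in which ROI centers are placed uniformly.
#' @param seed integer seed; identical configurations generate identical
#'   data.
#' @return a classed list (`sim_config`) of validated settings, including
#'   the constructed `genes` vector and the planted gene modules.
#' @export
sim_config <- function(n_patients = 25,
                       roi_count_range = c(2L, 9L),
                       n_genes = 2000,
                       n_negprobes = 100,
                       phenotype_dispersions = c(h = 0.6, m = 0.35, l = 0.15),
                       phenotype_effect = 2.5,
                       subtype_effect = 2.0,
                       mixing_prob = 0.25,
                       subtype_probs = c(A = 0.45, N = 0.30, P = 0.20, Y = 0.05),
                       ne_effect = 1.5,
                       immune_effect = 1.5,
                       n_immune = 20,
                       n_signature = 10,
                       n_phenotype_program = 30,
                       signature_effect = 2.0,
                       hcs_fraction = 0.5,
                       hazard_ratio = 3,
                       censor_frac = 0.3,
                       baseline_median_survival = 60,
                       nb_dispersion = 10,
                       coord_extent_um = 1600,
                       seed = 1L) {
  check_that(n_patients >= 1, "invalid n_patients: must be >= 1")
  check_that(length(roi_count_range) == 2 &&
               roi_count_range[1] >= 2 &&
               roi_count_range[2] >= roi_count_range[1],
             "invalid roi_count_range: need 2 <= min <= max")
  check_that(n_negprobes >= 2, "invalid n_negprobes: must be >= 2")
  check_that(identical(sort(names(phenotype_dispersions)), c("h", "l", "m")),
             "invalid phenotype_dispersions: names must be h, m, l")
  pd <- phenotype_dispersions
  check_that(pd[["h"]] > pd[["m"]] && pd[["m"]] > pd[["l"]] && pd[["l"]] >= 0,
             "invalid phenotype_dispersions: must satisfy h > m > l >= 0")
  for (f in c("mixing_prob", "hcs_fraction", "censor_frac")) {
    v <- get(f)
    check_that(is.numeric(v) && v >= 0 && v <= 1,
               "invalid %s: must be a probability in [0, 1]", f)
  }
  check_that(hazard_ratio > 0, "invalid hazard_ratio: must be > 0")
  check_that(nb_dispersion > 0, "invalid nb_dispersion: must be > 0")
  check_that(coord_extent_um > 0, "invalid coord_extent_um: must be > 0")
  check_that(all(subtype_probs >= 0) && sum(subtype_probs) > 0 &&
               identical(sort(names(subtype_probs)), c("A", "N", "P", "Y")),
             "invalid subtype_probs: need non-negative weights named A, N, P, Y")

  tfs <- c(A = "ASCL1", N = "NEUROD1", P = "POU2F3", Y = "YAP1")
  n_prog <- 5L  # extra markers per subtype program
  subtype_programs <- lapply(names(tfs), function(s) {
    list(genes = c(tfs[[s]], sprintf("%s_PRG%02d", s, seq_len(n_prog))),
         effect = subtype_effect)
  })
  names(subtype_programs) <- names(tfs)
  ne_panel <- list(up = sprintf("NEP%02d", 1:25),
                   down = sprintf("NEP%02d", 26:50))
  immune_module <- sprintf("IMM%02d", seq_len(n_immune))
  signature_module <- sprintf("SIG%02d", seq_len(n_signature))
  phenotype_programs <- list(
    h = list(genes = sprintf("PHH%02d", seq_len(n_phenotype_program)),
             effect = phenotype_effect),
    m = list(genes = sprintf("PHM%02d", seq_len(n_phenotype_program)),
             effect = phenotype_effect),
    l = list(genes = sprintf("PHL%02d", seq_len(n_phenotype_program)),
             effect = phenotype_effect))
  special <- c(unname(tfs),
               unlist(lapply(subtype_programs, function(p) p$genes[-1])),
               unlist(ne_panel), immune_module, signature_module,
               unlist(lapply(phenotype_programs, function(p) p$genes)))
  check_that(n_genes > length(special),
             "invalid n_genes: need more than %d genes to hold the planted modules",
             length(special))
  genes <- unname(c(special, sprintf("G%05d", seq_len(n_genes - length(special)))))

  structure(list(
    n_patients = as.integer(n_patients),
    roi_count_range = as.integer(roi_count_range),
    n_genes = as.integer(n_genes),
    n_negprobes = as.integer(n_negprobes),
    phenotype_dispersions = pd,
    phenotype_programs = phenotype_programs,
    subtype_programs = subtype_programs,
    subtype_tfs = tfs,
    subtype_probs = subtype_probs / sum(subtype_probs),
    mixing_prob = mixing_prob,
    ne_panel = ne_panel,
    ne_effect = ne_effect,
    immune_module = immune_module,
    immune_effect = immune_effect,
    signature_module = signature_module,
    signature_effect = signature_effect,
    hcs_fraction = hcs_fraction,
    hazard_ratio = hazard_ratio,
    censor_frac = censor_frac,
    baseline_median_survival = baseline_median_survival,
    nb_dispersion = nb_dispersion,
    coord_extent_um = coord_extent_um,
    genes = genes,
    seed = as.integer(seed)),
    class = "sim_config")
}

## up-/down-regulated halves of the signature module (up in HCs tumors
## first, down second)
signature_halves <- function(config) {
  g <- config$signature_module
  k <- ceiling(length(g) / 2)
  list(up = g[seq_len(k)], down = g[-seq_len(k)])
}

## ROI-count distribution over the configured range: long right tail with
## median 3 under the default 2..9 range
roi_count_weights <- function(range) {
  support <- seq.int(range[1], range[2])
  w <- c(0.35, 0.32, 0.12, 0.08, 0.05, 0.04, 0.025, 0.015)
  idx <- support - 1L            # support value 2 -> weight index 1
  idx[idx > length(w)] <- length(w)
  wt <- w[idx]
  list(support = support, prob = wt / sum(wt))
}

## per-gene baseline mean counts, log-normal across genes; the four
## subtype TFs share one baseline so the dominant-TF argmax rule is a
## fair comparison on the log2 scale
baseline_log2 <- function(config) {
  base <- stats::rnorm(config$n_genes, mean = log2(60), sd = 1.2)
  names(base) <- config$genes
  base[match(config$subtype_tfs, config$genes)] <- log2(60)
  base
}

#' Generate a synthetic DSP experiment with planted ground truth
#'
#' Draws negative-binomial counts around log-normal per-gene baselines.
#' Each ROI's expected expression is the baseline shifted (log2 scale,
#' hence multiplicatively on the mean) by its planted effects: the
#' stratum-specific phenotype program, the ROI subtype program, the NE
#' panel direction, the immune module in m-ITH ROIs, and the signature
#' module in ROIs of HCs patients; on top of that, per-ROI per-gene
#' Gaussian log2 noise with the stratum's dispersion SD plants the
#' h > m > l heterogeneity ordering that the DEPTH statistic should
#' recover. ROI centers are uniform in a disc of radius
#' `coord_extent_um` around a per-patient core center, so within-patient
#' distances fall in (0, 2 * coord_extent_um].
#'
#' @param config a [sim_config()].
#' @return list with `experiment` (a [DSPExperiment()]) and `truth`, a
#'   list with `roi_phenotype`, `roi_subtype`, `roi_ne_class` (named
#'   character vectors over ROIs), `patient_tme` (named over patients,
#'   `"HCs"`/`"LCs"`), and `survival` (data.frame `patient_id`, `time`,
#'   `event`).
#' @export
simulate_dsp_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    patients <- sprintf("P%02d", seq_len(config$n_patients))
    n_hcs <- round(config$hcs_fraction * config$n_patients)
    patient_tme <- stats::setNames(
      sample(c(rep("HCs", n_hcs), rep("LCs", config$n_patients - n_hcs))),
      patients)
    rw <- roi_count_weights(config$roi_count_range)
    n_rois <- if (length(rw$support) == 1) {
      rep(rw$support, config$n_patients)
    } else {
      sample(rw$support, config$n_patients, replace = TRUE, prob = rw$prob)
    }
    dominant <- stats::setNames(
      sample(names(config$subtype_probs), config$n_patients, replace = TRUE,
             prob = config$subtype_probs),
      patients)

    roi_patient <- rep(patients, n_rois)
    roi_ids <- sprintf("%s_R%d", roi_patient,
                       unlist(lapply(n_rois, seq_len)))

    ## ITH stratum per ROI: HCs patients carry at least one h-ITH ROI and
    ## may carry any stratum; LCs patients carry only m/l regions (so the
    ## any-h aggregation rule reconstructs the planted class exactly)
    roi_phenotype <- unlist(lapply(seq_along(patients), function(i) {
      k <- n_rois[i]
      if (patient_tme[i] == "HCs") {
        ph <- sample(c("h", "m", "l"), k, replace = TRUE,
                     prob = c(0.4, 0.3, 0.3))
        if (!any(ph == "h")) ph[sample.int(k, 1)] <- "h"
      } else {
        ph <- sample(c("m", "l"), k, replace = TRUE, prob = c(0.45, 0.55))
      }
      ph
    }))
    names(roi_phenotype) <- roi_ids

    ## subtype per ROI: patient-dominant program with occasional mixing
    roi_subtype <- vapply(seq_along(roi_ids), function(j) {
      dom <- dominant[[roi_patient[j]]]
      if (stats::runif(1) < config$mixing_prob) {
        sample(setdiff(c("A", "N", "P", "Y"), dom), 1)
      } else dom
    }, character(1))
    names(roi_subtype) <- roi_ids
    roi_ne_class <- ifelse(roi_subtype %in% c("A", "N"), "high", "low")
    names(roi_ne_class) <- roi_ids

    ## expected log2 expression per ROI
    base <- baseline_log2(config)
    names(base) <- config$genes
    gi <- function(ids) match(ids, config$genes)
    log2mu <- matrix(base, nrow = config$n_genes, ncol = length(roi_ids),
                     dimnames = list(config$genes, roi_ids))
    for (j in seq_along(roi_ids)) {
      ph <- roi_phenotype[[j]]
      prog <- config$phenotype_programs[[ph]]
      log2mu[gi(prog$genes), j] <- log2mu[gi(prog$genes), j] + prog$effect
      sub <- config$subtype_programs[[roi_subtype[[j]]]]
      log2mu[gi(sub$genes), j] <- log2mu[gi(sub$genes), j] + sub$effect
      ne_genes <- if (roi_ne_class[[j]] == "high") config$ne_panel$up else
        config$ne_panel$down
      log2mu[gi(ne_genes), j] <- log2mu[gi(ne_genes), j] + config$ne_effect
      if (ph == "m") {
        log2mu[gi(config$immune_module), j] <-
          log2mu[gi(config$immune_module), j] + config$immune_effect
      }
      if (patient_tme[[roi_patient[j]]] == "HCs") {
        ## bidirectional signature: first half up, second half down in
        ## HCs tumors, mirroring real heterogeneity signatures that mix
        ## risk-up and protective genes (and making within-signature
        ## rank patterns class-informative)
        sig_up <- gi(signature_halves(config)$up)
        sig_dn <- gi(signature_halves(config)$down)
        log2mu[sig_up, j] <- log2mu[sig_up, j] + config$signature_effect
        log2mu[sig_dn, j] <- log2mu[sig_dn, j] - config$signature_effect
      }
      log2mu[, j] <- log2mu[, j] +
        stats::rnorm(config$n_genes, 0,
                     config$phenotype_dispersions[[ph]])
    }

    counts <- matrix(
      stats::rnbinom(length(log2mu), mu = 2^log2mu,
                     size = config$nb_dispersion),
      nrow = config$n_genes,
      dimnames = list(config$genes, roi_ids))
    storage.mode(counts) <- "double"

    negprobes <- matrix(
      stats::rnbinom(config$n_negprobes * length(roi_ids), mu = 8,
                     size = config$nb_dispersion),
      nrow = config$n_negprobes,
      dimnames = list(sprintf("NegProbe%03d", seq_len(config$n_negprobes)),
                      roi_ids))
    storage.mode(negprobes) <- "double"

    ## coordinates: patient cores on a wide grid, ROIs uniform in a disc
    side <- ceiling(sqrt(config$n_patients))
    centers <- cbind(
      x = ((seq_len(config$n_patients) - 1) %% side) * 20 * config$coord_extent_um,
      y = ((seq_len(config$n_patients) - 1) %/% side) * 20 * config$coord_extent_um)
    r <- config$coord_extent_um * sqrt(stats::runif(length(roi_ids)))
    th <- 2 * pi * stats::runif(length(roi_ids))
    pidx <- match(roi_patient, patients)
    rois <- data.frame(
      roi_id = roi_ids,
      patient_id = roi_patient,
      x_um = centers[pidx, "x"] + r * cos(th),
      y_um = centers[pidx, "y"] + r * sin(th),
      segment = "tumor",
      stringsAsFactors = FALSE)

    survival <- simulate_survival(
      patient_tme, hazard_ratio = config$hazard_ratio,
      censor_frac = config$censor_frac,
      baseline_median = config$baseline_median_survival,
      seed = config$seed + 1L)

    list(experiment = DSPExperiment(counts, negprobes, rois),
         truth = list(roi_phenotype = roi_phenotype,
                      roi_subtype = roi_subtype,
                      roi_ne_class = roi_ne_class,
                      patient_tme = patient_tme,
                      survival = survival))
  })
}

#' Generate a synthetic bulk expression cohort
#'
#' One continuous (FPKM-like, log-normal) profile per sample, no ROI
#' structure: each sample carries a planted HCs-like or LCs-like class
#' and the same signature-module effect as the DSP generator, so a
#' signature classifier trained on either data type can be evaluated on
#' the other.
#'
#' @param config a [sim_config()]; `signature_effect` and
#'   `hcs_fraction` control the planted separation.
#' @param n_samples number of bulk samples (>= 2).
#' @param seed seed (defaults to `config$seed`).
#' @return list with `expression` (gene x sample matrix, linear FPKM-like
#'   scale) and `truth` (list with `sample_class` named vector and
#'   `survival` data.frame).
#' @export
simulate_bulk_cohort <- function(config, n_samples, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  check_that(n_samples >= 2, "n_samples must be >= 2")
  with_seed(seed, {
    ids <- sprintf("S%03d", seq_len(n_samples))
    n_hcs <- round(config$hcs_fraction * n_samples)
    cls <- stats::setNames(
      sample(c(rep("HCs", n_hcs), rep("LCs", n_samples - n_hcs))), ids)
    base <- baseline_log2(config)
    log2x <- matrix(base, nrow = config$n_genes, ncol = n_samples,
                    dimnames = list(config$genes, ids))
    halves <- signature_halves(config)
    up <- match(halves$up, config$genes)
    dn <- match(halves$down, config$genes)
    log2x[up, cls == "HCs"] <- log2x[up, cls == "HCs"] +
      config$signature_effect
    log2x[dn, cls == "HCs"] <- log2x[dn, cls == "HCs"] -
      config$signature_effect
    noise_sd <- 0.5  # sample-level biological + technical log2 noise
    log2x <- log2x + stats::rnorm(length(log2x), 0, noise_sd)
    survival <- simulate_survival(
      cls, hazard_ratio = config$hazard_ratio,
      censor_frac = config$censor_frac,
      baseline_median = config$baseline_median_survival,
      seed = seed + 1L)
    list(expression = 2^log2x,
         truth = list(sample_class = cls, survival = survival))
  })
}

#' Generate exponential survival outcomes for two planted classes
#'
#' Event times are exponential with the HCs hazard equal to
#' `hazard_ratio` times the LCs hazard (LCs median survival =
#' `baseline_median`); censoring is independent uniform on `(0, u)` with
#' `u` solved numerically so the expected censored fraction equals
#' `censor_frac`.
#'
#' @param classes named character vector, `"HCs"`/`"LCs"` per patient.
#' @param hazard_ratio positive; > 1 means HCs events occur faster.
#' @param censor_frac target censored fraction; 0 disables censoring.
#' @param baseline_median LCs median survival time (months).
#' @param seed integer seed.
#' @return data.frame with `patient_id`, `time`, `event` (1 = event
#'   observed, 0 = censored).
#' @export
simulate_survival <- function(classes, hazard_ratio, censor_frac = 0,
                              baseline_median = 60, seed = 1L) {
  check_that(hazard_ratio > 0, "hazard_ratio must be > 0")
  check_that(censor_frac >= 0 && censor_frac < 1,
             "censor_frac must be in [0, 1)")
  check_that(all(classes %in% c("HCs", "LCs")),
             "classes must be 'HCs' or 'LCs'")
  lam_l <- log(2) / baseline_median
  lam <- ifelse(classes == "HCs", hazard_ratio * lam_l, lam_l)
  with_seed(seed, {
    t_event <- stats::rexp(length(classes), rate = lam)
    if (censor_frac > 0) {
      ## P(C < T) for C ~ U(0, u), T ~ Exp(lambda): (1 - exp(-lu)) / (lu)
      pcens <- function(u) {
        mean((1 - exp(-lam * u)) / (lam * u)) - censor_frac
      }
      u <- stats::uniroot(pcens, lower = 1e-6, upper = 1e6)$root
      t_cens <- stats::runif(length(classes), 0, u)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(1L, length(classes))
      time <- t_event
    }
    data.frame(patient_id = names(classes), time = time, event = event,
               stringsAsFactors = FALSE)
  })
}

#' Reference NE/non-NE centroids matching the synthetic NE panel
#'
#' The NE centroid is high on the NE-up half of the panel and low on the
#' NE-down half; the non-NE centroid is the mirror image. Correlation
#' against these centroids is location/scale free, so the unit-contrast
#' pattern is sufficient.
#'
#' @param config a [sim_config()].
#' @return list with named numeric vectors `ne` and `non_ne` over the 50
#'   panel genes.
#' @export
simulate_ne_centroids <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- c(config$ne_panel$up, config$ne_panel$down)
  ne <- stats::setNames(c(rep(1, length(config$ne_panel$up)),
                          rep(-1, length(config$ne_panel$down))), panel)
  list(ne = ne, non_ne = -ne)
}

#' Write a simulated experiment and its ground truth to TSV files
#'
#' @param sim result of [simulate_dsp_experiment()].
#' @param dir output directory.
#' @return invisibly, the written file paths.
#' @export
write_simulation <- function(sim, dir) {
  paths <- write_dsp_experiment(sim$experiment, dir)
  tr <- sim$truth
  truth_df <- data.frame(roi_id = names(tr$roi_phenotype),
                         phenotype = unname(tr$roi_phenotype),
                         subtype = unname(tr$roi_subtype[names(tr$roi_phenotype)]),
                         ne_class = unname(tr$roi_ne_class[names(tr$roi_phenotype)]),
                         stringsAsFactors = FALSE)
  paths$truth <- file.path(dir, "ground_truth.tsv")
  utils::write.table(truth_df, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$patient_tme <- file.path(dir, "patient_tme.tsv")
  utils::write.table(
    data.frame(patient_id = names(tr$patient_tme),
               tme_class = unname(tr$patient_tme)),
    paths$patient_tme, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$survival <- file.path(dir, "survival.tsv")
  utils::write.table(tr$survival, paths$survival, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
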