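#' Bootstrap autoencoder signature-gene selection
#'
#' Ranks genes by unsupervised autoencoder importance aggregated over
#' bootstrap resamples: each iteration draws `subsample` of the samples
#' without replacement, z-scores each gene within the resample, fits a
#' tanh autoencoder (hidden layers 100/300/100, 10 epochs by default)
#' and ranks genes by importance; the final importance of a gene is its
#' mean rank across iterations (rank 1 = most important) and the
#' `n_genes` best-ranked genes form the signature. Deterministic given
#' `seed`.
#'
#' The default importance is the reconstruction-error ranking
#' ([ae_reconstruction_importance()]): genes whose variation the
#' bottleneck explains best are the ones carrying shared, class-driving
#' structure. The absolute weight-path (Garson) aggregation is available
#' via `importance = "garson"`; under a 10-epoch training budget it is
#' dominated by initialization weight mass and ranks poorly, which is
#' why it is not the default (see the methods vignette).
#'
#' @param matrix gene x sample expression matrix (log2 scale).
#' @param labels named character vector, sample -> class
#'   (`"HCs"`/`"LCs"`); both classes must be present. The labels are not
#'   used by the unsupervised ranking but are validated and recorded so
#'   the downstream classifier trains on the same cohort.
#' @param n_genes signature size (default 10).
#' @param n_bootstrap bootstrap iterations (desk default 25; set 500 to
#'   reproduce full-scale selection).
#' @param subsample fraction of samples drawn without replacement per
#'   iteration.
#' @param importance `"reconstruction"` (default) or `"garson"`.
#' @param hidden,epochs,lr autoencoder settings, see [autoencoder_fit()].
#' @param seed integer seed.
#' @return list of class `signature_model` (unfitted): `genes` (selected,
#'   best rank first), `importance` (named mean rank over all genes),
#'   `ae_config`, `seed`, `classes`.
#' @export
select_signature_genes <- function(matrix, labels, n_genes = 10,
                                   n_bootstrap = 25, subsample = 0.90,
                                   importance = c("reconstruction", "garson"),
                                   hidden = c(100, 300, 100), epochs = 10,
                                   lr = 0.5, seed = 1L) {
  importance <- match.arg(importance)
  check_expr_matrix(matrix, "matrix")
  check_that(n_genes >= 1 && n_genes <= nrow(matrix),
             "n_genes must be in [1, n_matrix_genes]")
  check_that(n_bootstrap >= 1, "n_bootstrap must be >= 1")
  check_that(subsample > 0 && subsample <= 1, "subsample must be in (0, 1]")
  cls <- labels[colnames(matrix)]
  check_that(!anyNA(cls), "sample(s) without label")
  check_that(length(unique(cls)) == 2, "labels must contain two classes")
  n <- ncol(matrix)
  x <- t(matrix)  # samples x genes
  rank_mat <- matrix(NA_real_, n_bootstrap, nrow(matrix))
  with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      idx <- sample.int(n, max(2, round(subsample * n)))
      xb <- scale(x[idx, , drop = FALSE])
      xb[, is.nan(colSums(xb))] <- 0   # genes constant in the resample
      fit <- autoencoder_fit(xb, hidden = hidden, epochs = epochs, lr = lr,
                             batch_size = 32,
                             seed = sample.int(.Machine$integer.max, 1))
      imp <- if (importance == "garson") ae_importance(fit) else
        ae_reconstruction_importance(fit, xb)
      rank_mat[b, ] <- rank(-imp, ties.method = "average")
    }
  })
  mean_rank <- stats::setNames(colMeans(rank_mat), rownames(matrix))
  ord <- order(mean_rank, rownames(matrix))
  structure(list(
    genes = rownames(matrix)[ord[seq_len(n_genes)]],
    importance = mean_rank,
    ae_config = list(hidden = hidden, activation = "tanh", epochs = epochs,
                     lr = lr, n_bootstrap = n_bootstrap,
                     subsample = subsample, importance = importance),
    classes = sort(unique(cls)),
    seed = seed),
    class = "signature_model")
}

## per-sample rank scaling of the signature-gene block: maps each
## sample's g signature values to (rank - 0.5) / g in (0, 1), making ROI
## (count-derived) and bulk (FPKM/RPKM-like) profiles commensurable
rank_scale <- function(m) {
  apply(m, 2, function(v) (rank(v, ties.method = "average") - 0.5) / length(v))
}

#' Train the ITHtyper gradient-boosted classifier
#'
#' Fits gradient-boosted trees (logistic objective; 100 rounds, maximum
#' depth 5, row and column subsampling 0.8, 5-fold cross-validation
#' recorded) on the signature genes to discriminate high-complex (HCs)
#' from low-complex (LCs) sub-TME samples. The train/test split
#' (default 70/30) is performed at the patient level so no patient
#' contributes to both sides; with `train_fraction = 1` no test split is
#' made and held-out evaluation is disabled (warning).
#'
#' @param matrix gene x sample expression matrix containing all
#'   signature genes.
#' @param labels named character vector, sample -> `"HCs"`/`"LCs"`.
#' @param model a `signature_model` from [select_signature_genes()], or
#'   a character vector of signature genes.
#' @param patients optional named character vector sample -> patient id;
#'   when given, the split is grouped by patient.
#' @param train_fraction fraction of samples (default 0.70) in the
#'   training split.
#' @param threshold score cut separating ITHtyper-hi from ITHtyper-lo
#'   (default 0.45).
#' @param harmonize `"none"` or `"rank"`: per-sample rank scaling of the
#'   signature block, applied identically at training and scoring time;
#'   use `"rank"` when the model must transfer across expression scales
#'   (ROI-trained model scoring bulk FPKM profiles).
#' @param nrounds,max_depth,subsample,colsample_bytree,nfold boosting
#'   hyperparameters.
#' @param seed integer seed.
#' @return the `signature_model` with elements `booster` (xgboost
#'   handle), `boost_config`, `threshold`, `harmonize`, `train_ids`,
#'   `test_ids`, `cv_error` (mean 5-fold CV error by round), and
#'   `positive_class` (`"HCs"`, the class scored toward 1).
#' @export
train_ithtyper <- function(matrix, labels, model, patients = NULL,
                           train_fraction = 0.70, threshold = 0.45,
                           harmonize = c("none", "rank"),
                           nrounds = 100, max_depth = 5, subsample = 0.8,
                           colsample_bytree = 0.8, nfold = 5, seed = 1L) {
  harmonize <- match.arg(harmonize)
  check_expr_matrix(matrix, "matrix")
  check_that(threshold > 0 && threshold < 1, "threshold must be in (0, 1)")
  check_that(train_fraction > 0 && train_fraction <= 1,
             "train_fraction must be in (0, 1]")
  genes <- if (inherits(model, "signature_model")) model$genes else model
  miss <- setdiff(genes, rownames(matrix))
  check_that(length(miss) == 0, "signature gene(s) missing from matrix: %s",
             paste(miss, collapse = ", "))
  cls <- labels[colnames(matrix)]
  check_that(!anyNA(cls), "sample(s) without label")
  check_that(all(cls %in% c("HCs", "LCs")),
             "labels must be 'HCs' or 'LCs'")
  feat <- matrix[genes, , drop = FALSE]
  if (harmonize == "rank") feat <- rank_scale(feat)
  y <- as.integer(cls == "HCs")

  ids <- colnames(matrix)
  with_seed(seed, {
    if (train_fraction == 1) {
      warning("train_fraction = 1: no test split, held-out evaluation disabled")
      train_ids <- ids
      test_ids <- character()
    } else if (is.null(patients)) {
      n_tr <- max(1, round(train_fraction * length(ids)))
      train_ids <- sample(ids, n_tr)
      test_ids <- setdiff(ids, train_ids)
    } else {
      pat <- patients[ids]
      check_that(!anyNA(pat), "sample(s) without patient id")
      up <- sample(unique(pat))
      csize <- cumsum(table(factor(pat, up))[up])
      n_keep <- which(csize >= train_fraction * length(ids))[1]
      train_ids <- ids[pat %in% up[seq_len(n_keep)]]
      test_ids <- setdiff(ids, train_ids)
    }
    check_that(length(unique(y[ids %in% train_ids])) == 2,
               "training split contains a single class; re-seed the split")
    if (length(test_ids) > 0) {
      check_that(length(unique(y[ids %in% test_ids])) == 2,
                 "test split contains a single class; re-seed the split")
    }
    params <- list(objective = "binary:logistic", max_depth = max_depth,
                   subsample = subsample, colsample_bytree = colsample_bytree,
                   nthread = 1, seed = seed)
    dtrain <- xgboost::xgb.DMatrix(
      t(feat[, train_ids, drop = FALSE]),
      label = y[match(train_ids, ids)])
    cv_error <- NULL
    if (nfold >= 2 && length(train_ids) >= 2 * nfold) {
      cv <- xgboost::xgb.cv(params = params, data = dtrain, nrounds = nrounds,
                            nfold = nfold, metrics = "error", verbose = 0)
      cv_error <- cv$evaluation_log$test_error_mean
    }
    booster <- xgboost::xgb.train(params = params, data = dtrain,
                                  nrounds = nrounds, verbose = 0)
  })
  out <- if (inherits(model, "signature_model")) model else
    structure(list(genes = genes), class = "signature_model")
  out$booster <- booster
  out$boost_config <- list(objective = "binary:logistic", nrounds = nrounds,
                           max_depth = max_depth, subsample = subsample,
                           colsample_bytree = colsample_bytree, nfold = nfold)
  out$threshold <- threshold
  out$harmonize <- harmonize
  out$train_fraction <- train_fraction
  out$train_ids <- train_ids
  out$test_ids <- test_ids
  out$cv_error <- cv_error
  out$positive_class <- "HCs"
  out$train_seed <- seed
  out
}

#' Score samples with a trained ITHtyper model
#'
#' Predicts the ITHtyper score in [0, 1] (probability of the
#' high-complex class) for each profile and dichotomizes at the model's
#' threshold (default 0.45): score >= threshold is `ITHtyper-hi`,
#' otherwise `ITHtyper-lo`. Profiles are harmonized exactly as at
#' training time (per-sample rank scaling of the signature block when
#' the model was trained with `harmonize = "rank"`).
#'
#' @param model a trained `signature_model` (see [train_ithtyper()]).
#' @param profiles gene x sample matrix (ROI or bulk); all signature
#'   genes must be present.
#' @return data.frame with `sample_id`, `score`, `label`.
#' @export
score_ithtyper <- function(model, profiles) {
  stopifnot(inherits(model, "signature_model"))
  check_that(!is.null(model$booster), "model has not been trained")
  check_expr_matrix(profiles, "profiles")
  miss <- setdiff(model$genes, rownames(profiles))
  check_that(length(miss) == 0, "missing signature gene(s): %s",
             paste(miss, collapse = ", "))
  feat <- profiles[model$genes, , drop = FALSE]
  if (identical(model$harmonize, "rank")) feat <- rank_scale(feat)
  score <- predict(model$booster, xgboost::xgb.DMatrix(t(feat)))
  data.frame(sample_id = colnames(profiles), score = score,
             label = ifelse(score >= model$threshold,
                            "ITHtyper-hi", "ITHtyper-lo"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC is computed as `(R1 - n1(n1+1)/2) / (n1 n2)` with midranks for
#' ties (the probability that a random positive scores above a random
#' negative, counting ties as 1/2); the curve enumerates every distinct
#' score threshold from (0,0) to (1,1).
#'
#' @param scores numeric vector of classifier scores (higher = more
#'   positive).
#' @param truth parallel vector with exactly two classes.
#' @param positive label of the positive class; defaults to `"HCs"` for
#'   HCs/LCs truth and to the alphabetically last level otherwise (so 1
#'   beats 0).
#' @return list with `auc` and `curve` (data.frame `fpr`, `tpr`,
#'   monotone from (0,0) to (1,1)).
#' @export
evaluate_roc <- function(scores, truth, positive = NULL) {
  check_that(length(scores) == length(truth),
             "scores and truth must have equal length")
  lv <- sort(unique(as.character(truth)))
  check_that(length(lv) == 2, "truth must contain exactly two classes")
  if (is.null(positive)) {
    positive <- if (setequal(lv, c("HCs", "LCs"))) "HCs" else lv[2]
  }
  check_that(positive %in% lv, "positive class '%s' not present", positive)
  pos <- as.character(truth) == positive
  n1 <- sum(pos); n2 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)))
  list(auc = auc, curve = curve)
}

#' Published ITHtyper reference signature
#'
#' The ten-gene signature reported for scoring real SCLC data
#' (PD-L1 given as its gene symbol CD274). Shipped as a reference asset
#' for applying the scoring pipeline to real cohorts; signatures learned
#' on synthetic data are independent of it.
#'
#' @return character vector of 10 gene symbols.
#' @export
ithtyper_reference_genes <- function() {
  c("NKX1-2", "TLE2", "TPBG", "GPR31", "SRSF6",
    "DAZ4", "CD274", "LYZ", "PCP4", "ZIC1")
}
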