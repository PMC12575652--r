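# End-to-end orchestration of the three pipeline stages: candidate
# filtering + MPS selection (step 1), nested risk models on a split cohort
# (step 2), and adjusted-AUC validation with paired bootstrap comparisons
# (step 3).

#' Step 1: filter the catalog, score the cohort and select the MPS
#'
#' Runs the exclusion cascade on the candidate catalog, computes and
#' standardizes the surviving PRSs on the development cohort, tunes the
#' elastic net by cross-validated confounder-adjusted AUC and assembles the
#' composite MPS.
#'
#' @param catalog list of [scoring_file()] candidates (non-CRC scores).
#' @param genotypes development-cohort [genotype_matrix()].
#' @param phenotypes matching phenotype data.frame (`individual_id`, `age`,
#'   `sex`, `platform`, `status`).
#' @param endpoint outcome for the selection fit; default
#'   `"advanced_neoplasia"` — development consortia count both CRC and
#'   advanced-adenoma diagnoses as cases.
#' @param grid optional [penalty_grid()]; default [default_penalty_grid()].
#' @param seed integer seed for CV fold assignment.
#' @param missingness_threshold cascade threshold (default 0.20).
#' @param method adjusted-AUC weight engine (default `"strata"`).
#' @param rule CV selection rule (see [cv_select()]); the pipeline defaults
#'   to `"1se"` — at study sizes where the CV curve is flat near its
#'   maximum, the one-SE rule keeps the composite from absorbing
#'   uninformative scores through fold noise.
#' @return list with `filter_report`, `scores` (standardized
#'   [score_matrix()] of kept PRSs), `fit` (the selected `penalized_fit`),
#'   `mps` (`composite_mps`) and `mps_score`.
#' @export
run_step1 <- function(catalog, genotypes, phenotypes,
                      endpoint = "advanced_neoplasia", grid = NULL,
                      seed = 1L,
                      missingness_threshold = 0.20,
                      method = c("strata", "model"), rule = "1se") {
  method <- match.arg(method)
  report <- filter_catalog(catalog, genotypes$variants$key,
                           missingness_threshold = missingness_threshold)
  if (length(report$kept) == 0L) {
    stop("run_step1 [catalog-filter]: no candidate PRS survives the cascade")
  }
  kept <- catalog[vapply(catalog, function(s) s$pgs_id %in% report$kept,
                         logical(1))]
  scores <- standardize_scores(compute_score_matrix(kept, genotypes))

  oc <- define_outcome(phenotypes, endpoint)
  scores_in <- score_matrix(as.matrix(scores)[oc$include, , drop = FALSE],
                            standardized = TRUE,
                            means = scores$means, sds = scores$sds)
  ph <- phenotypes[oc$include, , drop = FALSE]
  covariates <- cbind(age = ph$age - mean(ph$age),
                      sex = as.integer(ph$sex == "male"))
  confounders <- data.frame(age_bin = bin_age(ph$age), sex = ph$sex,
                            platform = ph$platform)
  fit <- cv_select(scores_in, covariates, oc$labels, confounders,
                   grid = grid, seed = seed, method = method, rule = rule)
  comp <- suppressWarnings(build_composite_mps(fit, scores_in))
  list(filter_report = report, scores = scores, fit = fit,
       mps = comp$mps, mps_score = comp$score)
}

# Internal: compute one standardized score column on train/validation using
# train-split moments only (leakage guard).
split_standardized_column <- function(raw, train_rows) {
  mu <- mean(raw[train_rows])
  sd_ <- stats::sd(raw[train_rows])
  if (sd_ <= 0) stop("zero-variance score on the training split")
  (raw - mu) / sd_
}

#' Steps 2 and 3: nested risk models and adjusted-AUC validation
#'
#' Splits the evaluation cohort, computes the CRC PRSs and the composite
#' MPS (standardizing every score with training-split moments only), fits
#' the six risk models on the training split, then on the validation split
#' estimates each model's confounder-adjusted AUC (bootstrap SE and 95\%
#' percentile CI) and the three paired comparisons — model 4 vs 1, 5 vs 2,
#' 6 vs 3 — with bootstrap z-tests. Each model is scored by the PRS part of
#' its linear predictor; age and sex enter through the adjusted-AUC
#' reweighting rather than the score.
#'
#' If the MPS has no components (empty selection), the MPS column is zero;
#' MPS-added models then drop the constant column and each comparison
#' degenerates to delta 0.
#'
#' @param mps a `composite_mps` from [run_step1()].
#' @param mps_catalog list of [scoring_file()]s covering the MPS components.
#' @param crc_catalog named list of two [scoring_file()]s for the CRC PRSs,
#'   names `CRC_KL200` and `CRC_LDpred`.
#' @param genotypes evaluation-cohort [genotype_matrix()].
#' @param phenotypes matching phenotype data.frame.
#' @param endpoint outcome (default `"advanced_neoplasia"`).
#' @param split_fraction training fraction (default 0.5, an equal split).
#' @param seed integer seed (split and bootstrap seeds derive from it).
#' @param n_boot bootstrap samples for SE/CI and comparisons (default 1000).
#' @param stratify_sex also fit per-sex model suites (combined AUC
#'   validation only).
#' @param method adjusted-AUC weight engine.
#' @return list with `model_fits`, `auc_table` (model, predictors, auc, se,
#'   ci), `comparisons` (the three paired `auc_comparison` results) and
#'   `split`.
#' @export
run_step2_step3 <- function(mps, mps_catalog, crc_catalog, genotypes,
                            phenotypes, endpoint = "advanced_neoplasia",
                            split_fraction = 0.5, seed = 1L, n_boot = 1000L,
                            stratify_sex = FALSE,
                            method = c("strata", "model")) {
  method <- match.arg(method)
  stopifnot(inherits(mps, "composite_mps"),
            all(c("CRC_KL200", "CRC_LDpred") %in% names(crc_catalog)))

  oc <- define_outcome(phenotypes, endpoint)
  ph <- phenotypes[oc$include, , drop = FALSE]
  labels <- oc$labels
  n <- nrow(ph)

  sp <- split_cohort(ph$individual_id, split_fraction, seed)
  train_rows <- ph$individual_id %in% sp$train

  # CRC PRSs, raw then train-moment standardization
  keep_rows <- which(oc$include)
  raw_col <- function(sf) compute_raw_prs(sf, genotypes)[keep_rows]
  kl200 <- split_standardized_column(raw_col(crc_catalog$CRC_KL200),
                                     train_rows)
  ldpred <- split_standardized_column(raw_col(crc_catalog$CRC_LDpred),
                                      train_rows)

  # MPS: component PRSs standardized with train moments, then combined and
  # itself standardized on train
  if (length(mps$components)) {
    comp_files <- mps_catalog[vapply(mps_catalog, function(s)
      s$pgs_id %in% names(mps$components), logical(1))]
    comp_raw <- vapply(comp_files, raw_col, numeric(n))
    colnames(comp_raw) <- vapply(comp_files, function(s) s$pgs_id,
                                 character(1))
    comp_std <- apply(comp_raw, 2L, split_standardized_column,
                      train_rows = train_rows)
    mps_raw <- drop(comp_std[, names(mps$components), drop = FALSE] %*%
                      mps$components)
    mps_col <- split_standardized_column(mps_raw, train_rows)
  } else {
    mps_col <- rep(0, n)
  }

  score_vals <- cbind(CRC_KL200 = kl200, CRC_LDpred = ldpred, MPS = mps_col)
  rownames(score_vals) <- ph$individual_id
  empty_mps <- length(mps$components) == 0L

  specs <- model_suite_specs()
  drop_empty <- function(pred) if (empty_mps) setdiff(pred, "MPS") else pred

  # step 2: fit the suite on the training split
  covars <- ph[train_rows, c("age", "sex"), drop = FALSE]
  model_fits <- lapply(specs, function(pred) {
    fit_risk_model(score_vals[train_rows, drop_empty(pred), drop = FALSE],
                   covars, labels[train_rows])
  })
  names(model_fits) <- names(specs)
  strat_fits <- if (stratify_sex) {
    run_model_suite(score_matrix(score_vals[train_rows, , drop = FALSE],
                                 standardized = TRUE),
                    ph[train_rows, , drop = FALSE], endpoint = endpoint,
                    stratify_sex = TRUE)
  } else NULL

  # step 3: validation-split adjusted AUC per model + paired comparisons
  val_rows <- !train_rows
  conf_val <- data.frame(age_bin = bin_age(ph$age[val_rows]),
                         sex = ph$sex[val_rows])
  model_lp <- function(model_no) {
    pred <- drop_empty(specs[[model_no]])
    beta <- model_fits[[model_no]]$coefficients[pred]
    drop(score_vals[val_rows, pred, drop = FALSE] %*% beta)
  }
  val_scores <- lapply(names(specs), model_lp)
  names(val_scores) <- names(specs)

  auc_rows <- lapply(names(specs), function(mno) {
    d <- labeled_scores(val_scores[[mno]], labels[val_rows], conf_val)
    res <- bootstrap_auc(d, method, n_boot = n_boot,
                         seed = seed + 100L + as.integer(mno))
    data.frame(model = mno,
               predictors = paste(specs[[mno]], collapse = "+"),
               auc = res$auc, se = res$se, ci_low = res$ci_low,
               ci_high = res$ci_high, stringsAsFactors = FALSE)
  })
  auc_table <- do.call(rbind, auc_rows)

  pairs <- list(c("4", "1"), c("5", "2"), c("6", "3"))
  comparisons <- lapply(pairs, function(pr) {
    dA <- labeled_scores(val_scores[[pr[2]]], labels[val_rows], conf_val)
    dB <- labeled_scores(val_scores[[pr[1]]], labels[val_rows], conf_val)
    cmp <- compare_auc_bootstrap(dA, dB, method, n_boot = n_boot,
                                 seed = seed + 200L + as.integer(pr[1]))
    cmp$comparison <- paste0("model", pr[1], "-model", pr[2])
    cmp
  })
  names(comparisons) <- vapply(comparisons, `[[`, "", "comparison")

  list(model_fits = model_fits, stratified_fits = strat_fits,
       auc_table = auc_table, comparisons = comparisons, split = sp,
       scores = score_vals, labels = labels)
}

#' Run the whole pipeline on simulated cohorts
#'
#' Simulates a case-control development set (the design of CRC GWAS
#' consortia: advanced-neoplasia cases enriched to ~48%) and a
#' population-structured evaluation cohort from one set of causal weights,
#' emits the candidate scoring files, and runs steps 1-3. The CRC PRSs
#' supplied to step 2 are built from the simulator's published (noisy) CRC
#' weights: `CRC_KL200` keeps the largest-effect fifth of the causal
#' variants (a known-loci score), `CRC_LDpred` uses all causal variants (a
#' genome-wide score).
#'
#' @param config a [simulation_config()].
#' @param grid optional [penalty_grid()] for step 1.
#' @param n_boot bootstrap samples for step 3.
#' @param crc_noiseless use the true (noise-free) CRC weights for the CRC
#'   PRSs instead of the published noisy ones.
#' @param scores_dir optional directory for the emitted scoring files
#'   (default a session temporary directory).
#' @return list with `step1` and `step23` results plus the `truth` object.
#' @export
run_pipeline <- function(config = simulation_config(), grid = NULL,
                         n_boot = 1000L, crc_noiseless = FALSE,
                         scores_dir = NULL) {
  truth <- simulate_trait_weights(config)

  dev <- simulate_case_control(config, truth)
  g_dev <- dev$genotypes
  ph_dev <- dev$phenotypes

  cfg_eval <- config
  cfg_eval$seed <- config$seed + 50000L
  g_eval <- simulate_genotypes(cfg_eval)
  ph_eval <- simulate_phenotypes(g_eval, truth, config,
                                 seed = cfg_eval$seed + 3L)

  scores_dir <- scores_dir %||% tempfile("mps_scores_")
  paths <- emit_scoring_files(truth, g_dev, scores_dir)
  trait_paths <- paths[names(paths) != "CRC"]
  catalog <- lapply(trait_paths, parse_scoring_file)

  step1 <- run_step1(catalog, g_dev, ph_dev, grid = grid,
                     seed = config$seed)

  crc_w <- if (crc_noiseless) truth$weights["CRC", ] else
    truth$published["CRC", ]
  crc_idx <- truth$causal_sets[["CRC"]]
  gv <- g_eval$variants
  mk_crc_file <- function(id, idx) {
    scoring_file(id, "colorectal cancer", data.frame(
      variant_id = paste0(gv$chr[idx], ":", gv$pos[idx]),
      chr = gv$chr[idx], pos = gv$pos[idx],
      effect_allele = gv$alt[idx], other_allele = gv$ref[idx],
      effect_weight = crc_w[idx], stringsAsFactors = FALSE))
  }
  top <- crc_idx[order(-abs(truth$weights["CRC", crc_idx]))]
  kl_idx <- sort(top[seq_len(max(1L, round(length(top) / 5)))])
  crc_catalog <- list(CRC_KL200 = mk_crc_file("CRC_KL200", kl_idx),
                      CRC_LDpred = mk_crc_file("CRC_LDpred", crc_idx))

  step23 <- run_step2_step3(step1$mps, catalog, crc_catalog, g_eval,
                            ph_eval, seed = config$seed, n_boot = n_boot)
  list(step1 = step1, step23 = step23, truth = truth)
}
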