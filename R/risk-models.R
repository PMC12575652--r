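# Outcome definitions, cohort splitting and the six nested logistic risk
# models (CRC-KL200 / CRC-LDpred / MPS combinations).

#' Endpoint specification
#'
#' `advanced_neoplasia` (the primary endpoint): cases are CRC or advanced
#' adenoma, everyone else is a control. `crc_only` (secondary): cases are
#' CRC, controls are all individuals except those with CRC or advanced
#' adenoma — advanced-adenoma records are excluded from the analysis set.
#'
#' @param name `"advanced_neoplasia"` or `"crc_only"`.
#' @return object of class `endpoint_spec` with `case_statuses`,
#'   `control_statuses`, `excluded_statuses`.
#' @export
endpoint_spec <- function(name = c("advanced_neoplasia", "crc_only")) {
  name <- match.arg(name)
  spec <- switch(name,
    advanced_neoplasia = list(case_statuses = c("crc", "advanced_adenoma"),
                              control_statuses = "control",
                              excluded_statuses = character(0)),
    crc_only = list(case_statuses = "crc",
                    control_statuses = "control",
                    excluded_statuses = "advanced_adenoma"))
  structure(c(list(name = name), spec), class = "endpoint_spec")
}

#' Derive case/control labels from phenotype records
#'
#' @param phenotypes data.frame with at least `individual_id` and `status`
#'   (one of `control`, `advanced_adenoma`, `crc`).
#' @param endpoint an [endpoint_spec()] (or its name).
#' @return list with `labels` (0/1 for the included individuals), `include`
#'   (logical mask over the input rows) and `ids` (included individual ids).
#' @export
define_outcome <- function(phenotypes, endpoint = "advanced_neoplasia") {
  if (!inherits(endpoint, "endpoint_spec")) endpoint <- endpoint_spec(endpoint)
  if (nrow(phenotypes) == 0L) {
    return(list(labels = integer(0), include = logical(0),
                ids = character(0)))
  }
  status <- as.character(phenotypes$status)
  bad <- !status %in% c("control", "advanced_adenoma", "crc")
  if (any(bad)) {
    stop("define_outcome: unknown status value(s): ",
         paste(unique(status[bad]), collapse = ", "))
  }
  include <- !status %in% endpoint$excluded_statuses
  labels <- as.integer(status[include] %in% endpoint$case_statuses)
  if (sum(labels) == 0L) {
    stop("define_outcome: no cases for endpoint '", endpoint$name, "'")
  }
  list(labels = labels, include = include,
       ids = as.character(phenotypes$individual_id)[include])
}

#' Randomly split a cohort into training and validation sets
#'
#' A seeded permutation of the ids; the first `floor(fraction * n)` go to
#' training, the rest to validation. Disjoint and exhaustive.
#'
#' @param ids vector of individual ids.
#' @param fraction training fraction in (0, 1); 0.5 mirrors the equal-size
#'   development/validation split.
#' @param seed integer seed.
#' @return list with `train` and `validation` id vectors.
#' @export
split_cohort <- function(ids, fraction = 0.5, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  perm <- with_seed(seed, sample(ids))
  n_train <- floor(fraction * length(ids))
  list(train = perm[seq_len(n_train)],
       validation = perm[setdiff(seq_along(perm), seq_len(n_train))])
}

#' Fit one logistic risk model
#'
#' Maximum-likelihood logistic regression of the outcome on standardized
#' score predictors plus covariates. Per predictor: OR = exp(beta) for a
#' 1-SD increment, Wald 95% CI = exp(beta +/- 1.96 SE), two-sided Wald p.
#'
#' @param predictors numeric matrix of standardized score columns (named).
#' @param covariates data.frame of covariates (e.g. `age`, `sex`); age is
#'   centered internally, sex coded male = 1.
#' @param labels binary outcome.
#' @return object of class `model_fit`: `estimates` data.frame (term, OR,
#'   ci_low, ci_high, p, type), `n_cases`, `n_controls`, `loglik`.
#' @export
fit_risk_model <- function(predictors, covariates, labels) {
  predictors <- as.matrix(predictors)
  labels <- as.integer(labels)
  stopifnot(nrow(predictors) == length(labels))
  if (length(unique(labels)) != 2L) {
    stop("fit_risk_model: need both classes present")
  }
  cov_df <- as.data.frame(covariates)
  if ("age" %in% names(cov_df)) {
    cov_df$age <- cov_df$age - mean(cov_df$age)
  }
  if ("sex" %in% names(cov_df) && !is.numeric(cov_df$sex)) {
    cov_df$sex <- as.integer(cov_df$sex == "male")
  }
  design <- cbind(predictors, as.matrix(cov_df))
  qr_d <- qr(cbind(1, design))
  if (qr_d$rank < ncol(design) + 1L) {
    aliased <- colnames(design)[qr_d$pivot[-seq_len(qr_d$rank)] - 1L]
    stop("fit_risk_model: rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }
  df <- data.frame(.y = labels, design, check.names = FALSE)
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)[-1L]
  terms <- gsub("`", "", terms)
  est <- data.frame(
    term = terms,
    OR = exp(sm[-1L, 1L]),
    ci_low = exp(sm[-1L, 1L] - 1.96 * sm[-1L, 2L]),
    ci_high = exp(sm[-1L, 1L] + 1.96 * sm[-1L, 2L]),
    p = sm[-1L, 4L],
    type = ifelse(terms %in% colnames(predictors), "score", "covariate"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(estimates = est,
                 n_cases = sum(labels), n_controls = sum(labels == 0L),
                 loglik = as.numeric(stats::logLik(fit)),
                 coefficients = stats::coef(fit)),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit> %d cases / %d controls\n", x$n_cases,
              x$n_controls))
  print(x$estimates, digits = 3)
  invisible(x)
}

# The six predictor sets: three CRC-PRS-only models and the three MPS-added
# counterparts compared against them (4 vs 1, 5 vs 2, 6 vs 3).
model_suite_specs <- function() {
  list(`1` = "CRC_KL200",
       `2` = "CRC_LDpred",
       `3` = c("CRC_KL200", "CRC_LDpred"),
       `4` = c("CRC_KL200", "MPS"),
       `5` = c("CRC_LDpred", "MPS"),
       `6` = c("CRC_KL200", "CRC_LDpred", "MPS"))
}

#' Fit the six-model risk suite
#'
#' Models: (1) CRC-KL200; (2) CRC-LDpred; (3) both; (4) KL200 + MPS;
#' (5) LDpred + MPS; (6) all three — each adjusted for age and sex
#' (age only within sex strata). With `stratify_sex = TRUE` the six models
#' are fitted separately per sex.
#'
#' @param scores [score_matrix()] (standardized) with columns `CRC_KL200`,
#'   `CRC_LDpred`, `MPS`.
#' @param phenotypes data.frame with `individual_id`, `age`, `sex`,
#'   `status`, aligned row-wise with `scores`.
#' @param endpoint an [endpoint_spec()] or its name.
#' @param stratify_sex fit per-sex models instead of the combined models.
#' @return list of `model_fit` objects named `"1"`..`"6"` (combined) or
#'   `"<sex>.<model>"` (stratified).
#' @export
run_model_suite <- function(scores, phenotypes,
                            endpoint = "advanced_neoplasia",
                            stratify_sex = FALSE) {
  stopifnot(inherits(scores, "score_matrix"))
  vals <- as.matrix(scores)
  needed <- c("CRC_KL200", "CRC_LDpred", "MPS")
  if (!all(needed %in% colnames(vals))) {
    stop("run_model_suite: score columns required: ",
         paste(setdiff(needed, colnames(vals)), collapse = ", "))
  }
  oc <- define_outcome(phenotypes, endpoint)
  vals <- vals[oc$include, , drop = FALSE]
  ph <- phenotypes[oc$include, , drop = FALSE]
  specs <- model_suite_specs()

  fit_block <- function(rows, covars) {
    out <- lapply(specs, function(pred) {
      fit_risk_model(vals[rows, pred, drop = FALSE],
                     ph[rows, covars, drop = FALSE],
                     oc$labels[rows])
    })
    names(out) <- names(specs)
    out
  }

  if (!stratify_sex) {
    fit_block(rep(TRUE, nrow(ph)), c("age", "sex"))
  } else {
    res <- list()
    for (sx in sort(unique(as.character(ph$sex)))) {
      rows <- ph$sex == sx
      block <- fit_block(rows, "age")
      names(block) <- paste(sx, names(block), sep = ".")
      res <- c(res, block)
    }
    res
  }
}
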