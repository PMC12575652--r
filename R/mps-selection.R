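# Elastic-net selection of non-CRC PRSs with unpenalized covariates, tuned
# by cross-validated confounder-adjusted AUC, and composite MPS assembly.

#' Define an (alpha, lambda) tuning grid
#'
#' @param alphas mixing parameters in \[0, 1\] (0 = ridge, 1 = lasso),
#'   ascending.
#' @param lambdas penalty strengths, descending.
#' @param n_folds number of CV folds (>= 2); the selection step uses 10.
#' @return object of class `penalty_grid`.
#' @export
penalty_grid <- function(alphas, lambdas, n_folds = 10L) {
  stopifnot(all(alphas >= 0), all(alphas <= 1),
            !is.unsorted(alphas, strictly = TRUE),
            all(lambdas > 0),
            !is.unsorted(rev(lambdas), strictly = TRUE),
            n_folds >= 2L)
  structure(list(alphas = alphas, lambdas = lambdas,
                 n_folds = as.integer(n_folds)),
            class = "penalty_grid")
}

#' Data-driven default tuning grid
#'
#' Alphas \{0, 0.25, 0.5, 0.75, 1\} (the ridge/elastic-net/lasso families);
#' 50 log-spaced lambdas from `lambda_max` — the smallest penalty that
#' zeroes every PRS coefficient at alpha = 1, computed from the gradient of
#' the log-likelihood at the covariate-only fit — down to `1e-4 *
#' lambda_max`.
#'
#' @param scores standardized [score_matrix()] of candidate PRSs.
#' @param covariates numeric matrix of unpenalized covariates (may have 0
#'   columns).
#' @param labels binary outcome.
#' @param n_lambda number of lambda values (default 50).
#' @param n_folds CV folds (default 10).
#' @return a [penalty_grid()].
#' @export
default_penalty_grid <- function(scores, covariates, labels,
                                 n_lambda = 50L, n_folds = 10L) {
  x <- as.matrix(scores)
  n <- nrow(x)
  covariates <- as.matrix(covariates)
  if (ncol(covariates) > 0L) {
    fit0 <- stats::glm.fit(cbind(1, covariates), labels,
                           family = stats::binomial())
    r <- labels - fit0$fitted.values
  } else {
    r <- labels - mean(labels)
  }
  lambda_max <- max(abs(crossprod(x, r))) / n
  lambdas <- exp(seq(log(lambda_max), log(1e-4 * lambda_max),
                     length.out = n_lambda))
  penalty_grid(alphas = c(0, 0.25, 0.5, 0.75, 1), lambdas = lambdas,
               n_folds = n_folds)
}

# Internal: glmnet rescales penalty.factor to sum to nvars. With c
# unpenalized covariates and K unit-penalty PRSs the PRS factors become
# (K+c)/K, so the lambda passed to glmnet is shrunk by K/(K+c) to realize
# the nominal objective (1/n)NLL + lambda*sum_PRS[a|b| + (1-a)b^2/2].
glmnet_lambda <- function(lambda, n_prs, n_cov) {
  lambda * n_prs / (n_prs + n_cov)
}

# Internal: one glmnet path fit with unpenalized covariates first.
fit_enet_path <- function(x_cov, x_prs, labels, alpha, lambdas_nominal) {
  n_cov <- ncol(x_cov)
  n_prs <- ncol(x_prs)
  x <- cbind(x_cov, x_prs)
  pf <- c(rep(0, n_cov), rep(1, n_prs))
  lam <- glmnet_lambda(lambdas_nominal, n_prs, n_cov)
  # warm-start ramp down to the requested values; keeps coordinate descent
  # accurate even when a single (possibly zero) lambda is requested
  top <- max(c(lam[lam > 0], 1)) * 10
  ramp <- exp(seq(log(top), log(top * 1e-5), length.out = 25))
  lam_fit <- sort(unique(c(ramp, lam)), decreasing = TRUE)
  fit <- glmnet::glmnet(x, labels, family = "binomial", alpha = alpha,
                        lambda = lam_fit, penalty.factor = pf,
                        standardize = FALSE, thresh = 1e-12, maxit = 1e7)
  keep <- match(lam, fit$lambda)
  if (anyNA(keep)) {
    # glmnet can drop path points; refit exactly at the missing values
    co <- stats::coef(fit, s = lam, exact = TRUE, x = x, y = labels,
                      penalty.factor = pf, standardize = FALSE,
                      thresh = 1e-12, maxit = 1e7)
  } else {
    co <- stats::coef(fit)[, keep, drop = FALSE]
  }
  list(intercept = as.numeric(co[1L, ]),
       beta_cov = as.matrix(co)[seq_len(n_cov) + 1L, , drop = FALSE],
       beta_prs = as.matrix(co)[n_cov + 1L + seq_len(n_prs), , drop = FALSE])
}

#' Penalized logistic fit with unpenalized covariates
#'
#' Minimizes
#' \deqn{\frac1n \sum_i -\ell_i(\beta) +
#'       \lambda \sum_{j \in PRS}
#'       \big[\alpha |\beta_j| + \tfrac{1-\alpha}{2} \beta_j^2\big]}
#' where the intercept and covariate coefficients carry no penalty. Fitted
#' by coordinate descent (glmnet) with the penalty-factor scaling adjusted
#' so that `lambda` is exactly the nominal per-PRS penalty of the objective
#' above.
#'
#' @param scores standardized [score_matrix()] (penalized block).
#' @param covariates numeric matrix of unpenalized covariates, with column
#'   names; may have zero columns.
#' @param labels binary outcome (both classes present).
#' @param alpha elastic-net mixing parameter in \[0, 1\].
#' @param lambda nominal penalty strength (>= 0).
#' @return object of class `penalized_fit`: `alpha`, `lambda`,
#'   `prs_coefficients` (named, standardized-predictor scale),
#'   `covariate_coefficients`, `intercept`, `cv_table` (NULL here; filled by
#'   [cv_select()]).
#' @export
fit_penalized_logistic <- function(scores, covariates, labels, alpha,
                                   lambda) {
  stopifnot(inherits(scores, "score_matrix"), isTRUE(scores$standardized),
            alpha >= 0, alpha <= 1, lambda >= 0)
  labels <- as.integer(labels)
  if (length(unique(labels)) != 2L) {
    stop("fit_penalized_logistic: need both classes in labels")
  }
  x_prs <- as.matrix(scores)
  x_cov <- as.matrix(covariates)
  if (is.null(colnames(x_cov)) && ncol(x_cov) > 0L) {
    colnames(x_cov) <- paste0("cov_", seq_len(ncol(x_cov)))
  }
  lam <- max(lambda, 1e-12 * 0)  # lambda = 0 is legal; glmnet accepts it
  path <- fit_enet_path(x_cov, x_prs, labels, alpha, lam)
  b_prs <- drop(path$beta_prs[, ncol(path$beta_prs)])
  b_cov <- drop(path$beta_cov[, ncol(path$beta_cov)])
  names(b_prs) <- colnames(x_prs)
  if (ncol(x_cov) > 0L) names(b_cov) <- colnames(x_cov)
  if (any(abs(b_prs) > 30)) {
    warning("fit_penalized_logistic: |coefficient| > 30 on standardized ",
            "scale suggests separation")
  }
  structure(list(alpha = alpha, lambda = lambda,
                 prs_coefficients = b_prs,
                 covariate_coefficients = if (ncol(x_cov)) b_cov else
                   stats::setNames(numeric(0), character(0)),
                 intercept = path$intercept[length(path$intercept)],
                 cv_table = NULL),
            class = "penalized_fit")
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat(sprintf(
    "<penalized_fit> alpha %.3g, lambda %.4g: %d/%d nonzero PRS coefficients\n",
    x$alpha, x$lambda, sum(x$prs_coefficients != 0),
    length(x$prs_coefficients)))
  invisible(x)
}

# Internal: label-stratified fold assignment by seeded shuffle.
stratified_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Tune (alpha, lambda) by cross-validated confounder-adjusted AUC
#'
#' Folds are assigned by a seeded label-stratified shuffle. For every grid
#' point the model is fitted on the held-in folds and the held-out fold is
#' scored with the PRS-only linear predictor (covariate effects are handled
#' as confounders inside the adjusted AUC, not added to the score, so the
#' metric credits the PRSs alone). The grid point maximizing the mean fold
#' adjusted AUC is selected — ties broken toward larger lambda, then larger
#' alpha (sparser models) — and the model is refitted on the full data at
#' the selected point.
#'
#' @inheritParams fit_penalized_logistic
#' @param confounders data.frame of confounders for the adjusted AUC
#'   (categorical for the `strata` engine).
#' @param grid a [penalty_grid()]; default [default_penalty_grid()].
#' @param seed integer seed for fold assignment.
#' @param method weight engine for the adjusted AUC, see
#'   [confounder_weights()].
#' @param rule `"max"` (default) selects the grid point with the highest
#'   mean fold AUC outright; `"1se"` selects the sparsest grid point
#'   (largest lambda, then largest alpha) whose mean fold AUC is within one
#'   standard error of the best — the usual parsimony rule for CV curves
#'   that are flat near their maximum, where the outright argmax is decided
#'   by fold noise and tends to keep uninformative scores.
#' @return a `penalized_fit` at the selected grid point with `cv_table`
#'   (alpha, lambda, mean_auc, sd_auc across folds) attached.
#' @export
cv_select <- function(scores, covariates, labels, confounders,
                      grid = NULL, seed = 1L,
                      method = c("strata", "model"),
                      rule = c("max", "1se")) {
  stopifnot(inherits(scores, "score_matrix"), isTRUE(scores$standardized))
  method <- match.arg(method)
  rule <- match.arg(rule)
  labels <- as.integer(labels)
  x_prs <- as.matrix(scores)
  x_cov <- as.matrix(covariates)
  if (is.null(grid)) {
    grid <- default_penalty_grid(scores, x_cov, labels)
  }
  n_folds <- grid$n_folds
  if (min(sum(labels == 1L), sum(labels == 0L)) < n_folds) {
    stop("cv_select: need at least n_folds cases and controls for ",
         "stratified folds")
  }
  fold <- stratified_folds(labels, n_folds, seed)
  n_a <- length(grid$alphas)
  n_l <- length(grid$lambdas)
  auc_arr <- array(NA_real_, dim = c(n_folds, n_a, n_l))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    ho <- !tr
    conf_ho <- confounders[ho, , drop = FALSE]
    d_ho <- NULL  # weights identical across grid points; compute once
    w_ho <- local({
      d <- labeled_scores(rep(0, sum(ho)), labels[ho], conf_ho)
      suppressWarnings(confounder_weights(d, method))
    })
    for (a in seq_len(n_a)) {
      path <- fit_enet_path(x_cov[tr, , drop = FALSE],
                            x_prs[tr, , drop = FALSE],
                            labels[tr], grid$alphas[a], grid$lambdas)
      lp <- x_prs[ho, , drop = FALSE] %*% path$beta_prs
      for (l in seq_len(n_l)) {
        auc_arr[f, a, l] <- empirical_auc(lp[, l], labels[ho], w_ho)
      }
    }
  }
  mean_auc <- apply(auc_arr, c(2, 3), mean)
  sd_auc <- apply(auc_arr, c(2, 3), stats::sd)
  cv_table <- data.frame(
    alpha = rep(grid$alphas, times = n_l),
    lambda = rep(grid$lambdas, each = n_a),
    mean_auc = as.vector(mean_auc),
    sd_auc = as.vector(sd_auc)
  )
  # argmax with ties to larger lambda then larger alpha; under "1se" the
  # tie set widens to everything within one SE of the best mean and the
  # sparsest member (fewest nonzero PRS coefficients on the full data) wins
  top <- max(cv_table$mean_auc)
  if (rule == "1se") {
    se_top <- cv_table$sd_auc[which.max(cv_table$mean_auc)] / sqrt(n_folds)
    best <- which(cv_table$mean_auc >= top - se_top)
    nnz <- matrix(NA_integer_, n_a, n_l)
    for (a in seq_len(n_a)) {
      path <- fit_enet_path(x_cov, x_prs, labels, grid$alphas[a],
                            grid$lambdas)
      nnz[a, ] <- colSums(path$beta_prs != 0)
    }
    best <- best[order(as.vector(nnz)[best], -cv_table$lambda[best],
                       -cv_table$alpha[best])][1L]
  } else {
    best <- which(cv_table$mean_auc == top)
    best <- best[order(-cv_table$lambda[best], -cv_table$alpha[best])][1L]
  }
  fit <- fit_penalized_logistic(scores, covariates, labels,
                                alpha = cv_table$alpha[best],
                                lambda = cv_table$lambda[best])
  fit$cv_table <- cv_table
  fit$cv_seed <- seed
  fit$cv_mean_auc <- cv_table$mean_auc[best]
  fit
}

#' Assemble the composite multiple polygenic score
#'
#' The MPS is the linear combination of the PRSs with nonzero refit
#' coefficients, \eqn{MPS_i = \sum_k c_k PRS_{ik}}, standardized to mean 0,
#' SD 1 with the moments recorded for reuse on new samples. When the refit
#' selects no PRS the composite is a zero vector and the returned
#' `components` are empty (flagged with a warning).
#'
#' @param fit a `penalized_fit` from [cv_select()] or
#'   [fit_penalized_logistic()].
#' @param scores [score_matrix()] containing every selected PRS column.
#' @return list with `score` (per-individual standardized MPS) and `mps`, an
#'   object of class `composite_mps` holding `components` (named nonzero
#'   coefficients), `mean` and `sd`.
#' @export
build_composite_mps <- function(fit, scores) {
  stopifnot(inherits(fit, "penalized_fit"), inherits(scores, "score_matrix"))
  comp <- fit$prs_coefficients[fit$prs_coefficients != 0]
  if (length(comp) == 0L) {
    warning("build_composite_mps: no PRS selected; composite is all zeros")
    mps <- structure(list(components = comp, mean = NA_real_, sd = NA_real_),
                     class = "composite_mps")
    return(list(score = rep(0, nrow(as.matrix(scores))), mps = mps))
  }
  missing_cols <- setdiff(names(comp), scores$score_ids)
  if (length(missing_cols)) {
    stop("build_composite_mps: score matrix lacks component column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- drop(as.matrix(scores)[, names(comp), drop = FALSE] %*% comp)
  mu <- mean(raw)
  sd_ <- stats::sd(raw)
  if (sd_ <= 0) stop("build_composite_mps: composite has zero variance")
  mps <- structure(list(components = comp, mean = mu, sd = sd_),
                   class = "composite_mps")
  list(score = (raw - mu) / sd_, mps = mps)
}

#' Apply a fitted composite MPS to new standardized scores
#'
#' @param mps a `composite_mps`.
#' @param scores [score_matrix()] standardized with the training moments.
#' @return per-individual MPS vector on the training standardization scale.
#' @export
apply_composite_mps <- function(mps, scores) {
  stopifnot(inherits(mps, "composite_mps"), inherits(scores, "score_matrix"))
  if (length(mps$components) == 0L) {
    return(rep(0, nrow(as.matrix(scores))))
  }
  missing_cols <- setdiff(names(mps$components), scores$score_ids)
  if (length(missing_cols)) {
    stop("apply_composite_mps: score matrix lacks component column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- drop(as.matrix(scores)[, names(mps$components), drop = FALSE] %*%
                mps$components)
  (raw - mps$mean) / mps$sd
}

#' @export
print.composite_mps <- function(x, ...) {
  cat(sprintf("<composite_mps> %d component PRS(s)\n", length(x$components)))
  invisible(x)
}
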