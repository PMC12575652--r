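# Penalized selection of candidate PRSs and composite MPS assembly.

make_sel_data <- function(n = 300, K = 5, beta = c(0.8, 0.5, rep(0, 3)),
                          seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * K), n, K,
              dimnames = list(NULL, paste0("PGS", seq_len(K))))
  sm <- standardize_scores(score_matrix(X))
  covar <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  eta <- drop(as.matrix(sm) %*% beta) - 0.2 * covar[, "age"] +
    0.3 * covar[, "sex"] - 1
  y <- rbinom(n, 1, plogis(eta))
  list(scores = sm, covariates = covar, labels = y)
}

test_that("infinite penalty zeroes PRSs and reproduces the covariate-only fit", {
  d <- make_sel_data()
  fit <- fit_penalized_logistic(d$scores, d$covariates, d$labels,
                                alpha = 0.75, lambda = 1e6)
  expect_true(all(fit$prs_coefficients == 0))
  ref <- glm(d$labels ~ d$covariates, family = binomial)
  expect_equal(unname(c(fit$intercept, fit$covariate_coefficients)),
               unname(coef(ref)), tolerance = 1e-6)
})

test_that("lambda = 0 matches an unpenalized fit by a generic optimizer", {
  d <- make_sel_data(n = 300, K = 5)
  fit <- fit_penalized_logistic(d$scores, d$covariates, d$labels,
                                alpha = 0.75, lambda = 0)
  par <- optim_penalized_fit(d$covariates, as.matrix(d$scores), d$labels,
                             alpha = 0.75, lambda = 0)
  got <- c(fit$intercept, fit$covariate_coefficients, fit$prs_coefficients)
  expect_equal(unname(got), par, tolerance = 1e-5)
})

test_that("ridge point matches independent objective minimization", {
  d <- make_sel_data(n = 50, K = 3, beta = c(0.6, -0.4, 0), seed = 3)
  lambda <- 0.05
  fit <- fit_penalized_logistic(d$scores, d$covariates, d$labels,
                                alpha = 0, lambda = lambda)
  par <- optim_penalized_fit(d$covariates, as.matrix(d$scores), d$labels,
                             alpha = 0, lambda = lambda)
  got <- c(fit$intercept, fit$covariate_coefficients, fit$prs_coefficients)
  expect_equal(unname(got), par, tolerance = 1e-5)

  # and the realized objective is no worse than the oracle's
  obj_fit <- penalized_objective(got, d$covariates, as.matrix(d$scores),
                                 d$labels, 0, lambda)
  obj_orc <- penalized_objective(par, d$covariates, as.matrix(d$scores),
                                 d$labels, 0, lambda)
  expect_lt(obj_fit, obj_orc + 1e-8)
})

test_that("objective at the solution beats the zero-PRS solution", {
  d <- make_sel_data()
  for (al in c(0.25, 1)) {
    fit <- fit_penalized_logistic(d$scores, d$covariates, d$labels,
                                  alpha = al, lambda = 0.02)
    sol <- c(fit$intercept, fit$covariate_coefficients,
             fit$prs_coefficients)
    ref <- glm(d$labels ~ d$covariates, family = binomial)
    zero <- c(coef(ref), rep(0, 5))
    obj <- function(p) penalized_objective(p, d$covariates,
                                           as.matrix(d$scores), d$labels,
                                           al, 0.02)
    expect_lte(obj(sol), obj(zero))
  }
})

test_that("lasso nonzero count is non-increasing in lambda", {
  d <- make_sel_data(n = 200, K = 6, beta = c(0.9, 0.6, 0.3, 0, 0, 0),
                     seed = 9)
  lambdas <- exp(seq(log(0.2), log(1e-4), length.out = 12))
  nz <- vapply(lambdas, function(l) {
    sum(fit_penalized_logistic(d$scores, d$covariates, d$labels,
                               alpha = 1, lambda = l)$prs_coefficients != 0)
  }, numeric(1))
  expect_true(all(diff(nz) >= 0))  # lambdas descend, support grows
})

test_that("single-point grid reduces cv_select to the full-data fit", {
  d <- make_sel_data(n = 240, K = 4, beta = c(0.7, 0, 0, 0), seed = 5)
  conf <- data.frame(sex = factor(d$covariates[, "sex"]))
  grid <- penalty_grid(alphas = 0.5, lambdas = 0.02, n_folds = 4)
  sel <- cv_select(d$scores, d$covariates, d$labels, conf, grid, seed = 2)
  direct <- fit_penalized_logistic(d$scores, d$covariates, d$labels,
                                   alpha = 0.5, lambda = 0.02)
  expect_equal(sel$prs_coefficients, direct$prs_coefficients)
  expect_equal(nrow(sel$cv_table), 1L)

  # bit-reproducible given the seed
  sel2 <- cv_select(d$scores, d$covariates, d$labels, conf, grid, seed = 2)
  expect_identical(sel$cv_table, sel2$cv_table)
  expect_identical(sel$prs_coefficients, sel2$prs_coefficients)
})

test_that("selected grid point maximizes mean CV AUC; null data stay near 0.5", {
  set.seed(13)
  null_aucs <- numeric(20)
  for (r in 1:20) {
    n <- 240
    X <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("PGS", 1:4)))
    sm <- standardize_scores(score_matrix(X))
    covar <- cbind(age = rnorm(n))
    y <- rbinom(n, 1, 0.3)
    conf <- data.frame(g = rep("x", n))
    grid <- penalty_grid(alphas = c(0.25, 1),
                         lambdas = exp(seq(log(0.3), log(0.003), length.out = 8)),
                         n_folds = 4)
    sel <- cv_select(sm, covar, y, conf, grid, seed = r)
    expect_gte(sel$cv_mean_auc, max(sel$cv_table$mean_auc) - 1e-12)
    null_aucs[r] <- sel$cv_mean_auc
  }
  expect_lte(mean(null_aucs), 0.55)
})

test_that("pleiotropic-trait PRSs are selected, pure-noise traits are not", {
  # simulator defaults: 3 of 10 traits share half their causal variants
  # with the CRC liability; published weights are noisy
  hit_shared <- matrix(NA, 20, 3)
  hit_noise <- matrix(NA, 20, 7)
  for (r in 1:20) {
    cfg <- simulation_config(seed = 7 + r)
    g <- simulate_genotypes(cfg)
    tw <- simulate_trait_weights(cfg)
    ph <- simulate_phenotypes(g, tw, cfg)
    prs <- t(tcrossprod(tw$published[seq_len(10), , drop = FALSE],
                        g$dosages))
    colnames(prs) <- paste0("trait_", 1:10)
    sm <- standardize_scores(score_matrix(prs))
    oc <- define_outcome(ph, "advanced_neoplasia")
    covar <- cbind(age = ph$age - mean(ph$age),
                   sex = as.integer(ph$sex == "male"))
    conf <- data.frame(ageb = bin_age(ph$age), sex = ph$sex)
    grid <- penalty_grid(alphas = c(0.5, 1),
                         lambdas = exp(seq(log(0.1), log(1e-3),
                                           length.out = 10)),
                         n_folds = 5)
    sel <- cv_select(sm, covar, oc$labels, conf, grid, seed = r)
    nz <- sel$prs_coefficients != 0
    hit_shared[r, ] <- nz[1:3]
    hit_noise[r, ] <- nz[4:10]
  }
  expect_gte(mean(hit_shared), 0.80)
  # CV-max tuning is known to overselect mildly, so pure-noise traits enter
  # some refits with small coefficients; selection must still be strongly
  # preferential
  expect_lte(mean(hit_noise), 0.50)
  expect_gt(mean(hit_shared), mean(hit_noise) + 0.3)
})

test_that("the one-SE rule prefers the sparsest near-optimal grid point", {
  d <- make_sel_data(n = 400, K = 6, beta = c(0.9, 0.7, 0, 0, 0, 0),
                     seed = 21)
  conf <- data.frame(g = rep("x", 400))
  grid <- penalty_grid(alphas = c(0, 0.5, 1),
                       lambdas = exp(seq(log(0.3), log(0.001),
                                         length.out = 10)),
                       n_folds = 5)
  sel_max <- cv_select(d$scores, d$covariates, d$labels, conf, grid,
                       seed = 3, rule = "max")
  sel_1se <- cv_select(d$scores, d$covariates, d$labels, conf, grid,
                       seed = 3, rule = "1se")
  # the 1se pick never keeps more scores than the outright argmax, stays
  # within one SE of the best mean CV AUC, and still finds the signal
  expect_lte(sum(sel_1se$prs_coefficients != 0),
             sum(sel_max$prs_coefficients != 0))
  best <- which.max(sel_max$cv_table$mean_auc)
  band <- sel_max$cv_table$mean_auc[best] -
    sel_max$cv_table$sd_auc[best] / sqrt(5)
  expect_gte(sel_1se$cv_mean_auc, band)
  expect_true(all(sel_1se$prs_coefficients[c("PGS1", "PGS2")] != 0))
})

test_that("composite MPS is the recorded linear combination, standardized", {
  d <- make_sel_data(n = 200, K = 4, beta = c(1, 0, 0, 0), seed = 8)
  fit <- fit_penalized_logistic(d$scores, d$covariates, d$labels,
                                alpha = 1, lambda = 0.05)
  comp <- build_composite_mps(fit, d$scores)
  expect_identical(comp$mps$components,
                   fit$prs_coefficients[fit$prs_coefficients != 0])
  expect_equal(mean(comp$score), 0, tolerance = 1e-12)
  expect_equal(sd(comp$score), 1, tolerance = 1e-12)

  # single component c = 1 -> MPS equals that standardized PRS
  fit1 <- fit
  fit1$prs_coefficients <- c(PGS1 = 1, PGS2 = 0, PGS3 = 0, PGS4 = 0)
  one <- build_composite_mps(fit1, d$scores)
  expect_equal(one$score, unname(as.matrix(d$scores)[, "PGS1"]),
               tolerance = 1e-12)

  # two components on a 4-individual toy table, hand-computed
  toy <- score_matrix(cbind(A = c(1, -1, 2, 0), B = c(0, 1, -1, 2)),
                      standardized = TRUE)
  fit2 <- fit
  fit2$prs_coefficients <- c(A = 0.5, B = -0.25)
  two <- build_composite_mps(fit2, toy)
  raw <- 0.5 * c(1, -1, 2, 0) - 0.25 * c(0, 1, -1, 2)
  expect_equal(two$score, (raw - mean(raw)) / sd(raw), tolerance = 1e-12)

  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  toy_p <- score_matrix(as.matrix(toy)[perm, ], standardized = TRUE)
  two_p <- build_composite_mps(fit2, toy_p)
  expect_equal(two_p$score, two$score[perm], tolerance = 1e-12)

  # missing component column errors with the pgs_id
  fit3 <- fit
  fit3$prs_coefficients <- c(NOT_THERE = 1)
  expect_error(build_composite_mps(fit3, d$scores), "NOT_THERE")
})

test_that("apply_composite_mps reuses training moments on new samples", {
  toy <- score_matrix(cbind(A = c(1, -1, 2, 0), B = c(0, 1, -1, 2)),
                      standardized = TRUE)
  fit <- structure(list(prs_coefficients = c(A = 0.5, B = -0.25)),
                   class = "penalized_fit")
  comp <- build_composite_mps(fit, toy)
  new <- score_matrix(cbind(A = c(2, 2), B = c(1, -1)), standardized = TRUE)
  got <- apply_composite_mps(comp$mps, new)
  raw_train <- 0.5 * c(1, -1, 2, 0) - 0.25 * c(0, 1, -1, 2)
  raw_new <- 0.5 * c(2, 2) - 0.25 * c(1, -1)
  expect_equal(got, (raw_new - mean(raw_train)) / sd(raw_train),
               tolerance = 1e-12)
})
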