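# Confounder-adjusted AUC: weight engines, bootstrap, paired comparison.

test_that("empirical_auc handles separation, ties and symmetry", {
  expect_equal(empirical_auc(c(2, 3, 0, 1), c(1, 1, 0, 0)), 1.0)
  # frozen from the 4-pair enumeration oracle: pairs (1>0), (1=1)/2, (0=0)/2,
  # (0<1) -> (1 + .5 + .5 + 0)/4 = 0.5
  expect_equal(auc_loop_oracle(c(1, 0, 0, 1), c(1, 1, 0, 0)), 0.5)
  expect_equal(empirical_auc(c(1, 0, 0, 1), c(1, 1, 0, 0)), 0.5)
  expect_equal(empirical_auc(rep(3, 6), rep(c(1, 0), 3)), 0.5)

  set.seed(1)
  for (i in 1:10) {
    s <- sample(0:5, 30, replace = TRUE)
    y <- rbinom(30, 1, 0.4)
    if (sum(y) %in% c(0, 30)) next
    expect_equal(empirical_auc(s, y) + empirical_auc(-s, y), 1)
  }
})

test_that("rank-based weighted AUC equals the pair-enumeration oracle", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(10:60, 1)
    s <- sample(seq(0, 2, by = 0.25), n, replace = TRUE)  # ties guaranteed
    y <- rbinom(n, 1, 0.4)
    if (sum(y) %in% c(0, n)) next
    w <- runif(sum(y), 0.1, 3)
    expect_equal(empirical_auc(s, y, w), auc_loop_oracle(s, y, w),
                 tolerance = 1e-12)
  }
})

test_that("strata weights equalize the case confounder distribution", {
  # constant confounders -> unit weights
  d <- labeled_scores(1:6, c(1, 1, 1, 0, 0, 0),
                      data.frame(g = rep("x", 6)))
  expect_equal(as.numeric(confounder_weights(d, "strata")), rep(1, 3))

  # two strata, cases 50/50, controls 80/20 -> weights 1.6 / 0.4
  strat <- c(rep("a", 5), rep("b", 5), rep("a", 8), rep("b", 2))
  y <- c(rep(1, 10), rep(0, 10))
  d2 <- labeled_scores(seq_along(y), y, data.frame(g = strat))
  w <- confounder_weights(d2, "strata")
  expect_equal(as.numeric(w), c(rep(1.6, 5), rep(0.4, 5)))
  expect_equal(mean(w), 1)

  # defining property: weighted case distribution == control distribution
  set.seed(5)
  strat3 <- sample(letters[1:3], 300, replace = TRUE)
  y3 <- rbinom(300, 1, ifelse(strat3 == "a", 0.6, 0.2))
  d3 <- labeled_scores(rnorm(300), y3, data.frame(g = strat3))
  w3 <- confounder_weights(d3, "strata")
  cases <- strat3[y3 == 1]
  for (lv in letters[1:3]) {
    expect_equal(sum(w3[cases == lv]) / sum(w3),
                 mean(strat3[y3 == 0] == lv), tolerance = 1e-12)
  }
})

test_that("cases in control-free strata get weight zero with a warning", {
  strat <- c("a", "a", "b", "a", "a")
  y <- c(1, 1, 1, 0, 0)
  d <- labeled_scores(1:5, y, data.frame(g = strat))
  expect_warning(w <- confounder_weights(d, "strata"), "no controls")
  expect_equal(attr(w, "n_dropped_cases"), 1L)
  expect_equal(w[3], 0)
})

test_that("model-based inverse-odds weights approximate strata weights", {
  set.seed(8)
  strat <- sample(c(0, 1), 500, replace = TRUE)
  y <- rbinom(500, 1, ifelse(strat == 1, 0.5, 0.2))
  d <- labeled_scores(rnorm(500), y, data.frame(g = factor(strat)))
  ws <- confounder_weights(d, "strata")
  wm <- confounder_weights(d, "model")
  # a saturated one-factor logistic model reproduces the strata ratios
  expect_equal(as.numeric(wm), as.numeric(ws), tolerance = 1e-6)
})

test_that("adjusted AUC removes confounder-driven discrimination", {
  d0 <- labeled_scores(c(3, 2, 0, 1), c(1, 1, 0, 0),
                       data.frame(g = rep("x", 4)))
  expect_equal(confounder_adjusted_auc(d0)$auc,
               empirical_auc(c(3, 2, 0, 1), c(1, 1, 0, 0)))

  # score IS the (binned) confounder: plain AUC > 0.5, adjusted ~ 0.5
  set.seed(21)
  n <- 4000
  ageb <- sample(1:5, n, replace = TRUE)
  y <- rbinom(n, 1, plogis(-2.5 + 0.5 * ageb))
  d <- labeled_scores(ageb, y, data.frame(ageb = factor(ageb)))
  plain <- empirical_auc(ageb, y)
  adj <- confounder_adjusted_auc(d, "strata")$auc
  expect_gt(plain, 0.55)
  expect_equal(adj, 0.5, tolerance = 0.02)

  # single stratum with perfect in-stratum separation -> adjusted AUC 1
  d1 <- labeled_scores(c(5, 4, 1, 2), c(1, 1, 0, 0),
                       data.frame(g = rep("s1", 4)))
  expect_equal(confounder_adjusted_auc(d1, "strata")$auc, 1.0)
})

test_that("bootstrap_auc is seed-deterministic and tightens with n", {
  set.seed(2)
  mk <- function(n) {
    s <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + s))
    labeled_scores(s, y, data.frame(sex = rbinom(n, 1, 0.5)))
  }
  d <- mk(300)
  r1 <- bootstrap_auc(d, "strata", n_boot = 150, seed = 99)
  r2 <- bootstrap_auc(d, "strata", n_boot = 150, seed = 99)
  expect_identical(r1, r2)
  expect_true(r1$ci_low <= r1$auc && r1$auc <= r1$ci_high)

  ses <- vapply(c(200, 800, 3200), function(n) {
    bootstrap_auc(mk(n), "strata", n_boot = 150, seed = 5)$se
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("bootstrap percentile CI covers the large-sample AUC at ~95%", {
  # generating model: s ~ N(0,1), logit p = -1 + s, no confounders;
  # large-sample AUC from a 2e6-draw Monte Carlo evaluation
  big_n <- 2e6
  truth <- local({
    set.seed(1234)
    s <- rnorm(big_n)
    y <- rbinom(big_n, 1, plogis(-1 + s))
    empirical_auc(s, y)
  })
  set.seed(77)
  hits <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    s <- rnorm(300)
    y <- rbinom(300, 1, plogis(-1 + s))
    if (sum(y) %in% c(0, 300)) next
    d <- labeled_scores(s, y)
    res <- bootstrap_auc(d, "strata", n_boot = 200, seed = r)
    if (res$ci_low <= truth && truth <= res$ci_high) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.90)
})

test_that("paired comparison honors its invariants", {
  set.seed(31)
  n <- 400
  s <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + s))
  conf <- data.frame(sex = factor(rbinom(n, 1, 0.5)))
  dA <- labeled_scores(s, y, conf)

  self <- compare_auc_bootstrap(dA, dA, "strata", n_boot = 100, seed = 3)
  expect_equal(self$delta, 0)
  expect_equal(self$z, 0)
  expect_equal(self$p_two_sided, 1)

  # monotone transform of the score leaves the AUC unchanged
  dB <- labeled_scores(exp(2 * s) + 5, y, conf)
  mono <- compare_auc_bootstrap(dA, dB, "strata", n_boot = 100, seed = 3)
  expect_equal(mono$delta, 0)

  # z * se = delta and p = 2(1 - Phi(|z|))
  dC <- labeled_scores(s + rnorm(n, 0, 0.5), y, conf)
  cmp <- compare_auc_bootstrap(dA, dC, "strata", n_boot = 200, seed = 9)
  expect_equal(cmp$z * cmp$se, cmp$delta, tolerance = 1e-9)
  expect_equal(cmp$p_two_sided, 2 * (1 - pnorm(abs(cmp$z))),
               tolerance = 1e-12)

  expect_error(compare_auc_bootstrap(
    dA, labeled_scores(s, rev(y), conf), "strata", 100, 1), "share")
})

test_that("bootstrap pipeline is bit-reproducible given seed and ordering", {
  set.seed(55)
  n <- 250
  s1 <- rnorm(n); s2 <- s1 + rnorm(n, 0, 0.3)
  y <- rbinom(n, 1, plogis(-1 + s1))
  conf <- data.frame(ab = factor(sample(1:3, n, TRUE)))
  a1 <- compare_auc_bootstrap(labeled_scores(s1, y, conf),
                              labeled_scores(s2, y, conf),
                              "strata", n_boot = 120, seed = 17)
  a2 <- compare_auc_bootstrap(labeled_scores(s1, y, conf),
                              labeled_scores(s2, y, conf),
                              "strata", n_boot = 120, seed = 17)
  expect_identical(a1, a2)
})
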