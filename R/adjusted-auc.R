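# Confounder-adjusted AUC by case reweighting, bootstrap SE/CI and the
# paired bootstrap z-test on AUC differences.

#' Bundle scores, case/control labels and confounders
#'
#' @param scores numeric risk score per individual.
#' @param labels binary outcome (1 = case, 0 = control); logical accepted.
#' @param confounders data.frame of per-individual confounders (e.g. binned
#'   age, sex, platform); may have zero columns for unadjusted analyses.
#' @return object of class `labeled_scores`.
#' @export
labeled_scores <- function(scores, labels,
                           confounders = data.frame(row.names =
                                                      seq_along(scores))) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            nrow(confounders) == length(scores),
            all(labels %in% c(0L, 1L)))
  if (sum(labels) == 0L || sum(labels) == length(labels)) {
    stop("labeled_scores: need at least one case and one control")
  }
  if (!all(is.finite(scores))) stop("labeled_scores: non-finite scores")
  structure(list(scores = as.numeric(scores), labels = labels,
                 confounders = confounders),
            class = "labeled_scores")
}

#' Weighted empirical AUC (Mann-Whitney)
#'
#' Computes
#' \deqn{\sum_{i \in cases} \sum_{j \in controls}
#'       w_i (1[s_i > s_j] + \tfrac12 1[s_i = s_j]) /
#'       (n_0 \sum_i w_i)}
#' via a sort-and-count algorithm (O((n0+n1) log n0)); ties contribute 1/2.
#' If all scores are identical the AUC is 0.5.
#'
#' @param scores,labels as in [labeled_scores()]; a `labeled_scores` object
#'   may be passed as `scores` with `labels` omitted.
#' @param case_weights optional nonnegative per-case weights, aligned with
#'   cases in data order; default unit weights.
#' @return scalar AUC in \[0, 1\].
#' @export
empirical_auc <- function(scores, labels = NULL, case_weights = NULL) {
  if (inherits(scores, "labeled_scores")) {
    labels <- scores$labels
    scores <- scores$scores
  }
  case <- labels == 1L
  s1 <- scores[case]
  s0 <- scores[!case]
  if (is.null(case_weights)) case_weights <- rep(1, length(s1))
  stopifnot(length(case_weights) == length(s1), all(case_weights >= 0))
  wsum <- sum(case_weights)
  if (wsum <= 0) stop("empirical_auc: case weights must have positive sum")
  s0s <- sort(s0)
  n_le <- findInterval(s1, s0s)                      # controls <= s_i
  n_lt <- findInterval(s1, s0s, left.open = TRUE)    # controls <  s_i
  contrib <- n_lt + 0.5 * (n_le - n_lt)
  sum(case_weights * contrib) / (wsum * length(s0))
}

# Internal: per-individual stratum codes from a categorical confounder frame.
stratum_codes <- function(confounders) {
  if (ncol(confounders) == 0L) return(rep(1L, nrow(confounders)))
  for (j in seq_along(confounders)) {
    col <- confounders[[j]]
    if (is.numeric(col) && length(unique(col)) > 12L) {
      stop("confounder_weights(strata): confounder '",
           names(confounders)[j],
           "' looks continuous; bin it first (see bin_age())")
    }
  }
  as.integer(interaction(confounders, drop = TRUE, lex.order = TRUE))
}

# Internal: strata weights from precomputed codes; returns per-case weights
# (data order), mean-normalized to 1. Cases in strata without controls get
# weight 0; the dropped count is returned as an attribute.
strata_weights_from_codes <- function(labels, codes) {
  case <- labels == 1L
  n1 <- sum(case)
  n0 <- sum(!case)
  k <- max(codes)
  t1 <- tabulate(codes[case], nbins = k)
  t0 <- tabulate(codes[!case], nbins = k)
  ratio <- ifelse(t1 > 0 & t0 > 0, (t0 / n0) / (t1 / n1), 0)
  w <- ratio[codes[case]]
  dropped <- sum(w == 0)
  w <- w / mean(w)
  attr(w, "n_dropped_cases") <- dropped
  w
}

#' Case weights that align the case confounder distribution with controls
#'
#' `strata` builds exact post-stratification weights
#' \eqn{w_i = \frac{P(stratum_i \mid control)}{P(stratum_i \mid case)}} over
#' the cells of the (categorical) confounder cross-classification. `model`
#' fits a main-effects logistic regression of the label on the confounders
#' and uses inverse-odds weights \eqn{w_i \propto (1-\hat p_i)/\hat p_i},
#' which allows continuous confounders. Either way weights are
#' mean-normalized to 1 over cases.
#'
#' @param data a [labeled_scores()] object.
#' @param method `"strata"` (default) or `"model"`.
#' @return nonnegative per-case weight vector (cases in data order), mean 1;
#'   attribute `n_dropped_cases` counts cases in strata with no controls
#'   (weight 0), reported with a warning.
#' @export
confounder_weights <- function(data, method = c("strata", "model")) {
  stopifnot(inherits(data, "labeled_scores"))
  method <- match.arg(method)
  conf <- data$confounders
  if (ncol(conf) == 0L) {
    w <- rep(1, sum(data$labels == 1L))
    attr(w, "n_dropped_cases") <- 0L
    return(w)
  }
  if (method == "strata") {
    codes <- stratum_codes(conf)
    w <- strata_weights_from_codes(data$labels, codes)
    if (attr(w, "n_dropped_cases") > 0) {
      warning("confounder_weights: ", attr(w, "n_dropped_cases"),
              " case(s) fall in strata with no controls and receive weight 0")
    }
    w
  } else {
    df <- data.frame(conf, .y = data$labels)
    fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
    p <- stats::fitted(fit)[data$labels == 1L]
    w <- (1 - p) / p
    w <- w / mean(w)
    attr(w, "n_dropped_cases") <- 0L
    unname_keep_attr(w)
  }
}

unname_keep_attr <- function(w) {
  a <- attributes(w)
  w <- unname(as.numeric(w))
  attr(w, "n_dropped_cases") <- a$n_dropped_cases
  w
}

#' Confounder-adjusted AUC (point estimate)
#'
#' [empirical_auc()] with [confounder_weights()]: the AUC of the score after
#' reweighting cases so their confounder distribution matches the controls',
#' so discrimination attributable to the confounders themselves is removed.
#'
#' @inheritParams confounder_weights
#' @return object of class `auc_result` with the point estimate (`se`, `ci`
#'   are `NA` until filled by [bootstrap_auc()]).
#' @export
confounder_adjusted_auc <- function(data, method = c("strata", "model")) {
  w <- confounder_weights(data, method)
  auc_result(empirical_auc(data$scores, data$labels, w))
}

auc_result <- function(auc, se = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, n_boot = 0L, n_redraws = 0L) {
  structure(list(auc = auc, se = se, ci_low = ci_low, ci_high = ci_high,
                 n_boot = as.integer(n_boot),
                 n_redraws = as.integer(n_redraws)),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("adjusted AUC %.4f", x$auc))
  if (x$n_boot > 0) {
    cat(sprintf("  (SE %.4f, 95%% CI %.4f-%.4f, %d bootstrap samples)",
                x$se, x$ci_low, x$ci_high, x$n_boot))
  }
  cat("\n")
  invisible(x)
}

# Internal fast path: evaluate the adjusted AUC for an index subset using
# precomputed stratum codes (strata method) or refitting (model method).
adjusted_auc_at <- function(scores, labels, conf, codes, method, idx) {
  s <- scores[idx]
  y <- labels[idx]
  if (method == "strata") {
    w <- suppressWarnings(strata_weights_from_codes(y, codes[idx]))
  } else {
    d <- labeled_scores(s, y, conf[idx, , drop = FALSE])
    w <- suppressWarnings(confounder_weights(d, "model"))
  }
  empirical_auc(s, y, w)
}

#' Bootstrap SE and percentile CI for the adjusted AUC
#'
#' Resamples individuals with replacement (full cohort, unstratified),
#' recomputes the adjusted AUC per replicate; `se` is the SD of replicates,
#' the CI the 2.5/97.5 percentiles. Replicates that lose either class are
#' redrawn (count recorded in `n_redraws`). Deterministic given `seed`.
#'
#' @inheritParams confounder_weights
#' @param n_boot number of bootstrap samples (>= 2); the validation analyses
#'   use 1000.
#' @param seed integer seed.
#' @return an `auc_result`.
#' @export
bootstrap_auc <- function(data, method = c("strata", "model"),
                          n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(data, "labeled_scores"), n_boot >= 2L)
  method <- match.arg(method)
  point <- confounder_adjusted_auc(data, method)$auc
  n <- length(data$scores)
  codes <- if (method == "strata") stratum_codes(data$confounders) else NULL
  reps <- numeric(n_boot)
  redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        ncase <- sum(data$labels[idx])
        if (ncase > 0L && ncase < n) break
        redraws <- redraws + 1L
      }
      reps[b] <- adjusted_auc_at(data$scores, data$labels, data$confounders,
                                 codes, method, idx)
    }
  })
  ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  auc_result(point, se = stats::sd(reps), ci_low = ci[1], ci_high = ci[2],
             n_boot = n_boot, n_redraws = redraws)
}

#' Paired bootstrap z-test on the difference of two adjusted AUCs
#'
#' Compares model B against model A on the same individuals: the point
#' difference `delta = AUC_B - AUC_A` is computed on the full data, then for
#' each bootstrap replicate the *same* resampled indices are applied to both
#' models (paired resampling, so the correlation between the two AUCs is
#' respected). `se` is the SD of replicate deltas, `z = delta / se`, and
#' `p = 2(1 - Phi(|z|))`.
#'
#' @param dataA,dataB [labeled_scores()] sharing labels and confounders and
#'   differing only in scores.
#' @inheritParams bootstrap_auc
#' @return object of class `auc_comparison`: `delta`, `se`, percentile
#'   `ci_low`/`ci_high`, `z`, `p_two_sided`, `n_boot`.
#' @export
compare_auc_bootstrap <- function(dataA, dataB,
                                  method = c("strata", "model"),
                                  n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(dataA, "labeled_scores"),
            inherits(dataB, "labeled_scores"), n_boot >= 2L)
  method <- match.arg(method)
  if (!identical(dataA$labels, dataB$labels) ||
      !identical(dataA$confounders, dataB$confounders)) {
    stop("compare_auc_bootstrap: dataA and dataB must share labels and ",
         "confounders (paired comparison)")
  }
  aucA <- confounder_adjusted_auc(dataA, method)$auc
  aucB <- confounder_adjusted_auc(dataB, method)$auc
  delta <- aucB - aucA
  n <- length(dataA$scores)
  codes <- if (method == "strata") stratum_codes(dataA$confounders) else NULL
  deltas <- numeric(n_boot)
  redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        ncase <- sum(dataA$labels[idx])
        if (ncase > 0L && ncase < n) break
        redraws <- redraws + 1L
      }
      deltas[b] <-
        adjusted_auc_at(dataB$scores, dataB$labels, dataB$confounders,
                        codes, method, idx) -
        adjusted_auc_at(dataA$scores, dataA$labels, dataA$confounders,
                        codes, method, idx)
    }
  })
  se <- stats::sd(deltas)
  if (se == 0) {
    if (delta == 0) {
      z <- 0
      p <- 1
    } else {
      warning("compare_auc_bootstrap: degenerate bootstrap (zero SE with ",
              "nonzero delta)")
      z <- sign(delta) * Inf
      p <- 0
    }
  } else {
    z <- delta / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  ci <- stats::quantile(deltas, c(0.025, 0.975), names = FALSE)
  structure(list(auc_a = aucA, auc_b = aucB, delta = delta, se = se,
                 ci_low = ci[1], ci_high = ci[2], z = z, p_two_sided = p,
                 n_boot = as.integer(n_boot), n_redraws = redraws),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf(
    "AUC difference %.4f (B %.4f - A %.4f), SE %.4f, 95%% CI %.4f-%.4f\n",
    x$delta, x$auc_b, x$auc_a, x$se, x$ci_low, x$ci_high))
  cat(sprintf("z = %.3f, two-sided p = %.4g (%d bootstrap samples)\n",
              x$z, x$p_two_sided, x$n_boot))
  invisible(x)
}

#' Bin ages by decade
#'
#' Convenience binning for the strata weight engine: ages are grouped into
#' decade-wide intervals covering \[30, 100).
#'
#' @param age numeric ages in years.
#' @return factor of decade bins.
#' @export
bin_age <- function(age) {
  cut(age, breaks = seq(30, 100, by = 10), right = FALSE,
      include.lowest = TRUE)
}
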