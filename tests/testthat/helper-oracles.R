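# Independent oracles and small fixture builders shared across tests.

# O(n1 * n0) pair-enumeration oracle for the weighted Mann-Whitney AUC.
auc_loop_oracle <- function(scores, labels, case_weights = NULL) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  if (is.null(case_weights)) case_weights <- rep(1, length(s1))
  total <- 0
  for (i in seq_along(s1)) {
    for (j in seq_along(s0)) {
      total <- total + case_weights[i] *
        ((s1[i] > s0[j]) + 0.5 * (s1[i] == s0[j]))
    }
  }
  total / (sum(case_weights) * length(s0))
}

# Explicit penalized-logistic objective: (1/n) NLL + lambda * sum over the
# PRS block of [alpha |b| + (1-alpha)/2 b^2]. params = (intercept, cov, prs).
penalized_objective <- function(params, x_cov, x_prs, y, alpha, lambda) {
  n_cov <- ncol(x_cov)
  b0 <- params[1]
  b_cov <- params[seq_len(n_cov) + 1]
  b_prs <- params[-(seq_len(n_cov + 1))]
  eta <- b0 + drop(x_cov %*% b_cov) + drop(x_prs %*% b_prs)
  nll <- mean(log1p(exp(eta)) - y * eta)
  nll + lambda * sum(alpha * abs(b_prs) + (1 - alpha) / 2 * b_prs^2)
}

# Independent minimizer of the (smooth) objective via optim; valid for
# alpha = 0 (ridge) and lambda = 0.
optim_penalized_fit <- function(x_cov, x_prs, y, alpha, lambda) {
  p <- 1 + ncol(x_cov) + ncol(x_prs)
  opt <- optim(rep(0, p), penalized_objective, x_cov = x_cov, x_prs = x_prs,
               y = y, alpha = alpha, lambda = lambda, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  opt$par
}

# Small genotype matrix with explicit dosages and A/G-style allele pairs.
toy_genotypes <- function(dosages, chr = NULL, pos = NULL,
                          ref = NULL, alt = NULL) {
  m <- ncol(dosages)
  genotype_matrix(dosages,
                  chr = chr %||% rep("1", m),
                  pos = pos %||% seq_len(m) * 100L,
                  ref = ref %||% rep("A", m),
                  alt = alt %||% rep("G", m))
}

# Scoring file over the first k variants of a toy genotype matrix, in
# as-is orientation (effect allele = alt).
toy_scoring <- function(genotypes, weights, pgs_id = "PGS_TOY",
                        trait = "toy trait") {
  gv <- genotypes$variants[seq_along(weights), , drop = FALSE]
  scoring_file(pgs_id, trait, data.frame(
    variant_id = paste0(gv$chr, ":", gv$pos),
    chr = gv$chr, pos = gv$pos,
    effect_allele = gv$alt, other_allele = gv$ref,
    effect_weight = weights, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a minimal PGS-Catalog-dialect file and return its path.
write_toy_scoring_file <- function(weights, path = tempfile(fileext = ".txt"),
                                   trait = "toy trait", pgs_id = "PGS_FILE",
                                   gz = FALSE) {
  lines <- c(paste0("#pgs_id=", pgs_id),
             paste0("#trait_reported=", trait),
             "chr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
             sprintf("1\t%d\tG\tA\t%s", seq_along(weights) * 100L, weights))
  if (gz) {
    con <- gzfile(path, "wt")
    writeLines(lines, con)
    close(con)
  } else {
    writeLines(lines, path)
  }
  path
}
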