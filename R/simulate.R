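# Liability-threshold cohort simulator with pleiotropic secondary traits,
# PGS-Catalog-dialect scoring-file emission and the catalog fixture used by
# the exclusion-cascade worked example.

#' Simulation configuration
#'
#' Defines the generating model for synthetic cohorts: Hardy-Weinberg
#' genotypes in linkage equilibrium; a colorectal-cancer liability with
#' heritability `h2_liability`, age and sex effects, and two thresholds
#' (advanced adenoma as a lower band of the same liability axis, CRC above
#' the upper threshold); `n_traits` secondary traits whose causal variant
#' sets overlap the CRC causal set by `shared_causal_fraction` (pleiotropy);
#' and noisy "published" weight versions emulating PGS-Catalog scoring
#' files.
#'
#' Defaults describe the study conditions exercised throughout: a cohort of
#' 10,000 with 1,000 variants, 10 secondary traits of which 3 share half
#' their causal variants with the CRC liability, liability-scale
#' heritability 0.25, 5\% CRC prevalence with a further 5\% advanced-adenoma
#' band, and published weights carrying noise of the same magnitude as the
#' true weights.
#'
#' @param n_individuals cohort size.
#' @param m_variants number of variants.
#' @param maf_range minor-allele-frequency range, in (0, 0.5\].
#' @param n_traits number of secondary (non-CRC) traits K.
#' @param shared_causal_fraction per-trait fraction of its causal set shared
#'   with the CRC causal set, recycled to length K.
#' @param causal_fraction fraction of variants causal for each trait.
#' @param h2_liability variance of the CRC genetic value on the liability
#'   scale, in \[0, 1\].
#' @param crc_threshold_quantile liability quantile above which status is
#'   CRC.
#' @param aa_band_quantile lower bound of the advanced-adenoma band (must be
#'   below `crc_threshold_quantile`).
#' @param age_effect,sex_effect liability-scale effects of standardized age
#'   and male sex.
#' @param weight_noise_sd SD of the additive noise on published weights,
#'   expressed as a multiple of the trait's causal-weight SD (1 = noise as
#'   large as the signal).
#' @param seed integer master seed; stage seeds are derived as
#'   `seed + 1..4` (genotypes, weights, phenotypes, emission).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 10000L,
                              m_variants = 1000L,
                              maf_range = c(0.05, 0.5),
                              n_traits = 10L,
                              shared_causal_fraction = c(rep(0.5, 3),
                                                         rep(0, 7)),
                              causal_fraction = 0.10,
                              h2_liability = 0.25,
                              crc_threshold_quantile = 0.95,
                              aa_band_quantile = 0.90,
                              age_effect = 0.5,
                              sex_effect = 0.3,
                              weight_noise_sd = 1,
                              seed = 1L) {
  shared_causal_fraction <- rep_len(shared_causal_fraction, n_traits)
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            all(shared_causal_fraction >= 0),
            all(shared_causal_fraction <= 1),
            causal_fraction > 0, causal_fraction <= 1,
            h2_liability >= 0, h2_liability <= 1,
            aa_band_quantile < crc_threshold_quantile,
            aa_band_quantile > 0, crc_threshold_quantile < 1,
            weight_noise_sd >= 0)
  structure(list(n_individuals = as.integer(n_individuals),
                 m_variants = as.integer(m_variants),
                 maf_range = maf_range,
                 n_traits = as.integer(n_traits),
                 shared_causal_fraction = shared_causal_fraction,
                 causal_fraction = causal_fraction,
                 h2_liability = h2_liability,
                 crc_threshold_quantile = crc_threshold_quantile,
                 aa_band_quantile = aa_band_quantile,
                 age_effect = age_effect, sex_effect = sex_effect,
                 weight_noise_sd = weight_noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Internal: the config's MAF draw, reproducible independently of the
# genotype matrix so weight scaling can use the exact same frequencies.
config_mafs <- function(config) {
  with_seed(config$seed + 1L, {
    runif(config$m_variants, config$maf_range[1], config$maf_range[2])
  })
}

#' Simulate Hardy-Weinberg genotypes in linkage equilibrium
#'
#' MAFs are drawn uniformly over `maf_range`; dosages are independent
#' Binomial(2, MAF) draws. Variants are laid out on chromosome 1 at 1 kb
#' spacing with alternating A/G and C/T allele pairs.
#'
#' @param config a [simulation_config()].
#' @return a [genotype_matrix()]; the MAF vector is attached as attribute
#'   `mafs`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  mafs <- config_mafs(config)
  with_seed(config$seed + 1L, {
    runif(config$m_variants)  # burn the maf draw; dosages continue the stream
    genotypes_from_mafs(config$n_individuals, mafs)
  })
}

# Internal: dosage draw at fixed MAFs from the current RNG stream; keeps
# the variant frequency distribution identical across cohorts and chunks.
genotypes_from_mafs <- function(n, mafs, id_prefix = "ind") {
  m <- length(mafs)
  d <- matrix(rbinom(n * m, 2L, rep(mafs, each = n)), nrow = n, ncol = m)
  ref <- rep(c("A", "C"), length.out = m)
  alt <- rep(c("G", "T"), length.out = m)
  g <- genotype_matrix(d, chr = rep("1", m), pos = seq_len(m) * 1000L,
                       ref = ref, alt = alt,
                       individual_ids = sprintf("%s_%05d", id_prefix,
                                                seq_len(n)))
  attr(g, "mafs") <- mafs
  g
}

#' Simulate causal weight vectors for the CRC liability and K traits
#'
#' Draws the CRC causal set (`causal_fraction` of variants) with normal
#' effect sizes scaled so the CRC genetic value has variance
#' `h2_liability` given the config's MAFs. Each secondary trait's causal set
#' shares `shared_causal_fraction[k]` of the CRC causal variants — with the
#' CRC weights reused on the shared variants — topped up with its own
#' variants scaled so every trait's genetic variance is also
#' `h2_liability`. "Published" versions of all weight vectors add
#' independent normal noise of SD `weight_noise_sd` times the trait's
#' causal-weight SD.
#'
#' @param config a [simulation_config()].
#' @return object of class `trait_weights`: `weights` ((K+1) x m matrix,
#'   rows `trait_1..K` then `CRC`), `published` (same shape, noisy, nonzero
#'   only on each trait's causal set), `causal_sets` (list of variant index
#'   vectors) and `config`.
#' @export
simulate_trait_weights <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  m <- config$m_variants
  K <- config$n_traits
  mafs <- config_mafs(config)
  var_dos <- 2 * mafs * (1 - mafs)
  n_causal <- max(1L, round(config$causal_fraction * m))

  scale_to_h2 <- function(w_idx, w_val, target) {
    if (target <= 0) return(w_val * 0)
    v <- sum(w_val^2 * var_dos[w_idx])
    if (v <= 0) return(w_val)
    w_val * sqrt(target / v)
  }

  with_seed(config$seed + 2L, {
    crc_idx <- sort(sample.int(m, n_causal))
    crc_w <- scale_to_h2(crc_idx, rnorm(n_causal), config$h2_liability)

    weights <- matrix(0, nrow = K + 1L, ncol = m,
                      dimnames = list(c(paste0("trait_", seq_len(K)), "CRC"),
                                      NULL))
    weights["CRC", crc_idx] <- crc_w
    causal_sets <- vector("list", K + 1L)
    names(causal_sets) <- rownames(weights)
    causal_sets[["CRC"]] <- crc_idx

    for (k in seq_len(K)) {
      n_shared <- round(config$shared_causal_fraction[k] * n_causal)
      shared <- if (n_shared > 0) sort(sample(crc_idx, n_shared)) else
        integer(0)
      n_own <- n_causal - n_shared
      own <- if (n_own > 0) {
        sort(sample(setdiff(seq_len(m), crc_idx), n_own))
      } else integer(0)
      w_shared <- weights["CRC", shared]
      var_shared <- sum(w_shared^2 * var_dos[shared])
      w_own <- scale_to_h2(own, rnorm(n_own),
                           max(config$h2_liability - var_shared, 0))
      row <- numeric(m)
      row[shared] <- w_shared
      row[own] <- w_own
      weights[k, ] <- row
      causal_sets[[k]] <- sort(c(shared, own))
    }

    published <- weights
    for (r in seq_len(K + 1L)) {
      idx <- causal_sets[[r]]
      w_sd <- stats::sd(weights[r, idx])
      if (!is.finite(w_sd) || w_sd == 0) w_sd <- 0
      published[r, idx] <- weights[r, idx] +
        rnorm(length(idx), 0, config$weight_noise_sd * w_sd)
    }

    structure(list(weights = weights, published = published,
                   causal_sets = causal_sets, config = config),
              class = "trait_weights")
  })
}

#' Simulate phenotypes from the liability-threshold model
#'
#' Liability = genetic value (centered weighted dosage sum) +
#' `age_effect * z(age)` + `sex_effect * male` + N(0, 1 - h2). Age is drawn
#' from N(65, 10^2) truncated to \[40, 90\]; sex is Bernoulli(0.5);
#' genotyping platform is a 3-category label. Status thresholds are the
#' theoretical normal quantiles of the liability distribution: above the
#' CRC quantile -> `crc`; between the advanced-adenoma and CRC quantiles ->
#' `advanced_adenoma`; else `control`.
#'
#' @param genotypes a [genotype_matrix()] from [simulate_genotypes()].
#' @param truth a `trait_weights` object (its `CRC` row drives liability).
#' @param config a [simulation_config()].
#' @param seed optional override of the phenotype-stage seed
#'   (default `config$seed + 3`), so several cohorts can share one truth.
#' @return data.frame (`individual_id`, `age`, `sex`, `platform`, `status`)
#'   with attributes `liability` and `genetic_value`.
#' @export
simulate_phenotypes <- function(genotypes, truth, config,
                                seed = config$seed + 3L) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(truth, "trait_weights"),
            inherits(config, "simulation_config"))
  n <- nrow(genotypes$dosages)
  mafs <- attr(genotypes, "mafs") %||% (colMeans(genotypes$dosages) / 2)
  w <- truth$weights["CRC", ]
  g <- drop(genotypes$dosages %*% w) - sum(2 * mafs * w)

  with_seed(seed, {
    p_lo <- stats::pnorm(40, 65, 10)
    p_hi <- stats::pnorm(90, 65, 10)
    age <- stats::qnorm(stats::runif(n, p_lo, p_hi), 65, 10)
    male <- stats::rbinom(n, 1L, 0.5)
    platform <- sample(c("platform_A", "platform_B", "platform_C"), n,
                       replace = TRUE)
    e <- stats::rnorm(n, 0, sqrt(1 - config$h2_liability))
    z_age <- (age - mean(age)) / stats::sd(age)
    liability <- g + config$age_effect * z_age +
      config$sex_effect * male + e

    # theoretical liability moments: Var = h2 + age^2 + sex^2/4 + (1 - h2)
    var_l <- 1 + config$age_effect^2 + config$sex_effect^2 / 4
    mean_l <- config$sex_effect * 0.5
    t_crc <- stats::qnorm(config$crc_threshold_quantile, mean_l,
                          sqrt(var_l))
    t_aa <- stats::qnorm(config$aa_band_quantile, mean_l, sqrt(var_l))
    status <- ifelse(liability > t_crc, "crc",
                     ifelse(liability > t_aa, "advanced_adenoma", "control"))

    out <- data.frame(individual_id = rownames(genotypes$dosages),
                      age = age,
                      sex = ifelse(male == 1L, "male", "female"),
                      platform = platform,
                      status = status,
                      stringsAsFactors = FALSE)
    attr(out, "liability") <- liability
    attr(out, "genetic_value") <- g
    out
  })
}

#' Write trait weights as PGS-Catalog-dialect scoring files
#'
#' One file per row of `published` weights, restricted to that trait's
#' causal set. A `missingness` fraction of each file's variants is rewritten
#' to positions absent from the genotype index (shifted beyond the simulated
#' region), injecting controlled scoring-file missingness.
#'
#' @param truth a `trait_weights` object.
#' @param genotypes the matching [genotype_matrix()].
#' @param out_dir output directory (created if needed).
#' @param missingness per-file missing fraction in \[0, 1), recycled across
#'   files.
#' @param seed seed for choosing which variants go missing (default
#'   `config$seed + 4`).
#' @return named character vector of file paths.
#' @export
emit_scoring_files <- function(truth, genotypes, out_dir, missingness = 0,
                               seed = truth$config$seed + 4L) {
  stopifnot(inherits(truth, "trait_weights"),
            inherits(genotypes, "genotype_matrix"),
            all(missingness >= 0), all(missingness < 1))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- rownames(truth$published)
  missingness <- rep_len(missingness, length(rows))
  gv <- genotypes$variants
  max_pos <- max(gv$pos)
  paths <- character(length(rows))
  names(paths) <- rows
  with_seed(seed, {
    for (r in seq_along(rows)) {
      trait <- rows[r]
      idx <- truth$causal_sets[[trait]]
      w <- truth$published[trait, idx]
      pos <- gv$pos[idx]
      n_miss <- round(missingness[r] * length(idx))
      if (n_miss > 0) {
        gone <- sample(seq_along(idx), n_miss)
        pos[gone] <- max_pos + gv$pos[idx[gone]]  # outside the region
      }
      tab <- data.frame(chr_name = gv$chr[idx],
                        chr_position = pos,
                        effect_allele = gv$alt[idx],
                        other_allele = gv$ref[idx],
                        effect_weight = sprintf("%.17g", w))
      path <- file.path(out_dir, paste0(trait, ".txt"))
      con <- file(path, "wt")
      writeLines(c(paste0("#pgs_id=", trait),
                   paste0("#trait_reported=", trait)), con)
      utils::write.table(tab, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      close(con)
      paths[r] <- path
    }
  })
  paths
}

#' Simulate a case-control study from the liability model
#'
#' Case-control designs (like CRC GWAS consortia) enrich cases far beyond
#' their population frequency. This sampler draws population chunks from
#' the generating model and retains advanced-neoplasia cases (CRC or
#' advanced adenoma) and controls until the requested design is filled:
#' `n_individuals` total at `case_fraction` cases.
#'
#' @param config a [simulation_config()]; `n_individuals` is the size of
#'   the returned case-control set, not of the underlying population.
#' @param truth a `trait_weights` object shared with other cohorts.
#' @param case_fraction fraction of cases in the assembled set (default
#'   0.48, a typical consortium balance).
#' @param seed base seed for the population chunks (default
#'   `config$seed + 10000`).
#' @return list with `genotypes` (a [genotype_matrix()]) and `phenotypes`,
#'   rows aligned.
#' @export
simulate_case_control <- function(config, truth, case_fraction = 0.48,
                                  seed = config$seed + 10000L) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(truth, "trait_weights"),
            case_fraction > 0, case_fraction < 1)
  n_cases <- round(case_fraction * config$n_individuals)
  n_controls <- config$n_individuals - n_cases
  mafs <- config_mafs(config)  # one MAF draw shared by every chunk
  kept_chunks <- list()
  n_case_have <- 0L
  n_ctrl_have <- 0L
  chunk <- 0L
  while (n_case_have < n_cases || n_ctrl_have < n_controls) {
    chunk <- chunk + 1L
    if (chunk > 50L) stop("simulate_case_control: case yield too low")
    chunk_seed <- seed + 100L * chunk
    g <- with_seed(chunk_seed,
                   genotypes_from_mafs(config$n_individuals, mafs,
                                       id_prefix = paste0("cc", chunk)))
    ph <- simulate_phenotypes(g, truth, config, seed = chunk_seed + 3L)
    is_case <- ph$status %in% c("crc", "advanced_adenoma")
    take_case <- which(is_case)[seq_len(min(sum(is_case),
                                            n_cases - n_case_have))]
    take_ctrl <- which(!is_case)[seq_len(min(sum(!is_case),
                                             n_controls - n_ctrl_have))]
    keep <- sort(c(take_case, take_ctrl))
    if (length(keep)) {
      kept_chunks[[chunk]] <- list(d = g$dosages[keep, , drop = FALSE],
                                   ph = ph[keep, , drop = FALSE])
      n_case_have <- n_case_have + length(take_case)
      n_ctrl_have <- n_ctrl_have + length(take_ctrl)
    }
    if (chunk == 1L) variants <- g$variants
  }
  dos <- do.call(rbind, lapply(kept_chunks, `[[`, "d"))
  ph_all <- do.call(rbind, lapply(kept_chunks, `[[`, "ph"))
  rownames(ph_all) <- NULL
  gm <- genotype_matrix(dos, chr = variants$chr, pos = variants$pos,
                        ref = variants$ref, alt = variants$alt,
                        individual_ids = ph_all$individual_id)
  attr(gm, "mafs") <- mafs
  list(genotypes = gm, phenotypes = ph_all)
}

# Trait labels drawn for kept fixture entries; includes CRC precursor
# lesions, which the cascade must retain.
fixture_kept_traits <- c(
  "type 2 diabetes", "body mass index", "coronary artery disease",
  "benign neoplasm of colon", "rectal polyps",
  "benign neoplasm of digestive system", "educational attainment",
  "hemorrhoids", "breast cancer", "prostate cancer", "height",
  "inflammatory bowel disease", "smoking status", "LDL cholesterol")

#' Deterministic 2,724-entry catalog fixture for the exclusion cascade
#'
#' Builds a candidate catalog with mutually exclusive strata mirroring the
#' documented cascade counts: 9 entries with zero overlap with the genotype
#' index; 485 with overlap in \[0.5, 0.8) (high missingness); 40 labeled
#' with CRC / colon-cancer / rectal-cancer traits at full overlap; 3 labeled
#' gastrointestinal-cancer or rectal/anal-cancer traits at full overlap; and
#' 2,187 passing entries with overlap in (0.8, 1.0\]. Each entry carries 10
#' variants; roughly half the matched variants are written in swapped allele
#' orientation to exercise orientation-free matching.
#'
#' With `overlapping_strata = TRUE` the CRC-trait entries are instead given
#' overlap 0.5, so they qualify for both the missingness and the trait
#' exclusion — a fixture for verifying the first-applicable-reason rule.
#'
#' @param seed integer seed (the packaged fixture uses 42).
#' @param overlapping_strata build the cascade-order variant instead.
#' @return list with `catalog` (list of [scoring_file()]), `variant_index`
#'   (canonical keys of the genotype index) and `expected` (kept count and
#'   per-reason counts implied by the construction).
#' @export
make_catalog_fixture <- function(seed = 42L, overlapping_strata = FALSE) {
  n_per <- 10L  # variants per scoring file
  strata <- c(kept = 2187L, high_missingness = 485L, no_overlap = 9L,
              crc_trait = 40L, broad_crc_trait = 3L)
  n_total <- sum(strata)

  with_seed(seed, {
    # genotype-index universe: 600 indexed variants + disjoint decoys
    n_idx <- 600L
    idx_df <- data.frame(
      chr = as.character(sample(1:22, n_idx, replace = TRUE)),
      pos = seq_len(n_idx) * 37L + 11L,
      a1 = rep(c("A", "C"), length.out = n_idx),
      a2 = rep(c("G", "T"), length.out = n_idx))
    variant_index <- variant_key(idx_df$chr, idx_df$pos, idx_df$a1,
                                 idx_df$a2)

    stratum <- sample(rep(names(strata), times = strata))
    ids <- sprintf("PGS%06d", seq_len(n_total))

    n_match_of <- function(st) {
      switch(st,
             kept = sample(9:10, 1L),
             high_missingness = if (overlapping_strata) 5L else
               sample(5:7, 1L),
             no_overlap = 0L,
             crc_trait = if (overlapping_strata) 5L else 10L,
             broad_crc_trait = 10L)
    }
    trait_of <- function(st) {
      switch(st,
             kept = sample(fixture_kept_traits, 1L),
             high_missingness = sample(fixture_kept_traits, 1L),
             no_overlap = sample(fixture_kept_traits, 1L),
             crc_trait = sample(c("colorectal cancer", "colon cancer",
                                  "rectal cancer"), 1L),
             broad_crc_trait = sample(c("gastrointestinal cancer",
                                        "rectal/anal cancer"), 1L))
    }

    catalog <- vector("list", n_total)
    decoy_pos <- 1e7L
    for (i in seq_len(n_total)) {
      st <- stratum[i]
      n_match <- n_match_of(st)
      take <- if (n_match > 0) sample.int(n_idx, n_match) else integer(0)
      swap <- sample(c(TRUE, FALSE), n_match, replace = TRUE)
      eff <- ifelse(swap, idx_df$a1[take], idx_df$a2[take])
      oth <- ifelse(swap, idx_df$a2[take], idx_df$a1[take])
      n_off <- n_per - n_match
      off_pos <- decoy_pos + seq_len(n_off)
      decoy_pos <- decoy_pos + n_off
      variants <- data.frame(
        chr = c(idx_df$chr[take], rep("1", n_off)),
        pos = c(idx_df$pos[take], off_pos),
        effect_allele = c(eff, rep("A", n_off)),
        other_allele = c(oth, rep("G", n_off)),
        effect_weight = round(stats::rnorm(n_per, 0, 0.05), 6),
        stringsAsFactors = FALSE)
      variants$variant_id <- paste0(variants$chr, ":", variants$pos)
      catalog[[i]] <- scoring_file(ids[i], trait_of(st), variants)
    }

    expected_reasons <- strata[c("no_overlap", "high_missingness",
                                 "crc_trait", "broad_crc_trait")]
    if (overlapping_strata) {
      # CRC-trait entries now fail the missingness stage first
      expected_reasons["high_missingness"] <-
        expected_reasons["high_missingness"] + expected_reasons["crc_trait"]
      expected_reasons["crc_trait"] <- 0L
    }
    list(catalog = catalog, variant_index = variant_index,
         expected = list(kept = unname(strata["kept"]),
                         reasons = expected_reasons))
  })
}
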