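# Allele-aware scoring: matching, weighted sums, standardization.

test_that("match_variants resolves orientation and rejects allele mismatches", {
  g <- toy_genotypes(matrix(c(0, 1, 2), 3, 3),
                     ref = c("A", "A", "A"), alt = c("G", "G", "G"))
  v <- data.frame(variant_id = paste0("1:", c(100L, 200L, 300L)),
                  chr = "1", pos = c(100L, 200L, 300L),
                  effect_allele = c("G", "A", "T"),
                  other_allele = c("A", "G", "C"),
                  effect_weight = c(0.5, 0.5, 0.5))
  mm <- match_variants(scoring_file("S", "t", v), g)
  expect_equal(nrow(mm), 2L)
  expect_equal(mm$orientation, c("as_is", "swapped"))
  expect_equal(attr(mm, "n_unmatched"), 1L)
})

test_that("strand-ambiguous pairs can be dropped on request", {
  g <- toy_genotypes(matrix(1, 2, 2), ref = c("A", "C"), alt = c("T", "G"))
  v <- data.frame(variant_id = paste0("1:", c(100L, 200L)),
                  chr = "1", pos = c(100L, 200L),
                  effect_allele = c("T", "G"), other_allele = c("A", "C"),
                  effect_weight = c(0.5, 0.5))
  sf <- scoring_file("AMB", "t", v)
  expect_equal(nrow(match_variants(sf, g)), 2L)
  mm <- match_variants(sf, g, drop_ambiguous = TRUE)
  expect_equal(nrow(mm), 0L)
  expect_equal(attr(mm, "n_unmatched"), 2L)
})

test_that("compute_raw_prs applies orientation algebra", {
  g <- toy_genotypes(matrix(2, 1, 1))
  sf_as_is <- toy_scoring(g, 0.5)
  expect_equal(as.numeric(compute_raw_prs(sf_as_is, g)), 1.0)

  v <- sf_as_is$variants
  v$effect_allele <- "A"  # effect allele now the ref -> swapped
  v$other_allele <- "G"
  sf_sw <- scoring_file("SW", "t", v)
  expect_equal(as.numeric(compute_raw_prs(sf_sw, g)), 0.0)
})

test_that("compute_raw_prs equals an elementwise loop oracle", {
  set.seed(42)
  n <- 20; m <- 10
  d <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  g <- toy_genotypes(d)
  w <- rnorm(m)
  swap <- sample(c(TRUE, FALSE), m, replace = TRUE)
  v <- data.frame(variant_id = paste0("1:", seq_len(m) * 100L),
                  chr = "1", pos = seq_len(m) * 100L,
                  effect_allele = ifelse(swap, "A", "G"),
                  other_allele = ifelse(swap, "G", "A"),
                  effect_weight = w)
  sf <- scoring_file("RND", "t", v)
  score <- compute_raw_prs(sf, g)
  oracle <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      dose <- if (swap[j]) 2 - d[i, j] else d[i, j]
      oracle[i] <- oracle[i] + w[j] * dose
    }
  }
  expect_equal(as.numeric(score), oracle, tolerance = 1e-12)
})

test_that("zero matched variants directs the caller to filter_catalog", {
  g <- toy_genotypes(matrix(0, 2, 2))
  v <- data.frame(variant_id = "9:9", chr = "9", pos = 9L,
                  effect_allele = "G", other_allele = "A",
                  effect_weight = 1)
  expect_error(compute_raw_prs(scoring_file("NOPE", "t", v), g),
               "filter_catalog")
})

test_that("missing dosages are mean-imputed per variant", {
  d <- matrix(c(0, 2, NA, 1, 1, 1), 3, 2)
  g <- toy_genotypes(d)
  sf <- toy_scoring(g, c(1, 1))
  sc <- compute_raw_prs(sf, g)
  expect_equal(as.numeric(sc), c(0 + 1, 2 + 1, 1 + 1))  # NA -> mean(0,2) = 1

  # with no missing entries, imputation is a no-op
  d2 <- matrix(c(0, 2, 2, 1, 1, 1), 3, 2)
  g2 <- toy_genotypes(d2)
  expect_equal(as.numeric(compute_raw_prs(sf, g2)), c(1, 3, 3))
})

test_that("scores are linear in weights and orientation-flip invariant", {
  set.seed(11)
  for (rep_i in 1:5) {
    n <- 15; m <- 8
    d <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    g <- toy_genotypes(d)
    w1 <- rnorm(m); w2 <- rnorm(m)
    s1 <- compute_raw_prs(toy_scoring(g, w1), g)
    s2 <- compute_raw_prs(toy_scoring(g, w2), g)
    s12 <- compute_raw_prs(toy_scoring(g, w1 + w2), g)
    expect_equal(s12, s1 + s2, tolerance = 1e-12, ignore_attr = TRUE)

    # flip the stored orientation of every variant: ref<->alt, d -> 2 - d
    g_flip <- genotype_matrix(2 - d, chr = g$variants$chr,
                              pos = g$variants$pos,
                              ref = g$variants$alt, alt = g$variants$ref)
    s_flip <- compute_raw_prs(toy_scoring(g, w1), g_flip)
    expect_equal(s_flip, s1, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("standardize_scores centers and scales with recorded moments", {
  sm <- score_matrix(cbind(a = c(1, 2, 3), b = c(5, 7, 9)))
  std <- standardize_scores(sm)
  expect_equal(unname(as.matrix(std)[, "a"]), c(-1, 0, 1))
  expect_equal(unname(std$means), c(2, 7))
  expect_equal(unname(std$sds), c(1, 2))

  # idempotence: standardizing a standardized matrix changes nothing
  again <- standardize_scores(std)
  expect_equal(as.matrix(again), as.matrix(std), tolerance = 1e-12)

  # re-standardizing raw values that already have mean 0 / sd 1
  z <- as.matrix(std)
  re <- standardize_scores(score_matrix(z))
  expect_equal(as.matrix(re), z, tolerance = 1e-12)
})

test_that("zero-variance columns raise an error naming the score", {
  sm <- score_matrix(cbind(ok = c(1, 2, 3), flat = c(4, 4, 4)))
  expect_error(standardize_scores(sm), "flat")
})

test_that("train moments transfer to held-out samples", {
  train <- score_matrix(cbind(s = c(2, 4, 6, 8)))
  std <- standardize_scores(train)
  held <- score_matrix(cbind(s = c(1, 3, 5, 7, 9)))
  out <- apply_standardization(held, std$means, std$sds)
  # hand-computed: mean 5, sample sd sqrt(20/3)
  expected <- (c(1, 3, 5, 7, 9) - 5) / sqrt(20 / 3)
  expect_equal(unname(as.matrix(out)[, 1]), expected, tolerance = 1e-12)
})

test_that("dosage TSV and VCF inputs reproduce the in-memory matrix", {
  set.seed(3)
  d <- matrix(sample(0:2, 12, replace = TRUE), 4, 3)
  g <- toy_genotypes(d)

  tsv <- tempfile(fileext = ".tsv")
  dos <- g$dosages
  colnames(dos) <- paste(g$variants$chr, g$variants$pos, g$variants$ref,
                         g$variants$alt, sep = ":")
  tab <- data.frame(individual_id = rownames(dos), dos, check.names = FALSE)
  write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  g2 <- read_dosage_tsv(tsv)
  expect_equal(g2$dosages, g$dosages)
  expect_equal(g2$variants, g$variants)

  vcf <- tempfile(fileext = ".vcf")
  gt <- c("0/0", "0/1", "1/1")[d + 1]
  dim(gt) <- dim(d)
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(g$dosages)), collapse = "\t"))
  for (j in 1:3) {
    lines <- c(lines, paste(c("1", j * 100L, ".", "A", "G", ".", ".", ".",
                              "GT", gt[, j]), collapse = "\t"))
  }
  writeLines(lines, vcf)
  g3 <- read_vcf_dosages(vcf)
  expect_equal(unname(g3$dosages), unname(d))
  expect_equal(g3$variants$key, g$variants$key)
})
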