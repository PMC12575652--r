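# PRS engine: allele-aware variant matching, weighted-dosage scoring and
# score standardization.

#' Construct a genotype dosage matrix
#'
#' Dosages count copies of the stored alt allele, in \[0, 2\] (fractional
#' values allowed for imputed data); `NA` marks missing calls.
#'
#' @param dosages numeric matrix, individuals x variants.
#' @param chr,pos,ref,alt per-variant metadata vectors (length = ncol).
#' @param individual_ids optional ids (default rownames or seq).
#' @return object of class `genotype_matrix`: list with `dosages` and a
#'   `variants` data.frame (chr, pos, ref, alt, key) where `key` is the
#'   orientation-free [variant_key()].
#' @export
genotype_matrix <- function(dosages, chr, pos, ref, alt,
                            individual_ids = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  stopifnot(length(chr) == m, length(pos) == m,
            length(ref) == m, length(alt) == m)
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop("genotype_matrix: dosages must lie in [0, 2]")
  }
  ids <- individual_ids %||% rownames(dosages) %||%
    paste0("ind_", seq_len(nrow(dosages)))
  if (anyDuplicated(ids)) stop("genotype_matrix: duplicate individual ids")
  key <- variant_key(chr, pos, ref, alt)
  if (anyDuplicated(key)) stop("genotype_matrix: duplicate variant keys")
  rownames(dosages) <- ids
  colnames(dosages) <- key
  structure(
    list(dosages = dosages,
         variants = data.frame(chr = chr, pos = pos, ref = ref, alt = alt,
                               key = key, stringsAsFactors = FALSE)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Read a dosage matrix from TSV
#'
#' Expects one header line of variant keys in `chr:pos:ref:alt` form, then
#' one row per individual: id followed by dosages (empty or NA for missing).
#'
#' @param path TSV path.
#' @return a [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  parts <- strsplit(colnames(mat), ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("read_dosage_tsv: malformed variant column name(s): ",
         paste(utils::head(colnames(mat)[bad], 3), collapse = ", "))
  }
  genotype_matrix(mat,
                  chr = vapply(parts, `[`, "", 1L),
                  pos = as.integer(vapply(parts, `[`, "", 2L)),
                  ref = vapply(parts, `[`, "", 3L),
                  alt = vapply(parts, `[`, "", 4L),
                  individual_ids = ids)
}

#' Read genotype dosages from a VCF
#'
#' Uses the DS FORMAT field when present, otherwise converts GT to 0/1/2
#' alt-allele counts. Multi-allelic records are skipped.
#'
#' @param path VCF path (plain or bgzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_vcf_dosages requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"], fixed = TRUE)
  fmt <- strsplit(v@gt[1L, 1L], ":", fixed = TRUE)[[1L]]
  if ("DS" %in% fmt) {
    d <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gsub("|", "/", gt, fixed = TRUE)
    d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    d[gt %in% c("0/0")] <- 0
    d[gt %in% c("0/1", "1/0")] <- 1
    d[gt %in% c("1/1")] <- 2
  }
  d <- t(d[biallelic, , drop = FALSE])  # individuals x variants
  fix <- fix[biallelic, , drop = FALSE]
  genotype_matrix(d,
                  chr = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                  ref = fix[, "REF"], alt = fix[, "ALT"],
                  individual_ids = rownames(d))
}

#' Match scoring-file variants to genotype columns with orientation
#'
#' A scoring variant matches a genotype column at the same chromosome and
#' position when its allele pair equals the genotype ref/alt pair in either
#' orientation: `as_is` when the effect allele is the stored alt allele,
#' `swapped` when it is the ref allele. Same-position records with a
#' different allele pair are unmatched.
#'
#' @param scoring a [scoring_file()].
#' @param genotypes a [genotype_matrix()].
#' @param drop_ambiguous drop strand-ambiguous allele pairs (A/T, C/G),
#'   whose orientation cannot be resolved without strand information;
#'   default `FALSE` (scored as matched).
#' @return data.frame with `col` (genotype column index), `orientation`
#'   (`"as_is"`/`"swapped"`) and `weight`; attribute `n_unmatched` counts the
#'   scoring variants without a genotype match.
#' @export
match_variants <- function(scoring, genotypes, drop_ambiguous = FALSE) {
  stopifnot(inherits(scoring, "scoring_file"),
            inherits(genotypes, "genotype_matrix"))
  gv <- genotypes$variants
  sv <- scoring$variants
  gpos <- paste0(gv$chr, ":", gv$pos)
  spos <- paste0(sv$chr, ":", sv$pos)
  col <- match(spos, gpos)
  hit <- !is.na(col)
  orientation <- rep(NA_character_, nrow(sv))
  as_is <- hit & sv$effect_allele == gv$alt[col] &
    sv$other_allele == gv$ref[col]
  swapped <- hit & sv$effect_allele == gv$ref[col] &
    sv$other_allele == gv$alt[col]
  orientation[as_is] <- "as_is"
  orientation[swapped] <- "swapped"
  if (drop_ambiguous) {
    pair <- paste(pmin(sv$effect_allele, sv$other_allele),
                  pmax(sv$effect_allele, sv$other_allele))
    orientation[pair %in% c("A T", "C G")] <- NA_character_
  }
  ok <- !is.na(orientation)
  out <- data.frame(col = col[ok],
                    orientation = orientation[ok],
                    weight = sv$effect_weight[ok],
                    stringsAsFactors = FALSE)
  attr(out, "n_unmatched") <- sum(!ok)
  out
}

#' Compute one raw PRS as a weighted sum of effect-allele dosages
#'
#' For each matched variant the effect-allele dosage is the stored dosage
#' (`as_is`) or `2 - dosage` (`swapped`); an individual's missing dosage is
#' replaced by that variant's sample-mean stored dosage before orientation.
#'
#' @param scoring a [scoring_file()].
#' @param genotypes a [genotype_matrix()].
#' @return named numeric vector of raw scores; attributes `n_matched` and
#'   `n_unmatched`.
#' @export
compute_raw_prs <- function(scoring, genotypes) {
  mm <- match_variants(scoring, genotypes)
  if (nrow(mm) == 0L) {
    stop("compute_raw_prs: no scoring variants match the genotypes for ",
         scoring$pgs_id, "; run filter_catalog first to drop such scores")
  }
  d <- genotypes$dosages[, mm$col, drop = FALSE]
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d))
    d[idx] <- mu[((idx - 1L) %/% nrow(d)) + 1L]
  }
  sw <- mm$orientation == "swapped"
  # swapped columns: effect dosage 2 - d; fold the constant into an offset
  w_eff <- ifelse(sw, -mm$weight, mm$weight)
  offset <- 2 * sum(mm$weight[sw])
  score <- drop(d %*% w_eff) + offset
  names(score) <- rownames(genotypes$dosages)
  attr(score, "n_matched") <- nrow(mm)
  attr(score, "n_unmatched") <- attr(mm, "n_unmatched")
  score
}

#' Compute a score matrix for a catalog of scoring files
#'
#' @param catalog list of [scoring_file()] objects.
#' @param genotypes a [genotype_matrix()].
#' @return object of class `score_matrix`: list with `values` (individuals x
#'   scores), `individual_ids`, `score_ids`, `standardized` flag and, once
#'   standardized, the per-score `means` and `sds`.
#' @export
compute_score_matrix <- function(catalog, genotypes) {
  ids <- vapply(catalog, function(s) s$pgs_id, character(1))
  vals <- vapply(catalog, compute_raw_prs, numeric(nrow(genotypes$dosages)),
                 genotypes = genotypes)
  vals <- matrix(vals, nrow = nrow(genotypes$dosages),
                 dimnames = list(rownames(genotypes$dosages), ids))
  score_matrix(vals)
}

#' Construct a score matrix object
#'
#' @param values numeric matrix, individuals x scores, with column names.
#' @param standardized logical flag.
#' @param means,sds recorded standardization moments (when standardized).
#' @return object of class `score_matrix`.
#' @export
score_matrix <- function(values, standardized = FALSE,
                         means = NULL, sds = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("score_", seq_len(ncol(values)))
  }
  if (!all(is.finite(values))) stop("score_matrix: non-finite score values")
  structure(
    list(values = values,
         individual_ids = rownames(values) %||%
           paste0("ind_", seq_len(nrow(values))),
         score_ids = colnames(values),
         standardized = standardized,
         means = means, sds = sds),
    class = "score_matrix"
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d individuals x %d scores%s\n",
              nrow(x$values), ncol(x$values),
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' @export
as.matrix.score_matrix <- function(x, ...) x$values

#' Standardize scores to mean 0, SD 1
#'
#' Column-wise `(x - mean) / sd` using the full-sample mean and sample SD
#' (n - 1 denominator). The original moments are recorded so the same
#' transform can be applied to held-out samples with
#' [apply_standardization()]. An already-standardized matrix is returned
#' unchanged.
#'
#' @param scores a [score_matrix()].
#' @return standardized `score_matrix` with `means`/`sds` recorded.
#' @export
standardize_scores <- function(scores) {
  stopifnot(inherits(scores, "score_matrix"))
  if (isTRUE(scores$standardized)) return(scores)
  mu <- colMeans(scores$values)
  sd_ <- apply(scores$values, 2L, stats::sd)
  zero <- sd_ <= 0 | !is.finite(sd_)
  if (any(zero)) {
    stop("standardize_scores: zero-variance score column(s): ",
         paste(scores$score_ids[zero], collapse = ", "))
  }
  vals <- sweep(sweep(scores$values, 2L, mu, "-"), 2L, sd_, "/")
  score_matrix(vals, standardized = TRUE, means = mu, sds = sd_)
}

#' Apply recorded standardization moments to new scores
#'
#' Used to carry training-sample moments onto a validation sample without
#' leaking validation information into the transform.
#'
#' @param scores a raw [score_matrix()].
#' @param means,sds named moments, covering every column of `scores`.
#' @return `score_matrix` transformed with the supplied moments
#'   (`standardized = TRUE`; the stored moments are the ones applied).
#' @export
apply_standardization <- function(scores, means, sds) {
  stopifnot(inherits(scores, "score_matrix"))
  ids <- scores$score_ids
  if (!all(ids %in% names(means)) || !all(ids %in% names(sds))) {
    stop("apply_standardization: moments missing for some score columns")
  }
  mu <- means[ids]
  sd_ <- sds[ids]
  if (any(sd_ <= 0)) stop("apply_standardization: nonpositive sd supplied")
  vals <- sweep(sweep(scores$values, 2L, mu, "-"), 2L, sd_, "/")
  score_matrix(vals, standardized = TRUE, means = mu, sds = sd_)
}

#' Write scores as TSV
#'
#' @param scores a [score_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_tsv <- function(scores, path) {
  stopifnot(inherits(scores, "score_matrix"))
  out <- data.frame(individual_id = scores$individual_ids,
                    scores$values, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
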