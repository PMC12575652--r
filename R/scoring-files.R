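# PGS-Catalog scoring-file input and the candidate-PRS exclusion cascade.

#' Default trait-exclusion patterns
#'
#' Trait labels matched (case-insensitive substring) against these patterns
#' are removed from the candidate catalog: CRC-specific traits first, then
#' broader traits whose case sets contain many CRC cases. Scores for
#' precursor lesions (benign colon neoplasms, rectal polyps) are deliberately
#' not excluded, since they predict precursors rather than CRC itself.
#'
#' @export
crc_trait_patterns <- c("colorectal cancer", "colon cancer", "rectal cancer")

#' @rdname crc_trait_patterns
#' @export
broad_crc_trait_patterns <- c("gastrointestinal cancer", "rectal/anal cancer")

#' Construct a scoring file object in memory
#'
#' @param pgs_id identifier string, unique within a catalog.
#' @param trait_label free-text reported trait (may be "").
#' @param variants data.frame with columns `variant_id`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `effect_weight`.
#' @param dropped_count number of rows dropped during parsing.
#' @return object of class `scoring_file`.
#' @export
scoring_file <- function(pgs_id, trait_label, variants, dropped_count = 0L) {
  stopifnot(is.character(pgs_id), length(pgs_id) == 1L, nzchar(pgs_id))
  stopifnot(is.data.frame(variants), nrow(variants) >= 1L)
  needed <- c("variant_id", "effect_allele", "other_allele", "effect_weight")
  missing_cols <- setdiff(needed, names(variants))
  if (length(missing_cols)) {
    stop("scoring_file: missing variant column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(variants$effect_weight))) {
    stop("scoring_file: non-finite effect weights in ", pgs_id)
  }
  same <- !is.na(variants$other_allele) &
    variants$effect_allele == variants$other_allele
  if (any(same)) {
    stop("scoring_file: effect and other allele identical for ",
         sum(same), " variant(s) in ", pgs_id)
  }
  structure(
    list(pgs_id = pgs_id,
         trait_label = trait_label %||% "",
         variants = variants,
         dropped_count = as.integer(dropped_count)),
    class = "scoring_file"
  )
}

#' @export
print.scoring_file <- function(x, ...) {
  cat(sprintf("<scoring_file> %s  trait: %s  variants: %d (dropped %d)\n",
              x$pgs_id,
              if (nzchar(x$trait_label)) x$trait_label else "<none>",
              nrow(x$variants), x$dropped_count))
  invisible(x)
}

#' Parse a PGS-Catalog-format scoring file
#'
#' Reads the PGS Catalog dialect: '#'-prefixed metadata lines (e.g.
#' `#pgs_id=...`, `#trait_reported=...`) followed by a tab-separated table
#' whose header names at least `effect_allele` and `effect_weight`.
#' Gzip-compressed files are accepted transparently. Rows whose weight does
#' not parse as a number are dropped and counted in `dropped_count`.
#'
#' @param path path to a plain or gzip-compressed scoring file.
#' @return a [scoring_file()] object. `variant_id` is
#'   `chromosome:position` when `chr_name`/`chr_position` are present,
#'   otherwise the `rsID` column.
#' @export
parse_scoring_file <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) < 2L) {
    stop("scoring file ", path, ": no variant rows")
  }

  meta_value <- function(field) {
    hit <- grep(paste0("^#", field, "="), meta, value = TRUE)
    if (length(hit)) sub(paste0("^#", field, "="), "", hit[1L]) else ""
  }
  pgs_id <- meta_value("pgs_id")
  if (!nzchar(pgs_id)) {
    pgs_id <- sub("\\.(txt|tsv)(\\.gz)?$", "", basename(path))
  }
  trait_label <- meta_value("trait_reported")

  tab <- utils::read.table(text = body, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "", check.names = TRUE)
  for (col in c("effect_allele", "effect_weight")) {
    if (!col %in% names(tab)) {
      stop("scoring file ", path, ": missing mandatory column '", col, "'")
    }
  }

  w <- suppressWarnings(as.numeric(tab$effect_weight))
  keep <- is.finite(w)
  dropped <- sum(!keep)
  tab <- tab[keep, , drop = FALSE]
  w <- w[keep]
  if (nrow(tab) == 0L) {
    stop("scoring file ", path, ": no rows with parseable effect weights")
  }

  has_pos <- all(c("chr_name", "chr_position") %in% names(tab))
  chr <- if (has_pos) tab$chr_name else rep(NA_character_, nrow(tab))
  pos <- if (has_pos) suppressWarnings(as.integer(tab$chr_position)) else
    rep(NA_integer_, nrow(tab))
  variant_id <- if (has_pos) {
    paste0(chr, ":", pos)
  } else if ("rsID" %in% names(tab)) {
    tab$rsID
  } else {
    stop("scoring file ", path,
         ": need either chr_name/chr_position or rsID to identify variants")
  }

  variants <- data.frame(
    variant_id = variant_id,
    chr = chr,
    pos = pos,
    effect_allele = tab$effect_allele,
    other_allele = if ("other_allele" %in% names(tab)) tab$other_allele else
      NA_character_,
    effect_weight = w,
    stringsAsFactors = FALSE
  )
  scoring_file(pgs_id, trait_label, variants, dropped_count = dropped)
}

#' Fraction of a score's variants present in a genotype variant index
#'
#' A scoring variant matches when its `chromosome:position:sorted-alleles`
#' key is in the index, i.e. position and allele pair agree in either
#' orientation.
#'
#' @param scoring a [scoring_file()].
#' @param variant_index character vector of canonical keys (see
#'   [variant_key()]), e.g. from a [genotype_matrix()]'s `variants$key`.
#' @return fraction in \[0, 1\]; an empty index yields 0.
#' @export
compute_overlap <- function(scoring, variant_index) {
  stopifnot(inherits(scoring, "scoring_file"))
  if (length(variant_index) == 0L) return(0)
  v <- scoring$variants
  keys <- variant_key(v$chr, v$pos, v$effect_allele, v$other_allele)
  mean(keys %in% variant_index)
}

#' Apply the four-stage exclusion cascade to a catalog of candidate scores
#'
#' Each score receives the first applicable exclusion reason, in order:
#' \enumerate{
#'   \item `no_overlap` — no scoring variant found in the genotype index;
#'   \item `high_missingness` — more than `missingness_threshold` of its
#'     variants are unavailable (overlap strictly below
#'     `1 - missingness_threshold`; a score with exactly the threshold
#'     fraction missing is kept);
#'   \item `crc_trait` — trait label matches a CRC/colon/rectal-cancer
#'     pattern;
#'   \item `broad_crc_trait` — trait label matches a broader trait whose
#'     cases substantially overlap CRC (gastrointestinal, rectal/anal
#'     cancer).
#' }
#' Survivors form the non-CRC candidate set used for composite-score
#' selection. Trait matching is case-insensitive substring matching.
#'
#' @param catalog list of [scoring_file()] objects with unique `pgs_id`s.
#' @param variant_index character vector of canonical variant keys.
#' @param missingness_threshold maximum tolerated missing fraction,
#'   in (0, 1); default 0.20.
#' @param excluded_traits,broad_excluded_traits character patterns; defaults
#'   [crc_trait_patterns] and [broad_crc_trait_patterns].
#' @return object of class `catalog_filter_report`: list with `kept`
#'   (pgs_ids), `excluded` (named reason codes), `overlap_fraction` (named),
#'   and `table` (per-score data.frame mirroring the report TSV columns).
#' @export
filter_catalog <- function(catalog, variant_index,
                           missingness_threshold = 0.20,
                           excluded_traits = crc_trait_patterns,
                           broad_excluded_traits = broad_crc_trait_patterns) {
  stopifnot(missingness_threshold > 0, missingness_threshold < 1)
  ids <- vapply(catalog, function(s) s$pgs_id, character(1))
  if (anyDuplicated(ids)) {
    stop("filter_catalog: duplicate pgs_id in catalog: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  traits <- vapply(catalog, function(s) s$trait_label, character(1))
  n_var <- vapply(catalog, function(s) nrow(s$variants), integer(1))
  ov <- vapply(catalog, compute_overlap, numeric(1),
               variant_index = variant_index)

  matches_any <- function(label, patterns) {
    if (!length(patterns) || !nzchar(label)) return(FALSE)
    lab <- tolower(label)
    any(vapply(patterns, function(p) grepl(tolower(p), lab, fixed = TRUE),
               logical(1)))
  }

  reason <- rep(NA_character_, length(catalog))
  reason[ov == 0] <- "no_overlap"
  open <- is.na(reason)
  reason[open & ov < (1 - missingness_threshold)] <- "high_missingness"
  open <- is.na(reason)
  is_crc <- vapply(traits, matches_any, logical(1), patterns = excluded_traits)
  reason[open & is_crc] <- "crc_trait"
  open <- is.na(reason)
  is_broad <- vapply(traits, matches_any, logical(1),
                     patterns = broad_excluded_traits)
  reason[open & is_broad] <- "broad_crc_trait"

  kept <- ids[is.na(reason)]
  excluded <- reason[!is.na(reason)]
  names(excluded) <- ids[!is.na(reason)]
  names(ov) <- ids

  tab <- data.frame(
    pgs_id = ids,
    trait_label = traits,
    n_variants = n_var,
    overlap_fraction = ov,
    status = ifelse(is.na(reason), "kept", "excluded"),
    reason = ifelse(is.na(reason), "", reason),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(
    list(kept = kept, excluded = excluded, overlap_fraction = ov,
         table = tab),
    class = "catalog_filter_report"
  )
}

#' @export
print.catalog_filter_report <- function(x, ...) {
  cat(sprintf("<catalog_filter_report> %d candidates: %d kept, %d excluded\n",
              length(x$kept) + length(x$excluded), length(x$kept),
              length(x$excluded)))
  if (length(x$excluded)) {
    counts <- table(factor(x$excluded,
                           levels = c("no_overlap", "high_missingness",
                                      "crc_trait", "broad_crc_trait")))
    for (r in names(counts)) cat(sprintf("  %-17s %d\n", r, counts[[r]]))
  }
  invisible(x)
}

#' Write a catalog filter report as TSV
#'
#' Columns: pgs_id, trait_label, n_variants, overlap_fraction, status,
#' reason.
#'
#' @param report a `catalog_filter_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "catalog_filter_report"))
  utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
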