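# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so seeded generators never perturb the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  code
}

#' Canonical variant key
#'
#' Builds the `chromosome:position:allele1_allele2` key with the allele pair
#' sorted alphabetically, so both orientations of a variant map to one key.
#'
#' @param chr chromosome labels.
#' @param pos base-pair positions.
#' @param a1,a2 allele strings (order irrelevant).
#' @return character vector of keys.
#' @export
variant_key <- function(chr, pos, a1, a2) {
  lo <- ifelse(a1 <= a2, a1, a2)
  hi <- ifelse(a1 <= a2, a2, a1)
  paste0(chr, ":", pos, ":", lo, "_", hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
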