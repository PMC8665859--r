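# Internal helpers shared across modules.

#' Clip values into a closed interval
#' @noRd
.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# All log output goes through message() -> standard error.
.log <- function(...) message("[methrisk] ", ...)

# Deterministic sub-seed for a named substream, derived from a master
# seed. Keeps independent components (sample covariates, probe effects,
# noise draws) on separate streams so enlarging one does not perturb
# the others. Kept inside 32-bit signed integer range.
.substreamSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 99991L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

.withSubstream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.substreamSeed(seed, name))
  force(expr)
}

# Strict controlled vocabularies for the sample sheet.
.SEX_LEVELS <- c("F", "M")
.DISEASE_LEVELS <- c("none", "asthma", "COPD", "other")
.EXPOSURE_LEVELS <- c("FA+S", "FA+A", "DE+A", "PDDE+A")
.COVID_LEVELS <- c("negative", "positive")
.FEATURE_LEVELS <- c("promoter", "5'UTR", "exon", "intron", "body",
                     "intergenic")
.DENSITY_LEVELS <- c("HC", "IC", "LC", "none")

.checkVocab <- function(x, allowed, what) {
  bad <- setdiff(unique(x[!is.na(x)]), allowed)
  if (length(bad))
    stop(sprintf("invalid %s value(s): %s (allowed: %s)", what,
                 paste(bad, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  invisible(x)
}
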