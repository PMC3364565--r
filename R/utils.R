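#' @keywords internal
"_PACKAGE"

## Complement / reverse-complement on plain character vectors.  Internal
## sequences are plain uppercase A/C/G/T strings; Biostrings objects are used
## only at the FASTA boundary.
complement_base <- function(x) chartr("ACGT", "TGCA", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(complement_base(s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Round half away from zero (commercial rounding), used for reported fold
## elevations; base round() rounds half to even.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

## Derive a stream-specific child seed below 2^31 from a user seed.
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * as.integer(k) %% 104729L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mutspectra <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

## An empty variant-record data.frame with the canonical column set.
empty_variant_records <- function() {
  data.frame(
    contig = character(0), pos = integer(0),
    ref = character(0), alt = character(0), kind = character(0),
    depth = numeric(0), variant_quality = numeric(0),
    mapping_quality = numeric(0), vaf = numeric(0),
    sample_id = character(0), stringsAsFactors = FALSE
  )
}

variant_kind <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "substitution",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

variant_key <- function(df) {
  paste(df$contig, df$pos, df$ref, df$alt, sep = ":")
}
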