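#' Round a percentage half-up, matching printed cohort tables
#'
#' Base R's `round()` rounds half to even; cohort reports conventionally
#' round half away from zero (42/167 prints as 25.1%).
#'
#' @param x Numeric vector of percentages (already on the 0-100 scale).
#' @param digits Decimal places to keep (default 1).
#' @return Numeric vector rounded half-up to `digits` places.
#' @export
#' @examples
#' percent_round(100 * 42 / 167) # 25.1
percent_round <- function(x, digits = 1) {
  m <- 10^digits
  # tiny epsilon guards against 0.05-type binary representation artifacts
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Canonical variant key
#'
#' @param chrom,pos,ref,alt Vectors describing biallelic variants.
#' @return Character vector `"chrom:pos:ref:alt"`.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Alleles must be left-trimmed/parsimonious so exact-key matching against the
# population reference is sound: a pair is rejected when a shared suffix, or a
# shared prefix with both alleles longer than one base, could still be trimmed.
is_parsimonious <- function(ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  ok <- nr >= 1 & na >= 1 & ref != alt
  shared_suffix <- nr >= 2 & na >= 2 &
    substr(ref, nr, nr) == substr(alt, na, na)
  shared_prefix <- nr >= 2 & na >= 2 &
    substr(ref, 1, 1) == substr(alt, 1, 1)
  ok & !shared_suffix & !shared_prefix
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# Deterministic sub-stream seed derivation: one user seed fans out to named
# stages so adding an artifact does not perturb the draws of another.
substream_seed <- function(seed, stream) {
  offsets <- c(
    variants = 11L, background = 23L, clinical = 37L,
    reference = 53L, panel = 71L, genotypes = 89L, vaf = 101L
  )
  off <- offsets[[stream]]
  if (is.null(off)) abort(paste0("unknown random sub-stream: ", stream))
  (as.integer(seed) %% 20000000L) * 101L + off
}
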