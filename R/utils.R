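#' Round half away from zero
#'
#' Fixed-point rounding where halves round up (away from zero), the convention
#' used for all reported percentages. Base R's `round()` rounds half to even,
#' which does not reproduce printed summary percentages.
#'
#' @param x numeric vector
#' @param digits number of decimal digits to keep
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. All randomness in the package flows through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Read a tab-separated table
#'
#' Thin wrapper around [utils::read.delim()] with the conventions used by all
#' package outputs (no factors, `NA` for missing, UTF-8).
#'
#' @param path file path
#' @param ... passed to [utils::read.delim()]
#' @return data.frame
#' @export
read_tsv_file <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a tab-separated table
#'
#' @param x data.frame
#' @param path file path
#' @return invisibly, `path`
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# stop() with sprintf formatting and no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Normalise a nucleotide sequence: uppercase, RNA U -> T, validate alphabet.
normalize_nt <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  if (any(nchar(x) == 0L)) abort("empty %s", what)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) abort("%s contains characters outside {A,C,G,T,N,U}", what)
  x
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# Validate a protein sequence over the 20 amino acids plus X.
normalize_aa <- function(x, what = "protein") {
  x <- toupper(x)
  if (any(nchar(x) == 0L)) abort("empty %s", what)
  bad <- grepl(sprintf("[^%sX]", paste(AA20, collapse = "")), x)
  if (any(bad)) abort("%s contains residues outside the 20 amino acids + X", what)
  x
}

# named character vector -> Biostrings::AAStringSet and back
as_named_chr <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    return(out)
  }
  if (is.character(x)) {
    if (length(x) && is.null(names(x)))
      names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  abort("expected a character vector or XStringSet")
}
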