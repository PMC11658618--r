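#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T, case-sensitive).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

#' GC fraction of DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return numeric vector in `[0, 1]`; `NA` for empty or `NA` input.
#' @export
gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  out <- gc / n
  out[is.na(x) | n == 0] <- NA_real_
  out
}

# Deterministic 31-bit hash of a string, for deriving per-stage RNG substreams
# from one master seed without coupling the streams.
stable_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (b in v) h <- (h * 131 + b) %% 2147483647L
  as.integer(h)
}

# Derive a substream seed from a master seed and a stage label.
substream_seed <- function(seed, label) {
  as.integer((as.numeric(seed) + stable_hash(label)) %% 2147483647)
}

# Run an expression under a local RNG state seeded for one stage.
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  expr
}

# Standard error of the mean.
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

variant_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
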