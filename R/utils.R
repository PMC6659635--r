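# Internal sequence helpers shared across modules. All coordinates in the
# package are 1-based closed intervals on the linearized plus strand.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a plain character string
#' @param s single DNA string over A/C/G/T/N
#' @return reverse complement as a character string
#' @export
revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# complement without reversal, vectorized over single characters
comp_chars <- function(x) unname(COMPLEMENT[x])

# split a string into single characters
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Random DNA string at a given GC content
#'
#' Uses the session RNG; callers set the seed.
#' @param n length in bases
#' @param gc GC content in `[0, 1]`
#' @return a DNA string
#' @export
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# rotate a circular sequence so that position `offset + 1` becomes position 1
rotate_seq <- function(s, offset) {
  n <- nchar(s)
  offset <- offset %% n
  if (offset == 0) return(s)
  paste0(substring(s, offset + 1, n), substring(s, 1, offset))
}

# map ambiguity codes other than N to N (with a warning), upper-case
sanitize_dna <- function(s) {
  s <- toupper(s)
  if (grepl("[^ACGTN]", s)) {
    warning("ambiguity codes other than N mapped to N", call. = FALSE)
    s <- gsub("[^ACGTN]", "N", s)
  }
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# maximal runs of TRUE in a logical vector -> data.frame(start, end) or
# zero-row frame
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
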