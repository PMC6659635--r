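# Gap-augmented multiple alignment container and column summaries.

#' Construct an aligned set from a character matrix or aligned FASTA
#'
#' @param x either a taxa-by-columns character matrix of single characters
#'   (`A/C/G/T/N/-`) with rownames as taxon labels, or a character vector of
#'   equal-length aligned sequences named by taxon
#' @param genomes optional named list of [plastome()] objects; if given, each
#'   ungapped row is checked against the stored genome length (a mismatch is a
#'   consistency error)
#' @return object of class `aligned_set` with elements `taxa` and `mat`
#' @export
aligned_set <- function(x, genomes = NULL) {
  if (is.matrix(x)) {
    mat <- x
  } else {
    stopifnot(is.character(x), !is.null(names(x)))
    if (length(unique(nchar(x))) != 1L) {
      stop("aligned sequences must all have equal length")
    }
    mat <- do.call(rbind, lapply(x, seq_chars))
    rownames(mat) <- names(x)
  }
  mat[] <- toupper(mat)
  if (is.null(rownames(mat))) stop("alignment rows must be named by taxon")
  if (!is.null(genomes)) {
    for (t in rownames(mat)) {
      if (!t %in% names(genomes)) next
      ungapped <- sum(mat[t, ] != "-")
      if (ungapped != genomes[[t]]$length) {
        stop("ConsistencyError: ungapped row of '", t, "' has ", ungapped,
             " bases but the stored genome has ", genomes[[t]]$length)
      }
    }
  }
  structure(list(taxa = rownames(mat), mat = mat), class = "aligned_set")
}

#' Read an aligned FASTA into an aligned set
#' @param path aligned FASTA file
#' @param genomes optional genomes for consistency checking
#' @return an `aligned_set`
#' @export
read_alignment <- function(path, genomes = NULL) {
  ss <- Biostrings::readBStringSet(path)
  v <- toupper(as.character(ss))
  names(v) <- sub("\\s.*$", "", names(ss))
  aligned_set(v, genomes = genomes)
}

#' Write an aligned set as aligned FASTA
#' @param a an `aligned_set`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_alignment <- function(a, path) {
  v <- apply(a$mat, 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(v)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# per-taxon map column -> genome coordinate (gap columns map to the previous
# residue; 0 before the first residue)
column_coord_map <- function(a, taxon) {
  cumsum(a$mat[taxon, ] != "-")
}

#' Alignment summary: length without gaps, variable and informative sites
#'
#' Columns containing any gap are excluded entirely. A column is variable if
#' it shows at least two of A/C/G/T (N is never a state), and parsimony
#' informative if at least two states each occur in at least two taxa.
#'
#' @param a an `aligned_set`
#' @return list with `aligned_length_without_gaps`, `variable_sites`,
#'   `informative_sites`
#' @export
alignment_summary <- function(a) {
  m <- a$mat
  gapfree <- colSums(m == "-") == 0L
  mm <- m[, gapfree, drop = FALSE]
  counts <- vapply(c("A", "C", "G", "T"),
                   function(b) colSums(mm == b), numeric(ncol(mm)))
  if (ncol(mm) == 1L) counts <- matrix(counts, nrow = 1L)
  n_states <- rowSums(counts > 0L)
  n_shared <- rowSums(counts >= 2L)
  list(aligned_length_without_gaps = sum(gapfree),
       variable_sites = sum(n_states >= 2L),
       informative_sites = sum(n_shared >= 2L & n_states >= 2L))
}
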