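#' Construct a plastome object
#'
#' A `plastome` holds one circular chloroplast genome: its linearized sequence
#' (stored at the deposited origin), annotated gene features, and optionally a
#' quadripartite partition. All coordinates are 1-based closed intervals on the
#' plus strand of the linearized sequence; features spanning the origin are
#' split into two exon intervals and flagged `wraps_origin`.
#'
#' @param id taxon label, unique within a genome set
#' @param seq DNA string over A/C/G/T/N (other ambiguity codes are mapped to N
#'   with a warning)
#' @param features a data.frame of gene features as returned by
#'   [gene_features()], or `NULL`
#' @param partition optional `quad_partition` (see [detect_quadripartite()])
#' @return an object of class `plastome` with elements `id`, `seq`, `length`,
#'   `features`, `partition`
#' @export
#' @examples
#' p <- plastome("toy", "ACGTACGTACGT")
#' p$length
plastome <- function(id, seq, features = NULL, partition = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- sanitize_dna(seq)
  n <- nchar(seq)
  if (n < 1L) stop("empty sequence for plastome '", id, "'")
  if (is.null(features)) features <- empty_features()
  validate_features(features, n, id)
  structure(
    list(id = id, seq = seq, length = n, features = features,
         partition = partition),
    class = "plastome"
  )
}

#' @export
print.plastome <- function(x, ...) {
  cat("plastome '", x$id, "': ", x$length, " bp, ",
      length(unique(x$features$feature_id)), " features",
      if (!is.null(x$partition)) " [quadripartite]" else "", "\n", sep = "")
  invisible(x)
}

# one row per exon; feature_id groups exons of one gene copy
empty_features <- function() {
  data.frame(feature_id = integer(), name = character(), kind = character(),
             strand = character(), start = integer(), end = integer(),
             exon_rank = integer(), copy_of_ir = logical(),
             pseudo = logical(), trans_spliced = logical(),
             stringsAsFactors = FALSE)
}

#' Build a gene feature table
#'
#' Features are stored one row per exon. Exons of a feature must be sorted and
#' non-overlapping; introns are implicitly the gaps between consecutive exons.
#'
#' @param name gene symbol (recycled over exons)
#' @param kind one of `"CDS"`, `"tRNA"`, `"rRNA"`
#' @param strand `"+"` or `"-"`
#' @param starts,ends integer vectors of exon intervals (1-based closed)
#' @param copy_of_ir flag for the duplicated inverted-repeat copy of a gene
#' @param pseudo flag for pseudogenes (reported separately in summaries)
#' @param trans_spliced flag for trans-spliced genes (e.g. rps12); such
#'   features are excluded from intron-context assignment
#' @return data.frame with one row per exon
#' @export
gene_features <- function(name, kind, strand, starts, ends,
                          copy_of_ir = FALSE, pseudo = FALSE,
                          trans_spliced = FALSE) {
  stopifnot(length(starts) == length(ends), length(starts) >= 1L)
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA"))
  strand <- match.arg(strand, c("+", "-"))
  data.frame(feature_id = 1L, name = name, kind = kind, strand = strand,
             start = as.integer(starts), end = as.integer(ends),
             exon_rank = seq_along(starts),
             copy_of_ir = copy_of_ir, pseudo = pseudo,
             trans_spliced = trans_spliced, stringsAsFactors = FALSE)
}

#' Combine feature tables, renumbering feature ids
#' @param ... feature tables from [gene_features()]
#' @return a single feature table
#' @export
bind_features <- function(...) {
  tabs <- list(...)
  tabs <- tabs[vapply(tabs, NROW, 1L) > 0L]
  if (!length(tabs)) return(empty_features())
  for (i in seq_along(tabs)) tabs[[i]]$feature_id <- i
  do.call(rbind, tabs)
}

validate_features <- function(f, n, id) {
  if (!NROW(f)) return(invisible(TRUE))
  bad <- f$start < 1L | f$end > n | f$start > f$end
  if (any(bad)) {
    stop("feature '", f$name[which(bad)[1]], "' of '", id,
         "' has an interval outside the sequence [1, ", n, "]")
  }
  for (fid in unique(f$feature_id)) {
    ex <- f[f$feature_id == fid, ]
    ex <- ex[order(ex$exon_rank), ]
    if (NROW(ex) > 1L && any(ex$start[-1] <= ex$end[-NROW(ex)]) &&
        !any(ex$trans_spliced)) {
      stop("exons of feature '", ex$name[1], "' overlap or are unsorted")
    }
  }
  invisible(TRUE)
}

#' Construct a genome set
#'
#' @param genomes list of [plastome()] objects with unique ids
#' @param outgroup_id taxon label of the outgroup; must be present
#' @return object of class `genome_set`
#' @export
genome_set <- function(genomes, outgroup_id) {
  ids <- vapply(genomes, function(g) g$id, "")
  if (anyDuplicated(ids)) stop("duplicate genome ids in genome set")
  if (length(genomes) < 2L) stop("a genome set needs at least 2 genomes")
  if (!outgroup_id %in% ids) stop("outgroup '", outgroup_id, "' not in set")
  names(genomes) <- ids
  structure(list(genomes = genomes, outgroup_id = outgroup_id),
            class = "genome_set")
}

#' Summarize unique gene content of a plastome
#'
#' Genes duplicated between the two inverted repeats are counted once
#' (deduplicated by name and kind). Pseudogene-flagged features are reported
#' separately rather than folded into the gene total, since plastome
#' literature is inconsistent about whether degraded ycf-class ORFs count as
#' genes.
#'
#' @param p a [plastome()]
#' @return list with `total`, `by_kind` (named integer vector over
#'   CDS/tRNA/rRNA), and `pseudogenes`
#' @export
#' @examples
#' f <- bind_features(
#'   gene_features("rbcL", "CDS", "+", 1, 9),
#'   gene_features("rrn16", "rRNA", "+", 11, 14),
#'   gene_features("rrn16", "rRNA", "-", 16, 19, copy_of_ir = TRUE))
#' gene_content_summary(plastome("toy", strrep("ACGTA", 4), f))
gene_content_summary <- function(p) {
  stopifnot(inherits(p, "plastome"))
  f <- p$features
  if (!NROW(f)) {
    warning("plastome '", p$id, "' has no features", call. = FALSE)
    return(list(total = 0L,
                by_kind = c(CDS = 0L, tRNA = 0L, rRNA = 0L),
                pseudogenes = 0L))
  }
  per_feat <- unique(f[, c("feature_id", "name", "kind", "pseudo")])
  genes <- unique(per_feat[!per_feat$pseudo, c("name", "kind")])
  pseudo <- unique(per_feat[per_feat$pseudo, c("name", "kind")])
  by_kind <- vapply(c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA"),
                    function(k) sum(genes$kind == k), 1L)
  list(total = nrow(genes), by_kind = by_kind, pseudogenes = nrow(pseudo))
}

#' Read plastome sequences from FASTA
#' @param path FASTA file; one record per genome
#' @return named list of [plastome()] objects (no features)
#' @export
read_plastome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(ss), function(i) {
    plastome(sub("\\s.*$", "", names(ss)[i]), as.character(ss[[i]]))
  })
  names(out) <- vapply(out, function(p) p$id, "")
  out
}

#' Write plastomes to FASTA
#' @param genomes list of [plastome()] objects
#' @param path output file
#' @return `path`, invisibly
#' @export
write_plastome_fasta <- function(genomes, path) {
  ss <- Biostrings::DNAStringSet(vapply(genomes, function(p) p$seq, ""))
  names(ss) <- vapply(genomes, function(p) p$id, "")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
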