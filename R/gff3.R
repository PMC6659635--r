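# GFF3 export/import of plastome feature tables (one line per exon),
# delegated to rtracklayer; coordinates are already 1-based closed.

#' Write a plastome feature table as GFF3
#'
#' One GFF3 line per exon, with the gene name, feature id, exon rank and the
#' pseudogene / trans-splice / IR-copy flags carried as attributes so the file
#' round-trips through [read_feature_table()] bit-exactly.
#'
#' @param p a [plastome()]
#' @param path output GFF3 file
#' @return `path`, invisibly
#' @export
write_feature_table <- function(p, path) {
  stopifnot(inherits(p, "plastome"))
  f <- p$features
  if (!NROW(f)) {
    gr <- GenomicRanges::GRanges()
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = p$id,
      ranges = IRanges::IRanges(start = f$start, end = f$end),
      strand = f$strand,
      type = f$kind,
      Name = f$name,
      feature_id = f$feature_id,
      exon_rank = f$exon_rank,
      copy_of_ir = f$copy_of_ir,
      pseudo = f$pseudo,
      trans_spliced = f$trans_spliced)
    GenomeInfoDb::seqlengths(gr) <- p$length
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path GFF3 file
#' @return feature data.frame in the internal one-row-per-exon layout
#' @export
read_feature_table <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (!length(gr)) return(empty_features())
  md <- S4Vectors::mcols(gr)
  f <- data.frame(
    feature_id = as.integer(md$feature_id),
    name = as.character(md$Name),
    kind = as.character(md$type),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    exon_rank = as.integer(md$exon_rank),
    copy_of_ir = as.logical(md$copy_of_ir),
    pseudo = as.logical(md$pseudo),
    trans_spliced = as.logical(md$trans_spliced),
    stringsAsFactors = FALSE)
  f <- f[order(f$feature_id, f$exon_rank), ]
  rownames(f) <- NULL
  f
}
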