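# Minimal GenBank flat-file reader for single-record circular plastomes.
# Only the feature kinds downstream stages use (gene/CDS/tRNA/rRNA) are kept;
# join() and complement() locations are resolved into plus-strand exon lists.

#' Read a plastome from a GenBank flat file
#'
#' Parses a single-record GenBank file: the ORIGIN sequence block (upper-cased,
#' ambiguity codes other than N mapped to N) and the CDS/tRNA/rRNA features,
#' with `join(...)` locations resolved into ordered exon lists and
#' `complement(...)` recorded as minus strand. Unknown feature kinds are
#' ignored with a warning. `gene` features are used only to recover a name for
#' unnamed CDS/tRNA/rRNA features.
#'
#' @param path GenBank flat file with one record
#' @param id taxon label; default is the LOCUS name
#' @return a [plastome()]
#' @export
read_genbank <- function(path, id = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty GenBank file: ", path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  locus_name <- if (length(locus)) strsplit(trimws(locus[1]), "\\s+")[[1]][2] else NULL

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank record has no ORIGIN sequence block: ", path)
  end_rec <- grep("^//", lines)
  end_rec <- if (length(end_rec)) end_rec[end_rec > ori[1]][1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(end_rec - 1L)]
  seq <- toupper(gsub("[0-9 /]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(seq)) stop("ORIGIN block contains no sequence: ", path)

  feats <- parse_genbank_features(lines, ori[1])
  p <- plastome(id %||% locus_name %||% basename(path), seq,
                features = resolve_genbank_features(feats, nchar(seq), path))
  p
}

# split the FEATURES table into (key, location, qualifiers) records
parse_genbank_features <- function(lines, origin_line) {
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) return(list())
  body <- lines[(fstart[1] + 1L):(origin_line - 1L)]
  # feature header lines have the key in columns 6-20
  is_key <- grepl("^ {1,10}\\S", body) & !grepl("^ {21}", body)
  idx <- which(is_key)
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    from <- idx[i]
    to <- if (i < length(idx)) idx[i + 1L] - 1L else length(body)
    block <- body[from:to]
    key <- sub("^\\s*(\\S+).*$", "\\1", block[1])
    rest <- c(sub("^\\s*\\S+\\s*", "", block[1]), trimws(block[-1]))
    # location = leading lines up to the first qualifier line
    qstart <- grep("^/", rest)
    loc_lines <- if (length(qstart)) rest[seq_len(qstart[1] - 1L)] else rest
    quals <- if (length(qstart)) rest[qstart[1]:length(rest)] else character()
    out[[i]] <- list(key = key,
                     location = paste(loc_lines, collapse = ""),
                     qualifiers = paste(quals, collapse = "\n"))
  }
  out
}

# parse a GenBank location string into exons + strand
parse_gb_location <- function(loc) {
  loc <- gsub("[<>\\s]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  # tolerate join(complement(..),..): any inner complement flips the strand
  if (grepl("complement", loc)) {
    strand <- "-"
    loc <- gsub("complement\\(([^)]*)\\)", "\\1", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", parts))
  if (any(vapply(m, length, 1L) == 0L)) return(NULL)
  starts <- as.integer(vapply(m, `[`, "", 2))
  ends <- vapply(m, `[`, "", 4)
  ends <- as.integer(ifelse(is.na(ends) | ends == "", vapply(m, `[`, "", 2), ends))
  list(starts = starts, ends = ends, strand = strand)
}

gb_qualifier <- function(quals, name) {
  m <- regmatches(quals, regexec(paste0("/", name, '="?([^"\n]*)"?'), quals))[[1]]
  if (length(m) >= 2L) m[2] else NA_character_
}

resolve_genbank_features <- function(feats, n, path) {
  keep_kinds <- c("CDS", "tRNA", "rRNA")
  gene_names <- list()  # location string -> /gene name, from `gene` features
  tabs <- list()
  skipped <- character()
  for (f in feats) {
    if (f$key == "source") next
    loc <- parse_gb_location(f$location)
    if (is.null(loc)) {
      warning("unparseable location '", f$location, "' for ", f$key,
              " in ", path, call. = FALSE)
      next
    }
    nm <- gb_qualifier(f$qualifiers, "gene")
    if (f$key == "gene") {
      gene_names[[f$location]] <- nm
      next
    }
    if (!f$key %in% keep_kinds) {
      skipped <- c(skipped, f$key)
      next
    }
    if (any(loc$starts < 1L | loc$ends > n)) {
      stop("feature '", if (is.na(nm)) f$key else nm,
           "' has an interval outside the sequence [1, ", n, "] in ", path)
    }
    if (is.na(nm)) nm <- gb_qualifier(f$qualifiers, "product")
    if (is.na(nm)) nm <- f$key
    pseudo <- grepl("/pseudo", f$qualifiers, fixed = TRUE)
    trans <- grepl("trans.?splic", f$qualifiers, ignore.case = TRUE)
    o <- order(loc$starts)
    tabs[[length(tabs) + 1L]] <- gene_features(
      nm, f$key, loc$strand, loc$starts[o], loc$ends[o],
      pseudo = pseudo, trans_spliced = trans)
  }
  if (length(skipped)) {
    warning("ignored ", length(skipped), " feature(s) of unknown kind: ",
            paste(unique(skipped), collapse = ", "), call. = FALSE)
  }
  do.call(bind_features, tabs)
}
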