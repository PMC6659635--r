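# SNV and indel event extraction from a multiple alignment, outgroup
# polarization, context annotation, densities and spectra.

#' Extract polarized SNV and indel events from a multiple alignment
#'
#' SNVs: every column showing at least two of A/C/G/T among non-gap rows
#' yields one event per derived state; the ancestral state is the outgroup
#' residue. If the outgroup is gap or N in that column the event is flagged
#' `unpolarized` and the majority state (ties broken alphabetically) stands in
#' as provisional ancestral. Indels: maximal runs of consecutive columns
#' sharing an identical gap pattern form one event; taxa gapped where the
#' outgroup has residues carry a deletion, taxa with residues where the
#' outgroup is gapped carry an insertion. Overlapping indels from different
#' branches are split at gap-pattern boundaries, so a two-taxon shared gap is
#' one event (tree-polarized counting), not two. Runs with an identical gap
#' pattern separated only by columns in which every carrier taxon is also
#' gapped are merged back into one event: in the carrier genomes that gap is
#' contiguous, and the interrupting columns belong to other lineages' events
#' (the merged length counts only the event's own columns). Finally,
#' column-adjacent insertion runs whose carrier sets are strictly nested are
#' resolved Dollo-style: an inserted sequence originates once, so the pair
#' becomes one insertion carried by the larger set plus a secondary deletion
#' of the interior slice in the taxa missing it.
#'
#' @param a an `aligned_set`
#' @param outgroup outgroup taxon label (must be a row of the alignment)
#' @param reference reference taxon for genomic coordinates; default is the
#'   first ingroup taxon
#' @return data.frame of class `variant_events`: one row per event with
#'   columns `event_id`, `vtype` (`SNV`/`insertion`/`deletion`), `col_start`,
#'   `col_end`, `length`, `ref_pos` (position on the reference; insertions
#'   absent from the reference anchor at the left-flanking reference base),
#'   `ancestral`, `derived`, `presence` (comma-separated derived ingroup
#'   taxa), `unpolarized`, plus `region`/`context`/`ira_mirror` columns filled
#'   by [annotate_context()]
#' @export
extract_events <- function(a, outgroup, reference = NULL) {
  stopifnot(inherits(a, "aligned_set"))
  if (!outgroup %in% a$taxa) stop("outgroup '", outgroup, "' not in alignment")
  ingroup <- setdiff(a$taxa, outgroup)
  reference <- reference %||% ingroup[1]
  stopifnot(reference %in% a$taxa)
  m <- a$mat
  nc <- ncol(m)
  refmap <- column_coord_map(a, reference)
  ref_is_res <- m[reference, ] != "-"

  ev <- list()
  add <- function(vtype, cs, ce, ancestral, derived, presence, unpol) {
    # reference coordinate: first column where the reference has a residue,
    # else the left-flanking reference base
    cols <- cs:ce
    with_res <- cols[ref_is_res[cols]]
    rp <- if (length(with_res)) refmap[with_res[1]] else refmap[cs]
    ev[[length(ev) + 1L]] <<- data.frame(
      vtype = vtype, col_start = cs, col_end = ce,
      length = ce - cs + 1L, ref_pos = as.integer(rp),
      ancestral = ancestral, derived = derived,
      presence = paste(presence, collapse = ","),
      unpolarized = unpol, stringsAsFactors = FALSE)
  }

  ## ---- SNVs -------------------------------------------------------------
  base_counts <- vapply(c("A", "C", "G", "T"),
                        function(b) colSums(m == b), numeric(nc))
  if (nc == 1L) base_counts <- matrix(base_counts, nrow = 1L,
                                      dimnames = list(NULL, c("A", "C", "G", "T")))
  snv_cols <- which(rowSums(base_counts > 0L) >= 2L)
  for (cc in snv_cols) {
    col <- m[, cc]
    og <- col[[outgroup]]
    states <- colnames(base_counts)[base_counts[cc, ] > 0L]
    if (og %in% c("A", "C", "G", "T")) {
      anc <- og; unpol <- FALSE
    } else {
      cnt <- base_counts[cc, states]
      anc <- states[order(-cnt, states)][1]
      unpol <- TRUE
    }
    for (st in setdiff(states, anc)) {
      carriers <- ingroup[col[ingroup] == st]
      if (!length(carriers)) next  # derived state only in the outgroup
      add("SNV", cc, cc, anc, st, carriers, unpol)
    }
  }

  ## ---- indels -----------------------------------------------------------
  gap <- m == "-"
  w <- 2^(seq_len(nrow(m)) - 1L)
  pattern <- as.vector(w %*% gap)   # exact for <= 53 taxa
  if (nrow(m) > 53L) pattern <- match(apply(gap, 2L, paste, collapse = ""),
                                      unique(apply(gap, 2L, paste, collapse = "")))
  r <- rle(pattern)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values != 0)) {
    cs <- starts[i]; ce <- ends[i]
    gapped <- rownames(m)[gap[, cs]]
    if (outgroup %in% gapped) {
      carriers <- setdiff(ingroup, gapped)
      if (!length(carriers)) next   # gap shared by outgroup and all ingroup
      add("insertion", cs, ce, "-", "seq", carriers, FALSE)
    } else {
      carriers <- intersect(ingroup, gapped)
      if (!length(carriers)) next   # outgroup-only gap: deletion on outgroup branch
      add("deletion", cs, ce, "seq", "-", carriers, FALSE)
    }
  }

  out <- if (length(ev)) do.call(rbind, ev) else data.frame(
    vtype = character(), col_start = integer(), col_end = integer(),
    length = integer(), ref_pos = integer(), ancestral = character(),
    derived = character(), presence = character(), unpolarized = logical(),
    stringsAsFactors = FALSE)
  out <- merge_nested_runs(out, gap)
  out <- resolve_nested_insertions(out, gap)
  out <- out[order(out$col_start, out$vtype, out$derived), ]
  out$event_id <- seq_len(NROW(out))
  out$region <- NA_character_
  out$context <- NA_character_
  out$ira_mirror <- FALSE
  rownames(out) <- NULL
  class(out) <- c("variant_events", "data.frame")
  out
}

# merge same-pattern indel runs whose separating columns are gapped in all
# carrier taxa (one contiguous gap in the carrier genomes, interrupted in the
# alignment by other lineages' events)
merge_nested_runs <- function(out, gap) {
  ind <- which(out$vtype %in% c("insertion", "deletion"))
  if (length(ind) < 2L) return(out)
  drop <- logical(NROW(out))
  key <- paste(out$vtype, out$presence)
  for (grp in split(ind, key[ind])) {
    if (length(grp) < 2L) next
    grp <- grp[order(out$col_start[grp])]
    carriers <- strsplit(out$presence[grp[1]], ",", fixed = TRUE)[[1]]
    cur <- grp[1]
    for (x in grp[-1]) {
      between <- (out$col_end[cur] + 1L):(out$col_start[x] - 1L)
      if (length(between) &&
          all(gap[carriers, between, drop = FALSE])) {
        out$col_end[cur] <- out$col_end[x]
        out$length[cur] <- out$length[cur] + out$length[x]
        drop[x] <- TRUE
      } else {
        cur <- x
      }
    }
  }
  out[!drop, , drop = FALSE]
}

# Dollo-style resolution of nested insertion fragments. An inserted sequence
# originates once, so adjacent insertion runs with nested carrier sets are
# re-read as one event where the evidence supports it:
#   (i)  sandwich [big][small][big]: an insertion interrupted by a younger
#        insertion in a nested subclade - the outer fragments are merged into
#        one insertion, the interior one stays its own insertion;
#   (ii) pair [big][small] flanked by a deletion event whose carriers are
#        exactly the taxa missing the small fragment: a deletion overhanging
#        from root sequence into the insertion - the fragments are merged
#        into one insertion and the flanking deletion absorbs the interior
#        columns into its length.
# A nested pair with neither corroboration stays two independent insertions:
# the alignment cannot distinguish that from an edge insertion, and
# insertions inside insertions are real. Deletion runs are never rewritten -
# unlike an inserted sequence, a deletion can recur independently.
resolve_nested_insertions <- function(out, gap) {
  pres <- function(i) strsplit(out$presence[i], ",", fixed = TRUE)[[1]]
  gapped_between <- function(rows, c1, c2) {
    c2 < c1 || all(gap[rows, c1:c2, drop = FALSE])
  }
  repeat {
    ins_idx <- which(out$vtype == "insertion")
    ins_idx <- ins_idx[order(out$col_start[ins_idx])]
    changed <- FALSE

    # (i) sandwich: merge the outer fragments of [big][small][big]
    if (length(ins_idx) >= 3L) {
      for (k in seq_len(length(ins_idx) - 2L)) {
        a <- ins_idx[k]; b <- ins_idx[k + 1L]; c_ <- ins_idx[k + 2L]
        pa <- pres(a); pb <- pres(b); pc <- pres(c_)
        if (!identical(sort(pa), sort(pc))) next
        if (!(all(pb %in% pa) && length(pb) < length(pa))) next
        if (!gapped_between(pa, out$col_end[a] + 1L, out$col_start[b] - 1L) ||
            !gapped_between(pa, out$col_end[b] + 1L, out$col_start[c_] - 1L)) next
        out$col_end[a] <- out$col_end[c_]
        out$length[a] <- out$length[a] + out$length[c_]
        out <- out[-c_, , drop = FALSE]
        changed <- TRUE
        break
      }
    }
    if (changed) next

    # (ii) pair corroborated by an abutting deletion of the missing taxa
    if (length(ins_idx) >= 2L) {
      for (k in seq_len(length(ins_idx) - 1L)) {
        a <- ins_idx[k]; b <- ins_idx[k + 1L]
        if (out$col_end[a] >= out$col_start[b]) next   # already containing
        pa <- pres(a); pb <- pres(b)
        if (length(pa) == length(pb)) {
          if (!identical(sort(pa), sort(pb))) next
          if (!gapped_between(pa, out$col_end[a] + 1L,
                              out$col_start[b] - 1L)) next
          out$col_end[a] <- out$col_end[b]
          out$length[a] <- out$length[a] + out$length[b]
          out <- out[-b, , drop = FALSE]
          changed <- TRUE
          break
        }
        nested <- all(pa %in% pb) || all(pb %in% pa)
        if (!nested) next
        big <- if (length(pa) > length(pb)) pa else pb
        small_i <- if (length(pa) < length(pb)) a else b
        lost <- sort(setdiff(big, pres(small_i)))
        if (!gapped_between(big, out$col_end[a] + 1L,
                            out$col_start[b] - 1L)) next
        # deletion with carriers == lost abutting the pair on either side
        del_idx <- which(out$vtype == "deletion")
        hit <- NA_integer_
        for (d in del_idx) {
          if (!identical(sort(pres(d)), lost)) next
          left_ok <- out$col_end[d] < out$col_start[a] &&
            gapped_between(big, out$col_end[d] + 1L, out$col_start[a] - 1L)
          right_ok <- out$col_start[d] > out$col_end[b] &&
            gapped_between(big, out$col_end[b] + 1L, out$col_start[d] - 1L)
          if (left_ok || right_ok) { hit <- d; break }
        }
        if (is.na(hit)) next
        out$length[hit] <- out$length[hit] + out$length[small_i]
        out$presence[a] <- paste(big, collapse = ",")
        out$col_end[a] <- out$col_end[b]
        out$length[a] <- out$length[a] + out$length[b]
        out <- out[-b, , drop = FALSE]
        changed <- TRUE
        break
      }
    }
    if (!changed) return(out)
  }
}

#' Annotate events with genomic region and feature context
#'
#' Region (`LSC`/`IRb`/`SSC`/`IRa`) is assigned from the reference partition
#' at the event's reference coordinate. Context follows the precedence
#' CDS-exon > RNA-gene > intron > intergenic when features overlap.
#' Trans-spliced features are excluded from intron-context assignment (their
#' "intron" is not a spliceosomal gap between adjacent exons). Events in IRa
#' whose type, length and presence match an IRb event at the mirrored
#' coordinate (within `mirror_tol` bp) are flagged `ira_mirror`, so each IR
#' mutation is counted once.
#'
#' @param events a `variant_events` frame from [extract_events()]
#' @param reference a [plastome()] carrying features and a `partition`
#' @param mirror_tol tolerance in bp for IRa/IRb mirror matching
#' @return the events frame with `region`, `context`, `ira_mirror` filled
#' @export
annotate_context <- function(events, reference, mirror_tol = 5L) {
  stopifnot(inherits(reference, "plastome"))
  q <- reference$partition
  if (is.null(q)) stop("reference plastome has no quadripartite partition")
  if (!NROW(events)) return(events)
  if (any(events$ref_pos > reference$length | events$ref_pos < 0L)) {
    stop("event coordinate outside the reference genome")
  }
  pos <- pmax(events$ref_pos, 1L)   # ref_pos 0 = insertion before base 1
  events$region <- region_at(q, pos)
  events$context <- context_at(reference, pos)
  ## IRa mirror flagging
  cpos <- to_canonical(q, pos)
  j <- q$junctions
  in_ira <- events$region == "IRa"
  if (any(in_ira)) {
    mirror <- q$length + j[["JLB"]] + 1L - cpos  # IRa pos -> mirrored IRb pos
    for (x in which(in_ira)) {
      hit <- which(events$region == "IRb" &
                     events$vtype == events$vtype[x] &
                     events$length == events$length[x] &
                     events$presence == events$presence[x] &
                     abs(cpos - mirror[x]) <= mirror_tol)
      if (length(hit)) events$ira_mirror[x] <- TRUE
    }
  }
  events
}

# context label at reference positions: CDS-exon > RNA-gene > intron > intergenic
context_at <- function(p, pos) {
  f <- p$features
  out <- rep("intergenic", length(pos))
  if (!NROW(f)) return(out)
  ex <- IRanges::IRanges(f$start, f$end)
  q <- IRanges::IRanges(pos, pos)
  hit <- IRanges::findOverlaps(q, ex)
  kind <- f$kind[S4Vectors::subjectHits(hit)]
  qh <- S4Vectors::queryHits(hit)
  is_rna <- kind %in% c("tRNA", "rRNA")
  out[unique(qh[is_rna])] <- "RNA-gene"
  # introns: gaps between consecutive exons of one (cis-spliced) feature
  introns <- do.call(rbind, lapply(split(f, f$feature_id), function(e) {
    if (NROW(e) < 2L || any(e$trans_spliced)) return(NULL)
    e <- e[order(e$exon_rank), ]
    data.frame(start = e$end[-NROW(e)] + 1L, end = e$start[-1L] - 1L)
  }))
  if (!is.null(introns) && NROW(introns)) {
    introns <- introns[introns$start <= introns$end, , drop = FALSE]
    if (NROW(introns)) {
      ih <- IRanges::findOverlaps(q, IRanges::IRanges(introns$start, introns$end))
      out[unique(S4Vectors::queryHits(ih))] <- "intron"
    }
  }
  out[unique(qh[is_rna])] <- "RNA-gene"          # RNA gene beats intron
  out[unique(qh[kind == "CDS"])] <- "CDS-exon"   # CDS exon beats everything
  out
}

#' Per-region variant density table
#'
#' Counts and counts-per-kb of SNVs, insertions and deletions per taxon and
#' region, against each taxon's own region lengths. The two IR copies are
#' pooled as one `IR` region by default and IRa-mirror duplicates are counted
#' once. The genus-wide mean is the unweighted mean over ingroup taxa.
#'
#' @param events annotated `variant_events`
#' @param partitions either one `quad_partition` (used for every taxon) or a
#'   named list of partitions per taxon
#' @param taxa ingroup taxon labels to tabulate; default: all taxa seen in
#'   presence strings
#' @param pool_ir pool the IR copies for reporting (default TRUE)
#' @return data.frame with columns `taxon`, `region` (including `genome`),
#'   `vtype`, `count`, `per_kb`; taxon `"mean"` rows hold the unweighted mean
#' @export
density_table <- function(events, partitions, taxa = NULL, pool_ir = TRUE) {
  ev <- events[!events$ira_mirror, , drop = FALSE]
  if (is.null(taxa)) {
    taxa <- sort(unique(unlist(strsplit(ev$presence, ",", fixed = TRUE))))
  }
  vtypes <- c("SNV", "deletion", "insertion")
  get_part <- function(t) if (inherits(partitions, "quad_partition")) partitions else partitions[[t]]
  rows <- list()
  for (t in taxa) {
    q <- get_part(t)
    rl <- region_lengths(q, pool_ir = pool_ir)
    carried <- ev[vapply(strsplit(ev$presence, ",", fixed = TRUE),
                         function(x) t %in% x, TRUE), , drop = FALSE]
    reg <- carried$region
    if (pool_ir) reg[reg %in% c("IRa", "IRb")] <- "IR"
    for (v in vtypes) {
      for (r in names(rl)) {
        cnt <- sum(carried$vtype == v & reg == r)
        rows[[length(rows) + 1L]] <- data.frame(
          taxon = t, region = r, vtype = v, count = cnt,
          per_kb = if (rl[[r]] > 0L) 1000 * cnt / rl[[r]] else NA_real_)
      }
      cnt <- sum(carried$vtype == v)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = t, region = "genome", vtype = v, count = cnt,
        per_kb = 1000 * cnt / q$length)
    }
  }
  tab <- do.call(rbind, rows)
  means <- stats::aggregate(cbind(count, per_kb) ~ region + vtype, tab, mean)
  means <- data.frame(taxon = "mean", means[, c("region", "vtype")],
                      count = means$count, per_kb = means$per_kb)
  out <- rbind(tab, means)
  rownames(out) <- NULL
  out
}

#' Indel length spectrum and summary fractions
#'
#' @param events `variant_events` (SNVs are ignored)
#' @return list with `lengths` (raw indel lengths), `bins` (counts in 1,
#'   2-9, 10-99, 100+), `frac_lt10`, `frac_lt100`, and
#'   `frac_multiple_of_3_in_cds` computed over CDS-exon events only
#' @export
indel_spectrum <- function(events) {
  ind <- events[events$vtype %in% c("insertion", "deletion") &
                  !events$ira_mirror, , drop = FALSE]
  len <- ind$length
  bins <- c(`1` = sum(len == 1L), `2-9` = sum(len >= 2L & len <= 9L),
            `10-99` = sum(len >= 10L & len <= 99L), `100+` = sum(len >= 100L))
  cds <- ind$length[!is.na(ind$context) & ind$context == "CDS-exon"]
  list(lengths = len, bins = bins,
       frac_lt10 = if (length(len)) mean(len < 10L) else NA_real_,
       frac_lt100 = if (length(len)) mean(len < 100L) else NA_real_,
       frac_multiple_of_3_in_cds =
         if (length(cds)) mean(cds %% 3L == 0L) else NA_real_)
}

#' Export variant events as TSV (and optionally a VCF-like file)
#'
#' The TSV round-trips through [import_variants()]. The VCF-like file uses
#' the reference taxon as REF with 1-based POS; deletions are written
#' left-anchored at `ref_pos - 1` with symbolic ALT, and multi-taxon presence
#' is carried in the `CARRIERS` INFO tag.
#'
#' @param events `variant_events`
#' @param path output TSV path
#' @param vcf_path optional output path for the VCF-like file
#' @param ref_id reference taxon label written in the VCF header
#' @return `path`, invisibly
#' @export
export_variants <- function(events, path, vcf_path = NULL, ref_id = "reference") {
  cols <- c("event_id", "vtype", "col_start", "col_end", "length", "ref_pos",
            "ancestral", "derived", "presence", "unpolarized", "region",
            "context", "ira_mirror")
  utils::write.table(as.data.frame(events)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(vcf_path)) {
    con <- file(vcf_path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2-like",
                 paste0("##reference=", ref_id),
                 "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Event length\">",
                 "##INFO=<ID=CARRIERS,Number=1,Type=String,Description=\"Derived taxa\">",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    for (i in seq_len(NROW(events))) {
      e <- events[i, ]
      if (e$vtype == "SNV") {
        pos <- e$ref_pos; ref <- e$ancestral; alt <- e$derived
      } else if (e$vtype == "deletion") {
        pos <- max(e$ref_pos - 1L, 1L); ref <- "N"; alt <- "<DEL>"
      } else {
        pos <- max(e$ref_pos, 1L); ref <- "N"; alt <- "<INS>"
      }
      writeLines(sprintf("%s\t%d\tev%d\t%s\t%s\t.\t.\tSVLEN=%d;CARRIERS=%s",
                         ref_id, pos, e$event_id, ref, alt, e$length,
                         e$presence), con)
    }
  }
  invisible(path)
}

#' Re-import a variant TSV written by [export_variants()]
#' @param path TSV file
#' @return `variant_events` data.frame
#' @export
import_variants <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(presence = "character",
                                         ancestral = "character",
                                         derived = "character"))
  ev$region <- as.character(ev$region)
  ev$context <- as.character(ev$context)
  class(ev) <- c("variant_events", "data.frame")
  ev
}
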