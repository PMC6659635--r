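# Detection of the plastome quadripartite structure (LSC / IRb / SSC / IRa)
# and junction-to-gene distance reporting.

#' Detect the quadripartite partition of a plastome
#'
#' Finds the maximal-length pair of exact inverted repeats of at least
#' `min_ir_len` bases on the circular genome (seed-and-extend on exact
#' k-mers, merged into maximal runs; the search is performed on the doubled
#' sequence so repeats spanning the deposited origin are found). The two arcs
#' between the IR copies become the single-copy regions; the longer arc is
#' labelled LSC. The partition is reported in canonical rotation (LSC starts
#' at position 1; order LSC, IRb, SSC, IRa), with `offset` mapping canonical
#' back to deposit coordinates.
#'
#' @param p a [plastome()] or a plain DNA string
#' @param min_ir_len minimum IR length in bases (default 1000)
#' @param k seed k-mer size
#' @return object of class `quad_partition`: intervals `lsc`, `irb`, `ssc`,
#'   `ira` (1-based closed, canonical coordinates), `junctions` (JLB, JSB,
#'   JSA, JLA: the canonical coordinate of the last base of the upstream
#'   region), `offset` (canonical position x maps to deposit position
#'   `((x - 1 + offset) %% length) + 1`), `length`, `ir_len`
#' @export
#' @examples
#' set.seed(1)
#' arm <- random_dna(200)
#' g <- paste0(random_dna(800), arm, random_dna(300), revcomp_chr(arm))
#' detect_quadripartite(g, min_ir_len = 100)
detect_quadripartite <- function(p, min_ir_len = 1000L, k = 25L) {
  s <- if (inherits(p, "plastome")) p$seq else sanitize_dna(p)
  n <- nchar(s)
  s2 <- paste0(s, s)
  r <- inverted_runs(s2, min_ir_len, k = k, disjoint = TRUE)
  if (nrow(r)) {
    r$len <- pmin(r$len, n)
    r$a <- ((r$i - 1L) %% n) + 1L
    r$b <- ((r$j - 1L) %% n) + 1L
    # canonical circular identity of a pair: unordered arm starts mod n + len
    key <- paste(pmin(r$a, r$b), pmax(r$a, r$b), r$len)
    r <- r[!duplicated(key), ]
    # arms must be disjoint on the circle and leave two arcs
    gap1 <- (r$b - (r$a + r$len)) %% n
    gap2 <- (r$a - (r$b + r$len)) %% n
    ok <- r$len <= n %/% 2L & (gap1 + gap2 + 2L * r$len) == n
    r <- r[ok, ]
  }
  if (!nrow(r)) {
    stop("NoIRStructure: no inverted repeat pair of length >= ", min_ir_len,
         " found; genome treated as IR-lacking")
  }
  r <- r[order(-r$len, r$a), ]
  best <- r[1L, ]
  build_quad_partition(n, best$a, best$b, best$len)
}

# assemble the canonical partition from the two arm starts (deposit coords)
build_quad_partition <- function(n, a, b, len) {
  arc_after_A <- (b - (a + len)) %% n   # arc from end of arm A to start of arm B
  arc_after_B <- (a - (b + len)) %% n
  if (arc_after_A >= arc_after_B) {
    lsc_start <- ((a + len - 1L) %% n) + 1L   # first base after arm A
    lsc_len <- arc_after_A
    ssc_len <- arc_after_B
    irb_start <- b
  } else {
    lsc_start <- ((b + len - 1L) %% n) + 1L
    lsc_len <- arc_after_B
    ssc_len <- arc_after_A
    irb_start <- a
  }
  if (lsc_len == 0L || ssc_len == 0L) {
    stop("degenerate partition: a single-copy arc has zero length")
  }
  structure(list(
    lsc = c(1L, lsc_len),
    irb = c(lsc_len + 1L, lsc_len + len),
    ssc = c(lsc_len + len + 1L, lsc_len + len + ssc_len),
    ira = c(lsc_len + len + ssc_len + 1L, n),
    junctions = c(JLB = lsc_len,
                  JSB = lsc_len + len,
                  JSA = lsc_len + len + ssc_len,
                  JLA = n),
    offset = lsc_start - 1L,
    length = n,
    ir_len = len
  ), class = "quad_partition")
}

#' @export
print.quad_partition <- function(x, ...) {
  cat("quadripartite partition (", x$length, " bp genome, IR ", x$ir_len,
      " bp)\n", sep = "")
  for (r in c("lsc", "irb", "ssc", "ira")) {
    cat(sprintf("  %-4s %8d..%-8d (%d bp)\n", toupper(r), x[[r]][1],
                x[[r]][2], x[[r]][2] - x[[r]][1] + 1L))
  }
  invisible(x)
}

#' Map deposit coordinates to canonical partition coordinates
#' @param q a `quad_partition`
#' @param pos positions in deposit coordinates
#' @return positions in canonical coordinates (LSC starts at 1)
#' @export
to_canonical <- function(q, pos) ((pos - 1L - q$offset) %% q$length) + 1L

#' Map canonical partition coordinates back to deposit coordinates
#' @param q a `quad_partition`
#' @param pos positions in canonical coordinates
#' @return positions in deposit coordinates
#' @export
to_deposit <- function(q, pos) ((pos - 1L + q$offset) %% q$length) + 1L

#' Region label at genome positions
#' @param q a `quad_partition`
#' @param pos positions in deposit coordinates
#' @return character vector over `"LSC"`, `"IRb"`, `"SSC"`, `"IRa"`
#' @export
region_at <- function(q, pos) {
  cpos <- to_canonical(q, pos)
  j <- q$junctions
  out <- character(length(cpos))
  out[cpos <= j["JLB"]] <- "LSC"
  out[cpos > j["JLB"] & cpos <= j["JSB"]] <- "IRb"
  out[cpos > j["JSB"] & cpos <= j["JSA"]] <- "SSC"
  out[cpos > j["JSA"]] <- "IRa"
  out
}

#' Region lengths of a partition, with the two IR copies pooled
#' @param q a `quad_partition`
#' @param pool_ir pool IRa+IRb as one `"IR"` region (default TRUE)
#' @return named integer vector of region lengths in bases
#' @export
region_lengths <- function(q, pool_ir = TRUE) {
  len <- function(iv) iv[2] - iv[1] + 1L
  if (pool_ir) {
    c(LSC = len(q$lsc), IR = len(q$irb) + len(q$ira), SSC = len(q$ssc))
  } else {
    c(LSC = len(q$lsc), IRb = len(q$irb), SSC = len(q$ssc), IRa = len(q$ira))
  }
}

#' Gene-to-junction distance table
#'
#' For each of the four junctions, reports the nearest feature end on each
#' side and the gap in bases; genes straddling a junction are reported with
#' distance 0 and `spans = TRUE`.
#'
#' @param p a [plastome()] with features
#' @param q a `quad_partition` for `p`
#' @return data.frame with columns `junction`, `side`
#'   (`"upstream"`/`"downstream"`/`"spans"`), `gene`, `distance` (bp)
#' @export
junction_gene_distances <- function(p, q) {
  stopifnot(inherits(p, "plastome"), inherits(q, "quad_partition"))
  f <- p$features
  out <- data.frame(junction = character(), side = character(),
                    gene = character(), distance = integer(),
                    stringsAsFactors = FALSE)
  if (!NROW(f)) return(out)
  n <- q$length
  # whole-gene extents in canonical coordinates (one row per feature)
  genes <- do.call(rbind, lapply(split(f, f$feature_id), function(ex) {
    cs <- to_canonical(q, ex$start)
    ce <- to_canonical(q, ex$end)
    # extent on the circle: smallest arc containing all exon bases
    gs <- min(cs); ge <- max(ce)
    if (ge - gs > n %/% 2L) { # wraps the canonical origin
      gs <- min(cs[cs > n %/% 2L]); ge <- max(ce[ce <= n %/% 2L])
    }
    data.frame(gene = ex$name[1], gs = gs, ge = ge)
  }))
  span_len <- (genes$ge - genes$gs) %% n
  rows <- list()
  for (jn in names(q$junctions)) {
    j <- q$junctions[[jn]]
    covers <- ((j - genes$gs) %% n) <= span_len &
      (((j %% n) + 1L - genes$gs) %% n) <= span_len
    for (g in which(covers)) {
      rows[[length(rows) + 1L]] <- data.frame(
        junction = jn, side = "spans", gene = genes$gene[g], distance = 0L)
    }
    free <- !covers
    if (any(free)) {
      gap_up <- (j - genes$ge[free]) %% n
      gap_dn <- (genes$gs[free] - j - 1L) %% n
      iu <- which.min(gap_up); idn <- which.min(gap_dn)
      rows[[length(rows) + 1L]] <- data.frame(
        junction = jn, side = "upstream",
        gene = genes$gene[free][iu], distance = as.integer(gap_up[iu]))
      rows[[length(rows) + 1L]] <- data.frame(
        junction = jn, side = "downstream",
        gene = genes$gene[free][idn], distance = as.integer(gap_dn[idn]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the four partition regions as a BED file
#'
#' Regions are written in deposit coordinates; a region that wraps the
#' deposited origin is written as two BED lines.
#'
#' @param q a `quad_partition`
#' @param genome_id sequence name for the BED records
#' @param path output BED file
#' @return `path`, invisibly
#' @export
write_partition_bed <- function(q, genome_id, path) {
  rows <- list()
  for (r in c("lsc", "irb", "ssc", "ira")) {
    iv <- q[[r]]
    s <- to_deposit(q, iv[1]); e <- to_deposit(q, iv[2])
    if (s <= e) {
      rows[[length(rows) + 1L]] <- data.frame(start = s, end = e, name = toupper(r))
    } else { # wraps deposited origin
      rows[[length(rows) + 1L]] <- data.frame(start = s, end = q$length, name = toupper(r))
      rows[[length(rows) + 1L]] <- data.frame(start = 1L, end = e, name = toupper(r))
    }
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(genome_id,
                               IRanges::IRanges(tab$start, tab$end),
                               name = tab$name)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
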