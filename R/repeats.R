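# Exact-match detection of tandem (Rt), palindromic (Rp) and dispersed (Rd)
# repeats and perfect microsatellites (SSRs); grouping of shared repeats
# across genomes; repeat gain/loss placement on the timetree.

repeat_frame <- function() {
  data.frame(genome = character(), category = character(),
             unit_length = integer(), start = integer(), end = integer(),
             start2 = integer(), end2 = integer(), copies = integer(),
             span = integer(), unit = character(), motif = character(),
             stringsAsFactors = FALSE)
}

# period-u equality vector with N never matching
period_eq <- function(chars, u) {
  n <- length(chars)
  if (n <= u) return(logical(0))
  a <- chars[1:(n - u)]; b <- chars[(u + 1):n]
  a == b & a != "N" & b != "N"
}

# maximal periodic regions of exact period u: start, end (incl. partial
# trailing copy), full-copy count
periodic_regions <- function(chars, u, min_copies = 2L) {
  eq <- period_eq(chars, u)
  if (!length(eq)) return(data.frame(start = integer(), end = integer(),
                                     copies = integer()))
  r <- true_runs(eq)
  m <- r$end - r$start + 1L
  keep <- m >= u * (min_copies - 1L)
  data.frame(start = r$start[keep], end = r$end[keep] + u,
             copies = (m[keep] + u) %/% u)
}

# smallest exact period of a substring (1 if mononucleotide run, etc.)
smallest_period <- function(chars) {
  L <- length(chars)
  for (p in seq_len(L - 1L)) {
    if (all(chars[1:(L - p)] == chars[(p + 1):L])) return(p)
  }
  L
}

#' Find tandem repeats (Rt)
#'
#' Maximal arrays of at least `min_copies` adjacent exact copies of a unit of
#' at least `min_unit` bases. Each array is reported once, at the smallest
#' unit length >= `min_unit` it supports; an array whose interval is contained
#' in a reported array with a smaller unit is suppressed. Reported intervals
#' include a partial trailing copy when present; `copies` counts full copies.
#'
#' @param seq DNA string (or [plastome()])
#' @param min_unit minimum unit length in bases (default 15)
#' @param min_copies minimum number of full copies (default 2)
#' @param max_unit largest unit length scanned (default 1000, capped at half
#'   the sequence length)
#' @return repeat occurrence data.frame (`category = "Rt"`)
#' @export
find_tandem <- function(seq, min_unit = 15L, min_copies = 2L,
                        max_unit = 1000L) {
  s <- if (inherits(seq, "plastome")) seq$seq else toupper(seq)
  chars <- seq_chars(s)
  n <- length(chars)
  max_unit <- min(max_unit, n %/% 2L)
  hits <- list()
  for (u in seq(from = min_unit, length.out = max(0L, max_unit - min_unit + 1L))) {
    pr <- periodic_regions(chars, u, min_copies)
    if (nrow(pr)) hits[[length(hits) + 1L]] <- cbind(pr, u = u)
  }
  if (!length(hits)) return(repeat_frame())
  h <- do.call(rbind, hits)
  h <- h[order(h$u, h$start), ]
  # keep the smallest unit for an interval; drop intervals contained in a
  # kept array with smaller (or equal) unit
  keep <- rep(TRUE, nrow(h))
  for (x in seq_len(nrow(h))) {
    if (!keep[x]) next
    prior <- which(keep & seq_len(nrow(h)) < x)
    if (any(h$start[x] >= h$start[prior] & h$end[x] <= h$end[prior])) {
      keep[x] <- FALSE
    }
  }
  h <- h[keep, ]
  data.frame(genome = NA_character_, category = "Rt",
             unit_length = h$u, start = h$start, end = h$end,
             start2 = NA_integer_, end2 = NA_integer_, copies = h$copies,
             span = h$end - h$start + 1L,
             unit = substring(s, h$start, h$start + h$u - 1L),
             motif = NA_character_, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Find palindromic repeats (Rp)
#'
#' Maximal exact inverted pairs: a segment and, further along the sequence,
#' its reverse complement, both of length at least `min_len`, with disjoint
#' arms. Pairs whose both arms are contained within a longer reported pair
#' are suppressed.
#'
#' @param seq DNA string (or [plastome()]); mask one IR copy first when
#'   scanning a whole plastome (see [find_repeats()])
#' @param min_len minimum arm length in bases (default 20)
#' @return repeat occurrence data.frame (`category = "Rp"`)
#' @export
find_palindromic <- function(seq, min_len = 20L) {
  s <- if (inherits(seq, "plastome")) seq$seq else toupper(seq)
  r <- inverted_runs(s, min_len, disjoint = TRUE)
  r <- drop_contained_pairs(r)
  if (!nrow(r)) return(repeat_frame())
  data.frame(genome = NA_character_, category = "Rp",
             unit_length = r$len, start = r$i, end = r$i + r$len - 1L,
             start2 = r$j, end2 = r$j + r$len - 1L, copies = 2L,
             span = 2L * r$len,
             unit = substring(s, r$i, r$i + r$len - 1L),
             motif = NA_character_, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Find dispersed repeats (Rd)
#'
#' Maximal exact direct (same-strand) pairs of length at least `min_len`
#' whose copies are neither adjacent (that is a tandem) nor overlapping
#' (that is a periodic array). Contained pairs are suppressed; pairs whose
#' both arms fall inside a single interval of `exclude` (e.g. reported
#' tandem arrays) are dropped, implementing the Rt > Rd precedence.
#'
#' @param seq DNA string (or [plastome()])
#' @param min_len minimum copy length in bases (default 30)
#' @param exclude optional data.frame with `start`/`end` intervals
#' @return repeat occurrence data.frame (`category = "Rd"`)
#' @export
find_dispersed <- function(seq, min_len = 30L, exclude = NULL) {
  s <- if (inherits(seq, "plastome")) seq$seq else toupper(seq)
  r <- direct_runs(s, min_len)
  r <- r[r$j - r$i > r$len, , drop = FALSE]   # non-adjacent, non-overlapping
  r <- drop_contained_pairs(r)
  if (!is.null(exclude) && NROW(exclude) && nrow(r)) {
    drop <- vapply(seq_len(nrow(r)), function(x) {
      any(r$i[x] >= exclude$start & r$j[x] + r$len[x] - 1L <= exclude$end)
    }, TRUE)
    r <- r[!drop, , drop = FALSE]
  }
  if (!nrow(r)) return(repeat_frame())
  data.frame(genome = NA_character_, category = "Rd",
             unit_length = r$len, start = r$i, end = r$i + r$len - 1L,
             start2 = r$j, end2 = r$j + r$len - 1L, copies = 2L,
             span = 2L * r$len,
             unit = substring(s, r$i, r$i + r$len - 1L),
             motif = NA_character_, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Find perfect microsatellites (SSRs)
#'
#' Perfect arrays of a primitive 2-5 bp unit whose total span (including a
#' partial trailing copy) meets the class threshold. Mononucleotide runs are
#' excluded, and a non-primitive unit (e.g. ATAT for an AT array) is never
#' reported. The motif is canonicalized by rotation only, never by
#' complementation, so counts are strand-specific.
#'
#' @param seq DNA string (or [plastome()])
#' @param thresholds named minimum spans in bases per unit length (defaults:
#'   di 8, tri 9, tetra 12, penta 15)
#' @return repeat occurrence data.frame (`category = "SSR"`)
#' @export
find_ssrs <- function(seq, thresholds = c(`2` = 8L, `3` = 9L, `4` = 12L,
                                          `5` = 15L)) {
  s <- if (inherits(seq, "plastome")) seq$seq else toupper(seq)
  chars <- seq_chars(s)
  rows <- list()
  for (u in as.integer(names(thresholds))) {
    pr <- periodic_regions(chars, u, min_copies = 2L)
    if (!nrow(pr)) next
    pr <- pr[pr$end - pr$start + 1L >= thresholds[[as.character(u)]], ,
             drop = FALSE]
    for (x in seq_len(nrow(pr))) {
      reg <- chars[pr$start[x]:pr$end[x]]
      if (any(reg == "N")) next
      if (smallest_period(reg) != u) next   # primitive units only
      unit <- paste(reg[1:u], collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        genome = NA_character_, category = "SSR", unit_length = u,
        start = pr$start[x], end = pr$end[x], start2 = NA_integer_,
        end2 = NA_integer_, copies = pr$copies[x],
        span = pr$end[x] - pr$start[x] + 1L, unit = unit,
        motif = canonical_rotation(unit), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(repeat_frame())
  out <- do.call(rbind, rows)
  out[order(out$start, out$unit_length), ]
}

# lexicographically smallest rotation of a unit
canonical_rotation <- function(unit) {
  u <- nchar(unit)
  rots <- vapply(seq_len(u), function(i) {
    paste0(substring(unit, i, u), substring(unit, 1, i - 1L))
  }, "")
  sort(rots)[1]
}

#' Scan a plastome for all repeat categories
#'
#' Runs the four finders with the Rt > Rp > Rd precedence applied (arms fully
#' inside a tandem array are not re-reported as dispersed or palindromic).
#' When a quadripartite partition is available and `mask_ira = TRUE`, the IRa
#' copy is masked with N first, so the genome-scale IR does not dominate the
#' palindromic output and every category is scanned over the same space.
#'
#' @param p a [plastome()] (partition used for masking if present) or string
#' @param min_tandem,min_palindromic,min_dispersed minimal copy sizes in bp
#' @param ssr_thresholds SSR class thresholds, see [find_ssrs()]
#' @param mask_ira mask the IRa copy before scanning (default TRUE)
#' @return combined repeat occurrence data.frame with `genome` filled
#' @export
find_repeats <- function(p, min_tandem = 15L, min_palindromic = 20L,
                         min_dispersed = 30L,
                         ssr_thresholds = c(`2` = 8L, `3` = 9L, `4` = 12L,
                                            `5` = 15L),
                         mask_ira = TRUE) {
  if (inherits(p, "plastome")) {
    s <- p$seq; id <- p$id; q <- p$partition
  } else {
    s <- toupper(p); id <- NA_character_; q <- NULL
  }
  if (mask_ira && !is.null(q)) {
    ira <- sort(to_deposit(q, q$ira[1]:q$ira[2]))
    ch <- seq_chars(s); ch[ira] <- "N"; s <- paste(ch, collapse = "")
  }
  rt <- find_tandem(s, min_unit = min_tandem)
  rp <- find_palindromic(s, min_len = min_palindromic)
  if (nrow(rt) && nrow(rp)) {
    inside <- vapply(seq_len(nrow(rp)), function(x) {
      any(rp$start[x] >= rt$start & rp$end2[x] <= rt$end)
    }, TRUE)
    rp <- rp[!inside, , drop = FALSE]
  }
  rd <- find_dispersed(s, min_len = min_dispersed,
                       exclude = rt[, c("start", "end"), drop = FALSE])
  ssr <- find_ssrs(s, thresholds = ssr_thresholds)
  out <- rbind(rt, rp, rd, ssr)
  out$genome <- id
  rownames(out) <- NULL
  out
}

#' Verify that reported repeat copies reproduce their units exactly
#' @param seq the scanned sequence (post-masking)
#' @param occ occurrence data.frame from a finder
#' @return TRUE invisibly; stops on the first inconsistent occurrence
#' @export
check_occurrences <- function(seq, occ) {
  s <- toupper(seq)
  for (x in seq_len(NROW(occ))) {
    o <- occ[x, ]
    if (o$category %in% c("Rp", "Rd")) {
      a <- substring(s, o$start, o$end)
      b <- substring(s, o$start2, o$end2)
      ok <- if (o$category == "Rp") identical(b, revcomp_chr(a)) else
        identical(b, a)
      if (!ok) stop("occurrence ", x, ": arms do not match")
    } else {
      for (cp in seq_len(o$copies)) {
        cs <- o$start + (cp - 1L) * o$unit_length
        if (substring(s, cs, cs + o$unit_length - 1L) != o$unit) {
          stop("occurrence ", x, ": copy ", cp, " does not match unit")
        }
      }
    }
  }
  invisible(TRUE)
}

#' Group orthologous ("shared") repeats across genomes
#'
#' Occurrences of one category whose start positions fall within `window`
#' alignment columns of each other and whose spans differ by at most
#' `length_tol` (as a fraction of the larger span) are grouped greedily in
#' column order. Groups carry flags for internal length variation and SNVs
#' relative to the first member.
#'
#' @param occs combined occurrence frame with `genome` filled
#' @param a an `aligned_set` covering all genomes with occurrences
#' @param window alignment-column window (default 50)
#' @param length_tol span tolerance as a fraction (default 0.2)
#' @return data.frame, one row per group: `group_id`, `category`,
#'   `anchor_col`, `members` (comma-separated genome ids), `n_members`,
#'   `has_length_variation`, `has_snv`
#' @export
group_shared_repeats <- function(occs, a, window = 50L, length_tol = 0.2) {
  stopifnot(inherits(a, "aligned_set"))
  if (!NROW(occs)) {
    return(data.frame(group_id = integer(), category = character(),
                      anchor_col = integer(), members = character(),
                      n_members = integer(), has_length_variation = logical(),
                      has_snv = logical(), stringsAsFactors = FALSE))
  }
  missing_tax <- setdiff(unique(occs$genome), a$taxa)
  if (length(missing_tax)) {
    stop("occurrence genome(s) absent from alignment: ",
         paste(missing_tax, collapse = ", "))
  }
  pos2col <- lapply(stats::setNames(a$taxa, a$taxa),
                    function(t) which(a$mat[t, ] != "-"))
  occs$col <- mapply(function(g, st) pos2col[[g]][st], occs$genome, occs$start)
  occs <- occs[order(occs$category, occs$col), ]
  groups <- list()
  for (cat in unique(occs$category)) {
    oc <- occs[occs$category == cat, ]
    gid <- integer(nrow(oc))
    cur <- 0L
    for (x in seq_len(nrow(oc))) {
      new_group <- cur == 0L ||
        oc$col[x] - oc$col[first_idx] > window ||
        abs(oc$span[x] - oc$span[first_idx]) >
          length_tol * max(oc$span[x], oc$span[first_idx])
      if (new_group) { cur <- cur + 1L; first_idx <- x }
      gid[x] <- cur
    }
    for (g in unique(gid)) {
      mem <- oc[gid == g, ]
      groups[[length(groups) + 1L]] <- data.frame(
        category = cat, anchor_col = min(mem$col),
        members = paste(unique(mem$genome), collapse = ","),
        n_members = length(unique(mem$genome)),
        has_length_variation = length(unique(mem$span)) > 1L,
        has_snv = any(mem$span == mem$span[1] & mem$unit != mem$unit[1]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, groups)
  out <- out[order(out$category, out$anchor_col), ]
  out$group_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("group_id", "category", "anchor_col", "members", "n_members",
          "has_length_variation", "has_snv")]
}

#' Place shared-repeat groups on the timetree and tally gains and losses
#'
#' Each group's membership is a binary presence vector placed with
#' [place_events()]; gains (repeat insertions) and losses (repeat deletions)
#' are tallied per category.
#'
#' @param groups frame from [group_shared_repeats()]
#' @param tree rooted timetree
#' @param outgroup outgroup tip label
#' @return list with `assignments` (per group) and `summary` (per category:
#'   `n_groups`, `gains`, `losses`), plus `share` (fraction of occurrences
#'   per category)
#' @export
repeat_events_on_tree <- function(groups, tree, outgroup) {
  ev <- data.frame(event_id = groups$group_id, vtype = groups$category,
                   presence = groups$members, stringsAsFactors = FALSE)
  asg <- place_events(ev, tree, outgroup)
  summ <- do.call(rbind, lapply(split(asg, asg$vtype), function(x) {
    data.frame(category = x$vtype[1], n_groups = nrow(x),
               gains = sum(x$n_independent_origins),
               losses = sum(x$n_losses), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  summ$share <- summ$n_groups / sum(summ$n_groups)
  list(assignments = asg, summary = summ)
}

#' Export repeat occurrences as GFF3 (one line per copy)
#' @param occs occurrence frame with `genome` filled
#' @param path output file
#' @return `path`, invisibly
#' @export
write_repeats_gff3 <- function(occs, path) {
  rows <- list()
  for (x in seq_len(NROW(occs))) {
    o <- occs[x, ]
    rows[[length(rows) + 1L]] <- data.frame(seq = o$genome, start = o$start,
                                            end = o$end, cat = o$category,
                                            id = x, copy = 1L)
    if (!is.na(o$start2)) {
      rows[[length(rows) + 1L]] <- data.frame(seq = o$genome, start = o$start2,
                                              end = o$end2, cat = o$category,
                                              id = x, copy = 2L)
    }
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(tab$seq, IRanges::IRanges(tab$start, tab$end),
                               type = tab$cat, ID = paste0("rep", tab$id,
                                                           ".", tab$copy))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
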