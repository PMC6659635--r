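# Permutation test for elevated variant density in repeats and their flanks
# versus equally sized interval sets placed uniformly at random.

# union of intervals clipped to [1, n]; returns data.frame(start, end)
interval_union <- function(iv, n) {
  iv <- iv[!is.na(iv$start) & !is.na(iv$end), , drop = FALSE]
  iv$start <- pmax(1L, as.integer(iv$start))
  iv$end <- pmin(as.integer(n), as.integer(iv$end))
  iv <- iv[iv$start <= iv$end, , drop = FALSE]
  if (!NROW(iv)) return(data.frame(start = integer(), end = integer()))
  ir <- IRanges::reduce(IRanges::IRanges(iv$start, iv$end))
  data.frame(start = BiocGenerics::start(ir), end = BiocGenerics::end(ir))
}

count_in_intervals <- function(pos, iv) {
  if (!NROW(iv) || !length(pos)) return(0L)
  inside <- rep(FALSE, length(pos))
  for (k in seq_len(NROW(iv))) {
    inside <- inside | (pos >= iv$start[k] & pos <= iv$end[k])
  }
  sum(inside)
}

# draw a non-overlapping interval set of the given lengths uniformly at
# random on [1, n], avoiding `avoid` intervals (rejection sampling)
draw_interval_set <- function(lengths, n, avoid = NULL, max_tries = 10000L) {
  placed <- data.frame(start = integer(), end = integer())
  for (L in sort(lengths, decreasing = TRUE)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      st <- sample.int(n - L + 1L, 1L)
      en <- st + L - 1L
      clash <- (NROW(placed) && any(st <= placed$end & en >= placed$start)) ||
        (!is.null(avoid) && NROW(avoid) &&
           any(st <= avoid$end & en >= avoid$start))
      if (!clash) { placed <- rbind(placed, data.frame(start = st, end = en))
        ok <- TRUE; break }
    }
    if (!ok) stop("could not place a random interval of length ", L,
                  " after ", max_tries, " tries")
  }
  placed
}

#' Permutation test for variant enrichment in an interval class
#'
#' The observed statistic is variants per site over the union of the class
#' intervals (each genomic site counted once). Each permutation redraws an
#' interval set of identical lengths placed uniformly at random without
#' overlap (avoiding `mask`, e.g. the masked IRa copy, so observed and null
#' share one searchable space) and recomputes the statistic. The empirical
#' one-sided p-value uses +1 smoothing: `p = (1 + #{null >= obs}) / (1 + n)`.
#'
#' @param variant_positions integer vector of variant sites (1-based)
#' @param intervals data.frame with `start`/`end` columns (1-based closed)
#' @param genome_length genome length in bases
#' @param n number of permutations (default 1000)
#' @param seed RNG seed (mandatory for reproducibility)
#' @param mask optional data.frame of intervals excluded from null placement
#' @return list of class `enrichment_result`: `statistic` (variants per
#'   site), `null` (permuted statistics), `p_empirical`, `n_permutations`,
#'   `seed`, `n_sites`, `n_variants_in`
#' @export
enrichment_test <- function(variant_positions, intervals, genome_length,
                            n = 1000L, seed, mask = NULL) {
  stopifnot(n >= 1L, !missing(seed))
  if (length(variant_positions) &&
      (min(variant_positions) < 1L || max(variant_positions) > genome_length)) {
    stop("variant positions outside the genome")
  }
  iv <- interval_union(intervals, genome_length)
  if (!NROW(iv)) stop("empty interval set")
  sites <- sum(iv$end - iv$start + 1L)
  if (sites >= genome_length) {
    stop("degenerate test: interval union covers the whole genome")
  }
  obs <- count_in_intervals(variant_positions, iv) / sites
  lens <- iv$end - iv$start + 1L
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null <- numeric(n)
  mask_u <- if (!is.null(mask)) interval_union(mask, genome_length) else NULL
  for (b in seq_len(n)) {
    rnd <- draw_interval_set(lens, genome_length, avoid = mask_u)
    null[b] <- count_in_intervals(variant_positions, rnd) / sites
  }
  structure(list(statistic = obs, null = null,
                 p_empirical = (1 + sum(null >= obs)) / (1 + n),
                 n_permutations = n, seed = seed, n_sites = sites,
                 n_variants_in = count_in_intervals(variant_positions, iv)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: %.4g variants/site (n=%d sites), p = %.4g (%d perms)\n",
              x$statistic, x$n_sites, x$p_empirical, x$n_permutations))
  invisible(x)
}

# flank intervals (+/- flank bp around each copy), repeat interiors excluded
flank_intervals <- function(iv, flank, n) {
  fl <- rbind(data.frame(start = iv$start - flank, end = iv$start - 1L),
              data.frame(start = iv$end + 1L, end = iv$end + flank))
  fl <- interval_union(fl, n)
  # subtract repeat interiors so repeat and flank classes are disjoint
  if (!NROW(fl)) return(fl)
  core <- IRanges::IRanges(iv$start, iv$end)
  out <- BiocGenerics::setdiff(IRanges::IRanges(fl$start, fl$end), core)
  data.frame(start = BiocGenerics::start(out), end = BiocGenerics::end(out))
}

#' Variant enrichment over repeat classes and their flanks
#'
#' Runs [enrichment_test()] for each repeat category present (Rt, Rp, Rd)
#' and its flanking class (RtF, RpF, RdF: `flank` bp up- and downstream of
#' each copy, repeat interiors excluded).
#'
#' @param variant_positions integer vector of variant sites on the genome
#' @param occs repeat occurrence frame for this genome (see [find_repeats()])
#' @param genome_length genome length in bases
#' @param flank flank width in bases (default 50)
#' @param n permutations per class (default 1000)
#' @param seed RNG seed
#' @param mask optional intervals excluded from null placement
#' @return data.frame: `class`, `statistic`, `p_empirical`, `n_sites`,
#'   `n_variants_in`
#' @export
variant_enrichment <- function(variant_positions, occs, genome_length,
                               flank = 50L, n = 1000L, seed, mask = NULL) {
  rows <- list()
  for (cat in intersect(c("Rd", "Rp", "Rt"), unique(occs$category))) {
    oc <- occs[occs$category == cat, ]
    copies <- rbind(data.frame(start = oc$start, end = oc$end),
                    data.frame(start = oc$start2, end = oc$end2))
    core <- interval_union(copies, genome_length)
    fl <- flank_intervals(core, flank, genome_length)
    for (cls in list(list(name = cat, iv = core),
                     list(name = paste0(cat, "F"), iv = fl))) {
      if (!NROW(cls$iv)) next
      res <- enrichment_test(variant_positions, cls$iv, genome_length,
                             n = n, seed = seed, mask = mask)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls$name, statistic = res$statistic,
        p_empirical = res$p_empirical, n_sites = res$n_sites,
        n_variants_in = res$n_variants_in, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows) %||% data.frame(
    class = character(), statistic = numeric(), p_empirical = numeric(),
    n_sites = integer(), n_variants_in = integer())
  rownames(out) <- NULL
  out
}
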