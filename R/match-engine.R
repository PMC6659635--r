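# Exact maximal-match engine shared by the IR detector and the repeat
# finders: seed on exact k-mers, group seed hits by diagonal, and merge
# consecutive hits into maximal exact runs. Matching is exact and N never
# matches anything (including another N).

# positions of each k-mer, excluding k-mers containing N
kmer_index <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(list(kmers = character(), pos = integer()))
  pos <- 1:(n - k + 1L)
  km <- substring(s, pos, pos + k - 1L)
  keep <- !grepl("N", km, fixed = TRUE)
  list(kmers = km[keep], pos = pos[keep])
}

# merge sorted seed positions along one diagonal into maximal runs
runs_from_positions <- function(i_sorted, k) {
  d <- diff(i_sorted)
  brk <- c(0L, which(d != 1L), length(i_sorted))
  starts <- i_sorted[brk[-length(brk)] + 1L]
  ends <- i_sorted[brk[-1L]]
  data.frame(i = starts, len = ends - starts + k)
}

# all maximal exact matches of length >= min_len between s1 and s2
# (pairs (i, j, len): s1[i..i+len-1] == s2[j..j+len-1]); diagonal = j - i
seed_diagonal_runs <- function(s1, s2, min_len, k = NULL) {
  k <- min(k %||% 25L, min_len)
  a <- kmer_index(s1, k)
  b <- kmer_index(s2, k)
  if (!length(a$pos) || !length(b$pos)) {
    return(data.frame(i = integer(), j = integer(), len = integer()))
  }
  common <- intersect(a$kmers, b$kmers)
  if (!length(common)) {
    return(data.frame(i = integer(), j = integer(), len = integer()))
  }
  ka <- a$pos[a$kmers %in% common]
  kb_split <- split(b$pos, b$kmers)
  akm <- a$kmers[a$kmers %in% common]
  # expand all (i, j) seed pairs
  js <- kb_split[akm]
  reps <- lengths(js)
  i_all <- rep(ka, reps)
  j_all <- unlist(js, use.names = FALSE)
  diag_ <- j_all - i_all
  out <- lapply(split(i_all, diag_), function(ii) {
    runs_from_positions(sort(unique(ii)), k)
  })
  dd <- as.integer(rep(names(out), vapply(out, nrow, 1L)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$j <- res$i + dd
  res <- res[res$len >= min_len, c("i", "j", "len")]
  rownames(res) <- NULL
  res
}

# maximal exact inverted matches within s: s[i..i+len-1] == revcomp(s[j..j+len-1])
# returned with i <= j and arms restricted per `disjoint`
inverted_runs <- function(s, min_len, k = NULL, disjoint = TRUE) {
  n <- nchar(s)
  rc <- revcomp_chr(s)
  r <- seed_diagonal_runs(s, rc, min_len, k)
  if (!nrow(r)) return(data.frame(i = integer(), j = integer(), len = integer()))
  # rc position p of length len corresponds to s position n - p - len + 2
  r$j <- n - r$j - r$len + 2L
  swap <- r$j < r$i
  tmp <- r$i[swap]; r$i[swap] <- r$j[swap]; r$j[swap] <- tmp
  r <- unique(r[, c("i", "j", "len")])
  if (disjoint) r <- r[r$j >= r$i + r$len, ]
  rownames(r) <- NULL
  r
}

# maximal exact direct (same-strand) matches within s, j > i
direct_runs <- function(s, min_len, k = NULL) {
  r <- seed_diagonal_runs(s, s, min_len, k)
  r <- r[r$j > r$i, ]
  rownames(r) <- NULL
  r
}

# drop pairs fully contained (both arms) in a longer kept pair
drop_contained_pairs <- function(r) {
  if (nrow(r) < 2L) return(r)
  r <- r[order(-r$len, r$i, r$j), ]
  keep <- rep(TRUE, nrow(r))
  for (x in seq_len(nrow(r))[-1]) {
    prior <- which(keep[seq_len(x - 1L)])
    contained <- r$i[x] >= r$i[prior] &
      r$i[x] + r$len[x] <= r$i[prior] + r$len[prior] &
      r$j[x] >= r$j[prior] &
      r$j[x] + r$len[x] <= r$j[prior] + r$len[prior]
    if (any(contained)) keep[x] <- FALSE
  }
  r <- r[keep, ]
  r <- r[order(r$i, r$j), ]
  rownames(r) <- NULL
  r
}
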