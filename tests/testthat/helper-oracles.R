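# Independent brute-force oracles. These re-derive every definition with
# plain loops and string comparisons, sharing no code with the package
# implementations they check.

.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## ---- variant extraction oracle -----------------------------------------

# column-scanning oracle for SNV and indel events. Implements, from scratch:
# per-column SNV calls; identical-gap-pattern runs; carrier-contiguity merge;
# Dollo resolution of nested adjacent insertion fragments.
oracle_extract_events <- function(mat, outgroup) {
  taxa <- rownames(mat)
  ingroup <- taxa[taxa != outgroup]
  nc <- ncol(mat)
  snv <- list(); runs <- list()

  for (cc in seq_len(nc)) {
    col <- mat[, cc]
    res <- col[col %in% c("A", "C", "G", "T")]
    states <- sort(unique(res))
    if (length(states) >= 2L) {
      og <- col[[outgroup]]
      if (og %in% c("A", "C", "G", "T")) { anc <- og; unpol <- FALSE }
      else {
        tabs <- table(factor(res, levels = states))
        anc <- names(tabs)[order(-tabs, names(tabs))][1]
        unpol <- TRUE
      }
      for (st in states[states != anc]) {
        carriers <- ingroup[col[ingroup] == st]
        if (length(carriers)) {
          snv[[length(snv) + 1L]] <- list(
            vtype = "SNV", col_start = cc, col_end = cc, length = 1L,
            presence = sort(carriers), unpolarized = unpol)
        }
      }
    }
  }

  # raw identical-gap-pattern runs
  patt <- character(nc)
  for (cc in seq_len(nc)) {
    patt[cc] <- paste(sort(taxa[mat[, cc] == "-"]), collapse = "|")
  }
  cc <- 1L
  while (cc <= nc) {
    if (patt[cc] == "") { cc <- cc + 1L; next }
    ce <- cc
    while (ce < nc && patt[ce + 1L] == patt[cc]) ce <- ce + 1L
    gapped <- strsplit(patt[cc], "|", fixed = TRUE)[[1]]
    if (outgroup %in% gapped) {
      carriers <- setdiff(ingroup, gapped)
      if (length(carriers)) {
        runs[[length(runs) + 1L]] <- list(vtype = "insertion", col_start = cc,
                                          col_end = ce, length = ce - cc + 1L,
                                          presence = sort(carriers))
      }
    } else {
      carriers <- intersect(ingroup, gapped)
      if (length(carriers)) {
        runs[[length(runs) + 1L]] <- list(vtype = "deletion", col_start = cc,
                                          col_end = ce, length = ce - cc + 1L,
                                          presence = sort(carriers))
      }
    }
    cc <- ce + 1L
  }

  all_gapped <- function(rows, c1, c2) {
    if (c2 < c1) return(TRUE)
    for (x in c1:c2) for (r in rows) if (mat[r, x] != "-") return(FALSE)
    TRUE
  }

  # carrier-contiguity merge of same-pattern runs
  repeat {
    merged <- FALSE
    if (length(runs) >= 2L) {
      ord <- order(vapply(runs, `[[`, 1L, "col_start"))
      runs <- runs[ord]
      for (i in seq_len(length(runs) - 1L)) {
        for (j in (i + 1L):length(runs)) {
          a <- runs[[i]]; b <- runs[[j]]
          if (a$vtype != b$vtype) next
          if (!identical(a$presence, b$presence)) next
          if (!all_gapped(a$presence, a$col_end + 1L, b$col_start - 1L)) next
          a$col_end <- b$col_end; a$length <- a$length + b$length
          runs[[i]] <- a; runs[[j]] <- NULL
          merged <- TRUE; break
        }
        if (merged) break
      }
    }
    if (!merged) break
  }

  # Dollo resolution: (i) sandwich [big][small][big] merges the outer
  # fragments; (ii) nested pair corroborated by an abutting deletion of the
  # missing taxa merges the fragments and grows that deletion; equal-carrier
  # adjacent fragments merge plainly
  repeat {
    changed <- FALSE
    ord <- order(vapply(runs, `[[`, 1L, "col_start"))
    runs <- runs[ord]
    ins_at <- which(vapply(runs, `[[`, "", "vtype") == "insertion")

    if (length(ins_at) >= 3L) {
      for (k in seq_len(length(ins_at) - 2L)) {
        i <- ins_at[k]; j <- ins_at[k + 1L]; l <- ins_at[k + 2L]
        a <- runs[[i]]; b <- runs[[j]]; cc2 <- runs[[l]]
        if (!identical(a$presence, cc2$presence)) next
        if (!(all(b$presence %in% a$presence) &&
              length(b$presence) < length(a$presence))) next
        if (!all_gapped(a$presence, a$col_end + 1L, b$col_start - 1L)) next
        if (!all_gapped(a$presence, b$col_end + 1L, cc2$col_start - 1L)) next
        a$col_end <- cc2$col_end; a$length <- a$length + cc2$length
        runs[[i]] <- a; runs[[l]] <- NULL
        changed <- TRUE; break
      }
    }
    if (!changed && length(ins_at) >= 2L) {
      for (k in seq_len(length(ins_at) - 1L)) {
        i <- ins_at[k]; j <- ins_at[k + 1L]
        a <- runs[[i]]; b <- runs[[j]]
        if (a$col_end >= b$col_start) next
        if (identical(a$presence, b$presence)) {
          if (!all_gapped(a$presence, a$col_end + 1L, b$col_start - 1L)) next
          a$col_end <- b$col_end; a$length <- a$length + b$length
          runs[[i]] <- a; runs[[j]] <- NULL
          changed <- TRUE; break
        }
        nested <- all(a$presence %in% b$presence) ||
          all(b$presence %in% a$presence)
        if (!nested) next
        big <- if (length(a$presence) > length(b$presence)) a$presence else
          b$presence
        small <- if (length(a$presence) < length(b$presence)) a else b
        lost <- sort(setdiff(big, small$presence))
        if (!all_gapped(big, a$col_end + 1L, b$col_start - 1L)) next
        hit <- 0L
        for (d in seq_along(runs)) {
          dd <- runs[[d]]
          if (dd$vtype != "deletion") next
          if (!identical(dd$presence, lost)) next
          left_ok <- dd$col_end < a$col_start &&
            all_gapped(big, dd$col_end + 1L, a$col_start - 1L)
          right_ok <- dd$col_start > b$col_end &&
            all_gapped(big, b$col_end + 1L, dd$col_start - 1L)
          if (left_ok || right_ok) { hit <- d; break }
        }
        if (hit == 0L) next
        runs[[hit]]$length <- runs[[hit]]$length + small$length
        a$presence <- sort(big)
        a$col_end <- b$col_end; a$length <- a$length + b$length
        runs[[i]] <- a; runs[[j]] <- NULL
        changed <- TRUE; break
      }
    }
    if (!changed) break
  }

  for (r in seq_along(runs)) runs[[r]]$unpolarized <- FALSE
  events <- c(snv, runs)
  if (!length(events)) {
    return(data.frame(vtype = character(), col_start = integer(),
                      col_end = integer(), length = integer(),
                      presence = character(), unpolarized = logical()))
  }
  out <- do.call(rbind, lapply(events, function(e) {
    data.frame(vtype = e$vtype, col_start = e$col_start, col_end = e$col_end,
               length = e$length, presence = paste(e$presence, collapse = ","),
               unpolarized = e$unpolarized, stringsAsFactors = FALSE)
  }))
  out[order(out$vtype, out$col_start, out$presence), ]
}

oracle_alignment_summary <- function(mat) {
  keep <- 0L; variable <- 0L; informative <- 0L
  for (cc in seq_len(ncol(mat))) {
    col <- mat[, cc]
    if (any(col == "-")) next
    keep <- keep + 1L
    tabs <- table(col[col %in% c("A", "C", "G", "T")])
    if (length(tabs) >= 2L) {
      variable <- variable + 1L
      if (sum(tabs >= 2L) >= 2L) informative <- informative + 1L
    }
  }
  list(aligned_length_without_gaps = keep, variable_sites = variable,
       informative_sites = informative)
}

## ---- repeat finder oracles ---------------------------------------------

# maximal period-u regions by direct position-wise scanning
.oracle_periodic <- function(ch, u, min_copies) {
  n <- length(ch)
  out <- list()
  i <- 1L
  while (i + u <= n) {
    matches <- ch[i] == ch[i + u] && ch[i] != "N" && ch[i + u] != "N"
    if (matches) {
      j <- i
      while (j + u + 1L <= n && ch[j + 1L] == ch[j + u + 1L] &&
             ch[j + 1L] != "N") j <- j + 1L
      m <- j - i + 1L
      if (m >= u * (min_copies - 1L)) {
        out[[length(out) + 1L]] <- c(start = i, end = j + u,
                                     copies = (m + u) %/% u)
      }
      i <- j + 2L
    } else i <- i + 1L
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer(),
                                      copies = integer()))
  as.data.frame(do.call(rbind, out))
}

oracle_tandem <- function(s, min_unit = 15L, min_copies = 2L, max_unit) {
  ch <- strsplit(toupper(s), "")[[1]]
  rows <- list()
  for (u in min_unit:max_unit) {
    pr <- .oracle_periodic(ch, u, min_copies)
    for (x in seq_len(nrow(pr))) {
      rows[[length(rows) + 1L]] <- c(u = u, start = pr$start[x],
                                     end = pr$end[x], copies = pr$copies[x])
    }
  }
  if (!length(rows)) return(data.frame(u = integer(), start = integer(),
                                       end = integer(), copies = integer()))
  h <- as.data.frame(do.call(rbind, rows))
  h <- h[order(h$u, h$start), ]
  keep <- rep(TRUE, nrow(h))
  for (x in seq_len(nrow(h))) {
    if (!keep[x]) next
    for (y in seq_len(x - 1L)) {
      if (keep[y] && h$start[x] >= h$start[y] && h$end[x] <= h$end[y]) {
        keep[x] <- FALSE; break
      }
    }
  }
  h <- h[keep, ]
  rownames(h) <- NULL
  h
}

# all maximal inverted pairs by anti-diagonal run scanning over the full
# match matrix
# full boolean match matrix between positions of s (complement-matching for
# inverted pairs, identity for direct pairs); N never matches
.oracle_match_matrix <- function(ch, inverted) {
  n <- length(ch)
  M <- matrix(FALSE, n, n)
  for (b in c("A", "C", "G", "T")) {
    target <- if (inverted) .comp[[b]] else b
    M[ch == b, ch == target] <- TRUE
  }
  M
}

# maximal inverted pairs via run-length DP over anti-diagonals of the match
# matrix: L[i, j] = M[i, j] * (L[i-1, j+1] + 1); a cell is the end of a
# maximal run when the next anti-diagonal cell does not match
oracle_palindromic <- function(s, min_len = 20L) {
  ch <- strsplit(toupper(s), "")[[1]]
  n <- length(ch)
  M <- .oracle_match_matrix(ch, inverted = TRUE)
  L <- matrix(0L, n, n)
  L[1, ] <- as.integer(M[1, ])
  for (i in 2:n) {
    jj <- 1:(n - 1L)
    L[i, jj] <- (L[i - 1L, jj + 1L] + 1L) * M[i, jj]
    L[i, n] <- as.integer(M[i, n])
  }
  ends <- which(L >= min_len, arr.ind = TRUE)
  dimnames(ends) <- NULL
  pairs <- list()
  for (x in seq_len(NROW(ends))) {
    i <- ends[x, 1]; j <- ends[x, 2]
    if (i < n && j > 1L && M[i + 1L, j - 1L]) next    # not maximal
    len <- L[i, j]
    i0 <- i - len + 1L; j0 <- j
    if (j0 >= i0 + len) {
      pairs[[length(pairs) + 1L]] <- c(i = i0, j = j0, len = len)
    }
  }
  .oracle_pair_filter(pairs)
}

# maximal direct pairs via the same DP along ordinary diagonals:
# L[i, j] = M[i, j] * (L[i-1, j-1] + 1)
oracle_dispersed <- function(s, min_len = 30L) {
  ch <- strsplit(toupper(s), "")[[1]]
  n <- length(ch)
  M <- .oracle_match_matrix(ch, inverted = FALSE)
  L <- matrix(0L, n, n)
  L[1, ] <- as.integer(M[1, ])
  for (i in 2:n) {
    jj <- 2:n
    L[i, jj] <- (L[i - 1L, jj - 1L] + 1L) * M[i, jj]
    L[i, 1L] <- as.integer(M[i, 1L])
  }
  ends <- which(L >= min_len, arr.ind = TRUE)
  dimnames(ends) <- NULL
  pairs <- list()
  for (x in seq_len(NROW(ends))) {
    i <- ends[x, 1]; j <- ends[x, 2]
    if (j <= i) next                                   # keep j > i half
    if (i < n && j < n && M[i + 1L, j + 1L]) next      # not maximal
    len <- L[i, j]
    i0 <- i - len + 1L; j0 <- j - len + 1L
    if (j0 - i0 > len) {                               # non-adjacent arms
      pairs[[length(pairs) + 1L]] <- c(i = i0, j = j0, len = len)
    }
  }
  .oracle_pair_filter(pairs)
}

# containment filter shared by the two pair oracles (longest first)
.oracle_pair_filter <- function(pairs) {
  if (!length(pairs)) return(data.frame(i = integer(), j = integer(),
                                        len = integer()))
  p <- unique(as.data.frame(do.call(rbind, pairs)))
  p <- p[order(-p$len, p$i, p$j), ]
  keep <- rep(TRUE, nrow(p))
  for (x in seq_len(nrow(p))) {
    if (x == 1L) next
    for (y in seq_len(x - 1L)) {
      if (!keep[y]) next
      if (p$i[x] >= p$i[y] && p$i[x] + p$len[x] <= p$i[y] + p$len[y] &&
          p$j[x] >= p$j[y] && p$j[x] + p$len[x] <= p$j[y] + p$len[y]) {
        keep[x] <- FALSE; break
      }
    }
  }
  p <- p[keep, ]
  p <- p[order(p$i, p$j), ]
  rownames(p) <- NULL
  p
}

# regex-style SSR scanner: enumerate every primitive 2-5 bp unit, find full
# copy runs, extend partial copies at both ends, dedupe regions
oracle_ssrs <- function(s, thresholds = c(`2` = 8L, `3` = 9L, `4` = 12L,
                                          `5` = 15L)) {
  s <- toupper(s)
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  bases <- c("A", "C", "G", "T")
  seen <- new.env(parent = emptyenv())
  rows <- list()
  for (u in as.integer(names(thresholds))) {
    units <- apply(expand.grid(rep(list(bases), u)), 1, paste, collapse = "")
    for (unit in units) {
      uch <- strsplit(unit, "")[[1]]
      if (length(unique(uch)) == 1L) next                 # mononucleotide
      primitive <- TRUE                                   # primitive unit?
      for (p in 1:(u - 1L)) {
        if (u %% p == 0L &&
            identical(uch, rep(uch[1:p], u / p))) { primitive <- FALSE; break }
      }
      if (!primitive) next
      g <- gregexpr(paste0("(", unit, "){2,}"), s)[[1]]
      if (g[1] == -1L) next
      for (k in seq_along(g)) {
        m <- g[k]; L <- attr(g, "match.length")[k]
        while (m + L <= n && ch[m + L] == ch[m + L - u] &&
               ch[m + L] != "N") L <- L + 1L
        while (m - 1L >= 1L && ch[m - 1L] == ch[m - 1L + u] &&
               ch[m - 1L] != "N") { m <- m - 1L; L <- L + 1L }
        key <- paste(m, m + L - 1L, u)
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        if (L < thresholds[[as.character(u)]]) next
        reg <- ch[m:(m + L - 1L)]
        small_p <- u
        for (p in 1:(u - 1L)) {
          if (all(reg[seq_len(L - p)] == reg[(p + 1L):L])) { small_p <- p; break }
        }
        if (small_p != u) next
        rows[[length(rows) + 1L]] <- data.frame(
          start = m, end = m + L - 1L, u = u,
          motif = min(vapply(seq_len(u), function(i) paste0(
            substring(unit, i, u), substring(unit, 1, i - 1L)), "")),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(data.frame(start = integer(), end = integer(),
                                       u = integer(), motif = character()))
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$start, out$u), ]
  rownames(out) <- NULL
  out
}

## ---- parsimony oracle ---------------------------------------------------

# exhaustive minimum-change count for a binary character on a rooted tree
oracle_min_changes <- function(tree, states) {
  nt <- length(tree$tip.label)
  internal <- (nt + 1L):(nt + tree$Nnode)
  free_tips <- which(is.na(states[tree$tip.label]))
  vars <- c(internal, free_tips)
  best <- Inf
  full <- integer(nt + tree$Nnode)
  full[seq_len(nt)] <- ifelse(is.na(states[tree$tip.label]), 0L,
                              states[tree$tip.label])
  for (code in 0:(2^length(vars) - 1L)) {
    bits <- as.integer(intToBits(code))[seq_along(vars)]
    full[vars] <- bits
    changes <- sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}
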