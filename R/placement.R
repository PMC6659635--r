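# Parsimony placement of polarized events on a rooted timetree and
# occurrence-rate estimation in events per million years.

#' Read and validate a time-calibrated tree
#'
#' @param path newick file with branch lengths in Myr
#' @param taxa optional taxon labels the tip set must equal
#' @param ultrametric_tol tolerance for the ultrametricity check
#' @return an `ape::phylo` tree, rooted, with positive branch lengths
#' @export
read_timetree <- function(path, taxa = NULL, ultrametric_tol = 1e-6) {
  tr <- ape::read.tree(path)
  validate_timetree(tr, taxa, ultrametric_tol)
  tr
}

validate_timetree <- function(tr, taxa = NULL, ultrametric_tol = 1e-6) {
  if (!ape::is.rooted(tr)) stop("timetree must be rooted")
  if (is.null(tr$edge.length) || any(tr$edge.length < 0)) {
    stop("timetree branch durations must be non-negative")
  }
  if (any(tr$edge.length == 0)) {
    warning("zero-duration branch(es): their rates will be undefined",
            call. = FALSE)
  }
  if (!is.null(taxa) && !setequal(tr$tip.label, taxa)) {
    stop("timetree tips do not match the taxon set")
  }
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  if (diff(range(depths)) > ultrametric_tol * max(depths)) {
    warning("timetree is not ultrametric within tolerance", call. = FALSE)
  }
  invisible(tr)
}

# branch table: one row per edge, named by the child node
branch_table <- function(tr) {
  child <- tr$edge[, 2]
  nt <- length(tr$tip.label)
  id <- ifelse(child <= nt, tr$tip.label[child], paste0("node", child))
  data.frame(edge = seq_len(nrow(tr$edge)), parent = tr$edge[, 1],
             child = child, branch_id = id, duration = tr$edge.length,
             stringsAsFactors = FALSE)
}

# Fitch small parsimony for one binary character with DELTRAN resolution.
# states: named 0/1/NA vector over tips. Returns per-edge change codes.
fitch_deltran <- function(tr, states) {
  nt <- length(tr$tip.label)
  nn <- nt + tr$Nnode
  po <- ape::reorder.phylo(tr, "postorder")
  sets <- integer(nn)             # bitmask: 1 = state0, 2 = state1
  st <- states[tr$tip.label]
  sets[seq_len(nt)] <- ifelse(is.na(st), 3L, ifelse(st == 1, 2L, 1L))
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; c_ <- po$edge[e, 2]
    if (sets[p] == 0L) sets[p] <- sets[c_]
    else {
      inter <- bitwAnd(sets[p], sets[c_])
      sets[p] <- if (inter != 0L) inter else bitwOr(sets[p], sets[c_])
    }
  }
  root <- po$edge[nrow(po$edge), 1]
  assign_state <- integer(nn)
  assign_state[root] <- if (bitwAnd(sets[root], 1L)) 0L else 1L
  pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]  # preorder
  gains <- integer(0); losses <- integer(0)
  edge_of_child <- integer(nn)
  edge_of_child[tr$edge[, 2]] <- seq_len(nrow(tr$edge))
  for (e in seq_len(nrow(pre))) {
    p <- pre[e, 1]; c_ <- pre[e, 2]
    ps <- assign_state[p]
    cs <- if (bitwAnd(sets[c_], bitwShiftL(1L, ps)) != 0L) ps else 1L - ps
    assign_state[c_] <- cs
    if (cs != ps) {
      ei <- edge_of_child[c_]
      if (cs == 1L) gains <- c(gains, ei) else losses <- c(losses, ei)
    }
  }
  list(gains = gains, losses = losses, changes = length(gains) + length(losses),
       node_states = assign_state)
}

#' Place events on a rooted timetree by binary-character parsimony
#'
#' Each event's presence vector (derived taxa) is reconstructed on the tree
#' with Fitch small parsimony; the outgroup fixes the ancestral state. When
#' the derived taxa form a clade the single stem branch of that clade is the
#' origin; otherwise the DELTRAN (delayed transformation) resolution is used,
#' yielding the most tip-ward set of independent origins among the
#' minimum-change reconstructions.
#'
#' @param events `variant_events` from [extract_events()] (or any data.frame
#'   with `event_id`, `vtype`, `presence` columns)
#' @param tree rooted `phylo` timetree whose tips cover all taxa in presence
#'   vectors plus the outgroup
#' @param outgroup outgroup tip label (ancestral state 0)
#' @return data.frame of class `branch_assignments`: `event_id`, `vtype`,
#'   `branches` (comma-separated origin branch ids), `n_independent_origins`,
#'   `n_losses`, `method` (`clade-consistent` or `multi-origin`); attribute
#'   `branch_table` holds the edge table
#' @export
place_events <- function(events, tree, outgroup) {
  validate_timetree(tree)
  if (!outgroup %in% tree$tip.label) stop("outgroup not a tree tip")
  bt <- branch_table(tree)
  rows <- vector("list", NROW(events))
  for (i in seq_len(NROW(events))) {
    carriers <- strsplit(events$presence[i], ",", fixed = TRUE)[[1]]
    carriers <- carriers[nzchar(carriers)]
    unknown <- setdiff(carriers, tree$tip.label)
    if (length(unknown)) {
      stop("event ", events$event_id[i], " references unknown tip(s): ",
           paste(unknown, collapse = ", "))
    }
    states <- stats::setNames(rep(0L, length(tree$tip.label)), tree$tip.label)
    states[carriers] <- 1L
    states[outgroup] <- 0L
    fd <- fitch_deltran(tree, states)
    rows[[i]] <- data.frame(
      event_id = events$event_id[i], vtype = events$vtype[i],
      branches = paste(bt$branch_id[fd$gains], collapse = ","),
      n_independent_origins = length(fd$gains),
      n_losses = length(fd$losses),
      method = if (length(fd$gains) == 1L && length(fd$losses) == 0L)
        "clade-consistent" else "multi-origin",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||% data.frame(
    event_id = integer(), vtype = character(), branches = character(),
    n_independent_origins = integer(), n_losses = integer(),
    method = character())
  attr(out, "branch_table") <- bt
  class(out) <- c("branch_assignments", "data.frame")
  out
}

# origins per branch and vtype from an assignment frame
origin_counts <- function(assignments, bt, vtypes) {
  counts <- matrix(0L, nrow = nrow(bt), ncol = length(vtypes),
                   dimnames = list(bt$branch_id, vtypes))
  for (i in seq_len(NROW(assignments))) {
    v <- assignments$vtype[i]
    if (!v %in% vtypes) next
    br <- strsplit(assignments$branches[i], ",", fixed = TRUE)[[1]]
    br <- br[nzchar(br)]
    for (b in br) counts[b, v] <- counts[b, v] + 1L
  }
  counts
}

#' Event occurrence rates per million years
#'
#' Per-branch rates are origin counts divided by branch duration. Lineage
#' rates are measured from the ingroup crown node (MRCA of all non-outgroup
#' tips) to each ingroup tip, divided by the crown age, so they are
#' insensitive to the unpolarizable outgroup branch. The genus-wide mean is
#' the unweighted mean of lineage rates over ingroup tips
#' (`convention = "lineage"`); `"branch_sum"` instead divides total origins
#' within the crown clade by the summed branch durations.
#'
#' @param assignments `branch_assignments` from [place_events()]
#' @param tree the same timetree
#' @param outgroup outgroup tip label
#' @param root_age crown age in Myr; default: tree depth below the crown node
#' @param convention `"lineage"` (default) or `"branch_sum"`
#' @return list with `per_branch` (branch, duration, counts and rates per
#'   vtype), `per_lineage` (tip-wise root-to-tip counts and rates), and
#'   `mean_rates` (named vector, events/Myr per vtype)
#' @export
rates_per_myr <- function(assignments, tree, outgroup, root_age = NULL,
                          convention = c("lineage", "branch_sum")) {
  convention <- match.arg(convention)
  bt <- attr(assignments, "branch_table") %||% branch_table(tree)
  vtypes <- unique(assignments$vtype)
  if (!length(vtypes)) vtypes <- c("insertion", "deletion")
  counts <- origin_counts(assignments, bt, vtypes)

  per_branch <- data.frame(bt, counts, check.names = FALSE)
  for (v in vtypes) {
    per_branch[[paste0(v, "_per_myr")]] <-
      ifelse(bt$duration > 0, counts[, v] / bt$duration, NA_real_)
  }

  ingroup <- setdiff(tree$tip.label, outgroup)
  crown <- if (length(ingroup) > 1L) ape::getMRCA(tree, ingroup) else
    which(tree$tip.label == ingroup)
  depths <- ape::node.depth.edgelength(tree)
  if (is.null(root_age)) {
    root_age <- max(depths[match(ingroup, tree$tip.label)]) - depths[crown]
  }
  # edges on the path crown -> tip, for each ingroup tip
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  edge_of_child <- integer(max(tree$edge))
  edge_of_child[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  lin_rows <- lapply(ingroup, function(t) {
    node <- which(tree$tip.label == t)
    path <- integer(0)
    while (node != crown && parent_of[node] != 0L) {
      path <- c(path, edge_of_child[node])
      node <- parent_of[node]
      if (node == crown) break
    }
    cnt <- colSums(counts[path, , drop = FALSE])
    data.frame(tip = t, t(cnt), t(cnt / root_age), check.names = FALSE)
  })
  per_lineage <- do.call(rbind, lin_rows)
  names(per_lineage) <- c("tip", vtypes, paste0(vtypes, "_per_myr"))

  if (convention == "lineage") {
    mean_rates <- colMeans(per_lineage[, paste0(vtypes, "_per_myr"),
                                       drop = FALSE])
    names(mean_rates) <- vtypes
  } else {
    crown_edges <- unique(unlist(lapply(ingroup, function(t) {
      node <- which(tree$tip.label == t); path <- integer(0)
      while (node != crown && parent_of[node] != 0L) {
        path <- c(path, edge_of_child[node]); node <- parent_of[node]
      }
      path
    })))
    tot_time <- sum(bt$duration[crown_edges])
    mean_rates <- colSums(counts[crown_edges, , drop = FALSE]) / tot_time
  }
  list(per_branch = per_branch, per_lineage = per_lineage,
       mean_rates = mean_rates, root_age = root_age,
       convention = convention)
}

#' Binary presence/absence matrix of events
#'
#' 0/1/? coding suitable for external parsimony software: carriers of the
#' derived state are `1`, other ingroup taxa `0`; for unpolarized events the
#' non-carrier entries are `?`. Column order follows `event_id` and is stable.
#'
#' @param events `variant_events`
#' @param taxa taxon labels (rows); typically ingroup plus outgroup
#' @param outgroup optional outgroup label fixed at `0`
#' @return character matrix taxa x events with entries `"0"`, `"1"`, `"?"`
#' @export
presence_matrix <- function(events, taxa, outgroup = NULL) {
  m <- matrix("0", nrow = length(taxa), ncol = NROW(events),
              dimnames = list(taxa, paste0("ev", events$event_id)))
  for (i in seq_len(NROW(events))) {
    carriers <- strsplit(events$presence[i], ",", fixed = TRUE)[[1]]
    if (isTRUE(events$unpolarized[i])) m[, i] <- "?"
    m[intersect(carriers, taxa), i] <- "1"
    if (!is.null(outgroup) && outgroup %in% taxa &&
        !outgroup %in% carriers) m[outgroup, i] <- "0"
  }
  m
}

#' Write a presence matrix as relaxed PHYLIP or NEXUS
#' @param m matrix from [presence_matrix()]
#' @param path output file
#' @param format `"phylip"` (relaxed) or `"nexus"`
#' @return `path`, invisibly
#' @export
write_presence_matrix <- function(m, path, format = c("phylip", "nexus")) {
  format <- match.arg(format)
  rows <- apply(m, 1L, paste, collapse = "")
  if (format == "phylip") {
    writeLines(c(paste(nrow(m), ncol(m)),
                 paste(rownames(m), rows)), path)
  } else {
    writeLines(c("#NEXUS", "BEGIN DATA;",
                 sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
                 "  FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"01\";",
                 "  MATRIX",
                 paste(" ", rownames(m), rows),
                 "  ;", "END;"), path)
  }
  invisible(path)
}

#' Read a relaxed-PHYLIP presence matrix written by [write_presence_matrix()]
#' @param path PHYLIP file
#' @return character matrix with entries `"0"`, `"1"`, `"?"`
#' @export
read_presence_matrix <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- strsplit(trimws(lines[-1]), "\\s+")
  body <- body[lengths(body) == 2L]
  m <- do.call(rbind, lapply(body, function(x) seq_chars(x[2])))
  rownames(m) <- vapply(body, `[`, "", 1L)
  stopifnot(nrow(m) == dims[1], ncol(m) == dims[2])
  m
}

#' Correlation between per-branch event counts and branch durations
#'
#' @param assignments `branch_assignments`
#' @param tree the timetree
#' @param n_perm permutations for the one-sided (greater) p-value
#' @param seed RNG seed for the permutation null
#' @return list with `pearson`, `spearman`, `p_pearson`, `p_spearman`,
#'   `n_branches`, `defined` (FALSE when either vector is constant)
#' @export
branch_length_correlation <- function(assignments, tree, n_perm = 999L,
                                      seed = 1L) {
  bt <- attr(assignments, "branch_table") %||% branch_table(tree)
  counts <- rowSums(origin_counts(assignments, bt,
                                  unique(assignments$vtype)))
  dur <- bt$duration
  if (length(unique(counts)) < 2L || length(unique(dur)) < 2L) {
    return(list(pearson = NA_real_, spearman = NA_real_,
                p_pearson = NA_real_, p_spearman = NA_real_,
                n_branches = length(dur), defined = FALSE))
  }
  pe <- stats::cor(counts, dur, method = "pearson")
  sp <- stats::cor(counts, dur, method = "spearman")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_pe <- null_sp <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample(counts)
    null_pe[b] <- stats::cor(perm, dur, method = "pearson")
    null_sp[b] <- stats::cor(perm, dur, method = "spearman")
  }
  list(pearson = pe, spearman = sp,
       p_pearson = (1 + sum(null_pe >= pe)) / (1 + n_perm),
       p_spearman = (1 + sum(null_sp >= sp)) / (1 + n_perm),
       n_branches = length(dur), defined = TRUE)
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
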