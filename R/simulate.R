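# Plastome evolution simulator: substitutions, length-skewed indels and
# tandem duplications drawn as Poisson processes along a timetree, with a
# master-coordinate true alignment and a complete ground-truth event log.
#
# Internal representation: every residue ever simulated has a unique site id;
# a node's genome is an ordered vector of (id, base); the master column order
# threads all ids ever inserted, so the true alignment is read off directly.

#' Build an ultrametric simulation timetree with an outgroup
#'
#' A random-coalescent ingroup topology scaled to `crown_age`, plus an
#' outgroup diverging at `outgroup_age`.
#'
#' @param n_ingroup number of ingroup tips (default 23, a genus-sized sample)
#' @param crown_age ingroup crown age in Myr (default 15.3)
#' @param outgroup_age outgroup divergence in Myr (default 18)
#' @param seed RNG seed
#' @param outgroup_label tip label for the outgroup
#' @return rooted ultrametric `phylo` with branch lengths in Myr
#' @export
sim_timetree <- function(n_ingroup = 23L, crown_age = 15.3,
                         outgroup_age = 18, seed = 1L,
                         outgroup_label = "outgroup") {
  stopifnot(outgroup_age > crown_age)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tin <- ape::rcoal(n_ingroup, tip.label = sprintf("sp%02d", seq_len(n_ingroup)))
  tin$edge.length <- tin$edge.length * crown_age /
    max(ape::node.depth.edgelength(tin))
  nwk <- sub(";$", "", ape::write.tree(tin))
  full <- paste0("(", outgroup_label, ":", outgroup_age, ",", nwk, ":",
                 outgroup_age - crown_age, ");")
  ape::read.tree(text = full)
}

#' Simulation configuration
#'
#' Defaults describe a plastome-scale experiment: a 134 kb root genome at 39%
#' GC with a 20.8 kb planted IR pair, ~0.001 substitutions/site/Myr, 7
#' insertions and 15 deletions per genome per Myr with a two-component
#' geometric length mixture (85% short, mean 3 bp; 15% long, mean 40 bp) that
#' reproduces the strongly short-skewed indel spectra of real plastomes, and
#' 0.5 tandem duplications per genome per Myr with unit lengths of 15 bp or
#' more.
#'
#' @param tree rooted timetree (branch lengths in Myr)
#' @param root_length root genome length in bases
#' @param gc GC content of the random root genome
#' @param ir_len planted inverted-repeat length (0 disables); the IR pair is
#'   placed Oryza-like around a short single-copy region
#' @param ssc_len single-copy region between the planted IR arms
#' @param sub_rate substitutions per site per Myr
#' @param ins_rate,del_rate indel events per genome per Myr
#' @param w_short,m_short,m_long indel length mixture: weight and geometric
#'   means (bases) of the short and long components
#' @param dup_rate tandem-duplication events per genome per Myr
#' @param dup_min,dup_mean minimum and mean duplication unit length (bases)
#' @param ir_sync mirror substitutions across the planted IR pair
#'   (plastid-like copy correction); indels are not mirrored
#' @return list of class `sim_config`
#' @export
sim_config <- function(tree, root_length = 134000L, gc = 0.39,
                       ir_len = 20800L, ssc_len = 12300L,
                       sub_rate = 0.001, ins_rate = 7, del_rate = 15,
                       w_short = 0.85, m_short = 3, m_long = 40,
                       dup_rate = 0.5, dup_min = 15L, dup_mean = 22,
                       ir_sync = TRUE) {
  validate_timetree(tree)
  stopifnot(root_length >= 1L, all(c(sub_rate, ins_rate, del_rate,
                                     dup_rate) >= 0),
            w_short >= 0, w_short <= 1, m_short >= 1, m_long >= 1)
  if (ir_len > 0 && 2L * ir_len + ssc_len >= root_length) {
    stop("planted IR plus SSC exceed the root genome length")
  }
  depths <- ape::node.depth.edgelength(tree)
  max_path <- max(depths)
  mean_len <- w_short * m_short + (1 - w_short) * m_long
  if (del_rate * max_path * mean_len > 0.5 * root_length) {
    stop("expected deletion load exceeds half the genome; lower del_rate ",
         "or shorten the tree")
  }
  structure(list(tree = tree, root_length = as.integer(root_length), gc = gc,
                 ir_len = as.integer(ir_len), ssc_len = as.integer(ssc_len),
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, w_short = w_short, m_short = m_short,
                 m_long = m_long, dup_rate = dup_rate,
                 dup_min = as.integer(dup_min), dup_mean = dup_mean,
                 ir_sync = ir_sync), class = "sim_config")
}

# indel length draw from the two-component geometric mixture
draw_indel_len <- function(k, cfg) {
  short <- stats::runif(k) < cfg$w_short
  m <- ifelse(short, cfg$m_short, cfg$m_long)
  1L + stats::rgeom(k, prob = 1 / m)
}

draw_dup_len <- function(cfg) {
  cfg$dup_min + stats::rgeom(1L, prob = 1 / max(cfg$dup_mean - cfg$dup_min + 1, 1.5))
}

# build the root genome with a planted IR pair; returns ids/bases/ir_pair
sim_root_genome <- function(cfg) {
  n <- cfg$root_length
  bases <- seq_chars(random_dna(n, gc = cfg$gc))
  ir_pair <- integer(n)
  if (cfg$ir_len > 0L) {
    # layout: LSC | IRb | SSC | IRa, Oryza-like proportions
    lsc <- n - 2L * cfg$ir_len - cfg$ssc_len
    # guard bases so the planted IR pair is exactly maximal (no chance
    # single-base extension at the four junctions)
    bases[c(1L, lsc)] <- "A"
    bases[c(lsc + cfg$ir_len + 1L, lsc + cfg$ir_len + cfg$ssc_len)] <- "A"
    irb <- (lsc + 1L):(lsc + cfg$ir_len)
    ira <- (lsc + cfg$ir_len + cfg$ssc_len + 1L):n
    bases[ira] <- rev(comp_chars(bases[irb]))
    ir_pair[irb] <- rev(ira)
    ir_pair[ira] <- rev(irb)
  }
  list(ids = seq_len(n), bases = bases, ir_pair = ir_pair)
}

#' Simulate plastome evolution along a timetree
#'
#' Events are drawn per branch as Poisson counts (`rate x duration`),
#' applied in drawn order with positions uniform over the current genome:
#' substitutions under a symmetric single-nucleotide model (optionally
#' mirrored across the planted IR), insertions of random sequence and
#' deletions with mixture-geometric lengths, and tandem duplications that
#' copy a segment in place (creating true Rt arrays). All inserted residues
#' receive fresh site ids threaded through a master column order, so the
#' true multiple alignment and a complete, replayable event log are emitted
#' alongside the tip genomes.
#'
#' @param cfg a [sim_config()]
#' @param seed RNG seed (mandatory)
#' @return list of class `sim_result`: `genomes` (named list of
#'   [plastome()]), `alignment` (`aligned_set` of all tips), `col_ids`
#'   (master site id per alignment column), `log` (event log with `clean`
#'   and `polarizable` flags), `tree`, `config`, `root` (ids/bases),
#'   `branch_events` (per-branch event counts)
#' @export
simulate_plastomes <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"), !missing(seed))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tr <- cfg$tree
  bt <- branch_table(tr)
  root_g <- sim_root_genome(cfg)
  env <- new.env(parent = emptyenv())
  env$master <- root_g$ids          # master column order
  env$counter <- cfg$root_length    # last assigned site id
  env$log <- vector("list", 0L)
  env$ir_pair <- root_g$ir_pair     # indexed by root site id

  nt <- length(tr$tip.label)
  tips <- vector("list", nt)
  names(tips) <- tr$tip.label
  children_of <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  root_node <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]

  recurse <- function(node, state) {
    for (e in children_of[[as.character(node)]]) {
      child <- tr$edge[e, 2]
      st <- sim_branch(state, bt$branch_id[e], bt$duration[e], cfg, env)
      if (child <= nt) tips[[tr$tip.label[child]]] <<- st
      else recurse(child, st)
    }
  }
  recurse(root_node, list(ids = root_g$ids, bases = root_g$bases))

  log_df <- do.call(rbind, env$log) %||% data.frame(
    branch = character(), type = character(), pos = integer(),
    length = integer(), payload = character(), ids = character(),
    anchor_id = integer(), stringsAsFactors = FALSE)
  res <- assemble_alignment(tips, env$master)
  log_df <- flag_truth_log(log_df, res$col_ids, tr)
  genomes <- lapply(names(tips), function(t) {
    plastome(t, paste(tips[[t]]$bases, collapse = ""))
  })
  names(genomes) <- names(tips)
  structure(list(genomes = genomes, alignment = res$alignment,
                 col_ids = res$col_ids, log = log_df, tree = tr,
                 config = cfg, root = root_g,
                 branch_events = table(log_df$branch, log_df$type)),
            class = "sim_result")
}

# apply one branch's events to a copy of the parent state, logging each
sim_branch <- function(state, branch_id, duration, cfg, env) {
  ids <- state$ids; bases <- state$bases
  L0 <- length(ids)
  n_sub <- stats::rpois(1L, cfg$sub_rate * L0 * duration)
  n_ins <- stats::rpois(1L, cfg$ins_rate * duration)
  n_del <- stats::rpois(1L, cfg$del_rate * duration)
  n_dup <- stats::rpois(1L, cfg$dup_rate * duration)
  kinds <- sample(rep(c("sub", "ins", "del", "dup"),
                      c(n_sub, n_ins, n_del, n_dup)))
  for (kind in kinds) {
    L <- length(ids)
    if (L == 0L) break
    if (kind == "sub") {
      p <- sample.int(L, 1L)
      newb <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
      ev_ids <- ids[p]; ev_bases <- newb
      bases[p] <- newb
      id <- ids[p]
      if (cfg$ir_sync && id <= length(env$ir_pair) &&
          env$ir_pair[id] > 0L) {
        q <- match(env$ir_pair[id], ids)
        if (!is.na(q)) {
          bases[q] <- comp_chars(newb)
          ev_ids <- c(ev_ids, ids[q]); ev_bases <- c(ev_bases, bases[q])
        }
      }
      env$log[[length(env$log) + 1L]] <- data.frame(
        branch = branch_id, type = "sub", pos = p, length = 1L,
        payload = paste(ev_bases, collapse = ","),
        ids = paste(ev_ids, collapse = ","), anchor_id = NA_integer_,
        stringsAsFactors = FALSE)
    } else if (kind == "del") {
      len <- draw_indel_len(1L, cfg)
      p <- sample.int(L, 1L)
      len <- min(len, L - p + 1L)
      rem <- p:(p + len - 1L)
      env$log[[length(env$log) + 1L]] <- data.frame(
        branch = branch_id, type = "del", pos = p, length = len,
        payload = paste(bases[rem], collapse = ""),
        ids = paste(ids[rem], collapse = ","), anchor_id = NA_integer_,
        stringsAsFactors = FALSE)
      ids <- ids[-rem]; bases <- bases[-rem]
    } else {
      if (kind == "ins") {
        len <- draw_indel_len(1L, cfg)
        newb <- seq_chars(random_dna(len, gc = cfg$gc))
        p <- sample.int(L + 1L, 1L) - 1L        # insert after position p
      } else {                                   # tandem duplication
        len <- min(draw_dup_len(cfg), L)
        start <- sample.int(L - len + 1L, 1L)
        newb <- bases[start:(start + len - 1L)]
        p <- start + len - 1L                    # adjacent copy
      }
      new_ids <- env$counter + seq_len(len)
      env$counter <- env$counter + len
      anchor <- if (p == 0L) 0L else ids[p]
      splice_master(env, anchor, new_ids, before_id =
                      if (p == 0L) ids[1L] else NA_integer_)
      ids <- append(ids, new_ids, after = p)
      bases <- append(bases, newb, after = p)
      env$log[[length(env$log) + 1L]] <- data.frame(
        branch = branch_id, type = if (kind == "ins") "ins" else "dup",
        pos = p + 1L, length = len, payload = paste(newb, collapse = ""),
        ids = paste(new_ids, collapse = ","), anchor_id = anchor,
        stringsAsFactors = FALSE)
    }
  }
  list(ids = ids, bases = bases)
}

# insert new ids into the master order after `anchor` (0 = before `before_id`)
splice_master <- function(env, anchor, new_ids, before_id = NA_integer_) {
  if (anchor == 0L) {
    at <- if (is.na(before_id)) 0L else match(before_id, env$master) - 1L
  } else {
    at <- match(anchor, env$master)
  }
  env$master <- append(env$master, new_ids, after = at)
}

# build the gap-augmented true alignment from tip id vectors
assemble_alignment <- function(tips, master) {
  keep <- master %in% unlist(lapply(tips, `[[`, "ids"), use.names = FALSE)
  cols <- master[keep]
  m <- matrix("-", nrow = length(tips), ncol = length(cols),
              dimnames = list(names(tips), NULL))
  idx <- seq_along(cols)
  names(idx) <- cols
  for (t in names(tips)) {
    m[t, idx[as.character(tips[[t]]$ids)]] <- tips[[t]]$bases
  }
  list(alignment = aligned_set(m), col_ids = cols)
}

# mark indel events that the alignment-based extractor can recover exactly:
# site ids touched by exactly one indel event, contiguous in the final
# alignment, flanked by event-free columns, and not on the outgroup branch
flag_truth_log <- function(log_df, col_ids, tr) {
  if (!NROW(log_df)) {
    log_df$clean <- logical(0); log_df$polarizable <- logical(0)
    return(log_df)
  }
  indel <- log_df$type %in% c("ins", "del", "dup")
  id_lists <- lapply(log_df$ids, function(x)
    as.integer(strsplit(x, ",", fixed = TRUE)[[1]]))
  touch <- table(unlist(id_lists[indel]))
  event_ids <- unique(unlist(id_lists[indel]))
  col_pos <- match(event_ids, col_ids)
  names(col_pos) <- event_ids
  in_any_event <- col_ids %in% event_ids
  # outgroup branch = edge whose child is the outgroup-labelled tip; callers
  # use tip 1 conventionally; detect from the tree: the root child that is a tip
  root_node <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
  root_children <- tr$edge[tr$edge[, 1] == root_node, 2]
  og_tips <- tr$tip.label[root_children[root_children <= length(tr$tip.label)]]
  clean <- rep(NA, NROW(log_df))
  for (i in which(indel)) {
    idv <- id_lists[[i]]
    pos <- col_pos[as.character(idv)]
    ok <- all(touch[as.character(idv)] == 1L)
    if (ok && anyNA(pos)) ok <- FALSE          # columns absent from alignment
    if (ok) {
      pos <- sort(pos)
      ok <- (pos[length(pos)] - pos[1] + 1L) == length(pos)
    }
    if (ok) {                                   # event-free flanking columns
      lo <- pos[1] - 1L; hi <- pos[length(pos)] + 1L
      if (lo >= 1L && in_any_event[lo]) ok <- FALSE
      if (hi <= length(col_ids) && in_any_event[hi]) ok <- FALSE
    }
    clean[i] <- ok
  }
  log_df$clean <- clean
  log_df$polarizable <- !(log_df$branch %in% og_tips)
  log_df
}

#' Replay a truth log from the root genome
#'
#' Deterministically re-applies the logged events down the tree by site id,
#' reproducing [simulate_plastomes()]'s tip genomes bit-exactly.
#'
#' @param log event log from a `sim_result`
#' @param root root genome (`ids`/`bases`) from a `sim_result`
#' @param tree the simulation timetree
#' @return named list of tip sequences (character strings)
#' @export
replay <- function(log, root, tree) {
  bt <- branch_table(tree)
  nt <- length(tree$tip.label)
  children_of <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  root_node <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  by_branch <- split(seq_len(NROW(log)), log$branch)
  tips <- list()
  apply_branch <- function(state, branch_id) {
    for (i in by_branch[[branch_id]] %||% integer(0)) {
      ev <- log[i, ]
      idv <- as.integer(strsplit(ev$ids, ",", fixed = TRUE)[[1]])
      if (ev$type == "sub") {
        pay <- strsplit(ev$payload, ",", fixed = TRUE)[[1]]
        at <- match(idv, state$ids)
        state$bases[at[!is.na(at)]] <- pay[!is.na(at)]
      } else if (ev$type == "del") {
        at <- match(idv, state$ids)
        at <- at[!is.na(at)]
        if (length(at)) { state$ids <- state$ids[-at]
          state$bases <- state$bases[-at] }
      } else {
        p <- if (ev$anchor_id == 0L) 0L else match(ev$anchor_id, state$ids)
        if (is.na(p)) stop("replay: anchor id ", ev$anchor_id,
                           " absent on branch ", branch_id)
        state$ids <- append(state$ids, idv, after = p)
        state$bases <- append(state$bases, seq_chars(ev$payload), after = p)
      }
    }
    state
  }
  recurse <- function(node, state) {
    for (e in children_of[[as.character(node)]]) {
      child <- tree$edge[e, 2]
      st <- apply_branch(state, bt$branch_id[e])
      if (child <= nt) tips[[tree$tip.label[child]]] <<- paste(st$bases,
                                                               collapse = "")
      else recurse(child, st)
    }
  }
  recurse(root_node, list(ids = root$ids, bases = root$bases))
  tips
}
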