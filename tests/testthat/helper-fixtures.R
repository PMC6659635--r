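# Fixture builders used across test files. All randomness is seeded by the
# calling test.

# random DNA with planted structures for repeat-finder tests
plant_in <- function(background, insert, at) {
  paste0(substring(background, 1, at - 1), insert,
         substring(background, at, nchar(background)))
}

# a random gappy alignment: start from one ancestral string, then punch
# random gap blocks and substitutions into random subsets of rows
random_gappy_alignment <- function(n_taxa = 6L, n_cols = 300L,
                                   n_indels = 6L, n_snvs = 8L) {
  taxa <- c("out", paste0("t", seq_len(n_taxa - 1L)))
  anc <- seq_chars(random_dna(n_cols))
  mat <- matrix(rep(anc, each = n_taxa), nrow = n_taxa,
                dimnames = list(taxa, NULL))
  for (i in seq_len(n_indels)) {
    len <- sample(1:8, 1)
    start <- sample(n_cols - len, 1)
    rows <- sample(taxa, sample(n_taxa - 1L, 1))
    mat[rows, start:(start + len - 1L)] <- "-"
  }
  for (i in seq_len(n_snvs)) {
    cc <- sample(n_cols, 1)
    rows <- sample(taxa, sample(2L, 1))
    for (r in rows) {
      if (mat[r, cc] != "-") mat[r, cc] <- sample(c("A", "C", "G", "T"), 1)
    }
  }
  # drop all-gap columns
  mat <- mat[, colSums(mat != "-") > 0L, drop = FALSE]
  mat
}

# toy plastome with a planted quadripartite layout; guard bases at the four
# arm boundaries stop the exact-match detector extending the IR by chance
toy_quadripartite_genome <- function(lsc = 800L, ir = 200L, ssc = 300L) {
  arm <- random_dna(ir)
  L <- seq_chars(random_dna(lsc))
  S <- seq_chars(random_dna(ssc))
  L[1] <- "A"; L[lsc] <- "A"   # outward: L end vs comp(first base)
  S[1] <- "A"; S[ssc] <- "A"   # inward: SSC first vs comp(SSC last)
  paste0(paste(L, collapse = ""), arm, paste(S, collapse = ""),
         revcomp_chr(arm))
}

# small simulation: 6 tips, fast
quick_sim <- function(seed, ins_rate = 2, del_rate = 3, sub_rate = 5e-4,
                      dup_rate = 0.3, root_length = 5000L, tree_seed = 3L,
                      n_ingroup = 5L) {
  tr <- sim_timetree(n_ingroup = n_ingroup, crown_age = 15.3,
                     outgroup_age = 18, seed = tree_seed)
  cfg <- sim_config(tr, root_length = root_length, ir_len = 600L,
                    ssc_len = 400L, sub_rate = sub_rate, ins_rate = ins_rate,
                    del_rate = del_rate, dup_rate = dup_rate)
  simulate_plastomes(cfg, seed = seed)
}
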