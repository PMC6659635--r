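# Simulator: determinism, closure under zero rates, replay, truth flags,
# length-law calibration.

test_that("zero rates give identical tips and a gap-free true alignment", {
  tr <- sim_timetree(n_ingroup = 4, seed = 2)
  cfg <- sim_config(tr, root_length = 2000, ir_len = 300, ssc_len = 200,
                    sub_rate = 0, ins_rate = 0, del_rate = 0, dup_rate = 0)
  sim <- simulate_plastomes(cfg, seed = 5)
  seqs <- vapply(sim$genomes, function(g) g$seq, "")
  expect_equal(length(unique(seqs)), 1L)
  expect_false(any(sim$alignment$mat == "-"))
  expect_equal(nrow(sim$log), 0L)
})

test_that("del_rate 0 yields no deletions in the log or the pipeline", {
  sim <- quick_sim(seed = 6, ins_rate = 2, del_rate = 0, dup_rate = 0)
  expect_false(any(sim$log$type == "del"))
  ev <- extract_events(sim$alignment, "outgroup")
  r <- rates_per_myr(place_events(ev, sim$tree, "outgroup"), sim$tree,
                     "outgroup", root_age = 15.3)
  # outgroup-branch insertions mirror onto the ingroup stem as apparent
  # deletions, but no crown-to-tip lineage can carry a deletion
  if ("deletion" %in% names(r$per_lineage)) {
    expect_true(all(r$per_lineage$deletion == 0))
  }
})

test_that("the same seed reproduces tip FASTA bytes exactly", {
  s1 <- quick_sim(seed = 77)
  s2 <- quick_sim(seed = 77)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_plastome_fasta(s1$genomes, f1)
  write_plastome_fasta(s2$genomes, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- quick_sim(seed = 78)
  expect_false(identical(vapply(s1$genomes, function(g) g$seq, ""),
                         vapply(s3$genomes, function(g) g$seq, "")))
})

test_that("replaying the log reproduces every tip bit-exactly", {
  sim <- quick_sim(seed = 81)
  tips <- replay(sim$log, sim$root, sim$tree)
  for (t in names(sim$genomes)) {
    expect_identical(tips[[t]], sim$genomes[[t]]$seq)
  }
  # empty log leaves the root unchanged
  tr <- sim_timetree(n_ingroup = 2, seed = 1)
  cfg <- sim_config(tr, root_length = 500, ir_len = 0, ssc_len = 0,
                    sub_rate = 0, ins_rate = 0, del_rate = 0, dup_rate = 0)
  sim0 <- simulate_plastomes(cfg, seed = 1)
  tips0 <- replay(sim0$log, sim0$root, sim0$tree)
  expect_identical(tips0[[1]], paste(sim0$root$bases, collapse = ""))
})

test_that("clean logged indels are recovered exactly from the true alignment", {
  sim <- quick_sim(seed = 91)
  ev <- extract_events(sim$alignment, "outgroup")
  ind <- ev[ev$vtype %in% c("insertion", "deletion"), ]
  lg <- sim$log[sim$log$type %in% c("ins", "del", "dup") &
                  sim$log$clean & sim$log$polarizable, ]
  expect_gt(nrow(lg), 20L)
  for (i in seq_len(nrow(lg))) {
    idv <- as.integer(strsplit(lg$ids[i], ",")[[1]])
    cp <- range(match(idv, sim$col_ids))
    want <- if (lg$type[i] == "del") "deletion" else "insertion"
    hit <- ind[ind$col_start == cp[1] & ind$col_end == cp[2] &
                 ind$vtype == want & ind$length == lg$length[i], ]
    expect_equal(nrow(hit), 1L,
                 info = paste("event", i, lg$type[i], "on", lg$branch[i]))
  }
})

test_that("indel lengths follow the configured geometric mixture", {
  tr <- sim_timetree(n_ingroup = 2, seed = 4)
  cfg <- sim_config(tr, root_length = 60000, ir_len = 0, ssc_len = 0,
                    sub_rate = 0, ins_rate = 60, del_rate = 0, dup_rate = 0)
  sim <- simulate_plastomes(cfg, seed = 13)
  lens <- sim$log$length[sim$log$type == "ins"]
  expect_gt(length(lens), 500L)
  # expected short fraction under the mixture law
  p_lt10 <- cfg$w_short * stats::pgeom(8, 1 / cfg$m_short) +
    (1 - cfg$w_short) * stats::pgeom(8, 1 / cfg$m_long)
  mc_se <- sqrt(p_lt10 * (1 - p_lt10) / length(lens))
  expect_lt(abs(mean(lens < 10) - p_lt10), 4 * mc_se)
  mean_expected <- cfg$w_short * cfg$m_short + (1 - cfg$w_short) * cfg$m_long
  expect_lt(abs(mean(lens) - mean_expected),
            4 * stats::sd(lens) / sqrt(length(lens)))
})

test_that("tandem duplications create true adjacent-copy arrays", {
  tr <- sim_timetree(n_ingroup = 2, seed = 8)
  cfg <- sim_config(tr, root_length = 20000, ir_len = 0, ssc_len = 0,
                    sub_rate = 0, ins_rate = 0, del_rate = 0, dup_rate = 3,
                    dup_min = 16L)
  sim <- simulate_plastomes(cfg, seed = 21)
  dups <- sim$log[sim$log$type == "dup", ]
  expect_gt(nrow(dups), 5L)
  # in a tip that carries a duplication, the copy sits next to its template
  one <- dups[1, ]
  tipseqs <- vapply(sim$genomes, function(g) g$seq, "")
  hits <- vapply(tipseqs, function(s) {
    grepl(strrep(one$payload, 2), s, fixed = TRUE)
  }, TRUE)
  expect_true(any(hits))
})

test_that("excessive deletion load is rejected at configuration time", {
  tr <- sim_timetree(n_ingroup = 4, seed = 2)
  expect_error(sim_config(tr, root_length = 500, ir_len = 0, ssc_len = 0,
                          del_rate = 50), "deletion load")
  expect_error(sim_config(tr, root_length = 1000, ir_len = 400,
                          ssc_len = 300), "exceed")
})

test_that("IR-synchronized substitutions keep the planted IR detectable", {
  tr <- sim_timetree(n_ingroup = 3, seed = 6)
  cfg <- sim_config(tr, root_length = 6000, ir_len = 800, ssc_len = 400,
                    sub_rate = 2e-3, ins_rate = 0, del_rate = 0,
                    dup_rate = 0, ir_sync = TRUE)
  sim <- simulate_plastomes(cfg, seed = 31)
  for (g in sim$genomes) {
    q <- detect_quadripartite(g, min_ir_len = 400)
    expect_equal(q$ir_len, 800L)
  }
})
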