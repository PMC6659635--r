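# Fitch/DELTRAN placement, rates per Myr, presence matrices, correlations.

five_taxon_tree <- function() {
  ape::read.tree(text = "(Out:3,((A:1,B:1):1,(C:1,D:1):1):1);")
}

test_that("clade-consistent events land on the clade stem", {
  tr <- five_taxon_tree()
  ev <- data.frame(event_id = 1:3, vtype = "insertion",
                   presence = c("A,B", "A,B,C,D", "A"))
  asg <- place_events(ev, tr, "Out")
  expect_equal(asg$n_independent_origins, c(1L, 1L, 1L))
  expect_equal(asg$method, rep("clade-consistent", 3))
  expect_equal(asg$branches[3], "A")                 # terminal branch
  # stems: (A,B) and the ingroup crown are internal nodes
  expect_match(asg$branches[1], "^node")
  expect_match(asg$branches[2], "^node")
  expect_true(asg$branches[1] != asg$branches[2])
})

test_that("homoplastic presence {A,C} resolves to two terminal origins", {
  tr <- five_taxon_tree()
  # oracle: exhaustive enumeration says the minimum is 2 changes
  states <- c(Out = 0L, A = 1L, B = 0L, C = 1L, D = 0L)
  expect_equal(oracle_min_changes(tr, states), 2L)
  asg <- place_events(data.frame(event_id = 1L, vtype = "insertion",
                                 presence = "A,C"), tr, "Out")
  expect_equal(asg$n_independent_origins, 2L)
  expect_setequal(strsplit(asg$branches, ",")[[1]], c("A", "C"))
  expect_equal(asg$method, "multi-origin")
})

test_that("unknown tips in a presence vector are a hard error", {
  tr <- five_taxon_tree()
  expect_error(place_events(data.frame(event_id = 1, vtype = "insertion",
                                       presence = "A,Z"), tr, "Out"),
               "unknown tip")
})

test_that("DELTRAN matches exhaustive minimum change on random cases", {
  set.seed(41)
  for (rep in 1:60) {
    nt <- sample(4:6, 1)
    tr <- ape::rcoal(nt, tip.label = paste0("s", seq_len(nt)))
    tr$edge.length <- tr$edge.length + 0.1
    states <- stats::setNames(sample(0:1, nt, replace = TRUE), tr$tip.label)
    states[1] <- 0L   # outgroup-like anchor
    fd <- plastovar:::fitch_deltran(tr, states)
    expect_equal(fd$changes, oracle_min_changes(tr, states),
                 info = paste("case", rep))
  }
})

test_that("parsimony scores agree with phangorn on random binary characters", {
  skip_if_not_installed("phangorn")
  set.seed(43)
  for (rep in 1:20) {
    nt <- sample(5:8, 1)
    tr <- ape::rcoal(nt, tip.label = paste0("s", seq_len(nt)))
    tr$edge.length <- tr$edge.length + 0.1
    states <- stats::setNames(sample(0:1, nt, replace = TRUE), tr$tip.label)
    if (length(unique(states)) < 2L) states[1] <- 1L - states[1]
    fd <- plastovar:::fitch_deltran(tr, states)
    pd <- phangorn::phyDat(matrix(as.character(states), ncol = 1,
                                  dimnames = list(names(states), NULL)),
                           type = "USER", levels = c("0", "1"))
    expect_equal(fd$changes, as.integer(phangorn::fitch(tr, pd)))
  }
})

test_that("branch and lineage rates do the arithmetic of the contract", {
  tr <- ape::read.tree(text = "(Out:3,(A:1.5,B:1.5):1.5);")
  ev <- data.frame(event_id = 1:3, vtype = "deletion", presence = "A")
  asg <- place_events(ev, tr, "Out")
  r <- rates_per_myr(asg, tr, "Out")
  branch_a <- r$per_branch[r$per_branch$branch_id == "A", ]
  expect_equal(branch_a$deletion, 3L)
  expect_equal(branch_a$deletion_per_myr, 2.0)       # 3 events / 1.5 Myr
  expect_equal(r$root_age, 1.5)
  expect_equal(unname(r$mean_rates["deletion"]), (3 / 1.5 + 0) / 2)
  # no events at all -> all rates 0
  r0 <- rates_per_myr(place_events(ev[0, ], tr, "Out"), tr, "Out")
  expect_true(all(r0$mean_rates == 0))
  # branch-sum convention: total origins / summed crown branch time
  rb <- rates_per_myr(asg, tr, "Out", convention = "branch_sum")
  expect_equal(unname(rb$mean_rates["deletion"]), 3 / 3.0)
})

test_that("total origins are conserved across the assignment table", {
  set.seed(47)
  tr <- five_taxon_tree()
  tips <- c("A", "B", "C", "D")
  pres <- replicate(30, paste(sample(tips, sample(4, 1)), collapse = ","))
  ev <- data.frame(event_id = seq_along(pres), vtype = "insertion",
                   presence = pres)
  asg <- place_events(ev, tr, "Out")
  bt <- attr(asg, "branch_table")
  counts <- plastovar:::origin_counts(asg, bt, "insertion")
  expect_equal(sum(counts), sum(asg$n_independent_origins))
})

test_that("presence matrices use 0/1/? coding and round-trip via PHYLIP", {
  ev <- data.frame(event_id = 1:2, vtype = "insertion",
                   presence = c("A,B", "C"), unpolarized = c(FALSE, TRUE))
  m <- presence_matrix(ev, c("A", "B", "C", "Out"), outgroup = "Out")
  expect_equal(dim(m), c(4L, 2L))
  expect_equal(unname(m[, 1]), c("1", "1", "0", "0"))
  expect_equal(unname(m["C", 2]), "1")
  expect_equal(unname(m["A", 2]), "?")               # unresolved polarity
  expect_equal(unname(m["Out", 2]), "0")
  tf <- withr::local_tempfile(fileext = ".phy")
  write_presence_matrix(m, tf)
  expect_equal(unname(read_presence_matrix(tf)), unname(m))
  expect_equal(rownames(read_presence_matrix(tf)), rownames(m))
  tn <- withr::local_tempfile(fileext = ".nex")
  write_presence_matrix(m, tn, format = "nexus")
  expect_true(any(grepl("DATATYPE=STANDARD", readLines(tn))))
})

test_that("count-duration correlation is 1 for proportional counts and flagged
           when degenerate", {
  tr <- five_taxon_tree()
  bt <- plastovar:::branch_table(tr)
  # assignments with exactly 2 origins per Myr on every branch
  branches <- rep(bt$branch_id, round(bt$duration * 2))
  asg <- data.frame(event_id = seq_along(branches), vtype = "insertion",
                    branches = branches, n_independent_origins = 1L,
                    n_losses = 0L, method = "clade-consistent",
                    stringsAsFactors = FALSE)
  attr(asg, "branch_table") <- bt
  class(asg) <- c("branch_assignments", "data.frame")
  r <- branch_length_correlation(asg, tr, n_perm = 99, seed = 5)
  expect_true(r$defined)
  expect_equal(r$pearson, 1.0, tolerance = 1e-9)
  # constant counts -> undefined
  r2 <- branch_length_correlation(asg[0, ], tr, n_perm = 99, seed = 5)
  expect_false(r2$defined)
  expect_true(is.na(r2$pearson))
})
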