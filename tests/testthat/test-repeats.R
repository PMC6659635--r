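# Repeat finders (Rt/Rp/Rd/SSR), category precedence, shared repeats and
# repeat gain/loss placement.

test_that("planted tandem arrays are found and sub-threshold units are not", {
  set.seed(51)
  unit <- random_dna(16)
  s <- plant_in(random_dna(1000), strrep(unit, 3), 501)
  rt <- find_tandem(s, max_unit = 60)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$unit_length, 16L)
  expect_gte(rt$copies, 3L)
  # the reported maximal array covers the planted one (it may extend into
  # the background by chance, so containment rather than identity)
  expect_lte(rt$start, 501L)
  expect_gte(rt$end, 548L)
  expect_equal(substring(s, rt$start + 16L, rt$start + 31L),
               substring(s, rt$start, rt$start + 15L))
  # 14-bp unit repeated twice is below the 15-bp minimum
  u14 <- random_dna(14)
  s2 <- plant_in(random_dna(1000), strrep(u14, 2), 501)
  expect_equal(nrow(find_tandem(s2, max_unit = 60)), 0L)
})

test_that("planted palindromes are found at >= 20 bp and not below", {
  set.seed(52)
  arm <- random_dna(22)
  s <- paste0(random_dna(300), arm, random_dna(50), revcomp_chr(arm),
              random_dna(300))
  rp <- find_palindromic(s)
  expect_equal(nrow(rp), 1L)
  expect_gte(rp$unit_length, 22L)        # exact run may extend by chance
  expect_lte(rp$start, 301L)
  arm19 <- random_dna(19)
  s2 <- paste0(random_dna(300), arm19, random_dna(50), revcomp_chr(arm19),
               random_dna(300))
  rp2 <- find_palindromic(s2)
  expect_true(nrow(rp2) == 0L || all(rp2$unit_length >= 20L))
})

test_that("dispersed pairs are found; adjacent copies classify as tandem", {
  set.seed(53)
  seg <- random_dna(35)
  s <- paste0(random_dna(200), seg, random_dna(400), seg, random_dna(200))
  rd <- find_dispersed(s)
  expect_equal(nrow(rd), 1L)
  expect_gte(rd$unit_length, 35L)
  # the same segment duplicated adjacently is Rt, not Rd
  s2 <- paste0(random_dna(200), seg, seg, random_dna(200))
  expect_equal(nrow(find_dispersed(s2)), 0L)
  rt <- find_tandem(s2, max_unit = 60)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$unit_length, 35L)
})

test_that("SSR spans sit exactly at the class thresholds", {
  set.seed(54)
  repeat {   # background certified SSR-free by the independent oracle
    bg <- random_dna(400)
    if (nrow(oracle_ssrs(bg)) == 0L) break
  }
  mk <- function(core) {   # C guards stop chance extension of the array
    paste0(substring(bg, 1, 200), "C", core, "C", substring(bg, 201, 400))
  }
  ssr <- find_ssrs(mk("ATATATAT"))
  expect_equal(nrow(ssr), 1L)
  expect_equal(ssr$motif, "AT")
  expect_equal(ssr$span, 8L)
  expect_equal(nrow(find_ssrs(mk("ATATAT"))), 0L)
  # primitive-unit rule: the AT array must not also be reported as ATAT
  long_at <- find_ssrs(mk(strrep("AT", 8)))
  expect_equal(long_at$unit_length, 2L)
  # mononucleotide runs are never SSRs
  expect_equal(nrow(find_ssrs(mk(strrep("A", 20)))), 0L)
})

test_that("every reported occurrence reproduces its unit from the sequence", {
  set.seed(55)
  for (i in 1:5) {
    s <- random_dna(1500)
    s <- plant_in(s, strrep(random_dna(17), 3), sample(400, 1))
    arm <- random_dna(25)
    s <- plant_in(s, paste0(arm, random_dna(30), revcomp_chr(arm)), 600)
    seg <- random_dna(32)
    s <- plant_in(s, paste0(seg, random_dna(200), seg), 900)
    occ <- find_repeats(s, mask_ira = FALSE)
    expect_true(check_occurrences(s, occ))
  }
})

test_that("no occurrence is reported under two of Rt/Rp/Rd", {
  set.seed(56)
  s <- random_dna(800)
  s <- plant_in(s, strrep(random_dna(40), 3), 400)  # long Rt, also a direct pair
  occ <- find_repeats(s, mask_ira = FALSE)
  rt <- occ[occ$category == "Rt", ]
  rd <- occ[occ$category == "Rd", ]
  expect_gte(nrow(rt), 1L)
  # no Rd pair fully inside a tandem array
  if (nrow(rd)) {
    for (x in seq_len(nrow(rd))) {
      expect_false(any(rd$start[x] >= rt$start & rd$end2[x] <= rt$end))
    }
  }
})

test_that("finder output is stable under rotations that avoid the repeats", {
  set.seed(57)
  s <- paste0(random_dna(300), strrep(random_dna(16), 3), random_dna(500))
  arm <- random_dna(21)
  s <- paste0(s, arm, random_dna(40), revcomp_chr(arm), random_dna(100))
  sig <- function(x) {
    occ <- find_repeats(x, mask_ira = FALSE)
    occ <- occ[order(occ$category, occ$unit_length), ]
    occ[, c("category", "unit_length", "copies", "span")]
  }
  a <- sig(s)
  b <- sig(plastovar:::rotate_seq(s, 150))  # rotation point in plain background
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("masking the IRa keeps the genome-scale IR out of the Rp output", {
  set.seed(58)
  g <- toy_quadripartite_genome(1500, 300, 400)
  p <- plastome("g", g)
  p$partition <- detect_quadripartite(p, min_ir_len = 200)
  occ <- find_repeats(p)
  expect_false(any(occ$category == "Rp" & occ$unit_length >= 250))
  occ2 <- find_repeats(p, mask_ira = FALSE)
  expect_true(any(occ2$category == "Rp" & occ2$unit_length >= 250))
})

test_that("shared repeats group by alignment position and membership", {
  set.seed(59)
  sim <- quick_sim(seed = 60, ins_rate = 0, del_rate = 0, sub_rate = 2e-4,
                   dup_rate = 0)
  taxa <- names(sim$genomes)
  occ <- do.call(rbind, lapply(taxa, function(t) {
    o <- find_tandem(sim$genomes[[t]]$seq, max_unit = 40)
    if (nrow(o)) o$genome <- t
    o
  }))
  # plant a shared tandem by construction instead: all genomes identical up
  # to substitutions, so any repeat present in all is one full group
  if (!is.null(occ) && NROW(occ)) {
    groups <- group_shared_repeats(occ, sim$alignment)
    expect_true(all(groups$n_members >= 1))
  }
  # explicit toy: same repeat in 2 of 3 taxa at orthologous positions
  mat <- rbind(out = seq_chars("AAAATTTTCCCCGGGGAAAA"),
               A   = seq_chars("AAAATTTTCCCCGGGGAAAA"),
               B   = seq_chars("AAAATTTTCCCCGGGGAAAA"))
  a <- aligned_set(mat)
  occ2 <- data.frame(genome = c("A", "B"), category = "Rt",
                     unit_length = 4L, start = c(5L, 5L), end = c(12L, 12L),
                     start2 = NA_integer_, end2 = NA_integer_, copies = 2L,
                     span = 8L, unit = "TTTT", motif = NA_character_)
  g2 <- group_shared_repeats(occ2, a)
  expect_equal(nrow(g2), 1L)
  expect_equal(g2$n_members, 2L)
  expect_error(group_shared_repeats(transform(occ2, genome = c("A", "zz")), a),
               "absent")
})

test_that("repeat groups place on the tree as gains on the right branches", {
  tr <- ape::read.tree(text = "(Out:3,((A:1,B:1):1,C:2):1);")
  groups <- data.frame(group_id = 1:3, category = c("Rt", "Rt", "Rp"),
                       anchor_col = c(10L, 50L, 90L),
                       members = c("A", "A,B,C", "A,B"),
                       n_members = c(1L, 3L, 2L),
                       has_length_variation = FALSE, has_snv = FALSE)
  ret <- repeat_events_on_tree(groups, tr, "Out")
  asg <- ret$assignments
  expect_equal(asg$branches[asg$event_id == 1], "A")       # tip gain
  expect_match(asg$branches[asg$event_id == 2], "^node")   # crown stem gain
  summ <- ret$summary
  expect_equal(summ$n_groups[summ$category == "Rt"], 2L)
  expect_equal(sum(summ$share), 1)
})

test_that("repeat GFF3 export writes one line per copy", {
  set.seed(61)
  seg <- random_dna(32)
  s <- paste0(random_dna(100), seg, random_dna(200), seg, random_dna(100))
  occ <- find_dispersed(s)
  occ$genome <- "g"
  tf <- withr::local_tempfile(fileext = ".gff3")
  write_repeats_gff3(occ, tf)
  gr <- rtracklayer::import(tf)
  expect_equal(length(gr), 2L * nrow(occ))
})
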