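# SNV/indel extraction, context annotation, densities, spectra and export.

test_that("a two-taxon shared gap is one deletion event", {
  a <- aligned_set(c(out = "ACGTACGT", A = "ACGTACGT",
                     B = "ACG--CGT", C = "ACG--CGT"))
  ev <- extract_events(a, "out")
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$vtype, "deletion")
  expect_equal(ev$length, 2L)
  expect_setequal(strsplit(ev$presence, ",")[[1]], c("B", "C"))
})

test_that("residues opposite an outgroup gap are one insertion event", {
  a <- aligned_set(c(out = "AC--GT", A = "ACTTGT", B = "ACTTGT"))
  ev <- extract_events(a, "out")
  expect_equal(ev$vtype, "insertion")
  expect_equal(ev$length, 2L)
  expect_setequal(strsplit(ev$presence, ",")[[1]], c("A", "B"))
})

test_that("multi-allelic SNV columns yield one event per derived state", {
  a <- aligned_set(c(out = "A", x = "C", y = "G", z = "C"))
  ev <- extract_events(a, "out")
  expect_equal(sort(ev$derived), c("C", "G"))
  expect_false(any(ev$unpolarized))
  # outgroup gap/N makes the column unpolarized
  a2 <- aligned_set(c(out = "N", x = "C", y = "G", z = "C"))
  ev2 <- extract_events(a2, "out")
  expect_true(all(ev2$unpolarized))
  expect_equal(ev2$ancestral, "C")   # majority provisional ancestral
})

test_that("extraction is invariant under taxon row order", {
  set.seed(21)
  mat <- random_gappy_alignment(6, 200)
  a1 <- aligned_set(mat)
  a2 <- aligned_set(mat[sample(nrow(mat)), , drop = FALSE])
  norm <- function(ev) {
    ev$presence <- vapply(strsplit(ev$presence, ","),
                          function(x) paste(sort(x), collapse = ","), "")
    ev <- ev[order(ev$vtype, ev$col_start, ev$presence, ev$derived),
             c("vtype", "col_start", "col_end", "length", "presence")]
    rownames(ev) <- NULL
    ev
  }
  expect_equal(norm(extract_events(a1, "out")),
               norm(extract_events(a2, "out")))
})

test_that("inconsistent genome lengths are a hard error", {
  g <- list(A = plastome("A", "ACG"))
  expect_error(aligned_set(c(out = "ACGTT", A = "AC-TT"), genomes = g),
               "ConsistencyError")
})

test_that("extraction equals the column-scanning oracle on random alignments", {
  set.seed(31)
  for (rep in 1:40) {
    mat <- random_gappy_alignment(6, sample(80:300, 1),
                                  n_indels = sample(2:8, 1),
                                  n_snvs = sample(0:10, 1))
    got <- extract_events(aligned_set(mat), "out")
    want <- oracle_extract_events(mat, "out")
    got$presence <- vapply(strsplit(got$presence, ","),
                           function(x) paste(sort(x), collapse = ","), "")
    got <- as.data.frame(got)[order(got$vtype, got$col_start, got$presence),
                              c("vtype", "col_start", "col_end", "length",
                                "presence", "unpolarized")]
    want <- want[order(want$vtype, want$col_start, want$presence), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = paste("replicate", rep))
  }
})

test_that("context annotation follows CDS > RNA > intron > intergenic", {
  set.seed(8)
  g <- toy_quadripartite_genome(800, 200, 300)
  f <- bind_features(
    gene_features("rbcL", "CDS", "+", c(100, 200), c(150, 260)),
    gene_features("trnX", "tRNA", "+", 140, 170),   # overlaps rbcL exon 1
    gene_features("rps12", "CDS", "+", c(400, 500), c(420, 520),
                  trans_spliced = TRUE))
  p <- plastome("ref", g, f)
  p$partition <- detect_quadripartite(p, min_ir_len = 100)
  ev <- data.frame(event_id = 1:5, vtype = "SNV",
                   col_start = 1:5, col_end = 1:5, length = 1L,
                   ref_pos = c(145L, 160L, 180L, 450L, 300L),
                   ancestral = "A", derived = "C", presence = "A",
                   unpolarized = FALSE, region = NA_character_,
                   context = NA_character_, ira_mirror = FALSE)
  ev <- annotate_context(ev, p)
  # 145: CDS exon beats overlapping tRNA; 160: tRNA only; 180: rbcL intron;
  # 450: between trans-spliced exons is NOT an intron; 300: intergenic
  expect_equal(ev$context,
               c("CDS-exon", "RNA-gene", "intron", "intergenic", "intergenic"))
  expect_equal(ev$region, rep("LSC", 5))
  ev_bad <- ev; ev_bad$ref_pos[1] <- 99999L
  expect_error(annotate_context(ev_bad, p), "outside")
})

test_that("density table does the per-kb arithmetic and pools the IR", {
  set.seed(9)
  g <- toy_quadripartite_genome(1700, 200, 300)  # LSC 1700 => genome 2400
  q <- detect_quadripartite(g, min_ir_len = 100)
  expect_equal(unname(region_lengths(q)["LSC"]), 1700L)
  # place 10 SNVs in the LSC and check the count / region-length arithmetic
  ev <- data.frame(event_id = 1:10, vtype = "SNV", col_start = 1:10,
                   col_end = 1:10, length = 1L,
                   ref_pos = seq(10L, 1000L, length.out = 10),
                   ancestral = "A", derived = "C", presence = "A",
                   unpolarized = FALSE, region = "LSC",
                   context = "intergenic", ira_mirror = FALSE)
  dt <- density_table(ev, q, taxa = "A")
  lsc <- dt[dt$taxon == "A" & dt$region == "LSC" & dt$vtype == "SNV", ]
  expect_equal(lsc$count, 10)
  expect_equal(lsc$per_kb, 1000 * 10 / 1700)
  genome <- dt[dt$taxon == "A" & dt$region == "genome" & dt$vtype == "SNV", ]
  expect_equal(genome$per_kb, 1000 * 10 / 2400)
  # per-region counts sum to the whole-genome count
  per_reg <- dt[dt$taxon == "A" & dt$region != "genome" & dt$vtype == "SNV", ]
  expect_equal(sum(per_reg$count), genome$count)
  # zero events
  dt0 <- density_table(ev[0, ], q, taxa = "A")
  expect_true(all(dt0$count == 0))
  expect_true(all(dt0$per_kb == 0))
})

test_that("indel spectrum bins, fractions and the in-CDS multiple-of-3 rule", {
  ev <- data.frame(event_id = 1:4, vtype = c("deletion", "insertion",
                                             "deletion", "insertion"),
                   col_start = 1:4, col_end = 1:4,
                   length = c(1L, 2L, 3L, 12L), ref_pos = 1:4,
                   ancestral = "x", derived = "y", presence = "A",
                   unpolarized = FALSE,
                   region = "LSC", context = "intergenic", ira_mirror = FALSE)
  sp <- indel_spectrum(ev)
  expect_equal(sp$frac_lt10, 0.75)
  expect_equal(unname(sp$bins), c(1L, 2L, 1L, 0L))
  ev$context <- c("CDS-exon", "CDS-exon", "CDS-exon", "intergenic")
  ev$length <- c(3L, 4L, 6L, 12L)
  expect_equal(indel_spectrum(ev)$frac_multiple_of_3_in_cds, 2 / 3)
})

test_that("alignment summary matches the site definitions and the oracle", {
  a <- aligned_set(matrix(c("A", "A", "C", "C"), ncol = 1,
                          dimnames = list(c("w", "x", "y", "z"), NULL)))
  s <- alignment_summary(a)
  expect_equal(s$variable_sites, 1L)
  expect_equal(s$informative_sites, 1L)
  a2 <- aligned_set(matrix(c("A", "A", "A", "C"), ncol = 1,
                           dimnames = list(c("w", "x", "y", "z"), NULL)))
  expect_equal(alignment_summary(a2)$informative_sites, 0L)
  ident <- aligned_set(matrix("A", 4, 100,
                              dimnames = list(c("w", "x", "y", "z"), NULL)))
  expect_equal(alignment_summary(ident),
               list(aligned_length_without_gaps = 100L, variable_sites = 0L,
                    informative_sites = 0L))
  set.seed(17)
  for (i in 1:20) {
    mat <- random_gappy_alignment(sample(4:8, 1), sample(50:200, 1))
    expect_equal(alignment_summary(aligned_set(mat)),
                 oracle_alignment_summary(mat))
  }
})

test_that("variant TSV export round-trips and the VCF-like file is anchored", {
  a <- aligned_set(c(out = "ACGTACGT", A = "ACGTACGT",
                     B = "ACG--CGT", C = "TCG--CGT"))
  ev <- extract_events(a, "out")
  tf <- withr::local_tempfile(fileext = ".tsv")
  vf <- withr::local_tempfile(fileext = ".vcf")
  export_variants(ev, tf, vcf_path = vf, ref_id = "A")
  back <- import_variants(tf)
  expect_equal(as.data.frame(back), as.data.frame(ev)[, names(back)])
  vcf <- readLines(vf)
  data_lines <- vcf[!startsWith(vcf, "#")]
  expect_equal(length(data_lines), nrow(ev))
  del <- strsplit(data_lines[grepl("<DEL>", data_lines)], "\t")[[1]]
  expect_equal(as.integer(del[2]), ev$ref_pos[ev$vtype == "deletion"] - 1L)
})
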