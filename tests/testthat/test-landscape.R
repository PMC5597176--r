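test_that("planted arrays start at the +1 and repeat at the period", {
  ## gene length chosen so exactly 5 array nucleosomes fit
  ann <- build_toy_genome(toy_genome_spec(
    chrom_lengths = c(chr1 = 60000L), n_genes = 4L, gene_length = 900L,
    intergenic_spacing = 9100L, seed = 1L))
  ls <- plant_landscape(ann, seed = 2L)
  g1 <- ann$genes[strand == "+"][1]
  dy <- ls$templates[gene_id == g1$gene_id &
                       role %in% c("plus1", "array")]$center
  expect_equal(sort(dy), g1$tss + 100L + (0:4) * 180L)
  ## minus strand mirrors
  g2 <- ann$genes[strand == "-"][1]
  dy2 <- ls$templates[gene_id == g2$gene_id &
                        role %in% c("plus1", "array")]$center
  expect_equal(sort(dy2, decreasing = TRUE), g2$tss - 100L - (0:4) * 180L)
})

test_that("planted occupancies respect the lability invariants", {
  ls <- small_experiment_landscape(n_genes = 10L, seed = 3L)
  tpl <- ls$templates
  m1 <- tpl[role == "minus1"]
  expect_true(all(m1$labile))
  expect_true(all(m1$occ_high < m1$occ_low))
  sub <- tpl[kind == "subNSP"]
  expect_true(all(sub$occ_high <= sub$occ_low))
  expect_true(all(template_occupancy(tpl, "light", "low") >= 0 &
                    template_occupancy(tpl, "light", "low") <= 1))
})

test_that("a zero dark condition factor silences the planted footprint", {
  tpl <- data.table::data.table(chrom = "chr1", center = 500L, width = 60L,
                                kind = "subNSP", occ_low = 0.8,
                                f_light = 1, f_dark = 0)
  ls <- manual_landscape(tpl, c(chr1 = 2000L))
  expect_equal(template_occupancy(ls$templates, "dark", "low"), 0)
  fr <- sample_fragments(ls, sample_spec("d", "dark", clean_digestion(),
                                         depth = 500, seed = 1))
  expect_equal(nrow(fr), 0L)
})

test_that("degenerate sampling limits behave exactly", {
  ## all occupancies zero, no background -> empty set
  tpl <- data.table::data.table(chrom = "chr1", center = 500L, width = 150L,
                                occ_low = 0)
  ls <- manual_landscape(tpl, c(chr1 = 2000L))
  expect_equal(nrow(sample_fragments(
    ls, sample_spec("s", "light", clean_digestion(), depth = 100,
                    seed = 1))), 0L)
  ## zero depth -> empty, not an error
  expect_equal(nrow(sample_fragments(
    ls, sample_spec("s", "light", clean_digestion(), depth = 0,
                    seed = 1))), 0L)
  ## occupancy 1, jitter 0, p_link 0 -> every fragment is the 150 bp span
  tpl2 <- data.table::data.table(chrom = "chr1", center = 500L,
                                 width = 150L, occ_low = 1)
  ls2 <- manual_landscape(tpl2, c(chr1 = 2000L))
  fr <- sample_fragments(ls2, sample_spec("s", "light", clean_digestion(),
                                          depth = 200, seed = 2))
  expect_equal(nrow(fr), 200L)
  expect_true(all(fr$start == 425L & fr$end == 575L))
})

test_that("full linkage of two adjacent nucleosomes yields 330 bp fragments", {
  tpl <- data.table::data.table(chrom = "chr1", center = c(500L, 680L),
                                width = 150L, occ_low = 1)
  ls <- manual_landscape(tpl, c(chr1 = 2000L))
  fr <- sample_fragments(ls, sample_spec(
    "s", "light", clean_digestion(p_link = 1), depth = 200, seed = 3))
  expect_true(all(fr$length == 330L))             # 2*150 + 30
  ## independent per-junction enumeration: p_link p gives mean fragment
  ## count 2 - p per pass (one junction, both nucleosomes always survive)
  p <- 0.4
  fr2 <- sample_fragments(ls, sample_spec(
    "s", "light", clean_digestion(p_link = p), depth = 4000, seed = 4))
  npass <- 4000 / ls$expected_yield
  expect_equal(nrow(fr2) / npass, 2 - p, tolerance = 0.05)
  expect_true(all(fr2$length %in% c(150L, 330L)))
})

test_that("per-template fragment counts follow the occupancy binomially", {
  tpl <- data.table::data.table(chrom = "chr1",
                                center = c(500L, 2000L, 3500L),
                                width = 150L, occ_low = c(0.2, 0.5, 0.9))
  ls <- manual_landscape(tpl, c(chr1 = 5000L))
  npass <- 1200L
  fr <- sample_fragments(ls, sample_spec(
    "s", "light", clean_digestion(), depth = npass * ls$expected_yield,
    seed = 8))
  for (i in 1:3) {
    n_obs <- sum(fr$start == tpl$center[i] - 75L)
    expected <- npass * tpl$occ_low[i]
    sd4 <- 4 * sqrt(npass * tpl$occ_low[i] * (1 - tpl$occ_low[i]))
    expect_lt(abs(n_obs - expected), sd4)
  }
})

test_that("with mild jitter nearly all mono fragments stay in [120, 180]", {
  tpl <- data.table::data.table(chrom = "chr1",
                                center = seq(500L, 9500L, by = 500L),
                                width = 150L, occ_low = 0.9)
  ls <- manual_landscape(tpl, c(chr1 = 10000L))
  fr <- sample_fragments(ls, sample_spec(
    "s", "light", clean_digestion(jitter = 5), depth = 20000, seed = 9))
  expect_gt(nrow(fr), 1000L)
  expect_gte(mean(fr$length >= 120 & fr$length <= 180), 0.99)
})

test_that("identical spec and seed reproduce fragment sets byte-identically", {
  ls <- small_experiment_landscape(n_genes = 6L, seed = 4L)
  sp <- sample_spec("s", "light", digestion_setting("low"), depth = 5000,
                    seed = 77L)
  f1 <- sample_fragments(ls, sp)
  f2 <- sample_fragments(ls, sp)
  expect_identical(f1, f2)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_fragment_bed(f1, p1); write_fragment_bed(f2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("digestion index rises from low to high digestion settings", {
  ls <- small_experiment_landscape(n_genes = 10L, seed = 5L)
  wins <- 0L
  runs <- 25L
  for (i in seq_len(runs)) {
    lo <- sample_fragments(ls, sample_spec(
      "lo", "light", digestion_setting("low", p_link = 0.6),
      depth = 2e4, seed = 1000L + i))
    hi <- sample_fragments(ls, sample_spec(
      "hi", "light", digestion_setting("high", p_link = 0.1),
      depth = 2e4, seed = 2000L + i))
    wins <- wins + (digestion_index(hi) > digestion_index(lo))
  }
  expect_gte(wins / runs, 0.95)
})
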