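ann6 <- build_toy_genome(toy_genome_spec(chrom_lengths = c(chr1 = 40000L),
                                         n_genes = 6L, seed = 2L))

test_that("anchors honor strand conventions and the shared-isoform filter", {
  tssa <- extract_anchors(ann6, "TSS")
  gp <- ann6$genes[strand == "+"][1]
  expect_equal(tssa[feature_id == gp$gene_id, pos], gp$tss)
  gm <- ann6$genes[strand == "-"][1]
  expect_equal(tssa[feature_id == gm$gene_id, pos], gm$end - 1L)
  cssa <- extract_anchors(ann6, "CSS")
  expect_equal(cssa[feature_id == gp$gene_id, pos], gp$tss + 300L)
  ann_mod <- ann6
  ann_mod$genes$shared_isoform <- rep(c(TRUE, FALSE), 3L)
  expect_equal(nrow(extract_anchors(ann_mod, "TSS", shared_only = TRUE)), 3L)
  expect_error(extract_anchors(ann6, "promoter"))
})

test_that("exon-boundary anchors come from the same machinery", {
  eb <- extract_anchors(ann6, "exon_boundary")
  ## two-exon genes: one donor + one acceptor each
  expect_equal(nrow(eb), 2L * nrow(ann6$genes))
  gp <- ann6$genes[strand == "+"][1]
  don <- eb[feature_id == paste0(gp$gene_id, ".donor1"), pos]
  expect_equal(don, gp$start + 1000L - 1L)        # last base of exon 1
  expect_true(all(eb$kind == "exon_boundary"))
})

test_that("profile rows slice the track, strand-flipped and NA off the edge", {
  vals <- seq(0, 999)
  tr <- occupancy_track(vals, "chr1", mode = "midpoint")
  a_plus <- data.table::data.table(feature_id = "a", chrom = "chr1",
                                   pos = 500L, strand = "+", kind = "TSS")
  pm <- profile_matrix(tr, a_plus, flank = 10L, bin = 1L)
  expect_equal(unname(pm$values[1, ]), vals[(500 - 10):(500 + 9) + 1])
  expect_equal(unname(pm$values[1, pm$offsets == 0]), 500)
  ## minus strand reverses so positive offsets run downstream
  a_minus <- data.table::data.table(feature_id = "b", chrom = "chr1",
                                    pos = 500L, strand = "-", kind = "TSS")
  pmm <- profile_matrix(tr, a_minus, flank = 10L, bin = 1L)
  expect_equal(unname(pmm$values[1, ]), vals[(500 + 10):(500 - 9) + 1])
  ## anchor 50 bp from the chromosome start: leading cells NA, not zero
  a_edge <- data.table::data.table(feature_id = "c", chrom = "chr1",
                                   pos = 50L, strand = "+", kind = "TSS")
  pme <- profile_matrix(tr, a_edge, flank = 500L, bin = 1L)
  expect_true(all(is.na(pme$values[1, pme$offsets < -50])))
  expect_false(anyNA(pme$values[1, pme$offsets >= -50]))
  expect_error(profile_matrix(tr, a_plus[0], flank = 10L), "anchors")
})

test_that("aggregates average per column and skip missing cells", {
  pm <- list(values = rbind(c(1, 2, 3), c(3, 2, 1)), offsets = c(-1L, 0L, 1L),
             bin_size = 1L, anchors = NULL)
  class(pm) <- "profile_matrix"
  agg <- aggregate_profile(pm)
  expect_equal(agg$value, c(2, 2, 2))
  pm$values[2, 1] <- NA
  agg2 <- aggregate_profile(pm)
  expect_equal(agg2$value[1], 1)                  # remaining row only
  expect_equal(agg2$n, c(1L, 2L, 2L))
})

test_that("mirrored deterministic landscapes give exactly mirrored profiles", {
  L <- 4000L
  mk <- function(centers, strand, tsspos) {
    tpl <- data.table::data.table(chrom = "chr1", center = centers,
                                  width = 150L, occ_low = 1)
    ls <- manual_landscape(tpl, c(chr1 = L))
    fr <- sample_fragments(ls, sample_spec("s", "light", clean_digestion(),
                                           depth = 100, seed = 1))
    tr <- midpoint_track(fr, c(chr1 = L))
    anc <- data.table::data.table(feature_id = "g", chrom = "chr1",
                                  pos = tsspos, strand = strand,
                                  kind = "TSS")
    aggregate_profile(profile_matrix(tr, anc, flank = 400L))
  }
  fwd <- mk(c(2100L, 2280L), "+", 2000L)
  rev <- mk(L - 1L - c(2100L, 2280L), "-", L - 1L - 2000L)
  expect_equal(fwd$value, rev$value)
})

test_that("digestion index computes the mono fraction and its limits", {
  fr <- fragment_set("chr1", c(0L, 0L), c(150L, 150L))
  expect_equal(digestion_index(fr), 1)
  fr2 <- fragment_set("chr1", c(0L, 0L, 500L, 500L),
                      c(150L, 150L, 830L, 830L))
  expect_equal(digestion_index(fr2), 0.5)
  fr3 <- fragment_set("chr1", 0L, 80L)
  expect_error(digestion_index(fr3), "nucleosomal")
  ## pluggable estimator
  expect_equal(digestion_index(fr2, estimator = function(f, s)
    median(f$length)), 240)
})

test_that("per-bin digestion correlation flags degenerate bins", {
  prof <- rbind(c(2, 5, 1), c(4, 5, 1), c(6, 5, 2), c(8, 5, 1))
  idx <- c(1, 2, 3, 4)
  dc <- digestion_correlation(prof, idx, offsets = c(0L, 10L, 20L), bin = 10L)
  expect_equal(dc$r[1], 1)                        # perfect linearity
  expect_true(dc$undefined[2])                    # zero variance
  expect_true(is.na(dc$r[2]))
  expect_true(all(dc$r >= -1 & dc$r <= 1, na.rm = TRUE))
  expect_error(digestion_correlation(prof[1:2, ], idx[1:2],
                                     offsets = c(0L, 10L, 20L)), ">= 3")
})

test_that("the window occupancy test matches the textbook Welch computation", {
  prof <- rbind(c(2, 10), c(4, 12), c(4, 10), c(6, 12),
                c(12, 11), c(14, 13), c(14, 9), c(16, 13))
  groups <- rep(c("low", "high"), each = 4L)
  res <- window_occupancy_test(prof, groups, offsets = c(-100L, 100L),
                               windows = list(minus1 = c(-125L, -75L),
                                              plus1 = c(75L, 125L)))
  o <- welch_oracle(c(2, 4, 4, 6), c(12, 14, 14, 16))
  m1 <- res[res$window == "minus1", ]
  expect_equal(m1$t, o$t, tolerance = 1e-9)
  expect_equal(m1$p, o$p, tolerance = 1e-9)
  expect_true(m1$significant)
  ## identical groups: t = 0, not significant
  prof2 <- rbind(c(10, 0), c(12, 0), c(10, 0), c(12, 0))
  res2 <- window_occupancy_test(prof2, c("low", "low", "high", "high"),
                                offsets = c(-100L, 100L))
  expect_equal(res2[res2$window == "minus1", ]$t, 0)
  expect_false(res2[res2$window == "minus1", ]$significant)
  ## constant equal groups are flagged degenerate
  expect_true(res2[res2$window == "plus1", ]$degenerate)
  expect_error(window_occupancy_test(prof2[1:3, ],
                                     c("low", "low", "high"),
                                     offsets = c(-100L, 100L)), ">= 2")
})

test_that("the +1 peak position is found, smoothed and NA when flat", {
  offsets <- -300:299
  vals <- numeric(600)
  vals[offsets == 100] <- 10                      # planted dyad at +100
  expect_equal(plus1_position(vals, offsets), 100L)
  expect_true(is.na(plus1_position(numeric(600), offsets)))
  ## jittered peak: smoothing keeps the argmax close
  set.seed(12)
  noisy <- vals + runif(600, 0, 0.3)
  noisy[offsets %in% 95:105] <- noisy[offsets %in% 95:105] + 5
  expect_lte(abs(plus1_position(noisy, offsets) - 100), 15)
})

test_that("a planted downstream shift is recovered per gene", {
  L <- 6000L
  mk_pm <- function(dyad) {
    tpl <- data.table::data.table(chrom = "chr1", center = dyad,
                                  width = 150L, occ_low = 0.9)
    ls <- manual_landscape(tpl, c(chr1 = L))
    fr <- sample_fragments(ls, sample_spec(
      "s", "light", clean_digestion(jitter = 8), depth = 150, seed = 21))
    tr <- midpoint_track(fr, c(chr1 = L))
    anc <- data.table::data.table(feature_id = "g", chrom = "chr1",
                                  pos = 3000L, strand = "+", kind = "TSS")
    profile_matrix(tr, anc, flank = 400L)
  }
  sh <- plus1_shift(mk_pm(3100L), mk_pm(3130L))
  expect_lt(abs(sh$shift - 30), 10)
})
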