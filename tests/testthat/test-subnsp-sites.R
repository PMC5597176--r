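test_that("position calling finds planted footprints and obeys its contracts", {
  ## one strong footprint over a diffuse small-particle floor -> exactly
  ## one call at the planted center
  tpl <- rbind(
    data.table::data.table(chrom = "chr1", center = 1000L, width = 60L,
                           kind = "subNSP", occ_low = 0.8),
    data.table::data.table(chrom = "chr1",
                           center = seq(200L, 4800L, by = 150L),
                           width = 50L, kind = "subNSP", occ_low = 0.05))
  ls <- manual_landscape(tpl, c(chr1 = 5000L))
  fr <- sample_fragments(ls, sample_spec(
    "s", "light", clean_digestion(jitter = 6), depth = 800, seed = 2))
  tr <- subnsp_midpoint_track(fr, c(chr1 = 5000L))
  pos <- call_subnsp_positions(tr)
  expect_equal(nrow(pos), 1L)
  expect_lte(abs(pos$pos - 1000L), 10L)
  ## all-zero track -> empty list
  empty <- list(chr1 = occupancy_track(numeric(2000), "chr1",
                                       mode = "midpoint"))
  expect_equal(nrow(call_subnsp_positions(empty)), 0L)
  ## two peaks 40 bp apart under min_sep 60: only the higher is kept
  v <- numeric(2000); v[1001] <- 10; v[1041] <- 6
  two <- list(chr1 = occupancy_track(v, "chr1", mode = "midpoint"))
  pos2 <- call_subnsp_positions(two, smooth_bw = 1L, threshold_k = 0.5,
                                min_sep = 60L)
  expect_equal(nrow(pos2), 1L)
  expect_equal(pos2$pos, 1000L)
  ## uniform noise below threshold -> no calls
  flat <- list(chr1 = occupancy_track(rep(1, 2000), "chr1",
                                      mode = "midpoint"))
  expect_equal(nrow(call_subnsp_positions(flat, threshold_k = 4)), 0L)
})

test_that("calling is deterministic and iteration-order independent", {
  set.seed(5)
  v1 <- pmax(0, rnorm(3000, 0.05, 0.2)); v1[c(501, 1501)] <- 8
  v2 <- pmax(0, rnorm(2000, 0.05, 0.2)); v2[801] <- 9
  t1 <- occupancy_track(v1, "chr1", mode = "midpoint")
  t2 <- occupancy_track(v2, "chr2", mode = "midpoint")
  a <- call_subnsp_positions(list(chr1 = t1, chr2 = t2))
  b <- call_subnsp_positions(list(chr2 = t2, chr1 = t1))
  expect_identical(a, b)
})

test_that("CDS distances equal the brute-force all-pairs oracle", {
  cds <- data.table::data.table(
    gene_id = "g", chrom = c("chr1", "chr1", "chr2"),
    start = c(5000L, 5200L, 100L), end = c(5100L, 5400L, 900L))
  ann <- structure(list(cds = cds), class = "genome_annotation")
  pos <- data.table::data.table(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2",
              "chr1", "chr1", "chr2", "chr1"),
    pos = c(5050L, 2000L, 5150L, 9000L, 0L, 500L, 4999L, 5400L, 899L,
            120000L))
  d <- distance_to_nearest_cds(pos, ann)
  expect_equal(d, brute_cds_distance(pos, cds))
  expect_equal(d[1], 0)                            # inside a CDS
  expect_equal(d[2], 3000)                         # 3 kb left of the start
  ## randomized instances
  set.seed(6)
  for (i in 1:10) {
    rc <- data.table::data.table(
      gene_id = "g", chrom = "chr1",
      start = sort(sample.int(100000L, 8L)))
    rc[, end := start + sample.int(2000L, 8L)]
    rann <- structure(list(cds = rc), class = "genome_annotation")
    rp <- data.table::data.table(chrom = "chr1",
                                 pos = sample.int(110000L, 30L))
    expect_equal(distance_to_nearest_cds(rp, rann),
                 brute_cds_distance(rp, rc))
  }
  expect_error(distance_to_nearest_cds(pos, structure(
    list(cds = cds[0]), class = "genome_annotation")), "CDS")
})

test_that("distal fractions count strict exceedance as percentages", {
  d <- c(0, 5000, 15000, 150000)
  fb <- fraction_beyond(d)
  expect_equal(unname(fb), c(50, 25))
  expect_equal(unname(fraction_beyond(rep(0, 10))), c(0, 0))
  ## order independence
  expect_equal(sort(unname(fraction_beyond(d, c(100000, 10000)))),
               sort(unname(fb)))
  expect_error(fraction_beyond(numeric()), "no distances")
})

test_that("TFBS aggregation contrasts conditions and is antisymmetric", {
  v <- numeric(4000); v[2001] <- 6
  light <- list(chr1 = occupancy_track(v, "chr1", mode = "midpoint",
                                       normalization = "per_million"))
  dark <- list(chr1 = occupancy_track(numeric(4000), "chr1",
                                      mode = "midpoint",
                                      normalization = "per_million"))
  sites <- data.table::data.table(chrom = "chr1", start = 1970L,
                                  end = 2031L, name = "TF", score = 0,
                                  strand = "+")
  agg <- tfbs_aggregate(light, dark, sites, flank = 100L)
  expect_equal(agg$light[offset == 0, value], 6)
  expect_true(all(agg$dark$value == 0))
  expect_equal(agg$difference[offset == 0, value], 6)
  ## identical tracks -> difference identically zero
  same <- tfbs_aggregate(light, light, sites, flank = 100L)
  expect_true(all(same$difference$value == 0))
  ## label swap negates the difference exactly
  swap <- tfbs_aggregate(dark, light, sites, flank = 100L)
  expect_equal(swap$difference$value, -agg$difference$value)
  expect_error(tfbs_aggregate(light, dark, sites[0]), "empty")
})

test_that("strand-flipped mirrored sites aggregate identically", {
  L <- 4000L
  mk_track <- function(peak_at) {
    tpl <- data.table::data.table(chrom = "chr1", center = peak_at,
                                  width = 60L, kind = "subNSP", occ_low = 1)
    ls <- manual_landscape(tpl, c(chr1 = L))
    fr <- sample_fragments(ls, sample_spec("s", "light", clean_digestion(),
                                           depth = 50, seed = 3))
    normalize_per_million(subnsp_midpoint_track(fr, c(chr1 = L)), nrow(fr))
  }
  fwd_tr <- mk_track(1500L)
  rev_tr <- mk_track(L - 1L - 1500L)
  site_f <- data.table::data.table(chrom = "chr1", start = 1470L,
                                   end = 1531L, name = "TF", score = 0,
                                   strand = "+")
  site_r <- data.table::data.table(chrom = "chr1", start = L - 1531L,
                                   end = L - 1470L, name = "TF", score = 0,
                                   strand = "-")
  agg_f <- tfbs_aggregate(fwd_tr, fwd_tr, site_f, flank = 200L)
  agg_r <- tfbs_aggregate(rev_tr, rev_tr, site_r, flank = 200L)
  expect_equal(agg_f$light$value, agg_r$light$value)
})

test_that("gene region reports orient 5'->3' and reject unknown genes", {
  ann <- build_toy_genome(toy_genome_spec(chrom_lengths = c(chr1 = 40000L),
                                          n_genes = 6L, seed = 8L))
  ls <- plant_landscape(ann, seed = 9L)
  frs <- list(s1 = sample_fragments(ls, sample_spec(
    "s1", "light", digestion_setting("low"), depth = 2e4, seed = 10L)))
  gid <- ann$genes$gene_id[1]
  rep1 <- gene_region_report(frs, ann, gid, flank = 200L)
  g <- ann$genes[gene_id == gid]
  expect_equal(rep1$region$start, max(0L, g$start - 200L))
  expect_equal(length(rep1$samples$s1$coverage),
               rep1$region$end - rep1$region$start)
  ## flank 0 -> exactly the gene span
  rep0 <- gene_region_report(frs, ann, gid, flank = 0L)
  expect_equal(rep0$region$start, g$start)
  expect_equal(rep0$region$end, g$end)
  ## minus-strand genes come out 5'->3' (positions descending)
  gm <- ann$genes[strand == "-"]$gene_id[1]
  repm <- gene_region_report(frs, ann, gm, flank = 0L)
  expect_true(all(diff(repm$positions) == -1L))
  expect_error(gene_region_report(frs, ann, "nope"), "known ids")
  ## bedGraph export writes one file per sample and class
  dir <- withr::local_tempdir()
  paths <- write_gene_region_report(rep1, dir)
  expect_equal(length(paths), 3L)
  expect_true(all(file.exists(paths)))
})
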