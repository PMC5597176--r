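#' Parameters of a planted chromatin landscape
#'
#' Defaults describe the canonical promoter architecture the analysis is
#' designed to recover: a +1 nucleosome dyad 100 bp downstream of the TSS
#' followed by an array at 180 bp period (150 bp core + 30 bp linker), a
#' digestion-labile -1 nucleosome 100 bp upstream, and one sub-nucleosomal
#' footprint in the 5' region (default TSS - 60) whose occupancy carries the
#' light/dark condition effect. Sparse stable nucleosomes fill intergenic
#' gaps, and each gap optionally carries one TF binding site footprint bound
#' in light only.
#'
#' Occupancies are survival probabilities per cell: `stable_occ` for array
#' and intergenic nucleosomes at both digestion levels, `minus1_occ` the
#' (low, high)-digestion pair for the fragile -1 (high < low), and subNSP
#' footprints survive high digestion only at a `sub_high_factor` multiple of
#' their low-digest occupancy. Per-gene subNSP base occupancy is drawn
#' uniformly on `sub_occ_range`; a `light_responsive_frac` fraction of genes
#' receives a light-vs-dark occupancy log2 fold change drawn from
#' `N(delta_responsive_mean, delta_responsive_sd)`, the remainder from
#' `N(0, delta_neutral_sd)`.
#'
#' @param plus1_offset +1 dyad offset downstream of the TSS, bp.
#' @param period Nucleosome repeat length, bp (core + linker).
#' @param minus1_offset -1 dyad offset (negative = upstream), bp.
#' @param subnsp_offset TSS footprint center offset, bp.
#' @param nuc_width Protected width of a nucleosome, bp.
#' @param sub_width_range Inclusive range the footprint protected width is
#'   drawn from, bp.
#' @param stable_occ Stable nucleosome occupancy (both digestion levels).
#' @param minus1_occ Named or ordered pair `c(low, high)` for the labile -1.
#' @param sub_occ_range Range of per-gene footprint base occupancy.
#' @param sub_high_factor Multiplier on footprint occupancy at high digest.
#' @param light_responsive_frac Fraction of genes with a condition effect.
#' @param delta_responsive_mean,delta_responsive_sd,delta_neutral_sd
#'   Parameters of the planted occupancy log2FC distributions.
#' @param diffuse_n,diffuse_occ,diffuse_width,diffuse_span Diffuse
#'   small-particle noise floor at promoters: `diffuse_n` subNSP templates
#'   tiled over `diffuse_span` (bp relative to the TSS) with total
#'   occupancy `diffuse_occ`, condition-independent. The TSS footprint must
#'   stand out against this floor, which is what makes the kurtosis of the
#'   subNSP peak a recruitment statistic.
#' @param intergenic_occ,intergenic_period Occupancy and spacing of
#'   background nucleosomes in intergenic gaps.
#' @param tfbs_per_gap Number of light-only TF footprints planted per
#'   intergenic gap (0 disables).
#' @param tfbs_occ,tfbs_width Occupancy (light, low digest) and protected
#'   width of TFBS footprints.
#' @return An object of class `landscape_params`.
#' @export
landscape_params <- function(plus1_offset = 100L, period = 180L,
                             minus1_offset = -100L, subnsp_offset = -60L,
                             nuc_width = 150L, sub_width_range = c(30L, 110L),
                             stable_occ = 0.85,
                             minus1_occ = c(low = 0.8, high = 0.3),
                             sub_occ_range = c(0.15, 0.9),
                             sub_high_factor = 0.35,
                             light_responsive_frac = 0.4,
                             delta_responsive_mean = 1.5,
                             delta_responsive_sd = 0.5,
                             delta_neutral_sd = 0.3,
                             diffuse_n = 8L, diffuse_occ = 0.25,
                             diffuse_width = 50L,
                             diffuse_span = c(-240L, 40L),
                             intergenic_occ = 0.45,
                             intergenic_period = 240L,
                             tfbs_per_gap = 1L, tfbs_occ = 0.6,
                             tfbs_width = 60L) {
  if (minus1_occ[2L] >= minus1_occ[1L])
    stop("labile -1 requires occupancy(high) < occupancy(low)")
  if (sub_high_factor > 1) stop("sub_high_factor must be <= 1")
  p <- as.list(environment())
  structure(p, class = "landscape_params")
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Plant a synthetic chromatin landscape on an annotation
#'
#' Lays down particle templates per gene (strand-aware: "downstream" follows
#' transcription): a +1 nucleosome and downstream array, a labile -1, and a
#' TSS-proximal subNSP footprint; plus intergenic background nucleosomes and
#' optional light-only TFBS footprints. Each template carries occupancies
#' for the four condition x digestion combinations via `occ_low`/`occ_high`
#' (digestion effect) and `f_light`/`f_dark` (condition effect); realized
#' occupancy is `clamp01(occ_digest * f_condition)`.
#'
#' @param annotation A `genome_annotation` from [build_toy_genome()].
#' @param params A [landscape_params()].
#' @param seed Integer seed for the per-gene draws (footprint widths, base
#'   occupancies, condition effects).
#' @return Object of class `synthetic_landscape`: list with `templates`
#'   (data.table of planted particles), `genes` (annotation genes plus
#'   planted subNSP occupancies and `delta`, the planted occupancy log2FC),
#'   `tfbs` (site table or NULL), `params`, and `expected_yield` (reference
#'   fragments per genome pass, averaged over the four combinations).
#' @export
plant_landscape <- function(annotation, params = landscape_params(),
                            seed = 1L) {
  stopifnot(inherits(annotation, "genome_annotation"))
  g <- copy(annotation$genes)
  if (nrow(g) == 0L) stop("annotation has no genes")
  set.seed(as.integer(seed))
  p <- params

  n <- nrow(g)
  g[, sub_occ_base := runif(n, p$sub_occ_range[1L], p$sub_occ_range[2L])]
  g[, light_responsive := runif(n) < p$light_responsive_frac]
  g[, delta := ifelse(light_responsive,
                      rnorm(n, p$delta_responsive_mean, p$delta_responsive_sd),
                      rnorm(n, 0, p$delta_neutral_sd))]
  g[, subnsp_occ_light := clamp01(sub_occ_base * 2^(delta / 2))]
  g[, subnsp_occ_dark := clamp01(sub_occ_base * 2^(-delta / 2))]
  sub_w <- sample(seq(p$sub_width_range[1L], p$sub_width_range[2L]), n,
                  replace = TRUE)

  cl <- stats::setNames(annotation$chroms$length, annotation$chroms$chrom)
  sgn <- ifelse(g$strand == "+", 1L, -1L)

  nd <- max(0L, as.integer(p$diffuse_n))
  diff_off <- if (nd > 0L)
    as.integer(round(seq(p$diffuse_span[1L], p$diffuse_span[2L],
                         length.out = nd))) else integer()
  gene_tpl <- lapply(seq_len(n), function(i) {
    tss <- g$tss[i]; s <- sgn[i]
    gene_span <- abs(g$tes[i] - tss) + 1L
    n_arr <- max(1L, 1L + (gene_span - p$plus1_offset -
                             p$nuc_width %/% 2) %/% p$period)
    dy <- tss + s * (p$plus1_offset + (seq_len(n_arr) - 1L) * p$period)
    data.table(
      chrom = g$chrom[i],
      center = c(dy, tss + s * p$minus1_offset, tss + s * p$subnsp_offset,
                 tss + s * diff_off),
      width = c(rep(p$nuc_width, n_arr + 1L), sub_w[i],
                rep(p$diffuse_width, nd)),
      kind = c(rep("nucleosome", n_arr + 1L), rep("subNSP", 1L + nd)),
      role = c("plus1", rep("array", n_arr - 1L), "minus1", "tss_footprint",
               rep("diffuse", nd)),
      gene_id = g$gene_id[i],
      labile = c(rep(FALSE, n_arr), TRUE, rep(FALSE, 1L + nd)),
      occ_low = c(rep(p$stable_occ, n_arr), p$minus1_occ[[1L]],
                  g$sub_occ_base[i], rep(p$diffuse_occ / max(nd, 1L), nd)),
      occ_high = c(rep(p$stable_occ, n_arr), p$minus1_occ[[2L]],
                   g$sub_occ_base[i] * p$sub_high_factor,
                   rep(p$diffuse_occ / max(nd, 1L) * p$sub_high_factor, nd)),
      f_light = c(rep(1, n_arr + 1L), 2^(g$delta[i] / 2), rep(1, nd)),
      f_dark = c(rep(1, n_arr + 1L), 2^(-g$delta[i] / 2), rep(1, nd)))
  })

  ## intergenic background nucleosomes and TFBS footprints, per gap
  gaps <- g[, .(chrom, start, end)][order(chrom, start)]
  gap_tpl <- list(); tfbs_rows <- list()
  margin <- 250L
  for (cn in names(cl)) {
    gs <- gaps[chrom == cn]
    edges <- rbind(data.table(a = 0L, b = if (nrow(gs)) gs$start[1L] else cl[[cn]]),
                   if (nrow(gs) > 1L)
                     data.table(a = gs$end[-nrow(gs)], b = gs$start[-1L]),
                   data.table(a = if (nrow(gs)) gs$end[nrow(gs)] else 0L,
                              b = cl[[cn]]))
    for (k in seq_len(nrow(edges))) {
      a <- edges$a[k] + margin; b <- edges$b[k] - margin
      if (b - a < p$nuc_width) next
      centers <- seq(a + p$nuc_width %/% 2, b - p$nuc_width %/% 2,
                     by = p$intergenic_period)
      gap_tpl[[length(gap_tpl) + 1L]] <- data.table(
        chrom = cn, center = as.integer(centers), width = p$nuc_width,
        kind = "nucleosome", role = "intergenic", gene_id = NA_character_,
        labile = FALSE, occ_low = p$intergenic_occ,
        occ_high = p$intergenic_occ, f_light = 1, f_dark = 1)
      if (p$tfbs_per_gap > 0L && b - a > 2L * p$tfbs_width) {
        tc <- as.integer(round((a + b) / 2)) + 7L  # off-grid of nucleosomes
        tfbs_rows[[length(tfbs_rows) + 1L]] <- data.table(
          chrom = cn, center = tc, width = p$tfbs_width,
          strand = if (length(tfbs_rows) %% 2L == 0L) "+" else "-")
      }
    }
  }
  tfbs <- if (length(tfbs_rows)) rbindlist(tfbs_rows) else NULL
  tfbs_tpl <- if (!is.null(tfbs)) data.table(
    chrom = tfbs$chrom, center = tfbs$center, width = tfbs$width,
    kind = "subNSP", role = "tfbs", gene_id = NA_character_, labile = FALSE,
    occ_low = p$tfbs_occ, occ_high = p$tfbs_occ * p$sub_high_factor,
    f_light = 1, f_dark = 0) else NULL

  tpl <- rbindlist(c(gene_tpl, gap_tpl, list(tfbs_tpl)), use.names = TRUE)
  tpl[, `:=`(start = as.integer(center - width %/% 2))]
  tpl[, end := as.integer(start + width)]
  setorder(tpl, chrom, center, start)
  tpl[, template_id := seq_len(.N)]

  yields <- vapply(
    list(c("light", "low"), c("light", "high"),
         c("dark", "low"), c("dark", "high")),
    function(cd) sum(template_occupancy(tpl, cd[1L], cd[2L])), numeric(1))

  structure(list(templates = tpl[], genes = g[],
                 tfbs = if (!is.null(tfbs))
                   data.table(chrom = tfbs$chrom,
                              start = tfbs$center - tfbs$width %/% 2L,
                              end = tfbs$center - tfbs$width %/% 2L + tfbs$width,
                              name = "synthTF", score = 0L,
                              strand = tfbs$strand) else NULL,
                 annotation = annotation, params = params,
                 seed = as.integer(seed),
                 expected_yield = mean(yields)),
            class = "synthetic_landscape")
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf(
    "<synthetic_landscape> %d templates over %d genes (%d TFBS); ~%.0f fragments/pass\n",
    nrow(x$templates), nrow(x$genes),
    if (is.null(x$tfbs)) 0L else nrow(x$tfbs), x$expected_yield))
  invisible(x)
}

#' Realized template occupancy for a condition and digestion level
#'
#' @param templates Template table of a `synthetic_landscape`.
#' @param condition `"light"` or `"dark"`.
#' @param level `"low"` or `"high"`.
#' @return Numeric vector of survival probabilities in `[0, 1]`.
#' @export
template_occupancy <- function(templates, condition = c("light", "dark"),
                               level = c("low", "high")) {
  condition <- match.arg(condition); level <- match.arg(level)
  occ <- if (level == "low") templates$occ_low else templates$occ_high
  f <- if (condition == "light") templates$f_light else templates$f_dark
  clamp01(occ * f)
}

#' Digestion settings for one MNase dose
#'
#' `p_link` is the probability that two adjacent surviving nucleosomes stay
#' joined in one protected fragment (multi-nucleosome generation is
#' junction-wise, so digestion completeness is the single monotone knob:
#' low dose keeps chains, high dose cleaves di-/tri-nucleosomes to
#' monomers). Fragment boundaries receive independent rounded-Gaussian
#' jitter; naked-DNA background fragments with uniform positions and
#' uniform lengths provide the low-level small-particle noise floor seen at
#' high digest.
#'
#' @param level `"low"` or `"high"`; picks defaults for the other knobs.
#' @param p_link Per-junction linkage probability (default 0.6 low / 0.1
#'   high).
#' @param boundary_jitter_sd Gaussian SD of each fragment boundary, bp
#'   (default 8, so mono fragments span roughly 135-165 bp).
#' @param background_rate Background fragments per kb of genome per pass
#'   (default 0.02 low / 0.05 high).
#' @param background_length_range Uniform background length range, bp.
#' @return An object of class `digestion_setting`.
#' @export
digestion_setting <- function(level = c("low", "high"), p_link = NULL,
                              boundary_jitter_sd = 8,
                              background_rate = NULL,
                              background_length_range = c(40L, 400L)) {
  level <- match.arg(level)
  if (is.null(p_link)) p_link <- if (level == "low") 0.6 else 0.1
  if (is.null(background_rate))
    background_rate <- if (level == "low") 0.02 else 0.05
  if (p_link < 0 || p_link > 1) stop("p_link must be in [0, 1]")
  structure(list(level = level, p_link = p_link,
                 boundary_jitter_sd = boundary_jitter_sd,
                 background_rate = background_rate,
                 background_length_range = as.integer(background_length_range)),
            class = "digestion_setting")
}

#' Specification of one simulated sample
#'
#' @param sample_id Unique label.
#' @param condition `"light"` or `"dark"`.
#' @param digestion A [digestion_setting()].
#' @param depth Target fragment count; converted to a whole number of
#'   genome passes (cell equivalents) via the landscape's reference yield,
#'   so all samples of an experiment receive equal chromatin input and the
#'   realized library size varies with digestion.
#' @param seed Integer seed for this sample's draws.
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(sample_id, condition = c("light", "dark"),
                        digestion = digestion_setting("low"),
                        depth = 2e5, seed = 1L) {
  condition <- match.arg(condition)
  if (depth < 0) stop("depth must be >= 0")
  structure(list(sample_id = sample_id, condition = condition,
                 digestion = digestion, depth = depth,
                 seed = as.integer(seed)),
            class = "sample_spec")
}

#' Draw a paired-end fragment set from a planted landscape
#'
#' Each genome pass corresponds to one cell: every template survives with
#' its occupancy for the sample's condition and digestion level; runs of
#' adjacent surviving nucleosomes (protected spans separated by no more than
#' the linker plus 10 bp) merge into single fragments with per-junction
#' probability `p_link`, giving lengths near `N * 150 + (N - 1) * 30`;
#' fragment boundaries then receive independent rounded-Gaussian jitter,
#' and Poisson background fragments are added. subNSP templates never
#' merge.
#'
#' @param landscape A `synthetic_landscape`.
#' @param sample A [sample_spec()].
#' @return A fragment set (sorted BED-convention intervals); zero depth
#'   yields an empty set.
#' @export
sample_fragments <- function(landscape, sample) {
  stopifnot(inherits(landscape, "synthetic_landscape"),
            inherits(sample, "sample_spec"))
  if (sample$depth == 0) return(empty_fragment_set())
  set.seed(sample$seed)
  tpl <- landscape$templates          # sorted by (chrom, center)
  dig <- sample$digestion
  occ <- template_occupancy(tpl, sample$condition, dig$level)
  ## equal chromatin input per sample: passes are cell equivalents (capped
  ## so that an all-zero landscape cannot request unbounded passes)
  npass <- max(1L, as.integer(min(
    round(sample$depth / landscape$expected_yield), 1e6)))

  nt <- nrow(tpl)
  ## junction j sits between template rows j and j+1
  mergeable <- c(tpl$kind[-nt] == "nucleosome" &
                   tpl$kind[-1L] == "nucleosome" &
                   tpl$chrom[-nt] == tpl$chrom[-1L] &
                   (tpl$start[-1L] - tpl$end[-nt]) <=
                     landscape$params$period - landscape$params$nuc_width + 10L &
                   (tpl$start[-1L] - tpl$end[-nt]) >= 0L,
                 FALSE)

  surv <- matrix(runif(nt * npass) < occ, nrow = nt)
  linked <- matrix(FALSE, nrow = nt, ncol = npass)
  if (any(mergeable) && dig$p_link > 0) {
    prev_ok <- surv[which(mergeable), , drop = FALSE] &
      surv[which(mergeable) + 1L, , drop = FALSE]
    draw <- matrix(runif(sum(mergeable) * npass) < dig$p_link,
                   nrow = sum(mergeable))
    linked[which(mergeable) + 1L, ] <- prev_ok & draw
  }
  ## column-major run labelling: a new fragment starts at each surviving
  ## template not linked to the surviving template above it
  newfrag <- surv & !linked
  fid <- matrix(cumsum(newfrag), nrow = nt)
  sel <- which(surv)
  if (base::length(sel)) {
    frags <- data.table(fid = fid[sel],
                        tpl = ((sel - 1L) %% nt) + 1L)
    frags <- frags[, .(tpl_first = min(tpl), tpl_last = max(tpl)), by = fid]
    out <- data.table(chrom = tpl$chrom[frags$tpl_first],
                      start = tpl$start[frags$tpl_first],
                      end = tpl$end[frags$tpl_last])
  } else {
    out <- data.table(chrom = character(), start = integer(),
                      end = integer())
  }

  ## background (naked DNA) fragments
  cl <- stats::setNames(landscape$annotation$chroms$length,
                        landscape$annotation$chroms$chrom)
  genome_kb <- sum(cl) / 1000
  n_bg <- rpois(1L, dig$background_rate * genome_kb * npass)
  if (n_bg > 0L) {
    bgc <- sample(names(cl), n_bg, replace = TRUE,
                  prob = as.numeric(cl) / sum(cl))
    bgl <- sample(seq(dig$background_length_range[1L],
                      dig$background_length_range[2L]), n_bg, replace = TRUE)
    bgs <- floor(runif(n_bg) * (cl[bgc] - bgl))
    out <- rbind(out, data.table(chrom = bgc, start = as.integer(bgs),
                                 end = as.integer(bgs + bgl)))
  }

  ## boundary jitter, clamped to the chromosome
  if (dig$boundary_jitter_sd > 0) {
    out[, start := start + as.integer(round(rnorm(.N, 0, dig$boundary_jitter_sd)))]
    out[, end := end + as.integer(round(rnorm(.N, 0, dig$boundary_jitter_sd)))]
  }
  out[, start := pmax(start, 0L)]
  out[, end := as.integer(unname(pmin(end, cl[chrom])))]
  out <- out[end > start]
  out[, length := end - start]
  setorder(out, chrom, start, end)
  setattr(out, "sample_id", sample$sample_id)
  out[]
}

#' Sample sheet of the default differential-digestion experiment
#'
#' Eight samples: {light, dark} x {low, high} digestion x 2 replicates,
#' mirroring the 2 x 2 x 2 design of the differential MNase study. Seeds
#' are derived deterministically from `base_seed`.
#'
#' @param depth Target fragment count per sample.
#' @param base_seed Integer; per-sample seeds are `base_seed * 100 + 1:8`.
#' @param n_replicates Replicates per condition x digestion cell.
#' @return data.table with columns sample_id, condition, digestion,
#'   replicate, depth, seed.
#' @export
default_experiment <- function(depth = 2e5, base_seed = 1L,
                               n_replicates = 2L) {
  sheet <- CJ(condition = c("light", "dark"), digestion = c("low", "high"),
              replicate = seq_len(n_replicates), sorted = FALSE)
  sheet[, sample_id := sprintf("%s_%s_r%d", condition, digestion, replicate)]
  sheet[, depth := depth]
  sheet[, seed := as.integer(base_seed) * 100L + seq_len(.N)]
  sheet[, .(sample_id, condition, digestion, replicate, depth, seed)]
}

#' Simulate all samples of a sample sheet
#'
#' @param landscape A `synthetic_landscape`.
#' @param sheet A sample sheet as from [default_experiment()].
#' @return Named list of fragment sets, one per `sample_id`.
#' @export
simulate_samples <- function(landscape, sheet = default_experiment()) {
  out <- lapply(seq_len(nrow(sheet)), function(i) {
    sp <- sample_spec(sheet$sample_id[i], sheet$condition[i],
                      digestion_setting(sheet$digestion[i]),
                      depth = sheet$depth[i], seed = sheet$seed[i])
    sample_fragments(landscape, sp)
  })
  stats::setNames(out, sheet$sample_id)
}
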