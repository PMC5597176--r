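#' Coupling between planted subNSP occupancy and expression
#'
#' The simulator ties each gene's expression to its planted TSS footprint:
#' the per-condition mean count is
#' `baseline_mean * (occ_cond / 0.5)^link_coefficient`, so a single positive
#' `link_coefficient` produces both the within-sample association between
#' subNSP recruitment and expression level and a cross-condition expression
#' log2 fold change equal to `link_coefficient * log2(occ_light / occ_dark)`.
#'
#' @param baseline_mean Expected count for a gene with footprint occupancy
#'   0.5.
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); values below 1e-8 switch to Poisson.
#' @param link_coefficient Exponent coupling occupancy to expression;
#'   0 decouples them.
#' @param n_replicates Replicates per condition (>= 2).
#' @return An object of class `expression_coupling`.
#' @export
expression_coupling <- function(baseline_mean = 200, dispersion = 0.05,
                                link_coefficient = 1, n_replicates = 4L) {
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (n_replicates < 2L) stop("at least 2 replicates per condition required")
  structure(list(baseline_mean = baseline_mean, dispersion = dispersion,
                 link_coefficient = link_coefficient,
                 n_replicates = as.integer(n_replicates)),
            class = "expression_coupling")
}

#' Simulate expression counts and a differential-expression table
#'
#' Per-replicate counts are negative-binomial with mean set by the planted
#' footprint occupancy (see [expression_coupling()]). The DE table is
#' deliberately simple plumbing standing in for an upstream RNA-seq
#' pipeline: log2FC is estimated as `log2((mean_light + 0.5) /
#' (mean_dark + 0.5))`, p from a Welch t-test on `log2(count + 1)`, and FDR
#' by Benjamini-Hochberg. The planted truth (occupancy log2FC `delta` and
#' expected expression log2FC) is returned alongside.
#'
#' @param landscape A `synthetic_landscape` (supplies per-gene planted
#'   occupancies).
#' @param coupling An [expression_coupling()].
#' @param seed Integer seed.
#' @return List with data.tables `expression` (gene_id, shared_isoform, one
#'   column per sample `light_r*` / `dark_r*`), `de` (gene_id, log2FC, p,
#'   FDR) and `truth` (gene_id, occ_light, occ_dark, delta,
#'   planted_expression_log2fc).
#' @export
simulate_expression <- function(landscape, coupling = expression_coupling(),
                                seed = 1L) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  g <- landscape$genes
  if (!all(c("subnsp_occ_light", "subnsp_occ_dark") %in% names(g)))
    stop("landscape genes lack planted subNSP occupancies")
  set.seed(as.integer(seed))
  k <- coupling$n_replicates
  eps <- 1e-3                                   # guard against occupancy 0
  mu_l <- coupling$baseline_mean *
    (pmax(g$subnsp_occ_light, eps) / 0.5)^coupling$link_coefficient
  mu_d <- coupling$baseline_mean *
    (pmax(g$subnsp_occ_dark, eps) / 0.5)^coupling$link_coefficient

  draw <- function(mu) {
    if (coupling$dispersion < 1e-8) rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / coupling$dispersion)
  }
  n <- nrow(g)
  counts_l <- vapply(seq_len(k), function(i) draw(mu_l), numeric(n))
  counts_d <- vapply(seq_len(k), function(i) draw(mu_d), numeric(n))
  colnames(counts_l) <- sprintf("light_r%d", seq_len(k))
  colnames(counts_d) <- sprintf("dark_r%d", seq_len(k))

  lg_l <- log2(counts_l + 1); lg_d <- log2(counts_d + 1)
  pvals <- vapply(seq_len(n), function(i) {
    x <- lg_l[i, ]; y <- lg_d[i, ]
    if (sd(x) == 0 && sd(y) == 0) {
      if (mean(x) == mean(y)) 1 else 0
    } else {
      stats::t.test(x, y)$p.value
    }
  }, numeric(1))
  de <- data.table(
    gene_id = g$gene_id,
    log2FC = log2((rowMeans(counts_l) + 0.5) / (rowMeans(counts_d) + 0.5)),
    p = pvals,
    FDR = p.adjust(pvals, method = "BH"))
  expression <- data.table(gene_id = g$gene_id,
                           shared_isoform = g$shared_isoform)
  expression <- cbind(expression, as.data.table(counts_l),
                      as.data.table(counts_d))
  truth <- data.table(
    gene_id = g$gene_id, occ_light = g$subnsp_occ_light,
    occ_dark = g$subnsp_occ_dark, delta = g$delta,
    planted_expression_log2fc = coupling$link_coefficient *
      log2(pmax(g$subnsp_occ_light, eps) / pmax(g$subnsp_occ_dark, eps)))
  list(expression = expression, de = de, truth = truth)
}
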