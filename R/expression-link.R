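#' Read an expression table (TSV)
#'
#' Requires a `gene_id` column; remaining numeric columns are per-sample
#' expression values. An optional `shared_isoform` column is preserved.
#'
#' @param path TSV path with header.
#' @return data.table.
#' @export
read_expression_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  if (!"gene_id" %in% names(dt)) stop("expression table needs a gene_id column")
  dt
}

#' Read a differential-expression table (TSV)
#'
#' Mandatory header columns: `gene_id`, `log2FC`, `FDR`.
#'
#' @param path TSV path.
#' @return data.table.
#' @export
read_de_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("gene_id", "log2FC", "FDR")
  if (!all(need %in% names(dt)))
    stop("DE table needs columns: ", paste(need, collapse = ", "))
  dt
}

assign_quartiles <- function(dt, value_col) {
  n <- nrow(dt)
  ord <- order(dt[[value_col]], dt$gene_id)    # ties broken by gene_id order
  rnk <- integer(n); rnk[ord] <- seq_len(n)
  dt[, quartile := paste0("Q", floor((rnk - 1L) * 4L / n) + 1L)]
  dt
}

#' Quartile genes by expression level
#'
#' Rank-based quartiles (Q1 = lowest 25%, Q4 = highest), sizes balanced to
#' within one gene; ties are broken deterministically by `gene_id` order.
#'
#' @param expression Expression table with `gene_id` and the sample column.
#' @param sample Column name holding the ranking values.
#' @return data.table gene_id, value, quartile.
#' @export
quartiles_by_expression <- function(expression, sample) {
  if (nrow(expression) < 4L) stop("need >= 4 genes for quartiles")
  if (!sample %in% names(expression)) stop("no such sample column: ", sample)
  dt <- data.table(gene_id = expression$gene_id,
                   value = expression[[sample]])
  assign_quartiles(dt, "value")[]
}

#' Fisher excess kurtosis
#'
#' Direct moment estimator \eqn{g_2 = m_4 / m_2^2 - 3} on the raw values.
#' Returns `NA` for fewer than 4 observations or zero variance. A large
#' positive value marks a leptokurtic (sharply peaked) distribution; a
#' uniform distribution has excess kurtosis -6/5.
#'
#' @param x Numeric vector.
#' @return Excess kurtosis, or `NA_real_`.
#' @export
excess_kurtosis <- function(x) {
  n <- base::length(x)
  if (n < 4L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  mean((x - m)^4) / m2^2 - 3
}

#' Per-gene subNSP footprint statistics at the TSS
#'
#' Collects the strand-oriented midpoint offsets of subNSP fragments
#' (length < `scheme$sub_max`) inside the TSS window and computes the
#' fragment count and the excess kurtosis of the offsets — the sharpness of
#' the footprint peak. Genes with fewer than `min_fragments` (default 20)
#' midpoints are flagged ineligible rather than imputed: fourth-moment
#' estimates are unstable below roughly 20 observations.
#'
#' @param fragments A fragment set.
#' @param anchors TSS anchors from [extract_anchors()].
#' @param scheme A [size_scheme()].
#' @param window Inclusive offset window around the anchor, bp. The default
#'   `[-250, +50]` spans the upstream footprint zone into the 5' UTR.
#' @param min_fragments Eligibility threshold.
#' @return data.table gene_id, n_fragments, kurtosis, eligible.
#' @export
tss_subnsp_stats <- function(fragments, anchors, scheme = size_scheme(),
                             window = c(-250L, 50L), min_fragments = 20L) {
  sub <- fragments[length < scheme$sub_max]
  mids <- sub[, .(chrom, mid = floor((start + end) / 2))]
  setorder(mids, chrom, mid)
  by_chrom <- split(mids$mid, mids$chrom)
  res <- lapply(seq_len(nrow(anchors)), function(i) {
    m <- by_chrom[[anchors$chrom[i]]]
    if (is.null(m)) m <- integer()
    s <- if (anchors$strand[i] == "-") -1L else 1L
    lo <- anchors$pos[i] + min(s * window)     # genomic window, strand-flipped
    hi <- anchors$pos[i] + max(s * window)
    sel <- m[m >= lo & m <= hi]
    off <- s * (sel - anchors$pos[i])
    data.table(gene_id = anchors$feature_id[i],
               n_fragments = base::length(off),
               kurtosis = excess_kurtosis(off))
  })
  out <- rbindlist(res)
  out[, eligible := n_fragments >= min_fragments & !is.na(kurtosis)]
  out[]
}

#' Quartile genes by subNSP recruitment at the TSS
#'
#' Quartiles over eligible genes only, by either the kurtosis of the TSS
#' footprint peak (default) or the raw fragment count (`"n_fragments"`);
#' both statistics are computed by [tss_subnsp_stats()] so the quartiling
#' statistic is a configuration choice. When an expression table is
#' supplied, per-quartile expression values are returned alongside; when a
#' TSS [profile_matrix()] is supplied, per-quartile mean subNSP profiles
#' are returned.
#'
#' @param stats Output of [tss_subnsp_stats()].
#' @param expression Optional expression table (`gene_id` + value columns).
#' @param expression_col Column of `expression` to group (default: mean of
#'   all numeric columns).
#' @param profile Optional [profile_matrix()] whose anchors are the same
#'   genes.
#' @param statistic `"kurtosis"` or `"n_fragments"`.
#' @return List with `assignment` (gene_id, value, quartile),
#'   `expression_by_quartile` (or NULL) and `profile_by_quartile` (or
#'   NULL; data.table offset x Q1..Q4).
#' @export
quartiles_by_kurtosis <- function(stats, expression = NULL,
                                  expression_col = NULL, profile = NULL,
                                  statistic = c("kurtosis", "n_fragments")) {
  statistic <- match.arg(statistic)
  elig <- stats[eligible == TRUE]
  if (nrow(elig) < 4L) stop("need >= 4 eligible genes for quartiles")
  dt <- data.table(gene_id = elig$gene_id, value = elig[[statistic]])
  assignment <- assign_quartiles(dt, "value")

  expr_by_q <- NULL
  if (!is.null(expression)) {
    e <- as.data.table(expression)
    if (is.null(expression_col)) {
      num <- names(e)[vapply(e, is.numeric, logical(1))]
      e <- e[, .(gene_id, expression = rowMeans(.SD)), .SDcols = num]
    } else {
      e <- data.table(gene_id = e$gene_id,
                      expression = e[[expression_col]])
    }
    expr_by_q <- e[assignment, on = "gene_id",
                   .(gene_id, quartile, expression)][!is.na(expression)]
  }
  prof_by_q <- NULL
  if (!is.null(profile)) {
    idx <- match(assignment$gene_id, profile$anchors$feature_id)
    keep <- !is.na(idx)
    qs <- split(idx[keep], assignment$quartile[keep])
    prof_by_q <- data.table(offset = profile$offsets)
    for (q in names(qs))
      prof_by_q[[q]] <- colMeans(profile$values[qs[[q]], , drop = FALSE],
                                 na.rm = TRUE)
  }
  list(assignment = assignment[], expression_by_quartile = expr_by_q,
       profile_by_quartile = prof_by_q)
}

#' Per-gene subNSP abundance log2 fold change between conditions
#'
#' Counts subNSP midpoints in the TSS window per gene for each condition
#' (replicates pooled within condition), converts to counts per million
#' retained fragments, and reports
#' `log2((cpm_light + pc) / (cpm_dark + pc))`. The pseudocount keeps genes
#' with zero counts finite and makes the statistic exactly antisymmetric
#' under swapping condition labels.
#'
#' @param fragments_light,fragments_dark Pooled fragment sets per condition.
#' @param anchors TSS anchors.
#' @param scheme A [size_scheme()].
#' @param window Inclusive offset window, bp.
#' @param pseudocount Added to both normalized abundances. Default 1.
#' @return data.table gene_id, n_light, n_dark, subnsp_log2fc.
#' @export
subnsp_log2fc <- function(fragments_light, fragments_dark, anchors,
                          scheme = size_scheme(), window = c(-250L, 50L),
                          pseudocount = 1) {
  if (is.null(fragments_light) || nrow(fragments_light) == 0L)
    stop("no fragments for condition 'light'")
  if (is.null(fragments_dark) || nrow(fragments_dark) == 0L)
    stop("no fragments for condition 'dark'")
  count_in_window <- function(fragments) {
    st <- tss_subnsp_stats(fragments, anchors, scheme, window,
                           min_fragments = 0L)
    stats::setNames(st$n_fragments, st$gene_id)
  }
  nl <- count_in_window(fragments_light)
  nd <- count_in_window(fragments_dark)
  Nl <- nrow(fragments_light); Nd <- nrow(fragments_dark)
  ## computed as a difference of logs so that swapping the condition
  ## labels negates every value bit-exactly
  data.table(gene_id = anchors$feature_id,
             n_light = as.integer(nl[anchors$feature_id]),
             n_dark = as.integer(nd[anchors$feature_id]),
             subnsp_log2fc =
               log2(nl[anchors$feature_id] / Nl * 1e6 + pseudocount) -
               log2(nd[anchors$feature_id] / Nd * 1e6 + pseudocount))
}

#' Assemble fold-change points from subNSP and DE tables
#'
#' One point per gene with data in both tables: the subNSP abundance log2FC
#' against the expression log2FC, with the FDR < `alpha` significance flag.
#'
#' @param subnsp Output of [subnsp_log2fc()].
#' @param de DE table (gene_id, log2FC, FDR).
#' @param alpha FDR threshold for the significance flag.
#' @return data.table gene_id, subnsp_log2fc, expression_log2fc, fdr,
#'   significant.
#' @export
fc_points <- function(subnsp, de, alpha = 0.05) {
  m <- merge(subnsp[, .(gene_id, subnsp_log2fc)],
             de[, .(gene_id, expression_log2fc = log2FC, fdr = FDR)],
             by = "gene_id")
  m <- m[is.finite(subnsp_log2fc) & is.finite(expression_log2fc)]
  m[, significant := fdr < alpha]
  m[]
}

#' Loess trend and rank correlation of the fold-change relationship
#'
#' Fits a local-linear (degree 1, tricube-weighted, nearest-neighbour span)
#' loess of expression log2FC against subNSP log2FC, evaluates it on a
#' grid, and attaches a bootstrap percentile confidence band (default 500
#' resamples, 0.95 level). Spearman rank correlations are reported over all
#' points and over the FDR-significant subset.
#'
#' @param points Output of [fc_points()].
#' @param span Loess span in (0, 1].
#' @param n_boot Bootstrap resamples for the band.
#' @param grid_n Grid size.
#' @param conf Confidence level of the band.
#' @param seed Optional seed for the bootstrap.
#' @return List: `trend` (data.table x, fit, lo, hi), `rho_all`, `p_all`,
#'   `rho_significant`, `p_significant`, `n`, `n_significant`.
#' @export
fc_correlation <- function(points, span = 0.5, n_boot = 500L,
                           grid_n = 100L, conf = 0.95, seed = NULL) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (nrow(points) < 20L) stop("need >= 20 points")
  if (!is.null(seed)) set.seed(seed)
  x <- points$subnsp_log2fc; y <- points$expression_log2fc
  grid <- seq(min(x), max(x), length.out = grid_n)
  fit_loess <- function(xx, yy)
    stats::loess(yy ~ xx, degree = 1L, span = span, surface = "direct",
                 family = "gaussian")
  fit <- predict(fit_loess(x, y), newdata = data.frame(xx = grid))
  boots <- matrix(NA_real_, nrow = n_boot, ncol = grid_n)
  n <- base::length(x)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bf <- try(predict(fit_loess(x[idx], y[idx]),
                      newdata = data.frame(xx = grid)), silent = TRUE)
    if (!inherits(bf, "try-error")) boots[b, ] <- bf
  }
  a <- (1 - conf) / 2
  lo <- apply(boots, 2L, quantile, probs = a, na.rm = TRUE)
  hi <- apply(boots, 2L, quantile, probs = 1 - a, na.rm = TRUE)
  ct_all <- suppressWarnings(cor.test(x, y, method = "spearman",
                                      exact = FALSE))
  sig <- points$significant
  ct_sig <- if (sum(sig) >= 3L)
    suppressWarnings(cor.test(x[sig], y[sig], method = "spearman",
                              exact = FALSE)) else NULL
  list(trend = data.table(x = grid, fit = fit, lo = lo, hi = hi),
       rho_all = unname(ct_all$estimate), p_all = ct_all$p.value,
       rho_significant = if (is.null(ct_sig)) NA_real_
         else unname(ct_sig$estimate),
       p_significant = if (is.null(ct_sig)) NA_real_ else ct_sig$p.value,
       n = n, n_significant = sum(sig))
}
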