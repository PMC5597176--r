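#' Extract anchor points from an annotation
#'
#' Anchors are the reference positions feature-aligned profiles are built
#' around: transcription start sites (TSS), coding start sites (CSS), or
#' intron/exon junctions (both the donor-side last exonic base and the
#' acceptor-side first exonic base of every intron, in transcription
#' orientation). `shared_only` restricts to genes flagged `shared_isoform`,
#' i.e. genes whose primary model is consistent across samples and whose
#' boundaries are therefore comparable.
#'
#' @param annotation A `genome_annotation`.
#' @param kind `"TSS"`, `"CSS"` or `"exon_boundary"`.
#' @param shared_only Restrict to shared-isoform genes.
#' @return data.table with columns feature_id, chrom, pos (0-based base),
#'   strand, kind.
#' @export
extract_anchors <- function(annotation, kind = c("TSS", "CSS",
                                                 "exon_boundary"),
                            shared_only = FALSE) {
  kind <- match.arg(kind)
  g <- annotation$genes
  if (shared_only) g <- g[shared_isoform == TRUE]
  if (kind == "TSS") {
    out <- g[, .(feature_id = gene_id, chrom, pos = tss, strand)]
  } else if (kind == "CSS") {
    out <- g[, .(feature_id = gene_id, chrom, pos = css, strand)]
  } else {
    ex <- annotation$exons[gene_id %in% g$gene_id]
    setorder(ex, gene_id, exon_number)
    out <- ex[, {
      if (.N < 2L) NULL
      else {
        don <- if (strand[1L] == "+") end[-.N] - 1L else start[-1L]
        acc <- if (strand[1L] == "+") start[-1L] else end[-.N] - 1L
        list(feature_id = c(paste0(gene_id[1L], ".donor", seq_len(.N - 1L)),
                            paste0(gene_id[1L], ".acceptor",
                                   seq_len(.N - 1L))),
             chrom = chrom[1L], pos = c(don, acc), strand = strand[1L])
      }
    }, by = gene_id][, .(feature_id, chrom, pos, strand)]
  }
  out[, kind := kind]
  out[]
}

#' Anchor-aligned profile matrix
#'
#' One row per anchor, one column per signed offset bin, strand-oriented so
#' that positive offsets run downstream of (in the transcription direction
#' from) the anchor. Column labels are bin start offsets; for `bin = 1` the
#' column labelled 0 is the anchor base itself. Cells that fall outside the
#' chromosome are `NA` (missing, not zero), so chromosome-edge anchors do
#' not drag aggregate profiles down.
#'
#' @param tracks Named list of [occupancy_track()] objects (per-base), as
#'   returned by the track builders, or a single track.
#' @param anchors Anchor table from [extract_anchors()] (columns chrom, pos,
#'   strand, feature_id).
#' @param flank Half-width of the window, bp; the window is
#'   `[pos - flank, pos + flank)`.
#' @param bin Bin width, bp; must divide `flank`.
#' @return Object of class `profile_matrix`: list with `values`
#'   (anchors x offsets), `offsets` (bin start offsets), `bin_size`,
#'   `anchors`.
#' @export
profile_matrix <- function(tracks, anchors, flank = 1000L, bin = 1L) {
  if (inherits(tracks, "occupancy_track"))
    tracks <- stats::setNames(list(tracks), tracks$chrom)
  if (nrow(anchors) == 0L) stop("no anchors supplied")
  if (flank %% bin != 0L) stop("flank must be a multiple of bin")
  rel <- seq(-flank, flank - 1L)
  vals <- matrix(NA_real_, nrow = nrow(anchors), ncol = length(rel))
  for (i in seq_len(nrow(anchors))) {
    tr <- tracks[[anchors$chrom[i]]]
    if (is.null(tr)) next
    s <- if (anchors$strand[i] == "-") -1L else 1L
    idx <- anchors$pos[i] + s * rel - tr$origin
    ok <- idx >= 0L & idx < base::length(tr$values)
    vals[i, ok] <- tr$values[idx[ok] + 1L]
  }
  if (bin > 1L) {
    grp <- rep(seq_len(length(rel) / bin), each = bin)
    vals <- t(apply(vals, 1L, function(v)
      tapply(v, grp, function(z) if (all(is.na(z))) NA_real_
             else mean(z, na.rm = TRUE))))
    offsets <- rel[seq(1L, length(rel), by = bin)]
  } else {
    offsets <- rel
  }
  colnames(vals) <- offsets
  structure(list(values = vals, offsets = as.integer(offsets),
                 bin_size = as.integer(bin), anchors = anchors),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d anchors x %d offsets (bin %d bp, [%d, %d))\n",
              nrow(x$values), ncol(x$values), x$bin_size,
              min(x$offsets), max(x$offsets) + x$bin_size))
  invisible(x)
}

#' Column-wise aggregate of a profile matrix
#'
#' Missing (out-of-chromosome) cells are excluded from the mean rather than
#' zero-filled; the number of contributing rows is reported per column.
#'
#' @param matrix A [profile_matrix()].
#' @param stat Aggregation function, applied per column over non-missing
#'   cells. Default `mean`.
#' @return data.table with columns offset, value, n.
#' @export
aggregate_profile <- function(matrix, stat = mean) {
  v <- matrix$values
  data.table(
    offset = matrix$offsets,
    value = apply(v, 2L, function(col) {
      col <- col[!is.na(col)]
      if (!base::length(col)) NA_real_ else stat(col)
    }),
    n = colSums(!is.na(v)))
}

#' Digestion-completeness index of a sample
#'
#' The study estimates each sample's digestion level from its
#' fragment-length distribution (the estimator itself is a design choice).
#' The default, `"mono_fraction"`, is the fraction of nucleosome-scale
#' fragments that are mono-sized:
#' `count(length in [120, 180]) / count(length >= 120)`. Complete digestion
#' cleaves di-/tri-nucleosomes to monomers, so the index rises
#' monotonically with digestion. Pass a function
#' `f(fragments, scheme)` to plug in another estimator (median fragment
#' length, 1 - multi fraction, ...).
#'
#' @param fragments A fragment set.
#' @param scheme A [size_scheme()].
#' @param estimator `"mono_fraction"` or a function.
#' @return A number in `[0, 1]` for the default estimator.
#' @export
digestion_index <- function(fragments, scheme = size_scheme(),
                            estimator = "mono_fraction") {
  if (is.function(estimator)) return(estimator(fragments, scheme))
  if (!identical(estimator, "mono_fraction"))
    stop("unknown estimator: ", estimator)
  nuc <- fragments$length[fragments$length >= scheme$sub_max]
  if (!base::length(nuc)) stop("no fragments of nucleosomal size or larger")
  sum(nuc <= scheme$nuc_unit + scheme$linker) / base::length(nuc)
}

#' Per-bin correlation between digestion level and occupancy
#'
#' For each offset bin, the Pearson correlation across samples between the
#' per-sample digestion index and the per-sample aggregate abundance at
#' that bin. Positive r marks positions that gain (mono-)occupancy as
#' digestion proceeds (genic arrays, via multi-to-mono cleavage); negative
#' r marks labile positions such as the fragile -1 nucleosome. Bins with
#' zero abundance variance across samples are flagged `undefined`, not
#' fabricated.
#'
#' @param profiles Matrix samples x offsets of per-sample aggregate
#'   profiles (rows in the same order as `indices`), or a list of
#'   [aggregate_profile()] outputs on identical offsets.
#' @param indices Numeric per-sample digestion indices.
#' @param offsets Offset vector matching the profile columns (taken from
#'   the list input when omitted).
#' @param bin Bin width in bp. Default 10.
#' @return data.table with columns offset (bin start), r, n_samples,
#'   undefined.
#' @export
digestion_correlation <- function(profiles, indices, offsets = NULL,
                                  bin = 10L) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    if (is.null(offsets)) offsets <- profiles[[1L]]$offset
    profiles <- do.call(rbind, lapply(profiles, function(p) p$value))
  }
  if (nrow(profiles) < 3L)
    stop("digestion correlation needs >= 3 samples")
  if (base::length(indices) != nrow(profiles))
    stop("one digestion index per profile row required")
  if (is.null(offsets)) stop("offsets required for matrix input")
  grp <- floor(offsets / bin) * bin
  ub <- sort(unique(grp))
  binned <- vapply(ub, function(b)
    rowMeans(profiles[, grp == b, drop = FALSE], na.rm = TRUE),
    numeric(nrow(profiles)))
  out <- data.table(offset = as.integer(ub),
                    r = NA_real_, n_samples = nrow(profiles),
                    undefined = FALSE)
  for (j in seq_along(ub)) {
    ab <- binned[, j]
    if (anyNA(ab) || sd(ab) == 0 || sd(indices) == 0) {
      out$undefined[j] <- TRUE
    } else {
      out$r[j] <- cor(indices, ab)
    }
  }
  out[]
}

#' Occupancy window test between digestion treatments
#'
#' For each window (defaults: `minus1 = [-125, -75)` and
#' `plus1 = [+75, +125)` around the TSS, the 50 bp neighborhoods of the -1
#' and +1 dyads), computes each sample's mean occupancy over the window and
#' compares the low- against the high-digestion group with a Welch
#' two-sample t-test. A fragile -1 nucleosome shows up as a significant
#' occupancy drop under high digestion while the stable +1 does not.
#'
#' @param profiles Matrix samples x offsets (or list of
#'   [aggregate_profile()] outputs) of per-sample profiles.
#' @param groups Factor/character per sample: `"low"` or `"high"`.
#' @param offsets Offset vector matching profile columns.
#' @param windows Named list of `[start, end)` offset windows, bp.
#' @param alpha Significance level. Default 0.05.
#' @return data.table with columns window, span_start, span_end, mean_low,
#'   mean_high, t, p, significant, degenerate.
#' @export
window_occupancy_test <- function(profiles, groups, offsets = NULL,
                                  windows = list(minus1 = c(-125L, -75L),
                                                 plus1 = c(75L, 125L)),
                                  alpha = 0.05) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    if (is.null(offsets)) offsets <- profiles[[1L]]$offset
    profiles <- do.call(rbind, lapply(profiles, function(p) p$value))
  }
  groups <- as.character(groups)
  if (base::length(groups) != nrow(profiles))
    stop("one group label per profile row required")
  if (min(table(groups)) < 2L) stop("need >= 2 samples per group")
  res <- lapply(names(windows), function(w) {
    span <- windows[[w]]
    sel <- offsets >= span[1L] & offsets < span[2L]
    m <- rowMeans(profiles[, sel, drop = FALSE], na.rm = TRUE)
    lo <- m[groups == "low"]; hi <- m[groups == "high"]
    degenerate <- sd(lo) == 0 && sd(hi) == 0
    if (degenerate) {
      tt <- list(statistic = c(t = 0), p.value = if (mean(lo) == mean(hi)) 1
                 else 0)
    } else {
      tt <- stats::t.test(lo, hi)           # Welch by default
    }
    data.table(window = w, span_start = span[1L], span_end = span[2L],
               mean_low = mean(lo), mean_high = mean(hi),
               t = unname(tt$statistic), p = tt$p.value,
               significant = is.finite(tt$p.value) && tt$p.value < alpha,
               degenerate = degenerate)
  })
  rbindlist(res)
}

moving_average <- function(x, width) {
  if (width <= 1L) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  as.numeric(stats::filter(x, rep(1 / width, width), sides = 2))
}

#' Position of the +1 nucleosome peak
#'
#' Offset of the maximum of the smoothed profile within the search span
#' (default `[0, +250]` bp downstream of the TSS). Smoothing is a centered
#' moving average (default 31 bp) so the argmax is stable under boundary
#' jitter; ties break leftmost. An all-zero (or all-missing) span yields
#' `NA`.
#'
#' @param values Profile values (one row of a [profile_matrix()] or an
#'   aggregate profile).
#' @param offsets Matching offsets.
#' @param span Search window `[lo, hi]`, bp.
#' @param smooth_width Moving-average width, bp.
#' @return Offset of the peak, or `NA_integer_`.
#' @export
plus1_position <- function(values, offsets, span = c(0L, 250L),
                           smooth_width = 31L) {
  sm <- moving_average(values, smooth_width)
  sel <- which(offsets >= span[1L] & offsets <= span[2L])
  v <- sm[sel]
  if (all(is.na(v)) || all(v[!is.na(v)] == 0)) return(NA_integer_)
  ## a maximal plateau (symmetric peak under moving-average smoothing)
  ## reports its center
  mx <- max(v, na.rm = TRUE)
  at <- which(!is.na(v) & abs(v - mx) < 1e-12)
  offsets[sel[at[ceiling(base::length(at) / 2)]]]
}

#' Per-gene +1 shift between two conditions
#'
#' Applies [plus1_position()] row-wise to two profile matrices on identical
#' anchors and reports the per-gene positional difference (b - a), the
#' basis of the +1 lateral-movement check.
#'
#' @param pm_a,pm_b [profile_matrix()] objects with identical anchors.
#' @param span,smooth_width Passed to [plus1_position()].
#' @return data.table with feature_id, pos_a, pos_b, shift.
#' @export
plus1_shift <- function(pm_a, pm_b, span = c(0L, 250L), smooth_width = 31L) {
  stopifnot(identical(pm_a$anchors$feature_id, pm_b$anchors$feature_id))
  pa <- apply(pm_a$values, 1L, plus1_position, offsets = pm_a$offsets,
              span = span, smooth_width = smooth_width)
  pb <- apply(pm_b$values, 1L, plus1_position, offsets = pm_b$offsets,
              span = span, smooth_width = smooth_width)
  data.table(feature_id = pm_a$anchors$feature_id, pos_a = pa, pos_b = pb,
             shift = pb - pa)
}
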