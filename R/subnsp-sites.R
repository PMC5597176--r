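#' Call discrete subNSP positions genome-wide
#'
#' Smooths the subNSP midpoint track with a centered moving average,
#' thresholds at `threshold_k` times the genome-wide nonzero median of the
#' smoothed signal, and keeps local maxima by greedy highest-first
#' selection enforcing a minimum separation (ties break leftmost). The
#' calling parameters are pragmatic defaults exposed for configuration;
#' positions are reported at summit resolution.
#'
#' @param tracks Named list of subNSP midpoint [occupancy_track()] objects
#'   (depth-normalized recommended) or a single track.
#' @param smooth_bw Moving-average width, bp. Default 15.
#' @param threshold_k Multiplier on the genome-wide nonzero median of the
#'   smoothed signal. Default 4.
#' @param min_sep Minimum distance between called positions, bp. Default
#'   60.
#' @return data.table chrom, pos (0-based summit), score (smoothed height),
#'   sorted by (chrom, pos); empty for an all-zero track.
#' @export
call_subnsp_positions <- function(tracks, smooth_bw = 15L, threshold_k = 4,
                                  min_sep = 60L) {
  if (inherits(tracks, "occupancy_track"))
    tracks <- stats::setNames(list(tracks), tracks$chrom)
  tracks <- tracks[sort(names(tracks))]   # iteration-order independence
  smoothed <- lapply(tracks, function(tr) {
    v <- moving_average(tr$values, smooth_bw)
    v[is.na(v)] <- 0
    v
  })
  nz <- unlist(smoothed, use.names = FALSE)
  nz <- nz[nz > 0]
  if (!base::length(nz))
    return(data.table(chrom = character(), pos = integer(),
                      score = numeric()))
  thr <- threshold_k * median(nz)
  cand <- rbindlist(lapply(names(smoothed), function(cn) {
    v <- smoothed[[cn]]
    n <- base::length(v)
    if (n < 3L) return(NULL)
    i <- 2:(n - 1L)
    peaks <- i[v[i] >= v[i - 1L] & v[i] >= v[i + 1L] & v[i] > thr]
    if (!base::length(peaks)) return(NULL)
    data.table(chrom = cn, pos = peaks - 1L + tracks[[cn]]$origin,
               score = v[peaks])
  }))
  if (is.null(cand) || nrow(cand) == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      score = numeric()))
  setorder(cand, -score, chrom, pos)       # greedy highest-first, leftmost tie
  keep <- logical(nrow(cand))
  acc <- list()
  for (i in seq_len(nrow(cand))) {
    cn <- cand$chrom[i]
    taken <- acc[[cn]]
    if (is.null(taken) || all(abs(taken - cand$pos[i]) >= min_sep)) {
      keep[i] <- TRUE
      acc[[cn]] <- c(taken, cand$pos[i])
    }
  }
  out <- cand[keep]
  setorder(out, chrom, pos)
  out[]
}

#' Write called subNSP positions as BED6
#'
#' One-base intervals at the summit; score column holds the call height.
#'
#' @param positions Output of [call_subnsp_positions()].
#' @param path Output path.
#' @param name Name column value.
#' @export
write_subnsp_positions <- function(positions, path, name = "subNSP") {
  out <- data.table(positions$chrom, positions$pos, positions$pos + 1L,
                    name, sprintf("%.6g", positions$score), ".")
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Distance from positions to the nearest annotated coding sequence
#'
#' Edge-to-edge gap against CDS features specifically (not gene or mRNA
#' spans), strand-ignored: 0 for a position inside a CDS, otherwise the
#' number of bases to the nearest CDS edge on either side, within the same
#' chromosome. A position on a chromosome without CDS gets `Inf` with a
#' warning.
#'
#' @param positions data.table with chrom, pos (0-based).
#' @param annotation A `genome_annotation` with a `cds` table.
#' @return Numeric vector of distances, one per position.
#' @export
distance_to_nearest_cds <- function(positions, annotation) {
  cds <- annotation$cds
  if (is.null(cds) || nrow(cds) == 0L) stop("annotation has no CDS features")
  out <- rep(Inf, nrow(positions))
  for (cn in unique(positions$chrom)) {
    sel <- which(positions$chrom == cn)
    cc <- cds[chrom == cn]
    if (nrow(cc) == 0L) next
    ## merge overlapping/adjacent CDS intervals
    setorder(cc, start)
    grp <- cumsum(c(1L, as.integer(cc$start[-1L] >
                                     cummax(cc$end[-nrow(cc)]))))
    mrg <- cc[, .(start = min(start), end = max(end)),
              by = .(grp = grp)]
    p <- positions$pos[sel]
    ## index of the last merged interval starting at or before p
    k <- findInterval(p, mrg$start)
    d_left <- ifelse(k >= 1L, p - (mrg$end[pmax(k, 1L)] - 1L), Inf)
    inside <- k >= 1L & p < mrg$end[pmax(k, 1L)]
    d_right <- ifelse(k < nrow(mrg), mrg$start[pmin(k + 1L, nrow(mrg))] - p,
                      Inf)
    d <- pmin(pmax(d_left, 0), pmax(d_right, 0))
    d[inside] <- 0
    out[sel] <- d
  }
  if (any(is.infinite(out)))
    warning("some positions lie on chromosomes without CDS features")
  out
}

#' Fraction of distances beyond thresholds
#'
#' Reports, as percentages, the fraction of positions strictly farther than
#' each threshold from the nearest coding sequence (the majority of subNSP
#' positions are promoter-proximal; the distal minority is quantified at 10
#' kb and 100 kb by default).
#'
#' @param distances Numeric distances (from [distance_to_nearest_cds()]).
#' @param thresholds Numeric thresholds, bp.
#' @return Named numeric vector of percentages (names = thresholds).
#' @export
fraction_beyond <- function(distances, thresholds = c(10000, 100000)) {
  if (!base::length(distances)) stop("no distances supplied")
  vapply(stats::setNames(thresholds, as.character(thresholds)),
         function(th) 100 * mean(distances > th), numeric(1))
}

#' Read a TFBS site set from BED6
#'
#' @param path BED path (>= 3 columns; strand column used when present,
#'   `+` assumed otherwise).
#' @param name Factor name attached to the set (defaults to the file's name
#'   column, else the basename).
#' @return data.table chrom, start, end, name, score, strand, sorted.
#' @export
read_tfbs_bed <- function(path, name = NULL) {
  dt <- fread(path, header = FALSE)
  if (ncol(dt) < 3L) stop("TFBS BED needs >= 3 columns")
  out <- data.table(chrom = as.character(dt[[1L]]),
                    start = as.integer(dt[[2L]]),
                    end = as.integer(dt[[3L]]),
                    name = if (ncol(dt) >= 4L) as.character(dt[[4L]])
                      else basename(path),
                    score = if (ncol(dt) >= 5L)
                      suppressWarnings(as.numeric(dt[[5L]])) else 0,
                    strand = if (ncol(dt) >= 6L) as.character(dt[[6L]])
                      else "+")
  out[!strand %in% c("+", "-"), strand := "+"]
  if (!is.null(name)) out[, name := name]
  setorder(out, chrom, start)
  out[]
}

#' Aggregate subNSP signal over a TFBS set, per condition
#'
#' Site-centered, strand-oriented profiles of the light and dark subNSP
#' tracks, their aggregates, and the light - dark difference profile;
#' per-site matrices are retained for heatmaps. Differential TF binding
#' shows as a condition-specific peak at offset 0.
#'
#' @param tracks_light,tracks_dark Named lists of subNSP midpoint tracks
#'   per condition (depth-normalized; a warning is emitted if raw).
#' @param sites TFBS table from [read_tfbs_bed()] (or the landscape's
#'   `tfbs` table).
#' @param flank Half-window, bp. Default 500.
#' @return List: `light`, `dark` (aggregate data.tables), `difference`
#'   (offset, value = light - dark), `per_site` (list of two
#'   [profile_matrix()] objects), `n_sites`.
#' @export
tfbs_aggregate <- function(tracks_light, tracks_dark, sites, flank = 500L) {
  if (is.null(sites) || nrow(sites) == 0L) stop("empty TFBS site set")
  norm <- function(trs) unique(vapply(trs, `[[`, "", "normalization"))
  if (any(c(norm(tracks_light), norm(tracks_dark)) == "raw"))
    warning("TFBS aggregation on raw (non-depth-normalized) tracks")
  anchors <- data.table(
    feature_id = sprintf("site%05d", seq_len(nrow(sites))),
    chrom = sites$chrom,
    pos = floor((sites$start + sites$end) / 2),
    strand = sites$strand, kind = "TFBS")
  pm_l <- profile_matrix(tracks_light, anchors, flank = flank, bin = 1L)
  pm_d <- profile_matrix(tracks_dark, anchors, flank = flank, bin = 1L)
  agg_l <- aggregate_profile(pm_l)
  agg_d <- aggregate_profile(pm_d)
  diff <- data.table(offset = agg_l$offset,
                     value = agg_l$value - agg_d$value)
  list(light = agg_l, dark = agg_d, difference = diff,
       per_site = list(light = pm_l, dark = pm_d), n_sites = nrow(sites))
}

#' Per-class track report over one gene
#'
#' Bundles subNSP midpoint, mono midpoint and total (>= nucleosomal)
#' coverage values over the gene span plus flank, per sample, oriented
#' 5' to 3' along the gene. Use [write_gene_region_report()] to export
#' bedGraph tracks (genomic orientation) and [plot_gene_region()] for a
#' quick figure.
#'
#' @param fragment_sets Named list of fragment sets (one per sample).
#' @param annotation A `genome_annotation`.
#' @param gene_id Gene to report.
#' @param flank Flank around the gene span, bp.
#' @param scheme A [size_scheme()].
#' @return Object of class `gene_region_report`.
#' @export
gene_region_report <- function(fragment_sets, annotation, gene_id,
                               flank = 500L, scheme = size_scheme()) {
  sel <- which(annotation$genes$gene_id == gene_id)
  g <- annotation$genes[sel]
  if (nrow(g) == 0L)
    stop("unknown gene '", gene_id, "'; known ids include: ",
         paste(head(annotation$genes$gene_id, 5L), collapse = ", "))
  cl <- stats::setNames(annotation$chroms$length, annotation$chroms$chrom)
  rs <- max(0L, g$start - flank)
  re <- min(cl[[g$chrom]], g$end + flank)
  region_positions <- seq(rs, re - 1L)
  samples <- lapply(fragment_sets, function(fr) {
    fr <- fr[chrom == g$chrom]
    sub <- subnsp_midpoint_track(fr, cl[g$chrom], scheme)[[g$chrom]]
    mono <- midpoint_track(fr, cl[g$chrom], scheme = scheme)[[g$chrom]]
    cov <- coverage_track(fr, cl[g$chrom], scheme = scheme)[[g$chrom]]
    slice <- function(tr) tr$values[(rs + 1L):re]
    ori <- function(v) if (g$strand == "-") rev(v) else v
    list(subnsp = ori(slice(sub)), mono = ori(slice(mono)),
         coverage = ori(slice(cov)))
  })
  structure(list(gene = g, region = list(chrom = g$chrom, start = rs,
                                         end = re),
                 positions = if (g$strand == "-") rev(region_positions)
                   else region_positions,
                 samples = samples, scheme = scheme),
            class = "gene_region_report")
}

#' Write a gene region report as bedGraph tracks
#'
#' One file per sample and particle class, in genomic orientation.
#'
#' @param report A [gene_region_report()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_gene_region_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- report$gene
  paths <- character()
  for (sn in names(report$samples)) {
    for (cls in c("subnsp", "mono", "coverage")) {
      v <- report$samples[[sn]][[cls]]
      if (g$strand == "-") v <- rev(v)     # back to genomic orientation
      tr <- occupancy_track(v, report$region$chrom,
                            origin = report$region$start,
                            mode = if (cls == "coverage") "coverage"
                              else "midpoint")
      p <- file.path(dir, sprintf("%s_%s_%s.bedGraph", g$gene_id, sn, cls))
      write_track(tr, p, format = "bedGraph")
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Plot a gene region report
#'
#' One panel per sample with the three particle-class traces, 5' to 3'
#' along the gene; the TSS and CSS are marked.
#'
#' @param report A [gene_region_report()].
#' @param classes Classes to draw.
#' @export
plot_gene_region <- function(report,
                             classes = c("subnsp", "mono", "coverage")) {
  g <- report$gene
  ns <- base::length(report$samples)
  op <- graphics::par(mfrow = c(ns, 1L), mar = c(2, 4, 1.5, 1))
  on.exit(graphics::par(op))
  s <- if (g$strand == "-") -1L else 1L
  xoff <- s * (report$positions - g$tss)
  cols <- c(subnsp = "firebrick", mono = "black", coverage = "steelblue")
  for (sn in names(report$samples)) {
    sm <- report$samples[[sn]]
    ylim <- c(0, max(1, unlist(sm[classes])))
    graphics::plot(NA, xlim = range(xoff), ylim = ylim, xlab = "",
                   ylab = "occupancy", main = paste(g$gene_id, sn))
    for (cls in classes)
      graphics::lines(xoff, sm[[cls]], col = cols[[cls]], lwd = 1)
    graphics::abline(v = 0, lty = 2)
    graphics::abline(v = s * (g$css - g$tss), lty = 3)
  }
  invisible(report)
}
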