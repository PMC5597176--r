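#' Per-base occupancy track
#'
#' A single-chromosome vector of non-negative values, either midpoint counts
#' (`mode = "midpoint"`: one count at each contributing fragment's midpoint)
#' or interpolated coverage (`mode = "coverage"`: every base of the protected
#' span counted). `origin` is the 0-based genomic coordinate of the first
#' value; tracks built by [midpoint_track()] / [coverage_track()] span whole
#' chromosomes with `origin = 0`.
#'
#' @param values Numeric vector of per-bin values (>= 0).
#' @param chrom Chromosome name.
#' @param origin 0-based coordinate of the first bin.
#' @param bin_size Bin width in bp (1 = per-base).
#' @param mode `"midpoint"` or `"coverage"`.
#' @param normalization `"raw"` or `"per_million"`.
#' @return An object of class `occupancy_track`.
#' @export
occupancy_track <- function(values, chrom, origin = 0L, bin_size = 1L,
                            mode = c("midpoint", "coverage"),
                            normalization = "raw") {
  mode <- match.arg(mode)
  if (any(values < 0)) stop("track values must be >= 0")
  structure(list(chrom = as.character(chrom), origin = as.integer(origin),
                 bin_size = as.integer(bin_size),
                 values = as.numeric(values), mode = mode,
                 normalization = normalization),
            class = "occupancy_track")
}

#' @export
print.occupancy_track <- function(x, ...) {
  cat(sprintf("<occupancy_track> %s:%d-%d %s (%s), %d bins of %d bp, sum %.4g\n",
              x$chrom, x$origin,
              x$origin + length(x$values) * x$bin_size,
              x$mode, x$normalization, length(x$values), x$bin_size,
              sum(x$values)))
  invisible(x)
}

chrom_length_vec <- function(chrom_lengths) {
  ## accepts a data.table/data.frame (chrom, length) or a named vector
  if (is.data.frame(chrom_lengths)) {
    stats::setNames(as.integer(chrom_lengths[[2L]]),
                    as.character(chrom_lengths[[1L]]))
  } else {
    stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))
  }
}

#' Midpoint occupancy tracks
#'
#' For each fragment whose length lies inside `size_window` (inclusive), one
#' count is added at the base containing its midpoint,
#' `floor((start + end) / 2)` (even-length midpoints round down). The raw
#' track sum therefore equals the number of contributing fragments. The
#' default window is the scheme's mono window, `nuc_unit +/- mono_mid_tol`
#' (150 +/- 15 bp); see [subnsp_midpoint_track()] for the < 120 bp
#' subsample.
#'
#' @param fragments A fragment set.
#' @param chrom_lengths Chromosome table (`chrom`, `length`) or named vector.
#' @param size_window Inclusive length window, bp.
#' @param scheme A [size_scheme()] (supplies the default window).
#' @return Named list of [occupancy_track()] objects, one per chromosome.
#' @export
midpoint_track <- function(fragments, chrom_lengths,
                           size_window = NULL, scheme = size_scheme()) {
  if (is.null(size_window))
    size_window <- c(scheme$nuc_unit - scheme$mono_mid_tol,
                     scheme$nuc_unit + scheme$mono_mid_tol)
  cl <- chrom_length_vec(chrom_lengths)
  f <- fragments[length >= size_window[1L] & length <= size_window[2L]]
  mids <- floor((f$start + f$end) / 2)
  out <- lapply(names(cl), function(cn) {
    m <- mids[f$chrom == cn]
    m <- m[m >= 0L & m < cl[[cn]]]
    occupancy_track(tabulate(m + 1L, nbins = cl[[cn]]), cn,
                    mode = "midpoint")
  })
  stats::setNames(out, names(cl))
}

#' subNSP midpoint tracks
#'
#' Convenience wrapper of [midpoint_track()] with the sub-nucleosomal window
#' (retained lengths strictly below `scheme$sub_max`).
#'
#' @inheritParams midpoint_track
#' @return Named list of [occupancy_track()] objects.
#' @export
subnsp_midpoint_track <- function(fragments, chrom_lengths,
                                  scheme = size_scheme()) {
  midpoint_track(fragments, chrom_lengths,
                 size_window = c(0L, scheme$sub_max - 1L), scheme = scheme)
}

#' Interpolated coverage tracks
#'
#' Every base of `[start, end)` of each fragment with
#' `min_length <= length <= max_length` is incremented by one ("interpolation
#' between sequenced paired reads"). Implemented by interval
#' difference-accumulation (`cumsum` of +1/-1 deltas), which equals the
#' naive per-base loop exactly; the raw sum equals the summed length of
#' contributing fragments. The default `min_length = scheme$sub_max` gives
#' the total nucleosomal-and-larger coverage of the paper's blue track.
#'
#' @inheritParams midpoint_track
#' @param min_length,max_length Inclusive length filter, bp.
#' @return Named list of [occupancy_track()] objects.
#' @export
coverage_track <- function(fragments, chrom_lengths,
                           min_length = NULL, max_length = Inf,
                           scheme = size_scheme()) {
  if (is.null(min_length)) min_length <- scheme$sub_max
  cl <- chrom_length_vec(chrom_lengths)
  f <- fragments[length >= min_length & length <= max_length]
  out <- lapply(names(cl), function(cn) {
    n <- cl[[cn]]
    fc <- f[chrom == cn]
    delta <- numeric(n + 1L)
    if (nrow(fc)) {
      s <- pmax(fc$start, 0L); e <- pmin(fc$end, n)
      ok <- s < e
      s <- s[ok]; e <- e[ok]
      add <- tabulate(s + 1L, nbins = n + 1L)
      sub <- tabulate(e + 1L, nbins = n + 1L)
      delta <- add - sub
    }
    occupancy_track(cumsum(delta)[seq_len(n)], cn, mode = "coverage")
  })
  stats::setNames(out, names(cl))
}

#' Depth-normalize a track to counts per million fragments
#'
#' Scales values by `1e6 / total_retained_fragments` and flips the
#' normalization flag. Re-normalizing an already normalized track is an
#' error, as is a zero total. Accepts a single track or a (nested) list of
#' tracks.
#'
#' @param track An [occupancy_track()] or list thereof.
#' @param total_retained_fragments Library size used as denominator.
#' @return Track(s) with `normalization = "per_million"`.
#' @export
normalize_per_million <- function(track, total_retained_fragments) {
  if (is.list(track) && !inherits(track, "occupancy_track"))
    return(lapply(track, normalize_per_million, total_retained_fragments))
  if (total_retained_fragments == 0) stop("total_retained_fragments is 0")
  if (track$normalization != "raw")
    stop("track is already normalized (", track$normalization, ")")
  track$values <- track$values * 1e6 / total_retained_fragments
  track$normalization <- "per_million"
  track
}

#' Size-by-position fragment matrix
#'
#' The 2D histogram behind the "V-plot"-style landscape: each fragment whose
#' midpoint falls inside `region` contributes one count at its
#' (length bin, midpoint bin) cell, so the matrix total equals the number of
#' in-region fragments whose length lies inside the binned size range, and
#' the marginal over sizes equals the all-size midpoint histogram on the
#' same position bins.
#'
#' @param fragments A fragment set.
#' @param region List or vector with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param size_bin,pos_bin Bin widths in bp (must be > 0).
#' @param size_range Inclusive-low, exclusive-high length range to bin;
#'   defaults to the scheme retention range.
#' @param scheme A [size_scheme()].
#' @return Object of class `size_position_matrix` with fields `counts`
#'   (size bins x position bins), `size_breaks`, `pos_breaks`, `region`,
#'   `normalization`.
#' @export
size_position_matrix <- function(fragments, region, size_bin = 10L,
                                 pos_bin = 10L, size_range = NULL,
                                 scheme = size_scheme()) {
  if (size_bin <= 0 || pos_bin <= 0) stop("bin sizes must be > 0")
  if (is.null(size_range))
    size_range <- c(scheme$retention[1L], scheme$retention[2L] + 1L)
  region <- as.list(region)
  rs <- as.integer(region$start); re <- as.integer(region$end)
  f <- fragments[chrom == as.character(region$chrom)]
  mids <- floor((f$start + f$end) / 2)
  keep <- mids >= rs & mids < re &
    f$length >= size_range[1L] & f$length < size_range[2L]
  mids <- mids[keep]; lens <- f$length[keep]
  size_breaks <- seq(size_range[1L],
                     size_range[1L] + size_bin *
                       ceiling(diff(size_range) / size_bin), by = size_bin)
  pos_breaks <- seq(rs, rs + pos_bin * ceiling((re - rs) / pos_bin),
                    by = pos_bin)
  si <- findInterval(lens, size_breaks, rightmost.closed = FALSE)
  pi_ <- findInterval(mids, pos_breaks, rightmost.closed = FALSE)
  counts <- matrix(0L, nrow = length(size_breaks) - 1L,
                   ncol = length(pos_breaks) - 1L,
                   dimnames = list(size = head(size_breaks, -1L),
                                   pos = head(pos_breaks, -1L)))
  for (k in seq_along(si)) counts[si[k], pi_[k]] <- counts[si[k], pi_[k]] + 1L
  structure(list(region = list(chrom = as.character(region$chrom),
                               start = rs, end = re),
                 size_breaks = size_breaks, pos_breaks = pos_breaks,
                 counts = counts, normalization = "raw"),
            class = "size_position_matrix")
}

#' @export
print.size_position_matrix <- function(x, ...) {
  cat(sprintf("<size_position_matrix> %s:%d-%d, %d size x %d position bins, total %d\n",
              x$region$chrom, x$region$start, x$region$end,
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}
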