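## Independent oracles: deliberately naive implementations used only to
## check the package's optimized paths.

library(data.table)

## per-base coverage by explicit looping over fragments and bases
naive_coverage <- function(fragments, chrom, chrom_len,
                           min_length = 0, max_length = Inf) {
  v <- numeric(chrom_len)
  f <- fragments[fragments$chrom == chrom &
                   fragments$length >= min_length &
                   fragments$length <= max_length, ]
  for (i in seq_len(nrow(f))) {
    for (b in seq(max(f$start[i], 0L), min(f$end[i], chrom_len) - 1L)) {
      v[b + 1L] <- v[b + 1L] + 1
    }
  }
  v
}

## all-pairs distance to CDS intervals (0 inside, else gap to nearest edge)
brute_cds_distance <- function(positions, cds) {
  vapply(seq_len(nrow(positions)), function(i) {
    cc <- cds[cds$chrom == positions$chrom[i], ]
    if (nrow(cc) == 0L) return(Inf)
    p <- positions$pos[i]
    min(vapply(seq_len(nrow(cc)), function(j) {
      if (p >= cc$start[j] && p < cc$end[j]) 0
      else min(abs(p - cc$start[j]), abs(p - (cc$end[j] - 1L)))
    }, numeric(1)))
  }, numeric(1))
}

## textbook Welch two-sample t statistic, df and two-sided p
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

## direct-moment Fisher excess kurtosis (independent arithmetic path)
moment_kurtosis <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  d <- x - m
  (sum(d^4) / n) / (sum(d^2) / n)^2 - 3
}

## random fragment set on one chromosome
random_fragments <- function(n, chrom_len = 5000L, chrom = "chr1",
                             max_len = 400L) {
  len <- sample.int(max_len - 19L, n, replace = TRUE) + 19L
  start <- vapply(len, function(l) sample.int(chrom_len - l, 1L) - 1L,
                  integer(1))
  fragment_set(rep(chrom, n), start, start + len)
}
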