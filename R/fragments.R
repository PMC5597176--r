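#' Construct a fragment set
#'
#' A fragment set is a `data.table` with columns `chrom`, `start`, `end`
#' (0-based half-open) and `length = end - start`, sorted by
#' `(chrom, start, end)`. This is the unit every downstream operation
#' consumes: one row per protected DNA interval inferred from a sequenced
#' read pair.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open.
#' @return A sorted fragment `data.table`.
#' @export
fragment_set <- function(chrom, start, end) {
  if (any(end <= start)) stop("fragment end must be > start")
  dt <- data.table(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end))
  dt[, length := end - start]
  setorder(dt, chrom, start, end)
  dt[]
}

empty_fragment_set <- function() {
  data.table(chrom = character(), start = integer(), end = integer(),
             length = integer())
}

#' Read paired-end fragments from a BED file
#'
#' Reads a >= 3 column BED (whitespace separated), validates coordinates and
#' drops fragments whose length falls outside the scheme's retention range
#' (default 20 bp - 1 kb, mirroring gel size selection). The drop tally is
#' attached as attribute `n_dropped` and reported via `message()`.
#'
#' @param path Path to a BED file.
#' @param scheme A [size_scheme()]; its `retention` range is applied.
#' @return A fragment set (see [fragment_set()]) with attribute `n_dropped`.
#' @export
read_fragment_bed <- function(path, scheme = size_scheme()) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    warning("empty BED file: ", path)
    out <- empty_fragment_set()
    setattr(out, "n_dropped", 0L)
    return(out)
  }
  raw <- fread(path, header = FALSE, colClasses = list(character = 1),
               fill = TRUE, blank.lines.skip = TRUE)
  if (ncol(raw) < 3L) stop("BED file needs >= 3 columns: ", path)
  s <- suppressWarnings(as.integer(raw[[2L]]))
  e <- suppressWarnings(as.integer(raw[[3L]]))
  bad <- which(is.na(s) | is.na(e) | is.na(raw[[1L]]) | raw[[1L]] == "")
  if (length(bad))
    stop("malformed BED line ", bad[1L], " in ", path)
  bad <- which(e <= s)
  if (length(bad))
    stop("end <= start at BED line ", bad[1L], " in ", path)
  dt <- data.table(chrom = raw[[1L]], start = s, end = e)
  dt[, length := end - start]
  keep <- dt$length >= scheme$retention[1L] & dt$length <= scheme$retention[2L]
  n_drop <- sum(!keep)
  if (n_drop)
    message(n_drop, " fragment(s) outside retention range [",
            scheme$retention[1L], ", ", scheme$retention[2L], "] dropped")
  dt <- dt[keep]
  setorder(dt, chrom, start, end)
  setattr(dt, "n_dropped", n_drop)
  dt[]
}

#' Write a fragment set as BED6
#'
#' Columns: chrom, start, end, name (= sample id), score (= fragment length),
#' strand (`.`).
#'
#' @param fragments A fragment set.
#' @param path Output path.
#' @param sample_id Name column value.
#' @export
write_fragment_bed <- function(fragments, path, sample_id = "sample") {
  out <- data.table(fragments$chrom, fragments$start, fragments$end,
                    sample_id, fragments$length, ".")
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract fragments from a coordinate-sorted paired-end BAM
#'
#' One fragment per properly paired template: the span runs from the
#' leftmost mate's start over `|TLEN|` bases. Only the leftmost mate of each
#' template (positive TLEN) is counted, so every template contributes exactly
#' once. Records with TLEN 0 (mate unmapped) or mapping quality below
#' `min_mapq` are excluded and tallied in attributes `n_low_mapq` /
#' `n_zero_tlen`.
#'
#' @param path Path to an indexed or unindexed BAM file.
#' @param min_mapq Minimum mapping quality (applied to the counted mate).
#' @param scheme A [size_scheme()]; retention range applied as in
#'   [read_fragment_bed()].
#' @return A fragment set.
#' @export
fragments_from_paired_bam <- function(path, min_mapq = 0L,
                                      scheme = size_scheme()) {
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                  isUnmappedQuery = FALSE),
    what = c("rname", "pos", "isize", "mapq"))
  res <- Rsamtools::scanBam(path, param = param)[[1L]]
  n_any <- length(Rsamtools::scanBam(
    path, param = Rsamtools::ScanBamParam(what = "pos"))[[1L]]$pos)
  if (length(res$pos) == 0L) {
    if (n_any > 0L)
      stop("no properly paired reads in ", path,
           "; for single-end or pre-paired data supply fragments as BED ",
           "via read_fragment_bed()")
    return(empty_fragment_set())
  }
  left <- which(res$isize > 0L)               # leftmost mate: count once
  n_zero <- sum(res$isize == 0L)
  mq_ok <- res$mapq[left] >= min_mapq | is.na(res$mapq[left])
  n_low <- sum(!mq_ok)
  left <- left[mq_ok]
  start0 <- res$pos[left] - 1L                # BAM POS is 1-based
  dt <- data.table(chrom = as.character(res$rname[left]),
                   start = start0, end = start0 + res$isize[left])
  dt[, length := end - start]
  keep <- dt$length >= scheme$retention[1L] & dt$length <= scheme$retention[2L]
  n_drop <- sum(!keep)
  dt <- dt[keep]
  setorder(dt, chrom, start, end)
  setattr(dt, "n_dropped", n_drop)
  setattr(dt, "n_low_mapq", n_low)
  setattr(dt, "n_zero_tlen", n_zero)
  dt[]
}
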