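#' Write occupancy tracks as wiggle or bedGraph
#'
#' Internal coordinates are 0-based half-open; `wiggle` fixedStep is written
#' 1-based per the format standard (`start = origin + 1`), `bedGraph`
#' 0-based half-open. bedGraph runs of adjacent equal values (including
#' zeros) are merged into single intervals, so a round trip through
#' [read_track()] reproduces the per-base values; numbers are printed with 6
#' significant figures.
#'
#' @param track An [occupancy_track()] or a named list of them
#'   (multi-chromosome file).
#' @param path Output path.
#' @param format `"wiggle"` (fixedStep) or `"bedGraph"`.
#' @param chrom_lengths Optional declared chromosome set; writing a track
#'   whose chromosome is absent from it is an error.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("wiggle", "bedGraph"),
                        chrom_lengths = NULL) {
  format <- match.arg(format)
  tracks <- if (inherits(track, "occupancy_track")) list(track) else track
  if (!is.null(chrom_lengths)) {
    declared <- names(chrom_length_vec(chrom_lengths))
    for (tr in tracks)
      if (!tr$chrom %in% declared)
        stop("chromosome '", tr$chrom, "' absent from declared set")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (tr in tracks) {
    if (format == "wiggle") {
      writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                         tr$chrom, tr$origin + 1L, tr$bin_size,
                         tr$bin_size), con)
      writeLines(sprintf("%.6g", tr$values), con)
    } else {
      rl <- rle(tr$values)
      e <- tr$origin + cumsum(rl$lengths) * tr$bin_size
      s <- c(tr$origin, head(e, -1L))
      writeLines(sprintf("%s\t%d\t%d\t%.6g", tr$chrom, s, e, rl$values), con)
    }
  }
  invisible(path)
}

#' Read a wiggle or bedGraph track file written by [write_track()]
#'
#' Format is auto-detected from the first line. Files may hold several
#' chromosomes; one [occupancy_track()] per chromosome is returned. bedGraph
#' intervals are expanded back to per-base values (the file must tile each
#' chromosome contiguously, as [write_track()] guarantees).
#'
#' @param path Input path.
#' @param mode,normalization Metadata to stamp on the rebuilt tracks (the
#'   text formats do not carry them).
#' @return Named list of [occupancy_track()] objects.
#' @export
read_track <- function(path, mode = "coverage", normalization = "raw") {
  lines <- readLines(path)
  if (!length(lines)) stop("empty track file: ", path)
  if (startsWith(lines[[1L]], "fixedStep")) {
    heads <- grep("^fixedStep", lines)
    bounds <- c(heads, length(lines) + 1L)
    out <- list()
    for (i in seq_along(heads)) {
      h <- lines[[heads[i]]]
      fld <- function(k) sub(sprintf(".*%s=([^ ]+).*", k), "\\1", h)
      vals <- as.numeric(lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)])
      out[[fld("chrom")]] <- occupancy_track(
        vals, fld("chrom"), origin = as.integer(fld("start")) - 1L,
        bin_size = as.integer(fld("step")), mode = mode,
        normalization = normalization)
    }
    return(out)
  }
  dt <- fread(path, header = FALSE,
              col.names = c("chrom", "start", "end", "value"))
  out <- lapply(split(dt, by = "chrom", sorted = TRUE), function(d) {
    setorder(d, start)
    occupancy_track(rep(d$value, d$end - d$start), d$chrom[1L],
                    origin = d$start[1L], bin_size = 1L, mode = mode,
                    normalization = normalization)
  })
  out
}
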