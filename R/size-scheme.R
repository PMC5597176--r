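#' Fragment size-classification scheme
#'
#' Collects the length thresholds used throughout CPSA. Sub-nucleosomal
#' particles (subNSP) protect strictly fewer than `sub_max` bp; nucleosome-
#' scale fragments are assigned an order \eqn{\hat N} by the rule
#' \eqn{\hat N = round((L + linker) / (nuc\_unit + linker))}, i.e. the number
#' of nucleosomes an undigested chain of that length would contain
#' (\eqn{L = N \cdot 150 + (N - 1) \cdot 30} for defaults). Two mono windows
#' coexist on purpose: midpoint tracks use the tight `nuc_unit +/-
#' mono_mid_tol` window, while coverage classification uses the \eqn{\hat N}
#' rule whose mono band is about \[120, 255).
#'
#' @param sub_max Exclusive upper bound of the subNSP class, bp. Default 120.
#' @param nuc_unit Nucleosome core protection, bp. Default 150.
#' @param linker Linker DNA between adjacent nucleosomes, bp. Default 30.
#' @param mono_mid_tol Half-width of the midpoint-track mono window, bp.
#'   Default 15, i.e. 150 +/- 15 (the "+/- 10%" window).
#' @param retention Two-element numeric: fragment lengths retained at ingest,
#'   bp. Default `c(20, 1000)`, mirroring gel size selection of 20 bp - 1 kb.
#' @return An object of class `size_scheme`.
#' @export
#' @examples
#' sc <- size_scheme()
#' classify_fragment(c(80, 150, 330), sc)
size_scheme <- function(sub_max = 120L, nuc_unit = 150L, linker = 30L,
                        mono_mid_tol = 15L, retention = c(20L, 1000L)) {
  sub_max <- as.integer(sub_max); nuc_unit <- as.integer(nuc_unit)
  linker <- as.integer(linker); mono_mid_tol <- as.integer(mono_mid_tol)
  retention <- as.integer(retention)
  if (sub_max >= nuc_unit) stop("sub_max must be < nuc_unit")
  if (mono_mid_tol >= nuc_unit / 2) stop("mono_mid_tol must be < nuc_unit/2")
  if (length(retention) != 2L || retention[1L] >= retention[2L])
    stop("retention must be an increasing length-2 range")
  if (retention[1L] > sub_max || retention[2L] < nuc_unit + linker)
    stop("retention range must contain the size-class windows")
  structure(list(sub_max = sub_max, nuc_unit = nuc_unit, linker = linker,
                 mono_mid_tol = mono_mid_tol, retention = retention),
            class = "size_scheme")
}

#' @export
print.size_scheme <- function(x, ...) {
  cat(sprintf(
    "<size_scheme> subNSP < %d bp; nucleosome unit %d bp + %d bp linker;\n",
    x$sub_max, x$nuc_unit, x$linker))
  cat(sprintf("  mono midpoint window %d +/- %d bp; retention [%d, %d] bp\n",
              x$nuc_unit, x$mono_mid_tol, x$retention[1L], x$retention[2L]))
  invisible(x)
}

## round-half-up: classification must not depend on banker's rounding
round_half_up <- function(x) floor(x + 0.5)

#' Classify fragment lengths into particle classes
#'
#' Every retained fragment maps to exactly one class: `"subNSP"` when the
#' length is strictly below `scheme$sub_max`, otherwise `"mono"` or
#' `"multiN"` according to the rounded nucleosome-order rule (see
#' [size_scheme()]). Lengths of 330 bp classify as `"multi2"`
#' (2 x 150 + 30); the boundary length 120 classifies as `"mono"` because
#' round(150/180) = 1.
#'
#' @param length Integer vector of fragment lengths (bp).
#' @param scheme A [size_scheme()].
#' @return Character vector: `"subNSP"`, `"mono"` or `"multi<N>"`.
#' @export
classify_fragment <- function(length, scheme = size_scheme()) {
  nhat <- pmax(1, round_half_up((length + scheme$linker) /
                                (scheme$nuc_unit + scheme$linker)))
  out <- ifelse(nhat == 1, "mono", paste0("multi", nhat))
  out[length < scheme$sub_max] <- "subNSP"
  out
}

#' Nucleosome order of a fragment length
#'
#' The \eqn{\hat N} of the classification rule, clamped to >= 1. subNSP
#' lengths are returned as `NA`.
#'
#' @inheritParams classify_fragment
#' @return Integer vector of nucleosome orders.
#' @export
nucleosome_order <- function(length, scheme = size_scheme()) {
  nhat <- pmax(1, round_half_up((length + scheme$linker) /
                                (scheme$nuc_unit + scheme$linker)))
  nhat[length < scheme$sub_max] <- NA_real_
  as.integer(nhat)
}
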