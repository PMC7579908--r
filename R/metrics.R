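# Evaluation metrics: minimum error correction and reconstruction rate.

# Hamming distance between an integer-with-NA haplotype and all fragments
.hd_rows_to_hap <- function(AM, O, hap) {
  def <- !is.na(hap)
  hv <- ifelse(def, hap, 0L)
  as.vector(AM %*% (def * (1 - hv)) + (O - AM) %*% (def * hv))
}

#' MEC score of a haplotype pair against a fragment matrix
#'
#' Sum over fragments of the smaller Hamming distance to either haplotype:
#' the number of allele corrections needed to make every fragment
#' consistent with its best-fitting chromosome copy.  Unphased (`-`)
#' haplotype positions are gaps and never count as mismatches.
#'
#' @param x an [snp_matrix()].
#' @param h a [haplotype_pair()] of matching length.
#' @return Non-negative integer.
#' @examples
#' mec_score(as_snp_matrix("0001"), haplotype_pair("0101", "1010"))  # 1
#' @export
mec_score <- function(x, h) {
  stopifnot(inherits(x, "snp_matrix"), inherits(h, "haplotype_pair"))
  if (h$n_sites != x$n_sites)
    stop("haplotype length does not match the fragment matrix")
  O <- x$observed * 1
  AM <- x$alleles * O
  d1 <- .hd_rows_to_hap(AM, O, h$h1)
  d2 <- .hd_rows_to_hap(AM, O, h$h2)
  as.integer(sum(pmin(d1, d2)))
}

#' Reconstruction rate of a haplotype pair against the truth
#'
#' `RR = 1 - min(HD(h1', h1) + HD(h2', h2), HD(h1', h2) + HD(h2', h1)) /
#' (2 n)`: one minus the label-swap-minimized total Hamming error over the
#' full length.  Gap positions on either side contribute no mismatch, so
#' unphased columns count as matches.
#'
#' @param h_hat reconstructed [haplotype_pair()].
#' @param h true [haplotype_pair()] of equal length.
#' @return Numeric in [0, 1]; 1 means perfect reconstruction up to label
#'   swap.
#' @examples
#' reconstruction_rate(haplotype_pair("0100", "1010"),
#'                     haplotype_pair("0101", "1010"))  # 1 - 1/8
#' @export
reconstruction_rate <- function(h_hat, h) {
  stopifnot(inherits(h_hat, "haplotype_pair"), inherits(h, "haplotype_pair"))
  n <- h$n_sites
  if (h_hat$n_sites != n) stop("haplotype pairs must have equal length")
  hd <- function(a, b) sum(!is.na(a) & !is.na(b) & a != b)
  direct <- hd(h_hat$h1, h$h1) + hd(h_hat$h2, h$h2)
  crossed <- hd(h_hat$h1, h$h2) + hd(h_hat$h2, h$h1)
  1 - min(direct, crossed) / (2 * n)
}
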