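#' Single-site mismatch indicator
#'
#' Returns 1 iff both alleles are observed and differ, else 0; a gap on
#' either side never counts as a mismatch.  This is the elementary term of
#' the Hamming distance between fragments.
#'
#' @param a,b alleles: 0, 1, `NA` or `"-"` (gap), or the characters
#'   `"0"`/`"1"`.
#' @return 0 or 1.
#' @examples
#' site_mismatch(0, 1)    # 1
#' site_mismatch("-", 1)  # 0
#' @export
site_mismatch <- function(a, b) {
  norm <- function(v) {
    if (is.character(v)) {
      if (v == "-") return(NA_integer_)
      v <- as.integer(v)
    }
    v <- as.integer(v)
    if (!is.na(v) && v != 0L && v != 1L) stop("allele must be 0, 1 or gap")
    v
  }
  a <- norm(a); b <- norm(b)
  if (is.na(a) || is.na(b)) return(0L)
  as.integer(a != b)
}

# internal: mismatch count and joint-overlap size of two (alleles, observed)
# rows of equal length
.pair_hd <- function(r1, r2) {
  both <- r1$observed & r2$observed
  list(hd = sum(both & (r1$alleles != r2$alleles)), s = sum(both))
}

#' Hamming distance between two fragments
#'
#' Number of jointly observed sites at which the fragments disagree.  Two
#' fragments are compatible (consistent with a common chromosome copy) iff
#' their Hamming distance is 0.
#'
#' @param f1,f2 fragment rows: strings over `{0,1,-}` or integer vectors
#'   with `NA` gaps, of equal length.
#' @return Non-negative integer.
#' @examples
#' hamming_distance("01-0", "0110")  # 0: the gap masks the difference
#' @export
hamming_distance <- function(f1, f2) {
  r1 <- .as_allele_row(f1); r2 <- .as_allele_row(f2)
  if (length(r1$alleles) != length(r2$alleles))
    stop("fragments must have equal length")
  .pair_hd(r1, r2)$hd
}

#' Normalized Hamming distance (NHD)
#'
#' Hamming distance divided by the number of sites jointly observed by both
#' fragments, so that the value ranges over [0, 1]: 0 for perfectly
#' consistent overlap, 1 for complementary overlap.  When the fragments
#' share no observed site the distance is undefined and `NA` is returned;
#' the conflict-graph builder treats that as "no edge".
#'
#' @inheritParams hamming_distance
#' @return Numeric in [0, 1], or `NA` when the fragments do not overlap.
#' @examples
#' nhd("010-", "100-")  # 2/3
#' nhd("0-", "-1")      # NA: empty overlap
#' @export
nhd <- function(f1, f2) {
  r1 <- .as_allele_row(f1); r2 <- .as_allele_row(f2)
  if (length(r1$alleles) != length(r2$alleles))
    stop("fragments must have equal length")
  p <- .pair_hd(r1, r2)
  if (p$s == 0L) return(NA_real_)
  p$hd / p$s
}
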