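#' Read a plain fragment matrix file
#'
#' One fragment per non-empty line as a string over `{0,1,-}`, optionally
#' preceded by a whitespace-separated fragment id.  All fragments must span
#' the same number of SNP sites.
#'
#' @param path path to the file.
#' @return An [snp_matrix()]; fragments keep file order.
#' @export
read_fragment_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("empty fragment file: ", path)
  ids <- character(length(keep))
  frs <- character(length(keep))
  for (k in seq_along(keep)) {
    tok <- strsplit(trimws(lines[keep[k]]), "[[:space:]]+")[[1]]
    if (length(tok) == 1L) {
      ids[k] <- paste0("f", k); frs[k] <- tok[1]
    } else if (length(tok) == 2L) {
      ids[k] <- tok[1]; frs[k] <- tok[2]
    } else {
      stop("line ", keep[k], ": expected [id] fragment, got ", length(tok),
           " fields")
    }
    if (grepl("[^01-]", frs[k]))
      stop("line ", keep[k], ": invalid character in fragment string")
  }
  if (length(unique(nchar(frs))) != 1L) {
    off <- keep[which(nchar(frs) != nchar(frs[1]))[1]]
    stop("ragged fragment lengths: line ", off, " differs from line ", keep[1])
  }
  if (any(grepl("^-+$", frs))) {
    off <- keep[which(grepl("^-+$", frs))[1]]
    stop("line ", off, ": fragment has no observed site")
  }
  as_snp_matrix(frs, fragment_ids = ids)
}

#' Read a HapCUT-style fragment file
#'
#' Each line is `B id start1 alleles1 [start2 alleles2 ...] [quality]`:
#' a block count `B`, a fragment id, then `B` pairs of 1-based start offset
#' and contiguous allele string.  A trailing quality string (one character
#' per allele, not matching `^[01]+$` placement) is parsed and ignored: the
#' clustering is unweighted.
#'
#' @param path path to the fragment file.
#' @param n_sites total number of SNP sites (matrix width).
#' @return An [snp_matrix()] of width `n_sites`.
#' @export
read_hapcut_fragments <- function(path, n_sites) {
  if (!file.exists(path)) stop("no such file: ", path)
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 1L) stop("'n_sites' must be >= 1")
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("empty fragment file: ", path)
  m <- length(keep)
  alleles <- matrix(0L, m, n_sites)
  observed <- matrix(FALSE, m, n_sites)
  ids <- character(m)
  for (k in seq_len(m)) {
    ln <- keep[k]
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    nb <- suppressWarnings(as.integer(tok[1]))
    if (is.na(nb) || nb < 1L)
      stop("line ", ln, ": block count must be a positive integer")
    need <- 2L + 2L * nb
    if (length(tok) < need)
      stop("line ", ln, ": block count ", nb, " does not match the number ",
           "of (offset, alleles) pairs")
    if (length(tok) > need + 1L)
      stop("line ", ln, ": trailing fields beyond blocks and quality string")
    ids[k] <- tok[2]
    for (b in seq_len(nb)) {
      start <- suppressWarnings(as.integer(tok[1L + 2L * b]))
      al <- tok[2L + 2L * b]
      if (is.na(start) || start < 1L)
        stop("line ", ln, ": block ", b, " has an invalid start offset")
      if (grepl("[^01]", al))
        stop("line ", ln, ": block ", b, " alleles must be over {0,1}")
      idx <- start:(start + nchar(al) - 1L)
      if (max(idx) > n_sites)
        stop("line ", ln, ": block ", b, " exceeds n_sites = ", n_sites)
      if (any(observed[k, idx]))
        stop("line ", ln, ": overlapping blocks within fragment ", ids[k])
      observed[k, idx] <- TRUE
      alleles[k, idx] <- as.integer(strsplit(al, "", fixed = TRUE)[[1]])
    }
  }
  snp_matrix(alleles, observed, ids)
}

#' Write / read a haplotype pair
#'
#' `write_haplotypes()` writes two lines, `h1` then `h2`, as strings over
#' `{0,1,-}`; `read_haplotypes()` reads them back, so the two round-trip.
#'
#' @param h a [haplotype_pair()].
#' @param path file path.
#' @return `write_haplotypes()` returns `invisible(path)`;
#'   `read_haplotypes()` returns a [haplotype_pair()].
#' @export
write_haplotypes <- function(h, path) {
  stopifnot(inherits(h, "haplotype_pair"))
  ok <- tryCatch({
    writeLines(as.character(h), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write haplotypes to '", path, "': ",
         conditionMessage(ok))
  invisible(path)
}

#' @rdname write_haplotypes
#' @export
read_haplotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 2L)
    stop("haplotype file must contain exactly two lines: ", path)
  haplotype_pair(trimws(lines[1]), trimws(lines[2]))
}
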