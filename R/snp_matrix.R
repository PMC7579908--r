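#' Fragment matrix over heterozygous SNP sites
#'
#' An `snp_matrix` holds `m` sequencing fragments restricted to `n`
#' heterozygous SNP sites.  Alleles are coded 0 (major) / 1 (minor); a site a
#' fragment does not confidently observe is a gap.  Internally the object
#' stores an integer allele matrix (gap positions canonicalized to 0) plus a
#' logical observation mask, so every consumer ignores unobserved entries.
#'
#' @param alleles integer or numeric matrix of 0/1 allele codes, one row per
#'   fragment.  Entries at unobserved positions are ignored.
#' @param observed logical matrix of the same dimension; `FALSE` marks a gap.
#' @param fragment_ids optional character vector of row labels; defaults to
#'   `f1, f2, ...`.
#'
#' @return An object of class `snp_matrix` with elements `alleles`,
#'   `observed`, `fragment_ids`, `n_fragments`, `n_sites`.
#'
#' @examples
#' x <- as_snp_matrix(c("01-0", "0110"))
#' x$observed[1, ]
#' @export
snp_matrix <- function(alleles, observed, fragment_ids = NULL) {
  alleles <- as.matrix(alleles)
  observed <- as.matrix(observed)
  if (!all(dim(alleles) == dim(observed)))
    stop("'alleles' and 'observed' must have identical dimensions")
  if (nrow(alleles) < 1L || ncol(alleles) < 1L)
    stop("an snp_matrix needs at least one fragment and one site")
  storage.mode(alleles) <- "integer"
  if (!is.logical(observed)) storage.mode(observed) <- "logical"
  if (anyNA(observed)) stop("'observed' must not contain NA")
  bad <- observed & !(alleles %in% c(0L, 1L) | is.na(alleles))
  if (any(alleles[observed] != 0L & alleles[observed] != 1L, na.rm = TRUE) ||
      anyNA(alleles[observed]))
    stop("observed alleles must be 0 or 1")
  alleles[!observed] <- 0L  # canonical gap value
  empty <- rowSums(observed) == 0L
  if (any(empty))
    stop("fragment(s) with zero observed sites: row ",
         paste(which(empty), collapse = ", "))
  if (is.null(fragment_ids)) fragment_ids <- paste0("f", seq_len(nrow(alleles)))
  if (length(fragment_ids) != nrow(alleles))
    stop("'fragment_ids' length must equal the number of fragments")
  dimnames(alleles) <- dimnames(observed) <- NULL
  structure(
    list(alleles = alleles, observed = observed,
         fragment_ids = as.character(fragment_ids),
         n_fragments = nrow(alleles), n_sites = ncol(alleles)),
    class = "snp_matrix")
}

#' Build an snp_matrix from fragment strings
#'
#' @param strings character vector; each element is one fragment over
#'   `{0,1,-}`, all of the same length.
#' @param fragment_ids optional row labels.
#' @return An [snp_matrix()].
#' @examples
#' as_snp_matrix(c("010-", "10-1"))
#' @export
as_snp_matrix <- function(strings, fragment_ids = NULL) {
  if (!is.character(strings) || length(strings) < 1L)
    stop("'strings' must be a non-empty character vector")
  lens <- nchar(strings)
  if (length(unique(lens)) != 1L)
    stop("fragment strings have unequal lengths")
  chars <- matrix(unlist(strsplit(strings, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(strings), byrow = TRUE)
  bad <- !(chars %in% c("0", "1", "-"))
  if (any(bad))
    stop("invalid character(s) in fragment strings: ",
         paste(unique(chars[bad]), collapse = " "))
  observed <- chars != "-"
  alleles <- matrix(0L, nrow(chars), ncol(chars))
  alleles[chars == "1"] <- 1L
  snp_matrix(alleles, observed, fragment_ids)
}

# fragment row -> string over {0,1,-}
.row_to_string <- function(alleles, observed) {
  ch <- ifelse(observed, as.character(alleles), "-")
  paste(ch, collapse = "")
}

# coerce a fragment row given as string / integer-with-NA vector to the
# internal (alleles, observed) pair
.as_allele_row <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    ch <- strsplit(x, "", fixed = TRUE)[[1]]
    if (!all(ch %in% c("0", "1", "-")))
      stop("fragment string may contain only 0, 1 and -")
    obs <- ch != "-"
    al <- integer(length(ch))
    al[ch == "1"] <- 1L
    return(list(alleles = al, observed = obs))
  }
  x <- as.integer(x)
  obs <- !is.na(x)
  if (any(x[obs] != 0L & x[obs] != 1L)) stop("alleles must be 0, 1 or NA")
  x[!obs] <- 0L
  list(alleles = x, observed = obs)
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat("SNP fragment matrix:", x$n_fragments, "fragments x", x$n_sites,
      "sites\n")
  cat(sprintf("mean coverage per site: %.2f; gap fraction: %.2f\n",
              mean(colSums(x$observed)),
              1 - mean(x$observed)))
  show <- utils::head(seq_len(x$n_fragments), 6L)
  for (i in show)
    cat(sprintf("  %-8s %s\n", x$fragment_ids[i],
                .row_to_string(x$alleles[i, ], x$observed[i, ])))
  if (x$n_fragments > 6L) cat("  ...\n")
  invisible(x)
}

#' Haplotype pair
#'
#' The two reconstructed (or true) haplotypes over `n` heterozygous SNP
#' sites.  Alleles are 0/1; `NA` marks a site that could not be phased
#' (written as `-` on file).
#'
#' @param h1,h2 integer vectors (or strings over `{0,1,-}`) of equal length.
#' @return An object of class `haplotype_pair` with elements `h1`, `h2`,
#'   `n_sites`.
#' @examples
#' haplotype_pair("0101", "1010")
#' @export
haplotype_pair <- function(h1, h2) {
  r1 <- .as_allele_row(h1)
  r2 <- .as_allele_row(h2)
  a1 <- ifelse(r1$observed, r1$alleles, NA_integer_)
  a2 <- ifelse(r2$observed, r2$alleles, NA_integer_)
  if (length(a1) != length(a2))
    stop("h1 and h2 must have equal length")
  structure(list(h1 = a1, h2 = a2, n_sites = length(a1)),
            class = "haplotype_pair")
}

#' @export
as.character.haplotype_pair <- function(x, ...) {
  c(.row_to_string(ifelse(is.na(x$h1), 0L, x$h1), !is.na(x$h1)),
    .row_to_string(ifelse(is.na(x$h2), 0L, x$h2), !is.na(x$h2)))
}

#' @export
print.haplotype_pair <- function(x, ...) {
  s <- as.character(x)
  cat("haplotype pair over", x$n_sites, "sites\n")
  cat("  h1:", s[1], "\n  h2:", s[2], "\n")
  invisible(x)
}
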