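# End-to-end reconstruction: conflict-graph seeding, NCM refinement,
# center rounding, and the fitted-model interface.

#' Round cluster centers into a complementary haplotype pair
#'
#' Every matrix site is a heterozygous SNP, so the two haplotypes must be
#' complementary at every covered column.  Per column the dominant center
#' (the one farther from the neutral value 0.5) decides: it rounds to its
#' nearest allele and the other haplotype takes the complement.  When both
#' centers are equally decisive and agree on complementary alleles those
#' are kept; at a complete tie (both centers at 0.5) the column defaults
#' to `h1 = 0`, `h2 = 1`.  Columns covered by no fragment are unphasable
#' and emit `-` in both haplotypes.
#'
#' @param centers 2 x n numeric matrix in [0,1].
#' @param coverage logical vector: does any fragment observe the column?
#'   Defaults to all `TRUE`.
#' @return A [haplotype_pair()].
#' @export
round_centers_to_haplotypes <- function(centers,
                                        coverage = rep(TRUE, ncol(centers))) {
  if (!is.matrix(centers) || nrow(centers) != 2L)
    stop("'centers' must be a 2 x n matrix")
  if (any(centers < 0 | centers > 1)) stop("center entries must lie in [0,1]")
  n <- ncol(centers)
  if (length(coverage) != n) stop("'coverage' length must be ncol(centers)")
  h1 <- integer(n); h2 <- integer(n)
  dev1 <- abs(centers[1, ] - 0.5)
  dev2 <- abs(centers[2, ] - 0.5)
  for (k in seq_len(n)) {
    if (dev1[k] > dev2[k]) {
      h1[k] <- as.integer(centers[1, k] > 0.5); h2[k] <- 1L - h1[k]
    } else if (dev2[k] > dev1[k]) {
      h2[k] <- as.integer(centers[2, k] > 0.5); h1[k] <- 1L - h2[k]
    } else if (dev1[k] == 0) {        # both centers exactly neutral
      h1[k] <- 0L; h2[k] <- 1L
    } else {
      v1 <- as.integer(centers[1, k] > 0.5)
      v2 <- as.integer(centers[2, k] > 0.5)
      if (v1 != v2) { h1[k] <- v1; h2[k] <- v2 }
      else { h1[k] <- v1; h2[k] <- 1L - v1 }  # equal pull: cluster 1 wins
    }
  }
  h1[!coverage] <- NA_integer_
  h2[!coverage] <- NA_integer_
  haplotype_pair(h1, h2)
}

#' Reconstruct haplotypes from a fragment matrix
#'
#' Fits the two-phase clustering model to a SNP fragment matrix.  In mode
#' `"ncmhap"` (the full method) a greedy bipartition of the fuzzy conflict
#' graph provides starting centers for the NCM refinement; `"ncm_random"`
#' skips phase 1 and starts NCM from random centers; `"initial_only"`
#' rounds the phase-1 centers directly.
#'
#' @param x an [snp_matrix()], or a character vector of fragment strings.
#' @param params an [ncm_params()].
#' @param mode one of `"ncmhap"`, `"ncm_random"`, `"initial_only"`.
#' @param seed optional integer seed (used for the random initialization
#'   in mode `"ncm_random"`; the other modes are deterministic).
#' @param truth optional true [haplotype_pair()]; when supplied the
#'   reconstruction rate is stored in the fit.
#' @return An object of class `ncmhap`: list with `haplotypes`
#'   ([haplotype_pair()]), `assignment` (fragment to haplotype, argmax of
#'   T, ties to 1), `ncm_state` (`NULL` in mode `"initial_only"`),
#'   `initial` (the phase-1 [initial_bipartition()]; `NULL` in mode
#'   `"ncm_random"`), `mec`, `rr` (`NULL` without truth), plus bookkeeping
#'   fields.  Methods: `print`, `summary`, `coef` (final centers),
#'   `fitted`/`haplotypes` (the haplotype pair), `residuals` (per-fragment
#'   mismatch counts against the assigned haplotype), `plot` (objective
#'   and cost traces).
#'
#' @examples
#' x <- as_snp_matrix(c("0101", "0101", "1010", "1010"))
#' fit <- ncmhap(x)
#' haplotypes(fit)
#' @export
ncmhap <- function(x, params = ncm_params(),
                   mode = c("ncmhap", "ncm_random", "initial_only"),
                   seed = NULL, truth = NULL) {
  if (is.character(x)) x <- as_snp_matrix(x)
  stopifnot(inherits(x, "snp_matrix"), inherits(params, "ncm_params"))
  mode <- match.arg(mode)
  coverage <- colSums(x$observed) > 0L
  initial <- NULL
  state <- NULL
  if (mode %in% c("ncmhap", "initial_only"))
    initial <- initial_bipartition(x)
  if (mode == "ncmhap")
    state <- ncm_cluster(x, init_centers = initial$centers, params = params)
  if (mode == "ncm_random")
    state <- ncm_cluster(x, init_centers = "random", params = params,
                         seed = seed)
  if (is.null(state)) {
    centers <- initial$centers
    assignment <- initial$assignment
  } else {
    centers <- state$centers
    assignment <- ifelse(state$T[, 2] > state$T[, 1], 2L, 1L)  # ties -> 1
    # a column that none of a cluster's own fragments observes carries no
    # information about that cluster: neutralize it (same 0.5 convention as
    # the phase-1 centers) so the covered cluster decides the column via
    # complementarity at rounding
    for (j in 1:2) {
      own <- assignment == j
      cov_j <- if (any(own)) colSums(x$observed[own, , drop = FALSE]) > 0L
               else rep(FALSE, x$n_sites)
      centers[j, !cov_j] <- 0.5
    }
  }
  haps <- round_centers_to_haplotypes(centers, coverage)
  rr <- if (is.null(truth)) NULL else reconstruction_rate(haps, truth)
  structure(
    list(haplotypes = haps, assignment = assignment, ncm_state = state,
         initial = initial, mec = mec_score(x, haps), rr = rr,
         mode = mode, params = params, seed = seed,
         n_fragments = x$n_fragments, n_sites = x$n_sites,
         x = x, call = match.call()),
    class = "ncmhap")
}

#' Extract the reconstructed haplotypes
#'
#' @param object a fitted object.
#' @param ... unused.
#' @return A [haplotype_pair()].
#' @export
haplotypes <- function(object, ...) UseMethod("haplotypes")

#' @export
haplotypes.ncmhap <- function(object, ...) object$haplotypes

#' @export
fitted.ncmhap <- function(object, ...) object$haplotypes

#' @export
coef.ncmhap <- function(object, ...) {
  if (is.null(object$ncm_state)) object$initial$centers
  else object$ncm_state$centers
}

#' @export
residuals.ncmhap <- function(object, ...) {
  x <- object$x
  O <- x$observed * 1
  AM <- x$alleles * O
  d1 <- .hd_rows_to_hap(AM, O, object$haplotypes$h1)
  d2 <- .hd_rows_to_hap(AM, O, object$haplotypes$h2)
  res <- ifelse(object$assignment == 1L, d1, d2)
  names(res) <- x$fragment_ids
  res
}

#' @export
print.ncmhap <- function(x, ...) {
  cat("Haplotype reconstruction (mode:", x$mode, ")\n")
  cat("  fragments:", x$n_fragments, " sites:", x$n_sites, "\n")
  cat("  MEC:", x$mec, "\n")
  if (!is.null(x$rr)) cat(sprintf("  reconstruction rate: %.4f\n", x$rr))
  if (!is.null(x$ncm_state))
    cat(sprintf("  NCM: %d iteration(s), %sconverged\n",
                x$ncm_state$n_iter,
                if (x$ncm_state$converged) "" else "NOT "))
  s <- as.character(x$haplotypes)
  w <- min(x$n_sites, 60L)
  cat("  h1:", substr(s[1], 1, w), if (x$n_sites > w) "..." else "", "\n")
  cat("  h2:", substr(s[2], 1, w), if (x$n_sites > w) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.ncmhap <- function(object, ...) {
  cl <- table(factor(object$assignment, levels = 1:2))
  out <- list(mode = object$mode, n_fragments = object$n_fragments,
              n_sites = object$n_sites, mec = object$mec, rr = object$rr,
              cluster_sizes = as.integer(cl),
              unphased = sum(is.na(object$haplotypes$h1)),
              residuals = residuals(object))
  if (!is.null(object$ncm_state)) {
    out$n_iter <- object$ncm_state$n_iter
    out$converged <- object$ncm_state$converged
    out$mean_indeterminacy <- mean(object$ncm_state$I)
    out$mean_falsity <- mean(object$ncm_state$F)
  }
  class(out) <- "summary.ncmhap"
  out
}

#' @export
print.summary.ncmhap <- function(x, ...) {
  cat("Haplotype reconstruction summary (mode:", x$mode, ")\n")
  cat("  fragments:", x$n_fragments, " sites:", x$n_sites,
      " unphased sites:", x$unphased, "\n")
  cat("  cluster sizes:", x$cluster_sizes[1], "/", x$cluster_sizes[2], "\n")
  cat("  MEC:", x$mec, "\n")
  if (!is.null(x$rr)) cat(sprintf("  reconstruction rate: %.4f\n", x$rr))
  if (!is.null(x$n_iter)) {
    cat(sprintf("  NCM iterations: %d (%sconverged)\n", x$n_iter,
                if (x$converged) "" else "NOT "))
    cat(sprintf("  mean indeterminacy: %.4f   mean falsity: %.4f\n",
                x$mean_indeterminacy, x$mean_falsity))
  }
  cat("  per-fragment residual mismatches: ",
      paste(utils::head(x$residuals, 10L), collapse = " "),
      if (length(x$residuals) > 10L) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
plot.ncmhap <- function(x, ...) {
  if (is.null(x$ncm_state))
    stop("mode \"initial_only\" has no clustering trace to plot")
  tr <- x$ncm_state$objective_trace
  plot(seq_along(tr), tr, type = "b", pch = 19, cex = 0.6,
       xlab = "iteration", ylab = "objective", main = "NCM convergence",
       ...)
  invisible(x)
}
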