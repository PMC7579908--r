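# Phase 2: neutrosophic c-means clustering of partially observed binary
# fragment vectors.  Each fragment carries a determinate membership T per
# cluster, an indeterminacy membership I (boundary points, judged against
# the midpoint of the two closest centers) and a falsity membership F
# (outliers, regularized by delta); T, I, F sum to one per fragment.

#' NCM hyperparameters
#'
#' @param m_fuzz fuzzification constant, > 1.  Default 2, the usual
#'   fuzzy-c-means choice.
#' @param epsilon convergence tolerance on the maximum absolute change of
#'   any center entry between successive iterations.  Default 1e-5.
#' @param delta outlier regularizer: the (unsquared) distance scale beyond
#'   which a fragment is better explained as an outlier than by any
#'   cluster.  Default 25.
#' @param w1,w2,w3 weights of the determinate, indeterminacy and falsity
#'   memberships.  Defaults 0.7, 0.2, 0.1; all must be positive (they need
#'   not sum to one).
#' @param max_iter iteration cap.  Default 100.
#' @param n_clusters number of determinate clusters; fixed at 2 for diploid
#'   phasing.
#' @return An object of class `ncm_params`.
#' @export
ncm_params <- function(m_fuzz = 2, epsilon = 1e-5, delta = 25,
                       w1 = 0.7, w2 = 0.2, w3 = 0.1,
                       max_iter = 100L, n_clusters = 2L) {
  stopifnot(m_fuzz > 1, epsilon > 0, delta > 0,
            w1 > 0, w2 > 0, w3 > 0, max_iter >= 1)
  if (n_clusters != 2L)
    stop("only two clusters are supported (diploid phasing)")
  structure(list(m_fuzz = m_fuzz, epsilon = epsilon, delta = delta,
                 w1 = w1, w2 = w2, w3 = w3,
                 max_iter = as.integer(max_iter), n_clusters = 2L),
            class = "ncm_params")
}

#' @export
print.ncm_params <- function(x, ...) {
  cat(sprintf(paste0("NCM parameters: m = %g, epsilon = %g, delta = %g, ",
                     "w = (%g, %g, %g), max_iter = %d\n"),
              x$m_fuzz, x$epsilon, x$delta, x$w1, x$w2, x$w3, x$max_iter))
  invisible(x)
}

#' Masked squared distance between a fragment and a center
#'
#' Mean of the squared coordinate differences over the fragment's observed
#' sites.  The mean (rather than the sum) makes fragments of different
#' coverage comparable and gives the outlier scale `delta` consistent
#' units.
#'
#' @param x a fragment row: string over `{0,1,-}` or integer vector with
#'   `NA` gaps.
#' @param center numeric vector in [0,1], fully defined, same length.
#' @return Non-negative numeric.
#' @examples
#' masked_distance2("1-0", c(0, 0.5, 0))  # (1 + 0) / 2
#' @export
masked_distance2 <- function(x, center) {
  r <- .as_allele_row(x)
  if (length(r$alleles) != length(center))
    stop("fragment and center must have equal length")
  if (!sum(r$observed)) stop("fragment has zero observed sites")
  mean((r$alleles[r$observed] - center[r$observed])^2)
}

# vectorized masked squared distances of all fragments to each center row;
# AM = alleles*observed, O = observed*1, ni = rowSums(O), cen = C x n
.masked_d2 <- function(AM, O, ni, cen) {
  d <- (rowSums(AM) - 2 * AM %*% t(cen) + O %*% t(cen * cen)) / ni
  pmax(d, 0)  # clip tiny negative round-off
}

#' Midpoint center governing a fragment's indeterminacy
#'
#' The indeterminacy membership of a point is judged against the mean of
#' the two centers with the largest determinate memberships for that
#' point.  With two clusters this is always the midpoint of the two
#' centers.
#'
#' @param T_row numeric vector of per-cluster determinate memberships of
#'   one point.
#' @param centers C x n numeric matrix of cluster centers.
#' @return Numeric vector of length n.
#' @export
indeterminacy_center <- function(T_row, centers) {
  C <- nrow(centers)
  if (length(T_row) != C) stop("'T_row' length must match nrow(centers)")
  if (C < 2L) stop("need at least two clusters")
  p <- which.max(T_row)
  q <- which.max(replace(T_row, p, -Inf))
  (centers[p, ] + centers[q, ]) / 2
}

# shared membership kernel: d = m x 2 squared distances, dbar = length-m
.memberships_from_d <- function(d, dbar, p) {
  ex <- -1 / (p$m_fuzz - 1)
  tt <- (1 / p$w1) * d^ex
  ii <- (1 / p$w2) * dbar^ex
  ff <- rep((1 / p$w3) * (p$delta^2)^ex, length(dbar))
  K <- 1 / (rowSums(tt) + ii + ff)
  Tm <- tt * K; Im <- ii * K; Fm <- ff * K
  # limit convention at exact coincidence: hard membership on the
  # zero-distance term(s)
  dmin <- do.call(pmin, as.data.frame(d))
  sing <- which(dmin == 0 | dbar == 0)
  for (i in sing) {
    Tm[i, ] <- 0; Im[i] <- 0; Fm[i] <- 0
    if (dmin[i] == 0) {
      z <- d[i, ] == 0
      Tm[i, z] <- 1 / sum(z)
    } else {
      Im[i] <- 1
    }
  }
  list(T = Tm, I = Im, F = Fm)
}

#' Update the T, I, F memberships given the centers
#'
#' Determinate memberships are proportional to
#' `(1/w1) * d_ij^(-1/(m-1))` with `d_ij` the masked squared distance to
#' center j; the indeterminacy term uses the distance to the midpoint
#' center ([indeterminacy_center()]) with weight `1/w2`; the falsity term
#' is `(1/w3) * (delta^2)^(-1/(m-1))`.  A per-point normalizer K makes
#' `sum_j T_ij + I_i + F_i = 1`.  A point at distance exactly 0 from a
#' center takes the hard-membership limit (T = 1 there, I = F = 0).
#'
#' @param x an [snp_matrix()].
#' @param centers 2 x n numeric matrix in [0,1].
#' @param params an [ncm_params()].
#' @return List with `T` (m x 2), `I` and `F` (length m).
#' @export
update_memberships <- function(x, centers, params = ncm_params()) {
  stopifnot(inherits(x, "snp_matrix"))
  if (!is.matrix(centers) || nrow(centers) != 2L ||
      ncol(centers) != x$n_sites)
    stop("'centers' must be a 2 x n_sites matrix")
  O <- x$observed * 1
  AM <- x$alleles * O
  ni <- rowSums(O)
  d <- .masked_d2(AM, O, ni, centers)
  cbar <- (centers[1, ] + centers[2, ]) / 2
  dbar <- .masked_d2(AM, O, ni, matrix(cbar, 1L))[, 1]
  .memberships_from_d(d, dbar, params)
}

#' Update the cluster centers given the determinate memberships
#'
#' Per-column weighted mean of the observed alleles with weights
#' `(w1 * T_ij)^m`, i.e. the masked form of the classical center update;
#' the constant `w1` cancels.  A column observed by no fragment with
#' positive weight keeps its previous value (`prev`, neutral 0.5 when not
#' supplied) and triggers a warning.
#'
#' @param x an [snp_matrix()].
#' @param T m x 2 matrix of determinate memberships.
#' @param params an [ncm_params()].
#' @param prev optional 2 x n matrix of previous centers used for dead
#'   columns.
#' @return 2 x n numeric matrix in [0,1].
#' @export
update_centers <- function(x, T, params = ncm_params(), prev = NULL) {
  stopifnot(inherits(x, "snp_matrix"))
  T <- as.matrix(T)
  if (nrow(T) != x$n_fragments || ncol(T) != 2L)
    stop("'T' must be an n_fragments x 2 matrix")
  O <- x$observed * 1
  AM <- x$alleles * O
  W <- (params$w1 * T)^params$m_fuzz
  centers <- if (is.null(prev)) matrix(0.5, 2L, x$n_sites) else prev
  dead <- FALSE
  for (j in 1:2) {
    den <- colSums(W[, j] * O)
    num <- colSums(W[, j] * AM)
    has <- den > 0
    centers[j, has] <- num[has] / den[has]
    dead <- dead || any(!has)
  }
  if (dead)
    warning("column(s) with zero membership weight kept their previous ",
            "center value")
  pmin(pmax(centers, 0), 1)
}

# masked T-only weighted-mean center step (the exported update_centers
# without the dead-column warning, for use inside the iteration loop)
.update_centers_masked <- function(AM, O, Tm, prev, p) {
  W <- (p$w1 * Tm)^p$m_fuzz
  centers <- prev
  for (j in 1:2) {
    den <- colSums(W[, j] * O)
    num <- colSums(W[, j] * AM)
    has <- den > 0
    centers[j, has] <- num[has] / den[has]
  }
  pmin(pmax(centers, 0), 1)
}

#' NCM objective
#'
#' The clustering objective
#' `sum_ij (w1 T_ij)^m d_ij + sum_i (w2 I_i)^m dbar_i +
#'  sum_i delta^2 (w3 F_i)^m`,
#' with all squared distances realized as masked means
#' ([masked_distance2()]) and `dbar_i` the distance to the midpoint
#' center.
#'
#' @details The alternating membership/center updates form a fixed-point
#' iteration, not an exact coordinate descent of this objective: the
#' determinate-only center step deliberately ignores the indeterminacy
#' term (that is what lets I and F absorb membership mass from noisy
#' fragments and down-weight them), so the recorded `objective_trace`
#' typically decreases but is not guaranteed monotone.  Convergence is
#' judged on the centers, not on the objective.
#'
#' @inheritParams update_memberships
#' @param T,I,F memberships as returned by [update_memberships()].
#' @return Non-negative numeric.
#' @export
ncm_objective <- function(x, T, I, F, centers, params = ncm_params()) {
  stopifnot(inherits(x, "snp_matrix"))
  O <- x$observed * 1
  AM <- x$alleles * O
  ni <- rowSums(O)
  d <- .masked_d2(AM, O, ni, centers)
  cbar <- (centers[1, ] + centers[2, ]) / 2
  dbar <- .masked_d2(AM, O, ni, matrix(cbar, 1L))[, 1]
  mf <- params$m_fuzz
  sum((params$w1 * T)^mf * d) + sum((params$w2 * I)^mf * dbar) +
    sum(params$delta^2 * (params$w3 * F)^mf)
}

#' Run the NCM clustering loop
#'
#' Alternates [update_memberships()] with the masked determinate-only
#' center step until the maximum absolute center change drops to `epsilon`
#' or `max_iter` is reached.
#'
#' @param x an [snp_matrix()].
#' @param init_centers 2 x n numeric matrix of starting centers, or
#'   `"random"` for uniform draws in [0,1] (seeded by `seed`).
#' @param params an [ncm_params()].
#' @param seed optional integer seed used when `init_centers = "random"`.
#' @return An object of class `ncm_state`: `T`, `I`, `F`, `centers`,
#'   `objective_trace` (objective value per iteration, evaluated at the
#'   freshly updated memberships and the centers they were computed
#'   from), `n_iter`, `converged`.
#' @export
ncm_cluster <- function(x, init_centers = "random", params = ncm_params(),
                        seed = NULL) {
  stopifnot(inherits(x, "snp_matrix"))
  n <- x$n_sites
  if (is.character(init_centers) && identical(init_centers, "random")) {
    if (!is.null(seed)) set.seed(seed)
    centers <- matrix(runif(2L * n), 2L, n)
  } else {
    centers <- as.matrix(init_centers)
    if (nrow(centers) != 2L || ncol(centers) != n)
      stop("'init_centers' must be a 2 x n_sites matrix or \"random\"")
    if (any(centers < 0 | centers > 1))
      stop("'init_centers' entries must lie in [0,1]")
  }
  O <- x$observed * 1
  AM <- x$alleles * O
  ni <- rowSums(O)
  objective_trace <- numeric(0)
  mem <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iter) {
    iter <- iter + 1L
    d <- .masked_d2(AM, O, ni, centers)
    cbar <- (centers[1, ] + centers[2, ]) / 2
    dbar <- .masked_d2(AM, O, ni, matrix(cbar, 1L))[, 1]
    mem <- .memberships_from_d(d, dbar, params)
    objective_trace <- c(objective_trace,
                         sum((params$w1 * mem$T)^params$m_fuzz * d) +
                           sum((params$w2 * mem$I)^params$m_fuzz * dbar) +
                           sum(params$delta^2 *
                                 (params$w3 * mem$F)^params$m_fuzz))
    new_centers <- .update_centers_masked(AM, O, mem$T, centers, params)
    delta <- max(abs(new_centers - centers))
    centers <- new_centers
    if (delta <= params$epsilon) { converged <- TRUE; break }
  }
  structure(list(T = mem$T, I = mem$I, F = mem$F, centers = centers,
                 objective_trace = objective_trace,
                 n_iter = iter, converged = converged),
            class = "ncm_state")
}
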