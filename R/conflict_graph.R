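# Phase 1: weighted fuzzy conflict graph and greedy bipartition.

# edges with |weight - 0.5| <= this are uninformative and dropped
.HALF_EDGE_TOL <- 1e-9

#' Build the weighted fuzzy conflict graph
#'
#' Nodes are fragments; every pair with at least one jointly observed site
#' gets an edge weighted by its normalized Hamming distance ([nhd()]).
#' Edges with weight 0.5 (within 1e-9) carry no information about whether
#' the two fragments share a chromosome copy and are removed.
#'
#' @param x an [snp_matrix()].
#' @return An object of class `conflict_graph`: list with `n_nodes` and
#'   `edges`, a data.frame `(i, j, weight)` with `i < j` (1-based, ordered
#'   lexicographically).
#' @examples
#' g <- build_conflict_graph(as_snp_matrix(c("01", "01", "10")))
#' g$edges
#' @export
build_conflict_graph <- function(x) {
  stopifnot(inherits(x, "snp_matrix"))
  O <- x$observed * 1
  AM <- x$alleles * O                      # masked alleles
  S <- tcrossprod(O)                       # joint-overlap counts
  D <- tcrossprod(AM, O - AM) ; D <- D + t(D)  # masked mismatch counts
  ut <- which(upper.tri(S), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  s <- S[ut]; d <- D[ut]
  keep <- s >= 1
  w <- ifelse(keep, d / pmax(s, 1), NA_real_)
  keep <- keep & abs(w - 0.5) > .HALF_EDGE_TOL
  structure(
    list(n_nodes = x$n_fragments,
         edges = data.frame(i = ut[keep, 1], j = ut[keep, 2],
                            weight = w[keep])),
    class = "conflict_graph")
}

#' @export
print.conflict_graph <- function(x, ...) {
  cat("fuzzy conflict graph:", x$n_nodes, "fragments,", nrow(x$edges),
      "informative edges\n")
  invisible(x)
}

# rounded per-column majority consensus of a set of fragment rows;
# NA where the cluster covers no site; ties go to 0
.consensus <- function(ones, covered) {
  out <- rep(NA_integer_, length(covered))
  has <- covered > 0L
  out[has] <- as.integer(2L * ones[has] > covered[has])
  out
}

# NHD of every row of (AM, O) against an integer consensus with NA gaps;
# returns list(w = NHD or NA, s = overlap sizes)
.nhd_to_consensus <- function(AM, O, cons) {
  cm <- !is.na(cons)
  cv <- ifelse(cm, cons, 0L)
  s <- as.vector(O %*% cm)
  d <- as.vector(AM %*% (cm * (1 - cv)) + (O - AM) %*% (cm * cv))
  list(w = ifelse(s > 0, d / pmax(s, 1), NA_real_), s = s)
}

#' Greedy bipartition of the conflict graph
#'
#' Seeds the two clusters with the endpoints of a maximum-weight edge
#' (ties broken by lexicographically smallest `(i, j)`), then repeatedly
#' finds, for each cluster in turn, the unassigned fragment with the
#' highest NHD to that cluster's rounded majority consensus and assigns it
#' to the *opposite* cluster, recomputing the consensus after every
#' assignment.  Fragments whose NHD to both consensuses is undefined are
#' deferred and finally placed in the cluster with the lower defined NHD
#' (cluster 1 when neither is defined).
#'
#' @param x an [snp_matrix()] with at least two fragments.
#' @param g the [build_conflict_graph()] of `x`; computed when missing.
#' @return An object of class `bipartition`: list with `assignment`
#'   (integer vector over {1,2}), `centers` (2 x n matrix of per-cluster
#'   column means of observed alleles; 0.5 where a cluster covers no site)
#'   and `mec` (MEC score of the rounded centers).
#' @export
initial_bipartition <- function(x, g = build_conflict_graph(x)) {
  stopifnot(inherits(x, "snp_matrix"))
  m <- x$n_fragments; n <- x$n_sites
  if (m < 2L) stop("bipartition needs at least two fragments")
  O <- x$observed * 1
  AM <- x$alleles * O
  assignment <- integer(m)          # 0 = unassigned

  # per-cluster running counts for the rounded consensus
  ones <- matrix(0L, 2L, n); covered <- matrix(0L, 2L, n)
  place <- function(i, cl) {
    assignment[i] <<- cl
    ones[cl, ] <<- ones[cl, ] + AM[i, ]
    covered[cl, ] <<- covered[cl, ] + O[i, ]
  }

  if (nrow(g$edges) == 0L) {
    warning("conflict graph has no informative edges; ",
            "all fragments assigned to one cluster")
    assignment[] <- 1L
    for (i in seq_len(m)) {
      ones[1L, ] <- ones[1L, ] + AM[i, ]
      covered[1L, ] <- covered[1L, ] + O[i, ]
    }
  } else {
    top <- which.max(g$edges$weight)  # first max = lexicographic tie-break
    place(g$edges$i[top], 1L)
    place(g$edges$j[top], 2L)
    src <- 1L
    while (any(assignment == 0L)) {
      un <- which(assignment == 0L)
      moved <- FALSE
      for (try in 1:2) {
        cons <- .consensus(ones[src, ], covered[src, ])
        w <- .nhd_to_consensus(AM[un, , drop = FALSE],
                               O[un, , drop = FALSE], cons)$w
        if (any(!is.na(w))) {
          pick <- un[which.max(w)]   # which.max skips NA; first = smallest i
          # place the picked node opposite the cluster it conflicts with:
          # the closer consensus wins (ties go opposite, per the greedy
          # narrative); without overlap evidence on the other side the
          # node joins the source cluster only if it agrees with it
          # (NHD below the uninformative value 0.5)
          d_src <- w[match(pick, un)]
          d_opp <- .nhd_to_consensus(AM[pick, , drop = FALSE],
                                     O[pick, , drop = FALSE],
                                     .consensus(ones[3L - src, ],
                                                covered[3L - src, ]))$w
          dst <- if (is.na(d_opp)) {
            if (d_src < 0.5) src else 3L - src
          } else if (d_src < d_opp) src else 3L - src
          place(pick, dst)
          src <- 3L - src
          moved <- TRUE
          break
        }
        src <- 3L - src              # other cluster may still see them
      }
      if (!moved) break              # nobody overlaps either cluster yet
    }
    # deferred pass: no overlap with either consensus during the main loop
    for (i in which(assignment == 0L)) {
      w1 <- .nhd_to_consensus(AM[i, , drop = FALSE], O[i, , drop = FALSE],
                              .consensus(ones[1L, ], covered[1L, ]))$w
      w2 <- .nhd_to_consensus(AM[i, , drop = FALSE], O[i, , drop = FALSE],
                              .consensus(ones[2L, ], covered[2L, ]))$w
      cl <- if (is.na(w1) && is.na(w2)) 1L
            else if (is.na(w2)) 1L
            else if (is.na(w1)) 2L
            else if (w2 < w1) 2L else 1L
      place(i, cl)
    }
  }

  centers <- matrix(0.5, 2L, n)
  for (cl in 1:2) {
    has <- covered[cl, ] > 0L
    centers[cl, has] <- ones[cl, has] / covered[cl, has]
  }
  haps <- round_centers_to_haplotypes(centers, colSums(x$observed) > 0L)
  structure(list(assignment = assignment, centers = centers,
                 mec = mec_score(x, haps)),
            class = "bipartition")
}
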