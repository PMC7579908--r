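# Benchmark instance generator: a random heterozygous haplotype pair,
# contiguous fragments drawn from either copy at a target coverage, and
# independent per-allele flip errors.

#' Simulation configuration
#'
#' @param l haplotype length in SNP sites (>= 2).  Benchmark grids use
#'   100, 350 and 700.
#' @param c target mean coverage: average number of fragments observing a
#'   column.  Benchmark grids use 3, 5, 8, 10.
#' @param e per-observed-allele flip probability in [0, 0.5).  Benchmark
#'   grids use 0.1, 0.2, 0.3.
#' @param frag_len_min,frag_len_max bounds of the uniform contiguous
#'   fragment-length law.  Default `ceiling(0.03 * l)` to
#'   `ceiling(0.07 * l)` (3--7 sites at `l = 100`), short shotgun-like
#'   fragments that reach the target coverage with realistic per-fragment
#'   SNP counts.
#' @param internal_gap_rate probability that a covered position inside a
#'   fragment is masked to a gap.  Default 0.
#' @param seed optional integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(l, c, e, frag_len_min = NULL, frag_len_max = NULL,
                       internal_gap_rate = 0, seed = NULL) {
  l <- as.integer(l)
  if (is.na(l) || l < 2L) stop("'l' must be an integer >= 2")
  if (c <= 0) stop("'c' must be positive")
  if (e < 0 || e >= 0.5) stop("'e' must lie in [0, 0.5)")
  # round before ceiling: 0.07 * 100 is 7 + 1e-15 in floating point
  if (is.null(frag_len_min))
    frag_len_min <- max(2L, ceiling(round(0.03 * l, 9)))
  if (is.null(frag_len_max)) frag_len_max <- ceiling(round(0.07 * l, 9))
  frag_len_min <- as.integer(frag_len_min)
  frag_len_max <- as.integer(frag_len_max)
  if (frag_len_min < 2L || frag_len_min > frag_len_max || frag_len_max > l)
    stop("need 2 <= frag_len_min <= frag_len_max <= l")
  if (internal_gap_rate < 0 || internal_gap_rate >= 1)
    stop("'internal_gap_rate' must lie in [0, 1)")
  structure(list(l = l, c = c, e = e,
                 frag_len_min = frag_len_min, frag_len_max = frag_len_max,
                 internal_gap_rate = internal_gap_rate, seed = seed),
            class = "sim_config")
}

#' Generate one benchmark instance
#'
#' Draws `h1` iid Bernoulli(0.5) over `l` sites with `h2` its complement
#' (every site heterozygous); generates `round(c * l / mean_frag_len)`
#' contiguous fragments, each copied from a uniformly chosen chromosome
#' copy at a uniform start, with covered positions masked at
#' `internal_gap_rate` and surviving alleles flipped independently with
#' probability `e`.  Fragments left with no observed site are redrawn.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `sim_instance`: `matrix` ([snp_matrix()]),
#'   `truth` ([haplotype_pair()]), `origin` (true chromosome copy per
#'   fragment), `flips` (injected error count per fragment), `config`.
#' @export
simulate_instance <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  l <- cfg$l
  h1 <- rbinom(l, 1L, 0.5)
  h2 <- 1L - h1
  haps <- rbind(h1, h2)
  mean_len <- (cfg$frag_len_min + cfg$frag_len_max) / 2
  m <- max(2L, as.integer(round(cfg$c * l / mean_len)))
  alleles <- matrix(0L, m, l)
  observed <- matrix(FALSE, m, l)
  origin <- integer(m)
  flips <- integer(m)
  draw_len <- function() {
    if (cfg$frag_len_min == cfg$frag_len_max) cfg$frag_len_min
    else cfg$frag_len_min +
      floor(runif(1) * (cfg$frag_len_max - cfg$frag_len_min + 1L))
  }
  for (i in seq_len(m)) {
    repeat {
      org <- 1L + rbinom(1L, 1L, 0.5)
      len <- draw_len()
      start <- 1L + floor(runif(1) * (l - len + 1L))
      idx <- start:(start + len - 1L)
      obs <- rep(TRUE, len)
      if (cfg$internal_gap_rate > 0)
        obs <- runif(len) >= cfg$internal_gap_rate
      if (!any(obs)) next
      al <- haps[org, idx]
      flip <- obs & (runif(len) < cfg$e)
      al[flip] <- 1L - al[flip]
      alleles[i, ] <- 0L
      observed[i, ] <- FALSE
      alleles[i, idx[obs]] <- al[obs]
      observed[i, idx[obs]] <- TRUE
      origin[i] <- org
      flips[i] <- sum(flip)
      break
    }
  }
  structure(list(matrix = snp_matrix(alleles, observed),
                 truth = haplotype_pair(h1, h2),
                 origin = origin, flips = flips, config = cfg),
            class = "sim_instance")
}

#' @export
print.sim_instance <- function(x, ...) {
  cat(sprintf(paste0("simulated instance: l = %d, c = %g, e = %g  ",
                     "(%d fragments, %d injected flips)\n"),
              x$config$l, x$config$c, x$config$e,
              x$matrix$n_fragments, sum(x$flips)))
  invisible(x)
}

#' Write an instance to disk
#'
#' Writes the fragment matrix in the plain one-line-per-fragment format
#' (`<prefix>.frags`) and the true haplotypes as a two-line file
#' (`<prefix>.truth`).
#'
#' @param instance a [simulate_instance()] result.
#' @param prefix output path prefix.
#' @return Invisibly, the two paths written.
#' @export
write_instance <- function(instance, prefix) {
  stopifnot(inherits(instance, "sim_instance"))
  x <- instance$matrix
  lines <- vapply(seq_len(x$n_fragments), function(i)
    paste(x$fragment_ids[i],
          .row_to_string(x$alleles[i, ], x$observed[i, ])),
    character(1))
  fr <- paste0(prefix, ".frags")
  tr <- paste0(prefix, ".truth")
  writeLines(lines, fr)
  write_haplotypes(instance$truth, tr)
  invisible(c(fragments = fr, truth = tr))
}

#' Run a simulation benchmark over a parameter grid
#'
#' For every configuration, generates `n_instances` instances (with
#' per-instance seeds derived deterministically from `base_seed`) and runs
#' [ncmhap()] in each requested mode, collecting reconstruction rate and
#' MEC.
#'
#' @param configs a list of [sim_config()] objects (or a single one).
#' @param n_instances instances per configuration.
#' @param base_seed integer seed from which all per-instance seeds derive.
#' @param modes subset of `c("initial_only", "ncm_random", "ncmhap")`.
#' @param params an [ncm_params()].
#' @return List with `results` (one row per instance x mode:
#'   `l, c, e, instance, mode, rr, mec`) and `summary` (one row per
#'   configuration x mode: `l, c, e, mode, n, mean_rr, sd_rr, mean_mec`).
#' @export
simulate_batch <- function(configs, n_instances, base_seed = 1L,
                           modes = c("initial_only", "ncm_random", "ncmhap"),
                           params = ncm_params()) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  stopifnot(all(vapply(configs, inherits, logical(1), "sim_config")),
            n_instances >= 1L)
  modes <- match.arg(modes, several.ok = TRUE)
  set.seed(base_seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                             2L * length(configs) * n_instances),
                  ncol = 2L)
  rows <- vector("list", length(configs) * n_instances * length(modes))
  k <- 0L; sidx <- 0L
  for (cfg in configs) {
    for (inst in seq_len(n_instances)) {
      sidx <- sidx + 1L
      cfg_i <- cfg
      cfg_i$seed <- seeds[sidx, 1]
      instance <- simulate_instance(cfg_i)
      for (mode in modes) {
        fit <- suppressWarnings(
          ncmhap(instance$matrix, params = params, mode = mode,
                 seed = seeds[sidx, 2], truth = instance$truth))
        k <- k + 1L
        rows[[k]] <- data.frame(l = cfg$l, c = cfg$c, e = cfg$e,
                                instance = inst, mode = mode,
                                rr = fit$rr, mec = fit$mec)
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(rr, mec) ~ l + c + e + mode, data = results,
                          FUN = mean)
  sdv <- stats::aggregate(rr ~ l + c + e + mode, data = results,
                          FUN = stats::sd)
  summary <- data.frame(l = agg$l, c = agg$c, e = agg$e, mode = agg$mode,
                        n = n_instances, mean_rr = agg$rr, sd_rr = sdv$rr,
                        mean_mec = agg$mec)
  summary <- summary[order(summary$l, summary$e, summary$c, summary$mode), ]
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}
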