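test_that("masked squared distance averages over observed sites only", {
  expect_equal(masked_distance2("11", c(1, 1)), 0)
  expect_equal(masked_distance2("1-0", c(0, 0.5, 0)), 0.5)
  expect_equal(masked_distance2("0", 1), 1)
  expect_error(masked_distance2("-", 0.5), "zero observed")
  expect_error(masked_distance2("01", c(0, 1, 0)), "equal length")
})

test_that("indeterminacy center is the midpoint of the two strongest clusters", {
  cen <- rbind(c(0, 0), c(1, 1))
  expect_equal(indeterminacy_center(c(0.9, 0.1), cen), c(0.5, 0.5))
  expect_equal(indeterminacy_center(c(0.1, 0.9), cen), c(0.5, 0.5))
  cen3 <- rbind(c(0, 0), c(1, 1), c(1, 0))
  expect_equal(indeterminacy_center(c(0.5, 0.3, 0.2), cen3), c(0.5, 0.5))
  expect_equal(indeterminacy_center(c(0.1, 0.3, 0.6), cen3), c(1, 0.5))
})

test_that("membership updates match a brute-force scalar evaluation", {
  set.seed(301)
  p <- ncm_params()
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    x <- as_snp_matrix(rand_frags(5, n))
    centers <- matrix(runif(2 * n), 2, n)
    got <- update_memberships(x, centers, p)
    want <- ora_memberships(x, centers, p)
    expect_equal(got$T, want$T, tolerance = 1e-10)
    expect_equal(got$I, want$I, tolerance = 1e-10)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    # partition-of-unity normalization
    expect_true(all(abs(rowSums(got$T) + got$I + got$F - 1) < 1e-12))
    expect_true(all(got$T >= 0) && all(got$I >= 0) && all(got$F >= 0))
  }
})

test_that("zero distance takes the hard-membership limit", {
  x <- as_snp_matrix(c("0101", "1010"))
  centers <- rbind(c(0, 1, 0, 1), c(0.3, 0.6, 0.4, 0.7))
  mem <- update_memberships(x, centers)
  expect_equal(mem$T[1, ], c(1, 0))
  expect_equal(mem$I[1], 0)
  expect_equal(mem$F[1], 0)
})

test_that("equidistant points split their determinate membership equally", {
  x <- as_snp_matrix("0000")
  centers <- rbind(c(0.2, 0.2, 0.2, 0.2), c(0.2, 0.2, 0.2, 0.2))
  mem <- update_memberships(x, centers)
  expect_equal(mem$T[1, 1], mem$T[1, 2])
})

test_that("center update is the masked determinate-weighted column mean", {
  p <- ncm_params()
  x <- as_snp_matrix(c("00", "00"))
  cen <- suppressWarnings(update_centers(x, matrix(c(1, 1, 0, 0), 2, 2), p))
  expect_equal(cen[1, ], c(0, 0))

  # disjoint coverage: each column comes from its sole observer (the
  # empty second cluster keeps neutral centers, with a warning)
  x2 <- as_snp_matrix(c("0-", "-1"))
  cen2 <- suppressWarnings(update_centers(x2, matrix(c(1, 1, 0, 0), 2, 2), p))
  expect_equal(cen2[1, ], c(0, 1))

  # w1 (and any column-wise scaling of T) cancels from the ratio
  set.seed(302)
  x3 <- as_snp_matrix(rand_frags(6, 5, gap_rate = 0))
  Tm <- matrix(runif(12, 0.05, 1), 6, 2)
  expect_equal(update_centers(x3, Tm, p),
               update_centers(x3, Tm * 0.37, p))

  # a column with zero weight keeps the supplied previous value
  prev <- matrix(0.25, 2, 2)
  expect_warning(
    cen4 <- update_centers(x2, matrix(c(1, 0, 0, 0), 2, 2), p, prev = prev),
    "previous")
  expect_equal(cen4[1, ], c(0, 0.25))
  expect_equal(cen4[2, ], c(0.25, 0.25))
})

test_that("objective matches a term-by-term scalar evaluation", {
  p <- ncm_params()
  # perfect fit: hard memberships on coincident centers
  x <- as_snp_matrix(c("01", "10"))
  Tm <- rbind(c(1, 0), c(0, 1))
  centers <- rbind(c(0, 1), c(1, 0))
  expect_equal(ncm_objective(x, Tm, c(0, 0), c(0, 0), centers, p), 0)

  # a single pure outlier contributes delta^2 * (w3 * 1)^m
  x1 <- as_snp_matrix("01")
  expect_equal(ncm_objective(x1, matrix(0, 1, 2), 0, 1, centers, p),
               p$delta^2 * p$w3^p$m_fuzz)

  set.seed(303)
  for (rep in 1:10) {
    n <- sample(3:8, 1); m <- sample(2:6, 1)
    x <- as_snp_matrix(rand_frags(m, n))
    centers <- matrix(runif(2 * n), 2, n)
    mem <- update_memberships(x, centers, p)
    expect_equal(ncm_objective(x, mem$T, mem$I, mem$F, centers, p),
                 ora_objective(x, mem$T, mem$I, mem$F, centers, p),
                 tolerance = 1e-12)
  }
})

test_that("the clustering loop converges on separable data", {
  x <- as_snp_matrix(rep(c("0101", "1010"), each = 3))
  truth <- rbind(c(0, 1, 0, 1), c(1, 0, 1, 0))
  st <- ncm_cluster(x, init_centers = truth)
  expect_true(st$converged)
  expect_lte(st$n_iter, 2L)
  expect_true(max(abs(st$centers - truth)) < 1e-3)
  expect_equal(ifelse(st$T[, 2] > st$T[, 1], 2L, 1L), rep(c(1L, 2L), each = 3))
})

test_that("an infinite tolerance stops after exactly one iteration", {
  x <- as_snp_matrix(rep(c("0101", "1010"), each = 2))
  st <- ncm_cluster(x, "random", ncm_params(epsilon = Inf), seed = 4)
  expect_equal(st$n_iter, 1L)
  expect_true(st$converged)
  expect_length(st$objective_trace, 1L)
})

test_that("identical input and seed give bit-identical clustering state", {
  x <- as_snp_matrix(rand_frags(10, 8))
  s1 <- ncm_cluster(x, "random", seed = 99)
  s2 <- ncm_cluster(x, "random", seed = 99)
  expect_identical(s1, s2)
})

test_that("memberships stay normalized along the whole trajectory", {
  set.seed(304)
  for (rep in 1:5) {
    x <- as_snp_matrix(rand_frags(sample(5:15, 1), sample(5:12, 1)))
    st <- ncm_cluster(x, "random", seed = rep)
    expect_true(all(abs(rowSums(st$T) + st$I + st$F - 1) < 1e-12))
  }
})

test_that("a fragment disagreeing with both haplotypes is flagged indeterminate", {
  set.seed(305)
  flagged <- 0L
  for (rep in 1:10) {
    inst <- simulate_instance(sim_config(40, 8, 0, seed = 500 + rep))
    x <- inst$matrix
    # craft an outlier spanning a window, agreeing ~50% with each haplotype
    n <- x$n_sites
    idx <- 5:24
    al <- integer(n); obs <- rep(FALSE, n)
    obs[idx] <- TRUE
    al[idx] <- ifelse(seq_along(idx) %% 2 == 0, inst$truth$h1[idx],
                      inst$truth$h2[idx])
    x2 <- snp_matrix(rbind(x$alleles, al), rbind(x$observed, obs))
    st <- ncm_cluster(x2, rbind(inst$truth$h1, inst$truth$h2) * 1.0)
    m <- x2$n_fragments
    noise_if <- st$I[m] + st$F[m]
    clean_if <- median(st$I[-m] + st$F[-m])
    if (noise_if > clean_if) flagged <- flagged + 1L
  }
  expect_gte(flagged, 8L)
})

test_that("with vanishing indeterminacy weights the clustering degenerates to FCM", {
  x <- as_snp_matrix(rep(c("00110", "11001"), each = 4))
  p <- ncm_params(w2 = 1e-6, w3 = 1e-6)
  st <- ncm_cluster(x, "random", p, seed = 8)
  cl <- ifelse(st$T[, 2] > st$T[, 1], 2L, 1L)
  expect_true(all(cl == rep(c(1L, 2L), each = 4)) ||
                all(cl == rep(c(2L, 1L), each = 4)))
  expect_true(all(st$I + st$F < 1e-3))
})
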