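test_that("conflict graph edges carry NHD weights over joint overlaps", {
  g <- build_conflict_graph(as_snp_matrix(c("01", "01", "10")))
  expect_equal(g$n_nodes, 3L)
  expect_equal(g$edges$i, c(1L, 1L, 2L))
  expect_equal(g$edges$j, c(2L, 3L, 3L))
  expect_equal(g$edges$weight, c(0, 1, 1))

  g2 <- build_conflict_graph(as_snp_matrix(c("10", "01", "-1")))
  # (1,3): single joint site, mismatch -> 1; (2,3): agreement -> 0
  w13 <- g2$edges$weight[g2$edges$i == 1 & g2$edges$j == 3]
  w23 <- g2$edges$weight[g2$edges$i == 2 & g2$edges$j == 3]
  expect_equal(w13, 1)
  expect_equal(w23, 0)
})

test_that("uninformative half-weight edges are removed", {
  # HD = 1 over S = 2 -> weight exactly 0.5 -> no edge
  g <- build_conflict_graph(as_snp_matrix(c("00", "01")))
  expect_equal(nrow(g$edges), 0L)
  # and a no-overlap pair contributes no edge either
  g2 <- build_conflict_graph(as_snp_matrix(c("0-", "-1")))
  expect_equal(nrow(g2$edges), 0L)
})

test_that("edge count equals all pairs minus no-overlap and half-weight pairs", {
  set.seed(77)
  for (rep in 1:15) {
    m <- sample(3:10, 1); n <- sample(3:10, 1)
    strings <- rand_frags(m, n)
    g <- build_conflict_graph(as_snp_matrix(strings))
    n_half <- 0L; n_noov <- 0L
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      w <- ora_nhd(strings[i], strings[j])
      if (is.na(w)) n_noov <- n_noov + 1L
      else if (abs(w - 0.5) <= 1e-9) n_half <- n_half + 1L
    }
    expect_equal(nrow(g$edges), choose(m, 2) - n_noov - n_half)
  }
})

test_that("greedy bipartition recovers the unique zero-MEC split", {
  x <- as_snp_matrix(c("0101", "0101", "1010", "1010"))
  bp <- initial_bipartition(x)
  # brute-force oracle: enumerate all 2^4 assignments; every assignment
  # whose per-cluster consensus reaches MEC 0 yields the same haplotype
  # pair {0101, 1010}
  n_zero <- 0L
  for (mask in 1:14) {
    asg <- 1L + as.integer(intToBits(mask)[1:4])
    cons <- sapply(1:2, function(cl) {
      rows <- which(asg == cl)
      v <- round(colMeans(x$alleles[rows, , drop = FALSE]))
      paste(v, collapse = "")
    })
    h <- haplotype_pair(cons[1], cons[2])
    if (mec_score(x, h) == 0L) {
      n_zero <- n_zero + 1L
      expect_setequal(as.character(h), c("0101", "1010"))
    }
  }
  expect_gte(n_zero, 2L)  # at least the two labelings of the true split
  expect_true(all(bp$assignment == c(1, 1, 2, 2)) ||
                all(bp$assignment == c(2, 2, 1, 1)))
  expect_equal(bp$mec, 0L)
  h <- round_centers_to_haplotypes(bp$centers)
  expect_setequal(as.character(h), c("0101", "1010"))
})

test_that("seed edge endpoints land in different clusters", {
  bp <- initial_bipartition(as_snp_matrix(c("01", "10")))
  expect_equal(sort(bp$assignment), c(1L, 2L))
})

test_that("bipartition is deterministic and validates its input", {
  set.seed(5)
  strings <- rand_frags(12, 8)
  x <- as_snp_matrix(strings)
  b1 <- initial_bipartition(x)
  b2 <- initial_bipartition(x)
  expect_identical(b1, b2)
  expect_error(initial_bipartition(as_snp_matrix("0101")), "at least two")
})

test_that("an edgeless graph falls back to one cluster with a warning", {
  x <- as_snp_matrix(c("00", "01"))  # single pair at weight 0.5
  expect_warning(bp <- initial_bipartition(x), "no informative edges")
  expect_equal(bp$assignment, c(1L, 1L))
})

test_that("noise-free connected instances split exactly by chromosome", {
  checked <- 0L
  for (s in 1:12) {
    inst <- simulate_instance(sim_config(60, 8, 0, seed = 900 + s))
    g <- build_conflict_graph(inst$matrix)
    if (graph_components(g) > 1L) next
    bp <- initial_bipartition(inst$matrix, g)
    agree <- mean(bp$assignment == inst$origin)
    expect_true(agree == 1 || agree == 0)
    checked <- checked + 1L
  }
  expect_gte(checked, 5L)
})

test_that("bipartition centers are column means with neutral uncovered columns", {
  x <- as_snp_matrix(c("11-", "10-", "01-"))
  bp <- suppressWarnings(initial_bipartition(x))
  expect_true(all(bp$centers >= 0 & bp$centers <= 1))
  # third column is covered by nobody: both centers neutral
  expect_equal(bp$centers[, 3], c(0.5, 0.5))
})
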