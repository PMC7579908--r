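# Independent scalar oracles and small fixture builders.  Everything here
# deliberately avoids the package's vectorized code paths: distances,
# memberships and objectives are recomputed with plain loops so the tests
# cross-check two independent routes.

# fragment string -> integer vector with NA gaps
ora_vec <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  v <- suppressWarnings(as.integer(ch))
  v[ch == "-"] <- NA_integer_
  v
}

# scalar NHD with intersection overlap; NA when no joint site
ora_nhd <- function(s1, s2) {
  a <- ora_vec(s1); b <- ora_vec(s2)
  hd <- 0L; s <- 0L
  for (k in seq_along(a)) {
    if (!is.na(a[k]) && !is.na(b[k])) {
      s <- s + 1L
      if (a[k] != b[k]) hd <- hd + 1L
    }
  }
  if (s == 0L) NA_real_ else hd / s
}

# scalar masked mean squared distance
ora_d2 <- function(v, cen) {
  tot <- 0; nobs <- 0L
  for (k in seq_along(v)) {
    if (!is.na(v[k])) {
      tot <- tot + (v[k] - cen[k])^2
      nobs <- nobs + 1L
    }
  }
  tot / nobs
}

# brute-force membership evaluation: unnormalized closed forms, then divide
# by their sum, with the same zero-distance limit convention
ora_memberships <- function(x, centers, p) {
  m <- x$n_fragments
  Tm <- matrix(0, m, 2); Im <- numeric(m); Fm <- numeric(m)
  ex <- -1 / (p$m_fuzz - 1)
  for (i in seq_len(m)) {
    v <- ifelse(x$observed[i, ], x$alleles[i, ], NA_integer_)
    d1 <- ora_d2(v, centers[1, ])
    d2 <- ora_d2(v, centers[2, ])
    db <- ora_d2(v, (centers[1, ] + centers[2, ]) / 2)
    if (min(d1, d2) == 0) {
      if (d1 == 0 && d2 == 0) Tm[i, ] <- c(0.5, 0.5)
      else if (d1 == 0) Tm[i, 1] <- 1
      else Tm[i, 2] <- 1
    } else if (db == 0) {
      Im[i] <- 1
    } else {
      t1 <- (1 / p$w1) * d1^ex
      t2 <- (1 / p$w1) * d2^ex
      ii <- (1 / p$w2) * db^ex
      ff <- (1 / p$w3) * (p$delta^2)^ex
      tot <- t1 + t2 + ii + ff
      Tm[i, ] <- c(t1, t2) / tot
      Im[i] <- ii / tot
      Fm[i] <- ff / tot
    }
  }
  list(T = Tm, I = Im, F = Fm)
}

# term-by-term scalar objective
ora_objective <- function(x, Tm, Im, Fm, centers, p) {
  J <- 0
  for (i in seq_len(x$n_fragments)) {
    v <- ifelse(x$observed[i, ], x$alleles[i, ], NA_integer_)
    for (j in 1:2)
      J <- J + (p$w1 * Tm[i, j])^p$m_fuzz * ora_d2(v, centers[j, ])
    J <- J + (p$w2 * Im[i])^p$m_fuzz *
      ora_d2(v, (centers[1, ] + centers[2, ]) / 2)
    J <- J + p$delta^2 * (p$w3 * Fm[i])^p$m_fuzz
  }
  J
}

# random fragment matrix with a guaranteed observed site per row
rand_frags <- function(m, n, gap_rate = 0.4) {
  strings <- character(m)
  for (i in seq_len(m)) {
    repeat {
      ch <- sample(c("0", "1", "-"), n, replace = TRUE,
                   prob = c((1 - gap_rate) / 2, (1 - gap_rate) / 2, gap_rate))
      if (any(ch != "-")) break
    }
    strings[i] <- paste(ch, collapse = "")
  }
  strings
}

# connected components of a conflict graph (union-find, small inputs)
graph_components <- function(g) {
  comp <- seq_len(g$n_nodes)
  find <- function(a) { while (comp[a] != a) a <- comp[a]; a }
  for (r in seq_len(nrow(g$edges))) {
    ra <- find(g$edges$i[r]); rb <- find(g$edges$j[r])
    if (ra != rb) comp[rb] <- ra
  }
  length(unique(vapply(seq_len(g$n_nodes), find, integer(1))))
}
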