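# Fixture generators and brute-force oracles, independent of the package's
# vectorized implementations.

make_random_psa <- function(n = 50, J = 4, seed = NULL,
                            labels = LETTERS[seq_len(J)]) {
  if (!is.null(seed)) set.seed(seed)
  psa_matrix(costs = matrix(stats::runif(n * J, 0, 5000), n, J),
             qalys = matrix(stats::runif(n * J, 0, 3), n, J),
             labels = labels)
}

# matrix values without the class/provenance attributes, for oracle comparison
bare <- function(m) {
  m <- unclass(m)
  attr(m, "lambda") <- NULL
  attr(m, "n_sims") <- NULL
  m
}

# per-simulation sort-and-tally rank probabilities (competition/min rank)
oracle_rank_prob <- function(nb) {
  nb <- unclass(nb)
  n <- nrow(nb)
  J <- ncol(nb)
  p <- matrix(0, J, J)
  for (i in seq_len(n)) {
    rk <- rank(-nb[i, ], ties.method = "min")
    for (j in seq_len(J)) p[j, rk[j]] <- p[j, rk[j]] + 1
  }
  dimnames(p) <- list(colnames(nb), seq_len(J))
  p / n
}

# an option is on the frontier iff it uniquely maximizes mean net benefit on
# some open interval of thresholds; decided by exact breakpoint enumeration
oracle_on_frontier <- function(mean_cost, mean_qaly) {
  J <- length(mean_cost)
  br <- c(0)
  for (a in seq_len(J - 1L)) for (b in (a + 1L):J) {
    if (mean_qaly[a] != mean_qaly[b]) {
      lam <- (mean_cost[a] - mean_cost[b]) / (mean_qaly[a] - mean_qaly[b])
      if (is.finite(lam) && lam > 0) br <- c(br, lam)
    }
  }
  br <- sort(unique(br))
  probes <- c((br[-length(br)] + br[-1L]) / 2, max(br) + 1, max(br) * 2 + 1)
  on_f <- rep(FALSE, J)
  for (lam in probes) {
    mnb <- lam * mean_qaly - mean_cost
    top <- which(mnb > max(mnb) - 1e-9 * max(1, abs(max(mnb))))
    if (length(top) == 1L) on_f[top] <- TRUE
  }
  on_f
}

expect_psa_equal <- function(a, b) {
  expect_equal(a$labels, b$labels)
  expect_identical(unname(a$costs), unname(b$costs))
  expect_identical(unname(a$qalys), unname(b$qalys))
}
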