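test_that("a single simulation yields a permutation matrix", {
  nb <- matrix(c(3, 1, 2), 1, dimnames = list(NULL, c("a", "b", "c")))
  p <- rank_matrix(nb)
  expect_equal(bare(p),
               matrix(c(1, 0, 0, 0, 0, 1, 0, 1, 0), 3, byrow = TRUE,
                      dimnames = list(c("a", "b", "c"), 1:3)))
  pc <- cumulative(p)
  expect_equal(unname(unclass(pc)["b", ]), c(0, 0, 1))  # step at held rank
})

test_that("rank_matrix equals the per-simulation sort-and-tally oracle", {
  for (rep in 1:20) {
    set.seed(200 + rep)
    J <- sample(2:6, 1)
    n <- sample(c(5, 50, 500), 1)
    nb <- matrix(stats::rnorm(n * J), n, J,
                 dimnames = list(NULL, letters[1:J]))
    expect_equal(bare(rank_matrix(nb)), oracle_rank_prob(nb),
                 info = paste("instance", rep))
  }
  # dedicated 5 x 200 case
  set.seed(77)
  nb <- matrix(stats::rnorm(1000), 200, 5, dimnames = list(NULL, letters[1:5]))
  expect_equal(bare(rank_matrix(nb)), oracle_rank_prob(nb))
})

test_that("rank matrices are doubly stochastic for continuous draws", {
  set.seed(31)
  nb <- matrix(stats::rnorm(500 * 5), 500, 5)
  p <- unclass(rank_matrix(nb))
  expect_equal(unname(rowSums(p)), rep(1, 5), tolerance = 1e-12)
  expect_equal(unname(colSums(p)), rep(1, 5), tolerance = 1e-12)
})

test_that("tie rules: competition rank by default, uniform under 'random'", {
  nb <- matrix(c(1, 1, 0), 1, dimnames = list(NULL, c("a", "b", "c")))
  p <- unclass(rank_matrix(nb))
  expect_equal(p["a", 1], 1)  # shared rank 1
  expect_equal(p["b", 1], 1)
  expect_equal(p["c", 3], 1)  # rank 2 skipped under competition ranking
  set.seed(1)
  pr <- unclass(rank_matrix(nb[rep(1, 4000), ], ties = "random"))
  expect_equal(pr["a", 1], 0.5, tolerance = 0.05)
  expect_equal(pr["b", 2], 0.5, tolerance = 0.05)
  expect_equal(pr["c", 3], 1)
})

test_that("symmetric two-option net benefits split rank 1 evenly", {
  set.seed(123)
  n <- 1e5
  d <- stats::rnorm(n)  # symmetric about 0
  nb <- cbind(a = d / 2, b = -d / 2)
  p <- unclass(rank_matrix(nb))
  expect_equal(p["a", 1], 0.5, tolerance = 3 * 0.5 / sqrt(n))
})

test_that("cumulative rows are monotone and end at exactly 1", {
  for (rep in 1:10) {
    set.seed(300 + rep)
    p <- rank_matrix(matrix(stats::rnorm(600), 100, 6))
    pc <- unclass(cumulative(p))
    expect_true(all(apply(pc, 1, function(r) all(diff(r) >= -1e-15))))
    expect_identical(unname(pc[, 6]), rep(1, 6))
  }
})

test_that("SUCRA boundary cases and the mean-rank identity hold", {
  # option always first / always last
  always <- matrix(c(rep(5, 10), rep(3, 10), rep(1, 10)), 10,
                   dimnames = list(NULL, c("top", "mid", "low")))
  pc <- cumulative(rank_matrix(always))
  s <- sucra(pc)
  expect_equal(s[["top"]], 1)
  expect_equal(s[["low"]], 0)
  mr <- mean_rank(rank_matrix(always))
  expect_equal(mr[["mid"]], 2)

  for (rep in 1:10) {
    set.seed(400 + rep)
    J <- sample(3:7, 1)
    p <- rank_matrix(matrix(stats::rnorm(50 * J), 50, J))
    expect_equal(unname(sucra(p)),
                 unname((J - mean_rank(p)) / (J - 1)), tolerance = 1e-9)
  }
})

test_that("median and quartile ranks follow the smallest-rank-reaching-q rule", {
  pc <- cum_rank_matrix(rbind(deg = c(0, 0, 1, 1),
                              other = c(0.2, 0.4, 0.6, 1),
                              lo = c(0.1, 0.2, 0.3, 1),
                              hi = c(0.7, 0.8, 0.9, 1)))
  mi <- median_iqr(pc)
  expect_equal(unlist(mi[mi$option == "deg", -1]),
               c(q25 = 3, median = 3, q75 = 3))
  expect_equal(unlist(mi[mi$option == "other", -1]),
               c(q25 = 2, median = 3, q75 = 4))
  expect_equal(unlist(mi[mi$option == "hi", -1]),
               c(q25 = 1, median = 1, q75 = 2))
})

test_that("top_r_probability reads cumulative columns with range checks", {
  p <- rank_matrix(matrix(stats::rnorm(300), 100, 3,
                          dimnames = list(NULL, c("a", "b", "c"))))
  pc <- cumulative(p)
  expect_equal(unname(top_r_probability(pc, 3)), rep(1, 3))
  expect_equal(top_r_probability(pc, 1), unclass(p)[, 1][c("a", "b", "c")])
  expect_error(top_r_probability(pc, 0), "between 1 and")
  expect_error(top_r_probability(pc, 4), "between 1 and")
})

test_that("FSD is a strict partial order and orders the rank summaries", {
  for (rep in 1:12) {
    set.seed(500 + rep)
    J <- sample(3:7, 1)
    p <- rank_matrix(matrix(stats::rnorm(80 * J), 80, J,
                            dimnames = list(NULL, LETTERS[1:J])))
    pc <- cumulative(p)
    v <- unclass(fsd(pc))
    expect_true(all(diag(v) == "equal"))
    dom <- v == "dominates"
    # antisymmetry
    expect_equal(t(v) == "dominated_by", dom)
    expect_false(any(dom & t(dom)))
    # transitivity: dominates composed with dominates stays inside dominates
    implied <- (dom %*% dom) > 0
    expect_true(all(!(implied & !dom)))
    # monotonicity of SUCRA and mean rank under FSD
    s <- sucra(pc); mr <- mean_rank(p)
    for (idx in which(dom)) {
      a <- (idx - 1) %% J + 1
      b <- (idx - 1) %/% J + 1
      expect_true(s[a] >= s[b] - 1e-12)
      expect_true(mr[a] <= mr[b] + 1e-12)
    }
  }
})

test_that("FSD edge lists export, with a transitively reduced variant", {
  pc <- cum_rank_matrix(rbind(A = c(0.6, 0.9, 1),
                              B = c(0.3, 0.7, 1),
                              C = c(0.1, 0.4, 1)))
  rel <- fsd(pc)
  e <- fsd_edges(rel)
  expect_setequal(paste(e$a, e$b), c("A B", "A C", "B C"))
  h <- fsd_edges(rel, reduced = TRUE)
  expect_setequal(paste(h$a, h$b), c("A B", "B C"))  # A->C implied
})

test_that("CEAC curves normalize, match rank-1 extraction, and the CEAF is definitional", {
  psa <- make_random_psa(n = 400, J = 5, seed = 21)
  grid <- c(0, 10000, 20000, 40000)
  cc <- ceac(psa, grid)
  expect_equal(unname(rowSums(cc$prob)), rep(1, length(grid)),
               tolerance = 1e-12)
  for (i in seq_along(grid)) {
    p <- rank_matrix(net_benefit(psa, grid[i]))
    expect_equal(cc$prob[i, ], unclass(p)[, 1])
    expect_equal(cc$frontier$option[i], max_mean_nb(psa, grid[i]))
    expect_identical(cc$frontier$prob[i],
                     unname(cc$prob[i, cc$frontier$option[i]]))
  }
  expect_error(ceac(psa, numeric(0)), "non-empty")
  expect_error(ceac(psa, c(10, 5)), "increasing")
  expect_error(ceac(psa, c(-5, 10)), ">= 0")
})

test_that("a uniformly superior option has a flat CEAC at 1", {
  psa <- psa_matrix(cbind(A = c(10, 20, 30), B = c(5, 15, 25)),
                    cbind(A = c(1, 1, 1), B = c(1.5, 1.4, 1.3)))
  cc <- ceac(psa, c(0, 20000, 50000))
  expect_equal(unname(cc$prob[, "B"]), rep(1, 3))
  expect_equal(ceaf(cc)$option, rep("B", 3))
  expect_equal(ceaf(cc)$prob, rep(1, 3))
})

test_that("constructors validate externally supplied matrices", {
  expect_error(rank_prob_matrix(matrix(0.5, 2, 3)), "square")
  expect_error(rank_prob_matrix(rbind(c(0.9, 0.3), c(0.5, 0.5)),
                                labels = c("a", "b")), "sum to 1")
  expect_error(cum_rank_matrix(rbind(c(0.5, 0.4, 1), c(0, 0.5, 1),
                                     c(0, 0, 1))), "non-decreasing")
  expect_error(cum_rank_matrix(rbind(c(0.2, 0.8), c(0.1, 0.9))),
               "equal 1")
  # loose tolerance admits whole-percent rounded published rows
  p <- rbind(a = c(0.34, 0.33, 0.34), b = c(0.33, 0.34, 0.33),
             c = c(0.33, 0.33, 0.33))
  expect_error(rank_prob_matrix(p), "sum to 1")
  expect_s3_class(rank_prob_matrix(p, tol = 0.02), "rank_prob")
})

test_that("Monte Carlo standard errors follow sqrt(p(1-p)/n)", {
  p <- rank_matrix(matrix(stats::rnorm(100 * 3), 100, 3))
  se <- rank_prob_se(p)
  expect_equal(se, sqrt(unclass(p) * (1 - unclass(p)) / 100),
               ignore_attr = TRUE)
  expect_error(rank_prob_se(rank_prob_matrix(diag(3) * 1)), "unknown")
})

test_that("rank_analysis assembles a consistent report object", {
  psa <- make_random_psa(n = 300, J = 4, seed = 55)
  fit <- rank_analysis(psa, 20000)
  expect_equal(unclass(fit$p), unclass(rank_matrix(net_benefit(psa, 20000))))
  expect_equal(fit$sucra, sucra(fit$pcum))
  expect_equal(fit$order, psa$labels[order(fit$mean_rank)])
  expect_equal(unname(fit$nb_rank[max_mean_nb(psa, 20000)]), 1L)
  tb <- rank_table(fit)
  expect_equal(tb$statistic[1], "rank_prob_1")
  expect_equal(names(tb)[-1], fit$order)
  # probability block columns sum to 1 pre-rounding
  pblock <- as.matrix(tb[1:4, -1])
  expect_equal(unname(colSums(pblock)), rep(1, 4), tolerance = 1e-12)
  expect_output(print(fit), "SUCRA")
  expect_s3_class(summary(fit), "data.frame")
})
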