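#' Rank-probability matrix of net benefit
#'
#' For each Monte Carlo simulation the options are ranked by descending net
#' benefit (rank 1 = greatest net benefit); \code{p[j, r]} is the fraction of
#' simulations in which option \code{j} took rank \code{r}. Row \code{j} is
#' option \code{j}'s rank distribution; column 1 is the CEAC value at the
#' matrix's threshold.
#'
#' Tied net benefits receive the minimum ("competition") rank under
#' \code{ties = "min"}, the convention of spreadsheet \code{RANK()}
#' functions; \code{ties = "random"} breaks ties uniformly using the current
#' RNG state (set a seed for reproducibility). Ties have probability zero for
#' continuous models but matter for degenerate inputs; note that under
#' \code{"min"} a shared rank makes column sums exceed 1.
#'
#' @param nb an \code{nb_matrix} from [net_benefit()], or any numeric
#'   \code{n_sims x J} matrix of net benefits with option labels as column
#'   names.
#' @param ties tie-handling rule, \code{"min"} (default) or \code{"random"}.
#' @return a \code{rank_prob} object: a \code{J x J} matrix (rows = options,
#'   columns = ranks) with attributes \code{lambda} (if known) and
#'   \code{n_sims}.
#' @examples
#' psa <- psa_matrix(cbind(A = c(0, 0), B = c(10, -10)),
#'                   cbind(A = c(1, 1), B = c(1, 1)))
#' rank_matrix(net_benefit(psa, 20000))
#' @export
rank_matrix <- function(nb, ties = c("min", "random")) {
  ties <- match.arg(ties)
  lambda <- attr(nb, "lambda")
  nb <- unclass(nb)
  stopifnot(is.matrix(nb), is.numeric(nb))
  n <- nrow(nb)
  J <- ncol(nb)
  labels <- colnames(nb)
  if (is.null(labels)) labels <- paste0("option", seq_len(J))
  # competition rank: 1 + number of options with strictly greater net benefit
  rk <- matrix(1L, n, J)
  for (j in seq_len(J)) {
    for (k in seq_len(J)) {
      if (k == j) next
      rk[, j] <- rk[, j] + (nb[, k] > nb[, j])
    }
  }
  if (ties == "random") {
    tied <- rowSums(rk) != sum(seq_len(J))  # min-rank sum deficit flags ties
    if (any(tied))
      rk[tied, ] <- t(apply(nb[tied, , drop = FALSE], 1L,
                            function(x) rank(-x, ties.method = "random")))
  }
  p <- vapply(seq_len(J), function(j) tabulate(rk[, j], J),
              numeric(J)) / n
  p <- t(p)  # rows = options, cols = ranks
  dimnames(p) <- list(labels, seq_len(J))
  new_rank_prob(p, lambda = lambda, n_sims = n)
}

new_rank_prob <- function(p, lambda = NULL, n_sims = NA_integer_) {
  structure(p, lambda = lambda, n_sims = n_sims,
            class = c("rank_prob", "matrix", "array"))
}

#' Construct a rank-probability matrix from given values
#'
#' Wraps an externally obtained \code{J x J} matrix of rank probabilities
#' (rows = options, columns = ranks) after validating that entries lie in
#' \[0, 1\] and rows sum to 1. Published tables rounded to whole percent can
#' violate row sums by up to a percent; raise \code{tol} accordingly.
#'
#' @param p numeric \code{J x J} matrix; row names are option labels.
#' @param labels option labels (default: row names).
#' @param lambda the willingness-to-pay threshold the ranks were computed at,
#'   if known.
#' @param n_sims the simulation count behind the estimates, if known.
#' @param tol allowed deviation of each row sum from 1.
#' @return a \code{rank_prob} object.
#' @export
rank_prob_matrix <- function(p, labels = rownames(p), lambda = NULL,
                             n_sims = NA_integer_, tol = 1e-6) {
  p <- as.matrix(p)
  J <- nrow(p)
  if (ncol(p) != J || J < 2L)
    stop_validation("'p' must be a square matrix with J >= 2")
  if (is.null(labels)) labels <- paste0("option", seq_len(J))
  check_labels(labels, J)
  if (any(!is.finite(p)) || any(p < -tol) || any(p > 1 + tol))
    stop_validation("rank probabilities must lie in [0, 1]")
  if (any(abs(rowSums(p) - 1) > tol))
    stop_validation("each row of rank probabilities must sum to 1 (tol = ",
                    tol, ")")
  dimnames(p) <- list(labels, seq_len(J))
  new_rank_prob(p, lambda = lambda, n_sims = n_sims)
}

#' Cumulative rank probabilities
#'
#' Running row sums of a rank-probability matrix: \code{pcum[j, r]} is the
#' probability that option \code{j} ranks \code{r}-th or better. Each row is
#' renormalized by its total before summing, and the final column is pinned
#' to exactly 1.
#'
#' @param p a \code{rank_prob} object (or plain matrix, rows = options).
#' @return a \code{cum_rank} object of the same shape.
#' @export
cumulative <- function(p) {
  lambda <- attr(p, "lambda")
  n_sims <- attr(p, "n_sims")
  m <- as.matrix(unclass(p))
  m <- m / rowSums(m)
  pc <- t(apply(m, 1L, cumsum))
  pc[, ncol(pc)] <- 1
  dimnames(pc) <- dimnames(m)
  new_cum_rank(pc, lambda = lambda, n_sims = n_sims)
}

new_cum_rank <- function(pc, lambda = NULL, n_sims = NA_integer_) {
  structure(pc, lambda = lambda, n_sims = n_sims,
            class = c("cum_rank", "matrix", "array"))
}

#' Construct a cumulative-rank matrix from given values
#'
#' Validates that rows are non-decreasing and reach 1 in the last column
#' (within \code{tol}; use a loose tolerance for tables rounded to whole
#' percent).
#'
#' @inheritParams rank_prob_matrix
#' @param pcum numeric \code{J x J} matrix of cumulative rank probabilities.
#' @return a \code{cum_rank} object.
#' @export
cum_rank_matrix <- function(pcum, labels = rownames(pcum), lambda = NULL,
                            n_sims = NA_integer_, tol = 1e-6) {
  pcum <- as.matrix(pcum)
  J <- nrow(pcum)
  if (ncol(pcum) != J || J < 2L)
    stop_validation("'pcum' must be a square matrix with J >= 2")
  if (is.null(labels)) labels <- paste0("option", seq_len(J))
  check_labels(labels, J)
  if (any(!is.finite(pcum)) || any(pcum < -tol) || any(pcum > 1 + tol))
    stop_validation("cumulative probabilities must lie in [0, 1]")
  if (any(apply(pcum, 1L, function(r) any(diff(r) < -tol))))
    stop_validation("cumulative probabilities must be non-decreasing in rank")
  if (any(abs(pcum[, J] - 1) > tol))
    stop_validation("final cumulative column must equal 1 (tol = ", tol, ")")
  dimnames(pcum) <- list(labels, seq_len(J))
  new_cum_rank(pcum, lambda = lambda, n_sims = n_sims)
}

#' Surface under the cumulative ranking (SUCRA)
#'
#' The mean of an option's first \eqn{J - 1} cumulative rank probabilities:
#' 1 for an option that always ranks first, 0 for one that always ranks last.
#' Equivalently \eqn{(J - \bar r_j) / (J - 1)} where \eqn{\bar r_j} is the
#' option's mean rank. SUCRA is a descriptive summary of a rank distribution;
#' being an unweighted average of cumulative rank probabilities it carries no
#' utility-theoretic justification and should not by itself drive a
#' preference-based choice between options.
#'
#' @param pcum a \code{cum_rank} object (or a \code{rank_prob}, which is
#'   accumulated first).
#' @return named numeric vector of SUCRA values in \[0, 1\].
#' @export
sucra <- function(pcum) {
  pcum <- as_cum(pcum)
  J <- ncol(pcum)
  v <- rowMeans(unclass(pcum)[, seq_len(J - 1L), drop = FALSE])
  stats::setNames(as.vector(v), rownames(pcum))
}

as_cum <- function(x) {
  if (inherits(x, "cum_rank")) return(x)
  if (inherits(x, "rank_prob")) return(cumulative(x))
  stop_validation("expected a 'cum_rank' or 'rank_prob' object")
}

as_prob <- function(x) {
  if (inherits(x, "rank_prob")) return(x)
  stop_validation("expected a 'rank_prob' object")
}

#' Mean rank
#'
#' The probability-weighted average rank \eqn{\sum_r r P_{jr}} per option.
#'
#' @param p a \code{rank_prob} object.
#' @return named numeric vector in \[1, J\].
#' @export
mean_rank <- function(p) {
  p <- as_prob(p)
  m <- unclass(p) / rowSums(unclass(p))
  stats::setNames(as.vector(m %*% seq_len(ncol(m))), rownames(p))
}

#' Median and interquartile range of rank
#'
#' For quantile \eqn{q} the reported rank is the smallest \eqn{r} whose
#' cumulative probability reaches \eqn{q} — the usual quantile convention for
#' a discrete rank distribution.
#'
#' @param pcum a \code{cum_rank} (or \code{rank_prob}) object.
#' @return data frame with columns \code{option}, \code{q25}, \code{median},
#'   \code{q75} (integer ranks).
#' @export
median_iqr <- function(pcum) {
  pcum <- as_cum(pcum)
  m <- unclass(pcum)
  qrank <- function(row, q) which(row >= q - 1e-9)[1L]
  data.frame(option = rownames(m),
             q25 = unname(apply(m, 1L, qrank, q = 0.25)),
             median = unname(apply(m, 1L, qrank, q = 0.50)),
             q75 = unname(apply(m, 1L, qrank, q = 0.75)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Probability of ranking in the top r
#'
#' Column \code{r} of the cumulative rank matrix: per option, the probability
#' of being ranked \code{r}-th or better. \code{r = 1} gives the CEAC values
#' at the matrix's threshold.
#'
#' @param pcum a \code{cum_rank} (or \code{rank_prob}) object.
#' @param r a rank, \code{1 <= r <= J}.
#' @return named numeric vector of probabilities.
#' @export
top_r_probability <- function(pcum, r) {
  pcum <- as_cum(pcum)
  J <- ncol(pcum)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 1 || r > J ||
      r != round(r))
    stop_domain("'r' must be an integer rank between 1 and ", J)
  stats::setNames(unclass(pcum)[, as.integer(r)], rownames(pcum))
}

#' Monte Carlo standard errors of rank probabilities
#'
#' Binomial standard error \eqn{\sqrt{p(1-p)/n}} for every entry, so the
#' precision of each estimated rank probability can be judged against the
#' simulation count. Requires the matrix to carry \code{n_sims}.
#'
#' @param p a \code{rank_prob} object with a known \code{n_sims}.
#' @return matrix of standard errors, same shape as \code{p}.
#' @export
rank_prob_se <- function(p) {
  p <- as_prob(p)
  n <- attr(p, "n_sims")
  if (is.null(n) || is.na(n))
    stop_validation("simulation count unknown; cannot compute standard errors")
  m <- unclass(p)
  se <- sqrt(m * (1 - m) / n)
  dimnames(se) <- dimnames(m)
  se
}

#' First-order stochastic dominance between options
#'
#' Option \code{a} first-order stochastically dominates option \code{b} when
#' \code{a}'s probability of ranking \code{r}-th or better is at least
#' \code{b}'s at every rank \code{r}, with strict inequality somewhere. FSD
#' orders options without any assumption about the decision maker's attitude
#' to risk, but only partially: pairs whose cumulative curves cross are
#' incomparable.
#'
#' @param pcum a \code{cum_rank} (or \code{rank_prob}) object.
#' @param tol numeric tolerance for comparing cumulative probabilities.
#' @return an \code{fsd} object: a \code{J x J} character matrix with entries
#'   \code{"dominates"}, \code{"dominated_by"}, \code{"equal"},
#'   \code{"incomparable"}; the diagonal is \code{"equal"}.
#' @seealso [fsd_edges()]
#' @export
fsd <- function(pcum, tol = 1e-12) {
  pcum <- as_cum(pcum)
  m <- unclass(pcum)
  J <- nrow(m)
  v <- matrix("equal", J, J, dimnames = list(rownames(m), rownames(m)))
  for (a in seq_len(J)) {
    for (b in seq_len(J)) {
      if (a == b) next
      d <- m[a, ] - m[b, ]
      if (all(abs(d) <= tol)) v[a, b] <- "equal"
      else if (all(d >= -tol)) v[a, b] <- "dominates"
      else if (all(d <= tol)) v[a, b] <- "dominated_by"
      else v[a, b] <- "incomparable"
    }
  }
  structure(v, lambda = attr(pcum, "lambda"),
            class = c("fsd", "matrix", "array"))
}

#' @export
print.fsd <- function(x, ...) {
  cat("First-order stochastic dominance relation\n")
  abbrev <- c(dominates = ">", dominated_by = "<", equal = "=",
              incomparable = "?")
  m <- matrix(abbrev[unclass(x)], nrow(x), dimnames = dimnames(x))
  print(m, quote = FALSE)
  cat("(row > column: row dominates; ?: incomparable)\n")
  invisible(x)
}

#' Edge list of an FSD relation
#'
#' One row per dominating pair. With \code{reduced = TRUE} edges implied by
#' transitivity are removed, giving the covering relation a Hasse diagram
#' draws.
#'
#' @param x an \code{fsd} object.
#' @param reduced drop transitively implied edges?
#' @return data frame with columns \code{a}, \code{b}, \code{verdict}
#'   (\code{a} dominates \code{b}).
#' @export
fsd_edges <- function(x, reduced = FALSE) {
  stopifnot(inherits(x, "fsd"))
  m <- unclass(x) == "dominates"
  if (reduced) {
    J <- nrow(m)
    keep <- m
    for (a in seq_len(J)) for (b in seq_len(J)) {
      if (!m[a, b]) next
      if (any(m[a, ] & m[, b])) keep[a, b] <- FALSE
    }
    m <- keep
  }
  idx <- which(m, arr.ind = TRUE)
  data.frame(a = rownames(x)[idx[, 1L]], b = colnames(x)[idx[, 2L]],
             verdict = rep("dominates", nrow(idx)),
             stringsAsFactors = FALSE)
}

#' Cost-effectiveness acceptability curves and frontier
#'
#' The CEAC of option \code{j} is the probability, across simulations, that
#' \code{j} has the greatest net benefit (ranks first), as a function of the
#' willingness-to-pay threshold. The CEAF picks, at each threshold, the CEAC
#' value of the option with the greatest \emph{mean} net benefit; it can jump
#' at frontier switches and can lie below other options' CEACs, because the
#' option maximizing mean net benefit need not be the most probable winner.
#'
#' @param psa a [psa_matrix()].
#' @param lambda_grid strictly increasing non-negative thresholds. The
#'   default spans 0 to 100,000 in steps of 500.
#' @param ties tie rule passed to the per-threshold ranking (see
#'   [rank_matrix()]).
#' @return a \code{ceac} object: a list with \code{lambda} (the grid),
#'   \code{prob} (a \code{length(grid) x J} matrix of rank-1 probabilities),
#'   and \code{frontier} (data frame: \code{lambda}, \code{option} with the
#'   greatest mean net benefit, \code{prob} — its CEAC value).
#' @examples
#' psa <- psa_matrix(cbind(A = c(0, 0, 0), B = c(5, -5, 2)),
#'                   cbind(A = c(1, 1, 1), B = c(1.1, 0.9, 1.05)))
#' ceac(psa, lambda_grid = c(0, 50, 100))
#' @export
ceac <- function(psa, lambda_grid = seq(0, 100000, by = 500),
                 ties = c("min", "random")) {
  stopifnot(inherits(psa, "psa_matrix"))
  ties <- match.arg(ties)
  if (!is.numeric(lambda_grid) || length(lambda_grid) == 0L)
    stop_domain("'lambda_grid' must be a non-empty numeric vector")
  if (any(!is.finite(lambda_grid)) || any(lambda_grid < 0))
    stop_domain("thresholds must be finite and >= 0")
  if (length(lambda_grid) > 1L && any(diff(lambda_grid) <= 0))
    stop_domain("'lambda_grid' must be strictly increasing")
  J <- n_options(psa)
  mc <- colMeans(psa$costs)
  mq <- colMeans(psa$qalys)
  prob <- matrix(NA_real_, length(lambda_grid), J,
                 dimnames = list(NULL, psa$labels))
  front <- character(length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    lam <- lambda_grid[i]
    p <- rank_matrix(net_benefit(psa, lam), ties = ties)
    prob[i, ] <- unclass(p)[, 1L]
    front[i] <- max_mean_nb_from_means(psa$labels, mc, mq, lam)
  }
  fidx <- match(front, psa$labels)
  structure(list(lambda = lambda_grid, prob = prob,
                 frontier = data.frame(
                   lambda = lambda_grid, option = front,
                   prob = prob[cbind(seq_along(lambda_grid), fidx)],
                   stringsAsFactors = FALSE)),
            class = "ceac")
}

#' Extract the cost-effectiveness acceptability frontier
#'
#' @param x a \code{ceac} object.
#' @return data frame with columns \code{lambda}, \code{option} (greatest
#'   mean net benefit at that threshold), \code{prob} (that option's CEAC
#'   value).
#' @export
ceaf <- function(x) {
  stopifnot(inherits(x, "ceac"))
  x$frontier
}

#' @export
print.ceac <- function(x, ...) {
  cat("CEAC over", length(x$lambda), "thresholds [",
      min(x$lambda), ",", max(x$lambda), "], options:",
      paste(colnames(x$prob), collapse = ", "), "\n")
  sw <- which(x$frontier$option[-1L] !=
                x$frontier$option[-nrow(x$frontier)])
  if (length(sw))
    cat("Frontier option switches at lambda in (",
        paste(x$frontier$lambda[sw], x$frontier$lambda[sw + 1L],
              sep = "-", collapse = ", "), ")\n")
  else
    cat("Frontier option:", x$frontier$option[1L], "throughout\n")
  invisible(x)
}

#' Plot CEAC curves with the acceptability frontier overlaid
#'
#' @param x a \code{ceac} object.
#' @param frontier overlay the CEAF as a heavy black line?
#' @param currency currency prefix for the x-axis label.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ceac <- function(x, frontier = TRUE, currency = "£", ...) {
  J <- ncol(x$prob)
  graphics::matplot(x$lambda, x$prob, type = "l", lty = 1,
                    col = grDevices::hcl.colors(J, "Dark 3"),
                    xlab = paste0("Willingness to pay, ", currency, "/QALY"),
                    ylab = "Probability of greatest net benefit",
                    ylim = c(0, 1), ...)
  if (frontier)
    graphics::lines(x$frontier$lambda, x$frontier$prob, lwd = 3)
  graphics::legend("topright", legend = colnames(x$prob), lty = 1,
                   col = grDevices::hcl.colors(J, "Dark 3"), bty = "n",
                   cex = 0.8)
  invisible(x)
}

#' Long-format table of CEAC/CEAF values
#'
#' @param x a \code{ceac} object.
#' @param ... unused.
#' @return data frame: \code{lambda}, one column per option's CEAC, then
#'   \code{ceaf_option} and \code{ceaf_prob}.
#' @export
as.data.frame.ceac <- function(x, ...) {
  out <- data.frame(lambda = x$lambda, x$prob, check.names = FALSE)
  out$ceaf_option <- x$frontier$option
  out$ceaf_prob <- x$frontier$prob
  out
}
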