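#' Rank-probability analysis of a PSA at a willingness-to-pay threshold
#'
#' The package's main entry point. Computes, at a single threshold, the full
#' presentation suite for a multi-option appraisal: the rank-probability
#' matrix (whose first column is the CEAC), cumulative rank probabilities,
#' SUCRA, mean rank, median rank with interquartile range, the ranking of
#' options by mean net benefit, the mean-outcome efficiency frontier, and the
#' pairwise first-order stochastic dominance relation.
#'
#' Options are reported in ascending order of mean rank (best first), the
#' conventional layout for rank tables. All stored values are full precision;
#' rounding to whole percent / one decimal happens only in the print method.
#'
#' @param psa a [psa_matrix()].
#' @param lambda willingness-to-pay threshold (single value \eqn{\ge 0}).
#' @param ties tie rule for per-simulation ranking, see [rank_matrix()].
#' @return an object of class \code{rank_analysis} with elements
#'   \code{lambda}, \code{p} (\code{rank_prob}), \code{pcum}
#'   (\code{cum_rank}), \code{sucra}, \code{mean_rank}, \code{median_iqr},
#'   \code{nb_rank} (rank of mean net benefit per option), \code{frontier}
#'   (a [ce_frontier()]), \code{fsd} (an [fsd()] relation), \code{se}
#'   (Monte Carlo standard errors of the rank probabilities), \code{order}
#'   (labels by ascending mean rank), and \code{n_sims}.
#' @examples
#' set.seed(1)
#' psa <- generate_psa(paradox_scenario(n_sims = 2000))
#' fit <- rank_analysis(psa, lambda = 20000)
#' fit
#' @export
rank_analysis <- function(psa, lambda, ties = c("min", "random")) {
  stopifnot(inherits(psa, "psa_matrix"))
  check_lambda(lambda)
  ties <- match.arg(ties)
  nb <- net_benefit(psa, lambda)
  p <- rank_matrix(nb, ties = ties)
  pcum <- cumulative(p)
  mnb <- colMeans(unclass(nb))
  structure(list(
    lambda = lambda,
    p = p,
    pcum = pcum,
    sucra = sucra(pcum),
    mean_rank = mean_rank(p),
    median_iqr = median_iqr(pcum),
    nb_rank = stats::setNames(rank(-mnb, ties.method = "min"), psa$labels),
    mean_nb = stats::setNames(as.vector(mnb), psa$labels),
    frontier = ce_frontier(psa),
    fsd = fsd(pcum),
    se = rank_prob_se(p),
    order = psa$labels[order(mean_rank(p))],
    n_sims = n_sims(psa),
    ties = ties),
    class = "rank_analysis")
}

#' Assemble the rank table of a rank analysis
#'
#' One column per option (by ascending mean rank), stacking the
#' rank-probability block, the cumulative block, SUCRA, rank of mean net
#' benefit, mean rank, and the median/quartile ranks. Values are full
#' precision; probabilities are proportions in \[0, 1\].
#'
#' @param x a [rank_analysis()] object.
#' @return data frame with a \code{statistic} column followed by one column
#'   per option.
#' @export
rank_table <- function(x) {
  stopifnot(inherits(x, "rank_analysis"))
  ord <- x$order
  J <- length(ord)
  p <- unclass(x$p)[ord, , drop = FALSE]
  pc <- unclass(x$pcum)[ord, , drop = FALSE]
  mi <- x$median_iqr[match(ord, x$median_iqr$option), ]
  block <- rbind(t(p), t(pc),
                 x$sucra[ord], x$nb_rank[ord], x$mean_rank[ord],
                 mi$median, mi$q25, mi$q75)
  out <- data.frame(
    statistic = c(paste0("rank_prob_", seq_len(J)),
                  paste0("cum_prob_", seq_len(J)),
                  "sucra", "rank_of_mean_nb", "mean_rank",
                  "median_rank", "q25_rank", "q75_rank"),
    block, check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("statistic", ord)
  rownames(out) <- NULL
  out
}

#' @export
print.rank_analysis <- function(x, currency = "£", ...) {
  ord <- x$order
  J <- length(ord)
  cat("Rank analysis of net benefit at lambda = ", currency,
      format(x$lambda, big.mark = ","), "/QALY  (", x$n_sims,
      " simulations)\n\n", sep = "")
  p <- round(100 * unclass(x$p)[ord, , drop = FALSE])
  pc <- round(100 * unclass(x$pcum)[ord, , drop = FALSE])
  mi <- x$median_iqr[match(ord, x$median_iqr$option), ]
  disp <- rbind(t(matrix(paste0(p, "%"), J, J)),
                t(matrix(paste0(pc, "%"), J, J)),
                paste0(round(100 * x$sucra[ord]), "%"),
                x$nb_rank[ord],
                format(round(x$mean_rank[ord], 1), nsmall = 1),
                paste0(mi$median, " (", mi$q25, "-", mi$q75, ")"))
  rownames(disp) <- c(paste0("P(rank ", seq_len(J), ")"),
                      paste0("P(rank <= ", seq_len(J), ")"),
                      "SUCRA", "Rank of mean NB", "Mean rank",
                      "Median rank (IQR)")
  colnames(disp) <- ord
  cat("  (row 'P(rank 1)' is the CEAC at this threshold)\n")
  print(disp, quote = FALSE, right = TRUE)
  dom <- fsd_edges(x$fsd, reduced = TRUE)
  if (nrow(dom))
    cat("\nFSD (covering relation):",
        paste(paste(dom$a, dom$b, sep = " > "), collapse = ", "), "\n")
  cat("Frontier:", paste(x$frontier$frontier, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
summary.rank_analysis <- function(object, ...) {
  ord <- object$order
  mi <- object$median_iqr[match(ord, object$median_iqr$option), ]
  st <- object$frontier$table
  data.frame(option = ord,
             ceac = unclass(object$p)[ord, 1L],
             sucra = object$sucra[ord],
             mean_rank = object$mean_rank[ord],
             median_rank = mi$median, q25_rank = mi$q25, q75_rank = mi$q75,
             nb_rank = object$nb_rank[ord],
             status = st$status[match(ord, st$option)],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rankogram plots
#'
#' \code{style = "bar"} draws, per option, the distribution of ranks as bars
#' (a rankogram); \code{style = "cumulative"} draws each option's cumulative
#' rank probability as a step curve (a cumulative rankogram), the display on
#' which first-order stochastic dominance can be read off directly: one curve
#' lying entirely above another means the upper option dominates.
#'
#' @param x a [rank_analysis()] object.
#' @param style \code{"bar"} or \code{"cumulative"}.
#' @param ... further graphical parameters.
#' @export
plot.rank_analysis <- function(x, style = c("bar", "cumulative"), ...) {
  style <- match.arg(style)
  ord <- x$order
  J <- length(ord)
  cols <- grDevices::hcl.colors(J, "Dark 3")
  if (style == "bar") {
    graphics::barplot(unclass(x$p)[ord, , drop = FALSE], beside = TRUE,
                      names.arg = seq_len(J), col = cols,
                      xlab = "Rank", ylab = "Probability",
                      legend.text = ord, args.legend = list(bty = "n"), ...)
  } else {
    m <- unclass(x$pcum)[ord, , drop = FALSE]
    graphics::plot(NA, xlim = c(1, J), ylim = c(0, 1), xlab = "Rank r",
                   ylab = "P(rank <= r)", xaxt = "n", ...)
    graphics::axis(1, at = seq_len(J))
    for (j in seq_len(J))
      graphics::lines(seq_len(J), m[j, ], type = "s", col = cols[j], lwd = 2)
    graphics::legend("bottomright", legend = ord, col = cols, lwd = 2,
                     bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Case-study rank table: seven-option varicose-veins appraisal
#'
#' Rank and cumulative-rank probabilities, at a threshold of £20,000/QALY,
#' for a published-style seven-option appraisal of treatments for severe
#' varicose veins (options A–G, where A is the standard interventional
#' comparator and B conservative care). The values are whole-percent rounded
#' output of a stochastic decision model and are shipped as a worked example
#' for the summary statistics: because each cell was rounded independently,
#' rows of the probability block can sum to 99–101% and the cumulative block
#' can differ from running sums of the probability block by a percent. The
#' constructors are therefore called with \code{tol = 0.02}.
#'
#' @return a list: \code{p} (a \code{rank_prob}), \code{pcum} (a
#'   \code{cum_rank}), \code{lambda} (20000), \code{labels} (in the table's
#'   mean-rank order D, F, C, A, G, B, E).
#' @examples
#' tb <- varicose_ranks()
#' round(100 * sucra(tb$pcum))
#' @export
varicose_ranks <- function() {
  path <- system.file("extdata", "varicose_rank_table.csv",
                      package = "psarank", mustWork = TRUE)
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  labels <- unique(tb$option)
  J <- length(labels)
  p <- matrix(tb$probability, J, J, byrow = TRUE,
              dimnames = list(labels, seq_len(J)))
  pc <- matrix(tb$cumulative, J, J, byrow = TRUE,
               dimnames = list(labels, seq_len(J)))
  list(p = rank_prob_matrix(p, lambda = 20000, tol = 0.02),
       pcum = cum_rank_matrix(pc, lambda = 20000, tol = 0.02),
       lambda = 20000, labels = labels)
}
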