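#' Incremental cost-effectiveness ratio
#'
#' \eqn{ICER = \Delta cost / \Delta QALY} between two options. Undefined when
#' the QALY difference is zero; equal-effect comparisons must be resolved by
#' cost minimization instead, so a zero denominator is an error here.
#'
#' @param delta_cost incremental cost.
#' @param delta_qaly incremental QALYs; must be non-zero.
#' @return the ratio, in currency per QALY.
#' @examples
#' icer(100, 0.5)  # 200
#' @export
icer <- function(delta_cost, delta_qaly) {
  stopifnot(is.numeric(delta_cost), is.numeric(delta_qaly),
            length(delta_cost) == 1L, length(delta_qaly) == 1L)
  if (!is.finite(delta_cost) || !is.finite(delta_qaly))
    stop_domain("ICER arguments must be finite")
  if (delta_qaly == 0)
    stop_domain("ICER undefined for zero QALY difference; ",
                "compare equal-effect options by cost minimization")
  delta_cost / delta_qaly
}

#' Mean-outcome cost-effectiveness efficiency frontier
#'
#' Classifies each option as on the frontier, strictly dominated, or
#' extendedly dominated, from its mean cost and mean QALYs, and reports the
#' frontier ICER sequence together with the willingness-to-pay interval on
#' which each frontier option maximizes mean net benefit.
#'
#' An option is strictly dominated if some other option has lower-or-equal
#' mean cost and greater-or-equal mean QALYs with at least one strict
#' inequality. The survivors are sorted by increasing mean QALYs and options
#' are removed, one at a time, whenever their ICER against the frontier
#' predecessor is not below the next option's ICER against them, until the
#' ICER sequence is strictly increasing (the lower-left convex hull of the
#' cost-effectiveness plane); removals are classified
#' \code{extendedly_dominated}. A dominated or extendedly dominated option
#' never maximizes mean net benefit at any threshold.
#'
#' Ties: options with identical mean QALYs keep only the cheapest; exactly
#' coincident (cost, QALY) points are resolved by input order with a warning.
#' The threshold intervals are half-open \code{[low, high)}: a threshold equal
#' to an ICER belongs to the more effective option.
#'
#' @param x a [psa_matrix()] (means are computed first) or a data frame with
#'   columns \code{option}, \code{mean_cost}, \code{mean_qaly}.
#' @param ... unused.
#' @return an object of class \code{ce_frontier}: a list with
#'   \describe{
#'     \item{table}{data frame: option, mean_cost, mean_qaly, status
#'       (\code{on_frontier} / \code{dominated} / \code{extendedly_dominated}),
#'       icer (vs frontier predecessor; NA for the anchor and off-frontier
#'       options), lambda_low, lambda_high.}
#'     \item{frontier}{frontier option labels by increasing mean QALYs.}
#'   }
#' @examples
#' m <- data.frame(option = c("A", "B", "C"),
#'                 mean_cost = c(0, 10, 11), mean_qaly = c(0, 1, 2))
#' ce_frontier(m)   # B extendedly dominated; frontier A -> C, ICER 5.5
#' @export
ce_frontier <- function(x, ...) UseMethod("ce_frontier")

#' @export
ce_frontier.psa_matrix <- function(x, ...) ce_frontier(mean_outcomes(x), ...)

#' @export
ce_frontier.data.frame <- function(x, ...) {
  need <- c("option", "mean_cost", "mean_qaly")
  if (!all(need %in% names(x)))
    stop_validation("need columns: ", paste(need, collapse = ", "))
  lab <- as.character(x$option)
  check_labels(lab, length(lab))
  cost <- as.numeric(x$mean_cost)
  qaly <- as.numeric(x$mean_qaly)
  J <- length(lab)
  if (J < 2L) stop_validation("at least two options required")
  if (!all(is.finite(cost)) || !all(is.finite(qaly)))
    stop_validation("mean outcomes must be finite")

  status <- rep("on_frontier", J)
  # coincident points: keep the first in input order
  dup <- duplicated(cbind(cost, qaly))
  if (any(dup)) {
    warning("coincident (cost, QALY) points resolved by input order: ",
            paste(lab[dup], collapse = ", "))
    status[dup] <- "dominated"
  }
  # strict dominance (covers equal-QALY cost ties: cheaper wins)
  for (j in seq_len(J)) {
    if (status[j] != "on_frontier") next
    for (k in seq_len(J)) {
      if (k == j || status[k] == "dominated") next
      if (cost[k] <= cost[j] && qaly[k] >= qaly[j] &&
          (cost[k] < cost[j] || qaly[k] > qaly[j])) {
        status[j] <- "dominated"
        break
      }
    }
  }

  cand <- which(status == "on_frontier")
  cand <- cand[order(qaly[cand], cost[cand])]
  # iterative extended dominance: enforce strictly increasing ICERs
  repeat {
    if (length(cand) <= 2L) break
    ic <- diff(cost[cand]) / diff(qaly[cand])
    bad <- which(diff(ic) <= 0)
    if (!length(bad)) break
    status[cand[bad[1L] + 1L]] <- "extendedly_dominated"
    cand <- cand[-(bad[1L] + 1L)]
  }

  icers <- rep(NA_real_, J)
  lambda_low <- rep(NA_real_, J)
  lambda_high <- rep(NA_real_, J)
  k <- length(cand)
  if (k >= 2L)
    icers[cand[-1L]] <- diff(cost[cand]) / diff(qaly[cand])
  breaks <- c(0, icers[cand[-1L]], Inf)
  for (i in seq_len(k)) {
    lambda_low[cand[i]] <- breaks[i]
    lambda_high[cand[i]] <- breaks[i + 1L]
  }

  structure(list(
    table = data.frame(option = lab, mean_cost = cost, mean_qaly = qaly,
                       status = status, icer = icers,
                       lambda_low = lambda_low, lambda_high = lambda_high,
                       stringsAsFactors = FALSE),
    frontier = lab[cand]), class = "ce_frontier")
}

#' @export
print.ce_frontier <- function(x, digits = 4, ...) {
  cat("Cost-effectiveness efficiency frontier\n")
  tb <- x$table
  tb$mean_cost <- signif(tb$mean_cost, digits + 2)
  tb$mean_qaly <- signif(tb$mean_qaly, digits + 2)
  tb$icer <- signif(tb$icer, digits)
  print(tb, row.names = FALSE)
  cat("Frontier (by increasing mean QALYs):",
      paste(x$frontier, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
as.data.frame.ce_frontier <- function(x, ...) x$table

#' Plot the cost-effectiveness plane with the efficiency frontier
#'
#' @param x a \code{ce_frontier}.
#' @param currency currency prefix used in axis labels.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ce_frontier <- function(x, currency = "£", ...) {
  tb <- x$table
  on_f <- tb$status == "on_frontier"
  graphics::plot(tb$mean_qaly, tb$mean_cost, pch = ifelse(on_f, 19, 1),
                 xlab = "Mean QALYs per person",
                 ylab = paste0("Mean cost per person (", currency, ")"), ...)
  idx <- match(x$frontier, tb$option)
  graphics::lines(tb$mean_qaly[idx], tb$mean_cost[idx], lty = 2)
  graphics::text(tb$mean_qaly, tb$mean_cost, tb$option, pos = 3, cex = 0.8)
  invisible(x)
}

#' Option with the greatest mean net benefit
#'
#' Mean-net-benefit ties are broken by lowest mean cost, then input order.
#'
#' @param psa a [psa_matrix()].
#' @param lambda willingness-to-pay threshold (single value \eqn{\ge 0}).
#' @return the label of the option maximizing mean net benefit at
#'   \code{lambda}.
#' @export
max_mean_nb <- function(psa, lambda) {
  stopifnot(inherits(psa, "psa_matrix"))
  check_lambda(lambda)
  mc <- colMeans(psa$costs)
  mq <- colMeans(psa$qalys)
  max_mean_nb_from_means(psa$labels, mc, mq, lambda)
}

max_mean_nb_from_means <- function(labels, mean_cost, mean_qaly, lambda) {
  mnb <- lambda * mean_qaly - mean_cost
  best <- which(mnb == max(mnb))
  if (length(best) > 1L)
    best <- best[order(mean_cost[best], best)]
  labels[best[1L]]
}

#' Serialize a frontier result
#'
#' Writes the classification table as CSV, or the full result (table plus
#' frontier order) as JSON, depending on \code{format}.
#'
#' @param x a \code{ce_frontier}.
#' @param path output file.
#' @param format \code{"csv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_frontier <- function(x, path, format = c("csv", "json")) {
  stopifnot(inherits(x, "ce_frontier"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(x$table, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(list(table = x$table, frontier = x$frontier), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  invisible(path)
}
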