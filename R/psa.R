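#' Construct a PSA sample matrix
#'
#' Bundles paired Monte Carlo cost and QALY draws for \code{J} mutually
#' exclusive options into a validated \code{psa_matrix} object, the input to
#' every downstream analysis (net benefit, ranking, CEAC, frontier).
#'
#' Each row of \code{costs} and \code{qalys} is one simulation of the decision
#' model; each column is one option. Values are unit-agnostic: costs are in
#' whatever currency the model used, effects in QALYs. Negative entries are
#' allowed (incremental analyses, disutilities); non-finite entries are not.
#'
#' @param costs numeric matrix, \code{n_sims x J}, simulated total costs.
#' @param qalys numeric matrix of identical shape, simulated total QALYs.
#' @param labels character vector of \code{J} unique, non-empty option labels.
#'   Defaults to the column names of \code{costs}. Labels may not contain a
#'   comma (they are embedded in CSV headers).
#' @param meta optional list of provenance information (source file, generator
#'   configuration, seed). Carried along, never interpreted.
#'
#' @return An object of class \code{psa_matrix}: a list with elements
#'   \code{costs}, \code{qalys}, \code{labels}, \code{meta}.
#' @seealso [read_psa_csv()], [net_benefit()], [rank_analysis()]
#' @examples
#' psa <- psa_matrix(costs = cbind(A = c(100, 120), B = c(90, 95)),
#'                   qalys = cbind(A = c(1.0, 1.1), B = c(0.8, 0.9)))
#' psa
#' @export
psa_matrix <- function(costs, qalys, labels = colnames(costs), meta = list()) {
  costs <- as.matrix(costs)
  qalys <- as.matrix(qalys)
  storage.mode(costs) <- "double"
  storage.mode(qalys) <- "double"
  if (!identical(dim(costs), dim(qalys)))
    stop_validation("'costs' and 'qalys' must have identical dimensions")
  if (nrow(costs) < 1L)
    stop_validation("at least one simulation row is required")
  if (ncol(costs) < 2L)
    stop_validation("at least two options (columns) are required")
  if (is.null(labels))
    labels <- paste0("option", seq_len(ncol(costs)))
  labels <- as.character(labels)
  check_labels(labels, ncol(costs))
  if (!all(is.finite(costs)) || !all(is.finite(qalys)))
    stop_validation("costs and qalys must be finite (no NA/NaN/Inf)")
  colnames(costs) <- colnames(qalys) <- labels
  rownames(costs) <- rownames(qalys) <- NULL
  structure(list(costs = costs, qalys = qalys, labels = labels,
                 meta = as.list(meta)),
            class = "psa_matrix")
}

check_labels <- function(labels, J) {
  if (length(labels) != J)
    stop_validation("expected ", J, " option labels, got ", length(labels))
  if (anyNA(labels) || any(!nzchar(labels)))
    stop_validation("option labels must be non-empty")
  if (anyDuplicated(labels))
    stop_validation("duplicate option labels: ",
                    paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (any(grepl(",", labels, fixed = TRUE)))
    stop_validation("option labels may not contain a comma")
  invisible(labels)
}

# Condition helpers: validation/format/parse problems get classed conditions so
# the CLI can map them onto its exit-code contract.
stop_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("psarank_validation_error", "psarank_error")))
}
stop_domain <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("psarank_domain_error", "psarank_error")))
}

#' @export
print.psa_matrix <- function(x, ...) {
  cat("PSA sample matrix:", n_sims(x), "simulations x", n_options(x),
      "options\n")
  cat("Options:", paste(x$labels, collapse = ", "), "\n")
  mo <- mean_outcomes(x)
  mo$mean_cost <- signif(mo$mean_cost, 6)
  mo$mean_qaly <- signif(mo$mean_qaly, 6)
  print(mo, row.names = FALSE)
  invisible(x)
}

#' @export
summary.psa_matrix <- function(object, ...) {
  mo <- mean_outcomes(object)
  mo$sd_cost <- apply(object$costs, 2, stats::sd)
  mo$sd_qaly <- apply(object$qalys, 2, stats::sd)
  structure(list(outcomes = mo, n_sims = n_sims(object),
                 meta = object$meta),
            class = "summary.psa_matrix")
}

#' @export
print.summary.psa_matrix <- function(x, ...) {
  cat("PSA summary (", x$n_sims, " simulations)\n", sep = "")
  print(x$outcomes, row.names = FALSE)
  invisible(x)
}

#' Number of simulations / options in a PSA object
#' @param psa a \code{psa_matrix}.
#' @return integer count.
#' @export
n_sims <- function(psa) nrow(psa$costs)

#' @rdname n_sims
#' @export
n_options <- function(psa) ncol(psa$costs)

#' Read PSA samples from a wide CSV file
#'
#' The expected layout is one row per Monte Carlo simulation with a paired
#' column \code{cost_<label>} / \code{qaly_<label>} for every option, e.g.
#' \code{cost_A,qaly_A,cost_B,qaly_B}. Option order follows the order of the
#' \code{cost_} columns in the header. Files written by [write_psa_csv()]
#' round-trip bit-identically.
#'
#' @param path path to a CSV file (UTF-8, comma separated, "." decimal mark,
#'   header row mandatory).
#' @return a [psa_matrix()] whose \code{meta} records the source path and row
#'   count.
#' @export
read_psa_csv <- function(path) {
  if (!file.exists(path))
    stop_validation("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         strip.white = TRUE)
  nm <- names(raw)
  cost_cols <- grep("^cost_", nm, value = TRUE)
  qaly_cols <- grep("^qaly_", nm, value = TRUE)
  extra <- setdiff(nm, c(cost_cols, qaly_cols))
  if (length(extra))
    stop_validation("unrecognized column(s): ", paste(extra, collapse = ", "),
                    " (expected cost_<label>/qaly_<label> pairs)")
  labels <- sub("^cost_", "", cost_cols)
  qlabels <- sub("^qaly_", "", qaly_cols)
  orphan_c <- setdiff(labels, qlabels)
  orphan_q <- setdiff(qlabels, labels)
  if (length(orphan_c))
    stop_validation("column 'cost_", orphan_c[1L],
                    "' has no matching 'qaly_", orphan_c[1L], "'")
  if (length(orphan_q))
    stop_validation("column 'qaly_", orphan_q[1L],
                    "' has no matching 'cost_", orphan_q[1L], "'")
  if (anyDuplicated(labels))
    stop_validation("duplicate option labels in header: ",
                    paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (nrow(raw) < 1L)
    stop_validation("no data rows in ", path)
  parse_col <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop_validation("non-numeric or non-finite value in column '", col,
                      "', data row ", bad[1L], ": '", raw[[col]][bad[1L]], "'")
    v
  }
  costs <- vapply(paste0("cost_", labels), parse_col, numeric(nrow(raw)))
  qalys <- vapply(paste0("qaly_", labels), parse_col, numeric(nrow(raw)))
  costs <- matrix(costs, nrow = nrow(raw))
  qalys <- matrix(qalys, nrow = nrow(raw))
  psa_matrix(costs, qalys, labels,
             meta = list(source = path, n_sims = nrow(raw)))
}

#' Write PSA samples to a wide CSV file
#'
#' Emits the paired-column layout accepted by [read_psa_csv()]. Numbers are
#' written with 17 significant digits so every double survives a round trip
#' exactly.
#'
#' @param psa a [psa_matrix()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_psa_csv <- function(psa, path) {
  stopifnot(inherits(psa, "psa_matrix"))
  J <- n_options(psa)
  out <- matrix("", nrow = n_sims(psa), ncol = 2L * J)
  hdr <- character(2L * J)
  for (j in seq_len(J)) {
    hdr[2L * j - 1L] <- paste0("cost_", psa$labels[j])
    hdr[2L * j] <- paste0("qaly_", psa$labels[j])
    out[, 2L * j - 1L] <- num_to_chr(psa$costs[, j])
    out[, 2L * j] <- num_to_chr(psa$qalys[, j])
  }
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop_validation("cannot open '", path, "' for writing: ",
                    conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(paste(hdr, collapse = ","),
               apply(out, 1L, paste, collapse = ",")), con)
  invisible(path)
}

# shortest decimal representation that reads back to the same double
num_to_chr <- function(x) {
  s <- formatC(x, format = "g", digits = 15)
  bad <- as.numeric(s) != x
  if (any(bad)) s[bad] <- formatC(x[bad], format = "g", digits = 17)
  trimws(s)
}

#' Net monetary benefit at a willingness-to-pay threshold
#'
#' Converts the bivariate (cost, QALY) outcome of every simulation into the
#' scalar net monetary benefit \eqn{NB = \lambda Q - C}, where \eqn{\lambda}
#' is the willingness-to-pay threshold in currency per QALY.
#'
#' @param psa a [psa_matrix()].
#' @param lambda willingness-to-pay threshold, a single finite number
#'   \eqn{\ge 0}.
#' @return an \code{nb_matrix}: an \code{n_sims x J} numeric matrix of net
#'   benefits with option labels as column names and attribute \code{lambda}.
#' @examples
#' psa <- psa_matrix(cbind(A = 100, B = 200), cbind(A = 1, B = 2))
#' net_benefit(psa, 100)   # both zero: exact cancellation
#' @export
net_benefit <- function(psa, lambda) {
  stopifnot(inherits(psa, "psa_matrix"))
  check_lambda(lambda)
  nb <- lambda * psa$qalys - psa$costs
  structure(nb, lambda = lambda, class = c("nb_matrix", class(nb)))
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0)
    stop_domain("'lambda' must be a single finite number >= 0")
  invisible(lambda)
}

#' Per-option mean costs and QALYs
#'
#' @param psa a [psa_matrix()].
#' @return a data frame with columns \code{option}, \code{mean_cost},
#'   \code{mean_qaly}, one row per option in input order.
#' @export
mean_outcomes <- function(psa) {
  stopifnot(inherits(psa, "psa_matrix"))
  data.frame(option = psa$labels,
             mean_cost = unname(colMeans(psa$costs)),
             mean_qaly = unname(colMeans(psa$qalys)),
             stringsAsFactors = FALSE)
}
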