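#' Define a synthetic PSA scenario
#'
#' A scenario fixes, for each option, marginal distributions of cost and
#' QALYs (family plus mean and standard deviation), a rank-correlation
#' structure across all \code{2J} cost/QALY dimensions, a simulation count
#' and a mandatory seed. [generate_psa()] turns the scenario into a
#' [psa_matrix()] via a Gaussian copula, so marginals and dependence are
#' controlled independently.
#'
#' Supported marginal families are \code{"normal"}, \code{"lognormal"},
#' \code{"gamma"} and \code{"beta"}; parameters are derived from the
#' requested mean and standard deviation by moment matching (lognormal and
#' gamma require a positive mean; beta requires mean in (0, 1) and variance
#' below \code{mean * (1 - mean)}). A standard deviation of exactly 0 yields
#' a degenerate constant column in any family — used e.g. for a
#' conservative-care option with no initial cost.
#'
#' @param options data frame with one row per option and columns
#'   \code{label}, \code{cost_mean}, \code{cost_sd}, \code{cost_dist},
#'   \code{qaly_mean}, \code{qaly_sd}, \code{qaly_dist}.
#' @param n_sims number of Monte Carlo simulations to draw.
#' @param seed integer seed; mandatory so no scenario depends on global RNG
#'   state.
#' @param correlation optional \code{2J x 2J} Spearman rank-correlation
#'   matrix over the dimensions (cost_1, qaly_1, cost_2, qaly_2, ...);
#'   identity (independence) if omitted. Must be symmetric with unit
#'   diagonal and positive semi-definite.
#' @param lambda optional annotation: the threshold at which the scenario's
#'   documented behaviour (e.g. a ranking paradox) is expected.
#' @param name optional scenario name for provenance.
#' @return an object of class \code{scenario_config}.
#' @seealso [generate_psa()], [paradox_scenario()], [casestudy_scenario()]
#' @export
scenario_config <- function(options, n_sims, seed, correlation = NULL,
                            lambda = NULL, name = NULL) {
  need <- c("label", "cost_mean", "cost_sd", "cost_dist",
            "qaly_mean", "qaly_sd", "qaly_dist")
  options <- as.data.frame(options, stringsAsFactors = FALSE)
  if (!all(need %in% names(options)))
    stop_validation("scenario 'options' needs columns: ",
                    paste(setdiff(need, names(options)), collapse = ", "))
  J <- nrow(options)
  if (J < 2L) stop_validation("a scenario needs at least two options")
  check_labels(as.character(options$label), J)
  if (!is.numeric(n_sims) || length(n_sims) != 1L || n_sims < 1 ||
      n_sims != round(n_sims))
    stop_validation("'n_sims' must be a positive integer")
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed) || seed != round(seed))
    stop_validation("'seed' is mandatory and must be a single integer")
  for (side in c("cost", "qaly")) {
    dist <- as.character(options[[paste0(side, "_dist")]])
    mu <- as.numeric(options[[paste0(side, "_mean")]])
    sd <- as.numeric(options[[paste0(side, "_sd")]])
    if (!all(dist %in% c("normal", "lognormal", "gamma", "beta")))
      stop_validation("unknown ", side, " distribution: ",
                      paste(setdiff(dist, c("normal", "lognormal", "gamma",
                                            "beta")), collapse = ", "))
    if (any(!is.finite(mu)) || any(!is.finite(sd)) || any(sd < 0))
      stop_validation(side, " means must be finite and sds finite and >= 0")
    for (j in seq_len(J))
      if (sd[j] > 0)
        marginal_params(dist[j], mu[j], sd[j],
                        what = paste0(side, " of option ",
                                      options$label[j]))
  }
  D <- 2L * J
  if (is.null(correlation)) correlation <- diag(D)
  correlation <- as.matrix(correlation)
  if (!identical(dim(correlation), c(D, D)))
    stop_validation("'correlation' must be ", D, " x ", D,
                    " (cost and QALY dimension per option)")
  if (any(abs(correlation - t(correlation)) > 1e-10))
    stop_validation("'correlation' must be symmetric")
  if (any(abs(diag(correlation) - 1) > 1e-10))
    stop_validation("'correlation' must have a unit diagonal")
  if (any(abs(correlation) > 1 + 1e-10))
    stop_validation("correlations must lie in [-1, 1]")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_validation("'correlation' is not positive semi-definite ",
                    "(smallest eigenvalue ", signif(min(ev), 4), ")")
  structure(list(options = options, n_sims = as.integer(n_sims),
                 seed = as.integer(seed), correlation = correlation,
                 lambda = lambda, name = name),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("PSA scenario", if (!is.null(x$name)) paste0("'", x$name, "'"),
      ":", nrow(x$options), "options,", x$n_sims, "simulations, seed",
      x$seed, "\n")
  print(x$options, row.names = FALSE)
  if (!is.null(x$lambda)) cat("Reference threshold:", x$lambda, "\n")
  invisible(x)
}

# moment-matched parameters for one marginal family
marginal_params <- function(dist, mu, sd, what = "marginal") {
  switch(dist,
    normal = list(mean = mu, sd = sd),
    lognormal = {
      if (mu <= 0)
        stop_validation(what, ": lognormal requires a positive mean")
      s2 <- log(1 + (sd / mu)^2)
      list(meanlog = log(mu) - s2 / 2, sdlog = sqrt(s2))
    },
    gamma = {
      if (mu <= 0)
        stop_validation(what, ": gamma requires a positive mean")
      list(shape = (mu / sd)^2, rate = mu / sd^2)
    },
    beta = {
      if (mu <= 0 || mu >= 1)
        stop_validation(what, ": beta requires mean in (0, 1)")
      if (sd^2 >= mu * (1 - mu))
        stop_validation(what, ": beta variance must be below mean*(1-mean)")
      nu <- mu * (1 - mu) / sd^2 - 1
      list(shape1 = mu * nu, shape2 = (1 - mu) * nu)
    },
    stop_validation("unknown distribution: ", dist))
}

q_marginal <- function(u, dist, mu, sd, what = "marginal") {
  pr <- marginal_params(dist, mu, sd, what)
  switch(dist,
    normal = stats::qnorm(u, pr$mean, pr$sd),
    lognormal = stats::qlnorm(u, pr$meanlog, pr$sdlog),
    gamma = stats::qgamma(u, shape = pr$shape, rate = pr$rate),
    beta = stats::qbeta(u, pr$shape1, pr$shape2))
}

#' Generate PSA samples from a scenario
#'
#' Draws from a Gaussian copula whose latent correlation reproduces the
#' scenario's target Spearman correlations (via the exact normal-score
#' relation \eqn{\rho = 2 \sin(\pi \rho_S / 6)}), then maps each dimension
#' through the moment-matched quantile function of its marginal family.
#'
#' Determinism contract: the generator seeds R's RNG with
#' \code{set.seed(seed, kind = "Mersenne-Twister", normal.kind =
#' "Inversion")} and restores the caller's RNG state on exit; identical
#' (scenario, seed) pairs produce bit-identical output on any platform
#' running the same R series.
#'
#' @param config a [scenario_config()].
#' @return a [psa_matrix()] whose \code{meta} records the generator, seed,
#'   scenario name and reference threshold.
#' @export
generate_psa <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  op <- config$options
  J <- nrow(op)
  n <- config$n_sims
  # exact Spearman -> Pearson conversion for the normal copula
  latent <- 2 * sin(pi * config$correlation / 6)
  diag(latent) <- 1
  ev <- eigen(latent, symmetric = TRUE)
  evals <- pmax(ev$values, 0)  # guard tiny negatives from the conversion
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  Z <- matrix(stats::rnorm(n * 2L * J), n) %*%
    (ev$vectors %*% (sqrt(evals) * t(ev$vectors)))
  U <- stats::pnorm(Z)
  costs <- matrix(NA_real_, n, J)
  qalys <- matrix(NA_real_, n, J)
  for (j in seq_len(J)) {
    costs[, j] <- draw_dim(U[, 2L * j - 1L], op$cost_dist[j],
                           op$cost_mean[j], op$cost_sd[j],
                           paste0("cost of option ", op$label[j]))
    qalys[, j] <- draw_dim(U[, 2L * j], op$qaly_dist[j],
                           op$qaly_mean[j], op$qaly_sd[j],
                           paste0("QALY of option ", op$label[j]))
  }
  psa_matrix(costs, qalys, as.character(op$label),
             meta = list(generator = "gaussian-copula",
                         name = config$name, seed = config$seed,
                         n_sims = n, lambda = config$lambda))
}

draw_dim <- function(u, dist, mu, sd, what) {
  if (sd == 0) return(rep(mu, length(u)))
  q_marginal(u, dist, mu, sd, what)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Packaged scenario: a dominated option that tops the CEAC
#'
#' A three-option scenario exhibiting the classic ranking paradox: option X
#' is strictly dominated on mean outcomes by option Y, yet at the reference
#' threshold of 20,000/QALY it has the greatest probability of ranking first
#' for net benefit. The mechanism is the documented one — X's net benefit is
#' far more variable than the others' (QALY sd 0.15 vs 0.015) while Y and Z
#' are strongly positively correlated (Spearman 0.8 between their QALYs) and
#' close in mean net benefit, so they split the "X loses" probability mass
#' between them. X also carries the largest probability of ranking last: a
#' "promising but risky" profile.
#'
#' @param n_sims simulation count (default 100,000).
#' @param seed RNG seed.
#' @return a [scenario_config()].
#' @examples
#' psa <- generate_psa(paradox_scenario(n_sims = 5000))
#' ce_frontier(psa)                       # X dominated
#' rank_analysis(psa, 20000)$p[, 1]       # ... yet X tops the CEAC
#' @export
paradox_scenario <- function(n_sims = 100000, seed = 101) {
  op <- data.frame(
    label = c("X", "Y", "Z"),
    cost_mean = c(1200, 1000, 900),
    cost_sd = c(0, 0, 0),
    cost_dist = "normal",
    qaly_mean = c(0.295, 0.300, 0.294),
    qaly_sd = c(0.150, 0.015, 0.015),
    qaly_dist = "normal",
    stringsAsFactors = FALSE)
  R <- diag(6)
  # dims: cost_X, qaly_X, cost_Y, qaly_Y, cost_Z, qaly_Z
  R[4, 6] <- R[6, 4] <- 0.8
  scenario_config(op, n_sims = n_sims, seed = seed, correlation = R,
                  lambda = 20000, name = "paradox")
}

#' Packaged scenario: stylized seven-option appraisal
#'
#' A seven-option scenario qualitatively mimicking a varicose-veins multiple
#' technology appraisal: A is the standard interventional comparator, B
#' conservative care with no initial cost and the lowest QALYs, D a cheap and
#' effective frontier winner, F a high-variance "promising" therapy that is
#' dominated on means yet retains a substantial probability of ranking
#' first, and C, E, G further dominated competitors. QALYs of the similar
#' interventional options A, C, D are strongly positively correlated
#' (Spearman 0.8). At the reference threshold of 20,000/QALY the mean-outcome
#' frontier is B -> D, and the FSD relation leaves F incomparable with C.
#' The configuration is stylized: it reproduces the qualitative structure of
#' such an appraisal, not any particular model's inputs.
#'
#' @param n_sims simulation count (default 10,000).
#' @param seed RNG seed.
#' @return a [scenario_config()].
#' @export
casestudy_scenario <- function(n_sims = 10000, seed = 7) {
  op <- data.frame(
    label = c("A", "B", "C", "D", "E", "F", "G"),
    cost_mean = c(1100, 0, 900, 600, 1300, 1500, 2500),
    cost_sd = c(150, 0, 150, 100, 200, 300, 400),
    cost_dist = c("gamma", "normal", "gamma", "gamma", "gamma", "gamma",
                  "gamma"),
    qaly_mean = c(2.80, 2.50, 2.83, 2.85, 2.65, 2.82, 2.78),
    qaly_sd = c(0.04, 0.05, 0.04, 0.04, 0.05, 0.15, 0.06),
    qaly_dist = "normal",
    stringsAsFactors = FALSE)
  R <- diag(14)
  qdim <- function(j) 2L * j  # qaly dimension of option j
  for (a in c(1L, 3L, 4L)) for (b in c(1L, 3L, 4L))
    if (a != b) R[qdim(a), qdim(b)] <- 0.8
  scenario_config(op, n_sims = n_sims, seed = seed, correlation = R,
                  lambda = 20000, name = "casestudy-like")
}

#' Read / write scenario configuration files
#'
#' Scenarios serialize to YAML (\code{.yaml}/\code{.yml}) or JSON
#' (\code{.json}), chosen by file extension. The file holds the option table
#' as a list of records, the Spearman correlation matrix row by row, and the
#' scalar fields \code{n_sims}, \code{seed}, \code{lambda}, \code{name}.
#'
#' @param path file path ending in \code{.yaml}, \code{.yml} or \code{.json}.
#' @return \code{read_scenario}: a [scenario_config()];
#'   \code{write_scenario}: \code{path}, invisibly.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path))
    stop_validation("file not found: ", path)
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop_validation("unsupported scenario file extension: ", path)
  if (is.null(x$options)) stop_validation("scenario file lacks 'options'")
  op <- do.call(rbind.data.frame,
                c(lapply(x$options, as.data.frame,
                         stringsAsFactors = FALSE),
                  list(stringsAsFactors = FALSE)))
  if (is.data.frame(x$options)) op <- x$options
  corr <- if (!is.null(x$correlation)) {
    m <- x$correlation
    if (is.list(m)) m <- do.call(rbind, lapply(m, unlist))
    as.matrix(m)
  }
  for (f in c("n_sims", "seed"))
    if (is.null(x[[f]])) stop_validation("scenario file lacks '", f, "'")
  scenario_config(op, n_sims = x$n_sims, seed = x$seed, correlation = corr,
                  lambda = x$lambda, name = x$name)
}

#' @rdname read_scenario
#' @param config a [scenario_config()].
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  payload <- list(
    name = config$name,
    n_sims = config$n_sims,
    seed = config$seed,
    lambda = config$lambda,
    options = lapply(seq_len(nrow(config$options)), function(i)
      as.list(config$options[i, ])),
    correlation = lapply(seq_len(nrow(config$correlation)), function(i)
      as.numeric(config$correlation[i, ])))
  payload <- payload[!vapply(payload, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(payload, path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else stop_validation("unsupported scenario file extension: ", path)
  invisible(path)
}
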