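#' Summary statistics of a simulated distribution
#'
#' Three scalar statistics confront a run with an observed presence/absence
#' distribution:
#' \describe{
#'   \item{ss1}{Bernoulli log-likelihood of the observed flags under the
#'     per-basin persistence probabilities,
#'     `sum(log(p + delta))` over presences plus `sum(log(1 - p + delta))`
#'     over absences, with `delta` a small guard (0.001) against
#'     `log(0)`. Larger (closer to 0) is better.}
#'   \item{ss2}{latitude of the northernmost populated basin
#'     (mean terminal recruitment strictly above the 50-juvenile rule);
#'     `NA` when no basin qualifies.}
#'   \item{ss3}{sum over basins of the squared deviation of the mean
#'     first-time spawner age from the target age (5 years); basins without
#'     first-time spawners do not contribute.}
#' }
#'
#' @param p_sust per-basin persistence probabilities in \[0, 1\]
#' @param observed logical presence flags over the same basins
#' @param delta boundary guard constant
#' @return `ss_presence_loglik()`: the log-likelihood value
#' @examples
#' ss_presence_loglik(c(1, 1, 0), c(TRUE, TRUE, FALSE))
#' @export
ss_presence_loglik <- function(p_sust, observed, delta = 0.001) {
  stopifnot(length(p_sust) == length(observed), is.logical(observed),
            all(p_sust >= 0 & p_sust <= 1))
  sum(log(p_sust[observed] + delta)) +
    sum(log(1 - p_sust[!observed] + delta))
}

#' @rdname ss_presence_loglik
#' @param result a [run_simulation()] result
#' @param recruitment_threshold,window_years the populated-basin rule
#' @return `ss_northern_limit()`: a latitude in decimal degrees, or `NA`
#' @export
ss_northern_limit <- function(result, recruitment_threshold = 50,
                              window_years = 10) {
  pop <- populated_basins(result, recruitment_threshold, window_years)
  if (length(pop) == 0) return(NA_real_)
  max(result$latitudes[result$basin_ids %in% pop])
}

#' @rdname ss_presence_loglik
#' @param mean_ages per-basin mean first-time spawner ages (years); `NA`
#'   entries (no first-time spawner) are dropped
#' @param target_age target mean age
#' @return `ss_spawner_age()`: a non-negative sum of squares
#' @export
ss_spawner_age <- function(mean_ages, target_age = 5) {
  ages <- mean_ages[!is.na(mean_ages)]
  sum((ages - target_age)^2)
}

#' @rdname ss_presence_loglik
#' @return `summary_statistics()`: a named list `(ss1, ss2, ss3)`
#' @export
summary_statistics <- function(result, observed, delta = 0.001,
                               recruitment_threshold = 50, window_years = 10,
                               target_age = 5) {
  if (!is.null(names(observed)))
    observed <- observed[result$basin_ids]
  list(
    ss1 = ss_presence_loglik(persistence_probability(result, window_years),
                             observed, delta),
    ss2 = ss_northern_limit(result, recruitment_threshold, window_years),
    ss3 = ss_spawner_age(mean_first_spawner_age(result, window_years),
                         target_age))
}

#' Complete two-level factorial design
#'
#' All `2^k` combinations of the min/max bounds of `k` parameters, each row
#' tagged with `replicates` replicate slots (replication absorbs simulator
#' stochasticity and provides pure-error degrees of freedom in the
#' sensitivity ANOVA). Columns of the coded matrix are orthogonal and
#' balanced.
#'
#' @param bounds named list of `c(min, max)` ranges, e.g.
#'   [parameter_ranges()]
#' @param replicates replicate runs per design row
#' @return an object of class `factorial_design` with elements `values`
#'   (data.frame of parameter values), `coded` (matrix of -1/+1 levels),
#'   `bounds` and `replicates`
#' @examples
#' nrow(factorial_design(parameter_ranges())$values)  # 2^11 = 2048
#' @export
factorial_design <- function(bounds, replicates = 1) {
  stopifnot(is.list(bounds), length(bounds) >= 1, replicates >= 1)
  if (is.null(names(bounds)) || any(names(bounds) == ""))
    stop("bounds must be a named list")
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || !is.numeric(b) || b[1] >= b[2])
      stop("bounds for '", nm, "' must be c(min, max) with min < max")
  }
  k <- length(bounds)
  coded <- as.matrix(expand.grid(rep(list(c(-1, 1)), k),
                                 KEEP.OUT.ATTRS = FALSE))
  colnames(coded) <- names(bounds)
  values <- as.data.frame(coded)
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    values[[nm]] <- ifelse(coded[, nm] < 0, b[1], b[2])
  }
  structure(list(values = values, coded = coded, bounds = bounds,
                 replicates = as.integer(replicates)),
            class = "factorial_design")
}

#' @export
print.factorial_design <- function(x, ...) {
  cat(sprintf("<factorial design: %d parameters, %d rows x %d replicate(s)>\n",
              length(x$bounds), nrow(x$values), x$replicates))
  invisible(x)
}

#' Run a simulator over a factorial design
#'
#' Calls `simulator(params_row, seed)` for every design row and replicate.
#' Replicate seeds derive deterministically from `(seed, row, replicate)`.
#'
#' @param design a [factorial_design()]
#' @param simulator function of a named numeric parameter vector and a seed,
#'   returning a named numeric vector of responses (e.g. summary statistics)
#' @param seed base seed
#' @return list of response matrices (rows x replicates), one per response
#' @export
evaluate_design <- function(design, simulator, seed = 1) {
  stopifnot(inherits(design, "factorial_design"))
  nrows <- nrow(design$values)
  reps <- design$replicates
  out <- NULL
  for (i in seq_len(nrows)) {
    row <- unlist(design$values[i, , drop = FALSE])
    for (r in seq_len(reps)) {
      resp <- unlist(simulator(row, derive_seed(seed, (i - 1L) * reps + r)))
      if (is.null(out))
        out <- lapply(stats::setNames(nm = names(resp)), function(nm)
          matrix(NA_real_, nrows, reps))
      for (nm in names(resp)) out[[nm]][i, r] <- resp[[nm]]
    }
  }
  out
}

#' Factorial-ANOVA sensitivity indices
#'
#' Decomposes the variance of a response observed on a complete two-level
#' factorial design into main-effect and pairwise-interaction shares: the
#' index of parameter i is its ANOVA sum-of-squares share of the total
#' response variance (the design is orthogonal, so shares are well defined),
#' interaction indices likewise, and main + interaction + residual shares
#' sum to 1. Replicates enter as pure-error degrees of freedom. A constant
#' response yields all-zero indices.
#'
#' @param design a [factorial_design()]
#' @param responses numeric vector (one value per design row) or matrix
#'   (rows x replicates)
#' @return an object of class `sensitivity_indices` with elements `main`
#'   (named vector), `interaction` (symmetric matrix), `residual` (scalar)
#' @export
sensitivity_indices <- function(design, responses) {
  stopifnot(inherits(design, "factorial_design"))
  coded <- design$coded
  k <- ncol(coded)
  nrows <- nrow(coded)
  if (is.matrix(responses)) {
    reps <- ncol(responses)
    y <- as.vector(responses)            # column-major: design recycled
    X <- coded[rep(seq_len(nrows), times = reps), , drop = FALSE]
  } else {
    stopifnot(length(responses) == nrows)
    y <- responses
    X <- coded
  }
  if (anyNA(y)) stop("responses contain NA")
  pnames <- colnames(coded)
  fnames <- paste0("f", seq_len(k))     # syntactic factor names for aov
  df <- as.data.frame(lapply(seq_len(k), function(j) factor(X[, j])))
  names(df) <- fnames
  df$y <- y
  main <- stats::setNames(numeric(k), pnames)
  inter <- matrix(0, k, k, dimnames = list(pnames, pnames))
  sst <- sum((y - mean(y))^2)
  if (sst <= 0)
    return(structure(list(main = main, interaction = inter, residual = 0),
                     class = "sensitivity_indices"))
  form <- stats::as.formula(paste("y ~ (", paste(fnames, collapse = "+"),
                                  ")^2"))
  fit <- stats::aov(form, data = df)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  ss <- tab[["Sum Sq"]]
  for (j in seq_len(k)) {
    hit <- terms == fnames[j]
    if (any(hit)) main[j] <- ss[hit] / sst
  }
  for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
    hit <- terms %in% c(paste0(fnames[a], ":", fnames[b]),
                        paste0(fnames[b], ":", fnames[a]))
    if (any(hit)) inter[a, b] <- inter[b, a] <- sum(ss[hit]) / sst
  }
  residual <- max(0, 1 - sum(main) - sum(inter[upper.tri(inter)]))
  structure(list(main = main, interaction = inter, residual = residual),
            class = "sensitivity_indices")
}

#' @export
print.sensitivity_indices <- function(x, ...) {
  cat("<sensitivity indices (variance shares)>\n")
  ord <- order(x$main, decreasing = TRUE)
  for (j in ord) cat(sprintf("  %-16s %.4f\n", names(x$main)[j], x$main[j]))
  cat(sprintf("  pairwise interactions: %.4f, residual: %.4f\n",
              sum(x$interaction[upper.tri(x$interaction)]), x$residual))
  invisible(x)
}

#' Summary-statistic simulator closure
#'
#' Wraps a basin network, climate, parameter set, configuration and observed
#' distribution into a function mapping a named vector of parameter
#' overrides plus a seed to the three summary statistics — the interface
#' consumed by [evaluate_design()] and [abc_calibrate()].
#'
#' @param network,climate,params,config simulator inputs (see
#'   [run_simulation()])
#' @param observed logical presence flags (named by basin id, or in network
#'   order)
#' @param ... passed to [summary_statistics()]
#' @return `function(overrides, seed)` returning `c(ss1, ss2, ss3)`
#' @export
make_summary_simulator <- function(network, climate, params, config,
                                   observed, ...) {
  force(network); force(climate); force(params); force(config)
  force(observed)
  dots <- list(...)
  function(overrides, seed = 1) {
    p <- do.call(species_parameters,
                 modifyList(as.list(unclass(params)),
                            as.list(overrides)))
    cfg <- config
    cfg$seed <- as.integer(seed)
    res <- run_simulation(network, climate, p, cfg)
    unlist(do.call(summary_statistics,
                   c(list(result = res, observed = observed), dots)))
  }
}

#' Simulate an ABC reference table
#'
#' Draws `n_draws` parameter sets from independent uniform priors and runs
#' the simulator once per draw (seeds derive deterministically from the base
#' seed). The table can be re-used for rejection against different observed
#' targets.
#'
#' @param simulator function `(named parameter vector, seed) -> named
#'   statistics`
#' @param priors named list of `c(min, max)` uniform prior ranges
#' @param n_draws number of prior draws
#' @param seed base seed
#' @return an object of class `abc_reference`: a data.frame of parameter
#'   draws and simulated statistics, with attributes `parameters` and
#'   `statistics`
#' @export
abc_reference_table <- function(simulator, priors, n_draws, seed = 1) {
  stopifnot(is.function(simulator), is.list(priors), length(priors) >= 1,
            n_draws >= 1)
  pnames <- names(priors)
  if (is.null(pnames) || any(pnames == ""))
    stop("priors must be a named list")
  set.seed(derive_seed(seed, 0L))
  draws <- vapply(priors, function(b) {
    stopifnot(length(b) == 2, b[1] < b[2])
    stats::runif(n_draws, b[1], b[2])
  }, numeric(n_draws))
  if (n_draws == 1) draws <- matrix(draws, 1, dimnames = list(NULL, pnames))
  stats <- NULL
  for (i in seq_len(n_draws)) {
    s <- unlist(simulator(draws[i, ], derive_seed(seed, i)))
    if (is.null(stats))
      stats <- matrix(NA_real_, n_draws, length(s),
                      dimnames = list(NULL, names(s)))
    stats[i, ] <- s
  }
  out <- cbind(as.data.frame(draws), as.data.frame(stats))
  structure(out, parameters = pnames, statistics = colnames(stats),
            class = c("abc_reference", "data.frame"))
}

#' Rejection-ABC calibration
#'
#' Likelihood-free posterior estimation for a small number of simulator
#' parameters. Parameter sets are drawn from uniform priors (or taken from a
#' precomputed [abc_reference_table()]), the simulator's summary statistics
#' are compared with target values through a scalar discrepancy — the
#' weighted sum of per-statistic absolute deviations, each normalized by its
#' spread (MAD, falling back to the standard deviation) across the prior
#' sample — and the configured quantile of closest draws is accepted. An
#' undefined statistic (e.g. no populated basin, so no northern limit) is
#' assigned the maximal discrepancy observed for that component. For the
#' distribution log-likelihood statistic a target of 0 turns the discrepancy
#' into sign-flipped maximization, matching "maximize ss1, minimize ss3,
#' bring ss2 to its target".
#'
#' @param priors named list of `c(min, max)` uniform prior ranges
#' @param targets named numeric vector/list of target statistic values (the
#'   names select which simulated statistics enter the discrepancy)
#' @param simulator function `(params, seed) -> named statistics`; required
#'   unless `reference` is supplied
#' @param n_draws prior draws (ignored when `reference` is supplied)
#' @param accept_rate accepted quantile of the discrepancy distribution
#' @param weights per-statistic weights on the normalized discrepancies
#'   (default: equal)
#' @param seed base seed
#' @param reference optional precomputed [abc_reference_table()]
#' @return an object of class `abc_result`: accepted draws, their
#'   discrepancies, per-parameter posterior summaries (mean, sd, mode,
#'   quantiles) and the acceptance settings
#' @export
abc_calibrate <- function(priors, targets, simulator = NULL, n_draws = 1000,
                          accept_rate = 0.1, weights = NULL, seed = 1,
                          reference = NULL) {
  if (is.null(reference)) {
    if (is.null(simulator))
      stop("either a simulator or a reference table must be supplied")
    reference <- abc_reference_table(simulator, priors, n_draws, seed)
  }
  pnames <- attr(reference, "parameters")
  snames <- names(targets)
  if (is.null(snames) || !all(snames %in% names(reference)))
    stop("targets must be named after simulated statistics")
  n <- nrow(reference)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(snames)),
                                                   snames)
  d <- matrix(NA_real_, n, length(snames), dimnames = list(NULL, snames))
  for (s in snames) {
    dev <- abs(reference[[s]] - as.numeric(targets[[s]]))
    sc <- stats::mad(dev, na.rm = TRUE)
    if (!is.finite(sc) || sc == 0) sc <- stats::sd(dev, na.rm = TRUE)
    if (!is.finite(sc) || sc == 0) sc <- 1
    dev <- dev / sc
    if (anyNA(dev)) {
      mx <- suppressWarnings(max(dev, na.rm = TRUE))
      dev[is.na(dev)] <- if (is.finite(mx)) mx else 1
    }
    d[, s] <- dev * weights[[s]]
  }
  dist <- rowSums(d)
  n_accept <- max(1L, floor(accept_rate * n))
  if (n_accept > n)
    stop("fewer simulations than requested acceptances")
  ord <- order(dist)
  acc <- ord[seq_len(n_accept)]
  accepted <- reference[acc, , drop = FALSE]
  summaries <- lapply(stats::setNames(nm = pnames), function(pn) {
    x <- accepted[[pn]]
    dens <- stats::density(x)
    c(mean = mean(x), sd = stats::sd(x), mode = dens$x[which.max(dens$y)],
      stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975)))
  })
  structure(list(accepted = accepted, distances = dist[acc],
                 all_distances = dist, summaries = summaries,
                 priors = priors, targets = targets,
                 accept_rate = accept_rate, n_draws = n,
                 n_accepted = n_accept),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf("<ABC result: %d / %d draws accepted (rate %.3f)>\n",
              x$n_accepted, x$n_draws, x$accept_rate))
  for (pn in names(x$summaries)) {
    s <- x$summaries[[pn]]
    cat(sprintf("  %-14s mode %.4g, 95%% CI [%.4g, %.4g]\n",
                pn, s[["mode"]], s[["2.5%"]], s[["97.5%"]]))
  }
  invisible(x)
}

#' Posterior credible interval check
#'
#' Whether every component of `truth` lies inside the central credible
#' interval of the accepted draws.
#'
#' @param result an [abc_calibrate()] result
#' @param truth named numeric vector of true parameter values
#' @param level credibility level of the central interval
#' @return logical scalar
#' @export
abc_contains <- function(result, truth, level = 0.95) {
  stopifnot(inherits(result, "abc_result"))
  a <- (1 - level) / 2
  all(vapply(names(truth), function(pn) {
    q <- stats::quantile(result$accepted[[pn]], c(a, 1 - a))
    truth[[pn]] >= q[1] && truth[[pn]] <= q[2]
  }, logical(1)))
}

#' Sample posterior parameter couples
#'
#' Draws `n` parameter sets (with replacement) from the accepted draws, as
#' used when propagating calibration uncertainty through projections.
#'
#' @param result an [abc_calibrate()] result
#' @param n number of couples
#' @param seed RNG seed
#' @return data.frame of parameter draws
#' @export
abc_posterior_sample <- function(result, n = 100, seed = 1) {
  stopifnot(inherits(result, "abc_result"))
  set.seed(derive_seed(seed, 0L))
  pnames <- names(result$summaries)
  result$accepted[sample.int(nrow(result$accepted), n, replace = TRUE),
                  pnames, drop = FALSE]
}
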