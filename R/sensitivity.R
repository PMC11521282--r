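#' Deterministic strategy evaluator bound to a configuration
#'
#' Returns a closure mapping a named parameter vector to the three-strategy
#' outcome table. The default backend is the cohort expectation, which is
#' noise-free and therefore suitable for tornado diagrams and threshold
#' searches; a microsimulation backend (common master seed across calls,
#' i.e. common random numbers) is available for checking.
#'
#' @param config A [sim_config()].
#' @param lt A `life_table`.
#' @param method `"cohort"` or `"microsim"`.
#' @return A function `f(v)` returning a tibble `strategy`, `cost`, `qaly`.
#' @export
make_evaluator <- function(config, lt, method = c("cohort", "microsim")) {
  method <- match.arg(method)
  function(v) evaluate_strategies(config, v, lt, method = method)
}

.pair_icer <- function(res, comparison, tol = 1e-6) {
  a <- res[res$strategy == comparison[1], ]
  b <- res[res$strategy == comparison[2], ]
  icer(a$cost, a$qaly, b$cost, b$qaly, tol = tol)
}

#' One-way sensitivity analysis for a single parameter
#'
#' Re-evaluates the pairwise ICER with one parameter set to its low and to
#' its high value, all others at base case. Degenerate increments are
#' reported as flags rather than numbers. Parameter values at which the
#' ICER crosses the willingness-to-pay threshold inside the range are
#' located by [find_threshold()].
#'
#' @param params A `cea_parameters` object.
#' @param name Parameter name (a row of `params$table`).
#' @param comparison Character pair `c(strategy, comparator)`, e.g.
#'   `c("SB_THA", "BHA")`.
#' @param config A [sim_config()]; `config$wtp` is the threshold used.
#' @param lt A `life_table`.
#' @param low,high Range endpoints (default: the parameter's range).
#' @param evaluator Optional evaluator closure (default cohort).
#' @return A one-row tibble: `parameter`, `icer_low`, `icer_high`,
#'   `flag_low`, `flag_high`, `span`, and a list column `thresholds`.
#' @export
one_way_sa <- function(params, name, comparison, config, lt,
                       low = NULL, high = NULL, evaluator = NULL) {
  tb <- params$table
  row <- tb[tb$name == name, ]
  if (nrow(row) != 1) stop("unknown parameter: ", name)
  if (is.null(low)) low <- row$low
  if (is.null(high)) high <- row$high
  if (low > high) stop("low > high for parameter ", name)
  if (is.null(evaluator)) evaluator <- make_evaluator(config, lt)
  v <- param_points(params)
  at <- function(x) {
    v[name] <- x
    .pair_icer(evaluator(v), comparison)
  }
  r_lo <- at(low)
  r_hi <- at(high)
  vals <- c(r_lo$value, r_hi$value)
  span <- if (all(!is.na(vals))) abs(diff(vals)) else Inf
  thr <- tryCatch(
    find_threshold(params, name, comparison, config, lt,
                   bracket = c(low, high), evaluator = evaluator),
    no_threshold = function(e) numeric(0))
  tibble::tibble(parameter = name,
                 icer_low = r_lo$value, icer_high = r_hi$value,
                 flag_low = r_lo$flag, flag_high = r_hi$flag,
                 span = span, thresholds = list(thr))
}

#' Tornado analysis over every uncertain parameter
#'
#' Runs [one_way_sa()] for each parameter with a non-degenerate range and
#' sorts the entries by descending ICER span (undefined/dominated ends sort
#' first, as they do on published tornado diagrams).
#'
#' @inheritParams one_way_sa
#' @param parameters Optional character vector restricting the analysis.
#' @return A tibble of one-way entries, widest span first.
#' @export
tornado <- function(params, comparison, config, lt, parameters = NULL) {
  tb <- params$table
  names_ <- if (is.null(parameters)) tb$name[tb$family != "fixed"] else parameters
  evaluator <- make_evaluator(config, lt)
  out <- dplyr::bind_rows(lapply(names_, function(nm) {
    one_way_sa(params, nm, comparison, config, lt, evaluator = evaluator)
  }))
  out[order(-out$span), ]
}

#' Willingness-to-pay threshold of a parameter
#'
#' Finds the parameter value at which the pairwise comparison crosses
#' cost-effectiveness at `config$wtp`, i.e. the root of the incremental net
#' monetary benefit `wtp * dQALY - dCost` on the bracket (equivalent to
#' ICER = WTP while the QALY increment keeps its sign, and well-defined
#' even where the ICER itself blows up). Uses bisection to a relative
#' tolerance of 1e-6 on the parameter after verifying a sign change.
#'
#' @inheritParams one_way_sa
#' @param bracket Numeric pair: search interval for the parameter.
#' @param rel_tol Relative bisection tolerance on the parameter.
#' @return The crossing value. Signals condition `no_threshold` if the
#'   incremental net benefit does not change sign on the bracket.
#' @export
find_threshold <- function(params, name, comparison, config, lt,
                           bracket, rel_tol = 1e-6, evaluator = NULL) {
  stopifnot(length(bracket) == 2, bracket[1] <= bracket[2])
  if (is.null(evaluator)) evaluator <- make_evaluator(config, lt)
  v <- param_points(params)
  inmb <- function(x) {
    v[name] <- x
    res <- evaluator(v)
    a <- res[res$strategy == comparison[1], ]
    b <- res[res$strategy == comparison[2], ]
    config$wtp * (a$qaly - b$qaly) - (a$cost - b$cost)
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- inmb(lo); f_hi <- inmb(hi)
  if (sign(f_lo) == sign(f_hi)) {
    cond <- structure(class = c("no_threshold", "error", "condition"),
                      list(message = paste0("no WTP threshold for ", name,
                                            " in [", lo, ", ", hi, "]"),
                           call = sys.call()))
    stop(cond)
  }
  while (hi - lo > rel_tol * max(1, abs(lo), abs(hi))) {
    mid <- (lo + hi) / 2
    f_mid <- inmb(mid)
    if (f_mid == 0) return(mid)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Probabilistic sensitivity analysis
#'
#' Jointly resamples every uncertain parameter from its assigned
#' distribution (gamma for costs, lognormal for relative risks, normal for
#' disutilities, beta for utilities and probabilities; draws independent
#' across parameters) and evaluates all three strategies on each common
#' draw. Sampled sets whose competing event probabilities exceed 1 in any
#' band are rejected and redrawn, with the rejection count reported.
#'
#' @param params A `cea_parameters` object.
#' @param config A [sim_config()]; `config$seed` seeds the sampling.
#' @param lt A `life_table`.
#' @param n_samples Number of PSA samples (published analysis: 10,000).
#' @param method Evaluator backend per sample, `"cohort"` (default) or
#'   `"microsim"` (the published nested design; far slower).
#' @return A `cea_psa` object: list with `cost` and `qaly` matrices
#'   (`n_samples` x 3, columns in strategy order), the `draws` matrix,
#'   `n_resampled`, and the configuration.
#' @export
run_psa <- function(params, config, lt, n_samples = 1e4,
                    method = c("cohort", "microsim")) {
  method <- match.arg(method)
  stopifnot(n_samples >= 1)
  dists <- parameter_distributions(params)
  uncertain <- names(dists)[vapply(dists, function(d) d$family != "fixed", TRUE)]
  base <- param_points(params)
  set.seed(.strategy_seed(config$seed, "SB_THA") + 17L)
  draws <- matrix(rep(base, each = n_samples), nrow = n_samples,
                  dimnames = list(NULL, names(base)))
  for (nm in uncertain) draws[, nm] <- sample_distribution(dists[[nm]], n_samples)
  feasible <- function(v) {
    !inherits(tryCatch(.check_event_probs(v, config), error = identity), "error")
  }
  n_resampled <- 0L
  for (i in seq_len(n_samples)) {
    while (!feasible(draws[i, ])) {
      n_resampled <- n_resampled + 1L
      for (nm in uncertain) draws[i, nm] <- sample_distribution(dists[[nm]], 1)
    }
  }
  cost <- matrix(NA_real_, n_samples, 3, dimnames = list(NULL, .strategies))
  qaly <- cost
  for (i in seq_len(n_samples)) {
    res <- suppressWarnings(
      evaluate_strategies(config, draws[i, ], lt, method = method))
    cost[i, ] <- res$cost[match(.strategies, res$strategy)]
    qaly[i, ] <- res$qaly[match(.strategies, res$strategy)]
  }
  structure(list(cost = cost, qaly = qaly, draws = draws,
                 n_resampled = n_resampled, config = config),
            class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat("<cea_psa> ", nrow(x$cost), " samples, ", x$n_resampled,
      " infeasible draws resampled\n", sep = "")
  invisible(x)
}

# Winner per PSA sample at one WTP: argmax NMB, ties broken by lower cost,
# then by fixed strategy order.
.psa_winners <- function(psa, wtp) {
  b <- wtp * psa$qaly - psa$cost
  w <- max.col(b, ties.method = "first")
  tie <- w != max.col(b, ties.method = "last")
  if (any(tie)) {
    for (i in which(tie)) {
      cand <- which(b[i, ] == max(b[i, ]))
      cand <- cand[psa$cost[i, cand] == min(psa$cost[i, cand])]
      w[i] <- cand[1]
    }
  }
  w
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability that each strategy is
#' cost-effective: the fraction of PSA samples in which it attains the
#' maximal net monetary benefit. Probabilities sum to one at every WTP.
#'
#' @param psa A `cea_psa` object.
#' @param wtp_grid WTP grid in yen/QALY (default 0 to 20,000,000 in
#'   250,000-yen steps, covering the published curves).
#' @return A tibble `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 2e7, by = 2.5e5)) {
  stopifnot(nrow(psa$cost) >= 1)
  out <- lapply(wtp_grid, function(w) {
    win <- .psa_winners(psa, w)
    tibble::tibble(wtp = w, strategy = .strategies,
                   probability = tabulate(win, 3) / length(win))
  })
  dplyr::bind_rows(out)
}

#' Incremental scatter summary with confidence ellipse
#'
#' Per-sample incremental effectiveness and cost of one strategy against a
#' comparator, the 95% confidence ellipse of the cloud (sample covariance
#' at the chi-square 2-df 0.95 quantile, 5.991), and counts of samples per
#' cost-effectiveness plane quadrant.
#'
#' @param psa A `cea_psa` object (at least 3 samples).
#' @param comparison Character pair `c(strategy, comparator)`.
#' @return A list: `points` (tibble `d_qaly`, `d_cost`), `ellipse` (center,
#'   semi-axis lengths, axis directions; `NULL` with a message if the
#'   covariance is singular), `quadrants` (named counts, NE/NW/SE/SW).
#' @export
scatter_summary <- function(psa, comparison) {
  stopifnot(nrow(psa$cost) >= 3)
  a <- match(comparison[1], .strategies)
  b <- match(comparison[2], .strategies)
  de <- psa$qaly[, a] - psa$qaly[, b]
  dc <- psa$cost[, a] - psa$cost[, b]
  pts <- tibble::tibble(d_qaly = de, d_cost = dc)
  S <- cov(cbind(de, dc))
  ellipse <- NULL
  if (all(is.finite(S)) && det(S) > 0) {
    eg <- eigen(S, symmetric = TRUE)
    ellipse <- list(center = c(d_qaly = mean(de), d_cost = mean(dc)),
                    semi_axes = sqrt(qchisq(0.95, df = 2) * eg$values),
                    directions = eg$vectors)
  } else {
    message("singular incremental covariance; ellipse omitted")
  }
  quadrants <- c(NE = sum(de > 0 & dc > 0), NW = sum(de <= 0 & dc > 0),
                 SE = sum(de > 0 & dc <= 0), SW = sum(de <= 0 & dc <= 0))
  list(points = pts, ellipse = ellipse, quadrants = quadrants)
}
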