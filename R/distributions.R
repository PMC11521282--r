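# MD5 of the shipped parameter fixture; packaged_parameters() refuses to
# load a silently edited file.
.params_fixture_md5 <- "80f4755dba7b2a0d9fc0b9c51f46b00c"

#' Build a sampling distribution for one uncertain parameter
#'
#' Distribution families follow the parameter's role: gamma for costs,
#' lognormal for relative risks, normal for disutilities, and beta for
#' utilities and probabilities. The standard error is recovered from the
#' range as `se = (high - low) / (2 * 1.96)`. Gamma and beta are
#' parameterized by method of moments from `(point, se)`; the normal is
#' `N(point, se)`; the lognormal is centered so its median equals the point
#' estimate, with `sdlog = (log(high) - log(low)) / (2 * 1.96)` (relative
#' risks are reported as point estimate plus a CI that is symmetric on the
#' log scale). A zero standard error degenerates to a fixed value. If the
#' beta moment equations are infeasible (`se^2 >= point * (1 - point)`),
#' a \[0, 1\]-truncated normal is used instead and flagged.
#'
#' @param point,low,high Point estimate and range.
#' @param family One of `"gamma"`, `"lognormal"`, `"normal"`, `"beta"`,
#'   `"fixed"`.
#' @return A `dist_spec` list with elements `family`, `pars` (two shape
#'   parameters, meaning per family) and `point`.
#' @export
build_distribution <- function(point, low, high, family) {
  stopifnot(low <= point, point <= high)
  se <- (high - low) / (2 * 1.96)
  if (se == 0 || family == "fixed") {
    return(structure(list(family = "fixed", pars = c(value = point, unused = 0),
                          point = point), class = "dist_spec"))
  }
  spec <- switch(
    family,
    gamma = {
      stopifnot(point > 0)
      list(family = "gamma",
           pars = c(shape = (point / se)^2, scale = se^2 / point))
    },
    lognormal = {
      stopifnot(point > 0, low > 0)
      list(family = "lognormal",
           pars = c(meanlog = log(point), sdlog = (log(high) - log(low)) / (2 * 1.96)))
    },
    normal = list(family = "normal", pars = c(mean = point, sd = se)),
    beta = {
      if (se^2 >= point * (1 - point)) {
        # moment equations infeasible: fall back to a truncated normal
        list(family = "truncnorm01", pars = c(mean = point, sd = se))
      } else {
        nu <- point * (1 - point) / se^2 - 1
        list(family = "beta", pars = c(shape1 = point * nu, shape2 = (1 - point) * nu))
      }
    },
    stop("unknown distribution family: ", family)
  )
  spec$point <- point
  structure(spec, class = "dist_spec")
}

#' Sample from a distribution specification
#'
#' Beta samples live in \[0, 1\] by construction; the truncated-normal
#' fallback resamples out-of-range draws.
#'
#' @param spec A `dist_spec` from [build_distribution()].
#' @param n Number of samples.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(spec, n) {
  p <- spec$pars
  switch(spec$family,
         fixed = rep(p[["value"]], n),
         gamma = rgamma(n, shape = p[["shape"]], scale = p[["scale"]]),
         lognormal = rlnorm(n, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]]),
         normal = rnorm(n, mean = p[["mean"]], sd = p[["sd"]]),
         beta = rbeta(n, shape1 = p[["shape1"]], shape2 = p[["shape2"]]),
         truncnorm01 = {
           x <- rnorm(n, mean = p[["mean"]], sd = p[["sd"]])
           while (any(bad <- x < 0 | x > 1)) {
             x[bad] <- rnorm(sum(bad), mean = p[["mean"]], sd = p[["sd"]])
           }
           x
         },
         stop("unknown distribution family: ", spec$family))
}

#' Distribution specifications for every parameter of a set
#'
#' @param params A `cea_parameters` object.
#' @return Named list of `dist_spec` objects, one per parameter row.
#' @export
parameter_distributions <- function(params) {
  tb <- params$table
  out <- lapply(seq_len(nrow(tb)), function(i) {
    build_distribution(tb$point[i], tb$low[i], tb$high[i], tb$family[i])
  })
  setNames(out, tb$name)
}
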