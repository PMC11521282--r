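#' Gompertz synthetic life table
#'
#' Generates a single-year life table with annual death probability
#' `q(a) = 1 - exp(-b * exp(c * (a - 65)))`: an exponentially increasing
#' hazard with baseline `b` at age 65 and log-hazard slope `c` per year.
#' Two parameters give a realistic old-age mortality shape with a closed
#' form, which is all the model needs from a life table.
#'
#' @param b Baseline hazard at age 65 (per year, positive).
#' @param c Log-hazard slope (per year of age, non-negative).
#' @param ages Integer ages to tabulate (default 65-100).
#' @param sex Sex label attached to the table.
#' @return A `life_table` object.
#' @examples
#' lt <- gompertz_life_table(0.01, 0.09)
#' mortality(lt, 65) # 1 - exp(-0.01)
#' @export
gompertz_life_table <- function(b, c, ages = 65:100, sex = c("female", "male")) {
  sex <- match.arg(sex)
  stopifnot(b > 0, c >= 0)
  qx <- 1 - exp(-b * exp(c * (ages - 65)))
  if (any(qx >= 1)) stop("hazard reaches certain death before the maximum age")
  life_table(ages, qx, sex = sex)
}

# Approximate Japanese 2022 old-age annual death probabilities, by sex.
# Order-of-magnitude anchors from general demographic knowledge; the
# official abridged-table cell values are not reproduced here.
.japan_anchors <- list(
  female = data.frame(age = c(65, 70, 75, 80, 85, 90, 95, 100),
                      qx = c(0.0040, 0.0063, 0.0107, 0.0195,
                             0.0410, 0.0900, 0.1800, 0.3000)),
  male = data.frame(age = c(65, 70, 75, 80, 85, 90, 95, 100),
                    qx = c(0.0100, 0.0157, 0.0253, 0.0435,
                           0.0800, 0.1450, 0.2400, 0.3600))
)

#' Synthetic Japan-2022-like life table
#'
#' Builds the synthetic stand-in for the 2022 Japanese abridged life table
#' used throughout the package: hazards `-log(1 - qx)` at 5-year anchor
#' ages are interpolated log-linearly to single years of age 65-100. The
#' anchors encode the approximate level and slope of recent Japanese
#' old-age mortality (e.g. female `q(75)` about 0.011, male about 0.025);
#' they are deliberately not the official cell values, which are an
#' external input this package does not bundle.
#'
#' @param sex `"female"` or `"male"`.
#' @return A `life_table` object covering ages 65-100.
#' @export
synthetic_japan_life_table <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  anc <- .japan_anchors[[sex]]
  ages <- seq(min(anc$age), max(anc$age))
  log_h <- approx(anc$age, log(-log(1 - anc$qx)), xout = ages)$y
  life_table(ages, 1 - exp(-exp(log_h)), sex = sex)
}

#' Randomized valid parameter set
#'
#' Draws a complete, validation-passing parameter set for property tests:
#' SB-THA band probabilities in (0, 0.2), relative risks around 1, utilities
#' in (0.3, 1), disutilities in (-0.3, 0), costs in (1e4, 1e7), with
#' 20%-standard-error rule ranges throughout and composite post-revision
#' utilities recomputed from the drawn well-state utility and disutilities.
#'
#' @param seed Integer seed; the same seed reproduces the same set.
#' @param p_max Upper bound for drawn annual probabilities.
#' @return A `cea_parameters` object.
#' @export
random_parameter_set <- function(seed, p_max = 0.2) {
  stopifnot(p_max > 0, p_max <= 0.2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ru <- function(lo, hi, n = 1) runif(n, lo, hi)
  bands <- .band_key
  prob_rows <- do.call(rbind, lapply(c("p_dis_sb", "p_revdis_sb", "p_revnondis_sb"),
                                     function(stub) {
    data.frame(name = paste0(stub, "_", bands),
               point = ru(1e-4, p_max, length(bands)), role = "probability")
  }))
  # keep chained BHA/DM probabilities inside (0, 1): modest relative risks
  rr_rows <- data.frame(
    name = c("rr_dis_dm_sb", "rr_dis_dm_bha", "rr_revdis_bha_dm",
             "rr_revnondis_bha_dm", "rr_revdis_dm_sb", "rr_revnondis_dm_sb"),
    point = ru(0.2, 2, 6), role = "rr")
  du <- ru(-0.3, -0.01, 3)
  du_rows <- data.frame(name = c("du_dis", "du_rtha", "du_rrtha"),
                        point = du, role = "disutility")
  u_well <- ru(0.5, 1, 3)
  u_dm <- u_well[3]
  u_rows <- data.frame(
    name = c("u_well_bha", "u_well_sb", "u_well_dm", "u_well_rtha",
             "u_well_rrtha", "u_dead"),
    point = c(u_well, clamp01(u_dm + du[2]), clamp01(u_dm + du[3]), 0),
    role = "utility")
  cost_rows <- data.frame(
    name = c("c_dislocation", "c_implant_bha", "c_implant_sb", "c_implant_dm",
             "fee_bha", "fee_tha", "fee_rtha", "c_initial_bha",
             "c_initial_tha", "c_well_annual"),
    point = round(ru(1e4, 1e7, 10)), role = "cost")
  tb <- rbind(prob_rows, rr_rows, du_rows, u_rows, cost_rows)
  tb$low <- NA_real_
  tb$high <- NA_real_
  # utilities/disutilities need rule ranges clipped to their support
  rng <- derive_range(tb$point)
  tb$low <- rng$low
  tb$high <- rng$high
  ut <- tb$role %in% c("utility", "probability")
  tb$low[ut] <- pmax(0, tb$low[ut])
  tb$high[ut] <- pmin(1, tb$high[ut])
  dis <- tb$role == "disutility"
  tb$low[dis] <- pmax(-1, tb$low[dis])
  tb$high[dis] <- pmin(0, tb$high[dis])
  tb[tb$name == "u_dead", c("low", "high")] <- 0
  cea_parameters(tb)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
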