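#' @importFrom stats setNames rgamma rlnorm rnorm rbeta runif qnorm sd var cov quantile
#' @importFrom utils read.delim write.table head tail
NULL

# Strategy labels, in fixed display order. SB_THA is the reference arm for
# probability derivation (only DM-referenced relative risks are available).
.strategies <- c("BHA", "SB_THA", "DM_THA")

#' Strategy labels
#'
#' The three modeled surgical strategies for a displaced femoral neck
#' fracture: bipolar hemiarthroplasty (`BHA`), single-bearing total hip
#' arthroplasty (`SB_THA`) and dual-mobility THA (`DM_THA`).
#'
#' @return Character vector of the three strategy labels, in display order.
#' @export
strategies <- function() .strategies

#' Derive a sensitivity range from a point estimate
#'
#' When only a point estimate is available, the model's convention assigns a
#' standard error of 20% of the point estimate and a symmetric 95% interval:
#' `low = point - 1.96 * se`, `high = point + 1.96 * se`.
#'
#' @param point Numeric point estimate(s).
#' @param round_yen If `TRUE`, round the bounds to the nearest yen
#'   (appropriate for monetary parameters).
#' @return A data frame with columns `point`, `low`, `high`.
#' @examples
#' derive_range(220679, round_yen = TRUE) # 134173 .. 307185
#' @export
derive_range <- function(point, round_yen = FALSE) {
  stopifnot(is.numeric(point), all(is.finite(point)))
  se <- 0.2 * abs(point)
  low <- point - 1.96 * se
  high <- point + 1.96 * se
  if (round_yen) {
    low <- round(low)
    high <- round(high)
  }
  data.frame(point = point, low = low, high = high)
}

# Age bands of the transition-probability table: 5-year bands covering 65-89.
.band_lo <- c(65, 70, 75, 80, 85)
.band_hi <- c(69, 74, 79, 84, 89)
.band_key <- c("65_69", "70_74", "75_79", "80_84", "85_89")

#' Age-band index for a given age
#'
#' Transition probabilities are banded in 5-year groups covering ages 65-89.
#' Ages beyond 89 are clamped to the last band (the model is not intended to
#' extrapolate past it, but long synthetic runs must not fail).
#'
#' @param age Age in years (numeric, floored internally).
#' @return Integer band index in 1..5.
#' @export
age_band <- function(age) {
  stopifnot(all(age >= 65))
  pmin(5L, (as.integer(floor(age)) - 65L) %/% 5L + 1L)
}

#' Model parameter set
#'
#' Container for every model input: the age-banded annual transition
#' probabilities of the reference arm (SB-THA), relative risks linking the
#' other arms, health-state utilities, one-cycle disutilities and costs.
#' Each uncertain parameter carries a point estimate, a low/high sensitivity
#' range and a distribution family for probabilistic sensitivity analysis.
#'
#' @param table A data frame with columns `name`, `point`, `low`, `high`,
#'   `role` (one of `probability`, `rr`, `utility`, `disutility`, `cost`,
#'   `fixed`) and optionally `label`. Rows with missing `low`/`high` get the
#'   20%-standard-error rule applied via [derive_range()].
#' @return An object of class `cea_parameters`.
#' @seealso [packaged_parameters()] for the transcribed published inputs,
#'   [random_parameter_set()] for randomized sets used in property tests.
#' @export
cea_parameters <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("name", "point", "low", "high", "role") %in% names(table)))
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (is.null(table$label)) table$label <- table$name
  if (anyDuplicated(table$name)) {
    stop("duplicated parameter names: ",
         paste(unique(table$name[duplicated(table$name)]), collapse = ", "))
  }
  fill <- is.na(table$low) | is.na(table$high)
  if (any(fill)) {
    rng <- derive_range(table$point[fill],
                        round_yen = FALSE)
    money <- table$role[fill] == "cost"
    table$low[fill] <- ifelse(money, round(rng$low), rng$low)
    table$high[fill] <- ifelse(money, round(rng$high), rng$high)
  }
  table$family <- .family_for_role(table$role)
  table$family[table$low == table$high] <- "fixed"
  obj <- structure(list(table = table), class = "cea_parameters")
  validate_parameters(obj)
  obj
}

.family_for_role <- function(role) {
  map <- c(probability = "beta", utility = "beta", rr = "lognormal",
           disutility = "normal", cost = "gamma", fixed = "fixed")
  unknown <- setdiff(unique(role), names(map))
  if (length(unknown)) stop("unknown parameter role: ", paste(unknown, collapse = ", "))
  unname(map[role])
}

#' Validate a parameter set
#'
#' Checks type invariants: probabilities and utilities in \[0, 1\], relative
#' risks positive, disutilities in \[-1, 0\], costs non-negative, and
#' `low <= point <= high` everywhere. Composite utilities (post-revision
#' states) must equal the well-state utility plus the corresponding
#' disutility when all three parameters are present.
#'
#' @param params A `cea_parameters` object.
#' @return Invisibly `TRUE`; stops with an informative message on violation.
#' @export
validate_parameters <- function(params) {
  tb <- params$table
  bad <- function(i, why) {
    if (any(i)) stop("invalid parameter(s) ", paste(tb$name[i], collapse = ", "), ": ", why)
  }
  bad(!is.finite(tb$point) | !is.finite(tb$low) | !is.finite(tb$high), "non-finite value")
  bad(tb$low > tb$point | tb$point > tb$high, "requires low <= point <= high")
  pr <- tb$role %in% c("probability", "utility")
  bad(pr & (tb$low < 0 | tb$high > 1), "probability/utility outside [0, 1]")
  bad(tb$role == "rr" & tb$low <= 0, "relative risk must be positive")
  bad(tb$role == "disutility" & (tb$low < -1 | tb$high > 0), "disutility outside [-1, 0]")
  bad(tb$role == "cost" & tb$low < 0, "negative cost")
  v <- param_points(params)
  comp <- function(target, base, dec) {
    if (all(c(target, base, dec) %in% names(v)) &&
        abs(v[[target]] - clamp01(v[[base]] + v[[dec]])) > 1e-9) {
      stop("composite utility invariant violated for ", target)
    }
  }
  comp("u_well_rtha", "u_well_dm", "du_rtha")
  comp("u_well_rrtha", "u_well_dm", "du_rrtha")
  invisible(TRUE)
}

#' @export
print.cea_parameters <- function(x, ...) {
  tb <- x$table
  cat("<cea_parameters> ", nrow(tb), " parameters (",
      sum(tb$family != "fixed"), " uncertain)\n", sep = "")
  print(tibble::as_tibble(tb), n = 8)
  invisible(x)
}

#' Point estimates as a named vector
#'
#' @param params A `cea_parameters` object.
#' @return Named numeric vector of point estimates, one per parameter.
#' @export
param_points <- function(params) {
  setNames(params$table$point, params$table$name)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Composite post-revision utilities
#'
#' The utilities of the post-revision states are calculated values: the
#' well post-DM-THA utility plus the (negative) one-cycle disutility of the
#' corresponding revision, clamped to \[0, 1\].
#'
#' @param u_well_dm Utility of the well post-DM-THA state.
#' @param du_rtha,du_rrtha Disutilities of first revision and re-revision.
#' @return Named numeric vector with elements `u_well_rtha`, `u_well_rrtha`.
#' @examples
#' composite_utilities(0.870, -0.185, -0.287) # 0.685, 0.583
#' @export
composite_utilities <- function(u_well_dm, du_rtha, du_rrtha) {
  c(u_well_rtha = clamp01(u_well_dm + du_rtha),
    u_well_rrtha = clamp01(u_well_dm + du_rrtha))
}

#' Per-strategy annual transition probabilities for one age band
#'
#' The published probability table reports SB-THA rates only; the other two
#' arms are derived by relative-risk chaining. DM-THA rates are SB-THA rates
#' times the corresponding DM-vs-SB relative risk. No direct BHA-vs-SB ratio
#' is available, so BHA rates are chained through DM-THA:
#' dislocation `p_dis_SB * rr_dis(DM vs SB) / rr_dis(DM vs BHA)`, revisions
#' `p_rev*_SB * rr_rev*(DM vs SB) * rr_rev*(BHA vs DM)`. Results are clamped
#' to \[0, 1\]; clamping from above is reported with a warning since it
#' signals an implausible draw.
#'
#' @param v Named numeric vector of parameter values (see [param_points()]).
#' @param band Integer age-band index (see [age_band()]).
#' @return Named list by strategy, each element a numeric vector with
#'   components `p_dis`, `p_revdis`, `p_revnondis`.
#' @export
derive_strategy_probabilities <- function(v, band) {
  key <- .band_key[band]
  sb <- c(p_dis = v[[paste0("p_dis_sb_", key)]],
          p_revdis = v[[paste0("p_revdis_sb_", key)]],
          p_revnondis = v[[paste0("p_revnondis_sb_", key)]])
  dm <- c(p_dis = sb[["p_dis"]] * v[["rr_dis_dm_sb"]],
          p_revdis = sb[["p_revdis"]] * v[["rr_revdis_dm_sb"]],
          p_revnondis = sb[["p_revnondis"]] * v[["rr_revnondis_dm_sb"]])
  bha <- c(p_dis = sb[["p_dis"]] * v[["rr_dis_dm_sb"]] / v[["rr_dis_dm_bha"]],
           p_revdis = sb[["p_revdis"]] * v[["rr_revdis_dm_sb"]] * v[["rr_revdis_bha_dm"]],
           p_revnondis = sb[["p_revnondis"]] * v[["rr_revnondis_dm_sb"]] *
             v[["rr_revnondis_bha_dm"]])
  out <- list(BHA = bha, SB_THA = sb, DM_THA = dm)
  lapply(out, function(p) {
    if (any(p > 1)) warning("transition probability clamped from above 1")
    clamp01(p)
  })
}

#' Transcribed published model inputs
#'
#' Returns the packaged parameter fixture: a verbatim transcription of the
#' published annual transition probabilities by age group and of the
#' clinical-effectiveness, utility, disutility and cost inputs (2022 yen),
#' including the printed low/high sensitivity ranges. Probability rows, for
#' which no published range exists, get the 20%-standard-error rule applied
#' at load time. The fixture file is checksum-pinned: an accidental edit
#' fails loudly rather than silently changing the model.
#'
#' @return A `cea_parameters` object.
#' @export
packaged_parameters <- function() {
  path <- system.file("extdata", "parameters_fnf_japan.tsv", package = "hipcea")
  if (path == "") stop("packaged parameter fixture not found")
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .params_fixture_md5)) {
    stop("packaged parameter fixture checksum mismatch: expected ",
         .params_fixture_md5, ", got ", sum)
  }
  read_parameters(path)
}

#' Read a parameter file
#'
#' Parameter files are tab-separated text with a header and columns `name`,
#' `label`, `point`, `low`, `high`, `role`; empty `low`/`high` cells mean
#' "derive by the 20%-standard-error rule".
#'
#' @param path Path to a parameter file.
#' @return A `cea_parameters` object.
#' @export
read_parameters <- function(path) {
  tb <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  cea_parameters(tb)
}

#' Write a parameter file
#'
#' @param params A `cea_parameters` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_parameters <- function(params, path) {
  tb <- params$table[, c("name", "label", "point", "low", "high", "role")]
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
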