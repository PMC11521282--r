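# Health-state codes shared by the microsimulation and the cohort evaluator.
.S_WELL <- 1L   # well on the primary implant
.S_RTHA <- 2L   # well after first revision (DM-THA implant)
.S_RRTHA <- 3L  # well after re-revision; no further revisions modeled
.S_DEAD <- 4L

# Per-cycle event codes (at most one event per patient-cycle).
.E_NONE <- 0L
.E_DEATH <- 1L
.E_REDUCTION <- 2L  # first dislocation on current implant, closed/open reduction
.E_REVISION <- 3L   # revision THA (to the R-THA state)
.E_REREVISION <- 4L # re-revision THA (to the RR-THA state)

event_labels <- c("none", "death", "reduction", "revision", "re-revision")

#' Simulation run configuration
#'
#' Collects every knob of a model run. Defaults are the base case: a
#' 75-year-old woman followed for five annual cycles, costs and QALYs both
#' discounted at 2% per year, 100,000 microsimulation trials, and a
#' willingness-to-pay threshold of 5,000,000 yen/QALY.
#'
#' Six switches pin down cycle semantics the model structure leaves open;
#' the defaults are the package's fixed convention (see the methods
#' vignette for how they were chosen):
#' \describe{
#'   \item{`revdis_mode`}{Where the banded "probability of revision
#'     dislocation" acts as a direct-to-revision event. `"r_state_only"`
#'     (default) restricts it to the post-R-THA state, so that on the
#'     primary implant revisions for dislocation arise only from the
#'     tracker's second dislocation; `"all_states"` applies it in every
#'     well state alongside the tracker rule.}
#'   \item{`first_cycle_events`}{Whether dislocation/revision events can
#'     occur in the surgery year (death always can). Default `TRUE`.}
#'   \item{`death_accrual`}{Fraction of the cycle's cost and utility
#'     credited in the cycle a patient dies: `"half"` (default; deaths
#'     happen mid-cycle on average), `"full"` (death takes effect at cycle
#'     end) or `"none"` (death supersedes the whole cycle).}
#'   \item{`revision_year_cost`}{Cost attached to a revision year beyond
#'     the revision fee and DM implant: `"full_initial"` (default) adds the
#'     initial-year THA cost on top of the annual well cost (a revision
#'     restarts an arthroplasty year); `"replace_maintenance"` adds it but
#'     nets out the annual well cost; `"event_only"` adds nothing.}
#'   \item{`revision_event_utility`}{Utility credited in the cycle of a
#'     revision. `"origin_toll"` (default) is the transition-reward
#'     convention: the origin state's utility plus the revision disutility
#'     as a one-cycle toll (for SB/DM-THA this equals the printed composite
#'     0.870 - 0.185), with the destination-state utility applying from the
#'     next cycle. `"composite"` credits the destination-state utility
#'     already in the event cycle; `"additive"` subtracts the one-cycle
#'     disutility on top of that.}
#'   \item{`bha_revision_rates`}{Annual revision probabilities of the BHA
#'     arm: `"shared"` (default) uses the reference SB-THA row; `"chained"`
#'     multiplies through the BHA-vs-DM and DM-vs-SB revision relative
#'     risks, which yields a revision-dislocation rate exceeding BHA's
#'     total dislocation rate and is kept only as a sensitivity variant.}
#' }
#'
#' @param start_age Starting age in years (>= 65).
#' @param sex `"female"` or `"male"`.
#' @param horizon Number of annual cycles (>= 1).
#' @param discount_rate Annual discount rate applied to both costs and
#'   QALYs; the first cycle is undiscounted (factor `1/(1+r)^(t-1)`).
#' @param n_trials Number of microsimulation trials.
#' @param seed Master RNG seed; strategies use derived substreams.
#' @param wtp Willingness-to-pay threshold, yen per QALY.
#' @param revdis_mode,first_cycle_events,death_accrual,revision_year_cost,revision_event_utility,bha_revision_rates
#'   Cycle semantics switches, see Details.
#' @param discount_first_cycle If `TRUE`, discounting starts in cycle 1
#'   (factor `1/(1+r)^t`) instead of cycle 2.
#' @return A `sim_config` list.
#' @export
sim_config <- function(start_age = 75, sex = c("female", "male"), horizon = 5,
                       discount_rate = 0.02, n_trials = 1e5, seed = 1L,
                       wtp = 5e6,
                       revdis_mode = c("r_state_only", "all_states"),
                       first_cycle_events = TRUE,
                       death_accrual = c("half", "full", "none"),
                       revision_year_cost = c("full_initial",
                                              "replace_maintenance",
                                              "event_only"),
                       revision_event_utility = c("origin_toll", "composite",
                                                  "additive"),
                       bha_revision_rates = c("shared", "chained"),
                       discount_first_cycle = FALSE) {
  sex <- match.arg(sex)
  revdis_mode <- match.arg(revdis_mode)
  death_accrual <- match.arg(death_accrual)
  revision_year_cost <- match.arg(revision_year_cost)
  revision_event_utility <- match.arg(revision_event_utility)
  bha_revision_rates <- match.arg(bha_revision_rates)
  stopifnot(start_age >= 65, horizon >= 1, discount_rate >= 0, wtp >= 0,
            n_trials >= 1, seed == floor(seed))
  structure(list(start_age = start_age, sex = sex, horizon = as.integer(horizon),
                 discount_rate = discount_rate, n_trials = as.integer(n_trials),
                 seed = as.integer(seed), wtp = wtp, revdis_mode = revdis_mode,
                 first_cycle_events = isTRUE(first_cycle_events),
                 death_accrual = death_accrual,
                 revision_year_cost = revision_year_cost,
                 revision_event_utility = revision_event_utility,
                 bha_revision_rates = bha_revision_rates,
                 discount_first_cycle = isTRUE(discount_first_cycle)),
            class = "sim_config")
}

# Fraction of a cycle's accrual credited when the patient dies that cycle.
.death_weight <- function(config) {
  switch(config$death_accrual, none = 0, half = 0.5, full = 1)
}

# Cost of a revision event (both R-THA and RR-THA use a DM implant).
.revision_cost <- function(v, config) {
  v[["fee_rtha"]] + v[["c_implant_dm"]] +
    switch(config$revision_year_cost,
           event_only = 0,
           full_initial = v[["c_initial_tha"]],
           replace_maintenance = v[["c_initial_tha"]] - v[["c_well_annual"]])
}

# Per-strategy banded probabilities as the engine uses them.
.engine_probs <- function(v, band, config) {
  pb <- derive_strategy_probabilities(v, band)
  if (config$bha_revision_rates == "shared") {
    pb$BHA[c("p_revdis", "p_revnondis")] <- pb$SB_THA[c("p_revdis", "p_revnondis")]
  }
  pb
}

# Discount factor for cycle t (1-based).
.discount_factor <- function(config, t) {
  shift <- if (config$discount_first_cycle) 0 else 1
  (1 + config$discount_rate)^-(t - shift)
}

# Surgery-year cost bundle: initial-year inpatient costs + implant + fee.
# Replaces the annual maintenance cost in cycle 1.
.initial_bundle <- function(v, strategy) {
  switch(strategy,
         BHA = v[["c_initial_bha"]] + v[["c_implant_bha"]] + v[["fee_bha"]],
         SB_THA = v[["c_initial_tha"]] + v[["c_implant_sb"]] + v[["fee_tha"]],
         DM_THA = v[["c_initial_tha"]] + v[["c_implant_dm"]] + v[["fee_tha"]])
}

# Competing event probabilities (rev_nondis, rev_dis, dislocation) for a
# given health state. In the primary state the implant is the strategy's;
# after revision it is DM-THA. Returns c(e_rn, e_rd, e_dis).
.state_event_probs <- function(probs_by_strategy, strategy, state, config) {
  if (state == .S_RRTHA) return(c(0, 0, 0))
  p <- if (state == .S_WELL) probs_by_strategy[[strategy]] else probs_by_strategy[["DM_THA"]]
  e_rd <- if (state == .S_WELL && config$revdis_mode == "r_state_only") 0 else p[["p_revdis"]]
  c(p[["p_revnondis"]], e_rd, p[["p_dis"]])
}

# Utility of occupying a state for a full uneventful cycle.
.state_utility <- function(v, strategy, state) {
  switch(state,
         switch(strategy, BHA = v[["u_well_bha"]], SB_THA = v[["u_well_sb"]],
                DM_THA = v[["u_well_dm"]]),
         v[["u_well_rtha"]],
         v[["u_well_rrtha"]],
         v[["u_dead"]])
}

# Event-cycle utility of a revision from origin-state utility `u_origin`
# into `dest` (R-THA or RR-THA state).
.revision_utility <- function(v, config, dest, u_origin) {
  du <- if (dest == .S_RTHA) v[["du_rtha"]] else v[["du_rrtha"]]
  u_dest <- if (dest == .S_RTHA) v[["u_well_rtha"]] else v[["u_well_rrtha"]]
  u <- switch(config$revision_event_utility,
              origin_toll = u_origin + du,
              composite = u_dest,
              additive = u_dest + du)
  max(0, u)
}

.check_event_probs <- function(v, config) {
  for (band in seq_along(.band_key)) {
    probs <- .engine_probs(v, band, config)
    for (strat in .strategies) {
      for (state in c(.S_WELL, .S_RTHA)) {
        if (sum(.state_event_probs(probs, strat, state, config)) > 1) {
          stop("competing event probabilities exceed 1 for ", strat,
               ", band ", .band_key[band])
        }
      }
    }
  }
  invisible(TRUE)
}

# Vectorized microsimulation engine: n patients of one strategy, common age
# trajectory, annual cycles. Returns per-trial discounted cost and QALY plus
# an n x horizon matrix of event codes.
.run_engine <- function(v, config, strategy, lt, n) {
  .check_event_probs(v, config)
  state <- rep(.S_WELL, n)
  tracker <- rep(0L, n)
  cost <- numeric(n)
  qaly <- numeric(n)
  events <- matrix(.E_NONE, n, config$horizon)
  rev_cost <- .revision_cost(v, config)
  dw <- .death_weight(config)
  for (t in seq_len(config$horizon)) {
    alive <- which(state != .S_DEAD)
    if (!length(alive)) break
    age <- config$start_age + t - 1
    q <- mortality(lt, age)
    probs <- .engine_probs(v, age_band(age), config)
    df <- .discount_factor(config, t)
    base_cost <- if (t == 1) .initial_bundle(v, strategy) else v[["c_well_annual"]]

    dies <- alive[runif(length(alive)) < q]
    if (length(dies) && dw > 0) {
      # death takes effect at cycle end: (partial) accrual of the cycle's
      # base cost and pre-event state utility, no events
      u_dying <- vapply(state[dies], function(s) .state_utility(v, strategy, s), 0)
      cost[dies] <- cost[dies] + dw * df * base_cost
      qaly[dies] <- qaly[dies] + dw * df * pmax(0, u_dying)
    }
    state[dies] <- .S_DEAD
    events[dies, t] <- .E_DEATH
    live <- setdiff(alive, dies)
    if (!length(live)) next

    cyc_cost <- rep(base_cost, length(live))
    cyc_util <- vapply(state[live], function(s) .state_utility(v, strategy, s), 0)
    if (t > 1 || config$first_cycle_events) {
      u2 <- runif(length(live))
      st0 <- state[live]  # snapshot: a same-cycle revision must not re-enter the loop
      for (s in c(.S_WELL, .S_RTHA)) {
        in_s <- st0 == s
        if (!any(in_s)) next
        e <- .state_event_probs(probs, strategy, s, config)
        dest <- if (s == .S_WELL) .S_RTHA else .S_RRTHA
        rev_ev <- if (s == .S_WELL) .E_REVISION else .E_REREVISION
        direct_rev <- in_s & u2 < e[1] + e[2]
        disloc <- in_s & u2 >= e[1] + e[2] & u2 < sum(e)
        second <- disloc & tracker[live] >= 1L
        first_dis <- disloc & !second
        revised <- direct_rev | second
        if (any(revised)) {
          cyc_cost[revised] <- cyc_cost[revised] + rev_cost
          cyc_util[revised] <- .revision_utility(v, config, dest,
                                                 .state_utility(v, strategy, s))
          state[live[revised]] <- dest
          tracker[live[revised]] <- 0L
          events[live[revised], t] <- rev_ev
        }
        if (any(first_dis)) {
          cyc_cost[first_dis] <- cyc_cost[first_dis] + v[["c_dislocation"]]
          cyc_util[first_dis] <- cyc_util[first_dis] + v[["du_dis"]]
          tracker[live[first_dis]] <- 1L
          events[live[first_dis], t] <- .E_REDUCTION
        }
      }
    }
    cost[live] <- cost[live] + df * cyc_cost
    qaly[live] <- qaly[live] + df * pmax(0, cyc_util)
  }
  list(cost = cost, qaly = qaly, events = events)
}

.strategy_seed <- function(seed, strategy) {
  k <- match(strategy, .strategies)
  as.integer((as.numeric(seed) + 104729 * k) %% .Machine$integer.max)
}

#' Simulate a single patient trajectory
#'
#' One first-order Monte Carlo trial: annual cycles from the surgery year to
#' the horizon, with the surgery cost bundle replacing maintenance in cycle
#' 1 and a dislocation tracker deciding whether a dislocation is reduced
#' (first on the implant) or revised (second).
#'
#' @param config A [sim_config()].
#' @param params A `cea_parameters` object or named parameter vector.
#' @param strategy One of [strategies()].
#' @param lt A `life_table` for the configured sex.
#' @param seed Optional seed for this trial (defaults to the config seed).
#' @return A list with discounted `cost` (yen), `qaly`, and `events`: a
#'   tibble of `(cycle, event)` rows for the non-trivial events.
#' @export
simulate_patient <- function(config, params, strategy, lt, seed = config$seed) {
  v <- .as_param_vector(params)
  set.seed(seed)
  out <- .run_engine(v, config, strategy, lt, 1L)
  ev <- out$events[1, ]
  keep <- ev != .E_NONE
  list(cost = out$cost[1], qaly = out$qaly[1],
       events = tibble::tibble(cycle = which(keep),
                               event = event_labels[ev[keep] + 1L]))
}

.as_param_vector <- function(params) {
  if (inherits(params, "cea_parameters")) param_points(params) else params
}

#' Run the microsimulation for one strategy
#'
#' Simulates `config$n_trials` independent patients and reports means and
#' Monte Carlo standard errors of discounted cost and QALY. Each strategy
#' draws from its own deterministic substream of the master seed, so the
#' three arms are compared on independent randomness and any run is exactly
#' reproducible.
#'
#' @inheritParams simulate_patient
#' @param keep_trials If `TRUE`, attach the per-trial outcome vectors and
#'   the event-code matrix as attributes.
#' @return A one-row tibble: `strategy`, `cost`, `qaly`, `se_cost`,
#'   `se_qaly`, `n_trials`.
#' @export
run_microsimulation <- function(config, params, strategy, lt,
                                keep_trials = FALSE) {
  stopifnot(config$n_trials >= 2)
  v <- .as_param_vector(params)
  set.seed(.strategy_seed(config$seed, strategy))
  out <- .run_engine(v, config, strategy, lt, config$n_trials)
  res <- tibble::tibble(
    strategy = strategy,
    cost = mean(out$cost), qaly = mean(out$qaly),
    se_cost = sd(out$cost) / sqrt(config$n_trials),
    se_qaly = sd(out$qaly) / sqrt(config$n_trials),
    n_trials = config$n_trials)
  if (keep_trials) {
    attr(res, "trials") <- out
  }
  res
}

#' Deterministic cohort expectation
#'
#' Exact expected discounted cost and QALY for one strategy, obtained by
#' propagating state-occupancy probabilities cycle by cycle over the finite
#' state space (health state x dislocation tracker x alive). This is the
#' expected-value counterpart of the microsimulation: the two agree in
#' expectation, which the test suite enforces, and the cohort form is the
#' default evaluator for sensitivity analyses where Monte Carlo noise would
#' obscure thresholds.
#'
#' @inheritParams simulate_patient
#' @return A one-row tibble shaped like [run_microsimulation()]'s, with
#'   zero standard errors.
#' @export
cohort_expectation <- function(config, params, strategy, lt) {
  v <- .as_param_vector(params)
  .check_event_probs(v, config)
  # occupancy: WELL tracker 0 / WELL tracker 1 / R-THA 0 / R-THA 1 / RR-THA / dead
  occ <- c(wp0 = 1, wp1 = 0, rt0 = 0, rt1 = 0, rr = 0, dead = 0)
  rev_cost <- .revision_cost(v, config)
  dw <- .death_weight(config)
  total_cost <- 0
  total_qaly <- 0
  for (t in seq_len(config$horizon)) {
    age <- config$start_age + t - 1
    q <- mortality(lt, age)
    probs <- .engine_probs(v, age_band(age), config)
    df <- .discount_factor(config, t)
    base_cost <- if (t == 1) .initial_bundle(v, strategy) else v[["c_well_annual"]]
    gate <- if (t == 1 && !config$first_cycle_events) 0 else 1
    nxt <- c(wp0 = 0, wp1 = 0, rt0 = 0, rt1 = 0, rr = 0, dead = occ[["dead"]])
    cyc_cost <- 0
    cyc_qaly <- 0
    for (s in c("wp0", "wp1", "rt0", "rt1", "rr")) {
      m <- occ[[s]]
      if (m == 0) next
      health <- switch(s, wp0 = .S_WELL, wp1 = .S_WELL, rt0 = .S_RTHA,
                       rt1 = .S_RTHA, rr = .S_RRTHA)
      # dying mass: (partial) accrual at pre-event state, then absorption
      cyc_cost <- cyc_cost + m * q * dw * base_cost
      cyc_qaly <- cyc_qaly + m * q * dw * max(0, .state_utility(v, strategy, health))
      nxt[["dead"]] <- nxt[["dead"]] + m * q
      m <- m * (1 - q)
      if (m == 0) next
      e <- gate * .state_event_probs(probs, strategy, health, config)
      tracked <- s %in% c("wp1", "rt1")
      p_rev <- e[1] + e[2] + if (tracked) e[3] else 0
      p_red <- if (tracked) 0 else e[3]
      p_none <- 1 - p_rev - p_red
      u_state <- .state_utility(v, strategy, health)
      dest_health <- if (health == .S_WELL) .S_RTHA else .S_RRTHA
      dest <- if (health == .S_WELL) "rt0" else "rr"
      stay <- s
      red_dest <- switch(s, wp0 = "wp1", rt0 = "rt1", s)
      cyc_cost <- cyc_cost + m * (base_cost + p_rev * rev_cost +
                                    p_red * v[["c_dislocation"]])
      u_rev <- if (health == .S_RRTHA) 0 else
        .revision_utility(v, config, dest_health, u_state)
      cyc_qaly <- cyc_qaly + m * (p_none * u_state +
                                    p_red * max(0, u_state + v[["du_dis"]]) +
                                    p_rev * u_rev)
      nxt[[dest]] <- nxt[[dest]] + m * p_rev
      nxt[[red_dest]] <- nxt[[red_dest]] + m * p_red
      nxt[[stay]] <- nxt[[stay]] + m * p_none
    }
    total_cost <- total_cost + df * cyc_cost
    total_qaly <- total_qaly + df * cyc_qaly
    occ <- nxt
  }
  tibble::tibble(strategy = strategy, cost = total_cost, qaly = total_qaly,
                 se_cost = 0, se_qaly = 0, n_trials = 0L)
}

#' Evaluate all three strategies
#'
#' Convenience wrapper running either the deterministic cohort expectation
#' or the microsimulation for every strategy on a common configuration.
#'
#' @inheritParams simulate_patient
#' @param method `"cohort"` (deterministic, default) or `"microsim"`.
#' @return A three-row tibble of per-strategy results, in display order.
#' @export
evaluate_strategies <- function(config, params, lt,
                                method = c("cohort", "microsim")) {
  method <- match.arg(method)
  fn <- if (method == "cohort") cohort_expectation else run_microsimulation
  dplyr::bind_rows(lapply(.strategies, function(s) fn(config, params, s, lt)))
}
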