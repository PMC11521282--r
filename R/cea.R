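#' Incremental cost-effectiveness ratio of two strategies
#'
#' `(cost_a - cost_b) / (qaly_a - qaly_b)` with `b` the comparator. When the
#' QALY increment is below `tol` in absolute value the ratio is reported as
#' `"undefined"` (the tornado's infinity case). Strict dominance is flagged:
#' `"dominated"` when `a` costs at least as much for no more effect,
#' `"dominant"` when `a` costs no more for at least as much effect.
#'
#' @param cost_a,qaly_a Outcomes of the strategy under evaluation.
#' @param cost_b,qaly_b Outcomes of the comparator.
#' @param tol Absolute QALY-increment tolerance below which the ratio is
#'   undefined.
#' @return A list with `value` (yen/QALY, or `NA` when flagged) and `flag`
#'   (`"ok"`, `"dominated"`, `"dominant"` or `"undefined"`).
#' @examples
#' icer(8669497, 4.021, 8326071, 3.792) # ~1,499,677 yen/QALY
#' @export
icer <- function(cost_a, qaly_a, cost_b, qaly_b, tol = 1e-6) {
  dc <- cost_a - cost_b
  de <- qaly_a - qaly_b
  if (de == 0 && dc == 0) return(list(value = NA_real_, flag = "undefined"))
  if (de == 0) {
    # exactly equal effectiveness: the cheaper option dominates
    return(list(value = NA_real_, flag = if (dc > 0) "dominated" else "dominant"))
  }
  if (abs(de) < tol) return(list(value = NA_real_, flag = "undefined"))
  if (dc >= 0 && de < 0) return(list(value = NA_real_, flag = "dominated"))
  if (dc <= 0 && de > 0) return(list(value = NA_real_, flag = "dominant"))
  list(value = dc / de, flag = "ok")
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost`: the strategy with the highest net monetary benefit
#' at a willingness-to-pay value is the cost-effective choice, equivalently
#' to the frontier-ICER decision rule.
#'
#' @param cost Cost in yen.
#' @param qaly Effectiveness in QALYs.
#' @param wtp Willingness-to-pay, yen per QALY.
#' @return Net monetary benefit in yen.
#' @export
nmb <- function(cost, qaly, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * qaly - cost
}

#' Cost-effectiveness frontier with dominance analysis
#'
#' Orders strategies by ascending cost, flags strict dominance (costlier and
#' no more effective than some other strategy), removes extended dominance
#' (a strategy whose incremental ICER exceeds that of the next more
#' effective one), and reports incremental cost, incremental QALYs and ICER
#' along the surviving frontier, on which ICERs are strictly increasing.
#'
#' @param results Data frame with columns `strategy`, `cost`, `qaly` (one
#'   row per strategy, at least two rows).
#' @param tol QALY tolerance passed to [icer()].
#' @return A tibble with columns `strategy`, `cost`, `qaly`, `incr_cost`,
#'   `incr_qaly`, `icer`, `status` (`reference`, `on-frontier`, `dominated`
#'   or `extended-dominated`), ordered by ascending cost.
#' @export
cea_frontier <- function(results, tol = 1e-6) {
  stopifnot(nrow(results) >= 2,
            all(c("strategy", "cost", "qaly") %in% names(results)))
  tb <- results[order(results$cost, results$qaly), c("strategy", "cost", "qaly")]
  tb$incr_cost <- NA_real_
  tb$incr_qaly <- NA_real_
  tb$icer <- NA_real_
  tb$status <- "on-frontier"
  n <- nrow(tb)
  # strict dominance against every other strategy
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (tb$cost[i] >= tb$cost[j] && tb$qaly[i] <= tb$qaly[j] &&
          (tb$cost[i] > tb$cost[j] || tb$qaly[i] < tb$qaly[j])) {
        tb$status[i] <- "dominated"
      }
    }
  }
  # extended dominance: drop strategies breaking ICER monotonicity
  repeat {
    idx <- which(tb$status %in% c("on-frontier", "reference"))
    if (length(idx) < 3) break
    icers <- vapply(seq_along(idx)[-1], function(k) {
      i <- idx[k]; j <- idx[k - 1]
      r <- icer(tb$cost[i], tb$qaly[i], tb$cost[j], tb$qaly[j], tol = tol)
      if (r$flag == "ok") r$value else Inf
    }, 0)
    drop <- which(diff(icers) < 0)
    if (!length(drop)) break
    tb$status[idx[drop[1] + 1]] <- "extended-dominated"
  }
  idx <- which(!tb$status %in% c("dominated", "extended-dominated"))
  tb$status[idx[1]] <- "reference"
  for (k in seq_along(idx)[-1]) {
    i <- idx[k]; j <- idx[k - 1]
    tb$incr_cost[i] <- tb$cost[i] - tb$cost[j]
    tb$incr_qaly[i] <- tb$qaly[i] - tb$qaly[j]
    r <- icer(tb$cost[i], tb$qaly[i], tb$cost[j], tb$qaly[j], tol = tol)
    tb$icer[i] <- r$value
  }
  tibble::as_tibble(tb)
}

#' Cost-effective strategy at a willingness-to-pay value
#'
#' The highest-effect strategy whose frontier ICER does not exceed the
#' willingness-to-pay; ties in net monetary benefit are broken by lower
#' cost, then by fixed strategy order.
#'
#' @param results Per-strategy outcomes (`strategy`, `cost`, `qaly`).
#' @param wtp Willingness-to-pay, yen per QALY.
#' @return The chosen strategy label.
#' @export
wtp_decision <- function(results, wtp) {
  b <- nmb(results$cost, results$qaly, wtp)
  ord <- order(-b, results$cost, match(results$strategy, .strategies))
  results$strategy[ord[1]]
}

#' Convert yen amounts to another currency
#'
#' @param amount_yen Amount(s) in yen.
#' @param rate_per_unit Yen per unit of the target currency (e.g. 162 for
#'   pounds sterling, 131 for US dollars at 2022 average rates).
#' @param digits Rounding digits for the converted amount (default whole
#'   units).
#' @return Converted amount(s).
#' @examples
#' convert_currency(1499440, 162) # about 9256 pounds
#' @export
convert_currency <- function(amount_yen, rate_per_unit, digits = 0) {
  stopifnot(rate_per_unit > 0)
  round(amount_yen / rate_per_unit, digits)
}
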