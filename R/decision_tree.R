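#' Path probabilities of the three-surgery decision tree
#'
#' Each patient undergoes a first surgery; positive margins (probability
#' `p_first`) trigger a second surgery; positive margins again
#' (probability `p_second`) trigger a third and final surgery.
#'
#' @param p_first Probability of positive margins after the first surgery.
#' @param p_second Probability of positive margins after the second surgery.
#' @return Named numeric vector of path probabilities for 1, 2 and
#'   3 total surgeries; always sums to 1.
#' @examples
#' path_distribution(0.3, 0.1)  # 0.70, 0.27, 0.03
#' @export
path_distribution <- function(p_first, p_second) {
  check_prob(p_first, "p_first")
  check_prob(p_second, "p_second")
  c(`1` = 1 - p_first,
    `2` = p_first * (1 - p_second),
    `3` = p_first * p_second)
}

#' Expected number of surgeries per patient
#'
#' Closed form of the decision tree: `1 + p_first * (1 + p_second)`.
#'
#' @inheritParams path_distribution
#' @return Expected surgeries, a number in \[1, 3\].
#' @examples
#' expected_surgeries(0.3, 0.1)  # 1.33 (ST base case)
#' expected_surgeries(0.1, 0.1)  # 1.11 (IFMI base case)
#' @export
expected_surgeries <- function(p_first, p_second) {
  check_prob(p_first, "p_first")
  check_prob(p_second, "p_second")
  1 + p_first * (1 + p_second)
}

#' Imaging-device cost per surgery
#'
#' Amortizes the device purchase price over its life span and annual
#' surgery volume, and adds annual maintenance (a fraction of the price)
#' spread over the same volume:
#' `price / (lifespan * volume) + maintenance_rate * price / volume`.
#'
#' @param price Purchase price, EUR.
#' @param maintenance_rate Annual maintenance as a fraction of the price.
#' @param lifespan Operational life span, years (positive).
#' @param volume Surgeries per year (positive).
#' @return Device cost per surgery, EUR.
#' @examples
#' device_cost_per_surgery(150000, 0.10, 7, 200)  # 182.14
#' @export
device_cost_per_surgery <- function(price, maintenance_rate, lifespan,
                                    volume) {
  if (!(lifespan > 0) || !(volume > 0)) {
    stop("device_cost_per_surgery: lifespan and volume must be positive",
         call. = FALSE)
  }
  if (price < 0 || maintenance_rate < 0) {
    stop("device_cost_per_surgery: price and maintenance_rate must be >= 0",
         call. = FALSE)
  }
  price / (lifespan * volume) + maintenance_rate * price / volume
}

# Per-surgery device cost for a cost_parameters object: the direct value
# when set, otherwise the amortization formula.
device_cost_per_surgery_from <- function(costs) {
  costs$device_cost %||%
    device_cost_per_surgery(costs$device_price, costs$maintenance_rate,
                            costs$device_lifespan, costs$surgeries_per_year)
}

#' Net cost of operating-time changes under IFMI
#'
#' Fluorescence inspection prolongs the first surgery; skipping frozen
#' section analysis (FSA) saves a fraction `s` of the FSA waiting time.
#' The net time difference is valued at the per-minute surgical cost `c`,
#' and a fixed per-procedure FSA saving `F` is subtracted:
#' `(prolongation - s * fsa_duration) * c - F`.
#'
#' @param prolongation Extra operating time, minutes.
#' @param fsa_duration FSA duration, minutes.
#' @param s Staff time saving factor in \[0, 1\].
#' @param c Surgical cost per minute, EUR/min.
#' @param F Fixed saving per avoided FSA procedure, EUR.
#' @return Net time-related cost, EUR (negative = saving).
#' @export
time_delta_cost <- function(prolongation, fsa_duration, s, c, F) {
  if (s < 0 || s > 1) {
    stop("time_delta_cost: 's' must lie in [0, 1]", call. = FALSE)
  }
  if (prolongation < 0 || fsa_duration < 0 || c < 0 || F < 0) {
    stop("time_delta_cost: durations, 'c' and 'F' must be nonnegative",
         call. = FALSE)
  }
  (prolongation - s * fsa_duration) * c - F
}

#' Per-minute surgical cost derived from the cost model
#'
#' The per-surgery lump sum (DRG plus lost productivity) divided by the
#' expected duration of a standard surgery. This is the principled
#' non-calibrated value of the per-minute cost; the calibrated default
#' stored in [cost_parameters()] is numerically close (68.23 vs 68.29
#' EUR/min at base case).
#'
#' @param costs A [cost_parameters()].
#' @return Cost per minute, EUR/min.
#' @export
derive_cost_per_minute <- function(costs) {
  (costs$drg_cost + costs$lost_productivity) / costs$st_duration
}

#' One-time IFMI add-on cost
#'
#' Sum of the cost components charged once per IFMI patient (IFMI is
#' applied during the first surgery only): fluorescent agent, device per
#' surgery, sterile draping, additional staff, and the net
#' operating-time cost from [time_delta_cost()].
#'
#' @param costs A [cost_parameters()].
#' @param cost_per_minute Per-minute surgical cost to use; defaults to the
#'   value stored in `costs` (the calibrated default). Pass
#'   [derive_cost_per_minute()] output to tie it to the DRG and duration
#'   inputs instead.
#' @return Add-on cost, EUR.
#' @examples
#' ifmi_addon_cost(cost_parameters())  # 223.38 at base case
#' @export
ifmi_addon_cost <- function(costs, cost_per_minute = costs$cost_per_minute) {
  costs$agent_cost +
    device_cost_per_surgery_from(costs) +
    costs$draping_cost +
    costs$staff_addon_cost +
    time_delta_cost(costs$prolongation, costs$fsa_duration,
                    costs$staff_time_saving_factor,
                    cost_per_minute, costs$fsa_fixed_saving)
}

#' Expected cost and surgeries of one strategy
#'
#' Every surgery in either arm costs `drg_cost + lost_productivity`; the
#' IFMI arm additionally pays the one-time add-on of
#' [ifmi_addon_cost()]. Expected cost is the per-surgery sum times the
#' expected number of surgeries, plus the add-on for IFMI.
#'
#' @param strategy `"IFMI"` or `"ST"`.
#' @param margins A [margin_model()].
#' @param costs A [cost_parameters()].
#' @param cost_per_minute Per-minute surgical cost; see
#'   [ifmi_addon_cost()].
#' @return An object of class `strategy_result` with elements `strategy`,
#'   `expected_surgeries`, `expected_cost` (full precision) and
#'   `expected_cost_display` (truncated to whole euros, the reporting
#'   convention).
#' @examples
#' expected_cost("ST", margin_model(), cost_parameters())    # 5358 EUR
#' expected_cost("IFMI", margin_model(), cost_parameters())  # 4695 EUR
#' @export
expected_cost <- function(strategy = c("IFMI", "ST"), margins, costs,
                          cost_per_minute = costs$cost_per_minute) {
  strategy <- match.arg(strategy)
  p_first <- if (strategy == "IFMI") margins$p_pos_ifmi else margins$p_pos_st
  n <- expected_surgeries(p_first, margins$p_pos_second)
  cost <- (costs$drg_cost + costs$lost_productivity) * n +
    if (strategy == "IFMI") ifmi_addon_cost(costs, cost_per_minute) else 0
  structure(list(strategy = strategy,
                 expected_surgeries = n,
                 expected_cost = cost,
                 expected_cost_display = floor(cost)),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s: %.4f expected surgeries, %d EUR (exact %.2f)\n",
              x$strategy, x$expected_surgeries, x$expected_cost_display,
              x$expected_cost))
  invisible(x)
}

#' Incremental endpoints, IFMI minus ST
#'
#' Both endpoints are differences of the per-strategy expectations:
#' `delta_surgeries = (p_pos_ifmi - p_pos_st) * (1 + p_pos_second)` and
#' `delta_cost = delta_surgeries * (drg_cost + lost_productivity) +
#' addon`.
#'
#' @inheritParams expected_cost
#' @return An object of class `incremental_result` with elements
#'   `delta_surgeries` and `delta_cost`, plus the two `strategy_result`
#'   objects.
#' @examples
#' incremental(margin_model(), cost_parameters())  # -0.22 surgeries, -663 EUR
#' @export
incremental <- function(margins, costs,
                        cost_per_minute = costs$cost_per_minute) {
  ifmi <- expected_cost("IFMI", margins, costs, cost_per_minute)
  st <- expected_cost("ST", margins, costs, cost_per_minute)
  structure(list(delta_surgeries = ifmi$expected_surgeries -
                   st$expected_surgeries,
                 delta_cost = ifmi$expected_cost - st$expected_cost,
                 ifmi = ifmi, st = st),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("<incremental_result> IFMI - ST: %.4f surgeries, %.2f EUR\n",
              x$delta_surgeries, x$delta_cost))
  invisible(x)
}

#' Strategy results as a data frame
#'
#' @param margins A [margin_model()].
#' @param costs A [cost_parameters()].
#' @return Data frame with columns `strategy`, `expected_surgeries`,
#'   `expected_cost_eur` (truncated euros) and `expected_cost_exact`.
#' @export
strategy_table <- function(margins, costs) {
  rows <- lapply(c("IFMI", "ST"), expected_cost,
                 margins = margins, costs = costs)
  data.frame(strategy = vapply(rows, `[[`, "", "strategy"),
             expected_surgeries = vapply(rows, `[[`, 0, "expected_surgeries"),
             expected_cost_eur = vapply(rows, `[[`, 0,
                                        "expected_cost_display"),
             expected_cost_exact = vapply(rows, `[[`, 0, "expected_cost"))
}

#' Calibrate the per-minute cost and fixed FSA saving
#'
#' The per-minute surgical cost is derived in the source cost model from
#' an unpublished DRG cost matrix; here it is an explicit parameter `c`
#' together with a fixed per-procedure FSA saving `F`. This routine
#' solves the 2x2 linear system that makes the deterministic incremental
#' cost hit two anchor values at two distinct staff time saving factors:
#' `delta_cost(s) = delta_surgeries * (drg + lost_productivity) + A0 +
#' (prolongation - s * fsa_duration) * c - F`, where `A0` collects the
#' agent, device, draping and staff components.
#'
#' The default anchors are the published base-case incremental cost
#' (-663 EUR at `s = 0.64`) and the no-staff-saving scenario
#' (+516 EUR at `s = 0`); with the default margins and costs the solution
#' is `c = 68.2292` EUR/min and `F = 92.05` EUR, which
#' [cost_parameters()] stores as defaults.
#'
#' @param margins A [margin_model()].
#' @param costs A [cost_parameters()] (its `cost_per_minute` and
#'   `fsa_fixed_saving` are ignored).
#' @param anchor_s Two distinct staff time saving factors.
#' @param anchor_delta_cost Incremental costs (EUR) at those factors.
#' @return List with elements `cost_per_minute` and `fsa_fixed_saving`.
#' @examples
#' calibrate_time_cost(margin_model(), cost_parameters())
#' @export
calibrate_time_cost <- function(margins, costs,
                                anchor_s = c(0.64, 0),
                                anchor_delta_cost = c(-663, 516)) {
  stopifnot(length(anchor_s) == 2L, length(anchor_delta_cost) == 2L)
  if (abs(anchor_s[1] - anchor_s[2]) < 1e-12) {
    stop("calibrate_time_cost: anchors must have distinct staff factors",
         call. = FALSE)
  }
  delta_surg <- (margins$p_pos_ifmi - margins$p_pos_st) *
    (1 + margins$p_pos_second)
  a0 <- costs$agent_cost + device_cost_per_surgery_from(costs) +
    costs$draping_cost + costs$staff_addon_cost
  # (prolongation - s_i * fsa) * c - F = anchor_i - delta_surg*(drg+lost) - A0
  lhs <- rbind(c(costs$prolongation - anchor_s[1] * costs$fsa_duration, -1),
               c(costs$prolongation - anchor_s[2] * costs$fsa_duration, -1))
  rhs <- anchor_delta_cost -
    delta_surg * (costs$drg_cost + costs$lost_productivity) - a0
  sol <- solve(lhs, rhs)
  list(cost_per_minute = sol[1], fsa_fixed_saving = sol[2])
}

check_prob <- function(p, name) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(p)
}
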