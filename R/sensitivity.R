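#' Relative-risk sweep of the incremental endpoints
#'
#' Evaluates the incremental endpoints over a grid of relative risks
#' `rr`, setting the first-surgery IFMI positive-margin proportion to
#' `rr * p_pos_st` at each node while holding every other parameter at
#' its base value. Both endpoints are affine in `rr`, so linear
#' interpolation between nodes is exact for the point estimates. When
#' `psa = TRUE`, a seeded PSA is run at each node (seed `seed + node
#' index`) to attach 95% percentile intervals.
#'
#' @param params A [parameter_set()].
#' @param grid Relative risks in \[0, 1\]; default the seven levels
#'   0, 1/6, ..., 1 (IFMI margins 0% to 30% in 5-point steps).
#' @param psa Attach PSA percentile intervals per node?
#' @param n,seed PSA draws and base seed.
#' @return Data frame of class `rr_sweep` with columns `rr`,
#'   `p_pos_ifmi`, `delta_surgeries`, `delta_cost` and, with `psa`,
#'   `ci_surgeries_lower/upper`, `ci_cost_lower/upper`.
#' @examples
#' rr_sweep(parameter_set(), psa = FALSE)
#' @export
rr_sweep <- function(params, grid = seq(0, 1, by = 1 / 6), psa = TRUE,
                     n = params$n_draws, seed = params$seed) {
  if (any(grid < 0 | grid > 1)) {
    stop("rr_sweep: grid values must lie in [0, 1]", call. = FALSE)
  }
  rows <- lapply(seq_along(grid), function(i) {
    p <- set_rr(params, grid[i])
    inc <- incremental(p$margins, p$costs)
    row <- data.frame(rr = grid[i], p_pos_ifmi = p$margins$p_pos_ifmi,
                      delta_surgeries = inc$delta_surgeries,
                      delta_cost = inc$delta_cost)
    if (psa) {
      res <- run_psa(p, n = n, seed = seed + i, mode = "fixed_rr")
      row$ci_surgeries_lower <- res$ci_surgeries[["lower"]]
      row$ci_surgeries_upper <- res$ci_surgeries[["upper"]]
      row$ci_cost_lower <- res$ci_cost[["lower"]]
      row$ci_cost_upper <- res$ci_cost[["upper"]]
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rr_sweep", "data.frame")
  out
}

# Re-point a parameter set at a new relative risk: p_pos_ifmi becomes
# rr * p_pos_st. The IFMI beta spec keeps its standard error where the
# moment fit stays feasible and degenerates to a fixed spec otherwise
# (only relevant in independent mode; fixed_rr never samples it).
set_rr <- function(params, rr) {
  m <- params$margins
  new_p <- rr * m$p_pos_st
  margins <- margin_model(p_pos_st = m$p_pos_st, p_pos_ifmi = new_p,
                          p_pos_second = m$p_pos_second,
                          psa_mode = m$psa_mode)
  specs <- params$psa_specs
  se <- specs$p_pos_ifmi$se %||% 0.018
  specs$p_pos_ifmi <- if (new_p > 0 && new_p < 1 &&
                          se^2 < new_p * (1 - new_p)) {
    dist_spec("beta", mean = new_p, se = se)
  } else {
    dist_spec("fixed", mean = new_p)
  }
  parameter_set(margins = margins, costs = params$costs, psa_specs = specs,
                tornado_fraction = params$tornado_fraction,
                n_draws = params$n_draws, seed = params$seed)
}

#' Interpolate a relative-risk sweep
#'
#' Linear interpolation of every endpoint (and CI bound) column of an
#' [rr_sweep()] between the bracketing grid nodes. Because the point
#' estimates are affine in the relative risk this is exact for them; the
#' interval bounds are approximate.
#'
#' @param sweep An `rr_sweep` data frame.
#' @param rr Relative risk within the grid span.
#' @return One-row data frame with the same columns as `sweep`.
#' @export
interpolate_sweep <- function(sweep, rr) {
  if (length(rr) != 1L || rr < min(sweep$rr) || rr > max(sweep$rr)) {
    stop("interpolate_sweep: 'rr' must lie within the grid span",
         call. = FALSE)
  }
  cols <- setdiff(names(sweep), "rr")
  out <- data.frame(rr = rr)
  for (col in cols) {
    out[[col]] <- stats::approx(sweep$rr, sweep[[col]], xout = rr,
                                ties = "ordered")$y
  }
  out
}

# ---------------------------------------------------------------------------
# Tornado

# Parameters varied one at a time in the tornado analysis.
tornado_parameters <- function() {
  c("p_pos_ifmi", "p_pos_st", "drg_cost", "st_duration", "prolongation",
    "fsa_duration", "staff_time_saving_factor", "staff_addon_cost",
    "agent_cost", "device_cost", "draping_cost", "lost_productivity")
}

# Per-minute cost used in deterministic one-way analyses: the calibrated
# base value rescaled by the ratio of derived per-minute costs, so the
# DRG lump sum, lost productivity and the ST duration propagate into the
# time-valuation term while the base case stays exactly calibrated.
scaled_cost_per_minute <- function(costs, base_costs) {
  base_costs$cost_per_minute *
    derive_cost_per_minute(costs) / derive_cost_per_minute(base_costs)
}

eval_delta_cost <- function(margins, costs, base_costs) {
  incremental(margins, costs,
              cost_per_minute = scaled_cost_per_minute(costs, base_costs)
  )$delta_cost
}

# Substitute one named parameter value into (margins, costs).
substitute_parameter <- function(margins, costs, name, value) {
  margin_fields <- c("p_pos_st", "p_pos_ifmi", "p_pos_second")
  if (name %in% margin_fields) {
    args <- margins[c(margin_fields, "psa_mode")]
    args[[name]] <- value
    list(margins = do.call(margin_model, args), costs = costs)
  } else if (name %in% names(costs)) {
    costs[[name]] <- value
    list(margins = margins, costs = validate_cost_parameters(costs))
  } else {
    stop(sprintf("unknown parameter '%s'", name), call. = FALSE)
  }
}

base_parameter_value <- function(margins, costs, name) {
  if (name %in% c("p_pos_st", "p_pos_ifmi", "p_pos_second")) {
    margins[[name]]
  } else if (name == "device_cost") {
    device_cost_per_surgery_from(costs)
  } else if (name %in% names(costs)) {
    costs[[name]]
  } else {
    stop(sprintf("unknown parameter '%s'", name), call. = FALSE)
  }
}

#' Tornado analysis of the incremental cost
#'
#' One-way deterministic sensitivity analysis: each parameter is set to
#' its mean minus and plus a fixed fraction (default 25%) with all other
#' parameters at base case, and the incremental cost is re-evaluated.
#' Entries are sorted by descending result range; ties break by
#' parameter name. The per-minute surgical cost is rescaled with the
#' varied DRG cost, lost productivity and ST duration (see
#' [derive_cost_per_minute()]), so those parameters influence the
#' time-valuation term as well.
#'
#' @param params A [parameter_set()].
#' @param fraction Relative perturbation (default
#'   `params$tornado_fraction`).
#' @param parameters Character vector of parameters to vary; defaults to
#'   the twelve uncertain model inputs.
#' @return Data frame of class `tornado` with columns `parameter`,
#'   `low_input`, `high_input`, `low_result`, `high_result`, `range`;
#'   attribute `base_result` carries the unperturbed incremental cost.
#' @examples
#' tornado(parameter_set())
#' @export
tornado <- function(params, fraction = params$tornado_fraction,
                    parameters = tornado_parameters()) {
  if (!(fraction >= 0)) {
    stop("tornado: 'fraction' must be nonnegative", call. = FALSE)
  }
  margins <- params$margins
  costs <- params$costs
  base_result <- eval_delta_cost(margins, costs, costs)
  rows <- lapply(parameters, function(nm) {
    base <- base_parameter_value(margins, costs, nm)
    lo <- (1 - fraction) * base
    hi <- (1 + fraction) * base
    lo_mod <- substitute_parameter(margins, costs, nm, lo)
    hi_mod <- substitute_parameter(margins, costs, nm, hi)
    data.frame(parameter = nm, low_input = lo, high_input = hi,
               low_result = eval_delta_cost(lo_mod$margins, lo_mod$costs,
                                            costs),
               high_result = eval_delta_cost(hi_mod$margins, hi_mod$costs,
                                             costs))
  })
  out <- do.call(rbind, rows)
  out$range <- abs(out$high_result - out$low_result)
  out <- out[order(-out$range, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_result") <- base_result
  class(out) <- c("tornado", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Scenarios

#' Named one-way scenario override sets
#'
#' The alternative parameter values explored one at a time: DRG lump sum
#' at its observed low and high levels, a shorter/longer standard
#' surgery, shorter/longer frozen section analysis, a higher agent
#' price, a lower ST positive-margin proportion, and the staff time
#' saving factor at its extremes. Entries with `se`, `min`, `max` also
#' update the corresponding PSA distribution.
#'
#' @return Named list of override lists for [run_scenario()].
#' @export
scenario_presets <- function() {
  list(
    drg_low = list(drg_cost = list(value = 2201, se = 110)),
    drg_high = list(drg_cost = list(value = 5047, se = 252)),
    st_short = list(st_duration = list(value = 35, min = 11, max = 59)),
    st_long = list(st_duration = list(value = 83, min = 59, max = 107)),
    fsa_short = list(fsa_duration = list(value = 13, min = 0, max = 26)),
    fsa_long = list(fsa_duration = list(value = 53, min = 40, max = 66)),
    agent_high = list(agent_cost = list(value = 800, se = 40)),
    p_pos_st_low = list(p_pos_st = list(value = 0.183, se = 0.035)),
    no_staff_saving = list(staff_time_saving_factor = 0),
    full_staff_saving = list(staff_time_saving_factor = 1)
  )
}

#' Run a one-way scenario
#'
#' Applies a set of parameter overrides (scalar values, or lists with
#' `value` plus distribution updates `se` or `min`/`max`), rebuilds a
#' validated parameter set whose PSA specs track the new point
#' estimates, and re-runs the deterministic incremental analysis plus,
#' optionally, the PSA and the relative-risk sweep. Triangular specs
#' overridden without explicit bounds are shifted with their mode. The
#' per-minute surgical cost is rescaled with the overridden DRG cost,
#' lost productivity or ST duration, as in [tornado()].
#'
#' @param params A [parameter_set()].
#' @param overrides Named list of overrides; names must be known margin
#'   or cost parameters. See [scenario_presets()].
#' @param psa Run the PSA under the scenario?
#' @param sweep_grid Optional relative-risk grid for a scenario sweep.
#' @param n,seed PSA draws and seed.
#' @return List of class `scenario_result`: `params` (the overridden
#'   set), `incremental`, and optionally `psa` and `sweep`.
#' @examples
#' run_scenario(parameter_set(),
#'              list(staff_time_saving_factor = 0), psa = FALSE)
#' @export
run_scenario <- function(params, overrides = list(), psa = TRUE,
                         sweep_grid = NULL, n = params$n_draws,
                         seed = params$seed) {
  margins <- params$margins
  costs <- params$costs
  base_costs <- costs
  specs <- params$psa_specs

  for (nm in names(overrides)) {
    ov <- overrides[[nm]]
    value <- if (is.list(ov)) ov$value else ov
    if (is.null(value)) {
      stop(sprintf("run_scenario: override '%s' has no value", nm),
           call. = FALSE)
    }
    mod <- substitute_parameter(margins, costs, nm, value)
    margins <- mod$margins
    costs <- mod$costs
    if (nm %in% names(specs)) {
      specs[[nm]] <- update_spec(specs[[nm]], value,
                                 se = if (is.list(ov)) ov$se,
                                 min = if (is.list(ov)) ov$min,
                                 max = if (is.list(ov)) ov$max)
    }
  }
  # keep derived spec means (e.g. device cost from an overridden price)
  # in step with the new point estimates
  specs$device_cost$mean <- device_cost_per_surgery_from(costs)

  cpm <- scaled_cost_per_minute(costs, base_costs)
  costs$cost_per_minute <- cpm
  out_params <- parameter_set(margins = margins, costs = costs,
                              psa_specs = specs,
                              tornado_fraction = params$tornado_fraction,
                              n_draws = params$n_draws, seed = params$seed)
  out <- list(params = out_params,
              overrides = overrides,
              incremental = incremental(margins, costs))
  if (psa) out$psa <- run_psa(out_params, n = n, seed = seed)
  if (!is.null(sweep_grid)) {
    out$sweep <- rr_sweep(out_params, grid = sweep_grid, psa = psa,
                          n = n, seed = seed)
  }
  class(out) <- "scenario_result"
  out
}

update_spec <- function(spec, value, se = NULL, min = NULL, max = NULL) {
  kind <- spec$kind
  if (kind == "triangular") {
    shift <- value - spec$mean
    dist_spec("triangular", mean = value,
              min = min %||% (spec$min + shift),
              max = max %||% (spec$max + shift))
  } else if (kind %in% c("beta", "gamma")) {
    dist_spec(kind, mean = value, se = se %||% spec$se)
  } else {
    dist_spec("fixed", mean = value)
  }
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> overrides:",
      paste(names(x$overrides), collapse = ", "), "\n")
  print(x$incremental)
  if (!is.null(x$psa)) print(x$psa)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Break-even staff time saving factor

#' Break-even staff time saving factor
#'
#' The incremental cost is strictly decreasing in the staff time saving
#' factor `s` (for a positive per-minute cost). Criterion `"point"`
#' solves `delta_cost(s*) = 0` in closed form from the linear model;
#' criterion `"significance"` finds the smallest `s` at which the 97.5th
#' percentile of the PSA incremental-cost distribution is at or below
#' zero, i.e. where the saving becomes statistically significant, by
#' bisection with a fixed seed per evaluation.
#'
#' @param params A [parameter_set()].
#' @param criterion `"point"` or `"significance"`.
#' @param seed Seed used for every PSA evaluation inside the bisection.
#' @param tol Bisection tolerance on `s` (default 0.005).
#' @param n PSA draws per evaluation.
#' @return List with `s_star`, `criterion`, and `boundary` (`TRUE` when
#'   no sign change exists on \[0, 1\] and a boundary value is reported).
#' @examples
#' threshold_staff_factor(parameter_set(), "point")  # about 0.28
#' @export
threshold_staff_factor <- function(params,
                                   criterion = c("point", "significance"),
                                   seed = params$seed, tol = 0.005,
                                   n = params$n_draws) {
  criterion <- match.arg(criterion)
  if (!(tol > 0)) stop("threshold_staff_factor: 'tol' must be positive",
                       call. = FALSE)
  margins <- params$margins
  costs <- params$costs

  if (criterion == "point") {
    at_s <- function(s) {
      costs$staff_time_saving_factor <- s
      incremental(margins, costs)$delta_cost
    }
    d0 <- at_s(0)
    slope <- costs$fsa_duration * costs$cost_per_minute  # cost drop per unit s
    if (d0 <= 0) {
      return(list(s_star = 0, criterion = criterion, boundary = TRUE))
    }
    s_star <- d0 / slope
    if (s_star > 1) {
      return(list(s_star = 1, criterion = criterion, boundary = TRUE))
    }
    return(list(s_star = s_star, criterion = criterion, boundary = FALSE))
  }

  upper_at <- function(s) {
    sc <- run_scenario(params, list(staff_time_saving_factor = s),
                       psa = TRUE, n = n, seed = seed)
    sc$psa$ci_cost[["upper"]]
  }
  lo <- 0
  hi <- 1
  if (upper_at(0) <= 0) {
    return(list(s_star = 0, criterion = criterion, boundary = TRUE))
  }
  if (upper_at(1) > 0) {
    return(list(s_star = 1, criterion = criterion, boundary = TRUE))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (upper_at(mid) <= 0) hi <- mid else lo <- mid
  }
  list(s_star = (lo + hi) / 2, criterion = criterion, boundary = FALSE)
}
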