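#' Percentile confidence interval
#'
#' Empirical quantiles at `(1 - level)/2` and `1 - (1 - level)/2`, with
#' linear interpolation between order statistics (R quantile type 7).
#'
#' @param draws Nonempty numeric sample.
#' @param level Coverage level in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
percentile_ci <- function(draws, level = 0.95) {
  if (length(draws) == 0L) {
    stop("percentile_ci: empty sample", call. = FALSE)
  }
  if (!(level > 0 && level < 1)) {
    stop("percentile_ci: 'level' must lie in (0, 1)", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  q <- stats::quantile(draws, probs = c(alpha, 1 - alpha), names = FALSE,
                       type = 7)
  c(lower = q[1], upper = q[2])
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of the parameter distributions through the
#' decision tree. Each draw samples every non-fixed parameter from its
#' [dist_spec()]; margin proportions come from beta laws, cost components
#' from gamma laws, durations from triangular laws, and the staff time
#' saving factor stays fixed. In mode `"fixed_rr"` the IFMI proportion is
#' tied to the sampled ST proportion through the base-case relative risk;
#' in mode `"independent"` it is sampled from its own beta law. The
#' second-surgery proportion is sampled once per draw and applied to both
#' arms. The per-minute surgical cost is recomputed per draw as
#' `(drg + lost_productivity) / st_duration` so that it co-varies with
#' the sampled DRG cost and duration, while the fixed FSA saving is held
#' at its point value.
#'
#' @param params A [parameter_set()].
#' @param n Number of draws (default `params$n_draws`).
#' @param seed Seed for the draw stream (default `params$seed`).
#' @param mode `"fixed_rr"` or `"independent"`; defaults to
#'   `params$margins$psa_mode`.
#' @param keep_draws If `TRUE`, retain the draw-level sample matrix.
#' @return An object of class `psa_result` with the sample means and 95%
#'   percentile intervals of incremental surgeries and incremental cost.
#' @examples
#' run_psa(parameter_set(), n = 1000, seed = 1)
#' @export
run_psa <- function(params, n = params$n_draws, seed = params$seed,
                    mode = params$margins$psa_mode, keep_draws = FALSE) {
  if (n < 1) stop("run_psa: 'n' must be at least 1", call. = FALSE)
  mode <- match.arg(mode, c("fixed_rr", "independent"))
  specs <- params$psa_specs
  margins <- params$margins
  costs <- params$costs

  set.seed(seed)
  p_st <- sample_dist(specs$p_pos_st, n)
  p_ifmi <- if (mode == "fixed_rr") {
    margins$rr * p_st
  } else {
    sample_dist(specs$p_pos_ifmi, n)
  }
  p_second <- sample_dist(specs$p_pos_second, n)
  drg <- sample_dist(specs$drg_cost, n)
  lost <- sample_dist(specs$lost_productivity, n)
  agent <- sample_dist(specs$agent_cost, n)
  device <- sample_dist(specs$device_cost, n)
  draping <- sample_dist(specs$draping_cost, n)
  staff_addon <- sample_dist(specs$staff_addon_cost, n)
  st_dur <- sample_dist(specs$st_duration, n)
  prolong <- sample_dist(specs$prolongation, n)
  fsa <- sample_dist(specs$fsa_duration, n)
  s <- sample_dist(specs$staff_time_saving_factor, n)

  cpm <- (drg + lost) / st_dur
  delta_surg <- (p_ifmi - p_st) * (1 + p_second)
  addon <- agent + device + draping + staff_addon +
    (prolong - s * fsa) * cpm - costs$fsa_fixed_saving
  delta_cost <- delta_surg * (drg + lost) + addon

  draws <- data.frame(draw = seq_len(n), p_pos_st = p_st,
                      p_pos_ifmi = p_ifmi, p_pos_second = p_second,
                      drg_cost = drg, lost_productivity = lost,
                      agent_cost = agent, device_cost = device,
                      draping_cost = draping, staff_addon_cost = staff_addon,
                      st_duration = st_dur, prolongation = prolong,
                      fsa_duration = fsa, staff_time_saving_factor = s,
                      cost_per_minute = cpm,
                      delta_surgeries = delta_surg, delta_cost = delta_cost)

  structure(list(n_draws = as.integer(n), seed = as.integer(seed),
                 mode = mode,
                 mean_delta_surgeries = mean(delta_surg),
                 mean_delta_cost = mean(delta_cost),
                 ci_surgeries = percentile_ci(delta_surg),
                 ci_cost = percentile_ci(delta_cost),
                 se_delta_surgeries = stats::sd(delta_surg) / sqrt(n),
                 se_delta_cost = stats::sd(delta_cost) / sqrt(n),
                 draws = if (keep_draws) draws else NULL),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws, seed %d, mode %s\n", x$n_draws,
              x$seed, x$mode))
  cat(sprintf("  incremental surgeries: %.3f [%.3f; %.3f]\n",
              x$mean_delta_surgeries, x$ci_surgeries[["lower"]],
              x$ci_surgeries[["upper"]]))
  cat(sprintf("  incremental cost:      %.1f [%.1f; %.1f] EUR\n",
              x$mean_delta_cost, x$ci_cost[["lower"]],
              x$ci_cost[["upper"]]))
  invisible(x)
}
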