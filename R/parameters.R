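#' Distribution specification for one uncertain parameter
#'
#' A `dist_spec` records the sampling law used for a parameter in the
#' probabilistic sensitivity analysis (PSA). Beta and gamma laws are
#' specified by their mean and standard error and fitted by the method of
#' moments; triangular laws by their mean (the base-case point estimate)
#' and support bounds, with the mode derived as `3 * mean - min - max` so
#' that the analytic mean equals the point estimate (for a symmetric
#' support this is simply the midpoint); `fixed` parameters always return
#' their mean. Every fitted law is mean-matched to its point estimate, a
#' property the linear model relies on: Monte-Carlo means then converge
#' to the deterministic estimates.
#'
#' @param kind One of `"beta"`, `"gamma"`, `"triangular"`, `"fixed"`.
#' @param mean Point estimate, in the parameter's natural units; for
#'   every law this is the analytic mean of the fitted distribution.
#' @param se Standard error (beta and gamma only).
#' @param min,max Support bounds (triangular only).
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("beta", mean = 0.3, se = 0.051)
#' dist_spec("triangular", mean = 59, min = 35, max = 83)
#' @export
dist_spec <- function(kind = c("beta", "gamma", "triangular", "fixed"),
                      mean, se = NULL, min = NULL, max = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean)) {
    stop("dist_spec: 'mean' must be a single finite number", call. = FALSE)
  }
  spec <- structure(list(kind = kind, mean = mean, se = se,
                         min = min, max = max),
                    class = "dist_spec")
  validate_dist_spec(spec)
}

validate_dist_spec <- function(spec) {
  kind <- spec$kind
  mean <- spec$mean
  if (kind == "beta") {
    if (is.null(spec$se) || spec$se < 0) {
      stop("dist_spec: beta requires a nonnegative 'se'", call. = FALSE)
    }
    if (mean <= 0 || mean >= 1) {
      stop("dist_spec: beta requires 0 < mean < 1", call. = FALSE)
    }
    if (spec$se^2 >= mean * (1 - mean)) {
      stop("dist_spec: beta moment matching infeasible, se^2 >= mean*(1-mean)",
           call. = FALSE)
    }
  } else if (kind == "gamma") {
    if (mean <= 0 || is.null(spec$se) || spec$se <= 0) {
      stop("dist_spec: gamma requires mean > 0 and se > 0", call. = FALSE)
    }
  } else if (kind == "triangular") {
    if (is.null(spec$min) || is.null(spec$max)) {
      stop("dist_spec: triangular requires 'min' and 'max'", call. = FALSE)
    }
    if (!(spec$min <= mean && mean <= spec$max && spec$min < spec$max)) {
      stop("dist_spec: triangular requires min <= mean <= max and min < max",
           call. = FALSE)
    }
    mode <- triangular_mode(spec)
    if (mode < spec$min || mode > spec$max) {
      stop(paste0("dist_spec: triangular mean ", mean,
                  " not attainable with support [", spec$min, ", ",
                  spec$max, "]"), call. = FALSE)
    }
  }
  spec
}

#' @export
print.dist_spec <- function(x, ...) {
  detail <- switch(x$kind,
    beta = ,
    gamma = sprintf("mean = %g, se = %g", x$mean, x$se),
    triangular = sprintf("min = %g, mean = %g, mode = %g, max = %g",
                         x$min, x$mean, triangular_mode(x), x$max),
    fixed = sprintf("value = %g", x$mean))
  cat(sprintf("<dist_spec> %s(%s)\n", x$kind, detail))
  invisible(x)
}

#' Moment-matched beta shape parameters
#'
#' Fits a beta distribution to a mean and standard error by the method of
#' moments: `shape1 + shape2 = mean (1 - mean) / se^2 - 1` and
#' `shape1 = mean * (shape1 + shape2)`.
#'
#' @param mean Mean, strictly inside (0, 1).
#' @param se Standard error with `se^2 < mean * (1 - mean)`.
#' @return Named numeric vector `c(shape1, shape2)`.
#' @examples
#' beta_from_mean_se(0.3, 0.051)
#' @export
beta_from_mean_se <- function(mean, se) {
  if (!(mean > 0 && mean < 1)) {
    stop("beta_from_mean_se: mean must lie in (0, 1)", call. = FALSE)
  }
  if (!(se > 0) || se^2 >= mean * (1 - mean)) {
    stop("beta_from_mean_se: need 0 < se^2 < mean*(1-mean)", call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Moment-matched gamma shape and scale
#'
#' `shape = (mean/se)^2`, `scale = se^2/mean`, so that the fitted
#' distribution has exactly the requested mean and standard deviation.
#'
#' @param mean Mean, positive.
#' @param se Standard error, positive.
#' @return Named numeric vector `c(shape, scale)`.
#' @examples
#' gamma_from_mean_se(500, 25)  # shape 400, scale 1.25
#' @export
gamma_from_mean_se <- function(mean, se) {
  if (!(mean > 0) || !(se > 0)) {
    stop("gamma_from_mean_se: mean and se must be positive", call. = FALSE)
  }
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Triangular random deviates
#'
#' Inverse-CDF sampler for the triangular distribution with the given
#' minimum, mode and maximum.
#'
#' @param n Number of draws.
#' @param min,mode,max Support and mode, `min <= mode <= max`, `min < max`.
#' @return Numeric vector of length `n` in `[min, max]`.
#' @export
rtriangular <- function(n, min, mode, max) {
  if (!(min <= mode && mode <= max && min < max)) {
    stop("rtriangular: need min <= mode <= max and min < max", call. = FALSE)
  }
  u <- stats::runif(n)
  fc <- (mode - min) / (max - min)
  lower <- u < fc
  out <- numeric(n)
  out[lower] <- min + sqrt(u[lower] * (max - min) * (mode - min))
  out[!lower] <- max - sqrt((1 - u[!lower]) * (max - min) * (max - mode))
  out
}

#' Sample from a distribution specification
#'
#' Draws `n` deviates from the law described by a [dist_spec()], using the
#' current R random number stream. `fixed` specs return the mean exactly.
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n` within the distribution's support.
#' @export
sample_dist <- function(spec, n = 1L) {
  validate_dist_spec(spec)
  switch(spec$kind,
    fixed = rep(spec$mean, n),
    beta = {
      sh <- beta_from_mean_se(spec$mean, spec$se)
      stats::rbeta(n, sh[["shape1"]], sh[["shape2"]])
    },
    gamma = {
      sh <- gamma_from_mean_se(spec$mean, spec$se)
      stats::rgamma(n, shape = sh[["shape"]], scale = sh[["scale"]])
    },
    triangular = rtriangular(n, spec$min, triangular_mode(spec), spec$max))
}

# Mode of a mean-parameterized triangular spec: mean = (min + mode + max)/3.
triangular_mode <- function(spec) {
  3 * spec$mean - spec$min - spec$max
}

#' Analytic mean and standard deviation of a distribution specification
#'
#' Closed-form moments of the fitted law, used to check moment recovery
#' without sampling. The triangular mean is `(min + mode + max) / 3`.
#'
#' @param spec A `dist_spec`.
#' @return Named numeric vector `c(mean, sd)`.
#' @export
dist_moments <- function(spec) {
  validate_dist_spec(spec)
  switch(spec$kind,
    fixed = c(mean = spec$mean, sd = 0),
    beta = {
      sh <- beta_from_mean_se(spec$mean, spec$se)
      a <- sh[["shape1"]]; b <- sh[["shape2"]]
      c(mean = a / (a + b),
        sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
    },
    gamma = {
      sh <- gamma_from_mean_se(spec$mean, spec$se)
      c(mean = sh[["shape"]] * sh[["scale"]],
        sd = sqrt(sh[["shape"]]) * sh[["scale"]])
    },
    triangular = {
      a <- spec$min; m <- triangular_mode(spec); b <- spec$max
      c(mean = (a + m + b) / 3,
        sd = sqrt((a^2 + m^2 + b^2 - a * m - a * b - m * b) / 18))
    })
}

# ---------------------------------------------------------------------------
# Margin model

#' First- and second-surgery positive-margin model
#'
#' The first surgery leaves positive margins with probability `p_pos_st`
#' under standard techniques (ST) and `p_pos_ifmi` under fluorescence
#' guidance (IFMI); a positive margin triggers re-excision. The second
#' surgery leaves positive margins with probability `p_pos_second` in both
#' arms, and a third surgery is always final. The relative risk
#' `rr = p_pos_ifmi / p_pos_st` is derived, never stored independently.
#'
#' @param p_pos_st Proportion of positive margins after the first ST
#'   surgery (base case 0.3).
#' @param p_pos_ifmi Proportion after the first IFMI surgery (base 0.1).
#' @param p_pos_second Proportion after the second surgery, shared by both
#'   arms (base 0.1).
#' @param psa_mode How the PSA treats the IFMI proportion: `"fixed_rr"`
#'   ties it to the sampled ST proportion through the base-case relative
#'   risk; `"independent"` samples it from its own beta law.
#' @return An object of class `margin_model` with derived element `rr`.
#' @examples
#' margin_model()           # base case, rr = 1/3
#' @export
margin_model <- function(p_pos_st = 0.3, p_pos_ifmi = 0.1,
                         p_pos_second = 0.1,
                         psa_mode = c("fixed_rr", "independent")) {
  psa_mode <- match.arg(psa_mode)
  for (nm in c("p_pos_st", "p_pos_ifmi", "p_pos_second")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("margin_model: '%s' must be a probability in [0, 1]", nm),
           call. = FALSE)
    }
  }
  structure(list(p_pos_st = p_pos_st,
                 p_pos_ifmi = p_pos_ifmi,
                 rr = if (p_pos_st > 0) p_pos_ifmi / p_pos_st else NA_real_,
                 p_pos_second = p_pos_second,
                 psa_mode = psa_mode),
            class = "margin_model")
}

# ---------------------------------------------------------------------------
# Cost parameters

# Default per-minute surgical cost and fixed frozen-section saving.
# Both are calibrated so that the deterministic model reproduces the two
# published incremental-cost anchors (-663 EUR at staff factor 0.64 and
# +516 EUR at factor 0) simultaneously; see calibrate_time_cost().
.default_cost_per_minute <- 68.22916666666667   # = 1179 / 17.28
.default_fsa_fixed_saving <- 92.05452380952381

#' Itemized cost parameters of the surgical cost model
#'
#' Per-surgery and per-IFMI-application cost components. Every surgery in
#' either arm costs `drg_cost + lost_productivity`. The one-time IFMI
#' add-on combines the fluorescent agent, the imaging device (amortized
#' per surgery), sterile draping, additional staff, and the net cost of
#' operating-time changes: the fluorescence inspection prolongs surgery by
#' `prolongation` minutes while skipping frozen section analysis (FSA)
#' saves `staff_time_saving_factor * fsa_duration` minutes of staff time,
#' the difference valued at `cost_per_minute`, less a fixed per-procedure
#' FSA saving `fsa_fixed_saving`.
#'
#' @param drg_cost DRG lump sum per surgery, EUR.
#' @param lost_productivity Indirect cost per surgery episode, EUR
#'   (14 working days lost are already folded in).
#' @param agent_cost Fluorescent agent (Bevacizumab-IRDye800CW) per IFMI
#'   application, EUR.
#' @param device_price Purchase price of the imaging system, EUR.
#' @param maintenance_rate Annual maintenance, fraction of the price.
#' @param device_lifespan Operational life span, years.
#' @param surgeries_per_year Breast-conserving surgeries per year over
#'   which the device is amortized.
#' @param device_cost Optional direct per-surgery device cost, EUR; when
#'   `NULL` (default) it is derived from the amortization inputs.
#' @param draping_cost Sterile draping per IFMI application, EUR.
#' @param staff_addon_cost Additional staff per IFMI application, EUR.
#' @param st_duration Duration of a standard surgery, minutes.
#' @param prolongation Extra operating time due to IFMI, minutes.
#' @param fsa_duration Duration of frozen section analysis, minutes.
#' @param staff_time_saving_factor Fraction in \[0, 1\] of FSA waiting time
#'   whose staff cost is actually saved when FSA is skipped.
#' @param cost_per_minute Surgical cost per minute, EUR/min.
#' @param fsa_fixed_saving Fixed saving per avoided FSA procedure, EUR.
#' @param working_days_lost Working days lost per surgery episode
#'   (informational; already reflected in `lost_productivity`).
#' @return An object of class `cost_parameters`.
#' @examples
#' cost_parameters()
#' @export
cost_parameters <- function(drg_cost = 3508,
                            lost_productivity = 521,
                            agent_cost = 500,
                            device_price = 150000,
                            maintenance_rate = 0.10,
                            device_lifespan = 7,
                            surgeries_per_year = 200,
                            device_cost = NULL,
                            draping_cost = 23,
                            staff_addon_cost = 107,
                            st_duration = 59,
                            prolongation = 10,
                            fsa_duration = 27,
                            staff_time_saving_factor = 0.64,
                            cost_per_minute = .default_cost_per_minute,
                            fsa_fixed_saving = .default_fsa_fixed_saving,
                            working_days_lost = 14) {
  costs <- structure(
    list(drg_cost = drg_cost, lost_productivity = lost_productivity,
         agent_cost = agent_cost, device_price = device_price,
         maintenance_rate = maintenance_rate,
         device_lifespan = device_lifespan,
         surgeries_per_year = surgeries_per_year,
         device_cost = device_cost,
         draping_cost = draping_cost, staff_addon_cost = staff_addon_cost,
         st_duration = st_duration, prolongation = prolongation,
         fsa_duration = fsa_duration,
         staff_time_saving_factor = staff_time_saving_factor,
         cost_per_minute = cost_per_minute,
         fsa_fixed_saving = fsa_fixed_saving,
         working_days_lost = working_days_lost),
    class = "cost_parameters")
  validate_cost_parameters(costs)
}

validate_cost_parameters <- function(costs) {
  monetary <- c("drg_cost", "lost_productivity", "agent_cost",
                "device_price", "draping_cost", "staff_addon_cost",
                "cost_per_minute", "fsa_fixed_saving")
  for (nm in monetary) {
    v <- costs[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop(sprintf("cost_parameters: '%s' must be a nonnegative number", nm),
           call. = FALSE)
    }
  }
  for (nm in c("st_duration", "prolongation", "fsa_duration",
               "device_lifespan", "surgeries_per_year")) {
    if (!(costs[[nm]] > 0)) {
      stop(sprintf("cost_parameters: '%s' must be positive", nm),
           call. = FALSE)
    }
  }
  s <- costs$staff_time_saving_factor
  if (!is.numeric(s) || is.na(s) || s < 0 || s > 1) {
    stop("cost_parameters: 'staff_time_saving_factor' must lie in [0, 1]",
         call. = FALSE)
  }
  if (!is.null(costs$device_cost) && costs$device_cost < 0) {
    stop("cost_parameters: 'device_cost' must be a nonnegative number",
         call. = FALSE)
  }
  costs
}

# ---------------------------------------------------------------------------
# Parameter set

#' Default PSA distribution specifications
#'
#' One [dist_spec()] per uncertain parameter: beta laws for the margin
#' proportions, gamma laws for the cost components, triangular laws for
#' the three durations, and a fixed spec for the staff time saving factor
#' (held constant in the PSA). Every mean equals the corresponding point
#' estimate in the supplied `margins` and `costs`.
#'
#' @param margins A [margin_model()].
#' @param costs A [cost_parameters()].
#' @return Named list of `dist_spec` objects.
#' @export
default_psa_specs <- function(margins = margin_model(),
                              costs = cost_parameters()) {
  # a proportion at the edge of [0, 1] cannot carry a beta law; it is
  # held fixed instead (the tree itself is still well defined there)
  beta_or_fixed <- function(mean, se) {
    if (mean > 0 && mean < 1 && se^2 < mean * (1 - mean)) {
      dist_spec("beta", mean = mean, se = se)
    } else {
      dist_spec("fixed", mean = mean)
    }
  }
  list(
    p_pos_st = beta_or_fixed(margins$p_pos_st, 0.051),
    p_pos_ifmi = beta_or_fixed(margins$p_pos_ifmi, 0.018),
    p_pos_second = beta_or_fixed(margins$p_pos_second, 0.018),
    drg_cost = dist_spec("gamma", mean = costs$drg_cost, se = 175),
    lost_productivity = dist_spec("gamma", mean = costs$lost_productivity,
                                  se = 52),
    agent_cost = dist_spec("gamma", mean = costs$agent_cost, se = 25),
    device_cost = dist_spec("gamma", mean = device_cost_per_surgery_from(costs),
                            se = 18),
    draping_cost = dist_spec("gamma", mean = costs$draping_cost, se = 2),
    staff_addon_cost = dist_spec("gamma", mean = costs$staff_addon_cost,
                                 se = 5),
    # triangular supports are the base-case ranges, translated with the
    # point estimate when it differs from the base case
    st_duration = dist_spec("triangular", mean = costs$st_duration,
                            min = costs$st_duration - 24,
                            max = costs$st_duration + 24),
    prolongation = dist_spec("triangular", mean = costs$prolongation,
                             min = costs$prolongation - 5,
                             max = costs$prolongation + 5),
    fsa_duration = dist_spec("triangular", mean = costs$fsa_duration,
                             min = costs$fsa_duration - 14,
                             max = costs$fsa_duration + 26),
    staff_time_saving_factor = dist_spec("fixed",
                                         mean = costs$staff_time_saving_factor)
  )
}

#' Full model parameterization
#'
#' Bundles the margin model, the cost parameters, the PSA distribution
#' specifications and the run settings into a single validated object.
#'
#' @param margins A [margin_model()].
#' @param costs A [cost_parameters()].
#' @param psa_specs Named list of [dist_spec()] objects; defaults to
#'   [default_psa_specs()] of `margins` and `costs`.
#' @param tornado_fraction Relative perturbation for the tornado analysis
#'   (default 0.25, i.e. inputs at 75% and 125% of the mean).
#' @param n_draws Monte-Carlo draws for the PSA (default 10000).
#' @param seed Master seed.
#' @return An object of class `param_set`.
#' @examples
#' params <- parameter_set()
#' params$margins$rr   # base-case relative risk, 1/3
#' @export
parameter_set <- function(margins = margin_model(),
                          costs = cost_parameters(),
                          psa_specs = default_psa_specs(margins, costs),
                          tornado_fraction = 0.25,
                          n_draws = 10000L,
                          seed = 1L) {
  if (!(tornado_fraction >= 0)) {
    stop("parameter_set: 'tornado_fraction' must be nonnegative",
         call. = FALSE)
  }
  if (!(n_draws >= 1)) {
    stop("parameter_set: 'n_draws' must be at least 1", call. = FALSE)
  }
  params <- structure(list(margins = margins, costs = costs,
                           psa_specs = psa_specs,
                           tornado_fraction = tornado_fraction,
                           n_draws = as.integer(n_draws),
                           seed = as.integer(seed)),
                      class = "param_set")
  validate_param_set(params)
}

validate_param_set <- function(params) {
  if (!inherits(params$margins, "margin_model")) {
    stop("param_set: 'margins' must be a margin_model", call. = FALSE)
  }
  if (!inherits(params$costs, "cost_parameters")) {
    stop("param_set: 'costs' must be cost_parameters", call. = FALSE)
  }
  point <- c(p_pos_st = params$margins$p_pos_st,
             p_pos_ifmi = params$margins$p_pos_ifmi,
             p_pos_second = params$margins$p_pos_second,
             drg_cost = params$costs$drg_cost,
             lost_productivity = params$costs$lost_productivity,
             agent_cost = params$costs$agent_cost,
             device_cost = device_cost_per_surgery_from(params$costs),
             draping_cost = params$costs$draping_cost,
             staff_addon_cost = params$costs$staff_addon_cost,
             st_duration = params$costs$st_duration,
             prolongation = params$costs$prolongation,
             fsa_duration = params$costs$fsa_duration,
             staff_time_saving_factor = params$costs$staff_time_saving_factor)
  for (nm in names(params$psa_specs)) {
    spec <- params$psa_specs[[nm]]
    if (!inherits(spec, "dist_spec")) {
      stop(sprintf("param_set: psa spec '%s' is not a dist_spec", nm),
           call. = FALSE)
    }
    validate_dist_spec(spec)
    if (nm %in% names(point) &&
        abs(spec$mean - point[[nm]]) > 1e-8 * max(1, abs(point[[nm]]))) {
      stop(sprintf(
        "param_set: psa spec '%s' has mean %g but point estimate is %g",
        nm, spec$mean, point[[nm]]), call. = FALSE)
    }
  }
  params
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set>\n")
  cat(sprintf("  margins: p_pos_st = %g, p_pos_ifmi = %g (rr = %.3f), p_pos_second = %g [%s]\n",
              x$margins$p_pos_st, x$margins$p_pos_ifmi, x$margins$rr,
              x$margins$p_pos_second, x$margins$psa_mode))
  cat(sprintf("  costs: drg = %g, lost productivity = %g, IFMI add-on = %.2f EUR\n",
              x$costs$drg_cost, x$costs$lost_productivity,
              ifmi_addon_cost(x$costs)))
  cat(sprintf("  run: %d PSA draws, seed %d, tornado fraction %g\n",
              x$n_draws, x$seed, x$tornado_fraction))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Configuration I/O

spec_to_list <- function(spec) {
  out <- list(kind = spec$kind, mean = spec$mean)
  if (spec$kind %in% c("beta", "gamma")) out$se <- spec$se
  if (spec$kind == "triangular") {
    out$min <- spec$min
    out$max <- spec$max
  }
  out
}

spec_from_list <- function(x, key) {
  if (is.null(x$kind) || is.null(x$mean)) {
    stop(sprintf("load_parameters: psa spec '%s' needs 'kind' and 'mean'",
                 key), call. = FALSE)
  }
  dist_spec(x$kind, mean = x$mean, se = x$se, min = x$min, max = x$max)
}

#' Load a model configuration
#'
#' Reads a flat JSON configuration with sections `margins`, `costs`,
#' `psa` and `run`, fills unspecified keys with the base-case defaults,
#' applies any in-memory `overrides` (same nested structure) on top, and
#' validates the result. Unknown keys and invariant violations raise an
#' error naming the offending key.
#'
#' @param path Path to a JSON configuration file, or `NULL` for defaults.
#' @param overrides Nested list of overrides applied after the file.
#' @return A validated [parameter_set()].
#' @examples
#' load_parameters()                      # base case
#' load_parameters(overrides = list(costs = list(drg_cost = 5047)))
#' @export
load_parameters <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE,
                               simplifyMatrix = FALSE)
  }
  cfg <- utils::modifyList(cfg, overrides)
  known_sections <- c("margins", "costs", "psa", "run")
  unknown <- setdiff(names(cfg), known_sections)
  if (length(unknown)) {
    stop(sprintf("load_parameters: unknown section(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }

  margin_args <- cfg$margins %||% list()
  check_known(margin_args, names(formals(margin_model)), "margins")
  margins <- do.call(margin_model, margin_args)

  cost_args <- cfg$costs %||% list()
  check_known(cost_args, names(formals(cost_parameters)), "costs")
  costs <- do.call(cost_parameters, cost_args)

  specs <- default_psa_specs(margins, costs)
  for (key in names(cfg$psa %||% list())) {
    if (!key %in% names(specs)) {
      stop(sprintf("load_parameters: unknown psa parameter '%s'", key),
           call. = FALSE)
    }
    specs[[key]] <- spec_from_list(cfg$psa[[key]], key)
  }

  run <- cfg$run %||% list()
  check_known(run, c("n_draws", "seed", "tornado_fraction"), "run")
  parameter_set(margins = margins, costs = costs, psa_specs = specs,
                tornado_fraction = run$tornado_fraction %||% 0.25,
                n_draws = run$n_draws %||% 10000L,
                seed = run$seed %||% 1L)
}

#' Write a model configuration
#'
#' Serializes a [parameter_set()] to the JSON dialect read by
#' [load_parameters()]; loading the written file reproduces the set.
#'
#' @param params A `param_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  cfg <- list(
    margins = params$margins[c("p_pos_st", "p_pos_ifmi", "p_pos_second",
                               "psa_mode")],
    costs = Filter(Negate(is.null),
                   params$costs[names(formals(cost_parameters))]),
    psa = lapply(params$psa_specs, spec_to_list),
    run = list(n_draws = params$n_draws, seed = params$seed,
               tornado_fraction = params$tornado_fraction)
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

check_known <- function(args, known, section) {
  unknown <- setdiff(names(args), known)
  if (length(unknown)) {
    stop(sprintf("load_parameters: unknown key(s) in '%s': %s",
                 section, paste(unknown, collapse = ", ")), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
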