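#' Simulate individual patients through the decision tree
#'
#' Patient-level brute-force counterpart of the cohort expectations:
#' each patient's first surgery leaves positive margins with the
#' strategy's probability (Bernoulli draw), a positive margin triggers a
#' second surgery whose margins are positive with the shared
#' second-surgery probability, and a third surgery is always final.
#' Costs accumulate deterministically along the realized path: every
#' surgery costs the DRG lump sum plus lost productivity, and IFMI
#' patients pay the one-time add-on. With `variant = "a"`, re-excision
#' after the first surgery is an additional Bernoulli draw conditional
#' on margin status (see [variant_a_params()]).
#'
#' @param params A [parameter_set()].
#' @param n_patients Number of patients to simulate.
#' @param seed Seed for the Bernoulli stream.
#' @param strategy `"IFMI"` or `"ST"`.
#' @param variant `"base"` or `"a"`.
#' @param va A [variant_a_params()], required for `variant = "a"`.
#' @return Data frame with one row per patient: `patient`, `strategy`,
#'   `margins` (dash-separated pos/neg sequence), `n_surgeries`,
#'   `total_cost`.
#' @examples
#' head(simulate_cohort(parameter_set(), 10, seed = 1, strategy = "ST"))
#' @export
simulate_cohort <- function(params, n_patients, seed,
                            strategy = c("IFMI", "ST"),
                            variant = c("base", "a"), va = NULL) {
  strategy <- match.arg(strategy)
  variant <- match.arg(variant)
  if (n_patients < 1) {
    stop("simulate_cohort: 'n_patients' must be at least 1", call. = FALSE)
  }
  margins <- params$margins
  costs <- params$costs
  p_first <- if (strategy == "IFMI") margins$p_pos_ifmi else margins$p_pos_st

  set.seed(seed)
  n <- n_patients
  pos1 <- stats::runif(n) < p_first
  reexcised <- if (variant == "base") {
    pos1
  } else {
    if (is.null(va)) {
      stop("simulate_cohort: variant 'a' requires 'va'", call. = FALSE)
    }
    p_re <- ifelse(pos1, va$p_reexcise_given_pos, va$p_reexcise_given_neg)
    stats::runif(n) < p_re
  }
  pos2 <- rep(FALSE, n)
  pos2[reexcised] <- stats::runif(sum(reexcised)) < margins$p_pos_second

  n_surg <- 1L + as.integer(reexcised) + as.integer(pos2)
  per_surgery <- costs$drg_cost + costs$lost_productivity
  addon <- if (strategy == "IFMI") ifmi_addon_cost(costs) else 0
  total_cost <- per_surgery * n_surg + addon

  lab <- function(x) ifelse(x, "pos", "neg")
  margins_seq <- lab(pos1)
  margins_seq[reexcised] <- paste(margins_seq[reexcised],
                                  lab(pos2[reexcised]), sep = "-")

  data.frame(patient = seq_len(n), strategy = strategy,
             margins = margins_seq, n_surgeries = n_surg,
             total_cost = total_cost)
}

#' Summarize a simulated cohort
#'
#' Sample means and standard errors of the surgery count and the total
#' cost, per strategy. With a single patient the standard errors are
#' reported as `NA`.
#'
#' @param records Data frame from [simulate_cohort()].
#' @return Data frame with one row per strategy: `n_patients`,
#'   `mean_surgeries`, `se_surgeries`, `mean_cost`, `se_cost`.
#' @export
summarize_cohort <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("summarize_cohort: empty cohort", call. = FALSE)
  }
  out <- lapply(split(records, records$strategy), function(df) {
    n <- nrow(df)
    se <- function(x) if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_
    data.frame(strategy = df$strategy[1L], n_patients = n,
               mean_surgeries = mean(df$n_surgeries),
               se_surgeries = se(df$n_surgeries),
               mean_cost = mean(df$total_cost),
               se_cost = se(df$total_cost))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
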