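#' Structural variant A: imperfect re-excision after the first surgery
#'
#' In practice not every patient with positive margins is re-excised and
#' some patients with negative margins are. Variant A gives the first
#' surgery's outcome a re-excision probability conditional on margin
#' status; from the second surgery on, positive margins always lead to
#' re-excision and negative margins never do, and the second-surgery
#' positive-margin probability is unchanged.
#'
#' @param p_reexcise_given_pos Probability of re-excision after positive
#'   first-surgery margins.
#' @param p_reexcise_given_neg Probability of re-excision after negative
#'   first-surgery margins.
#' @return An object of class `variant_a_params`. The pair (1, 0)
#'   reduces the variant to the base tree.
#' @export
variant_a_params <- function(p_reexcise_given_pos = 1,
                             p_reexcise_given_neg = 0) {
  check_prob(p_reexcise_given_pos, "p_reexcise_given_pos")
  check_prob(p_reexcise_given_neg, "p_reexcise_given_neg")
  structure(list(p_reexcise_given_pos = p_reexcise_given_pos,
                 p_reexcise_given_neg = p_reexcise_given_neg),
            class = "variant_a_params")
}

#' Expected surgeries under structural variant A
#'
#' The probability of a second surgery becomes
#' `q = p_first * p_reexcise_given_pos + (1 - p_first) *
#' p_reexcise_given_neg`, and the expectation is `1 + q * (1 +
#' p_second)` as in the base tree.
#'
#' @param p_first First-surgery positive-margin probability.
#' @param va A [variant_a_params()].
#' @param p_second Second-surgery positive-margin probability.
#' @return Expected number of surgeries.
#' @examples
#' variant_a_expected_surgeries(0.3, variant_a_params(1, 0), 0.1)  # 1.33
#' @export
variant_a_expected_surgeries <- function(p_first, va, p_second) {
  check_prob(p_first, "p_first")
  check_prob(p_second, "p_second")
  q <- p_first * va$p_reexcise_given_pos +
    (1 - p_first) * va$p_reexcise_given_neg
  1 + q * (1 + p_second)
}

#' Strategy result under structural variant A
#'
#' Expected surgeries from [variant_a_expected_surgeries()] with the
#' strategy's first-surgery margin probability; costs composed as in the
#' base tree (per-surgery lump sum plus one-time IFMI add-on).
#'
#' @param strategy `"IFMI"` or `"ST"`.
#' @param margins A [margin_model()].
#' @param costs A [cost_parameters()].
#' @param va A [variant_a_params()].
#' @return A `strategy_result`.
#' @export
variant_a_expected_cost <- function(strategy = c("IFMI", "ST"), margins,
                                    costs, va) {
  strategy <- match.arg(strategy)
  p_first <- if (strategy == "IFMI") margins$p_pos_ifmi else margins$p_pos_st
  n <- variant_a_expected_surgeries(p_first, va, margins$p_pos_second)
  cost <- (costs$drg_cost + costs$lost_productivity) * n +
    if (strategy == "IFMI") ifmi_addon_cost(costs) else 0
  structure(list(strategy = strategy, expected_surgeries = n,
                 expected_cost = cost,
                 expected_cost_display = floor(cost)),
            class = "strategy_result")
}

#' Incremental endpoints under structural variant A
#'
#' @inheritParams variant_a_expected_cost
#' @return An `incremental_result`.
#' @export
variant_a_incremental <- function(margins, costs, va) {
  ifmi <- variant_a_expected_cost("IFMI", margins, costs, va)
  st <- variant_a_expected_cost("ST", margins, costs, va)
  structure(list(delta_surgeries = ifmi$expected_surgeries -
                   st$expected_surgeries,
                 delta_cost = ifmi$expected_cost - st$expected_cost,
                 ifmi = ifmi, st = st),
            class = "incremental_result")
}

#' Structural variant B: empirical surgery-count distribution
#'
#' Instead of deriving surgery counts from margin outcomes, variant B
#' takes a per-strategy probability vector over total surgery counts
#' 1 to 4 (observed proportions of breast-conserving surgery counts,
#' including fourth surgeries, without stratification by margin type).
#'
#' @param probs Numeric vector of up to four probabilities for 1, 2, 3
#'   and 4 total surgeries; must be nonnegative and sum to 1 (within
#'   1e-12).
#' @return An object of class `variant_b_params`.
#' @export
variant_b_params <- function(probs) {
  if (length(probs) > 4L) {
    stop("variant_b_params: at most four surgery counts are modelled",
         call. = FALSE)
  }
  probs <- c(probs, rep(0, 4L - length(probs)))
  if (any(probs < 0)) {
    stop("variant_b_params: probabilities must be nonnegative",
         call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    stop(sprintf("variant_b_params: probabilities sum to %.15g, not 1",
                 sum(probs)), call. = FALSE)
  }
  structure(list(probs = stats::setNames(probs, 1:4)),
            class = "variant_b_params")
}

#' Strategy result under structural variant B
#'
#' Expected surgeries are `sum(k * p_k)` over the surgery-count
#' distribution; expected cost is the per-surgery lump sum times that
#' expectation, plus the one-time IFMI add-on for the IFMI strategy.
#'
#' @param vb A [variant_b_params()].
#' @param costs A [cost_parameters()].
#' @param strategy `"IFMI"` or `"ST"`.
#' @return A `strategy_result`.
#' @examples
#' variant_b_expected(variant_b_params(c(0.7, 0.27, 0.03)),
#'                    cost_parameters(), "ST")
#' @export
variant_b_expected <- function(vb, costs, strategy = c("IFMI", "ST")) {
  strategy <- match.arg(strategy)
  n <- sum(1:4 * vb$probs)
  cost <- (costs$drg_cost + costs$lost_productivity) * n +
    if (strategy == "IFMI") ifmi_addon_cost(costs) else 0
  structure(list(strategy = strategy, expected_surgeries = n,
                 expected_cost = cost,
                 expected_cost_display = floor(cost)),
            class = "strategy_result")
}
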