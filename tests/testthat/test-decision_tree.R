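test_that("path probabilities follow the tree and always sum to one", {
  expect_equal(unname(path_distribution(0.3, 0.1)), c(0.70, 0.27, 0.03))
  expect_equal(unname(path_distribution(0, 0.9)), c(1, 0, 0))
  set.seed(11)
  for (i in 1:50) {
    p <- path_distribution(runif(1), runif(1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  expect_error(path_distribution(1.2, 0.1), "p_first")
})

test_that("expected surgeries match the closed form and stay in [1, 3]", {
  expect_equal(expected_surgeries(0.3, 0.1), 1.33)
  expect_equal(expected_surgeries(0.1, 0.1), 1.11)
  expect_equal(expected_surgeries(0, 0), 1)
  set.seed(12)
  for (i in 1:50) {
    p1 <- runif(1); p2 <- runif(1)
    e <- expected_surgeries(p1, p2)
    expect_equal(e, sum(1:3 * path_distribution(p1, p2)),
                 tolerance = 1e-12)
    expect_true(e >= 1 && e <= 3)
  }
})

test_that("device amortization reproduces the per-surgery camera cost", {
  expect_equal(device_cost_per_surgery(150000, 0.10, 7, 200),
               150000 / 1400 + 0.10 * 150000 / 200, tolerance = 1e-12)
  expect_equal(round(device_cost_per_surgery(150000, 0.10, 7, 200)), 182)
  expect_equal(device_cost_per_surgery(0, 0.1, 7, 200), 0)
  expect_equal(device_cost_per_surgery(150000, 0, 7, 200), 150000 / 1400,
               tolerance = 1e-12)
  expect_error(device_cost_per_surgery(150000, 0.1, 0, 200))
})

test_that("time-delta cost is the prolongation/saving difference", {
  expect_equal(time_delta_cost(10, 27, 0.5, 2, 1), (10 - 13.5) * 2 - 1)
  expect_equal(time_delta_cost(10, 27, 0, 0, 0), 0)
  # strictly decreasing in the staff factor for a positive rate
  s <- seq(0, 1, by = 0.1)
  v <- vapply(s, function(x) time_delta_cost(10, 27, x, 68, 0), 0)
  expect_true(all(diff(v) < 0))
  expect_error(time_delta_cost(10, 27, 1.5, 68, 0), "\\[0, 1\\]")
})

test_that("the one-time IFMI add-on composes its published components", {
  expect_equal(ifmi_addon_cost(cost_parameters()), 223.38, tolerance = 1e-6)
  zero <- cost_parameters(agent_cost = 0, device_cost = 0, draping_cost = 0,
                          staff_addon_cost = 0, cost_per_minute = 0,
                          fsa_fixed_saving = 0)
  expect_equal(ifmi_addon_cost(zero), 0)
  # without any staff time saving the add-on is pure additional cost
  s0 <- cost_parameters(staff_time_saving_factor = 0)
  expect_equal(ifmi_addon_cost(s0), 1402.38, tolerance = 1e-6)
})

test_that("expected strategy costs reproduce the published euro figures", {
  m <- margin_model(); k <- cost_parameters()
  st <- expected_cost("ST", m, k)
  expect_equal(st$expected_cost, 4029 * 1.33, tolerance = 1e-9)
  expect_identical(st$expected_cost_display, 5358)
  ifmi <- expected_cost("IFMI", m, k)
  expect_equal(ifmi$expected_cost, 4029 * 1.11 + 223.38, tolerance = 1e-6)
  expect_identical(ifmi$expected_cost_display, 4695)
  # degenerate tree: exactly one surgery each
  m0 <- margin_model(0, 0, 0)
  expect_equal(expected_cost("ST", m0, k)$expected_cost, 4029)
  expect_equal(expected_cost("IFMI", m0, k)$expected_cost,
               4029 + ifmi_addon_cost(k), tolerance = 1e-9)
})

test_that("incremental endpoints hit the published base case", {
  inc <- incremental(margin_model(), cost_parameters())
  expect_equal(inc$delta_surgeries, -0.22, tolerance = 1e-12)
  expect_equal(inc$delta_cost, -663, tolerance = 1e-9)
  # no margin reduction: surgeries equal, cost difference is the add-on
  m1 <- margin_model(p_pos_st = 0.3, p_pos_ifmi = 0.3)
  inc1 <- incremental(m1, cost_parameters())
  expect_equal(inc1$delta_surgeries, 0)
  expect_equal(inc1$delta_cost, ifmi_addon_cost(cost_parameters()),
               tolerance = 1e-9)
})

test_that("both incremental endpoints are affine in the relative risk", {
  k <- cost_parameters()
  at_rr <- function(rr) {
    m <- margin_model(p_pos_ifmi = rr * 0.3)
    inc <- incremental(m, k)
    c(inc$delta_surgeries, inc$delta_cost)
  }
  a <- at_rr(0.1); b <- at_rr(0.5); mid <- at_rr(0.3)
  expect_equal(mid, (a + b) / 2, tolerance = 1e-12)
})

test_that("time-cost calibration solves and inverts the linear system", {
  m <- margin_model(); k <- cost_parameters()
  cal <- calibrate_time_cost(m, k)
  expect_equal(cal$cost_per_minute, 1179 / 17.28, tolerance = 1e-10)
  expect_equal(cal$fsa_fixed_saving, 92.0545, tolerance = 1e-4)
  # residuals at both anchors are zero
  k2 <- cost_parameters(cost_per_minute = cal$cost_per_minute,
                        fsa_fixed_saving = cal$fsa_fixed_saving)
  expect_equal(incremental(m, k2)$delta_cost, -663, tolerance = 1e-9)
  k2$staff_time_saving_factor <- 0
  expect_equal(incremental(m, k2)$delta_cost, 516, tolerance = 1e-9)

  # round-trip: anchors generated from a known (c, F) recover it exactly
  set.seed(21)
  for (i in 1:10) {
    kc <- random_costs(); mm <- random_margins()
    s_pair <- sort(runif(2))[2:1]
    anchors <- vapply(s_pair, function(s) {
      kc$staff_time_saving_factor <- s
      incremental(mm, kc)$delta_cost
    }, 0)
    cal <- calibrate_time_cost(mm, kc, anchor_s = s_pair,
                               anchor_delta_cost = anchors)
    expect_equal(cal$cost_per_minute, kc$cost_per_minute, tolerance = 1e-8)
    expect_equal(cal$fsa_fixed_saving, kc$fsa_fixed_saving,
                 tolerance = 1e-6)
  }
  expect_error(calibrate_time_cost(m, k, anchor_s = c(0.5, 0.5),
                                   anchor_delta_cost = c(-663, 516)),
               "distinct")
})

test_that("defaults reproduce both published cost anchors simultaneously", {
  m <- margin_model(); k <- cost_parameters()
  expect_equal(incremental(m, k)$delta_cost, -663, tolerance = 1e-9)
  k$staff_time_saving_factor <- 0
  expect_equal(incremental(m, k)$delta_cost, 516, tolerance = 1e-9)
})
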