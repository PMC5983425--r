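test_that("the relative-risk sweep reproduces the published endpoints", {
  sw <- rr_sweep(base_params(), grid = c(0, 1 / 3, 1), psa = FALSE)
  expect_equal(sw$delta_surgeries, c(-0.33, -0.22, 0), tolerance = 1e-12)
  # at rr = 1 the strategies differ only by the one-time add-on
  expect_equal(sw$delta_cost[3], ifmi_addon_cost(cost_parameters()),
               tolerance = 1e-9)
  expect_equal(sw$delta_cost[2], -663, tolerance = 1e-9)
  expect_error(rr_sweep(base_params(), grid = c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("linear interpolation is exact for the affine point estimates", {
  p <- base_params()
  sw <- rr_sweep(p, psa = FALSE)
  # grid nodes are returned unchanged
  node <- interpolate_sweep(sw, sw$rr[3])
  expect_equal(node$delta_cost, sw$delta_cost[3], tolerance = 1e-12)
  # midpoints are arithmetic means of the neighbours
  mid <- interpolate_sweep(sw, (sw$rr[2] + sw$rr[3]) / 2)
  expect_equal(mid$delta_surgeries,
               mean(sw$delta_surgeries[2:3]), tolerance = 1e-12)
  # arbitrary rr: interpolation equals direct evaluation
  for (rr in c(0.11, 0.44, 0.91)) {
    direct <- rr_sweep(p, grid = rr, psa = FALSE)
    interp <- interpolate_sweep(sw, rr)
    expect_equal(interp$delta_surgeries, direct$delta_surgeries,
                 tolerance = 1e-10)
    expect_equal(interp$delta_cost, direct$delta_cost, tolerance = 1e-10)
  }
  expect_error(interpolate_sweep(sw, 1.5), "span")
})

test_that("tornado inputs are the published +/-25% perturbations", {
  tor <- tornado(base_params())
  drg <- tor[tor$parameter == "drg_cost", ]
  expect_equal(c(drg$low_input, drg$high_input), c(2631, 4385))
  staff <- tor[tor$parameter == "staff_time_saving_factor", ]
  expect_equal(c(staff$low_input, staff$high_input), c(0.48, 0.80))
  agent <- tor[tor$parameter == "agent_cost", ]
  expect_equal(c(agent$low_input, agent$high_input), c(375, 625))
  # sorted by descending influence
  expect_true(all(diff(tor$range) <= 1e-12))
  expect_equal(attr(tor, "base_result"), -663, tolerance = 1e-9)
})

test_that("tornado ranges match the analytic slope for affine inputs", {
  p <- base_params()
  tor <- tornado(p)
  k <- p$costs
  # closed form: d delta_cost / d drg = delta_surgeries +
  # (prolongation - s * fsa) * c0 / (drg0 + lost0), since the per-minute
  # cost is rescaled proportionally to the per-surgery lump sum
  slope <- -0.22 + (k$prolongation - k$staff_time_saving_factor *
                      k$fsa_duration) *
    k$cost_per_minute / (k$drg_cost + k$lost_productivity)
  expect_equal(tor[tor$parameter == "drg_cost", "range"],
               abs(slope) * 0.5 * k$drg_cost, tolerance = 1e-9)
  # zero perturbation leaves nothing to rank
  tor0 <- tornado(p, fraction = 0)
  expect_true(all(tor0$range == 0))
})

test_that("scenarios override parameters and their distributions", {
  p <- base_params()

  # no overrides: identical to the base analysis
  sc0 <- run_scenario(p, list(), psa = FALSE)
  expect_equal(sc0$incremental$delta_cost, -663, tolerance = 1e-9)

  # published no-staff-saving scenario
  sc <- run_scenario(p, list(staff_time_saving_factor = 0), psa = FALSE)
  expect_equal(sc$incremental$delta_cost, 516, tolerance = 1e-9)

  # a dearer agent shifts the incremental cost by its price difference
  # at every relative risk (the add-on is charged once)
  sc800 <- run_scenario(p, scenario_presets()$agent_high, psa = FALSE,
                        sweep_grid = c(0, 0.5, 1))
  base_sw <- rr_sweep(p, grid = c(0, 0.5, 1), psa = FALSE)
  expect_equal(sc800$sweep$delta_cost, base_sw$delta_cost + 300,
               tolerance = 1e-9)
  expect_equal(sc800$params$psa_specs$agent_cost$se, 40)

  # distribution updates travel with the point estimate
  scst <- run_scenario(p, scenario_presets()$st_long, psa = FALSE)
  expect_equal(scst$params$psa_specs$st_duration$min, 59)
  expect_equal(scst$params$psa_specs$st_duration$max, 107)
  # a longer surgery dilutes the per-minute cost, shrinking the net
  # time saving: incremental cost shifts upwards
  expect_true(scst$incremental$delta_cost > -663)

  sc_low <- run_scenario(p, scenario_presets()$p_pos_st_low, psa = FALSE)
  expect_equal(sc_low$incremental$delta_surgeries, (0.1 - 0.183) * 1.1,
               tolerance = 1e-12)

  expect_error(run_scenario(p, list(nonsense = 1)), "nonsense")
})

test_that("every scenario preset yields a finite, seeded analysis", {
  p <- base_params()
  for (nm in names(scenario_presets())) {
    sc <- run_scenario(p, scenario_presets()[[nm]], psa = TRUE, n = 500)
    expect_true(is.finite(sc$incremental$delta_cost), info = nm)
    expect_true(sc$psa$ci_cost[["lower"]] <= sc$psa$ci_cost[["upper"]],
                info = nm)
  }
})

test_that("the break-even staff factor solves the linear model", {
  p <- base_params()
  th <- threshold_staff_factor(p, "point")
  expect_false(th$boundary)
  expect_equal(th$s_star, 516 / (27 * p$costs$cost_per_minute),
               tolerance = 1e-9)
  # the incremental cost vanishes at the break-even factor
  k <- p$costs
  k$staff_time_saving_factor <- th$s_star
  expect_equal(incremental(p$margins, k)$delta_cost, 0, tolerance = 1e-9)

  # already cost-saving without any staff saving: boundary at zero
  p_cheap <- parameter_set(costs = cost_parameters(drg_cost = 10000))
  th0 <- threshold_staff_factor(p_cheap, "point")
  expect_identical(th0$s_star, 0)
  expect_true(th0$boundary)
})

test_that("statistical significance needs more staff saving than break-even", {
  p <- base_params()
  pt <- threshold_staff_factor(p, "point")
  sig <- threshold_staff_factor(p, "significance", seed = 5, n = 2000)
  expect_false(sig$boundary)
  expect_true(sig$s_star > pt$s_star)
  # deterministic bracketing: same seed, same threshold
  sig2 <- threshold_staff_factor(p, "significance", seed = 5, n = 2000)
  expect_identical(sig$s_star, sig2$s_star)
})
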