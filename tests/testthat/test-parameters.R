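test_that("beta moment matching reproduces mean and variance", {
  # independent oracle: the method-of-moments formulas evaluated directly
  nu <- 0.3 * 0.7 / 0.051^2 - 1
  sh <- beta_from_mean_se(0.3, 0.051)
  expect_equal(unname(sh[1] + sh[2]), nu, tolerance = 1e-12)
  expect_equal(unname(sh[1]), 0.3 * nu, tolerance = 1e-12)
  # frozen values from the oracle
  expect_equal(unname(sh[1] + sh[2]), 79.73818, tolerance = 1e-5)
  expect_equal(unname(sh[1]), 23.92145, tolerance = 1e-5)

  # symmetry at mean 0.5
  sh5 <- beta_from_mean_se(0.5, 0.1)
  expect_equal(sh5[["shape1"]], sh5[["shape2"]])

  expect_error(beta_from_mean_se(0.3, 0.5), "se")
  expect_error(beta_from_mean_se(1.2, 0.05), "mean")
})

test_that("gamma moment matching reproduces mean and variance", {
  sh <- gamma_from_mean_se(3508, 175)
  expect_equal(unname(sh[1]), (3508 / 175)^2, tolerance = 1e-12)
  expect_equal(unname(sh[2]), 175^2 / 3508, tolerance = 1e-12)
  expect_equal(unname(sh[1]), 401.8307, tolerance = 1e-4)
  expect_equal(unname(sh[2]), 8.73005, tolerance = 1e-5)

  sh2 <- gamma_from_mean_se(500, 25)
  expect_equal(unname(sh2), c(400, 1.25), tolerance = 1e-12)

  expect_error(gamma_from_mean_se(-1, 25))
  expect_error(gamma_from_mean_se(500, 0))
})

test_that("analytic moments of every fitted law recover the inputs", {
  set.seed(404)
  for (i in 1:30) {
    m <- runif(1, 0.02, 0.98)
    se <- sqrt(m * (1 - m)) * runif(1, 0.05, 0.8)
    mom <- dist_moments(dist_spec("beta", mean = m, se = se))
    expect_equal(unname(mom), c(m, se), tolerance = 1e-10)

    mg <- runif(1, 1, 10000)
    seg <- mg * runif(1, 0.01, 0.5)
    mom <- dist_moments(dist_spec("gamma", mean = mg, se = seg))
    expect_equal(unname(mom), c(mg, seg), tolerance = 1e-10)
  }
  # triangular: analytic mean equals the point estimate even when the
  # support is asymmetric around it
  tri <- dist_spec("triangular", mean = 27, min = 13, max = 53)
  expect_equal(dist_moments(tri)[["mean"]], 27, tolerance = 1e-12)
})

test_that("sampling respects each law's support and moments", {
  set.seed(7)
  tri <- dist_spec("triangular", mean = 59, min = 35, max = 83)
  x <- sample_dist(tri, 1e5)
  expect_true(all(x >= 35 & x <= 83))
  expect_equal(mean(x), (35 + 59 + 83) / 3, tolerance = 0.01)

  b <- dist_spec("beta", mean = 0.3, se = 0.051)
  xb <- sample_dist(b, 1e5)
  expect_true(all(xb > 0 & xb < 1))
  expect_equal(sd(xb), 0.051, tolerance = 0.01)

  g <- dist_spec("gamma", mean = 3508, se = 175)
  expect_true(all(sample_dist(g, 1e4) > 0))

  expect_identical(sample_dist(dist_spec("fixed", mean = 0.64), 5),
                   rep(0.64, 5))
})

test_that("triangular rejects a mean its support cannot attain", {
  # mean must lie in the central third of [min, max]
  expect_error(dist_spec("triangular", mean = 14, min = 13, max = 53),
               "not attainable")
  expect_error(dist_spec("triangular", mean = 59, min = 60, max = 83))
})

test_that("default parameter set carries the base-case point estimates", {
  p <- base_params()
  expect_equal(p$costs$drg_cost, 3508)
  expect_equal(p$costs$agent_cost, 500)
  expect_equal(p$margins$rr, 1 / 3)
  expect_equal(p$n_draws, 10000L)
  # parameters without a stated distribution stay fixed in the PSA
  expect_identical(p$psa_specs$staff_time_saving_factor$kind, "fixed")
  # every spec mean equals the corresponding point estimate
  expect_equal(p$psa_specs$drg_cost$mean, p$costs$drg_cost)
  expect_equal(p$psa_specs$p_pos_st$mean, p$margins$p_pos_st)
})

test_that("load_parameters validates overrides and round-trips", {
  expect_equal(load_parameters()$costs$drg_cost, 3508)

  p <- load_parameters(overrides = list(
    costs = list(drg_cost = 5047),
    psa = list(drg_cost = list(kind = "gamma", mean = 5047, se = 252))))
  expect_equal(p$costs$drg_cost, 5047)
  expect_equal(p$psa_specs$drg_cost$se, 252)

  expect_error(load_parameters(overrides = list(
    costs = list(staff_time_saving_factor = 1.5))),
    "staff_time_saving_factor")
  expect_error(load_parameters(overrides = list(costs = list(bogus = 1))),
               "bogus")
  # a psa spec whose mean disagrees with the point estimate is rejected
  expect_error(load_parameters(overrides = list(
    psa = list(drg_cost = list(kind = "gamma", mean = 4000, se = 175)))),
    "point estimate")

  path <- tempfile(fileext = ".json")
  write_parameters(base_params(), path)
  expect_equal(load_parameters(path), base_params())

  pkg_cfg <- system.file("extdata", "base_config.json",
                         package = "ifmicost")
  expect_equal(load_parameters(pkg_cfg), base_params())
})
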