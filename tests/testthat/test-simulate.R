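test_that("a fully degenerate configuration reproduces the closed-form cost in every iteration", {
  cfg <- point_mass_config()
  sim <- mih_simulate(cfg, iterations = 50, seed = 99)
  expect_true(all(sim$basic == 175))
  expect_true(all(sim$advanced == 325))
  s <- summary(sim)
  expect_equal(s$median, c(175, 325))
  expect_equal(s$mean, c(175, 325))
  expect_equal(s$lower, c(175, 325))
  expect_equal(s$upper, c(175, 325))
  expect_equal(s$sd, c(0, 0))
})

test_that("simulation results are bit-identical under a repeated seed", {
  cfg <- mih_template()
  a <- mih_simulate(cfg, iterations = 300, seed = 7)
  b <- mih_simulate(cfg, iterations = 300, seed = 7)
  expect_identical(a$basic, b$basic)
  expect_identical(a$advanced, b$advanced)
  c <- mih_simulate(cfg, iterations = 300, seed = 8)
  expect_false(identical(a$basic, c$basic))
  expect_true(all(a$basic >= 0) && all(a$advanced >= 0))
})

test_that("summaries use linear-interpolation percentile intervals", {
  sv <- mihcost:::summarize_vector(1:100, 0.90)
  expect_equal(sv$lower, 5.95)
  expect_equal(sv$upper, 95.05)
  expect_equal(sv$median, 50.5)
  expect_error(mihcost:::summarize_vector(numeric(0), 0.9), "no values")
  expect_error(mihcost:::summarize_vector(1:10, 1.2), "\\(0, 1\\)")
  # interval bounds are ordered for arbitrary data
  set.seed(5)
  x <- rlnorm(500)
  sv2 <- mihcost:::summarize_vector(x, 0.9)
  expect_true(sv2$lower <= sv2$median && sv2$median <= sv2$upper)
})

test_that("the simulated mean matches the linearity-of-expectation oracle at fixed volume", {
  cfg <- mih_template()
  cfg$visit_mix <- visit_mix(pm(800), 0.6)  # fix the volume for the oracle
  means <- setNames(vapply(cfg$elements, function(e) pert_mean(e$pert), 0),
                    vapply(cfg$elements, `[[`, "", "id"))
  oracle <- per_visit_cost(means, cfg, 480, 320)
  sim <- mih_simulate(cfg, iterations = 2e4, seed = 31)
  expect_true(all(sim$n_basic == 480) && all(sim$n_advanced == 320))
  for (s in c("basic", "advanced")) {
    se <- sd(sim[[s]]) / sqrt(sim$iterations)
    expect_lt(abs(mean(sim[[s]]) - oracle[[s]]), 4 * se)
  }
})

test_that("scenario runs share draws, so unreimbursed costs never exceed full costs", {
  sc <- mih_scenarios(mih_template(), iterations = 500, seed = 13)
  expect_true(all(sc$unreimbursed$basic <= sc$full$basic + 1e-9))
  expect_true(all(sc$unreimbursed$advanced <= sc$full$advanced + 1e-9))
  s <- summary(sc)
  med <- function(scen, str) s$median[s$scenario == scen & s$stratum == str]
  expect_lt(med("unreimbursed", "basic"), med("full", "basic"))
  expect_lt(med("unreimbursed", "advanced"), med("full", "advanced"))
  # no reimbursable elements: the two scenarios coincide
  sc0 <- mih_scenarios(point_mass_config(), iterations = 20, seed = 2)
  expect_identical(sc0$full$basic, sc0$unreimbursed$basic)
  expect_identical(sc0$full$advanced, sc0$unreimbursed$advanced)
})

test_that("widening an element's range around a fixed mode never narrows the interval", {
  width_of <- function(halfrange) {
    cfg <- program_config(
      list(cost_element("staff", classification = "fixed",
                        pert = pert_params(1e5 - halfrange, 1e5, 1e5 + halfrange)),
           cost_element("meds", classification = "variable", basis = "per_visit",
                        pert = pm(10))),
      visit_mix(pm(800), 0.6))
    s <- summary(mih_simulate(cfg, iterations = 2000, seed = 17))
    s$upper[1] - s$lower[1]
  }
  widths <- vapply(c(0, 1e4, 3e4, 6e4), width_of, 0)
  expect_true(all(diff(widths) >= 0))
})

test_that("simulation accessors expose tidy per-iteration data", {
  sim <- mih_simulate(mih_template(), iterations = 50, seed = 4)
  df <- as.data.frame(sim)
  expect_equal(nrow(df), 100)
  expect_setequal(unique(df$stratum), c("basic", "advanced"))
  expect_equal(df$cost[df$stratum == "basic"], sim$basic)
  q <- quantile(sim, probs = c(0.25, 0.75))
  expect_equal(dim(q), c(2L, 2L))
  expect_true(all(q[, 1] <= q[, 2]))
})
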