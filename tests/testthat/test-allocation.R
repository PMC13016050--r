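test_that("visit splitting rounds half to even and always conserves the total", {
  expect_equal(split_visits(800, 0.6), list(n_basic = 480L, n_advanced = 320L))
  expect_equal(split_visits(1, 1.0), list(n_basic = 1L, n_advanced = 0L))
  expect_equal(split_visits(799, 0.6), list(n_basic = 479L, n_advanced = 320L))
  # independent round-half-to-even oracle, enumerated over totals 1..1000
  half_even <- function(x) {
    f <- floor(x); r <- x - f
    ifelse(abs(r - 0.5) < 1e-9, f + (f %% 2), ifelse(r > 0.5, f + 1, f))
  }
  for (p in c(0.25, 0.5, 0.6, 0.731)) {
    sv <- split_visits(1:1000, p)
    expect_equal(sv$n_basic, as.integer(half_even((1:1000) * p)))
    expect_true(all(sv$n_basic + sv$n_advanced == 1:1000))
    expect_true(all(sv$n_basic >= 0 & sv$n_advanced >= 0))
  }
  expect_error(split_visits(0, 0.6), ">= 1")
  expect_error(split_visits(10, 1.2), "\\[0, 1\\]")
})

test_that("pooled allocation is count-proportional and exactly conserving", {
  expect_equal(allocate_pooled(100000, 480, 320), list(basic = 60000, advanced = 40000))
  expect_equal(allocate_pooled(0, 480, 320), list(basic = 0, advanced = 0))
  expect_equal(allocate_pooled(100000, 800, 0), list(basic = 100000, advanced = 0))
  # resource-weighted variant: advanced visits weighted 3x
  w <- allocate_pooled(100000, 480, 320, weights = c(basic = 1, advanced = 3))
  expect_equal(w$basic, 100000 * 480 / (480 + 3 * 320))
  expect_equal(w$basic + w$advanced, 100000)
  expect_error(allocate_pooled(100, 0, 0), "at least one visit")
  expect_error(allocate_pooled(-5, 10, 10), "non-negative")
})

test_that("variable totals accumulate per basis and applicability", {
  mk <- function(...) program_config(c(list(
    cost_element("fix", classification = "fixed", pert = pm(0))), list(...)),
    visit_mix(pm(800), 0.6))
  cfg <- mk(cost_element("adv", classification = "variable", basis = "per_visit",
                         applicability = "advanced_only", pert = pm(120)))
  expect_equal(variable_totals(c(fix = 0, adv = 120), cfg, 480, 320),
               list(basic = 0, advanced = 120 * 320))
  cfg2 <- mk(cost_element("all", classification = "variable", basis = "per_visit",
                          applicability = "all", pert = pm(10)),
             cost_element("bas", classification = "variable", basis = "per_visit",
                          applicability = "basic_only", pert = pm(5)))
  expect_equal(variable_totals(c(fix = 0, all = 10, bas = 5), cfg2, 480, 320),
               list(basic = 480 * 15, advanced = 320 * 10))
  # per-period variable costs are split like the fixed pool
  cfg3 <- mk(cost_element("fuel", classification = "variable",
                          basis = "per_period", pert = pm(10000)))
  expect_equal(variable_totals(c(fix = 0, fuel = 10000), cfg3, 480, 320),
               list(basic = 6000, advanced = 4000))
  expect_error(variable_totals(c(fix = 0), cfg3, 480, 320), "fuel")
})

test_that("per-visit cost matches the hand-computed allocation", {
  cfg <- point_mass_config()
  pv <- per_visit_cost(c(staff = 1e5, meds_basic = 50, iv_advanced = 200),
                       cfg, 480, 320)
  expect_equal(pv$basic, 175)
  expect_equal(pv$advanced, 325)
  expect_equal(pv$fixed_share_basic, 60000)
  expect_equal(pv$fixed_share_advanced, 40000)
  # all-variable-zero: both strata equal the fixed cost per visit
  pv0 <- per_visit_cost(c(staff = 1e5, meds_basic = 0, iv_advanced = 0),
                        cfg, 480, 320)
  expect_equal(pv0$basic, 125)
  expect_equal(pv0$advanced, 125)
  # homogeneity of degree 1
  pv2 <- per_visit_cost(2 * c(staff = 1e5, meds_basic = 50, iv_advanced = 200),
                        cfg, 480, 320)
  expect_equal(pv2$basic, 2 * pv$basic)
  expect_equal(pv2$advanced, 2 * pv$advanced)
  # zero-visit stratum reports NA, not a division by zero
  pv1 <- per_visit_cost(c(staff = 1e5, meds_basic = 50, iv_advanced = 200),
                        cfg, 800, 0)
  expect_true(is.na(pv1$advanced))
  expect_equal(pv1$basic, 1e5 / 800 + 50)
  expect_error(per_visit_cost(c(staff = 1e5, meds_basic = 0, iv_advanced = 0),
                              cfg, 0, 0), "at least one visit")
})

test_that("allocation conserves total cost and is monotone in element values", {
  for (s in 1:30) {
    cfg <- random_config(s)
    ids <- vapply(cfg$elements, `[[`, "", "id")
    set.seed(s + 1000)
    vals <- setNames(vapply(cfg$elements, function(e) {
      if (e$pert$min == e$pert$max) e$pert$min else rpert(1, e$pert)
    }, 0), ids)
    sv <- split_visits(round(pert_mean(cfg$visit_mix$annual_visits)),
                       cfg$visit_mix$prop_basic)
    if (sv$n_basic == 0 || sv$n_advanced == 0) next
    pv <- per_visit_cost(vals, cfg, sv$n_basic, sv$n_advanced)
    # independent total: fixed sums once; per-period variable sums once;
    # per-visit variable multiplies by the visits it applies to
    total <- sum(vapply(cfg$elements, function(e) {
      v <- vals[[e$id]]
      if (e$classification == "fixed" || e$basis == "per_period") v
      else v * switch(e$applicability,
                      all = sv$n_basic + sv$n_advanced,
                      basic_only = sv$n_basic,
                      advanced_only = sv$n_advanced)
    }, 0))
    expect_equal(sv$n_basic * pv$basic + sv$n_advanced * pv$advanced,
                 total, tolerance = 1e-9)
    # bumping one element never decreases either stratum's cost
    bump <- sample(ids, 1)
    vals2 <- vals; vals2[bump] <- vals2[bump] + 100
    pv2 <- per_visit_cost(vals2, cfg, sv$n_basic, sv$n_advanced)
    expect_gte(pv2$basic, pv$basic - 1e-12)
    expect_gte(pv2$advanced, pv$advanced - 1e-12)
  }
})
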