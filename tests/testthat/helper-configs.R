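# In-code fixtures: small configurations built programmatically.

pm <- function(x) pert_params(x, x, x)  # point mass

# The hand-checkable deterministic program: fixed pool 100,000 USD, 800
# visits split 480/320, stratum-specific variable costs 50 (basic) and 200
# (advanced) per visit. Per-visit costs: 100000/800 + 50 = 175 basic,
# 125 + 200 = 325 advanced.
point_mass_config <- function() {
  program_config(
    list(cost_element("staff", classification = "fixed", pert = pm(1e5)),
         cost_element("meds_basic", classification = "variable",
                      basis = "per_visit", applicability = "basic_only",
                      pert = pm(50)),
         cost_element("iv_advanced", classification = "variable",
                      basis = "per_visit", applicability = "advanced_only",
                      pert = pm(200))),
    visit_mix(pm(800), prop_basic = 0.6))
}

# Randomized valid configuration for property tests: 1-3 fixed elements and
# 1-4 variable elements of mixed basis/applicability/reimbursability.
random_config <- function(seed) {
  set.seed(seed)
  rtriple <- function(scale) {
    a <- runif(1, 0, scale); w <- runif(2, 0, scale)
    pert_params(a, a + min(w), a + max(w) + 1e-6)
  }
  nf <- sample(1:3, 1); nv <- sample(1:4, 1)
  fixed <- lapply(seq_len(nf), function(i)
    cost_element(paste0("fix", i), classification = "fixed",
                 pert = rtriple(2e5)))
  vars <- lapply(seq_len(nv), function(i)
    cost_element(paste0("var", i), classification = "variable",
                 basis = sample(c("per_visit", "per_period"), 1),
                 applicability = sample(c("all", "basic_only", "advanced_only"), 1),
                 reimbursable = runif(1) < 0.3,
                 pert = rtriple(300)))
  program_config(c(fixed, vars),
                 visit_mix(rtriple(500) |> (\(p) pert_params(p$min + 50, p$mode + 50,
                                                             p$max + 50))(),
                           prop_basic = runif(1, 0.2, 0.8)),
                 seed = seed)
}
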