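#' Split a visit total into basic and advanced counts
#'
#' `n_basic = round(total * prop_basic)` with round-half-to-even (the default
#' IEEE rounding, via base `round`), and the remainder goes to advanced, so
#' the two counts always sum to the total.
#'
#' @param total Total visit count (>= 1); vectorized.
#' @param prop_basic Proportion of basic visits in `[0, 1]`.
#' @return A list with integer components `n_basic` and `n_advanced`.
#' @examples
#' split_visits(800, 0.6)  # 480 basic, 320 advanced
#' @export
split_visits <- function(total, prop_basic) {
  if (any(!is.finite(total)) || any(total < 1))
    stop("'total' must be >= 1", call. = FALSE)
  if (any(prop_basic < 0) || any(prop_basic > 1))
    stop("'prop_basic' must lie in [0, 1]", call. = FALSE)
  total <- as.integer(round(total))
  n_basic <- as.integer(round(total * prop_basic))
  list(n_basic = n_basic, n_advanced = total - n_basic)
}

#' Allocate a pooled cost across visit strata
#'
#' Pooled (fixed or per-period variable) costs are allocated proportionally to
#' the distribution of visits: the basic share is
#' `total * w_b * n_basic / (w_b * n_basic + w_a * n_advanced)` and the
#' advanced share is computed by subtraction, so the shares sum to the total
#' exactly. With the default unit weights the split is proportional to visit
#' counts, which makes the per-visit fixed share identical in both strata;
#' non-unit weights express resource-weighted allocation (e.g. by visit
#' duration).
#'
#' @param total Pooled cost (>= 0); vectorized.
#' @param n_basic,n_advanced Visit counts (not both zero); vectorized.
#' @param weights Named numeric `c(basic = , advanced = )`, both positive.
#' @return A list with components `basic` and `advanced` (USD).
#' @examples
#' allocate_pooled(100000, 480, 320)  # 60000 / 40000
#' @export
allocate_pooled <- function(total, n_basic, n_advanced,
                            weights = c(basic = 1, advanced = 1)) {
  if (any(total < 0)) stop("'total' must be non-negative", call. = FALSE)
  if (any(n_basic < 0) || any(n_advanced < 0) || any(n_basic + n_advanced < 1))
    stop("visit counts must be non-negative with at least one visit", call. = FALSE)
  wb <- weights[["basic"]] * n_basic
  wa <- weights[["advanced"]] * n_advanced
  basic <- total * wb / (wb + wa)
  list(basic = basic, advanced = total - basic)
}

# One deterministic realization: every element id mapped to a sampled value,
# plus the visit split. Pure arithmetic consumed by the simulation engine and
# usable directly for point-mass oracles.
check_realization <- function(values, config) {
  ids <- element_ids(config)
  missing <- setdiff(ids, names(values))
  if (length(missing))
    stop(sprintf("realization is missing sampled value(s) for element(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (any(unlist(values[ids]) < 0))
    stop("sampled cost values must be non-negative", call. = FALSE)
  invisible(values)
}

#' Accumulate variable costs per stratum
#'
#' For each variable element: a `per_visit` element contributes
#' `value * n_visits` to every stratum it applies to (`all` means both;
#' `basic_only`/`advanced_only` a single stratum); a `per_period` variable
#' element (fuel, vehicle maintenance) is a pooled operational cost, split
#' across strata like the fixed pool but kept in the variable totals.
#'
#' @param values Named numeric vector: element id -> sampled USD value.
#' @param config An `mih_config`.
#' @param n_basic,n_advanced Visit counts.
#' @return A list with components `basic` and `advanced`: total variable USD
#'   per stratum.
#' @export
variable_totals <- function(values, config, n_basic, n_advanced) {
  check_realization(values, config)
  vb <- va <- 0
  for (e in config$elements) {
    if (e$classification != "variable") next
    v <- values[[e$id]]
    if (e$basis == "per_period") {
      sh <- allocate_pooled(v, n_basic, n_advanced, config$allocation_weights)
      vb <- vb + sh$basic
      va <- va + sh$advanced
    } else {
      if (e$applicability != "advanced_only") vb <- vb + v * n_basic
      if (e$applicability != "basic_only")    va <- va + v * n_advanced
    }
  }
  list(basic = vb, advanced = va)
}

#' Per-visit cost for one realization of all cost elements
#'
#' The deterministic allocation step applied once: fixed elements are summed
#' into a pool and allocated across strata ([allocate_pooled()]), variable
#' costs accumulate per stratum ([variable_totals()]), and each stratum's
#' total is divided by its visit count. A stratum with zero visits reports
#' `NA` for its per-visit cost rather than dividing by zero.
#'
#' @param values Named numeric vector: element id -> sampled USD value.
#' @param config An `mih_config`.
#' @param n_basic,n_advanced Visit counts (not both zero).
#' @return A list: `basic` and `advanced` per-visit USD, plus
#'   `fixed_share_basic`, `fixed_share_advanced`, `variable_total_basic`,
#'   `variable_total_advanced`.
#' @examples
#' cfg <- program_config(
#'   list(cost_element("staff", classification = "fixed",
#'                     pert = pert_params(1e5, 1e5, 1e5)),
#'        cost_element("meds", classification = "variable", basis = "per_visit",
#'                     applicability = "basic_only",
#'                     pert = pert_params(50, 50, 50)),
#'        cost_element("iv", classification = "variable", basis = "per_visit",
#'                     applicability = "advanced_only",
#'                     pert = pert_params(200, 200, 200))),
#'   visit_mix(pert_params(800, 800, 800)))
#' per_visit_cost(c(staff = 1e5, meds = 50, iv = 200), cfg, 480, 320)
#' @export
per_visit_cost <- function(values, config, n_basic, n_advanced) {
  if (n_basic + n_advanced < 1)
    stop("at least one visit is required across strata", call. = FALSE)
  check_realization(values, config)
  fixed_ids <- vapply(config$elements, function(e)
    if (e$classification == "fixed") e$id else NA_character_, "")
  fixed_total <- sum(values[fixed_ids[!is.na(fixed_ids)]])
  fx <- allocate_pooled(fixed_total, n_basic, n_advanced, config$allocation_weights)
  vr <- variable_totals(values, config, n_basic, n_advanced)
  list(basic = if (n_basic > 0) (fx$basic + vr$basic) / n_basic else NA_real_,
       advanced = if (n_advanced > 0) (fx$advanced + vr$advanced) / n_advanced else NA_real_,
       fixed_share_basic = fx$basic, fixed_share_advanced = fx$advanced,
       variable_total_basic = vr$basic, variable_total_advanced = vr$advanced)
}
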