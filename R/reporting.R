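#' Benchmark unit costs for common care settings
#'
#' Published mean costs of the care settings a mobile integrated health visit
#' is weighed against: an outpatient clinic visit ($160), an emergency
#' department visit ($2,715), and an inpatient admission ($24,680). These are
#' literature values external to the cost model; override them when newer
#' figures apply.
#'
#' @param outpatient,ed,inpatient Positive USD unit costs.
#' @return A named numeric vector of class `mih_benchmarks`.
#' @export
mih_benchmarks <- function(outpatient = 160, ed = 2715, inpatient = 24680) {
  b <- c(outpatient_clinic_visit = outpatient, ed_visit = ed,
         inpatient_admission = inpatient)
  if (any(b <= 0)) stop("benchmark costs must be positive", call. = FALSE)
  structure(b, class = c("mih_benchmarks", "numeric"))
}

#' Compare a per-visit cost against care-setting benchmarks
#'
#' For each benchmark reports the absolute difference `benchmark - median`
#' (positive when the mobile visit is cheaper than the benchmark setting)
#' and the ratio `median / benchmark` (above 1 means the mobile visit is
#' more costly).
#'
#' @param median_cost Per-visit median cost (USD), e.g. the `median` column
#'   of [summary.mih_sim()].
#' @param benchmarks A [mih_benchmarks()] vector.
#' @return A data frame with columns `setting`, `benchmark_cost`,
#'   `difference`, `ratio`, `relation`.
#' @examples
#' compare_benchmarks(550)
#' @export
compare_benchmarks <- function(median_cost, benchmarks = mih_benchmarks()) {
  if (!is.numeric(median_cost) || length(median_cost) != 1L || median_cost < 0)
    stop("'median_cost' must be a single non-negative number", call. = FALSE)
  data.frame(setting = names(benchmarks),
             benchmark_cost = as.numeric(benchmarks),
             difference = as.numeric(benchmarks) - median_cost,
             ratio = median_cost / as.numeric(benchmarks),
             relation = ifelse(median_cost > as.numeric(benchmarks),
                               "more costly", "less costly"))
}

#' Bin simulated per-visit costs for histogram export
#'
#' Bins each stratum's simulated costs into `bins` equal-width intervals
#' spanning `[min, max]` of that stratum's values; counts sum to the number
#' of iterations. This is the plot-ready export of the simulated cost
#' distribution.
#'
#' @param sim An `mih_sim` object.
#' @param bins Number of bins (>= 1).
#' @return A data frame with columns `scenario`, `stratum`, `bin_low`,
#'   `bin_high`, `count`.
#' @export
export_histogram <- function(sim, bins = 30L) {
  stopifnot(inherits(sim, "mih_sim"))
  if (!is.numeric(bins) || bins < 1) stop("'bins' must be >= 1", call. = FALSE)
  bins <- as.integer(bins)
  one <- function(v, stratum) {
    v <- v[!is.na(v)]
    edges <- if (min(v) == max(v)) c(min(v) - 0.5, max(v) + 0.5)
             else seq(min(v), max(v), length.out = bins + 1L)
    h <- graphics::hist(v, breaks = edges, include.lowest = TRUE, plot = FALSE)
    data.frame(scenario = sim$scenario, stratum = stratum,
               bin_low = h$breaks[-length(h$breaks)],
               bin_high = h$breaks[-1], count = h$counts)
  }
  rbind(one(sim$basic, "basic"), one(sim$advanced, "advanced"))
}

#' Write cost summaries as JSON
#'
#' Machine-readable export: monetary values rounded to cents, with the seed,
#' configuration digest and package version recorded so the run can be
#' reproduced exactly.
#'
#' @param x An `mih_sim` or `mih_scenarios` object.
#' @param path Output path.
#' @param level Interval level passed to [summary.mih_sim()].
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path, level = NULL) {
  sims <- if (inherits(x, "mih_scenarios")) x else list(x)
  scen <- lapply(sims, function(sim) {
    s <- if (is.null(level)) summary(sim) else summary(sim, level = level)
    rows <- lapply(seq_len(nrow(s)), function(i)
      list(stratum = s$stratum[i], n = s$n[i],
           mean = round(s$mean[i], 2), sd = round(s$sd[i], 2),
           median = round(s$median[i], 2),
           interval_low = round(s$lower[i], 2),
           interval_high = round(s$upper[i], 2),
           interval_level = s$level[i]))
    list(scenario = sim$scenario, seed = sim$seed,
         iterations = sim$iterations, config_digest = sim$config_digest,
         strata = rows)
  })
  out <- list(package = "mihcost",
              version = as.character(utils::packageVersion("mihcost")),
              scenarios = unname(scen))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write per-iteration simulated costs as CSV
#'
#' One row per iteration, stratum and scenario with the simulated per-visit
#' cost in cents-rounded USD.
#'
#' @param x An `mih_sim` or `mih_scenarios` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_iterations_csv <- function(x, path) {
  sims <- if (inherits(x, "mih_scenarios")) x else list(x)
  df <- do.call(rbind, lapply(sims, as.data.frame))
  df$cost <- round(df$cost, 2)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
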