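# Deterministic substream seed for one named quantity. Keying draws on
# (master seed, element id) rather than element position means removing an
# element (the unreimbursed scenario) leaves every other element's draws
# untouched — common random numbers across scenarios for free.
substream_seed <- function(seed, id) {
  h <- 0
  for (k in utf8ToInt(id)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h + 1) %% 2147483647)
}

# iterations draws for every element (and the annual visit volume), each from
# its own substream; returns list(values = named list of vectors, n_total).
draw_realizations <- function(config, iterations, seed) {
  values <- list()
  for (e in config$elements) {
    set.seed(substream_seed(seed, e$id))
    values[[e$id]] <- rpert(iterations, e$pert)
  }
  set.seed(substream_seed(seed, ".annual_visits"))
  n_total <- pmax(1, round(rpert(iterations, config$visit_mix$annual_visits)))
  list(values = values, n_total = n_total)
}

#' Run the Monte Carlo cost simulation
#'
#' For each iteration: draw every cost element's value (and the annual visit
#' volume) from its PERT distribution, split the visits into basic and
#' advanced strata, pool and allocate fixed costs, accumulate variable costs,
#' and record the per-visit cost of each stratum. Each element draws from its
#' own seeded RNG substream keyed by `(seed, element id)`, so a given
#' `(config, iterations, seed)` always reproduces bit-identical results and
#' two configurations sharing elements share those elements' draws
#' (common random numbers — see [mih_scenarios()]).
#'
#' @param config An `mih_config`, e.g. from [read_program_config()] or
#'   [mih_template()].
#' @param iterations Number of iterations; defaults to the configuration's
#'   setting (1000).
#' @param seed Master RNG seed; defaults to the configuration's setting.
#' @param scenario Label stored with the result (`"full"` by default).
#' @return An object of class `mih_sim` with per-iteration vectors
#'   `basic` and `advanced` (USD per visit), the visit counts and cost
#'   components per iteration, and reproducibility metadata (`seed`,
#'   `config_digest`).
#' @examples
#' sim <- mih_simulate(mih_template(), iterations = 200, seed = 7)
#' summary(sim)
#' @export
mih_simulate <- function(config, iterations = config$simulation$iterations,
                         seed = config$simulation$seed, scenario = "full") {
  validate_config(config)
  if (!is.numeric(iterations) || length(iterations) != 1L || iterations < 1)
    stop("'iterations' must be a positive integer", call. = FALSE)
  iterations <- as.integer(iterations)
  draws <- draw_realizations(config, iterations, seed)
  values <- draws$values
  sv <- split_visits(draws$n_total, config$visit_mix$prop_basic)
  nb <- sv$n_basic
  na_ <- sv$n_advanced

  fixed_total <- rep(0, iterations)
  for (e in config$elements)
    if (e$classification == "fixed") fixed_total <- fixed_total + values[[e$id]]
  fx <- allocate_pooled(fixed_total, pmax(nb, 0), pmax(na_, 0),
                        config$allocation_weights)
  vr <- variable_totals(values, config, nb, na_)

  basic <- ifelse(nb > 0, (fx$basic + vr$basic) / nb, NA_real_)
  advanced <- ifelse(na_ > 0, (fx$advanced + vr$advanced) / na_, NA_real_)

  structure(list(basic = basic, advanced = advanced,
                 n_basic = nb, n_advanced = na_,
                 fixed_total = fixed_total,
                 variable_basic = vr$basic, variable_advanced = vr$advanced,
                 iterations = iterations, seed = as.integer(seed),
                 scenario = scenario, config = config,
                 config_digest = config_digest(config)),
            class = "mih_sim")
}

summarize_vector <- function(x, level) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no values to summarize", call. = FALSE)
  if (level <= 0 || level >= 1) stop("'level' must lie in (0, 1)", call. = FALSE)
  # linear-interpolation (type 7) percentile interval of the simulated costs
  q <- unname(stats::quantile(x, probs = c((1 - level) / 2, 0.5, (1 + level) / 2),
                              type = 7, names = FALSE))
  data.frame(n = length(x), mean = mean(x), sd = stats::sd(x),
             median = q[2], lower = q[1], upper = q[3], level = level)
}

#' Summarize simulated per-visit costs
#'
#' Median (the reported central estimate), mean and standard deviation, and
#' the probabilistic percentile interval — at level 0.90, the 5th and 95th
#' percentiles of the simulated per-visit cost distribution, computed with
#' linear-interpolation quantiles.
#'
#' @param object An `mih_sim` object.
#' @param level Interval level; defaults to the configuration's setting.
#' @param ... Unused.
#' @return A `summary.mih_sim` data frame with one row per stratum and
#'   columns `stratum`, `n`, `mean`, `sd`, `median`, `lower`, `upper`,
#'   `level`.
#' @export
summary.mih_sim <- function(object, level = object$config$simulation$interval_level,
                            ...) {
  out <- rbind(cbind(stratum = "basic", summarize_vector(object$basic, level)),
               cbind(stratum = "advanced", summarize_vector(object$advanced, level)))
  rownames(out) <- NULL
  attr(out, "scenario") <- object$scenario
  attr(out, "seed") <- object$seed
  attr(out, "config_digest") <- object$config_digest
  class(out) <- c("summary.mih_sim", "data.frame")
  out
}

#' @export
print.summary.mih_sim <- function(x, ...) {
  cat(sprintf("Per-visit cost summary (scenario '%s', %d iterations, seed %d)\n",
              attr(x, "scenario") %||% "?", x$n[1], attr(x, "seed") %||% NA))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-8s median $%s  (%.0f%% interval $%s-$%s), mean $%s\n",
                x$stratum[i], format(round(x$median[i]), big.mark = ","),
                100 * x$level[i],
                format(round(x$lower[i]), big.mark = ","),
                format(round(x$upper[i]), big.mark = ","),
                format(round(x$mean[i]), big.mark = ",")))
  invisible(x)
}

#' @export
print.mih_sim <- function(x, ...) {
  cat(sprintf("Monte Carlo cost simulation: %d iterations, seed %d, config %s\n",
              x$iterations, x$seed, x$config_digest))
  print(summary(x))
  invisible(x)
}

#' @export
quantile.mih_sim <- function(x, probs = c(0.05, 0.5, 0.95), ...) {
  rbind(basic = stats::quantile(x$basic, probs = probs, na.rm = TRUE, ...),
        advanced = stats::quantile(x$advanced, probs = probs, na.rm = TRUE, ...))
}

#' @export
as.data.frame.mih_sim <- function(x, ...) {
  data.frame(scenario = x$scenario,
             iteration = rep(seq_len(x$iterations), 2L),
             stratum = rep(c("basic", "advanced"), each = x$iterations),
             cost = c(x$basic, x$advanced))
}

#' @export
plot.mih_sim <- function(x, bins = 30, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (s in c("basic", "advanced")) {
    v <- x[[s]]
    graphics::hist(v, breaks = bins, main = paste(s, "visits"),
                   xlab = "Cost per visit (USD)", col = "grey85", border = "white", ...)
    graphics::abline(v = stats::median(v, na.rm = TRUE), lwd = 2)
  }
  invisible(x)
}

#' Run the full and unreimbursed scenarios with common random numbers
#'
#' Simulates the configuration as given (`"full"`) and with payor-reimbursed
#' elements removed (`"unreimbursed"`, via [filter_unreimbursed()]), using
#' the same seed. Because every element's draws are keyed by its id, the two
#' scenarios share identical draws for the elements they have in common, so
#' the unreimbursed cost is less than or equal to the full cost in every
#' single iteration and scenario contrasts are stable.
#'
#' @inheritParams mih_simulate
#' @return An object of class `mih_scenarios`: a list with `mih_sim`
#'   components `full` and `unreimbursed`.
#' @examples
#' sc <- mih_scenarios(mih_template(), iterations = 200, seed = 7)
#' summary(sc)
#' @export
mih_scenarios <- function(config, iterations = config$simulation$iterations,
                          seed = config$simulation$seed) {
  structure(list(full = mih_simulate(config, iterations, seed, scenario = "full"),
                 unreimbursed = mih_simulate(filter_unreimbursed(config),
                                             iterations, seed,
                                             scenario = "unreimbursed")),
            class = "mih_scenarios")
}

#' @export
summary.mih_scenarios <- function(object, ...) {
  out <- do.call(rbind, lapply(names(object), function(nm) {
    s <- summary(object[[nm]], ...)
    cbind(scenario = nm, as.data.frame(s))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.mih_scenarios <- function(x, ...) {
  for (nm in names(x)) print(summary(x[[nm]]))
  invisible(x)
}
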