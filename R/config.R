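#' Define one cost element
#'
#' A cost element is one line of the program's cost structure: a named cost
#' with a classification (fixed or variable), a basis (accrued once per
#' program period, or per visit), the visit stratum it applies to, whether a
#' payor already reimburses it (laboratory analysis and radiology studies with
#' interpretation, in the default taxonomy), and a PERT uncertainty triple.
#'
#' Fixed elements must have basis `"per_period"` and applicability `"all"`:
#' they are pooled and allocated across strata, so a stratum-specific fixed
#' cost has no meaning in this model. Variable elements may accrue per visit
#' (diagnostics, medications) or per period (fuel, vehicle maintenance, which
#' scale with operations rather than with a single visit); per-period variable
#' costs are split across strata by the same allocation rule as fixed costs
#' but stay in the variable totals.
#'
#' @param id Short unique key (string).
#' @param label Human-readable description.
#' @param classification `"fixed"` or `"variable"`.
#' @param basis `"per_period"` (USD per program period) or `"per_visit"`
#'   (USD per visit).
#' @param applicability `"all"`, `"basic_only"`, or `"advanced_only"`.
#' @param reimbursable Logical; `TRUE` only for payor-reimbursed diagnostic
#'   elements, which the unreimbursed scenario removes.
#' @param pert A [pert_params()] object (USD).
#' @return An object of class `cost_element`.
#' @export
cost_element <- function(id, label = id, classification = c("fixed", "variable"),
                         basis = c("per_period", "per_visit"),
                         applicability = c("all", "basic_only", "advanced_only"),
                         reimbursable = FALSE, pert) {
  classification <- match.arg(classification)
  basis <- match.arg(basis)
  applicability <- match.arg(applicability)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(label), length(label) == 1L,
            is.logical(reimbursable), length(reimbursable) == 1L,
            inherits(pert, "pert_params"))
  if (pert$min < 0)
    stop(sprintf("element '%s': cost values must be non-negative", id), call. = FALSE)
  if (classification == "fixed" && (basis != "per_period" || applicability != "all"))
    stop(sprintf("element '%s': fixed elements must have basis 'per_period' and applicability 'all'", id),
         call. = FALSE)
  structure(list(id = id, label = label, classification = classification,
                 basis = basis, applicability = applicability,
                 reimbursable = reimbursable, pert = pert),
            class = "cost_element")
}

#' Define the visit mix
#'
#' Annual encounter volume (PERT-varied, per the cost taxonomy that lists the
#' total annual number of encounters among the uncertain quantities) and the
#' deterministic split into basic and advanced complexity strata.
#'
#' @param annual_visits A [pert_params()] object for the annual encounter
#'   count; use a point-mass triple to fix the volume.
#' @param prop_basic,prop_advanced Stratum proportions; must sum to 1.
#' @return An object of class `visit_mix`.
#' @export
visit_mix <- function(annual_visits, prop_basic = 0.6,
                      prop_advanced = 1 - prop_basic) {
  stopifnot(inherits(annual_visits, "pert_params"))
  if (annual_visits$min <= 0)
    stop("annual_visits minimum must be > 0", call. = FALSE)
  if (!is.numeric(prop_basic) || !is.numeric(prop_advanced) ||
      prop_basic < 0 || prop_basic > 1 || prop_advanced < 0 || prop_advanced > 1)
    stop("visit proportions must lie in [0, 1]", call. = FALSE)
  if (abs(prop_basic + prop_advanced - 1) > 1e-9)
    stop(sprintf("prop_basic + prop_advanced must equal 1 (got %g + %g = %g)",
                 prop_basic, prop_advanced, prop_basic + prop_advanced),
         call. = FALSE)
  structure(list(annual_visits = annual_visits,
                 prop_basic = as.numeric(prop_basic),
                 prop_advanced = as.numeric(prop_advanced)),
            class = "visit_mix")
}

#' Assemble a program configuration
#'
#' The full model input: an ordered collection of cost elements, the visit
#' mix, simulation settings, and (optionally) per-stratum allocation weights.
#' With the default weights of 1 the fixed pool is allocated proportionally to
#' visit counts, which makes the per-visit fixed share identical across
#' strata; non-unit weights allocate proportionally to `weight * count`
#' (e.g. to reflect visit duration).
#'
#' @param elements List of [cost_element()] objects with unique ids; at least
#'   one fixed and one variable element.
#' @param visit_mix A [visit_mix()] object.
#' @param iterations Default Monte Carlo iterations (1000).
#' @param interval_level Probabilistic interval level (0.90 gives the
#'   5th-95th percentile interval).
#' @param seed Default master seed.
#' @param pert_shape PERT shape applied to triples loaded without one.
#' @param allocation_weights Named numeric `c(basic = , advanced = )`.
#' @return An object of class `mih_config`.
#' @export
program_config <- function(elements, visit_mix,
                           iterations = 1000L, interval_level = 0.90,
                           seed = 1L, pert_shape = 4,
                           allocation_weights = c(basic = 1, advanced = 1)) {
  cfg <- structure(list(elements = elements, visit_mix = visit_mix,
                        simulation = list(iterations = as.integer(iterations),
                                          interval_level = as.numeric(interval_level),
                                          seed = as.integer(seed),
                                          pert_shape = as.numeric(pert_shape)),
                        allocation_weights = c(basic = as.numeric(allocation_weights[["basic"]]),
                                               advanced = as.numeric(allocation_weights[["advanced"]]))),
                   class = "mih_config")
  validate_config(cfg)
}

#' Validate a program configuration
#'
#' Checks every structural invariant: element classes and unique ids, at
#' least one fixed and one variable element, visit-mix proportions, positive
#' simulation settings and allocation weights. Called by [program_config()]
#' and [read_program_config()]; exported so edited configurations can be
#' re-checked.
#'
#' @param config An `mih_config` object.
#' @return `config`, invisibly, if valid; otherwise an error naming the
#'   offending element or field.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "mih_config")) stop("not an 'mih_config' object", call. = FALSE)
  els <- config$elements
  if (length(els) == 0L) stop("configuration has no cost elements", call. = FALSE)
  for (e in els) if (!inherits(e, "cost_element"))
    stop("all elements must be 'cost_element' objects", call. = FALSE)
  ids <- vapply(els, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate element id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  cls <- vapply(els, `[[`, "", "classification")
  if (!any(cls == "fixed")) stop("configuration needs at least one fixed element", call. = FALSE)
  if (!any(cls == "variable")) stop("configuration needs at least one variable element", call. = FALSE)
  if (!inherits(config$visit_mix, "visit_mix"))
    stop("field 'visit_mix' must be a visit_mix object", call. = FALSE)
  sim <- config$simulation
  if (!is.numeric(sim$iterations) || sim$iterations < 1)
    stop("field 'simulation$iterations' must be a positive integer", call. = FALSE)
  if (!is.numeric(sim$interval_level) || sim$interval_level <= 0 || sim$interval_level >= 1)
    stop("field 'simulation$interval_level' must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(sim$pert_shape) || sim$pert_shape <= 0)
    stop("field 'simulation$pert_shape' must be positive", call. = FALSE)
  w <- config$allocation_weights
  if (length(w) != 2L || any(!is.finite(w)) || any(w <= 0))
    stop("field 'allocation_weights' must be two positive numbers", call. = FALSE)
  invisible(config)
}

element_ids <- function(config) vapply(config$elements, `[[`, "", "id")

get_element <- function(config, id) {
  i <- match(id, element_ids(config))
  if (is.na(i)) stop(sprintf("no element with id '%s'", id), call. = FALSE)
  config$elements[[i]]
}

#' @export
print.mih_config <- function(x, ...) {
  cls <- vapply(x$elements, `[[`, "", "classification")
  cat("Mobile integrated health program configuration\n")
  cat(sprintf("  %d cost elements (%d fixed, %d variable; %d reimbursable)\n",
              length(x$elements), sum(cls == "fixed"), sum(cls == "variable"),
              sum(vapply(x$elements, `[[`, NA, "reimbursable"))))
  cat(sprintf("  annual visits: PERT(%g, %g, %g); mix %.0f%% basic / %.0f%% advanced\n",
              x$visit_mix$annual_visits$min, x$visit_mix$annual_visits$mode,
              x$visit_mix$annual_visits$max,
              100 * x$visit_mix$prop_basic, 100 * x$visit_mix$prop_advanced))
  cat(sprintf("  simulation: %d iterations, %.0f%% interval, seed %d, PERT shape %g\n",
              x$simulation$iterations, 100 * x$simulation$interval_level,
              x$simulation$seed, x$simulation$pert_shape))
  invisible(x)
}

config_to_list <- function(config) {
  list(
    elements = lapply(config$elements, function(e)
      list(id = e$id, label = e$label, classification = e$classification,
           basis = e$basis, applicability = e$applicability,
           reimbursable = e$reimbursable,
           pert = list(min = e$pert$min, mode = e$pert$mode, max = e$pert$max))),
    visit_mix = list(
      annual_visits = list(min = config$visit_mix$annual_visits$min,
                           mode = config$visit_mix$annual_visits$mode,
                           max = config$visit_mix$annual_visits$max),
      prop_basic = config$visit_mix$prop_basic,
      prop_advanced = config$visit_mix$prop_advanced),
    simulation = config$simulation,
    allocation_weights = as.list(config$allocation_weights))
}

config_from_list <- function(x, source = "<config>") {
  need <- function(obj, field, where) {
    if (is.null(obj[[field]]))
      stop(sprintf("%s: missing required field '%s' in %s", source, field, where),
           call. = FALSE)
    obj[[field]]
  }
  sim <- x$simulation %||% list()
  shape <- sim$pert_shape %||% 4
  parse_pert <- function(p, where) {
    pert_params(need(p, "min", where), need(p, "mode", where), need(p, "max", where),
                shape = p$shape %||% shape)
  }
  els_raw <- need(x, "elements", "configuration")
  els <- lapply(els_raw, function(e) {
    id <- need(e, "id", "element")
    cost_element(id = id,
                 label = e$label %||% id,
                 classification = need(e, "classification", sprintf("element '%s'", id)),
                 basis = e$basis %||% if (identical(e$classification, "fixed")) "per_period" else "per_visit",
                 applicability = e$applicability %||% "all",
                 reimbursable = isTRUE(e$reimbursable),
                 pert = parse_pert(need(e, "pert", sprintf("element '%s'", id)),
                                   sprintf("element '%s' pert", id)))
  })
  vm_raw <- need(x, "visit_mix", "configuration")
  pb <- need(vm_raw, "prop_basic", "visit_mix")
  vm <- visit_mix(parse_pert(need(vm_raw, "annual_visits", "visit_mix"), "annual_visits"),
                  prop_basic = pb,
                  prop_advanced = vm_raw$prop_advanced %||% (1 - pb))
  w <- x$allocation_weights %||% list(basic = 1, advanced = 1)
  program_config(els, vm,
                 iterations = sim$iterations %||% 1000L,
                 interval_level = sim$interval_level %||% 0.90,
                 seed = sim$seed %||% 1L,
                 pert_shape = shape,
                 allocation_weights = c(basic = w$basic %||% 1,
                                        advanced = w$advanced %||% 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a program configuration from YAML or JSON
#'
#' Parses the documented structured-text schema (YAML primary, JSON accepted
#' by file extension), fills defaults (PERT shape 4, 1000 iterations, 90%
#' interval, unit allocation weights), and validates every invariant.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `mih_config` object.
#' @seealso [write_program_config()], [mih_template()] for the packaged
#'   cost-taxonomy template.
#' @export
read_program_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  config_from_list(raw, source = path)
}

#' Write a program configuration to YAML or JSON
#'
#' Serializes losslessly enough that
#' `read_program_config(write_program_config(cfg, f))` reproduces an equal
#' configuration.
#'
#' @param config An `mih_config` object.
#' @param path Output path; format chosen by extension as in
#'   [read_program_config()].
#' @return `path`, invisibly.
#' @export
write_program_config <- function(config, path) {
  validate_config(config)
  x <- config_to_list(config)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Remove payor-reimbursed cost elements
#'
#' Returns a copy of the configuration with every element whose
#' `reimbursable` flag is `TRUE` removed (laboratory analysis and radiology
#' in the default taxonomy), leaving all other fields identical. This is the
#' unreimbursed-cost scenario: the program's cost burden after excluding
#' services a payor already pays for. Idempotent; with no reimbursable
#' elements it is the identity.
#'
#' @param config An `mih_config` object.
#' @return An `mih_config` with reimbursable elements removed.
#' @export
filter_unreimbursed <- function(config) {
  validate_config(config)
  keep <- !vapply(config$elements, `[[`, NA, "reimbursable")
  config$elements <- config$elements[keep]
  validate_config(config)
}

#' Classify an encounter as basic or advanced
#'
#' A visit is advanced if it used two or more distinct diagnostic modalities
#' (laboratory and radiology each count once regardless of the number of
#' panels or studies) or any intravenous therapy (including fluids);
#' otherwise it is basic. A visit with no diagnostics and no IV therapy is
#' basic (evaluation, telehealth consult and referral only) — the advanced
#' triggers are the enumerated ones.
#'
#' @param encounters A data frame with columns `lab_panels`,
#'   `radiology_studies`, `iv_therapies` (non-negative counts), e.g. from
#'   [generate_encounters()].
#' @return Character vector, `"basic"` or `"advanced"` per row.
#' @examples
#' classify_visit(data.frame(lab_panels = c(1, 1, 0),
#'                           radiology_studies = c(0, 1, 0),
#'                           iv_therapies = c(0, 0, 1)))
#' @export
classify_visit <- function(encounters) {
  for (col in c("lab_panels", "radiology_studies", "iv_therapies")) {
    v <- encounters[[col]]
    if (is.null(v)) stop(sprintf("missing column '%s'", col), call. = FALSE)
    if (any(is.na(v)) || any(v < 0))
      stop(sprintf("column '%s' must contain non-negative counts", col), call. = FALSE)
  }
  modalities <- (encounters$lab_panels > 0) + (encounters$radiology_studies > 0)
  ifelse(modalities >= 2 | encounters$iv_therapies >= 1, "advanced", "basic")
}

# Polynomial rolling hash (two independent moduli) over the canonical JSON
# serialization; cheap content identity for reproducibility logging, not
# cryptographic.
config_digest <- function(config) {
  js <- jsonlite::toJSON(config_to_list(config), auto_unbox = TRUE, digits = 15)
  bytes <- utf8ToInt(as.character(js))
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% 2147483647
    h2 <- (h2 * 137 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

#' Path to the packaged cost-taxonomy template
#'
#' Returns the packaged `table1_template.yaml`: a program configuration with
#' the standard acute-care mobile integrated health cost taxonomy — personnel
#' (6.5 FTE paramedics, 1.0 FTE administrator, 0.5 FTE physician medical
#' direction), administrative costs, non-disposable clinical equipment, and
#' variable fuel, vehicle maintenance, laboratory analysis, radiology, and
#' medication/supply elements — with roughly 800 annual visits split 60/40
#' between basic and advanced strata. The dollar ranges are placeholder
#' orders of magnitude (public salary and equipment figures), not any
#' specific program's books; calibrate with [calibrate_config()] to match
#' target medians.
#'
#' @param load If `TRUE` (default) return the parsed `mih_config`; otherwise
#'   the file path.
#' @return An `mih_config` object or a file path.
#' @export
mih_template <- function(load = TRUE) {
  path <- system.file("extdata", "table1_template.yaml", package = "mihcost",
                      mustWork = TRUE)
  if (load) read_program_config(path) else path
}
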