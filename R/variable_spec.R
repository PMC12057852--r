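#' Per-variable dichotomization recipe
#'
#' A `variable_spec` describes how one cohort variable is turned into items:
#' a fixed clinical cut-off (`fixed_cutoff`), an equal-frequency median split
#' (`median_split`), or a pass-through of categorical levels
#' (`categorical_passthrough`). Orientation (`high_if`) says which comparison
#' against the cut-off yields the "high" state; the default `ge` means
#' value >= cutoff is high, matching the usual clinical conventions
#' (age >= 60 years is "old", CES-D >= 16 is "depressive symptoms",
#' BMI >= 30 is "obesity", one or more comorbidities is "comorbidities",
#' SF-12 standard score >= 50 is the high component score).
#'
#' @param variable column name in the cohort table.
#' @param method one of `fixed_cutoff`, `median_split`,
#'   `categorical_passthrough`.
#' @param cutoff numeric cut-off; required for (and only for) `fixed_cutoff`.
#' @param high_if comparison that defines the high state: `ge` (default),
#'   `gt`, `le`, or `lt`.
#' @param labels named character vector of human-readable state labels.
#'   For dichotomized variables names `high` and `low`; for categorical
#'   variables one label per level. Missing labels default to the state name.
#' @param levels admissible levels, for categorical variables.
#' @return an object of class `variable_spec`.
#' @export
variable_spec <- function(variable,
                          method = c("fixed_cutoff", "median_split",
                                     "categorical_passthrough"),
                          cutoff = NULL, high_if = "ge",
                          labels = NULL, levels = NULL) {
  known <- c("fixed_cutoff", "median_split", "categorical_passthrough")
  if (length(method) > 1) method <- method[1]
  if (!method %in% known) {
    stop_("config error: unknown method '%s' for variable '%s'",
          method, variable)
  }
  if (method == "fixed_cutoff") {
    if (is.null(cutoff) || !is.finite(cutoff)) {
      stop_("config error: variable '%s' uses fixed_cutoff but has no cutoff",
            variable)
    }
  } else if (!is.null(cutoff)) {
    stop_("config error: variable '%s' has a cutoff but method '%s'",
          variable, method)
  }
  if (!high_if %in% c("ge", "gt", "le", "lt")) {
    stop_("config error: variable '%s': high_if must be ge/gt/le/lt", variable)
  }
  if (method == "categorical_passthrough" && is.null(levels)) {
    stop_("config error: categorical variable '%s' needs levels", variable)
  }
  states <- if (method == "categorical_passthrough") levels else c("high", "low")
  lab <- stats::setNames(states, states)
  if (!is.null(labels)) {
    labels <- unlist(labels)
    unknown <- setdiff(names(labels), states)
    if (length(unknown) > 0) {
      stop_("config error: variable '%s': label for unknown state '%s'",
            variable, unknown[1])
    }
    lab[names(labels)] <- labels
  }
  if (anyDuplicated(lab)) {
    stop_("config error: variable '%s': state labels must be distinct", variable)
  }
  structure(list(variable = variable, method = method, cutoff = cutoff,
                 high_if = high_if, labels = lab, levels = levels),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  cut <- if (is.null(x$cutoff)) "" else sprintf(" (cutoff %s, high if %s)",
                                                format(x$cutoff), x$high_if)
  cat(sprintf("<variable_spec> %s: %s%s; states: %s\n", x$variable, x$method,
              cut, paste(x$labels, collapse = " / ")))
  invisible(x)
}

#' Read a per-variable dichotomization config
#'
#' The config is a YAML (or JSON) mapping from variable name to
#' `{method, cutoff, high_if, labels, levels}`; unspecified options take
#' their defaults (`high_if: ge`, state names as labels).
#'
#' @param path path to a YAML or JSON config file.
#' @return a named list of [variable_spec()] objects.
#' @export
read_variable_config <- function(path) {
  if (!file.exists(path)) stop_("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  if (is.null(y) || length(y) == 0) stop_("config error: no variables configured")
  specs <- lapply(names(y), function(v) {
    e <- y[[v]]
    variable_spec(v,
                  method = e$method %||% stop_("config error: variable '%s' has no method", v),
                  cutoff = e$cutoff,
                  high_if = e$high_if %||% "ge",
                  labels = e$labels,
                  levels = unlist(e$levels))
  })
  stats::setNames(specs, names(y))
}

#' Default dichotomization config
#'
#' The configuration shipped with the package: age >= 60 years, BMI >= 30
#' kg/m^2, CES-D >= 16, CCI >= 1 comorbidity, SF-12 component scores split at
#' the standard score 50, equal-frequency (median) splits for the
#' sit-to-stand time and the three WOMAC subscales, and categorical
#' pass-through for sex and artificial joint type.
#'
#' @return a named list of 16 [variable_spec()] objects.
#' @export
default_variable_specs <- function() {
  read_variable_config(system.file("extdata", "variables.yaml",
                                   package = "clinrules", mustWork = TRUE))
}
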