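#' Default conclusion items: low PCS and MCS at 1 and 2 years
#'
#' @return list of four `"variable=state"` consequent ids.
#' @export
default_consequents <- function() {
  c("pcs_1y=low", "pcs_2y=low", "mcs_1y=low", "mcs_2y=low")
}

#' Run the full screen over several consequents
#'
#' One [rule_screen()] per consequent (by default the four low postoperative
#' SF-12 components). A consequent whose prior is 0 or 1 in the given cohort
#' cannot be mined; it is reported as degenerate with an empty rule table
#' rather than aborting the run. An empty rule table is itself a valid,
#' reported outcome. When `out_dir` is given, writes one TSV rule table per
#' consequent plus `summary.json` and `manifest.json`.
#'
#' @param cohort a `cohort_table`.
#' @param consequents vector/list of consequent items.
#' @param specs dichotomization recipes.
#' @param ... gates and test options passed to [rule_screen()].
#' @param out_dir optional output directory.
#' @param seed optional seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return object of class `rule_analysis`: named list of `rule_screen`
#'   results (or degenerate-consequent notes), with the output inventory as
#'   an attribute when written.
#' @export
rule_analysis <- function(cohort, consequents = default_consequents(),
                          specs = default_variable_specs(), ...,
                          out_dir = NULL, seed = NULL) {
  screens <- lapply(consequents, function(cons) {
    tryCatch(rule_screen(cohort, consequent = cons, specs = specs, ...),
             error = function(e) {
               if (grepl("degenerate consequent", conditionMessage(e))) {
                 structure(list(consequent = cons_id_of(cons),
                                note = conditionMessage(e)),
                           class = "degenerate_consequent")
               } else {
                 stop(e)
               }
             })
  })
  names(screens) <- vapply(consequents, cons_id_of, "")
  out <- structure(screens, class = "rule_analysis")
  if (!is.null(out_dir)) {
    attr(out, "files") <- write_analysis(out, out_dir, specs, seed)
  }
  out
}

cons_id_of <- function(x) {
  it <- as_item(x)
  item_id(it[["variable"]], it[["state"]])
}

#' @export
print.rule_analysis <- function(x, ...) {
  cat(sprintf("Association rule analysis over %d consequent(s)\n", length(x)))
  for (nm in names(x)) {
    s <- x[[nm]]
    if (inherits(s, "degenerate_consequent")) {
      cat(sprintf("  %-12s degenerate consequent (prior 0 or 1), not mined\n", nm))
    } else {
      n_sig <- sum(s$tests$significant %||% logical(0))
      cat(sprintf("  %-12s %d single + %d combined rule(s), %d significant at alpha = %s\n",
                  nm, sum(s$rules$order == 1), sum(s$rules$order == 2),
                  n_sig, format(s$config$alpha)))
    }
  }
  invisible(x)
}

write_analysis <- function(analysis, out_dir, specs, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(analysis)) {
    s <- analysis[[nm]]
    if (inherits(s, "degenerate_consequent")) next
    path <- file.path(out_dir, paste0("rules_", gsub("=", "_", nm), ".tsv"))
    write_rules_table(s$rules, s$tests, path)
    files <- c(files, path)
  }
  summary_path <- file.path(out_dir, "summary.json")
  write_run_summary(analysis, summary_path)
  files <- c(files, summary_path)
  manifest_path <- file.path(out_dir, "manifest.json")
  write_manifest(analysis, files, manifest_path, specs, seed)
  c(files, manifest_path)
}

#' Write a TSV rule table
#'
#' One row per rule: antecedent and consequent labels, support and
#' confidence as percentages and lift, all rounded half-up to two decimals;
#' the 2x2 counts; the chosen test, its p-value (4 significant figures) and
#' the significance flag. An empty rule set yields a header-only file.
#'
#' @param rules a `rule_set`.
#' @param tests matching output of [test_all()] (same mining run).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rules_table <- function(rules, tests, path) {
  if (nrow(rules) > 0 && nrow(tests) != nrow(rules)) {
    stop_("rules and tests must come from the same run (%d vs %d rows)",
          nrow(rules), nrow(tests))
  }
  df <- merge_rules_tests(rules, tests)
  df$p_value <- if (nrow(df) > 0) formatC(signif(df$p_value, 4), format = "fg") else character(0)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_("cannot write rule table to '%s'", path)
  invisible(path)
}

#' Write the JSON run summary
#'
#' Per consequent: N, prior, lift ceiling, the gates used, rule counts per
#' order and the number of significant rules.
#'
#' @param analysis a `rule_analysis` (or named list of `rule_screen`s).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(analysis, path) {
  entries <- lapply(names(analysis), function(nm) {
    s <- analysis[[nm]]
    if (inherits(s, "degenerate_consequent")) {
      return(list(consequent = nm, degenerate = TRUE, note = s$note))
    }
    list(consequent = nm, n = s$n, prior = s$prior,
         lift_ceiling = s$lift_ceiling,
         gates = list(min_confidence = s$config$min_confidence,
                      min_lift = s$config$min_lift,
                      min_support = s$config$min_support,
                      max_order = s$config$max_order,
                      alpha = s$config$alpha),
         n_single = sum(s$rules$order == 1),
         n_combined = sum(s$rules$order == 2),
         n_significant = sum(s$tests$significant %||% logical(0)))
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

config_digest <- function(obj) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(analysis, files, path, specs, seed) {
  gates <- NULL
  for (s in analysis) if (inherits(s, "rule_screen")) { gates <- s$config; break }
  spec_repr <- lapply(specs, function(sp) {
    list(variable = sp$variable, method = sp$method, cutoff = sp$cutoff,
         high_if = sp$high_if, labels = as.list(sp$labels))
  })
  manifest <- list(
    package = "clinrules",
    version = as.character(utils::packageVersion("clinrules")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_digest = config_digest(list(specs = spec_repr, gates = gates)),
    consequents = names(analysis),
    files = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Recompute metrics and tests from labelled 2x2 counts
#'
#' Audit path: given rows of published applicable/non-applicable counts,
#' recomputes support, confidence and lift (rounded half-up to two decimals)
#' and runs the contingency-table test, without needing individual-level
#' data. A malformed row (e.g. an antecedent that never holds) is reported
#' in its `error` column; the remaining rows are still processed.
#'
#' @param x a data.frame with columns `label`, `a`, `b`, `c`, `d`, or a path
#'   to a TSV with those columns.
#' @param alpha significance level.
#' @return data.frame with per-row metrics, test results, and `error`.
#' @export
#' @examples
#' verify_counts(data.frame(label = "comorbidities", a = 10, b = 0, c = 22, d = 12))
verify_counts <- function(x, alpha = 0.05) {
  if (is.character(x)) {
    x <- utils::read.delim(x, stringsAsFactors = FALSE)
  }
  needed <- c("label", "a", "b", "c", "d")
  if (!all(needed %in% names(x))) {
    stop_("counts table needs columns: %s", paste(needed, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(x)), function(i) {
    base <- data.frame(label = x$label[i], a = x$a[i], b = x$b[i],
                       c = x$c[i], d = x$d[i], stringsAsFactors = FALSE)
    tryCatch({
      met <- rule_metrics_from_counts(x$a[i], x$b[i], x$c[i], x$d[i])
      tst <- test_rule(c(x$a[i], x$b[i], x$c[i], x$d[i]), alpha = alpha)
      cbind(base,
            data.frame(support_pct = round_half_up(100 * met$support, 2),
                       confidence_pct = round_half_up(100 * met$confidence, 2),
                       lift = round_half_up(met$lift, 2),
                       test_used = tst$test_used, p_value = tst$p_value,
                       significant = tst$significant,
                       error = NA_character_, stringsAsFactors = FALSE))
    }, error = function(e) {
      cbind(base,
            data.frame(support_pct = NA_real_, confidence_pct = NA_real_,
                       lift = NA_real_, test_used = NA_character_,
                       p_value = NA_real_, significant = NA,
                       error = sprintf("row %d: %s", i, conditionMessage(e)),
                       stringsAsFactors = FALSE))
    })
  })
  do.call(rbind, rows)
}
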