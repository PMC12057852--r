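#' Screen a cohort for association rules against one consequent
#'
#' The central fitting step: dichotomizes the cohort into the item universe,
#' exhaustively mines 1- and 2-condition rules for the given consequent
#' under the confidence/lift/support gates, tests each surviving rule's
#' applicable/non-applicable 2x2 table (Fisher's exact or chi-squared by
#' Cochran's rule), and compares every combined rule against its constituent
#' single rules.
#'
#' @param cohort a `cohort_table` (see [read_cohort()], [simulate_cohort()]).
#' @param consequent conclusion item, e.g. `"pcs_2y=low"` or
#'   `c(variable = "pcs_2y", state = "low")`.
#' @param specs dichotomization recipes; default [default_variable_specs()].
#' @param max_order,min_confidence,min_lift,min_support,excluded_variables
#'   mining gates, see [mine_rules()]. Defaults: order <= 2, confidence
#'   >= 0.80, lift >= 1.1, no support floor.
#' @param alpha significance level for the contingency-table tests.
#' @param adjustment multiplicity adjustment, see [test_all()].
#' @param test,correct test choice and Yates correction, see [test_rule()].
#' @return object of class `rule_screen`: list with `consequent`, `n`,
#'   `prior`, `lift_ceiling`, `item_matrix`, `rules` (a `rule_set`), `tests`,
#'   `comparison`, and the configuration used.
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_config(seed = 1))
#' fit <- rule_screen(cohort, "pcs_2y=low")
#' print(fit)
rule_screen <- function(cohort, consequent = c(variable = "pcs_2y", state = "low"),
                        specs = default_variable_specs(), max_order = 2,
                        min_confidence = 0.80, min_lift = 1.1,
                        min_support = 0, excluded_variables = NULL,
                        alpha = 0.05, adjustment = "none",
                        test = "auto", correct = FALSE) {
  im <- build_item_matrix(cohort, unname(specs))
  rules <- mine_rules(im, consequent, max_order = max_order,
                      min_confidence = min_confidence, min_lift = min_lift,
                      min_support = min_support,
                      excluded_variables = excluded_variables)
  tests <- if (nrow(rules) > 0) {
    test_all(rules, alpha = alpha, adjustment = adjustment,
             test = test, correct = correct)
  } else {
    data.frame(antecedent = character(), a = integer(), b = integer(),
               c = integer(), d = integer(), test_used = character(),
               p_value = numeric(), significant = logical(),
               stringsAsFactors = FALSE)
  }
  singles <- rules[rules$order == 1, , drop = FALSE]
  combined <- rules[rules$order == 2, , drop = FALSE]
  for (s in c("consequent", "n_total", "prior")) {
    attr(singles, s) <- attr(rules, s); attr(combined, s) <- attr(rules, s)
  }
  comparison <- compare_single_vs_combined(singles, combined)
  structure(list(consequent = attr(rules, "consequent"),
                 consequent_label = if (nrow(rules) > 0) rules$consequent[1] else
                   attr(rules, "consequent"),
                 n = attr(rules, "n_total"),
                 prior = attr(rules, "prior"),
                 lift_ceiling = 1 / attr(rules, "prior"),
                 item_matrix = im, rules = rules, tests = tests,
                 comparison = comparison,
                 config = c(attr(rules, "config"),
                            list(alpha = alpha, adjustment = adjustment,
                                 test = test, correct = correct))),
            class = "rule_screen")
}

#' @export
print.rule_screen <- function(x, ...) {
  cat(sprintf("Association rule screen: consequent %s\n", x$consequent))
  cat(sprintf("  N = %d, prior = %.4f, lift ceiling = %.4f\n",
              x$n, x$prior, x$lift_ceiling))
  cat(sprintf("  gates: confidence >= %s, lift >= %s, support >= %s, order <= %d\n",
              x$config$min_confidence, x$config$min_lift,
              x$config$min_support, x$config$max_order))
  n1 <- sum(x$rules$order == 1); n2 <- sum(x$rules$order == 2)
  cat(sprintf("  %d single and %d combined rule(s) pass the gates\n", n1, n2))
  if (nrow(x$rules) > 0) {
    df <- merge_rules_tests(x$rules, x$tests)
    show <- utils::head(df, 10)
    cat("\n")
    print(data.frame(antecedent = show$antecedent,
                     `support %` = show$support_pct,
                     `confidence %` = show$confidence_pct,
                     lift = show$lift, p = format_p(show$p_value),
                     check.names = FALSE), row.names = FALSE)
    if (nrow(df) > 10) cat(sprintf("  ... and %d more\n", nrow(df) - 10))
  }
  invisible(x)
}

#' @export
summary.rule_screen <- function(object, ...) {
  out <- merge_rules_tests(object$rules, object$tests)
  if (nrow(object$comparison) > 0) {
    out <- merge(out,
                 object$comparison[, c("antecedent", "strengthened",
                                       "lift_ceiling")],
                 by = "antecedent", all.x = TRUE, sort = FALSE)
    # restore the deterministic rule order after merge
    out <- out[order(-out$lift, -out$confidence_pct, -out$support_pct,
                     out$antecedent), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

merge_rules_tests <- function(rules, tests) {
  df <- as.data.frame(rules)
  df$support_pct <- round_half_up(100 * df$support, 2)
  df$confidence_pct <- round_half_up(100 * df$confidence, 2)
  df$lift <- round_half_up(df$lift, 2)
  keep <- c("antecedent", "consequent", "order", "a", "b", "c", "d",
            "support_pct", "confidence_pct", "lift")
  df <- df[, intersect(keep, names(df)), drop = FALSE]
  if (nrow(tests) > 0) {
    extra <- setdiff(names(tests), c("antecedent", "a", "b", "c", "d"))
    df <- cbind(df, tests[, extra, drop = FALSE])
  } else {
    df$test_used <- character(0); df$p_value <- numeric(0)
    df$significant <- logical(0)
  }
  df
}
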