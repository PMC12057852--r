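expected_counts_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  outer(c(a + b, c + d), c(a + c, b + d)) / n
}

#' Choose Fisher's exact or chi-squared test for a 2x2 table
#'
#' Applies Cochran's rule: Fisher's exact test whenever any expected cell
#' count (row total x column total / N) is below 5, the chi-squared test
#' otherwise.
#'
#' @param a,b,c,d 2x2 counts, rows applicable/non-applicable, columns
#'   consequent present/absent. Both row margins must be positive.
#' @return `"fisher"` or `"chisq"`.
#' @export
#' @examples
#' choose_test(10, 0, 22, 12) # "fisher": expected a-row high-outcome = 2.73
choose_test <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop_("counts must be finite and non-negative")
  }
  if (a + b == 0 || c + d == 0) {
    stop_("degenerate margin: empty applicable or non-applicable row")
  }
  if (min(expected_counts_2x2(a, b, c, d)) < 5) "fisher" else "chisq"
}

#' Test one rule's 2x2 table for association
#'
#' Two-sided test of whether the consequent proportion differs between the
#' applicable and non-applicable groups. The test is chosen by Cochran's rule
#' unless forced; Fisher's two-sided p-value sums the probabilities of all
#' tables with the given margins whose probability does not exceed the
#' observed table's. The chi-squared test uses no continuity correction by
#' default (`correct = TRUE` enables Yates' correction).
#'
#' @param rule a one-row `rule_set`, a list with fields `a`-`d`, or a numeric
#'   vector `c(a, b, c, d)`.
#' @param alpha significance level (default 0.05).
#' @param test `"auto"` (Cochran's rule), `"fisher"`, or `"chisq"`.
#' @param correct apply Yates' continuity correction to the chi-squared test.
#' @return object of class `rule_test`: list with `counts`, `expected`,
#'   `test_used`, `p_value`, `alpha`, `significant`.
#' @export
test_rule <- function(rule, alpha = 0.05, test = c("auto", "fisher", "chisq"),
                      correct = FALSE) {
  test <- match.arg(test)
  if (is.numeric(rule) && length(rule) == 4) {
    counts <- stats::setNames(as.numeric(rule), c("a", "b", "c", "d"))
  } else {
    counts <- c(a = as.numeric(rule$a), b = as.numeric(rule$b),
                c = as.numeric(rule$c), d = as.numeric(rule$d))
  }
  if (alpha <= 0 || alpha >= 1) stop_("alpha must lie in (0, 1)")
  auto <- choose_test(counts[1], counts[2], counts[3], counts[4])
  test_used <- if (test == "auto") auto else test
  tab <- matrix(counts, nrow = 2, byrow = TRUE,
                dimnames = list(c("applicable", "non_applicable"),
                                c("consequent", "no_consequent")))
  p <- if (test_used == "fisher") {
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  } else {
    suppressWarnings(stats::chisq.test(tab, correct = correct)$p.value)
  }
  p <- min(1, p)
  structure(list(counts = counts,
                 expected = expected_counts_2x2(counts[1], counts[2],
                                                counts[3], counts[4]),
                 test_used = test_used, p_value = p, alpha = alpha,
                 significant = p < alpha),
            class = "rule_test")
}

#' @export
print.rule_test <- function(x, ...) {
  cat(sprintf("<rule_test> %s: p = %s (%ssignificant at alpha = %s)\n",
              x$test_used, format_p(x$p_value),
              if (x$significant) "" else "not ", format(x$alpha)))
  invisible(x)
}

format_p <- function(p, digits = 4) {
  ifelse(p < 0.001, "<0.001", formatC(signif(p, digits), format = "fg"))
}

#' Test every rule in a mined set
#'
#' One two-sided test per rule, in input order. No multiplicity adjustment is
#' applied by default; `adjustment = "benjamini_hochberg"` additionally
#' reports BH-adjusted p-values (and a separate significance flag) alongside
#' the raw ones.
#'
#' @param rules a `rule_set` (or data.frame with columns `a`-`d`).
#' @param alpha significance level.
#' @param adjustment `"none"` or `"benjamini_hochberg"`.
#' @param test,correct passed to [test_rule()].
#' @return data.frame with one row per rule: counts, `test_used`, `p_value`,
#'   `significant`, and when adjusted also `p_adjusted`,
#'   `significant_adjusted`.
#' @export
test_all <- function(rules, alpha = 0.05,
                     adjustment = c("none", "benjamini_hochberg"),
                     test = "auto", correct = FALSE) {
  adjustment <- match.arg(adjustment)
  if (nrow(rules) == 0) stop_("no rules to test")
  res <- lapply(seq_len(nrow(rules)), function(i) {
    t <- test_rule(c(rules$a[i], rules$b[i], rules$c[i], rules$d[i]),
                   alpha = alpha, test = test, correct = correct)
    data.frame(antecedent = rules$antecedent[i] %||% NA_character_,
               a = rules$a[i], b = rules$b[i], c = rules$c[i], d = rules$d[i],
               test_used = t$test_used, p_value = t$p_value,
               significant = t$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjustment == "benjamini_hochberg") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant_adjusted <- out$p_adjusted < alpha
  }
  out
}
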