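#' Support, confidence and lift from 2x2 counts
#'
#' For a rule A -> B with applicable/non-applicable counts `a` (A and B),
#' `b` (A and not B), `c` (not A and B), `d` (neither):
#' support = a/N, confidence = a/(a+b), and lift = confidence divided by the
#' consequent's prior (a+c)/N. Lift above 1 means the antecedent raises the
#' probability of the consequent; its ceiling is N/(a+c), attained exactly
#' when confidence is 1.
#'
#' @param a,b,c,d non-negative 2x2 counts.
#' @return list with `support`, `confidence`, `lift` (all unrounded
#'   fractions/ratios) plus `n` and `prior`.
#' @export
#' @examples
#' rule_metrics_from_counts(10, 0, 22, 12) # support 0.2273, conf 1, lift 1.375
rule_metrics_from_counts <- function(a, b, c, d) {
  a <- unname(a); b <- unname(b); c <- unname(c); d <- unname(d)
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop_("counts must be finite and non-negative")
  }
  n <- a + b + c + d
  if (a + b == 0) stop_("undefined confidence: antecedent never holds (a + b = 0)")
  if (a + c == 0) stop_("undefined lift: consequent never holds (a + c = 0)")
  confidence <- a / (a + b)
  prior <- (a + c) / n
  list(support = a / n, confidence = confidence, lift = confidence / prior,
       n = n, prior = prior)
}

#' Cross-tabulate a rule against an item matrix
#'
#' A participant is "applicable" when all antecedent items are true for them
#' (conjunction); the 2x2 table crosses applicability with the consequent
#' item and always partitions N.
#'
#' @param im an `item_matrix`.
#' @param antecedent character vector of 1 or 2 item ids (`"variable=state"`),
#'   from distinct variables, none sharing the consequent's variable.
#' @param consequent a single item id.
#' @return named numeric vector `c(a =, b =, c =, d =)`.
#' @export
count_rule <- function(im, antecedent, consequent) {
  all_ids <- colnames(im$membership)
  unknown <- setdiff(c(antecedent, consequent), all_ids)
  if (length(unknown) > 0) {
    stop_("unknown item(s): %s", paste(unknown, collapse = ", "))
  }
  vars <- im$items$variable[match(antecedent, all_ids)]
  if (anyDuplicated(vars)) {
    stop_("antecedent uses two states of variable '%s'", vars[duplicated(vars)][1])
  }
  cons_var <- im$items$variable[match(consequent, all_ids)]
  if (cons_var %in% vars) {
    stop_("antecedent and consequent share variable '%s'", cons_var)
  }
  M <- im$membership
  applicable <- rowSums(M[, antecedent, drop = FALSE]) == length(antecedent)
  con <- M[, consequent]
  c(a = sum(applicable & con), b = sum(applicable & !con),
    c = sum(!applicable & con), d = sum(!applicable & !con))
}

#' Exhaustively mine 1- and 2-condition rules for one consequent
#'
#' Enumerates every antecedent of one item, and every pair of items from two
#' distinct variables, against the fixed consequent, excluding the
#' consequent's own variable (and any variable in `excluded_variables`, e.g.
#' to restrict a sensitivity analysis to preoperative conditions). A rule is
#' kept when confidence >= `min_confidence`, lift >= `min_lift`, and
#' support >= `min_support`; there is no support floor by default. Output
#' order is deterministic: lift, confidence, support all descending, then
#' antecedent label.
#'
#' @param im an `item_matrix`.
#' @param consequent the conclusion item, as `"variable=state"` or
#'   `c(variable =, state =)`.
#' @param max_order 1 or 2 antecedent conditions.
#' @param min_confidence,min_lift,min_support extraction gates; defaults
#'   confidence 0.80, lift 1.1, no support floor.
#' @param excluded_variables variables barred from antecedents (the
#'   consequent's variable always is).
#' @return a `rule_set`: data.frame with one row per surviving rule
#'   (antecedent label, item ids, counts a-d, support, confidence, lift,
#'   order), with the consequent, N, prior and gates as attributes.
#' @export
mine_rules <- function(im, consequent, max_order = 2,
                       min_confidence = 0.80, min_lift = 1.1,
                       min_support = 0, excluded_variables = NULL) {
  if (!max_order %in% c(1, 2)) stop_("max_order must be 1 or 2")
  # min_confidence above 1 is allowed as an (unattainable) gate
  if (min_confidence < 0) stop_("min_confidence must be non-negative")
  if (min_support < 0 || min_support > 1) stop_("min_support must lie in [0, 1]")
  if (min_lift <= 0) stop_("min_lift must be positive")
  cons <- as_item(consequent)
  cons_id <- item_id(cons[["variable"]], cons[["state"]])
  M <- im$membership
  if (!cons_id %in% colnames(M)) stop_("unknown consequent item '%s'", cons_id)
  n <- nrow(M)
  prior <- mean(M[, cons_id])
  if (prior <= 0 || prior >= 1) stop_("degenerate consequent: prior is %s", prior)

  barred <- union(cons[["variable"]], excluded_variables)
  cand <- which(!(im$items$variable %in% barred))
  cand_ids <- colnames(M)[cand]
  cand_vars <- im$items$variable[cand]

  antecedents <- lapply(cand_ids, function(id) id)
  if (max_order == 2 && length(cand_ids) >= 2) {
    pairs <- utils::combn(seq_along(cand_ids), 2, simplify = FALSE)
    pairs <- Filter(function(p) cand_vars[p[1]] != cand_vars[p[2]], pairs)
    antecedents <- c(antecedents,
                     lapply(pairs, function(p) cand_ids[p]))
  }

  con <- M[, cons_id]
  rows <- lapply(antecedents, function(ids) {
    applicable <- if (length(ids) == 1) M[, ids] else M[, ids[1]] & M[, ids[2]]
    a <- sum(applicable & con); b <- sum(applicable) - a
    if (a + b == 0) return(NULL)  # antecedent never holds: no rule emitted
    cc <- sum(con) - a; d <- n - a - b - cc
    conf <- a / (a + b)
    sup <- a / n
    lift <- conf / prior
    if (conf < min_confidence || lift < min_lift || sup < min_support) return(NULL)
    labels <- sort(im$items$label[match(ids, colnames(M))])
    data.frame(antecedent = paste(labels, collapse = " + "),
               antecedent_items = I(list(ids)),
               consequent = im$items$label[match(cons_id, colnames(M))],
               a = a, b = b, c = cc, d = d, n = n,
               support = sup, confidence = conf, lift = lift,
               order = length(ids), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows) == 0) empty_rule_set() else do.call(rbind, rows)
  if (nrow(out) > 0) {
    ord <- order(-out$lift, -out$confidence, -out$support, out$antecedent)
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out,
            class = c("rule_set", "data.frame"),
            consequent = cons_id, n_total = n, prior = prior,
            config = list(max_order = max_order,
                          min_confidence = min_confidence,
                          min_lift = min_lift, min_support = min_support,
                          excluded_variables = excluded_variables))
}

empty_rule_set <- function() {
  data.frame(antecedent = character(), antecedent_items = I(list()),
             consequent = character(), a = integer(), b = integer(),
             c = integer(), d = integer(), n = integer(),
             support = numeric(), confidence = numeric(), lift = numeric(),
             order = integer(), stringsAsFactors = FALSE)
}

#' @export
print.rule_set <- function(x, digits = 2, ...) {
  cat(sprintf("<rule_set> %d rule(s) for consequent '%s' (N = %s, prior = %.4g)\n",
              nrow(x), attr(x, "consequent") %||% "?",
              attr(x, "n_total") %||% "?", attr(x, "prior") %||% NA))
  if (nrow(x) > 0) {
    show <- data.frame(antecedent = x$antecedent,
                       `support %` = round_half_up(100 * x$support, digits),
                       `confidence %` = round_half_up(100 * x$confidence, digits),
                       lift = round_half_up(x$lift, digits),
                       check.names = FALSE)
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' Compare combined rules against their constituent single rules
#'
#' For each 2-condition rule, finds which of its conditions also passed the
#' gates as single rules, and flags the combined rule as "strengthened" when
#' its confidence and lift both strictly exceed every such constituent's.
#' Also reports the theoretical lift ceiling N/(a+c), the value every
#' confidence-100% rule attains.
#'
#' @param singles a `rule_set` of order-1 rules.
#' @param combined a `rule_set` of order-2 rules; must share the consequent
#'   and N of `singles`.
#' @return data.frame with one row per combined rule: antecedent, metrics,
#'   constituents present among the singles, `strengthened` flag (`NA` when
#'   no constituent passed the gates), and `lift_ceiling`.
#' @export
compare_single_vs_combined <- function(singles, combined) {
  if (!identical(attr(singles, "consequent"), attr(combined, "consequent"))) {
    stop_("single and combined rule sets have different consequents")
  }
  if (!identical(attr(singles, "n_total"), attr(combined, "n_total"))) {
    stop_("single and combined rule sets have different N")
  }
  if (any(singles$order != 1) || any(combined$order != 2)) {
    stop_("expected order-1 singles and order-2 combined rules")
  }
  single_item <- vapply(singles$antecedent_items, `[[`, "", 1)
  rows <- lapply(seq_len(nrow(combined)), function(i) {
    ids <- combined$antecedent_items[[i]]
    hit <- which(single_item %in% ids)
    strengthened <- if (length(hit) == 0) NA else {
      all(combined$confidence[i] > singles$confidence[hit]) &&
        all(combined$lift[i] > singles$lift[hit])
    }
    data.frame(antecedent = combined$antecedent[i],
               confidence = combined$confidence[i],
               lift = combined$lift[i],
               constituents_passing = paste(singles$antecedent[hit], collapse = "; "),
               n_constituents_passing = length(hit),
               strengthened = strengthened,
               lift_ceiling = combined$n[i] / (combined$a[i] + combined$c[i]),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(antecedent = character(), confidence = numeric(),
                      lift = numeric(), constituents_passing = character(),
                      n_constituents_passing = integer(),
                      strengthened = logical(), lift_ceiling = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
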