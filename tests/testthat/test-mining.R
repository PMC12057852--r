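test_that("metrics from counts reproduce the published worked examples", {
  m <- rule_metrics_from_counts(10, 0, 22, 12)
  expect_equal(m$support, 10 / 44)
  expect_equal(m$confidence, 1)
  expect_equal(m$lift, 1.375)

  m <- rule_metrics_from_counts(24, 3, 8, 9)
  expect_equal(round_half_up(m$support, 4), 0.5455)
  expect_equal(round_half_up(m$confidence, 4), 0.8889)
  expect_equal(round_half_up(m$lift, 4), 1.2222)

  # perfect-rule closed form: (k, 0, 0, m) -> conf 1, lift (k+m)/k
  for (k in c(1, 5, 13)) {
    for (mm in c(1, 7, 31)) {
      met <- rule_metrics_from_counts(k, 0, 0, mm)
      expect_equal(met$support, k / (k + mm))
      expect_equal(met$confidence, 1)
      expect_equal(met$lift, (k + mm) / k)
    }
  }

  expect_error(rule_metrics_from_counts(0, 0, 5, 5), "undefined confidence")
  expect_error(rule_metrics_from_counts(0, 5, 0, 5), "undefined lift")
  expect_error(rule_metrics_from_counts(-1, 2, 3, 4), "non-negative")
})

test_that("counting matches the published combined-rule table", {
  im <- old_age_pain_matrix()
  expect_equal(count_rule(im, "age=high", "pcs_2y=low"),
               c(a = 22, b = 4, c = 10, d = 8))
  expect_equal(count_rule(im, "womac_pain=high", "pcs_2y=low"),
               c(a = 19, b = 2, c = 13, d = 10))
  expect_equal(count_rule(im, c("age=high", "womac_pain=high"), "pcs_2y=low"),
               c(a = 13, b = 0, c = 19, d = 12))
  expect_error(count_rule(im, c("age=high", "age=low"), "pcs_2y=low"),
               "two states")
  expect_error(count_rule(im, "pcs_2y=high", "pcs_2y=low"), "share variable")
})

test_that("an antecedent identical to the consequent is a perfect rule", {
  set.seed(21)
  n <- 30
  hi <- stats::runif(n) < 0.6
  membership <- cbind("x=high" = hi, "x=low" = !hi,
                      "y=high" = hi, "y=low" = !hi)
  im <- item_matrix(membership,
                    data.frame(variable = rep(c("x", "y"), each = 2),
                               state = rep(c("high", "low"), 2)))
  k <- count_rule(im, "x=high", "y=high")
  expect_equal(unname(k), c(sum(hi), 0, 0, sum(!hi)))
})

test_that("counts equal a per-participant brute force on random matrices", {
  set.seed(31)
  for (rep in 1:5) {
    im <- random_item_matrix(30, 6)
    ids <- colnames(im$membership)
    vars <- im$items$variable
    cons <- ids[1]
    singles <- ids[vars != vars[1]]
    for (s in singles) {
      expect_equal(count_rule(im, s, cons), brute_counts(im, s, cons))
    }
    pairs <- utils::combn(singles, 2, simplify = FALSE)
    pairs <- Filter(function(p) {
      vars[match(p[1], ids)] != vars[match(p[2], ids)]
    }, pairs)
    for (p in pairs) {
      expect_equal(count_rule(im, p, cons), brute_counts(im, p, cons))
    }
  }
})

test_that("mining the reconstructed single-rule cohort ranks comorbidities first", {
  im <- build_item_matrix(margin_cohort(), unname(default_variable_specs()))
  rules <- mine_rules(im, "pcs_2y=low", max_order = 1)
  expect_equal(nrow(rules), 8)
  expect_equal(rules$antecedent[1], "Comorbidities")
  expect_equal(rules$confidence[1], 1)
  expect_equal(rules$lift[1], 1.375)
  # full Table-3 surface, half-up rounded
  got <- data.frame(antecedent = rules$antecedent,
                    support = round_half_up(100 * rules$support, 2),
                    confidence = round_half_up(100 * rules$confidence, 2),
                    lift = round_half_up(rules$lift, 2),
                    stringsAsFactors = FALSE)
  want <- data.frame(
    antecedent = c("Comorbidities",
                   "High preoperative WOMAC-physical function score",
                   "High preoperative WOMAC-pain score",
                   "Low preoperative PCS",
                   "Decreased ability to stand",
                   "Old age",
                   "High preoperative WOMAC-stiffness score",
                   "Low PCS at 1 year postoperatively"),
    support = c(22.73, 45.45, 43.18, 54.55, 43.18, 50.00, 34.09, 50.00),
    confidence = c(100, 90.91, 90.48, 88.89, 86.36, 84.62, 83.33, 81.48),
    lift = c(1.38, 1.25, 1.24, 1.22, 1.19, 1.16, 1.15, 1.12),
    stringsAsFactors = FALSE)
  expect_equal(got, want)
})

test_that("unattainable thresholds and degenerate consequents are handled", {
  im <- build_item_matrix(margin_cohort(), unname(default_variable_specs()))
  expect_equal(nrow(mine_rules(im, "pcs_2y=low", min_confidence = 1.01)), 0)
  # a consequent item true for everyone cannot be mined
  membership <- cbind("x=high" = c(TRUE, TRUE, FALSE), "x=low" = c(FALSE, FALSE, TRUE),
                      "y=high" = rep(TRUE, 3), "y=low" = rep(FALSE, 3))
  im2 <- item_matrix(membership,
                     data.frame(variable = rep(c("x", "y"), each = 2),
                                state = rep(c("high", "low"), 2)))
  expect_error(mine_rules(im2, "y=high"), "degenerate consequent")
})

test_that("mining equals an independent exhaustive enumerator", {
  set.seed(57)
  for (rep in 1:10) {
    n <- sample(15:50, 1)
    im <- random_item_matrix(n, sample(4:8, 1))
    cons <- "v01=high"
    prior <- mean(im$membership[, cons])
    if (prior <= 0 || prior >= 1) next
    mined <- mine_rules(im, cons, min_confidence = 0.6, min_lift = 1.05)
    oracle <- brute_mine(im, cons, min_conf = 0.6, min_lift = 1.05)
    keys <- vapply(mined$antecedent_items,
                   function(x) paste(sort(x), collapse = " & "), "")
    okeys <- if (length(oracle)) names(oracle) else character(0)
    expect_setequal(keys, okeys)
    for (i in seq_len(nrow(mined))) {
      o <- oracle[[keys[i]]]
      expect_equal(unname(mined$a[i]), unname(o[["a"]]))
      expect_equal(mined$support[i], unname(o[["support"]]))
      expect_equal(mined$confidence[i], unname(o[["confidence"]]))
      expect_equal(mined$lift[i], unname(o[["lift"]]))
    }
  }
})

test_that("mined sets satisfy anti-monotonicity and the metric identities", {
  set.seed(77)
  for (rep in 1:5) {
    im <- random_item_matrix(40, 8)
    cons <- "v01=low"
    prior <- mean(im$membership[, cons])
    if (prior <= 0 || prior >= 1) next
    rules <- mine_rules(im, cons, min_confidence = 0, min_lift = 1e-9)
    expect_true(all(rules$a + rules$b + rules$c + rules$d == nrow(im$membership)))
    expect_true(all(rules$support <= rules$confidence + 1e-12))
    expect_equal(rules$lift * prior, rules$confidence)
    expect_true(all(rules$lift <= rules$n / (rules$a + rules$c) + 1e-12))
    # combined support and a-count never exceed any constituent's
    singles_a <- stats::setNames(rules$a[rules$order == 1],
                                 vapply(rules$antecedent_items[rules$order == 1],
                                        `[[`, "", 1))
    for (i in which(rules$order == 2)) {
      for (id in rules$antecedent_items[[i]]) {
        if (id %in% names(singles_a)) {
          expect_lte(rules$a[i], singles_a[[id]])
        }
      }
    }
  }
})

test_that("mining output is deterministic and fully ordered", {
  im <- build_item_matrix(margin_cohort(), unname(default_variable_specs()))
  r1 <- mine_rules(im, "pcs_2y=low")
  r2 <- mine_rules(im, "pcs_2y=low")
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_true(!is.unsorted(rev(r1$lift)))
  path1 <- withr::local_tempfile(); path2 <- withr::local_tempfile()
  write_rules_table(r1, test_all(r1), path1)
  write_rules_table(r2, test_all(r2), path2)
  expect_identical(readLines(path1), readLines(path2))
})

test_that("combined rules are flagged only on strict improvement", {
  im <- old_age_pain_matrix()
  rules <- mine_rules(im, "pcs_2y=low")
  singles <- rules[rules$order == 1, ]
  combined <- rules[rules$order == 2, ]
  for (s in c("consequent", "n_total", "prior")) {
    attr(singles, s) <- attr(rules, s)
    attr(combined, s) <- attr(rules, s)
  }
  cmp <- compare_single_vs_combined(singles, combined)
  row <- cmp[cmp$antecedent == "High preoperative WOMAC-pain score + Old age", ]
  expect_equal(nrow(row), 1)
  expect_true(row$strengthened)        # 100%/1.375 beats 84.62%/1.16 and 90.48%/1.24
  expect_equal(row$n_constituents_passing, 2)
  expect_equal(row$lift_ceiling, 44 / 32)

  # a pseudo-combination with an always-true condition cannot strengthen
  n <- 44
  low <- seq_len(n) <= 32
  age_hi <- seq_len(n) %in% c(1:22, 33:36)
  membership <- cbind("age=high" = age_hi, "age=low" = !age_hi,
                      "dummy=high" = rep(TRUE, n), "dummy=low" = rep(FALSE, n),
                      "pcs_2y=low" = low, "pcs_2y=high" = !low)
  im2 <- item_matrix(membership,
                     data.frame(variable = rep(c("age", "dummy", "pcs_2y"), each = 2),
                                state = c("high", "low", "high", "low", "low", "high")))
  rules2 <- mine_rules(im2, "pcs_2y=low", min_confidence = 0.5, min_lift = 1.0)
  singles2 <- rules2[rules2$order == 1, ]
  combined2 <- rules2[rules2$order == 2, ]
  for (s in c("consequent", "n_total", "prior")) {
    attr(singles2, s) <- attr(rules2, s)
    attr(combined2, s) <- attr(rules2, s)
  }
  cmp2 <- compare_single_vs_combined(singles2, combined2)
  pseudo <- cmp2[grepl("dummy", cmp2$antecedent), ]
  expect_true(all(!pseudo$strengthened))

  # mixed consequents refuse to compare
  attr(combined2, "consequent") <- "other=low"
  expect_error(compare_single_vs_combined(singles2, combined2),
               "different consequents")
})
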