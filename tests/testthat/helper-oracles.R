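# Independent oracles and fixtures, built in code.

# Two-sided Fisher p-value by direct hypergeometric summation over all
# tables with the observed margins, counting those no more probable than
# the observed one.
fisher_oracle_p <- function(a, b, c, d) {
  N <- a + b + c + d
  m <- a + b          # applicable row total
  K <- a + c          # consequent column total
  xs <- max(0, K - (c + d)):min(m, K)
  probs <- stats::dhyper(xs, K, N - K, m)
  p_obs <- stats::dhyper(a, K, N - K, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force 2x2 counts by a per-participant loop (independent of the
# vectorized path in count_rule()).
brute_counts <- function(im, antecedent, consequent) {
  M <- im$membership
  a <- b <- cc <- d <- 0
  for (r in seq_len(nrow(M))) {
    app <- all(M[r, antecedent])
    con <- M[r, consequent]
    if (app && con) a <- a + 1
    else if (app) b <- b + 1
    else if (con) cc <- cc + 1
    else d <- d + 1
  }
  c(a = a, b = b, c = cc, d = d)
}

# Independent exhaustive enumerator: every order-1 and order-2 antecedent,
# metrics from scratch, gates applied, keyed by sorted antecedent ids.
brute_mine <- function(im, cons_id, max_order = 2, min_conf = 0.8,
                       min_lift = 1.1, min_sup = 0) {
  M <- im$membership
  ids <- colnames(M)
  vars <- im$items$variable
  n <- nrow(M)
  cons_var <- vars[match(cons_id, ids)]
  cand <- which(vars != cons_var)
  antes <- lapply(cand, function(i) ids[i])
  if (max_order == 2 && length(cand) >= 2) {
    for (i in seq_along(cand)[-length(cand)]) {
      for (j in seq((i + 1), length(cand))) {
        if (vars[cand[i]] != vars[cand[j]]) {
          antes <- c(antes, list(ids[c(cand[i], cand[j])]))
        }
      }
    }
  }
  out <- list()
  for (ante in antes) {
    k <- brute_counts(im, ante, cons_id)
    if (k["a"] + k["b"] == 0) next
    sup <- k[["a"]] / n
    conf <- k[["a"]] / (k[["a"]] + k[["b"]])
    lift <- conf / ((k[["a"]] + k[["c"]]) / n)
    if (conf >= min_conf && lift >= min_lift && sup >= min_sup) {
      key <- paste(sort(ante), collapse = " & ")
      out[[key]] <- c(k, support = sup, confidence = conf, lift = lift)
    }
  }
  out
}

# Random dichotomous item matrix: n participants x n_vars variables, each
# with a high/low item pair.
random_item_matrix <- function(n, n_vars) {
  cols <- list()
  meta <- list()
  for (v in seq_len(n_vars)) {
    nm <- sprintf("v%02d", v)
    hi <- stats::runif(n) < stats::runif(1, 0.2, 0.8)
    cols[[item_id_chr(nm, "high")]] <- hi
    cols[[item_id_chr(nm, "low")]] <- !hi
    meta[[nm]] <- data.frame(variable = nm, state = c("high", "low"),
                             stringsAsFactors = FALSE)
  }
  membership <- do.call(cbind, cols)
  items <- do.call(rbind, meta)
  items <- items[order(match(item_id_chr(items$variable, items$state),
                             colnames(membership))), ]
  item_matrix(membership, items)
}

item_id_chr <- function(variable, state) paste(variable, state, sep = "=")

# Cohort whose binarized columns reproduce the study's published
# single-rule 2x2 margins against the 2-year PCS (synthetic joint
# structure: each antecedent set is placed independently).
margin_cohort <- function() {
  n <- 44
  lows <- 1:32   # low 2-year PCS group
  in_set <- function(lo, hi) {
    v <- rep(FALSE, n); v[lo] <- TRUE; v[hi] <- TRUE; v
  }
  df <- data.frame(
    participant_id = sprintf("P%02d", 1:n),
    sex = ifelse(1:n %% 2 == 1, "female", "male"),
    joint_type = c(rep("unilateral", 41), rep("bilateral", 3)),
    stringsAsFactors = FALSE
  )
  df$pcs_2y <- ifelse(seq_len(n) %in% lows, 40, 55)
  df$cci <- ifelse(in_set(1:10, NULL), 1, 0)                     # (10, 0)
  df$womac_physfunc <- ifelse(in_set(1:20, 33:34), 30, 5)        # (20, 2)
  df$womac_pain <- ifelse(in_set(1:19, 33:34), 8, 1)             # (19, 2)
  df$pcs_pre <- ifelse(in_set(1:24, 33:35), 40, 55)              # (24, 3) low
  df$sit_to_stand_s <- ifelse(in_set(1:19, 33:35), 14, 9)        # (19, 3)
  df$age <- ifelse(in_set(1:22, 33:36), 70, 50)                  # (22, 4)
  df$womac_stiffness <- ifelse(in_set(1:15, 33:35), 5, 1)        # (15, 3)
  df$pcs_1y <- ifelse(in_set(1:22, 33:37), 40, 55)               # (22, 5) low
  df$bmi <- ifelse(in_set(1:14, 33:38), 33, 26)       # conf 14/20 < 0.8
  df$cesd <- ifelse(in_set(1:2, 33:34), 20, 2)        # conf 2/4 < 0.8
  df$mcs_pre <- ifelse(seq_len(n) %in% c(3, 9, 15, 21, 27, 33, 39), 45, 55)
  df$mcs_1y <- ifelse(seq_len(n) %% 3 == 0, 45, 55)
  df$mcs_2y <- ifelse(seq_len(n) %% 3 == 2, 45, 55)
  validate_cohort(df)
  df
}

# Published applicable/non-applicable counts for the eight single rules
# against the low 2-year PCS.
single_rule_counts <- function() {
  data.frame(
    label = c("comorbidities", "high_womac_physfunc", "high_womac_pain",
              "low_pcs_pre", "decreased_stand", "old_age",
              "high_womac_stiffness", "low_pcs_1y"),
    a = c(10, 20, 19, 24, 19, 22, 15, 22),
    b = c(0, 2, 2, 3, 3, 4, 3, 5),
    c = c(22, 12, 13, 8, 13, 10, 17, 10),
    d = c(12, 10, 10, 9, 9, 8, 9, 7),
    stringsAsFactors = FALSE
  )
}

# Item matrix on three variables realizing the published joint structure of
# the old age / high pain single rules and their combination.
old_age_pain_matrix <- function() {
  n <- 44
  low <- seq_len(n) <= 32
  age_hi <- seq_len(n) %in% c(1:22, 33:36)        # (22, 4)
  pain_hi <- seq_len(n) %in% c(10:28, 37:38)      # (19, 2); joint (13, 0)
  membership <- cbind(
    "age=high" = age_hi, "age=low" = !age_hi,
    "womac_pain=high" = pain_hi, "womac_pain=low" = !pain_hi,
    "pcs_2y=low" = low, "pcs_2y=high" = !low
  )
  items <- data.frame(
    variable = rep(c("age", "womac_pain", "pcs_2y"), each = 2),
    state = c("high", "low", "high", "low", "low", "high"),
    label = c("Old age", "Young age", "High preoperative WOMAC-pain score",
              "Low preoperative WOMAC-pain score",
              "Low PCS at 2 years postoperatively",
              "High PCS at 2 years postoperatively"),
    stringsAsFactors = FALSE
  )
  item_matrix(membership, items)
}
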