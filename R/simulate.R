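#' Default marginal distributions for the synthetic cohort
#'
#' Families per variable: truncated normal for age, BMI and the SF-12
#' component scores; log-normal for the sit-to-stand time; zero-inflated
#' shifted Poisson for the comorbidity index; zero-inflated gamma (rounded)
#' for CES-D and the WOMAC subscales; categorical for sex and joint type.
#' Location parameters of the SF-12 scores are set so that the below-50
#' prevalence matches the observed group proportions of the study cohort
#' (e.g. 32/44 below 50 for the 2-year PCS); only this binarized structure
#' matters downstream, the shapes are cosmetic.
#'
#' @return named list of marginal specifications, one per cohort variable.
#' @export
default_marginals <- function() {
  # mean chosen so that P(value < 50) equals the target prevalence
  norm_prev <- function(p_low, sd) {
    list(family = "normal", mean = 50 - stats::qnorm(p_low) * sd, sd = sd,
         lower = 0, upper = 100)
  }
  list(
    sex = list(family = "categorical", levels = c("female", "male"),
               probs = c(18, 26) / 44),
    age = list(family = "normal", mean = 64.1, sd = 9.8, lower = 40, upper = 90),
    joint_type = list(family = "categorical",
                      levels = c("unilateral", "bilateral"),
                      probs = c(41, 3) / 44),
    sit_to_stand_s = list(family = "lognormal", meanlog = log(11.4),
                          sdlog = 0.28),
    bmi = list(family = "normal", mean = 29.4, sd = 4.3, lower = 15, upper = 50),
    cci = list(family = "zipois", p_zero = 34 / 44, lambda = 0.1),
    cesd = list(family = "zigamma", p_zero = 0.15, shape = 1.1, scale = 5.5,
                upper = 60, digits = 0),
    womac_pain = list(family = "zigamma", p_zero = 0.25, shape = 1.2,
                      scale = 3.5, upper = 20, digits = 1),
    womac_stiffness = list(family = "zigamma", p_zero = 0.2, shape = 1.5,
                           scale = 1.6, upper = 8, digits = 0),
    womac_physfunc = list(family = "zigamma", p_zero = 0.2, shape = 1.2,
                          scale = 12, upper = 68, digits = 1),
    pcs_pre = norm_prev(27 / 44, 8),
    pcs_1y = norm_prev(27 / 44, 8),
    pcs_2y = norm_prev(32 / 44, 10.4),
    mcs_pre = norm_prev(7 / 44, 6.6),
    mcs_1y = norm_prev(13 / 44, 6.7),
    mcs_2y = norm_prev(17 / 44, 9)
  )
}

#' Declare a planted antecedent-outcome dependency
#'
#' A planted rule fixes, for one outcome variable, the probability of its
#' target state given that all antecedent states hold
#' (`conditional_probability`) and otherwise (`baseline_probability`).
#' Planting operates on the binarized states and then maps back to a value
#' drawn from the state-conditional side of the outcome's marginal, so the
#' rule survives discretization exactly.
#'
#' @param antecedent named character vector of antecedent states, e.g.
#'   `c(cci = "high")` or `c(age = "high", womac_pain = "high")` (1 or 2
#'   entries, distinct variables).
#' @param outcome_variable outcome column name; must use a fixed cut-off or
#'   be a two-level categorical variable.
#' @param outcome_state the planted state (e.g. `"low"`).
#' @param conditional_probability P(outcome state | antecedent states hold).
#' @param baseline_probability P(outcome state | otherwise); at most the
#'   conditional probability.
#' @return object of class `planted_rule`.
#' @export
planted_rule <- function(antecedent, outcome_variable, outcome_state,
                         conditional_probability, baseline_probability) {
  if (length(antecedent) < 1 || length(antecedent) > 2 ||
      is.null(names(antecedent)) || anyDuplicated(names(antecedent))) {
    stop_("antecedent must be 1 or 2 states named by distinct variables")
  }
  probs <- c(conditional_probability, baseline_probability)
  if (any(probs < 0 | probs > 1)) stop_("probabilities must lie in [0, 1]")
  if (conditional_probability < baseline_probability) {
    stop_("planted rules are positive: conditional must be >= baseline")
  }
  if (outcome_variable %in% names(antecedent)) {
    stop_("outcome variable cannot appear in the antecedent")
  }
  structure(list(antecedent = antecedent,
                 outcome_variable = outcome_variable,
                 outcome_state = outcome_state,
                 conditional_probability = conditional_probability,
                 baseline_probability = baseline_probability),
            class = "planted_rule")
}

#' Default planted rules
#'
#' One rule mirroring the structure of the comorbidity finding: participants
#' with one or more comorbidities always end with a low 2-year PCS
#' (conditional probability 1), others with probability 22/34, so the
#' marginal low-PCS prevalence stays at 32/44.
#'
#' @return list of [planted_rule()] objects.
#' @export
default_planted_rules <- function() {
  list(planted_rule(c(cci = "high"), "pcs_2y", "low",
                    conditional_probability = 1.0,
                    baseline_probability = 22 / 34))
}

#' Assemble a simulation configuration
#'
#' @param n_participants cohort size (default 44, the study cohort size).
#' @param marginals named list of marginal specs; see [default_marginals()].
#' @param planted_rules list of [planted_rule()] objects; at most one per
#'   outcome variable (two rules on one outcome would contradict each other).
#' @param specs dichotomization recipes used to realize antecedent states.
#' @param seed optional integer seed stored with the config.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 44,
                              marginals = default_marginals(),
                              planted_rules = default_planted_rules(),
                              specs = default_variable_specs(),
                              seed = NULL) {
  if (n_participants < 2) stop_("config error: n_participants must be >= 2")
  spec_vars <- vapply(specs, `[[`, "", "variable")
  for (pr in planted_rules) {
    refd <- c(names(pr$antecedent), pr$outcome_variable)
    unknown <- setdiff(refd, intersect(names(marginals), spec_vars))
    if (length(unknown) > 0) {
      stop_("config error: planted rule references unconfigured variable '%s'",
            unknown[1])
    }
  }
  outcomes <- vapply(planted_rules, `[[`, "", "outcome_variable")
  if (anyDuplicated(outcomes)) {
    stop_("config error: contradictory planted rules on outcome '%s'",
          outcomes[duplicated(outcomes)][1])
  }
  structure(list(n_participants = n_participants, marginals = marginals,
                 planted_rules = planted_rules, specs = specs, seed = seed),
            class = "simulation_config")
}

rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  if (pu - pl < 1e-12) stop_("degenerate truncation interval")
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

draw_marginal <- function(m, n) {
  switch(m$family,
    normal = rtnorm(n, m$mean, m$sd, m$lower %||% -Inf, m$upper %||% Inf),
    lognormal = stats::rlnorm(n, m$meanlog, m$sdlog),
    zipois = ifelse(stats::runif(n) < m$p_zero, 0,
                    1 + stats::rpois(n, m$lambda)),
    zigamma = {
      v <- ifelse(stats::runif(n) < m$p_zero, 0,
                  stats::rgamma(n, shape = m$shape, scale = m$scale))
      v <- pmin(v, m$upper %||% Inf)
      round(v, m$digits %||% 1)
    },
    categorical = sample(m$levels, n, replace = TRUE, prob = m$probs),
    stop_("unknown marginal family '%s'", m$family)
  )
}

# Draw outcome values conditional on the binarized state for a fixed-cutoff
# normal variable (high_if "ge": low < cutoff <= high).
draw_conditional_value <- function(m, spec, state, k) {
  if (k == 0) return(numeric(0))
  if (m$family != "normal" || spec$method != "fixed_cutoff" ||
      spec$high_if != "ge") {
    stop_("config error: planted outcome '%s' must be a fixed-cutoff (>=) normal variable or 2-level categorical",
          spec$variable)
  }
  eps <- 1e-6
  if (state == "high") {
    rtnorm(k, m$mean, m$sd, lower = spec$cutoff,
           upper = m$upper %||% Inf)
  } else {
    rtnorm(k, m$mean, m$sd, lower = m$lower %||% -Inf,
           upper = spec$cutoff - eps)
  }
}

#' Simulate a synthetic cohort
#'
#' Draws every variable from its configured marginal, realizes the
#' antecedent states of each planted rule by dichotomizing the drawn values
#' (median splits use the full simulated sample), then assigns each planted
#' outcome's state with the rule's conditional/baseline probabilities and
#' redraws the outcome value from the matching side of its marginal. All
#' randomness derives from the single seed; identical config + seed gives an
#' identical cohort. The result passes [validate_cohort()].
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; defaults to the seed stored in the config.
#' @return a `cohort_table` with `config$n_participants` rows.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_participants
  df <- data.frame(participant_id = sprintf("P%04d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (v in names(config$marginals)) {
    df[[v]] <- draw_marginal(config$marginals[[v]], n)
  }
  spec_by_var <- stats::setNames(config$specs,
                                 vapply(config$specs, `[[`, "", "variable"))
  for (pr in config$planted_rules) {
    ante_specs <- spec_by_var[names(pr$antecedent)]
    im <- build_item_matrix(df, unname(ante_specs))
    ids <- vapply(seq_along(pr$antecedent), function(i) {
      item_id(names(pr$antecedent)[i], pr$antecedent[[i]])
    }, "")
    unknown <- setdiff(ids, colnames(im$membership))
    if (length(unknown) > 0) {
      stop_("config error: planted antecedent state '%s' not realized", unknown[1])
    }
    applicable <- rowSums(im$membership[, ids, drop = FALSE]) == length(ids)
    p <- ifelse(applicable, pr$conditional_probability,
                pr$baseline_probability)
    planted_state <- stats::runif(n) < p
    out_spec <- spec_by_var[[pr$outcome_variable]]
    m <- config$marginals[[pr$outcome_variable]]
    if (out_spec$method == "categorical_passthrough") {
      if (length(out_spec$levels) != 2) {
        stop_("config error: planted categorical outcome '%s' must have 2 levels",
              pr$outcome_variable)
      }
      other <- setdiff(out_spec$levels, pr$outcome_state)
      df[[pr$outcome_variable]] <- ifelse(planted_state, pr$outcome_state, other)
    } else {
      other <- if (pr$outcome_state == "high") "low" else "high"
      v <- df[[pr$outcome_variable]]
      v[planted_state] <- draw_conditional_value(m, out_spec, pr$outcome_state,
                                                 sum(planted_state))
      v[!planted_state] <- draw_conditional_value(m, out_spec, other,
                                                  sum(!planted_state))
      df[[pr$outcome_variable]] <- v
    }
  }
  validate_cohort(df)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Recover planted rules from a large simulated cohort
#'
#' Simulates a cohort of `n_large` participants from the config, binarizes
#' it, counts each planted rule's 2x2 table, and reports the estimated
#' confidence and lift next to their planted values. The planted lift is
#' the conditional probability divided by the implied consequent prior
#' (realized antecedent prevalence x conditional + rest x baseline);
#' standard errors are binomial, based on the realized antecedent count.
#'
#' @param config a [simulation_config()] with at least one planted rule.
#' @param n_large cohort size for the recovery run (default 2000).
#' @param seed integer seed.
#' @return data.frame with one row per planted rule: antecedent, outcome,
#'   realized antecedent count `m`, planted vs estimated confidence (with
#'   `se_confidence`), planted vs estimated lift.
#' @export
recover_planted_rules <- function(config, n_large = 2000, seed = 1) {
  if (length(config$planted_rules) == 0) stop_("no planted rules to recover")
  big <- simulation_config(n_participants = n_large,
                           marginals = config$marginals,
                           planted_rules = config$planted_rules,
                           specs = config$specs)
  cohort <- simulate_cohort(big, seed = seed)
  im <- build_item_matrix(cohort, unname(config$specs))
  rows <- lapply(config$planted_rules, function(pr) {
    ids <- vapply(seq_along(pr$antecedent), function(i) {
      item_id(names(pr$antecedent)[i], pr$antecedent[[i]])
    }, "")
    cons <- item_id(pr$outcome_variable, pr$outcome_state)
    k <- count_rule(im, ids, cons)
    met <- rule_metrics_from_counts(k["a"], k["b"], k["c"], k["d"])
    m_ante <- k[["a"]] + k[["b"]]
    p_ante <- m_ante / n_large
    prior_planted <- p_ante * pr$conditional_probability +
      (1 - p_ante) * pr$baseline_probability
    data.frame(antecedent = paste(ids, collapse = " + "),
               outcome = cons, m = m_ante,
               planted_confidence = pr$conditional_probability,
               est_confidence = met$confidence,
               se_confidence = sqrt(met$confidence * (1 - met$confidence) /
                                      max(m_ante, 1)),
               planted_lift = pr$conditional_probability / prior_planted,
               est_lift = met$lift,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a simulation config from YAML
#'
#' Recognized keys: `n_participants`, `seed`, `marginals` (overrides merged
#' into [default_marginals()]), and `planted_rules`, each with `antecedent`
#' (mapping variable to state), `outcome_variable`, `outcome_state`,
#' `conditional_probability`, `baseline_probability`. An explicit
#' `planted_rules: []` disables the default planted rule.
#'
#' @param path YAML file path.
#' @return a [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop_("config file not found: %s", path)
  y <- yaml::read_yaml(path) %||% list()
  marginals <- default_marginals()
  for (v in names(y$marginals %||% list())) marginals[[v]] <- y$marginals[[v]]
  planted <- if (is.null(y$planted_rules)) {
    default_planted_rules()
  } else {
    lapply(y$planted_rules, function(e) {
      planted_rule(unlist(e$antecedent), e$outcome_variable, e$outcome_state,
                   e$conditional_probability, e$baseline_probability)
    })
  }
  simulation_config(n_participants = y$n_participants %||% 44,
                    marginals = marginals, planted_rules = planted,
                    seed = y$seed)
}
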