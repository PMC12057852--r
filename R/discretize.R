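#' Dichotomize at a fixed cut-off
#'
#' Assigns each value to the `"high"` or `"low"` state by comparison against
#' a fixed clinical cut-off. With the default orientation `high_if = "ge"`
#' the cut-off is inclusive on the high side, so a CES-D of exactly 16 or an
#' age of exactly 60 falls in the high group.
#'
#' @param values numeric vector; names, if any, identify participants in
#'   error messages.
#' @param cutoff finite numeric cut-off.
#' @param high_if comparison defining the high state: `ge` (default), `gt`,
#'   `le`, `lt`.
#' @return character vector of `"high"`/`"low"`, same length as `values`.
#' @export
#' @examples
#' dichotomize_fixed(c(59, 60, 62), 60) # "low" "high" "high"
dichotomize_fixed <- function(values, cutoff, high_if = "ge") {
  if (!is.finite(cutoff)) stop_("cutoff must be finite")
  bad <- !is.finite(values)
  if (any(bad)) {
    who <- names(values)[which(bad)[1]] %||% as.character(which(bad)[1])
    stop_("non-finite value for participant %s", who)
  }
  high <- switch(high_if,
                 ge = values >= cutoff,
                 gt = values > cutoff,
                 le = values <= cutoff,
                 lt = values < cutoff,
                 stop_("high_if must be one of ge/gt/le/lt"))
  ifelse(high, "high", "low")
}

#' Equal-frequency (median) split
#'
#' Splits a continuous variable at its sample median so the two groups are as
#' close to equal-sized as ties permit. The high state is strictly greater
#' than the median; ties at the median fall in the low group. For even N the
#' median is the midpoint of the two central order statistics, so a tie-free
#' even-sized sample splits exactly in half.
#'
#' @param values numeric vector of length >= 2; names identify participants
#'   in error messages.
#' @return character vector of `"high"`/`"low"`.
#' @export
#' @examples
#' dichotomize_median(c(1, 2, 3, 4)) # "low" "low" "high" "high"
dichotomize_median <- function(values) {
  if (length(values) < 2) stop_("median split needs at least 2 values")
  bad <- !is.finite(values)
  if (any(bad)) {
    who <- names(values)[which(bad)[1]] %||% as.character(which(bad)[1])
    stop_("non-finite value for participant %s", who)
  }
  if (length(unique(values)) == 1) {
    stop_("degenerate variable: single-valued")
  }
  med <- stats::median(values)
  ifelse(values > med, "high", "low")
}

#' Build the participants-by-items boolean membership matrix
#'
#' Every dichotomized variable contributes exactly two items (its high and
#' low states), so either state can serve as a rule condition; every
#' categorical variable contributes one item per configured level. For each
#' participant exactly one item per variable is true, so a variable's item
#' column counts always sum to N. Median splits are computed on the full
#' sample.
#'
#' @param cohort a cohort table (see [read_cohort()]).
#' @param specs list of [variable_spec()] recipes; each spec's variable must
#'   be a column of `cohort`.
#' @return an `item_matrix`: list with `membership` (logical N x items
#'   matrix, columns named `variable=state`), `items` (data.frame with
#'   `variable`, `state`, `label`), `participants` (character ids).
#' @export
build_item_matrix <- function(cohort, specs) {
  if (inherits(specs, "variable_spec")) specs <- list(specs)
  missing_vars <- setdiff(vapply(specs, `[[`, "", "variable"), names(cohort))
  if (length(missing_vars) > 0) {
    stop_("variable(s) not in cohort: %s", paste(missing_vars, collapse = ", "))
  }
  ids <- as.character(cohort$participant_id %||% seq_len(nrow(cohort)))
  cols <- list()
  meta <- list()
  for (spec in specs) {
    v <- cohort[[spec$variable]]
    if (spec$method == "categorical_passthrough") {
      bad <- !(v %in% spec$levels)
      if (any(bad)) {
        stop_("variable '%s': value '%s' not a configured level",
              spec$variable, v[which(bad)[1]])
      }
      observed <- spec$levels[spec$levels %in% v]
      for (lev in observed) {
        id <- item_id(spec$variable, lev)
        cols[[id]] <- v == lev
        meta[[id]] <- data.frame(variable = spec$variable, state = lev,
                                 label = unname(spec$labels[[lev]]),
                                 stringsAsFactors = FALSE)
      }
    } else {
      vals <- stats::setNames(as.numeric(v), ids)
      states <- if (spec$method == "fixed_cutoff") {
        dichotomize_fixed(vals, spec$cutoff, spec$high_if)
      } else {
        dichotomize_median(vals)
      }
      for (st in c("high", "low")) {
        id <- item_id(spec$variable, st)
        cols[[id]] <- states == st
        meta[[id]] <- data.frame(variable = spec$variable, state = st,
                                 label = unname(spec$labels[[st]]),
                                 stringsAsFactors = FALSE)
      }
    }
  }
  membership <- do.call(cbind, cols)
  rownames(membership) <- ids
  item_matrix(membership, do.call(rbind, meta), ids)
}

#' Construct an item matrix from explicit membership
#'
#' Low-level constructor used by [build_item_matrix()] and useful for
#' reconstructing a matrix from published margins. Validates the partition
#' property: within each variable, every participant belongs to exactly one
#' item.
#'
#' @param membership logical participants x items matrix with `variable=state`
#'   column names.
#' @param items data.frame with columns `variable`, `state` and optionally
#'   `label`, one row per membership column.
#' @param participants character participant ids (defaults to row names).
#' @return an object of class `item_matrix`.
#' @export
item_matrix <- function(membership, items, participants = rownames(membership)) {
  membership <- as.matrix(membership)
  storage.mode(membership) <- "logical"
  if (nrow(items) != ncol(membership)) {
    stop_("items metadata must have one row per membership column")
  }
  if (is.null(items$label)) items$label <- item_id(items$variable, items$state)
  ids <- item_id(items$variable, items$state)
  if (anyDuplicated(ids)) stop_("duplicate (variable, state) item")
  colnames(membership) <- ids
  if (is.null(participants)) participants <- as.character(seq_len(nrow(membership)))
  rownames(membership) <- participants
  for (v in unique(items$variable)) {
    sub <- membership[, items$variable == v, drop = FALSE]
    per_row <- rowSums(sub)
    if (any(per_row != 1)) {
      stop_("partition violated for variable '%s': participant %s is in %d states",
            v, participants[which(per_row != 1)[1]],
            per_row[which(per_row != 1)[1]])
    }
  }
  structure(list(membership = membership,
                 items = `rownames<-`(items, NULL),
                 participants = participants),
            class = "item_matrix")
}

#' @export
print.item_matrix <- function(x, ...) {
  cat(sprintf("<item_matrix> %d participants x %d items (%d variables)\n",
              nrow(x$membership), ncol(x$membership),
              length(unique(x$items$variable))))
  counts <- colSums(x$membership)
  print(data.frame(item = colnames(x$membership), n = counts,
                   row.names = NULL))
  invisible(x)
}

#' Write the binarized matrix as TSV for audit
#'
#' @param x an `item_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_item_matrix <- function(x, path) {
  df <- data.frame(participant_id = x$participants,
                   ifelse(x$membership, 1L, 0L),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
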