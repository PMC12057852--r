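`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used in the package's printed rule tables (so a lift of 1.1875
#' prints as 1.19, and 10/44 prints as 22.73%). Base R's `round()` rounds
#' half to even, which disagrees on exact ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(1.1875, 2) # 1.19
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small guard against representation error just below an exact .5 tie
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

item_id <- function(variable, state) paste(variable, state, sep = "=")

# Normalise an item reference: either "variable=state" or
# c(variable = ..., state = ...). Returns c(variable=, state=).
as_item <- function(x) {
  if (is.character(x) && length(x) == 1 && grepl("=", x, fixed = TRUE)) {
    parts <- strsplit(x, "=", fixed = TRUE)[[1]]
    return(c(variable = parts[[1]],
             state = paste(parts[-1], collapse = "=")))
  }
  if (!is.null(names(x)) && all(c("variable", "state") %in% names(x))) {
    return(c(variable = unname(x[["variable"]]),
             state = unname(x[["state"]])))
  }
  stop("item must be given as \"variable=state\" or c(variable = , state = )",
       call. = FALSE)
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
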