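#' Abundance state of a growing system
#'
#' A `function_tally` records the abundance distribution of a system: one
#' positive integer count per existing function (a distinct occupation, a
#' distinct expressed protein, ...).  The system size `N` is the total
#' number of individuals, `sum(counts)`; the function diversity `D` is the
#' number of distinct functions, `length(counts)`.  Both are always derived
#' from the counts, never stored separately.
#'
#' @param counts Vector of positive integer abundances, one per function.
#' @param labels Optional character vector of function identifiers aligned
#'   with `counts`.  Defaults to `f1, f2, ...`.
#'
#' @return An object of class `function_tally` with elements `counts`
#'   (integer) and `labels` (character).
#'
#' @examples
#' tal <- function_tally(c(5, 3, 2), labels = c("A", "B", "C"))
#' system_size(tal)  # 10
#' diversity(tal)    # 3
#' @export
function_tally <- function(counts, labels = NULL) {
  if (length(counts) < 1) {
    stop("a function tally needs at least one function (D >= 1)")
  }
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts))) {
    bad <- which(!is.finite(counts) | counts < 1 | counts != round(counts))[1]
    stop(sprintf("counts must be positive integers; offending entry %d: %s",
                 bad, format(counts[bad])))
  }
  if (is.null(labels)) {
    labels <- paste0("f", seq_along(counts))
  }
  if (length(labels) != length(counts)) {
    stop("labels must align with counts")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate function labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(list(counts = as.integer(counts), labels = as.character(labels)),
            class = "function_tally")
}

#' @rdname function_tally
#' @param x,tally A `function_tally`.
#' @export
system_size <- function(tally) {
  stopifnot(inherits(tally, "function_tally"))
  sum(tally$counts)
}

#' @rdname function_tally
#' @export
diversity <- function(tally) {
  stopifnot(inherits(tally, "function_tally"))
  length(tally$counts)
}

#' @rdname function_tally
#' @param ... Ignored.
#' @export
print.function_tally <- function(x, ...) {
  cat(sprintf("<function_tally> N = %d individuals, D = %d functions\n",
              system_size(x), diversity(x)))
  k <- sort(x$counts, decreasing = TRUE)
  show <- utils::head(k, 8L)
  cat("  counts (sorted): ", paste(show, collapse = " "),
      if (length(k) > 8L) "..." else "", "\n", sep = "")
  invisible(x)
}
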