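#' Canonical sleep stage set
#'
#' The five-class AASM stage set used throughout the package, in the fixed
#' order that indexes every transition matrix, softmax distribution and
#' transition vector: wake, N1, N2, N3 (slow-wave sleep; R&K N3/N4 merged),
#' and REM.
#'
#' @return Character vector `c("W", "N1", "N2", "N3", "REM")`.
#' @export
#' @examples
#' sleep_stages()
sleep_stages <- function() {
  c("W", "N1", "N2", "N3", "REM")
}

#' Label for epochs rejected by the confidence rule
#' @return The string `"NC"` (not classified).
#' @export
nc_label <- function() "NC"

# Internal: check labels against a stage order, stop on unknowns.
check_stage_labels <- function(labels, stages = sleep_stages()) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), stages)
  if (length(bad) > 0L) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  }
  labels
}

# Internal: validate that a vector is (numerically) a probability distribution.
check_simplex <- function(p, tol = 1e-6, what = "probability vector") {
  if (any(!is.finite(p)) || any(p < -tol) || abs(sum(p) - 1) > tol) {
    stop(what, " must be nonnegative and sum to 1")
  }
  invisible(p)
}
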