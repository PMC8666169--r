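#' Summary-level performance of a prediction rule at one cut-point
#'
#' Bundles the three quantities that determine a natural-frequency table:
#' sensitivity and specificity of the rule at a given cut-point, and the
#' prevalence of the event in the reference population. This is the usual
#' summary-level entry point when a publication reports percentages rather
#' than raw cell counts.
#'
#' @param sensitivity Probability of an "at risk" classification given the
#'   event occurs, in `[0, 1]`.
#' @param specificity Probability of a "not at risk" classification given the
#'   event does not occur, in `[0, 1]`.
#' @param prevalence Event probability in the reference population, strictly
#'   inside `(0, 1)`.
#' @param label Free-text cut-point label, e.g. `"low risk"` or `">=20%"`.
#' @return An object of class `perf_summary`.
#' @examples
#' perf_summary(0.40, 0.88, 0.09, label = ">=20%")
#' @seealso [nf_from_summary()] to convert to whole-person counts.
#' @export
perf_summary <- function(sensitivity, specificity, prevalence, label = "") {
  stop_if_not_proportion(sensitivity, "sensitivity")
  stop_if_not_proportion(specificity, "specificity")
  stop_if_not_proportion(prevalence, "prevalence", open = TRUE)
  stopifnot(is.character(label), length(label) == 1L)
  structure(
    list(sensitivity = sensitivity, specificity = specificity,
         prevalence = prevalence, label = label),
    class = "perf_summary"
  )
}

#' @export
print.perf_summary <- function(x, ...) {
  cat("Prediction-rule performance summary",
      if (nzchar(x$label)) sprintf("[%s]", x$label), "\n")
  cat(sprintf("  sensitivity %.3f, specificity %.3f, prevalence %.5f\n",
              x$sensitivity, x$specificity, x$prevalence))
  invisible(x)
}

#' @export
format.perf_summary <- function(x, ...) {
  sprintf("%s: sens %.2f, spec %.2f, prev %.4f",
          if (nzchar(x$label)) x$label else "(unlabelled)",
          x$sensitivity, x$specificity, x$prevalence)
}
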