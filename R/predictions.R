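#' Individual-level predictions with observed outcomes
#'
#' Holds one predicted risk (or raw score) and one observed binary outcome
#' per subject — the individual-level pathway from which summary
#' sensitivity/specificity at any cut-point, and the C-statistic, can be
#' computed.
#'
#' @param risk Numeric vector of predicted risks in `[0, 1]` or raw scores
#'   (any finite real; classification uses `>=` on whatever scale is given).
#' @param outcome Binary event indicator per subject, 0/1 (logical accepted).
#' @return An object of class `pred_data`: a data.frame with columns `risk`
#'   and `outcome`.
#' @examples
#' pred_data(c(0.1, 0.6, 0.9), c(0, 0, 1))
#' @seealso [read_predictions()], [nf_from_predictions()], [c_statistic()]
#' @export
pred_data <- function(risk, outcome) {
  risk <- as.numeric(risk)
  if (is.logical(outcome)) outcome <- as.integer(outcome)
  if (length(risk) < 1L || length(risk) != length(outcome)) {
    stop("`risk` and `outcome` must be non-empty and the same length",
         call. = FALSE)
  }
  if (any(!is.finite(risk))) stop("`risk` must be finite", call. = FALSE)
  if (!all(outcome %in% c(0, 1))) {
    stop("`outcome` must be coded 0/1", call. = FALSE)
  }
  structure(data.frame(risk = risk, outcome = as.integer(outcome)),
            class = c("pred_data", "data.frame"))
}

#' Read individual-level predictions from CSV
#'
#' Expects a header line `risk,outcome` with one subject per row: `risk` a
#' real number, `outcome` 0 or 1.
#'
#' @param path Path to the CSV file.
#' @return A [pred_data()] object.
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("risk", "outcome") %in% names(df))) {
    stop("predictions CSV must have columns `risk` and `outcome`",
         call. = FALSE)
  }
  pred_data(df$risk, df$outcome)
}

check_two_classes <- function(data) {
  stopifnot(inherits(data, "pred_data"))
  if (sum(data$outcome == 1) < 1L || sum(data$outcome == 0) < 1L) {
    stop("dataset must contain at least one event and one non-event",
         call. = FALSE)
  }
  invisible(data)
}

#' Classify individual predictions at a cut-point
#'
#' Dichotomises predicted risk at a cut-point — the directive-rule reading of
#' a prediction model — and tabulates the resulting natural frequencies.
#' Subjects with `risk >= cutpoint` are classified "at risk" (inclusive
#' threshold; a source that uses an exclusive convention can negate its
#' scores). The reference population is the dataset itself.
#'
#' @param data A [pred_data()] with at least one event and one non-event.
#' @param cutpoint Classification threshold on the scale of `risk`.
#' @return An [nf_table()] with `population` equal to `nrow(data)`.
#' @examples
#' d <- pred_data(c(0.1, 0.9), c(0, 1))
#' nf_from_predictions(d, 0.5)
#' @export
nf_from_predictions <- function(data, cutpoint) {
  check_two_classes(data)
  stopifnot(is.numeric(cutpoint), length(cutpoint) == 1L, is.finite(cutpoint))
  at_risk <- data$risk >= cutpoint
  event <- data$outcome == 1L
  nf_table(tp = sum(at_risk & event), fp = sum(at_risk & !event),
           fn = sum(!at_risk & event), tn = sum(!at_risk & !event))
}

#' C-statistic (area under the ROC curve)
#'
#' The probability that a randomly chosen subject who has the event received
#' a higher predicted risk than a randomly chosen subject who did not, with
#' ties counted as 1/2 — the Mann–Whitney concordance estimator. Computed
#' from mid-ranks in O(n log n); identical to the average over all
#' event/non-event pairs.
#'
#' Because it is a pure rank statistic, the C-statistic is invariant under
#' any strictly increasing transform of the risks, and it summarises
#' discrimination across all cut-points at once — which is exactly why it
#' cannot convey the trade-offs at any particular cut-point.
#'
#' @param data A [pred_data()] with at least one event and one non-event.
#' @return A proportion in `[0, 1]`.
#' @examples
#' c_statistic(pred_data(c(0.2, 0.8), c(0, 1)))   # 1: perfect separation
#' @export
c_statistic <- function(data) {
  check_two_classes(data)
  r <- rank(data$risk)            # mid-ranks handle ties as 1/2
  n_event <- sum(data$outcome == 1L)
  n_non <- sum(data$outcome == 0L)
  (sum(r[data$outcome == 1L]) - n_event * (n_event + 1) / 2) /
    (n_event * n_non)
}
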