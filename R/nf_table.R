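#' Natural-frequency 2x2 table on a reference population
#'
#' A natural-frequency table expresses the joint distribution of event
#' status and rule classification as whole-person counts on a reference
#' population (1000 people by default): `tp` people at risk who have the
#' event, `fp` at risk without the event, `fn` not at risk with the event,
#' and `tn` not at risk without the event. The four cells always sum to the
#' population.
#'
#' `nf_table()` stores raw cell counts verbatim, the entry point when a
#' source publication reports its counts directly.
#'
#' @param tp,fp,fn,tn Non-negative integer person counts; at least one must
#'   be positive.
#' @param flags Internal; character vector of provenance flags (e.g.
#'   `"clamped"` when rounding pathological inputs forced a negative cell to
#'   zero).
#' @return An object of class `nf_table` with fields `tp`, `fp`, `fn`, `tn`,
#'   `population`, and `flags`.
#' @examples
#' nf_table(36, 110, 54, 800)        # QRISK2 at the 20% cut-point, per 1000
#' @seealso [nf_from_summary()], [nf_from_predictions()], [nf_rescale()],
#'   [nf_metrics()]
#' @export
nf_table <- function(tp, fp, fn, tn, flags = character()) {
  tp <- stop_if_not_count(tp, "tp")
  fp <- stop_if_not_count(fp, "fp")
  fn <- stop_if_not_count(fn, "fn")
  tn <- stop_if_not_count(tn, "tn")
  if (tp + fp + fn + tn < 1L) {
    stop("at least one cell count must be positive", call. = FALSE)
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         population = tp + fp + fn + tn, flags = flags),
    class = "nf_table"
  )
}

#' Derive a natural-frequency table from summary performance
#'
#' Converts sensitivity, specificity and prevalence into whole-person counts
#' on a reference population. Events are `prevalence * population` rounded
#' half away from zero; `tp` is rounded from the unrounded product
#' `sensitivity * prevalence * population` (not from the already-rounded
#' event margin), with `fn` obtained by subtraction. `tn` and `fp` are
#' derived the same way on the non-event side. Rounding from the unrounded
#' products keeps the cells faithful to the printed percentages: e.g.
#' sensitivity 0.93 at prevalence 0.03647 per 1000 gives 36 events, 34 true
#' positives and 2 false negatives.
#'
#' If extreme inputs make a subtraction-derived cell negative it is clamped
#' to zero, the adjacent cell is adjusted to conserve the population, and the
#' result carries a `"clamped"` flag.
#'
#' @param summary A [perf_summary()].
#' @param population Positive integer reference population (default 1000).
#' @return An [nf_table()].
#' @examples
#' nf_from_summary(perf_summary(0.93, 0.56, 0.03647, "low risk"))
#' nf_from_summary(perf_summary(0.40, 0.88, 0.09, ">=20%"))
#' @export
nf_from_summary <- function(summary, population = 1000) {
  if (!inherits(summary, "perf_summary")) {
    stop("`summary` must be a perf_summary object", call. = FALSE)
  }
  population <- stop_if_not_count(population, "population", positive = TRUE)

  events <- as.integer(round_half_out(summary$prevalence * population))
  non_events <- population - events
  tp <- as.integer(round_half_out(summary$sensitivity * summary$prevalence * population))
  tn <- as.integer(round_half_out(summary$specificity * (1 - summary$prevalence) * population))
  fn <- events - tp
  fp <- non_events - tn

  flags <- character()
  # Rounding the product can exceed the rounded margin by 1 in edge cases;
  # clamp and conserve.
  if (fn < 0L) { tp <- events; fn <- 0L; flags <- c(flags, "clamped") }
  if (fp < 0L) { tn <- non_events; fp <- 0L; flags <- c(flags, "clamped") }
  if (length(flags)) {
    warning("rounding forced a negative cell; clamped to 0", call. = FALSE)
  }
  nf_table(tp, fp, fn, tn, flags = flags)
}

#' Rescale a natural-frequency table to a new reference population
#'
#' Cells are scaled proportionally and integer-allocated by the
#' largest-remainder method, so the four cells sum exactly to the new
#' population and each is within one person of its exact proportional value.
#'
#' @param table An [nf_table()].
#' @param population New positive integer reference population.
#' @return An [nf_table()] with `population` equal to `population`.
#' @examples
#' nf_rescale(nf_table(34, 426, 2, 538), 100)
#' @export
nf_rescale <- function(table, population) {
  stopifnot(inherits(table, "nf_table"))
  population <- stop_if_not_count(population, "population", positive = TRUE)
  cells <- largest_remainder(
    c(table$tp, table$fp, table$fn, table$tn), population)
  nf_table(cells[1], cells[2], cells[3], cells[4], flags = table$flags)
}

#' Per-cut-point performance metrics of a natural-frequency table
#'
#' Computes the conventional conditional metrics (sensitivity, specificity,
#' positive and negative predictive values), the margin counts, and the two
#' trade-off summaries the natural-frequency presentation emphasises: the
#' overtreatment ratio (false positives per true positive: "for every person
#' identified as needing treatment, another N treated unnecessarily") and
#' the missed fraction (share of events classified not at risk).
#'
#' Metrics whose denominator is zero are not an error: they are returned as
#' `NA` and named in the `undefined` field, so sweep tables can render a
#' placeholder.
#'
#' @param table An [nf_table()].
#' @return An object of class `nf_metrics`: a list with fields
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `events`, `non_events`,
#'   `at_risk`, `not_at_risk`, `overtreat_ratio`, `missed_fraction`, and
#'   `undefined` (character vector of metrics with zero denominators).
#' @examples
#' m <- nf_metrics(nf_table(36, 110, 54, 800))
#' m$overtreat_ratio    # ~3: three overtreated per person correctly treated
#' @export
nf_metrics <- function(table) {
  stopifnot(inherits(table, "nf_table"))
  und <- character()
  ratio <- function(num, den, name) {
    if (den > 0) return(num / den)
    und <<- c(und, name)
    NA_real_
  }
  events <- table$tp + table$fn
  non_events <- table$fp + table$tn
  at_risk <- table$tp + table$fp
  not_at_risk <- table$fn + table$tn
  out <- list(
    sensitivity = ratio(table$tp, events, "sensitivity"),
    specificity = ratio(table$tn, non_events, "specificity"),
    ppv = ratio(table$tp, at_risk, "ppv"),
    npv = ratio(table$tn, not_at_risk, "npv"),
    events = events, non_events = non_events,
    at_risk = at_risk, not_at_risk = not_at_risk,
    overtreat_ratio = ratio(table$fp, table$tp, "overtreat_ratio"),
    missed_fraction = ratio(table$fn, events, "missed_fraction")
  )
  out$undefined <- und
  structure(out, class = "nf_metrics")
}

#' @export
print.nf_table <- function(x, ...) {
  cat(sprintf("Natural frequencies per %d people\n", x$population))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(c("at risk", "not at risk"),
                              c("event", "no event")))
  print(m)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.nf_table <- function(object, ...) {
  nf_metrics(object)
}

#' @export
print.nf_metrics <- function(x, digits = 3, ...) {
  fmt <- function(v) if (is.na(v)) "\u2014" else formatC(v, digits = digits, format = "fg")
  cat("Per-cut-point metrics\n")
  cat(sprintf("  events %d / %d (at risk %d, not at risk %d)\n",
              x$events, x$events + x$non_events, x$at_risk, x$not_at_risk))
  cat(sprintf("  sensitivity %s  specificity %s  PPV %s  NPV %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv)))
  cat(sprintf("  overtreatment ratio %s FP per TP; missed fraction %s of events\n",
              fmt(x$overtreat_ratio), fmt(x$missed_fraction)))
  invisible(x)
}

#' @export
as.data.frame.nf_table <- function(x, ...) {
  data.frame(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
             population = x$population)
}
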