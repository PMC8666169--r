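#' Natural-frequency trade-off sweeps
#'
#' A sweep is an ordered collection of natural-frequency tables sharing one
#' reference population, indexed either by cut-point (one population, the
#' rule read at several thresholds) or by prevalence (one cut-point, the
#' rule applied to populations with different baseline risk). Laying the
#' rows side by side makes the trade-off between ruling-in and ruling-out
#' visible as whole-person counts rather than conditional probabilities.
#'
#' @name nf_sweep
#' @seealso [sweep_cutpoints()], [sweep_cutpoints_pred()],
#'   [sweep_prevalence()], [sweep_to_table()]
NULL

new_sweep <- function(rows, axis) {
  labels <- vapply(rows, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    stop("sweep labels must be unique", call. = FALSE)
  }
  structure(list(rows = rows, axis = axis), class = "nf_sweep")
}

sweep_row <- function(label, table) {
  list(label = label, table = table, metrics = nf_metrics(table))
}

#' Sweep across cut-points from summary-level performance
#'
#' One row per cut-point summary, in input order. All summaries must share
#' one prevalence: a cut-point sweep describes a single population, and
#' mixing prevalences would make the columns incomparable.
#'
#' @param summaries List of [perf_summary()] objects (at least one), with
#'   equal prevalence.
#' @param population Reference population shared by all rows (default 1000).
#' @return An object of class `nf_sweep` with `axis = "cutpoint"`.
#' @examples
#' s <- sweep_cutpoints(list(
#'   perf_summary(0.99, 0.25, 0.04, "very low"),
#'   perf_summary(0.93, 0.56, 0.04, "low")))
#' sweep_to_table(s, "markdown")
#' @export
sweep_cutpoints <- function(summaries, population = 1000) {
  if (!is.list(summaries) || length(summaries) < 1L ||
      !all(vapply(summaries, inherits, TRUE, "perf_summary"))) {
    stop("`summaries` must be a non-empty list of perf_summary objects",
         call. = FALSE)
  }
  prevs <- vapply(summaries, `[[`, 0, "prevalence")
  if (diff(range(prevs)) > 1e-12) {
    stop("all summaries in a cut-point sweep must share one prevalence",
         call. = FALSE)
  }
  rows <- lapply(summaries, function(s) {
    sweep_row(s$label, nf_from_summary(s, population))
  })
  new_sweep(rows, "cutpoint")
}

#' Sweep across cut-points from individual-level predictions
#'
#' Classifies the dataset at each cut-point (inclusive `>=` threshold) and
#' returns one row per cut-point, sorted ascending. Raising the cut-point
#' can only move subjects out of the at-risk class, so the at-risk count is
#' non-increasing down the rows.
#'
#' @param data A [pred_data()].
#' @param cutpoints Numeric vector of thresholds (at least one).
#' @return An `nf_sweep` with `axis = "cutpoint"`.
#' @export
sweep_cutpoints_pred <- function(data, cutpoints) {
  check_two_classes(data)
  if (length(cutpoints) < 1L || !is.numeric(cutpoints)) {
    stop("`cutpoints` must be a non-empty numeric vector", call. = FALSE)
  }
  cutpoints <- sort(unique(cutpoints))
  rows <- lapply(cutpoints, function(ct) {
    sweep_row(format(ct), nf_from_predictions(data, ct))
  })
  new_sweep(rows, "cutpoint")
}

#' Sweep across prevalence values at a fixed cut-point
#'
#' Holds sensitivity and specificity fixed and varies the baseline risk —
#' how the same rule plays out in populations with different underlying
#' event rates. Events rise with prevalence while the conditional metrics
#' stay put, which is why predictive values alone cannot be transported
#' across settings.
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @param prevalences Vector of proportions strictly inside `(0, 1)`.
#' @param population Reference population (default 1000).
#' @return An `nf_sweep` with `axis = "prevalence"`.
#' @examples
#' sweep_prevalence(0.40, 0.88, c(0.05, 0.09), 1000)
#' @export
sweep_prevalence <- function(sensitivity, specificity, prevalences,
                             population = 1000) {
  if (length(prevalences) < 1L) {
    stop("`prevalences` must contain at least one value", call. = FALSE)
  }
  rows <- lapply(prevalences, function(p) {
    s <- perf_summary(sensitivity, specificity, p,
                      label = format(p))
    sweep_row(s$label, nf_from_summary(s, population))
  })
  new_sweep(rows, "prevalence")
}

#' Build a sweep from pre-tabulated natural-frequency tables
#'
#' Entry point when the per-cut-point cells are known directly (e.g. a
#' source that reports raw counts), rather than re-derived from rounded
#' percentages. All tables must share one reference population.
#'
#' @param tables Non-empty list of [nf_table()] objects; names are used as
#'   row labels when present.
#' @param labels Optional character vector of row labels, one per table.
#' @param axis Sweep axis the rows vary over (default `"cutpoint"`).
#' @return An `nf_sweep`.
#' @examples
#' sweep_from_tables(list("low risk" = nf_table(34, 426, 2, 538),
#'                        "cut-point 3" = nf_table(24, 95, 12, 869)))
#' @export
sweep_from_tables <- function(tables, labels = names(tables),
                              axis = c("cutpoint", "prevalence")) {
  axis <- match.arg(axis)
  if (!is.list(tables) || length(tables) < 1L ||
      !all(vapply(tables, inherits, TRUE, "nf_table"))) {
    stop("`tables` must be a non-empty list of nf_table objects",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- paste("row", seq_along(tables))
  pops <- vapply(tables, `[[`, 0L, "population")
  if (length(unique(pops)) != 1L) {
    stop("all tables in a sweep must share one reference population",
         call. = FALSE)
  }
  new_sweep(mapply(sweep_row, labels, tables, SIMPLIFY = FALSE), axis)
}

#' @export
as.data.frame.nf_sweep <- function(x, ...) {
  do.call(rbind, lapply(x$rows, function(r) {
    t <- r$table; m <- r$metrics
    data.frame(label = r$label, tp = t$tp, fp = t$fp, fn = t$fn, tn = t$tn,
               at_risk = m$at_risk, not_at_risk = m$not_at_risk,
               sensitivity = m$sensitivity, specificity = m$specificity,
               ppv = m$ppv, npv = m$npv,
               overtreat_ratio = m$overtreat_ratio,
               missed_fraction = m$missed_fraction,
               stringsAsFactors = FALSE)
  }))
}

#' Render a sweep as a CSV or Markdown table
#'
#' Columns: label, the four cells, the margin counts, and the derived
#' metrics. Counts are integers; proportions are rendered to `digits`
#' decimals; metrics undefined because of a zero denominator are rendered as
#' an em dash.
#'
#' @param result An `nf_sweep`.
#' @param format `"csv"` or `"markdown"`.
#' @param digits Decimals for proportions (default 2, matching the usual
#'   percentage-style reporting).
#' @return A single string containing the document.
#' @export
sweep_to_table <- function(result, format = c("csv", "markdown"), digits = 2) {
  stopifnot(inherits(result, "nf_sweep"))
  if (length(result$rows) < 1L) stop("empty sweep", call. = FALSE)
  format <- match.arg(format)
  df <- as.data.frame(result)
  prop_cols <- c("sensitivity", "specificity", "ppv", "npv",
                 "overtreat_ratio", "missed_fraction")
  disp <- df
  for (cc in prop_cols) {
    disp[[cc]] <- ifelse(is.na(df[[cc]]), "\u2014",
                         formatC(df[[cc]], digits = digits, format = "f"))
  }
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(disp, con, row.names = FALSE, quote = FALSE)
    close(con)
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }
  cells <- rbind(names(disp), c("---")[rep(1, ncol(disp))],
                 as.matrix(format(disp, justify = "left")))
  paste0(apply(cells, 1, function(r) {
    paste0("| ", paste(trimws(r), collapse = " | "), " |")
  }), collapse = "\n")
}

#' @export
print.nf_sweep <- function(x, ...) {
  cat(sprintf("Natural-frequency sweep over %s (%d rows, population %d)\n",
              x$axis, length(x$rows), x$rows[[1]]$table$population))
  print(as.data.frame(x), digits = 3)
  invisible(x)
}
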