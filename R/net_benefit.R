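#' Decision-analytic strategies for net-benefit comparison
#'
#' A strategy is either the prediction rule itself (summarised by its
#' natural-frequency table at the chosen cut-point), treat everyone, or
#' treat no one. The two reference strategies need only a prevalence and
#' population; the rule needs its table.
#'
#' @param kind `"rule"`, `"treat_all"`, or `"treat_none"`.
#' @param table An [nf_table()]; required when `kind = "rule"`, ignored
#'   otherwise.
#' @return An object of class `nb_strategy`.
#' @export
nb_strategy <- function(kind = c("rule", "treat_all", "treat_none"),
                        table = NULL) {
  kind <- match.arg(kind)
  if (kind == "rule") {
    if (!inherits(table, "nf_table")) {
      stop("a rule strategy needs an nf_table", call. = FALSE)
    }
  } else {
    table <- NULL
  }
  structure(list(kind = kind, table = table), class = "nb_strategy")
}

#' Net benefit of a strategy at a threshold probability
#'
#' Net benefit weighs true positives against false positives at the
#' threshold odds: `NB = TP/N - (FP/N) * t / (1 - t)` for threshold
#' probability `t`. Treat-none has net benefit zero by construction;
#' treat-all classifies everyone at risk, so its TP count is the number of
#' events and its FP count the number of non-events. The strategy with the
#' highest net benefit at a threshold is optimal under the assumption that
#' the trade-off at that threshold is acceptable — net benefit compares
#' strategies, it does not choose the threshold.
#'
#' When only a summary-level table is available, the rule's cells are held
#' fixed across thresholds (no per-threshold reclassification is possible
#' without individual-level data).
#'
#' @param strategy An [nb_strategy()].
#' @param threshold Threshold probability, strictly inside `(0, 1)`.
#' @param prevalence Event proportion; required for the reference
#'   strategies, taken from the table for a rule when omitted.
#' @param population Reference population; defaults to the rule table's
#'   population, or 1000 for reference strategies.
#' @return Net benefit per person (a real number, at most the prevalence).
#' @examples
#' q <- nf_table(36, 110, 54, 800)
#' net_benefit(nb_strategy("rule", q), 0.20)          # 0.0085
#' net_benefit(nb_strategy("treat_all"), 0.20, 0.09)  # negative here
#' @export
net_benefit <- function(strategy, threshold, prevalence = NULL,
                        population = NULL) {
  stopifnot(inherits(strategy, "nb_strategy"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly in (0, 1)", call. = FALSE)
  }
  odds <- threshold / (1 - threshold)
  switch(strategy$kind,
    treat_none = 0,
    treat_all = {
      if (is.null(prevalence)) {
        stop("treat_all needs a prevalence", call. = FALSE)
      }
      stop_if_not_proportion(prevalence, "prevalence")
      prevalence - (1 - prevalence) * odds
    },
    rule = {
      t <- strategy$table
      t$tp / t$population - (t$fp / t$population) * odds
    }
  )
}

#' Decision curve over a set of strategies and thresholds
#'
#' Evaluates every strategy at every threshold probability — the full
#' cross-product, ordered by threshold then by strategy input position —
#' giving the table behind a decision-curve plot.
#'
#' @param strategies Non-empty list of [nb_strategy()] objects; names are
#'   used as strategy labels when present.
#' @param thresholds Non-empty vector of threshold probabilities in (0, 1).
#' @param prevalence Event proportion used by the reference strategies.
#' @param population Reference population (default 1000).
#' @return A data.frame of class `decision_curve` with columns `threshold`,
#'   `strategy`, `net_benefit`.
#' @examples
#' q <- nf_table(36, 110, 54, 800)
#' dc <- decision_curve(
#'   list(QRISK2 = nb_strategy("rule", q),
#'        "treat all" = nb_strategy("treat_all"),
#'        "treat none" = nb_strategy("treat_none")),
#'   thresholds = c(0.05, 0.1, 0.2), prevalence = 0.09)
#' @export
decision_curve <- function(strategies, thresholds, prevalence,
                           population = 1000) {
  if (!is.list(strategies) || length(strategies) < 1L ||
      !all(vapply(strategies, inherits, TRUE, "nb_strategy"))) {
    stop("`strategies` must be a non-empty list of nb_strategy objects",
         call. = FALSE)
  }
  if (length(thresholds) < 1L) {
    stop("`thresholds` must be non-empty", call. = FALSE)
  }
  labels <- names(strategies)
  if (is.null(labels)) labels <- rep("", length(strategies))
  labels <- ifelse(nzchar(labels), labels,
                   vapply(strategies, `[[`, "", "kind"))
  rows <- expand.grid(strategy_i = seq_along(strategies),
                      threshold = thresholds, KEEP.OUT.ATTRS = FALSE)
  rows <- rows[order(rows$threshold, rows$strategy_i), ]
  out <- data.frame(
    threshold = rows$threshold,
    strategy = labels[rows$strategy_i],
    net_benefit = mapply(function(i, t) {
      net_benefit(strategies[[i]], t, prevalence, population)
    }, rows$strategy_i, rows$threshold),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("decision_curve", "data.frame")
  out
}

#' Plot a decision curve
#'
#' One line per strategy, net benefit against threshold probability, on the
#' active base-graphics device.
#'
#' @param x A [decision_curve()] result.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.decision_curve <- function(x, ...) {
  wide <- stats::reshape(as.data.frame(x), direction = "wide",
                         idvar = "threshold", timevar = "strategy")
  graphics::matplot(wide$threshold, wide[, -1, drop = FALSE], type = "l",
                    lty = 1, xlab = "threshold probability",
                    ylab = "net benefit", ...)
  graphics::legend("topright", legend = unique(x$strategy), lty = 1,
                   col = seq_along(unique(x$strategy)), bty = "n")
  invisible(x)
}
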