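#' Binormal score separation for a target C-statistic
#'
#' Under the equal-variance binormal model — non-event scores standard
#' normal, event scores normal with unit variance and mean `mu` — the
#' C-statistic has the closed form `C = pnorm(mu / sqrt(2))`. Inverting
#' gives the separation needed to hit a target: `mu = sqrt(2) * qnorm(C)`.
#'
#' @param target_c Target C-statistic, strictly inside `(0.5, 1)`.
#' @return The event/non-event mean separation `mu`.
#' @examples
#' binormal_separation(0.77)
#' @export
binormal_separation <- function(target_c) {
  if (!is.numeric(target_c) || length(target_c) != 1L ||
      target_c <= 0.5 || target_c >= 1) {
    stop("`target_c` must lie strictly in (0.5, 1)", call. = FALSE)
  }
  sqrt(2) * stats::qnorm(target_c)
}

#' Simulate risk scores with controlled discrimination
#'
#' Draws outcomes with the given prevalence, then scores from the
#' equal-variance binormal model calibrated so the population C-statistic
#' equals `target_c`; scores are mapped to `(0, 1)` risks by the logistic
#' transform. The mapping is strictly increasing, so it changes no rank and
#' leaves the C-statistic untouched; the simulated risks control
#' discrimination only and are not calibrated to the true event
#' probabilities.
#'
#' The draw is fully reproducible from `seed`, and the caller's RNG state
#' is left unchanged.
#'
#' @param n Number of subjects (at least 2).
#' @param prevalence Event probability, strictly inside `(0, 1)`.
#' @param target_c Target C-statistic, strictly inside `(0.5, 1)`.
#' @param seed Integer seed (required).
#' @return A [pred_data()] of `n` subjects.
#' @examples
#' d <- simulate_scores(500, prevalence = 0.09, target_c = 0.77, seed = 1)
#' c_statistic(d)
#' @export
simulate_scores <- function(n, prevalence, target_c, seed) {
  n <- stop_if_not_count(n, "n", positive = TRUE)
  if (n < 2L) stop("`n` must be at least 2", call. = FALSE)
  stop_if_not_proportion(prevalence, "prevalence", open = TRUE)
  mu <- binormal_separation(target_c)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("an integer `seed` is required", call. = FALSE)
  }
  local_seed(seed, {
    outcome <- stats::rbinom(n, 1L, prevalence)
    score <- stats::rnorm(n, mean = mu * outcome, sd = 1)
    pred_data(stats::plogis(score), outcome)
  })
}

#' Packaged case-study fixtures
#'
#' Returns the summary-level performance and prose-derived cell counts for
#' the two packaged case studies:
#'
#' * `"csrs"` — the Canadian Syncope Risk Score (serious adverse events
#'   after emergency-department presentation with syncope): prevalence
#'   0.03647, sensitivity 93% at the "low risk" cut-point, with the
#'   specificity stored in both printed variants (53% in the tabulated
#'   report, 56% in the diagram caption; the prose-consistent cells imply
#'   about 55.8%).
#' * `"qrisk2"` — the QRISK2 cardiovascular score at the 20% cut-point
#'   (external validation, males 35–74): prevalence 0.09, sensitivity 40%,
#'   specificity 88%, C-statistic 0.77.
#'
#' Each fixture carries its reference cell counts as [nf_table()] objects
#' with provenance notes, and (for CSRS) a set of synthetic cut-point
#' summaries for sweep demonstrations, flagged as such.
#'
#' @param name `"csrs"` or `"qrisk2"`.
#' @return A list with elements `name`, `description`, `prevalence`,
#'   `c_statistic`, `summaries` (list of [perf_summary()]), `counts` (named
#'   list of [nf_table()]), `notes` (named character), and optionally
#'   `synthetic_sweep`.
#' @export
case_study_fixture <- function(name = c("csrs", "qrisk2")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "natfreq",
                      mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  as_summary <- function(s) {
    perf_summary(s$sensitivity, s$specificity, s$prevalence, s$label)
  }
  out <- list(
    name = raw$name,
    description = raw$description,
    prevalence = raw$prevalence,
    c_statistic = raw$c_statistic,
    summaries = lapply(raw$summaries, as_summary),
    counts = lapply(raw$counts, function(cc) {
      nf_table(cc$tp, cc$fp, cc$fn, cc$tn)
    }),
    notes = vapply(raw$counts, function(cc) cc$note %||% "", "")
  )
  if (!is.null(raw$synthetic_sweep)) {
    out$synthetic_sweep <- lapply(raw$synthetic_sweep, as_summary)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
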