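# Internal numeric helpers shared across the package.

# Round half away from zero. base::round() rounds half to even, which does
# not reproduce natural-frequency cells derived from printed percentages
# (e.g. 0.93 * 36.47 = 33.917 must give 34, and 36.5 events must give 37,
# never 36).
round_half_out <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Largest-remainder (Hamilton) integer allocation: scale `counts` so they
# sum exactly to `total`, each allocated value within 1 of its exact
# proportional share. Ties on the remainder are broken by position, so the
# result is deterministic.
largest_remainder <- function(counts, total) {
  shares <- counts * total / sum(counts)
  base <- floor(shares)
  short <- total - sum(base)
  if (short > 0) {
    ord <- order(shares - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

is_proportion <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

stop_if_not_proportion <- function(x, name, open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (open) {
    if (x <= 0 || x >= 1) {
      stop(sprintf("`%s` must lie strictly in (0, 1), got %g", name, x),
           call. = FALSE)
    }
  } else if (x < 0 || x > 1) {
    stop(sprintf("`%s` must lie in [0, 1], got %g", name, x), call. = FALSE)
  }
  invisible(x)
}

stop_if_not_count <- function(x, name, positive = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    abs(x - round(x)) < 1e-8 && x >= if (positive) 1 else 0
  if (!ok) {
    stop(sprintf("`%s` must be a %s integer", name,
                 if (positive) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(as.integer(round(x)))
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so package randomness never perturbs the session stream.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Minimal {placeholder} interpolation used by the narrative templates.
interpolate <- function(template, values) {
  for (key in names(values)) {
    template <- gsub(paste0("{", key, "}"), as.character(values[[key]]),
                     template, fixed = TRUE)
  }
  template
}
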