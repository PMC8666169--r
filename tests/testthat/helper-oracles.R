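# Independent brute-force oracles, kept deliberately naive so they cannot
# share a code path with the implementation.

# Classify each subject one at a time with an explicit loop.
bf_classify <- function(risk, outcome, cutpoint) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(risk)) {
    if (risk[i] >= cutpoint) {
      if (outcome[i] == 1) tp <- tp + 1L else fp <- fp + 1L
    } else {
      if (outcome[i] == 1) fn <- fn + 1L else tn <- tn + 1L
    }
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# O(n^2) pairwise concordance with ties counted 1/2.
bf_cstat <- function(risk, outcome) {
  ev <- risk[outcome == 1]
  ne <- risk[outcome == 0]
  total <- 0
  for (e in ev) {
    for (x in ne) {
      total <- total + if (e > x) 1 else if (e == x) 0.5 else 0
    }
  }
  total / (length(ev) * length(ne))
}

random_pred <- function(n, seed, ties = FALSE) {
  set.seed(seed)
  risk <- if (ties) sample(seq(0, 1, by = 0.1), n, replace = TRUE)
          else runif(n)
  outcome <- rbinom(n, 1, 0.3)
  # guarantee both classes
  outcome[1] <- 1L
  outcome[2] <- 0L
  pred_data(risk, outcome)
}
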