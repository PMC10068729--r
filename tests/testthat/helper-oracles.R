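# Independent brute-force oracles used to check the optimizers and the
# multiplicity adjustment.

# Textbook Benjamini-Hochberg step-up, written directly from its definition.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Exhaustive search over every real threshold (all observed values plus
# sentinels and midpoints) for the two-step sieve, returning the same choice
# contract as optimize_secondary_threshold.
sieve_oracle <- function(data, labels, secondary_score, direction,
                         sens_min = 0.95, primary_threshold = 9) {
  y <- as.logical(labels)
  sec <- data[[secondary_score]]
  values <- sort(unique(sec))
  # midpoints cover every distinct classification a real threshold can induce
  cand <- unique(c(-Inf, values, values + 0.5, values - 0.5, Inf))
  rows <- lapply(cand, function(th) {
    step1 <- data$fwt_total <= primary_threshold
    step2 <- if (direction == "less_than") sec < th else sec > th
    pred <- step1 | (!step1 & step2)
    tp <- sum(pred & y); fp <- sum(pred & !y)
    tn <- sum(!pred & !y); fn <- sum(!pred & y)
    data.frame(threshold = th, sens = tp / (tp + fn), spec = tn / (tn + fp),
               positives = tp + fp)
  })
  g <- do.call(rbind, rows)
  feasible <- g$sens >= sens_min
  if (any(feasible)) {
    gf <- g[feasible, ]
    gf <- gf[order(-gf$spec, gf$positives), ]
    gf[1, ]
  } else {
    g <- g[order(-g$sens, -g$spec, g$positives), ]
    g[1, ]
  }
}

# Exhaustive search over the defined candidate set for the probability
# threshold (the distinct fitted probabilities plus the 0 sentinel).
prob_threshold_oracle <- function(probs, labels, sens_min = 0.95) {
  y <- as.logical(labels)
  cand <- sort(unique(c(0, probs)))
  rows <- lapply(cand, function(tau) {
    pred <- probs >= tau
    tp <- sum(pred & y); fp <- sum(pred & !y)
    tn <- sum(!pred & !y); fn <- sum(!pred & y)
    data.frame(tau = tau, sens = tp / (tp + fn), spec = tn / (tn + fp),
               positives = tp + fp)
  })
  g <- do.call(rbind, rows)
  feasible <- g$sens >= sens_min
  if (any(feasible)) {
    gf <- g[feasible, ]
    gf <- gf[order(-gf$spec, gf$positives), ]
    gf[1, ]
  } else {
    g <- g[order(-g$sens, -g$spec, g$positives), ]
    g[1, ]
  }
}

# Small random sieve training set with integer secondary scores.
random_sieve_data <- function(n = 30, n_values = 8) {
  tibble::tibble(
    fwt_total = sample(c(7:10), n, replace = TRUE,
                       prob = c(0.1, 0.15, 0.25, 0.5)),
    nct_good = sample.int(n_values, n, replace = TRUE)
  )
}
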