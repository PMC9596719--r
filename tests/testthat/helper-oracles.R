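# Independent oracles, coded without reference to the package internals.

# One-way ANOVA F through R's linear-model machinery.
oracle_anova_f <- function(values, labels) {
  a <- stats::anova(stats::lm(values ~ factor(labels)))
  list(f = a$`F value`[1L], p = a$`Pr(>F)`[1L],
       between = a$`Sum Sq`[1L], within = a$`Sum Sq`[2L])
}

# Brute-force minimum reciprocal-F loss over all contiguous partitions of the
# sorted data into k groups (boundaries at every position, ties ignored --
# use on continuous data only).  Independent sum-of-squares routine.
oracle_best_loss <- function(values, k) {
  xs <- sort(values)
  n <- length(xs)
  cut_sets <- utils::combn(seq_len(n - 1L), k - 1L)
  best <- Inf
  for (j in seq_len(ncol(cut_sets))) {
    cuts <- cut_sets[, j]
    g <- findInterval(seq_len(n), cuts + 0.5) # group index per sorted position
    means <- tapply(xs, g, mean)
    within <- sum((xs - means[as.character(g)])^2)
    between <- sum(tapply(xs, g, length) * (means - mean(xs))^2)
    if (between > 0) {
      best <- min(best, (within / (n - k)) / (between / (k - 1)))
    }
  }
  best
}

# Sample skewness (method-of-moments).
oracle_skewness <- function(v) {
  mean((v - mean(v))^3) / stats::sd(v)^3
}

random_exposure <- function(n, ties = FALSE) {
  x <- stats::rnorm(n)
  if (ties) {
    x <- round(x, 1)
  }
  x
}

# Random valid labelling with every group nonempty.
random_labels <- function(n, k) {
  repeat {
    lab <- sort(sample.int(k, n, replace = TRUE) - 1L)
    if (length(unique(lab)) == k) return(lab)
  }
}

make_monotonic_scenario <- function(n, m) {
  sim_scenario(n = n, m = m, alpha = c(0.4, 0.3, 0.2, 0.1),
               effect_model = "monotonic")
}

make_nonmonotonic_scenario <- function(n, m) {
  sim_scenario(n = n, m = m, alpha = c(0.4, 0.3, 0.2, 0.1),
               effect_model = "nonmonotonic")
}
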