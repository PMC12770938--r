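# Independent brute-force oracles used across tests.

# Mann-Whitney AUC by explicit enumeration of all case/control pairs.
brute_auc <- function(values, is_case) {
  x <- values[is_case]; y <- values[!is_case]
  total <- 0
  for (a in x) for (b in y)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(x) * length(y))
}

# Weighted median by expanding integer weights and taking the lower
# median of the expanded sample.
brute_weighted_median <- function(values, weights) {
  expanded <- sort(rep(values, times = weights))
  expanded[ceiling(length(expanded) / 2)]
}

# DeLong AUC variance from hand-expanded structural components.
brute_delong_var <- function(scores, is_case) {
  x <- scores[is_case]; y <- scores[!is_case]
  m <- length(x); n <- length(y)
  v10 <- numeric(m); v01 <- numeric(n)
  for (i in seq_len(m)) {
    s <- 0
    for (j in seq_len(n)) s <- s + (x[i] > y[j]) + 0.5 * (x[i] == y[j])
    v10[i] <- s / n
  }
  for (j in seq_len(n)) {
    s <- 0
    for (i in seq_len(m)) s <- s + (x[i] > y[j]) + 0.5 * (x[i] == y[j])
    v01[j] <- s / m
  }
  auc <- mean(v10)
  v <- sum((v10 - mean(v10))^2) / (m - 1) / m +
    sum((v01 - mean(v01))^2) / (n - 1) / n
  list(auc = auc, var = v)
}

# small paired-platform cohort on the miniature genome; any argument of
# sim_config() can be overridden
small_sim_config <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(seed = seed,
         n_per_cohort = c(NE = 6, NDBE = 10, LGD = 4, HGD = 6, EAC = 8),
         n_regions = 40, n_true_markers = 6,
         genome = toy_genome()),
    list(...))
  do.call(sim_config, args)
}
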