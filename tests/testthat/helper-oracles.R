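# Independent brute-force oracles, implemented directly from the defining
# formulas with plain loops; they deliberately share no code with the
# package internals they cross-check.

# Fleiss' kappa from first principles on an items-by-categories count table.
fleiss_oracle <- function(tab) {
  N <- nrow(tab); n <- sum(tab[1, ])
  P_i <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0
    for (j in seq_len(ncol(tab))) s <- s + tab[i, j] * (tab[i, j] - 1)
    P_i[i] <- s / (n * (n - 1))
  }
  p_j <- numeric(ncol(tab))
  for (j in seq_len(ncol(tab))) p_j[j] <- sum(tab[, j]) / (N * n)
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  if (abs(1 - Pe) < 1e-14) return(if (Pbar >= 1 - 1e-12) 1 else 0)
  (Pbar - Pe) / (1 - Pe)
}

# Cohen's kappa by looping over categories.
cohen_oracle <- function(a, b) {
  levs <- sort(unique(c(a, b)))
  n <- length(a)
  p_o <- sum(a == b) / n
  p_e <- 0
  for (l in levs) p_e <- p_e + (sum(a == l) / n) * (sum(b == l) / n)
  if (abs(1 - p_e) < 1e-14) return(if (p_o >= 1 - 1e-12) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

# ICC(2,1) via an aov() two-way ANOVA table (independent route through the
# fitted mean squares rather than hand-computed sums of squares).
icc_oracle <- function(first, second) {
  y <- c(first, second)
  item <- factor(rep(seq_along(first), 2L))
  rater <- factor(rep(1:2, each = length(first)))
  ms <- summary(stats::aov(y ~ item + rater))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- length(first); k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Exhaustive consensus oracle for a 3-vote senior panel.
consensus_oracle <- function(votes, leader_index) {
  counts <- table(votes)
  if (max(counts) == 1) return(votes[leader_index])
  as.integer(names(counts)[which.max(counts)])
}

# Binomial three-standard-error band check.
within_3se <- function(observed, p, n) {
  abs(observed - p) <= 3 * sqrt(p * (1 - p) / n) + 1e-12
}

# Small helper cohort: n images all of one class (or a class vector).
toy_cohort <- function(classes) {
  data.frame(image_id = sprintf("t%05d", seq_along(classes)),
             true_class = as.integer(classes),
             raw_label = NA_integer_,
             site_id = "siteA", camera_id = "camA",
             excluded = FALSE, stringsAsFactors = FALSE)
}
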