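# Independent oracles used across the suite.  Each re-derives the target
# quantity by a different route (brute force, enumeration, closed form) than
# the implementation under test.

# Partial correlation as the Pearson correlation of the residuals from
# regressing age and expression on sex.
oracle_partial_residual <- function(age, expr, sex) {
  ra <- resid(lm(age ~ sex))
  re <- resid(lm(expr ~ sex))
  cor(ra, re)
}

# Benjamini-Hochberg step-up computed from first principles.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Upper-tail hypergeometric probability by exhaustive enumeration over the
# overlap count, using exact binomial coefficients.
oracle_hyper <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Pearson chi-square statistic for a 2x2 table from the closed-form
# cross-product formula.
oracle_chi2_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# Product-limit survival curve by day-by-day risk-set bookkeeping.
oracle_km <- function(day, death) {
  times <- sort(unique(day[death]))
  s <- 1
  surv <- numeric(length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    at_risk <- sum(day >= t)
    died <- sum(day == t & death)
    s <- s * (1 - died / at_risk)
    surv[i] <- s
  }
  data.frame(day = times, surv = surv)
}

# Small survival dataset in the package's record layout.
make_records <- function(day, arm, event = rep("death", length(day)),
                         repeat_id = 1) {
  data.frame(animal_id = sprintf("a%03d", seq_along(day)),
             arm = arm, repeat_id = repeat_id, day = day, event = event,
             stringsAsFactors = FALSE)
}

# Tiny expression study with fully controlled values.
make_study <- function(exprs, age, sex,
                       condition = rep("healthy", length(age)),
                       platform = "rnaseq", tissue = "t1") {
  if (is.null(rownames(exprs)))
    rownames(exprs) <- sprintf("g%03d", seq_len(nrow(exprs)))
  colnames(exprs) <- sprintf("s%03d", seq_len(ncol(exprs)))
  expression_study(
    exprs,
    data.frame(sample_id = colnames(exprs), age = age, sex = sex,
               tissue = tissue, condition = condition, dataset_id = "d1",
               stringsAsFactors = FALSE),
    platform = platform)
}
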