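# Independent brute-force oracles and small fixture builders shared across
# the test files. Oracles deliberately use the most literal textbook formulas
# so they stay independent of the package's implementation paths.

# Botstein PIC by explicit double loop over ordered pairs
pic_brute <- function(p) {
  s <- 1 - sum(p^2)
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      if (i < j) s <- s - 2 * p[i]^2 * p[j]^2
    }
  }
  s
}

# Pearson r and two-sided p via the direct covariance / t-distribution route
pearson_brute <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# paired t via d-bar / (s_d / sqrt(n))
paired_t_brute <- function(a, b) {
  d <- a - b
  n <- length(d)
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 1))
}

# Welch two-sample t with Welch-Satterthwaite df
welch_brute <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(tstat), df = df)
}

rand_spectrum <- function(k = sample(2:6, 1)) {
  p <- stats::rgamma(k, 1) + 1e-3
  allele_spectrum(p / sum(p))
}

# 40 inbred diploids: n_b of them fixed for B, the rest fixed for A
fixed_line_panel <- function(n = 40, n_b = 1) {
  genotype_panel(
    markers = data.frame(name = "M1"),
    individuals = data.frame(id = sprintf("i%02d", 1:n), ploidy = 2L),
    calls = matrix(c(rep("A", n - n_b), rep("B", n_b)), ncol = 1)
  )
}

# small multi-locus panel with known mixed calls
toy_mixed_panel <- function() {
  genotype_panel(
    markers = data.frame(name = c("M1", "M2"), chromosome = c(1L, 2L)),
    individuals = data.frame(
      id = c("d1", "d2", "t1"),
      ploidy = c(2L, 2L, 4L),
      subgroup = c("indica", "japonica", "indica"),
      pair_id = c("p1", NA, "p1")
    ),
    calls = matrix(c("A/B", "A", "A/B/C",
                     "B", NA, "C"), nrow = 3)
  )
}

# trait table with exact entity means for heterosis arithmetic
simple_trial <- function() {
  mk <- function(entity, trait, vals) {
    data.frame(entity = entity, trait = trait,
               replicate = seq_along(vals), value = vals)
  }
  trait_table(rbind(
    mk("p1", "GY", c(10, 10, 10)), mk("p2", "GY", c(8, 8, 8)),
    mk("h2x", "GY", c(12, 12, 12)),
    mk("p1t", "GY", c(9, 9, 9)), mk("p2t", "GY", c(7, 7, 7)),
    mk("h4x", "GY", c(15, 15, 15))
  ))
}

simple_plan <- function() {
  cross_plan(data.frame(
    female = c("p1", "p1t"), male = c("p2", "p2t"),
    hybrid_id = c("h2x", "h4x"), ploidy = c(2L, 4L),
    counterpart_2x_hybrid = c(NA, "h2x")
  ))
}
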