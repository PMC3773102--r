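test_that("Pearson r and p match the direct formula oracle", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    x <- stats::rnorm(n)
    y <- 0.5 * x + stats::rnorm(n)
    res <- pearson_correlation(x, y)
    oracle <- pearson_brute(x, y)
    expect_equal(res$r, oracle$r, tolerance = 1e-9)
    expect_equal(res$p, oracle$p, tolerance = 1e-9)
    expect_equal(res$n, n)
  }
})

test_that("Pearson handles exact fits, degeneracies and affine maps", {
  x <- 1:10
  res <- pearson_correlation(x, 2 * x + 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$p, 1e-12)
  expect_identical(res$stars, "**")

  expect_warning(res0 <- pearson_correlation(x, rep(3, 10)), "zero variance")
  expect_true(is.na(res0$r))
  expect_warning(resn <- pearson_correlation(1:2, 2:1), "fewer than 3")
  expect_true(is.na(resn$r))

  set.seed(9)
  y <- stats::rnorm(10)
  r0 <- pearson_correlation(x, y)$r
  expect_equal(pearson_correlation(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_correlation(-2 * x, y)$r, -r0, tolerance = 1e-12)

  # pairwise-complete filtering
  xm <- c(x, NA); ym <- c(y, 5)
  expect_equal(pearson_correlation(xm, ym)$n, 10)
})

test_that("regression recovers exact lines and satisfies R^2 = r^2", {
  # suppress lm's "essentially perfect fit" note on the exact line
  res <- suppressWarnings(simple_linear_regression(1:10, 3 * (1:10) - 2))
  expect_equal(res$slope, 3, tolerance = 1e-12)
  expect_equal(res$intercept, -2, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)

  # orthogonal construction: slope and R^2 are 0
  x <- c(-2, -1, 0, 1, 2)
  y <- c(1, -1, 0, -1, 1)  # even function, uncorrelated with x
  res0 <- simple_linear_regression(x, y)
  expect_equal(res0$slope, 0, tolerance = 1e-12)
  expect_equal(res0$r_squared, 0, tolerance = 1e-12)

  set.seed(15)
  for (rep in 1:25) {
    x <- stats::rnorm(12)
    y <- stats::rnorm(12)
    expect_equal(simple_linear_regression(x, y)$r_squared,
                 pearson_correlation(x, y)$r^2, tolerance = 1e-9)
  }
})

test_that("regression slope lands within 2 SE of the generating coefficient", {
  set.seed(42)
  hits <- 0L
  beta <- 2.5
  for (rep in 1:100) {
    gd <- stats::runif(30, 0.1, 0.8)
    hb <- beta * gd + stats::rnorm(30, sd = 0.4)
    fit <- stats::lm(hb ~ gd)
    se <- summary(fit)$coefficients["gd", "Std. Error"]
    est <- simple_linear_regression(gd, hb)$slope
    hits <- hits + (abs(est - beta) <= 2 * se)
  }
  expect_gte(hits, 93L)
})

test_that("GD-heterosis table couples and nulls as constructed", {
  # constant genetic distance -> zero variance -> missing r
  recs <- data.frame(hybrid_id = paste0("h", 1:5), female = "f", male = "m",
                     ploidy = 2L, trait = "GY", HB = stats::rnorm(5),
                     MP = NA_real_, CH = NA_real_)
  class(recs) <- c("heterosis_records", "data.frame")
  dm <- matrix(0.3, 2, 2, dimnames = list(c("f", "m"), c("f", "m")))
  diag(dm) <- 0
  plan <- cross_plan(data.frame(female = "f", male = "m",
                                hybrid_id = paste0("h", 1:5), ploidy = 2L))
  tab <- gd_heterosis_table(dm, recs, plan)
  expect_true(is.na(tab$r))

  # a coupled simulation yields a significantly positive tetraploid r
  rep1 <- gd_coupling_replicate(1)
  r4 <- rep1[rep1$ploidy == 4, ]
  expect_gt(r4$r, 0)
  expect_lt(r4$p, 0.05)
  expect_equal(r4$n, 28)

  # under the null (beta = 0 in both groups) significance stays at noise level
  sig <- 0L
  for (seed in 1:12) {
    r <- gd_coupling_replicate(seed, beta_4x = 0, n_pairs = 12, n_loci = 30,
                               n_female = 3, n_male = 5)
    sig <- sig + sum(r$p < 0.05, na.rm = TRUE)
  }
  expect_lte(sig, 4L)  # 24 tests at the 5% level
})

test_that("missing parents in the distance matrix drop crosses with warning", {
  recs <- data.frame(hybrid_id = c("h1", "h2"), female = c("f1", "f2"),
                     male = c("m1", "m1"), ploidy = 2L, trait = "GY",
                     HB = c(1, 2), MP = NA_real_, CH = NA_real_)
  class(recs) <- c("heterosis_records", "data.frame")
  labs <- c("f1", "m1")
  dm <- matrix(c(0, .5, .5, 0), 2, 2, dimnames = list(labs, labs))
  plan <- cross_plan(data.frame(female = c("f1", "f2"), male = "m1",
                                hybrid_id = c("h1", "h2"), ploidy = 2L))
  expect_warning(tab <- gd_heterosis_table(dm, recs, plan), "dropped")
  expect_equal(tab$n, 1L)
})

test_that("yield correlation table reproduces constructed couplings", {
  hb_y <- stats::rnorm(8)
  mk <- function(trait, hb) data.frame(
    hybrid_id = paste0("h", 1:8), female = "f", male = "m", ploidy = 4L,
    trait = trait, HB = hb, MP = NA_real_, CH = NA_real_
  )
  recs <- rbind(mk("GY", hb_y), mk("PH", hb_y), mk("GW", -hb_y),
                mk("PL", stats::rnorm(8)))
  class(recs) <- c("heterosis_records", "data.frame")
  tab <- yield_trait_correlation_table(recs)
  expect_equal(tab$r[tab$trait == "PH"], 1, tolerance = 1e-12)
  expect_equal(tab$r[tab$trait == "GW"], -1, tolerance = 1e-12)
  expect_false("GY" %in% tab$trait)
  expect_error(yield_trait_correlation_table(recs, yield_trait = "XX"),
               "not present")
})

test_that("null association p-values are uniform (KS screen)", {
  set.seed(77)
  pvals <- replicate(400, {
    pearson_correlation(stats::rnorm(20), stats::rnorm(20))$p
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("optional BH adjustment re-stars from adjusted p-values", {
  set.seed(1)
  rep1 <- gd_coupling_replicate(2)
  # rebuild the full table with adjustment on a fresh replicate
  panel <- simulate_panel(panel_sim_config(n_pairs = 8, n_loci = 20,
                                           missing_rate = 0, seed = 2))
  plan <- make_diallel_plan(panel, 2, 3)
  dm <- nei_distance_matrix(panel)
  traits <- simulate_diallel_traits(panel, plan, trait_sim_config(seed = 3), dm)
  recs <- heterosis_records(traits, plan)
  tab <- suppressWarnings(gd_heterosis_table(dm, recs, plan, adjust = "BH"))
  expect_true("p_adjusted" %in% names(tab))
  expect_true(all(tab$p_adjusted >= tab$p - 1e-12, na.rm = TRUE))
})
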