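# Worked frequency pairs whose statistics are analytically forced:
#   (0.975, 0.025): He 0.04875, I 0.1169068, Botstein PIC 0.0475617, Ae 1.0512484
#   (0.5, 0.5):     He 0.5, I log(2), PIC 0.375
#   (0.65, 0.35):   He 0.455, I 0.6474466, PIC 0.3514875

test_that("diversity statistics reproduce hand-computed spectra", {
  cases <- list(
    list(p = c(0.975, 0.025),
         Ae = 1 / (0.975^2 + 0.025^2), He = 0.04875,
         I = -(0.975 * log(0.975) + 0.025 * log(0.025)),
         PIC = 0.04875 - 2 * 0.975^2 * 0.025^2),
    list(p = c(0.5, 0.5), Ae = 2, He = 0.5, I = log(2), PIC = 0.375),
    list(p = c(0.65, 0.35), Ae = 1 / 0.545, He = 0.455,
         I = -(0.65 * log(0.65) + 0.35 * log(0.35)), PIC = 0.3514875),
    list(p = 1, Ae = 1, He = 0, I = 0, PIC = 0)
  )
  for (cs in cases) {
    s <- allele_spectrum(cs$p)
    expect_equal(observed_allele_count(s), length(cs$p))
    expect_equal(effective_allele_count(s), cs$Ae, tolerance = 1e-12)
    expect_equal(expected_heterozygosity(s), cs$He, tolerance = 1e-12)
    expect_equal(shannon_index(s), cs$I, tolerance = 1e-12)
    expect_equal(pic_botstein(s), cs$PIC, tolerance = 1e-12)
    expect_equal(pic_simple(s), cs$He, tolerance = 1e-12)
  }
})

test_that("copy-mode frequencies follow the equal-dose convention", {
  # 39 lines fixed for A + 1 fixed for B: 78/80 vs 2/80 copies
  s <- allele_frequencies(fixed_line_panel(40, 1), "M1")
  expect_equal(unname(s$freqs), c(0.975, 0.025))
  expect_equal(s$n_scored, 40L)

  # a tetraploid showing {A,B} contributes 2 copies of each; with one
  # A-fixed tetraploid alongside: A 6/8, B 2/8
  pan <- genotype_panel(
    markers = data.frame(name = "M1"),
    individuals = data.frame(id = c("t1", "t2"), ploidy = c(4, 4)),
    calls = matrix(c("A/B", "A"), ncol = 1)
  )
  s <- allele_frequencies(pan, "M1", "copy")
  expect_equal(unname(s$freqs), c(0.75, 0.25))
  # presence mode: one count per distinct allele per individual
  sp <- allele_frequencies(pan, "M1", "presence")
  expect_equal(unname(sp$freqs), c(2 / 3, 1 / 3))

  # monomorphic locus
  mono <- allele_frequencies(fixed_line_panel(10, 0), "M1")
  expect_equal(unname(mono$freqs), 1)

  # all-missing locus errors with the locus name
  pan$calls[, 1] <- NA_character_
  expect_error(allele_frequencies(pan, "M1"), "M1")
})

test_that("modes coincide on panels of fixed lines and on uniform set sizes", {
  # every individual carries the same number of distinct alleles, so the two
  # weighting schemes are proportional
  s_copy <- allele_frequencies(fixed_line_panel(20, 7), "M1", "copy")
  s_pres <- allele_frequencies(fixed_line_panel(20, 7), "M1", "presence")
  expect_equal(s_copy$freqs, s_pres$freqs, tolerance = 1e-12)
})

test_that("spectrum invariants hold over random spectra", {
  set.seed(11)
  for (rep in 1:200) {
    s <- rand_spectrum()
    k <- observed_allele_count(s)
    he <- expected_heterozygosity(s)
    expect_gte(effective_allele_count(s), 1)
    expect_lte(effective_allele_count(s), k + 1e-12)
    expect_gte(he, 0)
    expect_lte(he, 1 - 1 / k + 1e-12)
    expect_gte(shannon_index(s), 0)
    expect_lte(shannon_index(s), log(k) + 1e-12)
    expect_lte(pic_botstein(s), he + 1e-12)
    expect_equal(pic_simple(s), he, tolerance = 1e-15)
    # brute-force double-sum oracle
    expect_equal(pic_botstein(s), pic_brute(unname(s$freqs)), tolerance = 1e-12)
  }
})

test_that("equifrequent spectra hit their closed forms", {
  for (k in 2:6) {
    s <- allele_spectrum(rep(1 / k, k))
    expect_equal(effective_allele_count(s), k, tolerance = 1e-12)
    expect_equal(expected_heterozygosity(s), 1 - 1 / k, tolerance = 1e-12)
    expect_equal(shannon_index(s), log(k), tolerance = 1e-12)
    # 1 - 1/k - (k-1)/k^3: the double sum over C(k,2) pairs of 2/k^4 each
    expect_equal(pic_botstein(s), 1 - 1 / k - (k - 1) / k^3, tolerance = 1e-12)
    expect_equal(pic_botstein(s), pic_brute(rep(1 / k, k)), tolerance = 1e-14)
  }
})

test_that("statistics are invariant to individual order", {
  set.seed(4)
  pan <- simulate_panel(panel_sim_config(n_pairs = 6, n_loci = 8, seed = 4))
  perm <- sample(nrow(pan$individuals))
  pan2 <- subset_panel(pan, perm)
  for (loc in c("L001", "L005")) {
    expect_equal(locus_diversity(pan, loc)[-1],
                 locus_diversity(pan2, loc)[-1])
  }
})

test_that("unbiased heterozygosity applies the 2n/(2n-1) correction", {
  s <- allele_frequencies(fixed_line_panel(40, 1), "M1")
  expect_equal(expected_heterozygosity(s, unbiased = TRUE),
               80 / 79 * 0.04875, tolerance = 1e-12)
})

test_that("diversity_table assembles rows, footer and total allele count", {
  pan <- toy_mixed_panel()
  div <- diversity_table(pan)
  expect_s3_class(div, "diversity_summary")
  expect_equal(nrow(div), 2L)
  summ <- attr(div, "summary")
  expect_equal(unname(summ["mean", ]), unname(colMeans(as.matrix(
    as.data.frame(div)[c("Na", "Ae_eff", "He", "I", "PIC_botstein", "PIC_simple")]
  ))), tolerance = 1e-9)
  expect_equal(attr(div, "total_alleles"), sum(div$Na))

  # single-locus panel: sample sd undefined, reported missing
  single <- genotype_panel(
    markers = data.frame(name = "M1"),
    individuals = data.frame(id = c("a", "b"), ploidy = c(2, 2)),
    calls = matrix(c("A", "B"), ncol = 1)
  )
  div1 <- diversity_table(single)
  expect_true(all(is.na(attr(div1, "summary")["st_dev", ])))
  expect_equal(unname(attr(div1, "summary")["mean", "He"]), 0.5)

  # all-missing locus dropped with a warning and absent from the footer
  pan2 <- toy_mixed_panel()
  pan2$calls[, "M2"] <- NA_character_
  expect_warning(div2 <- diversity_table(pan2), "all-missing")
  expect_equal(nrow(div2), 1L)
  expect_identical(attr(div2, "dropped"), "M2")
})

test_that("report rounding is half away from zero at 3 decimals", {
  expect_equal(round_half_away(0.04875, 3), 0.049)
  expect_equal(round_half_away(0.0485, 3), 0.049)   # banker's would give 0.048
  expect_equal(round_half_away(-0.0485, 3), -0.049)
  expect_equal(round_half_away(0.3514875, 3), 0.351)
  expect_equal(round_half_away(0.6931472, 3), 0.693)
})

test_that("diversity report files carry footer rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  div <- diversity_table(toy_mixed_panel())
  write_diversity_report(div, path)
  lines <- readLines(path)
  expect_equal(length(lines), 1 + 2 + 4)  # header + loci + footer
  expect_match(lines[4], "^Mean\t")
  expect_match(lines[5], "^St.Dev\t")
})
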