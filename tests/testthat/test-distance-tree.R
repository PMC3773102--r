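# Worked identity: one locus, A = (0.5, 0.5), B = (0.9, 0.1)
#   Jxy = 0.5, Jx = 0.5, Jy = 0.82 -> I = 0.5/sqrt(0.41), D = -ln I = 0.2473481
worked_I <- 0.5 / sqrt(0.41)

spec_list <- function(...) {
  ps <- list(...)
  out <- list()
  for (nm in names(ps)) out[[nm]] <- allele_spectrum(ps[[nm]], locus = nm)
  out
}

test_that("Nei identity matches hand computation and its boundary cases", {
  a <- spec_list(L1 = c(A = 0.5, B = 0.5))
  b <- spec_list(L1 = c(A = 0.9, B = 0.1))
  expect_equal(nei_identity(a, b), worked_I, tolerance = 1e-12)
  expect_equal(nei_identity(a, a), 1, tolerance = 1e-12)
  # fixed for different alleles
  expect_equal(nei_identity(spec_list(L1 = c(A = 1)), spec_list(L1 = c(B = 1))), 0)
  # symmetry
  expect_equal(nei_identity(a, b), nei_identity(b, a), tolerance = 1e-15)
  # no shared locus
  expect_error(nei_identity(a, spec_list(L2 = c(A = 1))), "no shared")
  # pairwise-complete locus exclusion: adding a locus absent from b changes nothing
  a2 <- c(a, spec_list(L9 = c(A = 1)))
  expect_equal(nei_identity(a2, b), nei_identity(a, b))
})

test_that("Nei distance matrix has zero diagonal, symmetry, and the worked value", {
  pan <- genotype_panel(
    markers = data.frame(name = c("M1", "M2")),
    individuals = data.frame(id = c("x", "y", "z"), ploidy = c(2, 2, 2)),
    calls = matrix(c("A/B", "A", "B",
                     "C", "C", "C"), nrow = 3)
  )
  dm <- nei_distance_matrix(pan)
  expect_equal(unname(diag(dm)), c(0, 0, 0))
  expect_equal(dm, t(dm))
  expect_true(all(dm >= 0))
  # x={.5,.5}, y={1,0}: Jxy=.5, Jx=.5, Jy=1 over locus M1; M2 identical adds
  # Jxy=Jx=Jy=1 -> means .75, .75, 1 -> I = .75/sqrt(.75) = sqrt(.75)
  expect_equal(dm["x", "y"], -log(sqrt(0.75)), tolerance = 1e-12)

  # individuals-as-units reproduce the worked pair via own-copy proportions
  pan2 <- genotype_panel(
    markers = data.frame(name = "M1"),
    individuals = data.frame(id = c("het", "hom"), ploidy = c(2, 2)),
    calls = matrix(c("A/B", "A"), ncol = 1)
  )
  dm2 <- nei_distance_matrix(pan2)
  # het = (.5,.5), hom = (1): Jxy=.5, Jx=.5, Jy=1 -> D = -log(1/sqrt(2))
  expect_equal(dm2["het", "hom"], log(sqrt(2)), tolerance = 1e-12)

  # disjoint allele sets at every locus -> capped
  pan3 <- genotype_panel(
    markers = data.frame(name = "M1"),
    individuals = data.frame(id = c("a", "b"), ploidy = c(2, 2)),
    calls = matrix(c("A", "B"), ncol = 1)
  )
  expect_warning(dm3 <- nei_distance_matrix(pan3), "capped")
  expect_equal(dm3["a", "b"], 10)
  expect_warning(dm3b <- nei_distance_matrix(pan3, cap = 5), "capped")
  expect_equal(dm3b["a", "b"], 5)
})

test_that("the unbiased (1978) identity exceeds the 1972 identity on groups", {
  set.seed(21)
  pan <- simulate_panel(panel_sim_config(n_pairs = 8, n_loci = 20,
                                         missing_rate = 0, seed = 21))
  d72 <- nei_distance_matrix(pan, unit = "group", variant = "nei1972")
  d78 <- nei_distance_matrix(pan, unit = "group", variant = "nei1978")
  expect_equal(rownames(d72), sort(c("indica", "japonica")))
  expect_lte(d78["indica", "japonica"], d72["indica", "japonica"])
})

test_that("three-taxon NJ solves the three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  cd <- cophenetic_distances(tr)
  expect_equal(cd["A", "B"], 3, tolerance = 1e-12)
  expect_equal(cd["A", "C"], 4, tolerance = 1e-12)
  # l_A = (3 + 4 - 5)/2 = 1
  la <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "A")]
  expect_equal(la, 1, tolerance = 1e-12)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
  dd <- d; dd[1, 2] <- 99
  expect_error(neighbor_joining(dd), "symmetric")
  dd <- d; dd[1, 2] <- dd[2, 1] <- -1
  expect_error(neighbor_joining(dd), "negative")
})

test_that("NJ recovers additive matrices exactly (topology and lengths)", {
  # classic 4-taxon additive matrix from a known tree
  d <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 8,
                9, 10, 8, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_equal(cophenetic_distances(tr)[LETTERS[1:4], LETTERS[1:4]], d,
               tolerance = 1e-12)
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    ref <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
    dm <- stats::cophenetic(ref)
    rec <- neighbor_joining(dm)
    cd <- cophenetic_distances(rec)
    expect_equal(cd[rownames(dm), colnames(dm)], dm, tolerance = 1e-9)
  }
})

test_that("NJ agrees with an independent implementation on random matrices", {
  set.seed(5)
  for (rep in 1:5) {
    n <- 7
    # noisy (non-additive) but tie-free symmetric matrix
    m <- matrix(stats::runif(n * n, 0.5, 2), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(letters[1:n], letters[1:n])
    ours <- neighbor_joining(m)
    theirs <- ape::nj(m)
    expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(theirs)), 0,
                 ignore_attr = TRUE)
    cd_o <- cophenetic_distances(ours)
    cd_t <- stats::cophenetic(theirs)[rownames(cd_o), colnames(cd_o)]
    expect_equal(cd_o, cd_t, tolerance = 1e-8)
  }
})

test_that("NJ tie-break is deterministic and label-permutation equivariant", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  dimnames(d) <- list(c("b", "a", "d", "c"), c("b", "a", "d", "c"))
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_identical(to_newick(t1), to_newick(t2))
  # every pairwise path length reproduces the input distance 1: tip branches
  # 0.5, internal branch 0
  cd <- cophenetic_distances(t1)
  expect_true(all(abs(cd[upper.tri(cd)] - 1) < 1e-12))
  tip_edges <- t1$edge[, 2] <= length(t1$tip.label)
  expect_true(all(abs(t1$edge.length[tip_edges] - 0.5) < 1e-12))
  expect_true(all(abs(t1$edge.length[!tip_edges]) < 1e-12))
  # lexicographically first pair (a, b) forms a cherry
  cherry <- t1$edge[t1$edge[, 2] %in% match(c("a", "b"), t1$tip.label), 1]
  expect_equal(cherry[1], cherry[2])

  set.seed(13)
  n <- 8
  m <- matrix(stats::runif(n * n, 0.5, 2), n, n); m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(letters[1:n], letters[1:n])
  perm <- sample(n)
  t_orig <- neighbor_joining(m)
  t_perm <- neighbor_joining(m[perm, perm])
  expect_equal(cophenetic_distances(t_orig), cophenetic_distances(t_perm),
               tolerance = 1e-12)
})

test_that("negative branch-length estimates are clamped to zero", {
  # strongly non-additive matrix known to produce a negative NJ estimate
  d <- matrix(c(0, 1, 4, 4,
                1, 0, 4, 4.8,
                4, 4, 0, 1,
                4, 4.8, 1, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("Newick serialization round-trips and quotes awkward labels", {
  set.seed(31)
  ref <- ape::rtree(8, br = function(k) stats::runif(k, 0.1, 1))
  nwk <- to_newick(ref, precision = 10)
  back <- ape::read.tree(text = nwk)
  expect_equal(stats::cophenetic(back)[ref$tip.label, ref$tip.label],
               stats::cophenetic(ref)[ref$tip.label, ref$tip.label],
               tolerance = 1e-8)
  expect_match(nwk, ";$")

  star <- ape::read.tree(text = "(A:1,B:2,C:3);")
  star$tip.label <- c("Taichung 65-2x", "B", "C")
  q <- to_newick(star)
  expect_match(q, "'Taichung 65-2x':1.000000", fixed = TRUE)
})

test_that("simulated subspecies panels split into two subtrees", {
  hits <- 0L
  for (seed in 1:10) {
    pan <- simulate_panel(panel_sim_config(n_pairs = 8, n_loci = 25,
                                           missing_rate = 0, seed = seed))
    dm <- suppressWarnings(nei_distance_matrix(pan))
    tr <- neighbor_joining(dm)
    grp <- pan$individuals$id[pan$individuals$subgroup == "indica"]
    hits <- hits + is_monophyletic_split(tr, grp)
  }
  expect_gte(hits, 9L)
})

test_that("between-subgroup distance grows with the divergence parameter", {
  between <- function(seed, f) {
    pan <- simulate_panel(panel_sim_config(n_pairs = 6, n_loci = 30,
                                           divergence = f, missing_rate = 0,
                                           seed = seed))
    dm <- suppressWarnings(nei_distance_matrix(pan))
    w <- outer(pan$individuals$subgroup, pan$individuals$subgroup, "!=")
    mean(dm[w])
  }
  seeds <- 1:25
  expect_gt(mean(vapply(seeds, between, numeric(1), f = 0.4)),
            mean(vapply(seeds, between, numeric(1), f = 0.05)))
})

test_that("distance matrices round-trip through delimited and PHYLIP files", {
  set.seed(8)
  pan <- simulate_panel(panel_sim_config(n_pairs = 4, n_loci = 10,
                                         missing_rate = 0, seed = 8))
  # tiny panels have fully disjoint pairs whose distance is capped
  dm <- suppressWarnings(nei_distance_matrix(pan))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(dm, path, "delim")
  back <- read_distance_matrix(path)
  expect_equal(back, unclass(dm)[rownames(back), colnames(back)],
               tolerance = 1e-6, ignore_attr = TRUE)
  phy <- withr::local_tempfile(fileext = ".phy")
  write_distance_matrix(dm, phy, "phylip")
  lines <- readLines(phy)
  expect_equal(as.integer(trimws(lines[1])), nrow(dm))
  expect_equal(length(lines), nrow(dm) + 1L)
})
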