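#' Configuration for the paired 2x/4x panel simulator
#'
#' Defaults emulate a two-subspecies (indica/japonica) rice panel of 40
#' diploid cultivars and their colchicine-derived autotetraploid lines,
#' genotyped at 99 SSR loci carrying 2-5 alleles each (allele-count
#' probabilities follow the empirical spectrum of such panels).
#'
#' @param n_pairs number of 2x/4x cultivar pairs (default 40).
#' @param n_loci number of SSR loci (default 99).
#' @param allele_count_probs probabilities of 2..5 alleles per locus.
#' @param n_subgroups number of subspecies groups (default 2).
#' @param divergence between-subgroup divergence F in `[0, 1)`: subgroup
#'   frequencies are Dirichlet draws around the ancestral spectrum with
#'   concentration `(1-F)/F` (a Balding-Nichols-style model); larger F means
#'   stronger indica/japonica differentiation. Default 0.35, a strongly
#'   structured inter-subspecific panel.
#' @param mu_tetra per-locus probability that a tetraploid line gains or loses
#'   an allele relative to its diploid parent (default 0.08, so a minority of
#'   pairs stay genotypically identical).
#' @param missing_rate per-call missing probability (default 0.01).
#' @param residual_het per-locus probability that a nominally inbred diploid
#'   cultivar retains two alleles (default 0: fully fixed lines).
#' @param seed integer RNG seed (optional).
#' @return a list of class `panel_sim_config`.
#' @export
panel_sim_config <- function(n_pairs = 40, n_loci = 99,
                             allele_count_probs = c(`2` = 0.42, `3` = 0.36,
                                                    `4` = 0.14, `5` = 0.08),
                             n_subgroups = 2, divergence = 0.35,
                             mu_tetra = 0.08, missing_rate = 0.01,
                             residual_het = 0, seed = NULL) {
  if (abs(sum(allele_count_probs) - 1) > 1e-9) {
    stopf("allele_count_probs must sum to 1")
  }
  rates <- c(divergence, mu_tetra, missing_rate, residual_het)
  if (any(rates < 0) || any(rates > 1) || divergence >= 1) {
    stopf("divergence must be in [0,1) and rates in [0,1]")
  }
  if (n_pairs < 1 || n_loci < 1 || n_subgroups < 1) {
    stopf("n_pairs, n_loci and n_subgroups must be positive")
  }
  structure(list(
    n_pairs = as.integer(n_pairs), n_loci = as.integer(n_loci),
    allele_count_probs = allele_count_probs,
    n_subgroups = as.integer(n_subgroups), divergence = divergence,
    mu_tetra = mu_tetra, missing_rate = missing_rate,
    residual_het = residual_het, seed = seed
  ), class = "panel_sim_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-6))
  g <- pmax(g, 1e-12)
  g / sum(g)
}

#' Simulate a paired diploid/autotetraploid SSR panel
#'
#' Per locus: an allele count is drawn from the configured spectrum and an
#' ancestral frequency vector from a flat Dirichlet; each subgroup gets its
#' own frequencies by a Dirichlet draw with concentration `(1-F)/F` around the
#' ancestral vector. Diploid cultivars are inbred lines fixed for one allele
#' sampled from their subgroup's frequencies (optionally retaining a second
#' allele at the `residual_het` rate); each tetraploid line copies its diploid
#' parent's alleles, then with probability `mu_tetra` gains or loses one
#' allele within the locus allele pool. Locus draws are rejected (up to 50
#' times) until every allele is observed among the diploids, so the realized
#' allele-count spectrum matches the configured one. Deterministic given the
#' seed.
#'
#' @param cfg a [panel_sim_config()].
#' @return a [genotype_panel()] of `2 * n_pairs` individuals with `pair_id`
#'   and `subgroup` metadata.
#' @export
simulate_panel <- function(cfg = panel_sim_config()) {
  stopifnot(inherits(cfg, "panel_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  np <- cfg$n_pairs; nl <- cfg$n_loci
  sg_names <- if (cfg$n_subgroups == 2) c("indica", "japonica") else
    paste0("G", seq_len(cfg$n_subgroups))
  pair_sg <- sg_names[rep_len(seq_len(cfg$n_subgroups), np)]
  pair_ids <- sprintf("P%02d", seq_len(np))
  ids_2x <- paste0(pair_ids, "_2x")
  ids_4x <- paste0(pair_ids, "_4x")
  calls_2x <- matrix(NA_character_, np, nl)
  calls_4x <- matrix(NA_character_, np, nl)
  ks <- as.integer(sample(names(cfg$allele_count_probs), nl, replace = TRUE,
                          prob = cfg$allele_count_probs))
  F <- cfg$divergence
  conc <- if (F > 0) (1 - F) / F else Inf
  for (j in seq_len(nl)) {
    k <- ks[j]
    alleles <- LETTERS[seq_len(k)]
    for (try in seq_len(50L)) {
      anc <- rdirichlet1(rep(1, k))
      freqs <- lapply(seq_len(cfg$n_subgroups), function(s) {
        if (is.finite(conc)) rdirichlet1(anc * conc) else anc
      })
      names(freqs) <- sg_names
      sets <- vector("list", np)
      for (i in seq_len(np)) {
        p <- freqs[[pair_sg[i]]]
        a <- sample_safe(alleles, 1, prob = p)
        if (cfg$residual_het > 0 && k > 1 &&
            stats::runif(1) < cfg$residual_het) {
          a <- c(a, sample_safe(setdiff(alleles, a), 1))
        }
        sets[[i]] <- a
      }
      if (length(unique(unlist(sets))) == k) break
      if (try == 50L) {
        # force the unseen alleles onto random cultivars
        missing_al <- setdiff(alleles, unique(unlist(sets)))
        for (a in missing_al) sets[[sample.int(np, 1)]] <- a
      }
    }
    for (i in seq_len(np)) {
      set2 <- sets[[i]]
      calls_2x[i, j] <- paste(sort(set2), collapse = "/")
      set4 <- set2
      if (stats::runif(1) < cfg$mu_tetra) {
        can_add <- setdiff(alleles, set4)
        drop_it <- length(set4) > 1 &&
          (length(can_add) == 0 || stats::runif(1) < 0.5)
        if (drop_it) {
          set4 <- setdiff(set4, sample_safe(set4, 1))
        } else if (length(can_add)) {
          set4 <- c(set4, sample_safe(can_add, 1))
        }
      }
      calls_4x[i, j] <- paste(sort(set4), collapse = "/")
    }
  }
  calls <- rbind(calls_2x, calls_4x)
  if (cfg$missing_rate > 0) {
    calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_character_
  }
  genotype_panel(
    markers = data.frame(
      name = sprintf("L%03d", seq_len(nl)),
      chromosome = rep_len(1:12, nl), stringsAsFactors = FALSE
    ),
    individuals = data.frame(
      id = c(ids_2x, ids_4x),
      ploidy = rep(c(2L, 4L), each = np),
      subgroup = rep(pair_sg, 2),
      pair_id = rep(pair_ids, 2),
      stringsAsFactors = FALSE
    ),
    calls = calls
  )
}

#' Default trait panel for the diallel trait simulator
#'
#' Eleven agronomic traits typical of rice hybrid trials (plant height,
#' panicle length, effective panicle number, grain length/width and their
#' ratio, grains per panicle, grain density, 1000-grain weight, grain yield,
#' seed set ratio) with diploid parent-mean ranges and tetraploid/diploid
#' multipliers drawn from published group means of a 40-pair panel.
#'
#' @return data frame with columns `name`, `lo_2x`, `hi_2x`, `ploidy_mult`,
#'   `dominance_pct`, `beta_2x`, `beta_4x`, `noise_cv`.
#' @export
default_trait_panel <- function() {
  df <- data.frame(
    name = c("PH", "PL", "EPN", "GL", "GW", "L/W", "GPP", "GD", "GWT", "GY", "SS"),
    lo_2x = c(66.67, 14.59, 4.33, 6.15, 2.00, 1.74, 82.67, 37.40, 19.60, 0.63, 25.68),
    hi_2x = c(152.00, 35.87, 11.00, 11.97, 3.53, 5.07, 229.00, 92.90, 43.03, 5.74, 96.76),
    ploidy_mult = c(0.91, 1.13, 0.72, 1.23, 1.12, 1.08, 0.70, 0.62, 1.38, 0.50, 0.42),
    dominance_pct = c(5, 5, 5, 2, 2, 2, 5, 5, 5, 10, 5),
    beta_2x = 0,
    beta_4x = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 40, 0),
    noise_cv = 0.05,
    stringsAsFactors = FALSE
  )
  df
}

#' Configuration for the diallel trait simulator
#'
#' @param traits data frame in the layout of [default_trait_panel()]:
#'   per-trait diploid parent-mean range (`lo_2x`, `hi_2x`), tetraploid mean
#'   multiplier, dominance (percent of mid-parent), genetic-distance coupling
#'   `beta_2x`/`beta_4x` (heterosis percent per unit Nei D), and replicate
#'   noise as a CV fraction.
#' @param n_replicates replicates per entity (default 3, an RCBD-style trial).
#' @param seed integer RNG seed (optional).
#' @return a list of class `trait_sim_config`.
#' @export
trait_sim_config <- function(traits = default_trait_panel(),
                             n_replicates = 3, seed = NULL) {
  if (any(traits$noise_cv < 0)) stopf("noise_cv must be >= 0")
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  structure(list(traits = traits, n_replicates = as.integer(n_replicates),
                 seed = seed), class = "trait_sim_config")
}

#' Simulate a diallel trait table
#'
#' Parent trait means are uniform draws from the configured diploid range
#' (times the ploidy multiplier for tetraploids). Each F1 mean is
#' `MP * (1 + (dominance + beta * D(parents)) / 100)` with MP the mid-parent
#' mean and D the parents' Nei distance, so the configured dominance and
#' coupling are exactly the expected mid-parent heterosis percentages.
#' Replicates add Gaussian noise with sd `noise_cv * |mean|`. Deterministic
#' given the seed.
#'
#' @param panel a [genotype_panel()] (supplies ploidy of each parent).
#' @param plan a [cross_plan()] whose parents are panel individuals.
#' @param cfg a [trait_sim_config()].
#' @param dm labeled distance matrix covering all parents (required whenever
#'   any `beta` is nonzero).
#' @return a [trait_table()] covering every parent and hybrid in the plan.
#' @export
simulate_diallel_traits <- function(panel, plan, cfg = trait_sim_config(),
                                    dm = NULL) {
  stopifnot(inherits(cfg, "trait_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cr <- plan$crosses
  parents <- unique(c(cr$female, cr$male))
  idx <- match(parents, panel$individuals$id)
  if (anyNA(idx)) stopf("cross parent '%s' not in panel", parents[is.na(idx)][1L])
  ploidy <- stats::setNames(panel$individuals$ploidy[idx], parents)
  tr <- cfg$traits
  needs_dm <- any(tr$beta_2x != 0 | tr$beta_4x != 0)
  if (needs_dm && is.null(dm)) stopf("dm is required when any beta is nonzero")
  rows <- list()
  add <- function(entity, trait, mu) {
    reps <- mu + stats::rnorm(cfg$n_replicates,
                              sd = tr$noise_cv[tr$name == trait] * abs(mu))
    rows[[length(rows) + 1L]] <<- data.frame(
      entity = entity, trait = trait, replicate = seq_len(cfg$n_replicates),
      value = reps, stringsAsFactors = FALSE
    )
  }
  pmean <- matrix(NA_real_, length(parents), nrow(tr),
                  dimnames = list(parents, tr$name))
  for (p in parents) {
    for (k in seq_len(nrow(tr))) {
      mu <- stats::runif(1, tr$lo_2x[k], tr$hi_2x[k])
      if (ploidy[[p]] == 4L) mu <- mu * tr$ploidy_mult[k]
      pmean[p, k] <- mu
      add(p, tr$name[k], mu)
    }
  }
  for (i in seq_len(nrow(cr))) {
    d <- if (!is.null(dm)) dm[cr$female[i], cr$male[i]] else 0
    beta_col <- if (cr$ploidy[i] == 4L) "beta_4x" else "beta_2x"
    for (k in seq_len(nrow(tr))) {
      mp <- (pmean[cr$female[i], k] + pmean[cr$male[i], k]) / 2
      mu <- mp * (1 + (tr$dominance_pct[k] + tr[[beta_col]][k] * d) / 100)
      add(cr$hybrid_id[i], tr$name[k], mu)
    }
  }
  trait_table(do.call(rbind, rows))
}

#' Build an incomplete-diallel cross plan from a paired panel
#'
#' Selects `n_female` cultivar pairs from one subgroup and `n_male` from the
#' other (in pair order), and creates every female x male cross at both ploidy
#' levels, linking each tetraploid hybrid to its diploid counterpart.
#'
#' @param panel a [genotype_panel()] with `subgroup` and `pair_id` metadata.
#' @param n_female,n_male number of female / male cultivar pairs.
#' @param female_subgroup subgroup supplying the females (default the first
#'   subgroup label in sort order).
#' @return a [cross_plan()].
#' @export
make_diallel_plan <- function(panel, n_female, n_male,
                              female_subgroup = NULL) {
  ind <- panel$individuals
  sgs <- sort(unique(stats::na.omit(ind$subgroup)))
  if (length(sgs) < 2) stopf("panel needs >= 2 subgroups for an inter-subspecific diallel")
  fsg <- female_subgroup %||% sgs[1L]
  msg <- setdiff(sgs, fsg)[1L]
  complete_pairs <- function(sg) {
    pid <- unique(ind$pair_id[!is.na(ind$pair_id) & ind$subgroup == sg])
    pid[vapply(pid, function(p)
      all(c(2L, 4L) %in% ind$ploidy[!is.na(ind$pair_id) & ind$pair_id == p]),
      logical(1))]
  }
  fp <- complete_pairs(fsg); mp <- complete_pairs(msg)
  if (length(fp) < n_female || length(mp) < n_male) {
    stopf("not enough complete 2x/4x pairs (have %d female, %d male)",
          length(fp), length(mp))
  }
  fp <- fp[seq_len(n_female)]; mp <- mp[seq_len(n_male)]
  id_of <- function(pair, pl) ind$id[!is.na(ind$pair_id) & ind$pair_id == pair &
                                       ind$ploidy == pl]
  rows <- list()
  for (f in fp) {
    for (m in mp) {
      h2 <- paste0(f, "x", m, "_2x")
      rows[[length(rows) + 1L]] <- data.frame(
        female = id_of(f, 2L), male = id_of(m, 2L), hybrid_id = h2,
        ploidy = 2L, counterpart_2x_hybrid = NA_character_,
        stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- data.frame(
        female = id_of(f, 4L), male = id_of(m, 4L),
        hybrid_id = paste0(f, "x", m, "_4x"),
        ploidy = 4L, counterpart_2x_hybrid = h2, stringsAsFactors = FALSE
      )
    }
  }
  cross_plan(do.call(rbind, rows))
}

#' Small end-to-end simulated fixture
#'
#' A fast panel (12 cultivar pairs, 20 loci) with a 2 x 3 inter-subspecific
#' diallel at both ploidy levels and a matching trait table — enough to
#' exercise every pipeline stage in a few seconds. Byte-identical for a given
#' seed.
#'
#' @param seed integer RNG seed.
#' @return list with `panel`, `plan`, `traits`, and the parents' Nei distance
#'   matrix `dm`.
#' @export
end_to_end_fixture <- function(seed = 1) {
  panel <- simulate_panel(panel_sim_config(
    n_pairs = 12, n_loci = 20, missing_rate = 0, seed = seed
  ))
  plan <- make_diallel_plan(panel, n_female = 2, n_male = 3)
  dm <- nei_distance_matrix(panel)
  traits <- simulate_diallel_traits(panel, plan,
                                    trait_sim_config(seed = seed + 1L), dm)
  list(panel = panel, plan = plan, traits = traits, dm = dm)
}

#' Genetic-distance coupling recovery study (one replicate)
#'
#' Simulates a paired panel plus an inter-subspecific diallel in which yield
#' heterosis is coupled to parental Nei distance in the tetraploids only
#' (`beta_4x` percent heterosis per unit D, `beta_2x = 0`), then runs the
#' association stage and returns the genetic-distance / yield-heterobeltiosis
#' correlation for each ploidy group. Parent yield means are drawn from a
#' narrow elite band (2.5-3.5 t) so the coupling, not parent asymmetry,
#' dominates the heterobeltiosis variance — the configuration a parameter
#' recovery study calls for.
#'
#' @param seed integer RNG seed.
#' @param beta_4x coupling in the tetraploid crosses (default 60 %/D).
#' @param beta_2x coupling in the diploid crosses (default 0).
#' @param n_pairs,n_loci panel size (defaults 16 pairs, 48 loci).
#' @param n_female,n_male diallel dimensions (defaults 4 x 7, a 28-cross
#'   incomplete diallel per ploidy).
#' @return data frame with one row per ploidy: `ploidy`, `n`, `r`, `p`.
#' @export
gd_coupling_replicate <- function(seed, beta_4x = 60, beta_2x = 0,
                                  n_pairs = 16, n_loci = 48,
                                  n_female = 4, n_male = 7) {
  panel <- simulate_panel(panel_sim_config(
    n_pairs = n_pairs, n_loci = n_loci, missing_rate = 0, seed = seed
  ))
  plan <- make_diallel_plan(panel, n_female, n_male)
  dm <- nei_distance_matrix(panel)
  tp <- default_trait_panel()
  tp$lo_2x[tp$name == "GY"] <- 2.5
  tp$hi_2x[tp$name == "GY"] <- 3.5
  tp$beta_4x[tp$name == "GY"] <- beta_4x
  tp$beta_2x[tp$name == "GY"] <- beta_2x
  # large offset keeps the trait RNG stream disjoint from the panel streams
  # of neighbouring replicate seeds
  traits <- simulate_diallel_traits(
    panel, plan, trait_sim_config(traits = tp, seed = seed + 500000L), dm
  )
  recs <- heterosis_records(traits, plan)
  tab <- gd_heterosis_table(dm, recs, plan)
  out <- tab[tab$trait == "GY", c("ploidy", "n", "r", "p")]
  rownames(out) <- NULL
  out
}
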