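#' Seed set ratio
#'
#' Percentage of filled grains: `100 * filled / total`.
#' @param filled count of filled grains (0 <= filled <= total).
#' @param total total grain count (> 0).
#' @return percent.
#' @export
seed_set_ratio <- function(filled, total) {
  if (any(total <= 0)) stopf("total grain count must be positive")
  if (any(filled < 0 | filled > total)) stopf("filled must lie in [0, total]")
  100 * filled / total
}

#' Heterobeltiosis: superiority of a hybrid over its better parent
#'
#' `100 * (F1 - BP) / BP` where the better parent BP is the parent with the
#' larger mean (or the smaller mean when `larger_is_better = FALSE`, in which
#' case the sign is flipped so positive always means superiority in the
#' preferred direction).
#'
#' @param f1,p1,p2 trait means of the hybrid and the two parents.
#' @param larger_is_better direction flag for the trait (default `TRUE`).
#' @return percent, or `NA` with a warning when the better-parent mean is 0.
#' @export
heterobeltiosis <- function(f1, p1, p2, larger_is_better = TRUE) {
  bp <- if (larger_is_better) pmax(p1, p2) else pmin(p1, p2)
  out <- ifelse(bp == 0, NA_real_,
                if (larger_is_better) 100 * (f1 - bp) / bp
                else 100 * (bp - f1) / bp)
  if (anyNA(out) && any(bp == 0, na.rm = TRUE)) {
    warnf("better-parent mean is 0; heterobeltiosis undefined")
  }
  out
}

#' Mid-parent heterosis
#'
#' `100 * (F1 - MP) / MP` with `MP = (P1 + P2)/2`. Companion statistic to
#' [heterobeltiosis()]; always at least the heterobeltiosis when larger is
#' better.
#'
#' @inheritParams heterobeltiosis
#' @return percent, or `NA` with a warning when the mid-parent mean is 0.
#' @export
midparent_heterosis <- function(f1, p1, p2) {
  mp <- (p1 + p2) / 2
  out <- ifelse(mp == 0, NA_real_, 100 * (f1 - mp) / mp)
  if (anyNA(out) && any(mp == 0, na.rm = TRUE)) {
    warnf("mid-parent mean is 0; mid-parent heterosis undefined")
  }
  out
}

#' Competitive heterosis of a tetraploid hybrid over its diploid counterpart
#'
#' `100 * (F1_4x - F1_2x) / F1_2x`, comparing a tetraploid hybrid with the
#' diploid hybrid made from the same cultivar pair.
#'
#' @param f1_4x,f1_2x trait means of the tetraploid hybrid and its diploid
#'   counterpart.
#' @return percent, or `NA` with a warning when the diploid hybrid mean is 0.
#' @export
competitive_heterosis <- function(f1_4x, f1_2x) {
  out <- ifelse(f1_2x == 0, NA_real_, 100 * (f1_4x - f1_2x) / f1_2x)
  if (anyNA(out) && any(f1_2x == 0, na.rm = TRUE)) {
    warnf("diploid counterpart mean is 0; competitive heterosis undefined")
  }
  out
}

entity_means <- function(traits) {
  ag <- stats::aggregate(value ~ entity + trait, data = traits$data, FUN = mean)
  ag
}

lookup_mean <- function(means, entity, trait) {
  v <- means$value[means$entity == entity & means$trait == trait]
  if (length(v) != 1L) NA_real_ else v
}

#' Per-cross, per-trait heterosis records
#'
#' Computes heterobeltiosis (HB), mid-parent heterosis (MP) and — for
#' tetraploid crosses with a declared counterpart — competitive heterosis (CH)
#' for every cross in the plan and every trait measured on the hybrid, all on
#' entity means (replicate means). Optionally attaches a per-cross Welch-t
#' significance flag of the hybrid replicates against the better parent's
#' replicates.
#'
#' @param traits a [trait_table()] covering parents and hybrids.
#' @param plan a [cross_plan()].
#' @param significance add the Welch-t flag (default `FALSE`).
#' @param alpha significance level for the flag.
#' @return data frame of class `heterosis_records` with columns `hybrid_id`,
#'   `female`, `male`, `ploidy`, `trait`, `HB`, `MP`, `CH`, and optionally
#'   `significant`.
#' @export
heterosis_records <- function(traits, plan, significance = FALSE, alpha = 0.05) {
  means <- entity_means(traits)
  cr <- plan$crosses
  out <- list()
  for (i in seq_len(nrow(cr))) {
    for (tr in names(traits$directions)) {
      f1 <- lookup_mean(means, cr$hybrid_id[i], tr)
      if (is.na(f1)) next
      p1 <- lookup_mean(means, cr$female[i], tr)
      p2 <- lookup_mean(means, cr$male[i], tr)
      lib <- traits$directions[[tr]]
      hb <- mp <- ch <- NA_real_
      if (!is.na(p1) && !is.na(p2)) {
        hb <- suppressWarnings(heterobeltiosis(f1, p1, p2, lib))
        mp <- suppressWarnings(midparent_heterosis(f1, p1, p2))
      }
      if (!is.na(cr$counterpart_2x_hybrid[i])) {
        f1_2x <- lookup_mean(means, cr$counterpart_2x_hybrid[i], tr)
        if (!is.na(f1_2x)) ch <- suppressWarnings(competitive_heterosis(f1, f1_2x))
      }
      rec <- data.frame(
        hybrid_id = cr$hybrid_id[i], female = cr$female[i], male = cr$male[i],
        ploidy = cr$ploidy[i], trait = tr, HB = hb, MP = mp, CH = ch,
        stringsAsFactors = FALSE
      )
      if (significance && !is.na(p1) && !is.na(p2)) {
        bp <- if (xor(p1 >= p2, !lib)) cr$female[i] else cr$male[i]
        rec$significant <- per_cross_significance(
          traits$data$value[traits$data$entity == cr$hybrid_id[i] &
                              traits$data$trait == tr],
          traits$data$value[traits$data$entity == bp & traits$data$trait == tr],
          alpha = alpha
        )
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stopf("no (cross, trait) combination could be evaluated")
  class(res) <- c("heterosis_records", "data.frame")
  res
}

#' Welch-t significance flag for one cross
#'
#' Two-sample Welch t-test (two-sided) of the hybrid's replicates against the
#' better parent's replicates.
#'
#' @param f1_reps,bp_reps replicate vectors (each of length >= 2).
#' @param alpha significance level (default 0.05).
#' @return logical, or `NA` when replicates are insufficient or degenerate.
#' @export
per_cross_significance <- function(f1_reps, bp_reps, alpha = 0.05) {
  if (length(f1_reps) < 2L || length(bp_reps) < 2L) return(NA)
  if (stats::sd(f1_reps) == 0 && stats::sd(bp_reps) == 0) {
    # constant data: identical sets are trivially non-significant, otherwise
    # the Welch statistic is undefined
    return(if (f1_reps[1L] == bp_reps[1L]) FALSE else NA)
  }
  tt <- tryCatch(stats::t.test(f1_reps, bp_reps), error = function(e) NULL)
  if (is.null(tt)) return(NA)
  tt$p.value < alpha
}

#' Per-trait heterosis summary (min / max / mean, +/− counts)
#'
#' Summarizes [heterosis_records()] per trait, separately for each ploidy
#' group (heterobeltiosis) and for competitive heterosis: minimum, maximum,
#' mean, and the counts of crosses with positive, negative and zero effect.
#'
#' @param records a `heterosis_records` data frame.
#' @param statistic `"HB"`, `"MP"` or `"CH"`.
#' @param zero_tol values within `zero_tol` of 0 count as zero effect.
#' @return data frame with one row per (trait, group).
#' @export
heterosis_summary_table <- function(records, statistic = c("HB", "MP", "CH"),
                                    zero_tol = 0) {
  statistic <- match.arg(statistic)
  recs <- as.data.frame(records)
  if (statistic == "CH") {
    recs <- recs[!is.na(recs$CH), , drop = FALSE]
    recs$group <- "4x_vs_2x"
  } else {
    recs <- recs[!is.na(recs[[statistic]]), , drop = FALSE]
    recs$group <- paste0(recs$ploidy, "x")
  }
  if (!nrow(recs)) stopf("no non-missing %s values to summarize", statistic)
  sp <- split(recs, list(recs$trait, recs$group), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    v <- g[[statistic]]
    data.frame(
      trait = g$trait[1L], group = g$group[1L], statistic = statistic,
      n = length(v), min = min(v), max = max(v), mean = mean(v),
      n_positive = sum(v > zero_tol), n_negative = sum(v < -zero_tol),
      n_zero = sum(abs(v) <= zero_tol),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(out$group, out$trait), ]
}

#' Trait variation summary with paired comparison across ploidy levels
#'
#' For each trait and ploidy group: mean, range and coefficient of variation
#' (CV % = 100 * sample sd / mean) over per-cultivar means, plus a paired
#' two-sided t-test across `pair_id`-matched diploid/tetraploid cultivars
#' (df = n_pairs - 1). Degenerate cases (fewer than 2 complete pairs, or zero
#' variance of the paired differences) report missing t/p with a warning.
#'
#' @param traits a [trait_table()] of parent measurements.
#' @param panel a [genotype_panel()] supplying `pair_id` metadata, or a data
#'   frame with columns `id`, `ploidy`, `pair_id`.
#' @return data frame with one row per trait: per-group mean/min/max/CV and
#'   `t`, `p`, `n_pairs`.
#' @export
trait_variation_table <- function(traits, panel) {
  ind <- if (inherits(panel, "genotype_panel")) panel$individuals else
    as.data.frame(panel)
  means <- entity_means(traits)
  means$ploidy <- ind$ploidy[match(means$entity, ind$id)]
  means$pair_id <- ind$pair_id[match(means$entity, ind$id)]
  out <- list()
  for (tr in names(traits$directions)) {
    m <- means[means$trait == tr & !is.na(means$ploidy), , drop = FALSE]
    g2 <- m$value[m$ploidy == 2L]; g4 <- m$value[m$ploidy == 4L]
    row <- data.frame(trait = tr, stringsAsFactors = FALSE)
    for (g in list(c("2x", "g2"), c("4x", "g4"))) {
      v <- get(g[2L])
      row[[paste0("mean_", g[1L])]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0("min_", g[1L])]] <- if (length(v)) min(v) else NA_real_
      row[[paste0("max_", g[1L])]] <- if (length(v)) max(v) else NA_real_
      row[[paste0("cv_", g[1L])]] <-
        if (length(v) > 1 && mean(v) != 0) 100 * stats::sd(v) / mean(v) else NA_real_
    }
    pm <- m[!is.na(m$pair_id), , drop = FALSE]
    wide <- merge(pm[pm$ploidy == 2L, c("pair_id", "value")],
                  pm[pm$ploidy == 4L, c("pair_id", "value")],
                  by = "pair_id", suffixes = c("_2x", "_4x"))
    row$n_pairs <- nrow(wide)
    row$t <- row$p <- NA_real_
    if (nrow(wide) >= 2L) {
      diffs <- wide$value_4x - wide$value_2x
      if (stats::sd(diffs) == 0) {
        if (all(diffs == 0)) {
          row$t <- 0; row$p <- 1
        } else {
          warnf("trait '%s': paired differences have zero variance; t undefined", tr)
        }
      } else {
        tt <- stats::t.test(wide$value_4x, wide$value_2x, paired = TRUE)
        row$t <- unname(tt$statistic); row$p <- tt$p.value
      }
    }
    out[[tr]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a heterosis summary report
#'
#' Delimited table in the classical layout: one row per trait, with
#' min/max/mean and "+ (−)" count columns for diploid heterobeltiosis,
#' tetraploid heterobeltiosis and competitive heterosis. Percentages are
#' rounded to `digits` decimals (default 2), half away from zero.
#'
#' @param records a [heterosis_records()] result.
#' @param path output file.
#' @param digits decimals (default 2).
#' @export
write_heterosis_report <- function(records, path, digits = 2) {
  hb <- heterosis_summary_table(records, "HB")
  ch <- tryCatch(heterosis_summary_table(records, "CH"), error = function(e) NULL)
  blocks <- split(hb, hb$group)
  if (!is.null(ch)) blocks$CH <- ch
  traits <- unique(as.data.frame(records)$trait)
  out <- data.frame(trait = traits, stringsAsFactors = FALSE)
  for (bn in names(blocks)) {
    b <- blocks[[bn]]
    idx <- match(traits, b$trait)
    fmt <- function(v) ifelse(is.na(v), "",
                              formatC(round_half_away(v, digits),
                                      format = "f", digits = digits))
    out[[paste0(bn, "_min")]] <- fmt(b$min[idx])
    out[[paste0(bn, "_max")]] <- fmt(b$max[idx])
    out[[paste0(bn, "_mean")]] <- fmt(b$mean[idx])
    out[[paste0(bn, "_pos_neg")]] <-
      ifelse(is.na(idx), "", sprintf("%d (%d)", b$n_positive[idx], b$n_negative[idx]))
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
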