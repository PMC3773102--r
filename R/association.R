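#' Pearson correlation with two-sided p-value
#'
#' Standard Pearson r after pairwise-complete filtering; p from
#' `t = r * sqrt((n-2)/(1-r^2))` with n-2 degrees of freedom, two-sided.
#' Significance stars: `*` at 0.05, `**` at 0.01.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `n`, `r`, `p`, `stars`; `r` and `p` are `NA` (with a
#'   warning) when fewer than 3 complete pairs remain or either variable has
#'   zero variance.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    warnf("fewer than 3 complete pairs; correlation undefined")
    return(list(n = n, r = NA_real_, p = NA_real_, stars = ""))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warnf("zero variance; correlation undefined")
    return(list(n = n, r = NA_real_, p = NA_real_, stars = ""))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- ct$p.value
  list(n = n, r = r, p = p, stars = star_string(p))
}

star_string <- function(p) {
  if (is.na(p)) "" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Ordinary least-squares regression of y on x
#'
#' @param x,y numeric vectors (pairwise-complete filtered).
#' @return list with `slope`, `intercept`, `r_squared`, `n`; all `NA` when x
#'   has zero variance or fewer than 3 pairs remain.
#' @export
simple_linear_regression <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || stats::sd(x) == 0) {
    warnf("regression undefined (need >= 3 pairs and non-constant x)")
    return(list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
                n = length(x)))
  }
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared,
       n = length(x))
}

# parental Nei distance for each cross, NA (with warning) when a parent is
# absent from the matrix
cross_parent_distance <- function(dm, plan) {
  cr <- plan$crosses
  labs <- rownames(dm)
  gd <- rep(NA_real_, nrow(cr))
  for (i in seq_len(nrow(cr))) {
    if (cr$female[i] %in% labs && cr$male[i] %in% labs) {
      gd[i] <- dm[cr$female[i], cr$male[i]]
    }
  }
  if (anyNA(gd)) {
    warnf("%d cross(es) dropped: parent(s) missing from the distance matrix",
          sum(is.na(gd)))
  }
  gd
}

#' Correlation of parental genetic distance with heterobeltiosis
#'
#' For each trait and ploidy group, the Pearson correlation between the Nei
#' distance separating a cross's parents and the cross's heterobeltiosis.
#'
#' @param dm labeled distance matrix containing all parents (see
#'   [nei_distance_matrix()]).
#' @param records a [heterosis_records()] result.
#' @param plan the [cross_plan()] the records were computed from.
#' @param adjust optional p-value adjustment method (e.g. `"BH"`); default
#'   `"none"`, matching the classical single-table report.
#' @return data frame with columns `trait`, `ploidy`, `n`, `r`, `p`, `stars`.
#' @export
gd_heterosis_table <- function(dm, records, plan, adjust = "none") {
  cr <- plan$crosses
  gd <- cross_parent_distance(dm, plan)
  gd_by_hybrid <- stats::setNames(gd, cr$hybrid_id)
  recs <- as.data.frame(records)
  recs$gd <- gd_by_hybrid[recs$hybrid_id]
  sp <- split(recs, list(recs$trait, recs$ploidy), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(g) {
    res <- suppressWarnings(pearson_correlation(g$gd, g$HB))
    data.frame(trait = g$trait[1L], ploidy = g$ploidy[1L],
               n = res$n, r = res$r, p = res$p, stars = res$stars,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (adjust != "none") {
    out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
    out$stars <- vapply(out$p_adjusted, star_string, character(1))
  }
  out[order(out$ploidy, out$trait), ]
}

#' Correlation of yield heterobeltiosis with each trait's heterobeltiosis
#'
#' @param records a [heterosis_records()] result.
#' @param yield_trait name of the yield trait (default `"GY"`).
#' @param adjust optional p-value adjustment method; default `"none"`.
#' @return data frame with columns `trait`, `ploidy`, `n`, `r`, `p`, `stars`
#'   (one row per non-yield trait per ploidy group).
#' @export
yield_trait_correlation_table <- function(records, yield_trait = "GY",
                                          adjust = "none") {
  recs <- as.data.frame(records)
  if (!yield_trait %in% recs$trait) {
    stopf("yield trait '%s' not present in the records", yield_trait)
  }
  out <- list()
  for (pl in sort(unique(recs$ploidy))) {
    sub <- recs[recs$ploidy == pl, , drop = FALSE]
    ymap <- stats::setNames(sub$HB[sub$trait == yield_trait],
                            sub$hybrid_id[sub$trait == yield_trait])
    for (tr in setdiff(unique(sub$trait), yield_trait)) {
      g <- sub[sub$trait == tr, , drop = FALSE]
      res <- suppressWarnings(pearson_correlation(ymap[g$hybrid_id], g$HB))
      out[[length(out) + 1L]] <- data.frame(
        trait = tr, ploidy = pl, n = res$n, r = res$r, p = res$p,
        stars = res$stars, stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  if (adjust != "none") {
    res$p_adjusted <- stats::p.adjust(res$p, method = adjust)
    res$stars <- vapply(res$p_adjusted, star_string, character(1))
  }
  res
}

#' Write the association report
#'
#' One row per trait; columns hold r (with stars) for yield-HB correlation and
#' GD-HB correlation in each ploidy group, followed by a per-group regression
#' summary of yield heterobeltiosis on genetic distance.
#'
#' @param gd_tab result of [gd_heterosis_table()].
#' @param yield_tab result of [yield_trait_correlation_table()].
#' @param regressions named list of [simple_linear_regression()] results
#'   (names become rows of the regression block), or `NULL`.
#' @param path output file.
#' @param digits decimals (default 3).
#' @export
write_association_report <- function(gd_tab, yield_tab, regressions = NULL,
                                     path, digits = 3) {
  traits <- unique(c(yield_tab$trait, gd_tab$trait))
  fmt_cell <- function(tab, tr, pl) {
    i <- which(tab$trait == tr & tab$ploidy == pl)
    if (!length(i) || is.na(tab$r[i])) return("")
    paste0(formatC(round_half_away(tab$r[i], digits), format = "f",
                   digits = digits), tab$stars[i])
  }
  out <- data.frame(trait = traits, stringsAsFactors = FALSE)
  for (pl in sort(unique(c(gd_tab$ploidy, yield_tab$ploidy)))) {
    out[[paste0("yield_", pl, "x")]] <-
      vapply(traits, fmt_cell, character(1), tab = yield_tab, pl = pl)
    out[[paste0("gd_", pl, "x")]] <-
      vapply(traits, fmt_cell, character(1), tab = gd_tab, pl = pl)
  }
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(regressions)) {
    writeLines("", con)
    writeLines("group\tslope\tintercept\tr_squared\tn", con)
    for (nm in names(regressions)) {
      r <- regressions[[nm]]
      writeLines(paste(c(nm, formatC(round_half_away(
        c(r$slope, r$intercept, r$r_squared), digits),
        format = "f", digits = digits), r$n), collapse = "\t"), con)
    }
  }
  invisible(path)
}
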