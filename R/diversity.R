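#' Per-locus allele frequencies under an explicit dosage convention
#'
#' SSR banding patterns give the *set* of alleles an individual carries but,
#' for tetraploids, not their dosage. Two conventions are offered:
#'
#' * `"copy"` (equal-dose; default): each non-missing individual contributes
#'   `ploidy` allele copies, split equally among its distinct observed alleles
#'   (a tetraploid showing bands A,B contributes 2 copies of each). On
#'   dosage-resolved diploid data (homozygote `A`, heterozygote `A/B`) this is
#'   the ordinary allele-copy count.
#' * `"presence"`: each distinct allele per individual contributes one count —
#'   band-presence scoring, ploidy-agnostic.
#'
#' Frequencies are renormalized over the individuals actually scored at the
#' locus, so missing data shrink `n_scored` rather than distorting the
#' spectrum.
#'
#' @param panel a [genotype_panel()].
#' @param locus marker name.
#' @param mode `"copy"` or `"presence"`.
#' @return object of class `allele_spectrum`: list with `locus`, `freqs`
#'   (named numeric, strictly positive, summing to 1), `n_scored`, `mode`.
#' @export
allele_frequencies <- function(panel, locus, mode = c("copy", "presence")) {
  mode <- match.arg(mode)
  j <- match(locus, panel$markers$name)
  if (is.na(j)) stopf("locus '%s' not in panel", locus)
  cells <- panel$calls[, j]
  scored <- which(!is.na(cells))
  if (!length(scored)) stopf("all calls missing at locus '%s'", locus)
  counts <- numeric(0)
  for (i in scored) {
    al <- call_alleles(cells[i], panel$sep)
    w <- if (mode == "copy") panel$individuals$ploidy[i] / length(al) else 1
    for (a in al) counts[a] <- (if (is.na(counts[a])) 0 else counts[a]) + w
  }
  counts <- counts[sort(names(counts))]
  allele_spectrum(counts / sum(counts), locus = locus,
                  n_scored = length(scored), mode = mode)
}

#' Build an allele spectrum from frequencies or counts
#'
#' Mostly used in tests and worked examples; [allele_frequencies()] is the
#' data-driven route.
#'
#' @param freqs positive numeric vector (normalized to sum 1), optionally named.
#' @param locus,n_scored,mode metadata carried along.
#' @return an `allele_spectrum`.
#' @export
allele_spectrum <- function(freqs, locus = NA_character_, n_scored = NA_integer_,
                            mode = NA_character_) {
  if (!length(freqs) || any(freqs <= 0)) {
    stopf("spectrum frequencies must be strictly positive (locus '%s')", locus)
  }
  freqs <- freqs / sum(freqs)
  if (is.null(names(freqs))) names(freqs) <- paste0("a", seq_along(freqs))
  structure(list(locus = locus, freqs = freqs,
                 n_scored = n_scored, mode = mode),
            class = "allele_spectrum")
}

#' @export
print.allele_spectrum <- function(x, ...) {
  cat(sprintf("allele_spectrum [%s] (%s, n=%s): %s\n", x$locus, x$mode,
              x$n_scored,
              paste(sprintf("%s=%.3f", names(x$freqs), x$freqs), collapse = " ")))
  invisible(x)
}

#' Observed number of alleles (Na)
#' @param spec an `allele_spectrum`.
#' @return integer count of distinct alleles.
#' @export
observed_allele_count <- function(spec) length(spec$freqs)

#' Effective number of alleles, Ae = 1 / sum(p^2)
#'
#' The allele count of an equifrequent locus with the same homozygosity;
#' equals Na exactly when alleles are equifrequent, and 1 when monomorphic.
#' @param spec an `allele_spectrum`.
#' @return numeric in `[1, Na]`.
#' @export
effective_allele_count <- function(spec) 1 / sum(spec$freqs^2)

#' Expected heterozygosity (Nei gene diversity), He = 1 - sum(p^2)
#'
#' @param spec an `allele_spectrum`.
#' @param unbiased if `TRUE`, apply the small-sample correction
#'   `2n/(2n-1) * (1 - sum p^2)` with `n = n_scored` individuals; the plain
#'   (uncorrected) form is the default.
#' @return numeric in `[0, 1 - 1/Na]` (uncorrected).
#' @export
expected_heterozygosity <- function(spec, unbiased = FALSE) {
  he <- 1 - sum(spec$freqs^2)
  if (unbiased) {
    n <- spec$n_scored
    if (is.na(n) || n < 2) stopf("unbiased He needs n_scored >= 2")
    he <- 2 * n / (2 * n - 1) * he
  }
  he
}

#' Shannon information index, I = -sum(p log p) in nats
#' @param spec an `allele_spectrum`.
#' @return numeric in `[0, log(Na)]`.
#' @export
shannon_index <- function(spec) -sum(spec$freqs * log(spec$freqs))

#' Polymorphism information content, Botstein form
#'
#' `PIC = 1 - sum(p^2) - sum_{i<j} 2 p_i^2 p_j^2` (Botstein et al. 1980):
#' the probability that a random offspring is informative for linkage, always
#' at most the simplified `1 - sum(p^2)` form.
#'
#' @param spec an `allele_spectrum`.
#' @return numeric in `[0, 1)`.
#' @export
pic_botstein <- function(spec) {
  p2 <- spec$freqs^2
  s <- sum(p2)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - s - (s^2 - sum(p2^2))
}

#' Polymorphism information content, simplified form
#'
#' The literal `1 - sum(p^2)`, numerically identical to
#' [expected_heterozygosity()]; retained because some reports use this
#' simplification under the PIC name.
#' @param spec an `allele_spectrum`.
#' @return numeric.
#' @export
pic_simple <- function(spec) 1 - sum(spec$freqs^2)

#' All diversity statistics for one locus
#'
#' @inheritParams allele_frequencies
#' @return one-row data frame with columns `locus`, `n_scored`, `Na`,
#'   `Ae_eff`, `He`, `I`, `PIC_botstein`, `PIC_simple`.
#' @export
locus_diversity <- function(panel, locus, mode = c("copy", "presence")) {
  spec <- allele_frequencies(panel, locus, mode)
  data.frame(
    locus = locus,
    n_scored = spec$n_scored,
    Na = observed_allele_count(spec),
    Ae_eff = effective_allele_count(spec),
    He = expected_heterozygosity(spec),
    I = shannon_index(spec),
    PIC_botstein = pic_botstein(spec),
    PIC_simple = pic_simple(spec),
    stringsAsFactors = FALSE
  )
}

#' Per-locus diversity table with column summaries
#'
#' The per-ploidy-group report: one row per marker (in marker order) plus a
#' footer of column means, sample standard deviations (n-1 denominator;
#' reported missing for a single locus), minima, maxima and the total allele
#' count (sum of Na). Loci with fewer than two scored individuals are kept but
#' flagged; all-missing loci are dropped with a warning and listed in the
#' `dropped` attribute.
#'
#' @inheritParams allele_frequencies
#' @return a data frame of class `diversity_summary` with attributes
#'   `summary` (stats x columns matrix), `total_alleles`, `dropped`, `flagged`.
#' @export
diversity_table <- function(panel, mode = c("copy", "presence")) {
  mode <- match.arg(mode)
  loci <- panel$markers$name
  rows <- vector("list", length(loci))
  dropped <- character(0)
  for (k in seq_along(loci)) {
    j <- match(loci[k], panel$markers$name)
    if (all(is.na(panel$calls[, j]))) {
      dropped <- c(dropped, loci[k])
      next
    }
    rows[[k]] <- locus_diversity(panel, loci[k], mode)
  }
  if (length(dropped)) {
    warnf("dropping %d all-missing locus/loci: %s", length(dropped),
          paste(dropped, collapse = ", "))
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stopf("no locus with scored calls")
  tab$chromosome <- panel$markers$chromosome[match(tab$locus, panel$markers$name)]
  tab <- tab[c("locus", "chromosome", "n_scored", "Na", "Ae_eff", "He", "I",
               "PIC_botstein", "PIC_simple")]
  rownames(tab) <- NULL
  stat_cols <- c("Na", "Ae_eff", "He", "I", "PIC_botstein", "PIC_simple")
  m <- as.matrix(tab[stat_cols])
  sdv <- if (nrow(m) > 1) apply(m, 2, stats::sd) else rep(NA_real_, ncol(m))
  summ <- rbind(mean = colMeans(m), st_dev = sdv,
                min = apply(m, 2, min), max = apply(m, 2, max))
  structure(tab,
            class = c("diversity_summary", "data.frame"),
            summary = summ,
            total_alleles = sum(tab$Na),
            dropped = dropped,
            flagged = tab$locus[tab$n_scored < 2],
            mode = mode)
}

#' @export
print.diversity_summary <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "chromosome"
  df[num] <- lapply(df[num], round_half_away, digits = digits)
  print.data.frame(utils::head(df, 10), row.names = FALSE)
  if (nrow(df) > 10) cat("  ... (", nrow(df) - 10, " more loci)\n", sep = "")
  cat("\nSummary over", nrow(df), "loci (total alleles:",
      attr(x, "total_alleles"), ")\n")
  print(round_half_away(attr(x, "summary"), digits))
  fl <- attr(x, "flagged")
  if (length(fl)) cat("flagged (<2 scored individuals):",
                      paste(fl, collapse = ", "), "\n")
  invisible(x)
}

#' Write a diversity report
#'
#' Delimited table mirroring the classical POPGENE-style per-locus layout:
#' marker, chromosome, then the statistics, followed by Mean / St.Dev / Min /
#' Max footer rows. Values are rounded to `digits` decimals, half away from
#' zero.
#'
#' @param div a [diversity_table()] result.
#' @param path output file.
#' @param digits decimals in the report (default 3).
#' @export
write_diversity_report <- function(div, path, digits = 3) {
  df <- as.data.frame(div)
  stat_cols <- c("Na", "Ae_eff", "He", "I", "PIC_botstein", "PIC_simple")
  df[stat_cols] <- lapply(df[stat_cols], function(v)
    formatC(round_half_away(v, digits), format = "f", digits = digits))
  summ <- attr(div, "summary")
  foot <- data.frame(
    locus = c("Mean", "St.Dev", "Min", "Max"),
    chromosome = NA, n_scored = NA,
    stringsAsFactors = FALSE
  )
  for (cc in stat_cols) {
    foot[[cc]] <- formatC(round_half_away(summ[, cc], digits),
                          format = "f", digits = digits)
  }
  out <- rbind(df, foot[names(df)])
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
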