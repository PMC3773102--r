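#' Per-unit, per-locus allele spectra
#'
#' Builds the frequency substrate for Nei's genetic identity. For
#' `unit = "individual"` each cultivar is treated as a (near-)fixed inbred
#' line whose "population frequencies" are its own equal-dose copy
#' proportions — an individual showing bands A,B at a locus has frequencies
#' (0.5, 0.5) regardless of ploidy. For `unit = "group"` individuals are
#' pooled by their `subgroup` label and frequencies estimated with
#' [allele_frequencies()].
#'
#' @param panel a [genotype_panel()].
#' @param unit `"individual"` or `"group"`.
#' @param mode dosage convention passed to [allele_frequencies()].
#' @return named list (one element per unit) of named lists (one
#'   `allele_spectrum` per scored locus).
#' @export
unit_spectra <- function(panel, unit = c("individual", "group"),
                         mode = c("copy", "presence")) {
  unit <- match.arg(unit)
  mode <- match.arg(mode)
  if (unit == "individual") {
    members <- stats::setNames(as.list(seq_len(nrow(panel$individuals))),
                               panel$individuals$id)
  } else {
    sg <- panel$individuals$subgroup
    if (all(is.na(sg))) stopf("unit = 'group' needs subgroup metadata")
    members <- split(seq_len(nrow(panel$individuals)), sg)
  }
  lapply(members, function(idx) {
    sub <- subset_panel(panel, idx)
    out <- list()
    for (loc in sub$markers$name) {
      j <- match(loc, sub$markers$name)
      if (all(is.na(sub$calls[, j]))) next
      out[[loc]] <- allele_frequencies(sub, loc, mode)
    }
    out
  })
}

#' Nei (1972) normalized genetic identity between two units
#'
#' `I = Jxy / sqrt(Jx * Jy)` with `Jxy`, `Jx`, `Jy` the arithmetic means over
#' shared scored loci of `sum(p_x p_y)`, `sum(p_x^2)`, `sum(p_y^2)`. Loci
#' missing in either unit are excluded pairwise. The 1978 unbiased variant
#' replaces the within-unit homozygosities by
#' `(2n sum(p^2) - 1) / (2n - 1)` using each unit's per-locus sample size.
#'
#' @param specA,specB per-locus spectra for the two units (named lists of
#'   `allele_spectrum`, as one element of [unit_spectra()]).
#' @param variant `"nei1972"` (standard) or `"nei1978"` (unbiased).
#' @return identity in `[0, 1]` (values marginally above 1 from rounding are
#'   clamped to 1).
#' @export
nei_identity <- function(specA, specB, variant = c("nei1972", "nei1978")) {
  variant <- match.arg(variant)
  shared <- intersect(names(specA), names(specB))
  if (!length(shared)) stopf("no shared scored locus between the two units")
  jxy <- jx <- jy <- numeric(length(shared))
  for (k in seq_along(shared)) {
    a <- specA[[shared[k]]]; b <- specB[[shared[k]]]
    common <- intersect(names(a$freqs), names(b$freqs))
    jxy[k] <- sum(a$freqs[common] * b$freqs[common])
    jx[k] <- sum(a$freqs^2)
    jy[k] <- sum(b$freqs^2)
    if (variant == "nei1978") {
      na <- 2 * a$n_scored; nb <- 2 * b$n_scored
      if (is.na(na) || is.na(nb) || na < 2 || nb < 2) {
        stopf("nei1978 needs n_scored for every locus")
      }
      jx[k] <- (na * jx[k] - 1) / (na - 1)
      jy[k] <- (nb * jy[k] - 1) / (nb - 1)
    }
  }
  denom <- sqrt(mean(jx) * mean(jy))
  if (denom <= 0) return(0)
  min(mean(jxy) / denom, 1)
}

#' Nei standard genetic distance matrix
#'
#' `D = -ln I` over all unit pairs. A pair with identity 0 (fully disjoint
#' allele sets at every shared locus) has infinite distance; it is replaced by
#' `cap` with a warning so such pairs remain clusterable.
#'
#' @inheritParams unit_spectra
#' @param variant Nei formulation, see [nei_identity()].
#' @param cap replacement for infinite distances (default 10).
#' @return symmetric labeled matrix of class `c("nei_dist", "matrix")`.
#' @export
nei_distance_matrix <- function(panel, unit = c("individual", "group"),
                                mode = c("copy", "presence"),
                                variant = c("nei1972", "nei1978"),
                                cap = 10) {
  spectra <- unit_spectra(panel, unit, mode)
  if (length(spectra) < 2L) stopf("need at least 2 units for a distance matrix")
  labs <- names(spectra)
  n <- length(labs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  capped <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      I <- nei_identity(spectra[[i]], spectra[[j]], variant)
      if (I <= 0) {
        d[i, j] <- d[j, i] <- cap
        capped <- capped + 1L
      } else {
        d[i, j] <- d[j, i] <- max(-log(I), 0)
      }
    }
  }
  if (capped) warnf("%d pair(s) had identity 0; distance capped at %g", capped, cap)
  structure(d, class = c("nei_dist", class(matrix())))
}

#' Band-sharing similarity distances (Dice / Jaccard)
#'
#' Optional presence/absence backend: each individual is a set of
#' (locus, allele) bands; distance is `1 - similarity` with Dice
#' `2|A∩B|/(|A|+|B|)` or Jaccard `|A∩B|/|A∪B|`. Loci missing in either
#' individual are excluded pairwise.
#'
#' @param panel a [genotype_panel()].
#' @param method `"dice"` or `"jaccard"`.
#' @return symmetric labeled distance matrix.
#' @export
band_distance_matrix <- function(panel, method = c("dice", "jaccard")) {
  method <- match.arg(method)
  ids <- panel$individuals$id
  n <- length(ids)
  bands <- lapply(seq_len(n), function(i) {
    cells <- panel$calls[i, ]
    ok <- which(!is.na(cells))
    unlist(lapply(ok, function(j)
      paste0(panel$markers$name[j], ":",
             call_alleles(cells[j], panel$sep))), use.names = FALSE)
  })
  scored <- lapply(seq_len(n), function(i)
    panel$markers$name[!is.na(panel$calls[i, ])])
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      loci <- intersect(scored[[i]], scored[[j]])
      a <- bands[[i]][sub(":.*", "", bands[[i]]) %in% loci]
      b <- bands[[j]][sub(":.*", "", bands[[j]]) %in% loci]
      inter <- length(intersect(a, b))
      sim <- if (method == "dice") {
        if (length(a) + length(b) == 0) 1 else 2 * inter / (length(a) + length(b))
      } else {
        u <- length(union(a, b)); if (u == 0) 1 else inter / u
      }
      d[i, j] <- d[j, i] <- 1 - sim
    }
  }
  d
}

#' Write a distance matrix
#'
#' @param d symmetric labeled matrix.
#' @param path output file.
#' @param format `"delim"` (tab-separated with header row and label column) or
#'   `"phylip"` (square PHYLIP: count line, then label + row values).
#' @param digits decimals written.
#' @export
write_distance_matrix <- function(d, path, format = c("delim", "phylip"),
                                  digits = 6) {
  format <- match.arg(format)
  labs <- rownames(d)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "delim") {
    writeLines(paste(c("", labs), collapse = "\t"), con)
    for (i in seq_along(labs)) {
      writeLines(paste(c(labs[i], formatC(d[i, ], format = "f",
                                          digits = digits)), collapse = "\t"), con)
    }
  } else {
    writeLines(sprintf("%5d", length(labs)), con)
    safe <- gsub("[ \t]", "_", labs)
    for (i in seq_along(labs)) {
      writeLines(paste(c(formatC(safe[i], width = -10),
                         formatC(d[i, ], format = "f", digits = digits)),
                       collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read a delimited distance matrix written by [write_distance_matrix()]
#' @param path input file.
#' @return symmetric labeled matrix.
#' @export
read_distance_matrix <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE)
  as.matrix(m)
}
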