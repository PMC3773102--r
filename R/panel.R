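#' Construct a mixed-ploidy SSR genotype panel
#'
#' The central genetic container: a set of individuals (diploid cultivars and,
#' optionally, their autotetraploid derivatives) scored at a set of SSR loci.
#' Each call is a *set* of 1..ploidy distinct allele labels; for tetraploids
#' the dosage of each allele within the set is typically unknown (a banding
#' pattern, not a counted genotype), which is why downstream frequency
#' estimation exposes explicit dosage conventions.
#'
#' @param markers data frame with columns `name` (unique marker identifiers)
#'   and optionally `chromosome` (positive integer; `NA` allowed).
#' @param individuals data frame with columns `id` (unique), `ploidy` (2 or 4),
#'   and optionally `subgroup` (e.g. `"indica"`/`"japonica"`) and `pair_id`
#'   (label linking a diploid cultivar with its tetraploid derivative; at most
#'   one individual of each ploidy may share a `pair_id`).
#' @param calls character matrix, individuals x markers: allele labels joined
#'   by `sep`, `NA` for missing. Repeated labels within a cell (e.g. `"A/A"`
#'   for a homozygous diploid) collapse to the label set; a cell with more
#'   label tokens than the individual's ploidy is rejected.
#' @param sep separator used inside call cells (default `"/"`).
#' @return an object of class `genotype_panel`.
#' @examples
#' pan <- genotype_panel(
#'   markers = data.frame(name = "RM1"),
#'   individuals = data.frame(id = c("a", "b"), ploidy = c(2, 2)),
#'   calls = matrix(c("A/B", "A/A"), ncol = 1)
#' )
#' n_alleles(pan, "RM1")  # 2
#' @export
genotype_panel <- function(markers, individuals, calls, sep = "/") {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  if (is.null(markers$chromosome)) markers$chromosome <- NA_integer_
  if (is.null(individuals$subgroup)) individuals$subgroup <- NA_character_
  if (is.null(individuals$pair_id)) individuals$pair_id <- NA_character_
  individuals$id <- as.character(individuals$id)
  individuals$ploidy <- as.integer(individuals$ploidy)
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (!identical(dim(calls), c(nrow(individuals), nrow(markers)))) {
    stopf("calls matrix is %d x %d but panel has %d individuals and %d markers",
          nrow(calls), ncol(calls), nrow(individuals), nrow(markers))
  }
  dimnames(calls) <- list(individuals$id, markers$name)
  obj <- structure(
    list(markers = markers, individuals = individuals, calls = calls, sep = sep),
    class = "genotype_panel"
  )
  obj$calls <- canonicalize_calls(obj)
  validate_panel(obj)
  obj
}

# split a call cell into its distinct allele labels (NULL when missing)
call_alleles <- function(cell, sep = "/") {
  if (is.na(cell) || !nzchar(cell)) return(NULL)
  unique(strsplit(cell, sep, fixed = TRUE)[[1L]])
}

# sort-unique every cell so set semantics become string equality
canonicalize_calls <- function(panel) {
  calls <- panel$calls
  ploidy <- panel$individuals$ploidy
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(ncol(calls))) {
      cell <- calls[i, j]
      if (is.na(cell) || !nzchar(cell)) {
        calls[i, j] <- NA_character_
        next
      }
      toks <- strsplit(cell, panel$sep, fixed = TRUE)[[1L]]
      if (length(toks) > ploidy[i]) {
        stopf(
          "call '%s' for individual '%s' at locus '%s' has %d labels but ploidy is %d",
          cell, rownames(calls)[i], colnames(calls)[j], length(toks), ploidy[i]
        )
      }
      if (any(!nzchar(toks))) {
        stopf("empty allele label in call '%s' (individual '%s', locus '%s')",
              cell, rownames(calls)[i], colnames(calls)[j])
      }
      calls[i, j] <- paste(sort(unique(toks)), collapse = panel$sep)
    }
  }
  calls
}

validate_panel <- function(panel) {
  m <- panel$markers; ind <- panel$individuals
  if (anyDuplicated(m$name)) stopf("duplicate marker name: %s",
                                   m$name[duplicated(m$name)][1L])
  if (any(!is.na(m$chromosome) & m$chromosome < 1)) {
    stopf("marker chromosome must be >= 1")
  }
  if (anyDuplicated(ind$id)) stopf("duplicate individual id: %s",
                                   ind$id[duplicated(ind$id)][1L])
  bad <- !ind$ploidy %in% c(2L, 4L)
  if (any(bad)) stopf("unknown ploidy %s for individual '%s' (must be 2 or 4)",
                      ind$ploidy[bad][1L], ind$id[bad][1L])
  if (!identical(dim(panel$calls), c(nrow(ind), nrow(m)))) {
    stopf("calls matrix is %d x %d but panel has %d individuals and %d markers",
          nrow(panel$calls), ncol(panel$calls), nrow(ind), nrow(m))
  }
  pid <- ind$pair_id[!is.na(ind$pair_id)]
  if (length(pid)) {
    key <- paste(ind$pair_id, ind$ploidy)[!is.na(ind$pair_id)]
    if (anyDuplicated(key)) {
      stopf("pair_id '%s' is shared by more than one individual of the same ploidy",
            sub(" .*", "", key[duplicated(key)][1L]))
    }
  }
  invisible(panel)
}

#' @export
print.genotype_panel <- function(x, ...) {
  tab <- table(factor(x$individuals$ploidy, levels = c(2, 4)))
  cat(sprintf(
    "genotype_panel: %d individuals (%sx2, %sx4) x %d SSR loci\n",
    nrow(x$individuals), tab[["2"]], tab[["4"]], nrow(x$markers)
  ))
  sg <- unique(stats::na.omit(x$individuals$subgroup))
  if (length(sg)) cat("  subgroups:", paste(sg, collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Number of distinct alleles observed at a locus
#' @param panel a [genotype_panel()].
#' @param locus marker name.
#' @return integer count of distinct allele labels across non-missing calls.
#' @export
n_alleles <- function(panel, locus) {
  length(locus_allele_set(panel, locus))
}

locus_allele_set <- function(panel, locus) {
  j <- match(locus, panel$markers$name)
  if (is.na(j)) stopf("locus '%s' not in panel", locus)
  cells <- panel$calls[, j]
  sort(unique(unlist(lapply(cells[!is.na(cells)], call_alleles, sep = panel$sep))))
}

#' Split a panel by ploidy level
#'
#' @param panel a [genotype_panel()].
#' @return list with components `diploid` and `tetraploid`; the two sub-panels
#'   partition the individuals and share the marker list.
#' @export
split_by_ploidy <- function(panel) {
  list(
    diploid = subset_panel(panel, panel$individuals$ploidy == 2L),
    tetraploid = subset_panel(panel, panel$individuals$ploidy == 4L)
  )
}

#' Subset a panel to selected individuals
#' @param panel a [genotype_panel()].
#' @param which logical/integer/character index into the individuals.
#' @return a `genotype_panel` with the selected rows.
#' @export
subset_panel <- function(panel, which) {
  if (is.character(which)) which <- match(which, panel$individuals$id)
  ind <- panel$individuals[which, , drop = FALSE]
  rownames(ind) <- NULL
  structure(
    list(markers = panel$markers, individuals = ind,
         calls = panel$calls[which, , drop = FALSE], sep = panel$sep),
    class = "genotype_panel"
  )
}

#' Infer 2x/4x pairing from cultivar name suffixes
#'
#' Convenience for panels whose individual ids encode ploidy as a `-2x`/`-4x`
#' suffix (case-insensitive): individuals sharing the stripped base name are
#' assigned a common `pair_id`. Pairing is otherwise explicit metadata.
#'
#' @param panel a [genotype_panel()].
#' @return the panel with `pair_id` filled in where a suffix match was found.
#' @export
infer_pairs_from_suffix <- function(panel) {
  ids <- panel$individuals$id
  base <- sub("[-_ ]?[24]x$", "", ids, ignore.case = TRUE)
  has_suffix <- base != ids
  dup <- base %in% base[duplicated(base)]
  fill <- has_suffix & dup & is.na(panel$individuals$pair_id)
  panel$individuals$pair_id[fill] <- base[fill]
  validate_panel(panel)
  panel
}
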