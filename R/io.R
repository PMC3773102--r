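#' Read a genotype table
#'
#' Delimited text (comma or tab, auto-detected), UTF-8. The header row names
#' the markers after four fixed metadata columns `id`, `ploidy`, `subgroup`,
#' `pair_id`. An optional second line whose first field is `#chr` carries the
#' chromosome number of each marker. Call cells are allele labels joined by
#' `sep_cell` (default `/`); the missing token (default `.`) or an empty cell
#' is a missing call.
#'
#' @param path file to read.
#' @param sep_cell separator between allele labels inside a cell.
#' @param missing token representing a missing call.
#' @return a validated [genotype_panel()].
#' @export
read_genotype_table <- function(path, sep_cell = "/", missing = ".") {
  if (!file.exists(path)) stopf("genotype table '%s' does not exist", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stopf("genotype table '%s' is empty", path)
  delim <- if (grepl("\t", lines[[1L]])) "\t" else ","
  header <- strsplit(lines[[1L]], delim, fixed = TRUE)[[1L]]
  meta_cols <- c("id", "ploidy", "subgroup", "pair_id")
  if (length(header) < 5L || !identical(header[1:4], meta_cols)) {
    stopf("genotype table header must start with %s followed by marker names",
          paste(meta_cols, collapse = ","))
  }
  marker_names <- header[-(1:4)]
  chrom <- rep(NA_integer_, length(marker_names))
  body <- lines[-1L]
  if (length(body) && startsWith(body[[1L]], "#chr")) {
    ch <- strsplit(body[[1L]], delim, fixed = TRUE)[[1L]]
    vals <- ch[-(1:4)]
    chrom <- suppressWarnings(as.integer(vals[seq_along(marker_names)]))
    body <- body[-1L]
  }
  rows <- strsplit(body, delim, fixed = TRUE)
  n <- length(rows)
  ind <- data.frame(
    id = character(n), ploidy = integer(n),
    subgroup = character(n), pair_id = character(n),
    stringsAsFactors = FALSE
  )
  calls <- matrix(NA_character_, n, length(marker_names))
  for (i in seq_len(n)) {
    r <- rows[[i]]
    length(r) <- 4L + length(marker_names)  # pad short rows with NA
    ind$id[i] <- r[[1L]]
    pl <- suppressWarnings(as.integer(r[[2L]]))
    if (is.na(pl)) stopf("row %d ('%s'): unreadable ploidy '%s'", i, r[[1L]], r[[2L]])
    ind$ploidy[i] <- pl
    ind$subgroup[i] <- r[[3L]]
    ind$pair_id[i] <- r[[4L]]
    cells <- r[-(1:4)]
    cells[is.na(cells) | cells == missing | !nzchar(cells)] <- NA_character_
    calls[i, ] <- cells
  }
  ind$subgroup[!nzchar(ind$subgroup) | ind$subgroup == missing] <- NA_character_
  ind$pair_id[!nzchar(ind$pair_id) | ind$pair_id == missing] <- NA_character_
  genotype_panel(
    markers = data.frame(name = marker_names, chromosome = chrom,
                         stringsAsFactors = FALSE),
    individuals = ind, calls = calls, sep = sep_cell
  )
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]: `read(write(panel))` reproduces the
#' panel field-for-field (calls compare as label sets).
#'
#' @param panel a valid [genotype_panel()].
#' @param path output file.
#' @param delim field delimiter (default tab).
#' @param missing token to write for missing calls.
#' @export
write_genotype_table <- function(panel, path, delim = "\t", missing = ".") {
  validate_panel(panel)
  if (nrow(panel$markers) == 0L) stopf("panel has no markers; nothing to serialize")
  meta_cols <- c("id", "ploidy", "subgroup", "pair_id")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c(meta_cols, panel$markers$name), collapse = delim), con)
  if (any(!is.na(panel$markers$chromosome))) {
    writeLines(paste(c("#chr", "", "", "", panel$markers$chromosome), collapse = delim), con)
  }
  for (i in seq_len(nrow(panel$individuals))) {
    cells <- panel$calls[i, ]
    cells[is.na(cells)] <- missing
    meta <- c(panel$individuals$id[i], panel$individuals$ploidy[i],
              panel$individuals$subgroup[i] %|NA|% "",
              panel$individuals$pair_id[i] %|NA|% "")
    writeLines(paste(c(meta, cells), collapse = delim), con)
  }
  invisible(path)
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

#' Construct a trait table
#'
#' Long-format replicate phenotypes for parents and hybrids. Replicate counts
#' may differ between entities (unbalanced designs are fine).
#'
#' @param data data frame with columns `entity`, `trait`, `replicate`, `value`.
#' @param directions named logical vector, `TRUE` = larger-is-better (the
#'   default for any trait not named).
#' @return an object of class `trait_table`.
#' @export
trait_table <- function(data, directions = NULL) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  need <- c("entity", "trait", "replicate", "value")
  if (!all(need %in% names(data))) {
    stopf("trait table needs columns %s", paste(need, collapse = ", "))
  }
  data$value <- as.numeric(data$value)
  key <- paste(data$entity, data$trait, data$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- data[duplicated(key), ][1L, ]
    stopf("duplicated (entity, trait, replicate) key: (%s, %s, %s)",
          d$entity, d$trait, d$replicate)
  }
  traits <- unique(data$trait)
  dir <- stats::setNames(rep(TRUE, length(traits)), traits)
  if (!is.null(directions)) {
    unknown <- setdiff(names(directions), traits)
    dir[intersect(names(directions), traits)] <-
      directions[intersect(names(directions), traits)]
    if (length(unknown)) warnf("direction given for unknown trait(s): %s",
                               paste(unknown, collapse = ", "))
  }
  structure(list(data = data, directions = dir), class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d entities x %d traits, %d measurements\n",
              length(unique(x$data$entity)), length(x$directions), nrow(x$data)))
  invisible(x)
}

#' Read a long-format trait table
#'
#' @param path delimited file (comma or tab auto-detected) with columns
#'   `entity`, `trait`, `replicate`, `value`.
#' @param directions_path optional sidecar with columns `trait`,
#'   `larger_is_better` (logical); traits absent from it default to
#'   larger-is-better.
#' @return a [trait_table()]. Replicates whose value reads as `NA` are dropped
#'   with a warning; any other non-numeric value is an error.
#' @export
read_trait_table <- function(path, directions_path = NULL) {
  df <- read_delim_auto(path)
  need <- c("entity", "trait", "replicate", "value")
  if (!all(need %in% names(df))) {
    stopf("trait table '%s' needs columns %s", path, paste(need, collapse = ", "))
  }
  raw <- as.character(df$value)
  na_like <- is.na(raw) | raw %in% c("NA", "")
  num <- suppressWarnings(as.numeric(raw))
  bad <- !na_like & is.na(num)
  if (any(bad)) stopf("non-numeric trait value '%s' at row %d of '%s'",
                      raw[bad][1L], which(bad)[1L], path)
  if (any(na_like)) {
    warnf("dropping %d replicate(s) with missing values from '%s'",
          sum(na_like), path)
    df <- df[!na_like, , drop = FALSE]
    num <- num[!na_like]
  }
  df$value <- num
  dirs <- NULL
  if (!is.null(directions_path)) {
    dd <- read_delim_auto(directions_path)
    dirs <- stats::setNames(as.logical(dd$larger_is_better), dd$trait)
  }
  trait_table(df, dirs)
}

#' Write a trait table (and optional direction sidecar)
#' @param traits a [trait_table()].
#' @param path output file (tab-delimited).
#' @param directions_path optional path for the direction sidecar.
#' @export
write_trait_table <- function(traits, path, directions_path = NULL) {
  utils::write.table(traits$data, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(directions_path)) {
    dd <- data.frame(trait = names(traits$directions),
                     larger_is_better = unname(traits$directions))
    utils::write.table(dd, directions_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Construct a cross plan
#'
#' Links each hybrid to its female and male parents, and each tetraploid
#' hybrid to the diploid hybrid made from the same cultivar pair (its
#' "counterpart", the reference for competitive heterosis).
#'
#' @param crosses data frame with columns `female`, `male`, `hybrid_id`,
#'   `ploidy`, and optional `counterpart_2x_hybrid` (NA for diploid crosses).
#' @return an object of class `cross_plan`.
#' @export
cross_plan <- function(crosses) {
  crosses <- as.data.frame(crosses, stringsAsFactors = FALSE)
  need <- c("female", "male", "hybrid_id", "ploidy")
  if (!all(need %in% names(crosses))) {
    stopf("cross plan needs columns %s", paste(need, collapse = ", "))
  }
  if (is.null(crosses$counterpart_2x_hybrid)) {
    crosses$counterpart_2x_hybrid <- NA_character_
  }
  crosses$ploidy <- as.integer(crosses$ploidy)
  if (anyDuplicated(crosses$hybrid_id)) stopf("duplicate hybrid_id in cross plan")
  if (!all(crosses$ploidy %in% c(2L, 4L))) stopf("cross ploidy must be 2 or 4")
  cp <- crosses$counterpart_2x_hybrid
  has <- !is.na(cp)
  if (any(has & crosses$ploidy != 4L)) {
    stopf("only tetraploid crosses may declare a diploid counterpart")
  }
  if (anyDuplicated(cp[has])) stopf("counterpart map must be injective")
  missing_cp <- setdiff(cp[has], crosses$hybrid_id[crosses$ploidy == 2L])
  if (length(missing_cp)) {
    stopf("counterpart hybrid '%s' not present among diploid crosses", missing_cp[1L])
  }
  structure(list(crosses = crosses), class = "cross_plan")
}

#' @export
print.cross_plan <- function(x, ...) {
  tab <- table(factor(x$crosses$ploidy, levels = c(2, 4)))
  cat(sprintf("cross_plan: %d crosses (%s diploid, %s tetraploid; %d counterpart links)\n",
              nrow(x$crosses), tab[["2"]], tab[["4"]],
              sum(!is.na(x$crosses$counterpart_2x_hybrid))))
  invisible(x)
}

#' Check that counterpart crosses use the same cultivar pair at both ploidies
#'
#' Verifies, through the panel's `pair_id` metadata, that the (female, male)
#' parents of each tetraploid cross are the 4x derivatives of the parents of
#' its declared diploid counterpart.
#'
#' @param plan a [cross_plan()].
#' @param panel a [genotype_panel()] supplying `pair_id` metadata.
#' @return `TRUE` invisibly, or an error naming the first offending pair.
#' @export
check_counterpart_parents <- function(plan, panel) {
  ind <- panel$individuals
  pid <- stats::setNames(ind$pair_id, ind$id)
  cr <- plan$crosses
  for (i in which(!is.na(cr$counterpart_2x_hybrid))) {
    j <- match(cr$counterpart_2x_hybrid[i], cr$hybrid_id)
    for (side in c("female", "male")) {
      a <- unname(pid[cr[[side]][i]])
      b <- unname(pid[cr[[side]][j]])
      if (is.na(a) || is.na(b) || a != b) {
        stopf("counterpart crosses '%s'/'%s' do not share the same %s cultivar",
              cr$hybrid_id[i], cr$hybrid_id[j], side)
      }
    }
  }
  invisible(TRUE)
}

#' Read a cross plan
#' @param path delimited file with columns `female`, `male`, `hybrid_id`,
#'   `ploidy`, `counterpart_2x_hybrid`.
#' @return a [cross_plan()].
#' @export
read_cross_plan <- function(path) {
  df <- read_delim_auto(path)
  if (!is.null(df$counterpart_2x_hybrid)) {
    df$counterpart_2x_hybrid[df$counterpart_2x_hybrid %in% c("", ".")] <- NA
  }
  cross_plan(df)
}

#' Write a cross plan
#' @param plan a [cross_plan()].
#' @param path output file (tab-delimited).
#' @export
write_cross_plan <- function(plan, path) {
  utils::write.table(plan$crosses, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = ".")
  invisible(path)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stopf("file '%s' does not exist", path)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, sep = delim, header = TRUE,
                    stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = character(), check.names = FALSE)
}
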