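#' Published per-locus diversity statistics for the 40-pair rice panel
#'
#' The per-locus report of a published 40-pair diploid/autotetraploid rice
#' panel genotyped at 99 SSR loci: observed allele count (`Na`), expected
#' heterozygosity (`He`), Shannon information index (`I`) and polymorphism
#' information content (`PIC`) for each ploidy group, with the marker's
#' chromosome. Bundled as a plain-text fixture so column summaries (e.g. mean
#' alleles per locus) can be recomputed without the undeposited raw genotypes.
#'
#' @return data frame with columns `marker`, `chr`, `Na_2x`, `He_2x`, `I_2x`,
#'   `PIC_2x`, `Na_4x`, `He_4x`, `I_4x`, `PIC_4x` (99 rows).
#' @export
rice_panel_locus_stats <- function() {
  path <- system.file("extdata", "rice_panel_locus_stats.tsv",
                      package = "ssrheterosis", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
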