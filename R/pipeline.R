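#' Pipeline run configuration
#'
#' Collects input locations (or simulation configs), statistical mode flags
#' and output settings for the `run_*` stages. For each data source exactly
#' one of \{file path, simulation config\} must be given.
#'
#' @param genotypes path to a genotype table, or `NULL`.
#' @param sim_panel a [panel_sim_config()], or `NULL`.
#' @param traits path to a trait table, or `NULL`.
#' @param sim_traits a [trait_sim_config()], or `NULL`.
#' @param crossplan path to a cross plan (required for heterosis /
#'   association stages unless `sim_traits` is used, in which case a diallel
#'   plan is built from the simulated panel).
#' @param directions path to a trait-direction sidecar, or `NULL`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed applied to simulation configs lacking one.
#' @param mode allele-frequency mode, `"copy"` or `"presence"`.
#' @param variant Nei formulation, `"nei1972"` or `"nei1978"`.
#' @param unit distance unit, `"individual"` or `"group"`.
#' @param pic PIC variant for reports, `"botstein"` or `"simple"`.
#' @param cap replacement for infinite Nei distances.
#' @param precision report decimals.
#' @param n_female,n_male diallel dimensions when the plan is simulated.
#' @return a list of class `run_config`.
#' @export
run_config <- function(genotypes = NULL, sim_panel = NULL,
                       traits = NULL, sim_traits = NULL,
                       crossplan = NULL, directions = NULL,
                       out_dir = "ssr_out", seed = 1,
                       mode = c("copy", "presence"),
                       variant = c("nei1972", "nei1978"),
                       unit = c("individual", "group"),
                       pic = c("botstein", "simple"),
                       cap = 10, precision = 3,
                       n_female = 2, n_male = 3) {
  if (!is.null(genotypes) && !is.null(sim_panel)) {
    stopf("give either a genotype file or a panel simulation config, not both")
  }
  if (!is.null(traits) && !is.null(sim_traits)) {
    stopf("give either a trait file or a trait simulation config, not both")
  }
  structure(list(
    genotypes = genotypes, sim_panel = sim_panel, traits = traits,
    sim_traits = sim_traits, crossplan = crossplan, directions = directions,
    out_dir = out_dir, seed = as.integer(seed),
    mode = match.arg(mode), variant = match.arg(variant),
    unit = match.arg(unit), pic = match.arg(pic),
    cap = cap, precision = precision,
    n_female = n_female, n_male = n_male
  ), class = "run_config")
}

resolve_panel <- function(cfg) {
  if (!is.null(cfg$genotypes)) return(read_genotype_table(cfg$genotypes))
  sp <- cfg$sim_panel %||% panel_sim_config()
  if (is.null(sp$seed)) sp$seed <- cfg$seed
  simulate_panel(sp)
}

resolve_plan <- function(cfg, panel) {
  if (!is.null(cfg$crossplan)) return(read_cross_plan(cfg$crossplan))
  make_diallel_plan(panel, cfg$n_female, cfg$n_male)
}

resolve_traits <- function(cfg, panel, plan, dm) {
  if (!is.null(cfg$traits)) return(read_trait_table(cfg$traits, cfg$directions))
  st <- cfg$sim_traits %||% trait_sim_config()
  if (is.null(st$seed)) st$seed <- cfg$seed + 1L
  simulate_diallel_traits(panel, plan, st, dm)
}

pipeline_log <- function(cfg, lines) {
  path <- file.path(cfg$out_dir, "run.log")
  cat(paste0(lines, "\n"), file = path, append = TRUE, sep = "")
  message(paste(lines, collapse = "\n"))
}

write_provenance <- function(cfg, stage, inputs = character(0)) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  plain <- unclass(cfg)
  plain$sim_panel <- if (!is.null(cfg$sim_panel)) unclass(cfg$sim_panel)
  plain$sim_traits <- if (!is.null(cfg$sim_traits)) {
    st <- unclass(cfg$sim_traits); st$traits <- as.list(st$traits); st
  }
  tmp <- tempfile()
  saveRDS(plain, tmp, version = 2)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  input_md5 <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  rec <- list(stage = stage, seed = cfg$seed, config_hash = hash,
              config = plain, inputs = input_md5,
              package_version = as.character(utils::packageVersion("ssrheterosis")))
  jsonlite::write_json(rec, file.path(cfg$out_dir, paste0("provenance_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(rec)
}

#' Run the per-ploidy diversity stage
#'
#' Writes a per-locus diversity report for each ploidy group present
#' (`diversity_2x.tsv`, `diversity_4x.tsv`), logging dropped (all-missing)
#' and flagged (<2 scored individuals) loci.
#'
#' @param cfg a [run_config()].
#' @return named list of [diversity_table()] results, invisibly.
#' @export
run_diversity <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- resolve_panel(cfg)
  halves <- split_by_ploidy(panel)
  res <- list()
  for (nm in names(halves)) {
    sub <- halves[[nm]]
    if (!nrow(sub$individuals)) next
    tag <- if (nm == "diploid") "2x" else "4x"
    div <- withCallingHandlers(
      diversity_table(sub, cfg$mode),
      warning = function(w) {
        pipeline_log(cfg, paste0("[diversity ", tag, "] ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    write_diversity_report(div, file.path(cfg$out_dir, paste0("diversity_", tag, ".tsv")),
                           digits = cfg$precision)
    fl <- attr(div, "flagged")
    if (length(fl)) pipeline_log(cfg, paste0("[diversity ", tag, "] flagged loci: ",
                                             paste(fl, collapse = ", ")))
    res[[tag]] <- div
  }
  if (!length(res)) stopf("panel has no individuals")
  write_provenance(cfg, "diversity",
                   inputs = if (!is.null(cfg$genotypes)) cfg$genotypes else character(0))
  invisible(res)
}

#' Run the distance + tree stage
#'
#' Writes the Nei distance matrix (delimited and PHYLIP square) and the
#' neighbor-joining tree (Newick).
#'
#' @param cfg a [run_config()].
#' @return list with `dm` and `tree`, invisibly.
#' @export
run_tree <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- resolve_panel(cfg)
  if (nrow(panel$individuals) < 3L) {
    stopf("tree stage needs at least 3 individuals, got %d", nrow(panel$individuals))
  }
  dm <- withCallingHandlers(
    nei_distance_matrix(panel, unit = cfg$unit, mode = cfg$mode,
                        variant = cfg$variant, cap = cfg$cap),
    warning = function(w) {
      pipeline_log(cfg, paste0("[tree] ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
  write_distance_matrix(dm, file.path(cfg$out_dir, "distance_matrix.tsv"), "delim")
  write_distance_matrix(dm, file.path(cfg$out_dir, "distance_matrix.phy"), "phylip")
  tree <- neighbor_joining(dm)
  if (length(attr(tree, "clamped"))) {
    pipeline_log(cfg, sprintf("[tree] %d negative branch length(s) clamped to 0 (min %.3g)",
                              length(attr(tree, "clamped")), min(attr(tree, "clamped"))))
  }
  write_newick(tree, file.path(cfg$out_dir, "nj_tree.nwk"))
  write_provenance(cfg, "tree",
                   inputs = if (!is.null(cfg$genotypes)) cfg$genotypes else character(0))
  invisible(list(dm = dm, tree = tree))
}

#' Run the heterosis stage
#'
#' Writes per-cross heterosis records, the per-trait summary report
#' (heterobeltiosis per ploidy group and competitive heterosis), and the
#' trait-variation table with the paired ploidy comparison.
#'
#' @param cfg a [run_config()].
#' @return list with `records`, `traits`, `plan`, `panel`, `dm`, invisibly.
#' @export
run_heterosis <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  panel <- resolve_panel(cfg)
  plan <- resolve_plan(cfg, panel)
  dm <- nei_distance_matrix(panel, unit = "individual", mode = cfg$mode,
                            variant = cfg$variant, cap = cfg$cap)
  traits <- resolve_traits(cfg, panel, plan, dm)
  records <- heterosis_records(traits, plan, significance = TRUE)
  missing_ch <- vapply(split(is.na(records$CH), records$hybrid_id), all, logical(1))
  ch_expected <- plan$crosses$hybrid_id[!is.na(plan$crosses$counterpart_2x_hybrid)]
  no_ch <- intersect(names(missing_ch)[missing_ch], ch_expected)
  if (length(no_ch)) {
    pipeline_log(cfg, paste0("[heterosis] competitive heterosis missing for: ",
                             paste(no_ch, collapse = ", ")))
  }
  rec_out <- as.data.frame(records)
  num <- vapply(rec_out, is.numeric, logical(1)) & !names(rec_out) %in% "ploidy"
  rec_out[num] <- lapply(rec_out[num], round_half_away, digits = 2)
  utils::write.table(rec_out, file.path(cfg$out_dir, "heterosis_records.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  write_heterosis_report(records, file.path(cfg$out_dir, "heterosis_summary.tsv"))
  tv <- withCallingHandlers(
    trait_variation_table(traits, panel),
    warning = function(w) {
      pipeline_log(cfg, paste0("[heterosis] ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
  tvr <- tv
  num <- vapply(tvr, is.numeric, logical(1))
  tvr[num] <- lapply(tvr[num], function(v) signif(v, 6))
  utils::write.table(tvr, file.path(cfg$out_dir, "trait_variation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  write_provenance(cfg, "heterosis",
                   inputs = Filter(Negate(is.null),
                                   c(cfg$genotypes, cfg$traits, cfg$crossplan)))
  invisible(list(records = records, traits = traits, plan = plan,
                 panel = panel, dm = dm))
}

#' Run the association stage
#'
#' Correlates parental Nei distance with per-cross heterobeltiosis and yield
#' heterobeltiosis with the other traits' heterobeltiosis, and regresses yield
#' heterobeltiosis on genetic distance per ploidy group. Accepts precomputed
#' stage outputs so the pipeline composes.
#'
#' @param cfg a [run_config()].
#' @param stage optional output of [run_heterosis()] to reuse.
#' @param yield_trait name of the yield trait (default `"GY"`).
#' @return list with `gd_tab`, `yield_tab`, `regressions`, invisibly.
#' @export
run_association <- function(cfg, stage = NULL, yield_trait = "GY") {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(stage)) stage <- run_heterosis(cfg)
  gd_tab <- withCallingHandlers(
    gd_heterosis_table(stage$dm, stage$records, stage$plan),
    warning = function(w) {
      pipeline_log(cfg, paste0("[association] ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
  yield_tab <- suppressWarnings(
    yield_trait_correlation_table(stage$records, yield_trait)
  )
  recs <- as.data.frame(stage$records)
  gd <- cross_parent_distance(stage$dm, stage$plan)
  gd_by_hybrid <- stats::setNames(gd, stage$plan$crosses$hybrid_id)
  regs <- list()
  for (pl in sort(unique(recs$ploidy))) {
    sub <- recs[recs$ploidy == pl & recs$trait == yield_trait, ]
    regs[[paste0(pl, "x")]] <- suppressWarnings(
      simple_linear_regression(gd_by_hybrid[sub$hybrid_id], sub$HB)
    )
  }
  write_association_report(gd_tab, yield_tab, regs,
                           file.path(cfg$out_dir, "association.tsv"),
                           digits = cfg$precision)
  write_provenance(cfg, "association",
                   inputs = Filter(Negate(is.null),
                                   c(cfg$genotypes, cfg$traits, cfg$crossplan)))
  invisible(list(gd_tab = gd_tab, yield_tab = yield_tab, regressions = regs))
}

#' Run every pipeline stage
#'
#' @param cfg a [run_config()].
#' @return list with the results of all stages, invisibly.
#' @export
run_all <- function(cfg) {
  div <- run_diversity(cfg)
  tre <- run_tree(cfg)
  het <- run_heterosis(cfg)
  assoc <- run_association(cfg, stage = het)
  invisible(list(diversity = div, tree = tre, heterosis = het,
                 association = assoc))
}
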