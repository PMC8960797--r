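# End-to-end orchestration: read inputs, reconstruct module completeness,
# assemble the trait matrix, build both similarity matrices, cluster
# genomes (GFCs) and traits (LTCs), interpret, and (when hit tables are
# present) run the environmental mapping and synchrony stage. Every output
# is a TSV or JSON file under out_dir, plus a machine-readable
# summary.json and a run manifest.

# prefix bare synthetic/planted trait ids with their category code so they
# are comparable with assembled-matrix column ids
prefix_trait_ids <- function(ids, meta) {
  i <- match(ids, meta$trait_id)
  paste0(CATEGORY_PREFIX[meta$category[i]], ":", ids)
}

#' Run the complete atlas pipeline
#'
#' Expects under `input_dir` the files written by
#' [write_synthetic_inputs()] (or real data in the same formats):
#' `genomes.tsv`, `ko_annotations.tsv`, `module_definitions.json`, any
#' `trait_calls_<category>.tsv`, `interaction_traits.txt`,
#' `trait_tags.tsv`, and optionally `hits.tsv`, `pair_scores.tsv`,
#' `otu_abundances.tsv` for the environmental stage. A `config.json` in
#' the directory is used unless `cfg` is given.
#'
#' Stages: module completeness calls -> trait matrix assembly -> genome
#' similarity (phi) -> GFC clustering -> trait prevalence filter -> trait
#' similarity (phi, negatives zeroed, FDR-retained) -> LTC clustering ->
#' coherence / LTC presence / vitamin strategies / configurations /
#' interaction counts / size expectation / enrichment -> environmental
#' mapping and synchrony at each identity threshold.
#'
#' @param input_dir directory of input tables.
#' @param out_dir output directory (created).
#' @param cfg optional [ta_config()] overriding `config.json`.
#' @param run_sensitivity also run the q-scan / down-sampling sensitivity
#'   analysis (slower; off by default).
#' @return invisibly, the run manifest (list); all results are also on
#'   disk under `out_dir`.
#' @export
run_all <- function(input_dir, out_dir, cfg = NULL, run_sensitivity = FALSE) {
  t0 <- Sys.time()
  if (is.null(cfg)) {
    cfg_path <- file.path(input_dir, "config.json")
    cfg <- if (file.exists(cfg_path)) read_config(cfg_path) else ta_config()
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      ta_stop("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  genomes <- stage("read_genomes", read_genomes(file.path(input_dir, "genomes.tsv")))
  ko <- stage("read_ko", read_ko_table(file.path(input_dir, "ko_annotations.tsv")))
  defs <- stage("read_defs", read_module_defs(file.path(input_dir, "module_definitions.json")))
  calls <- list()
  for (cat in c("secondary_metabolite", "transporter",
                "phytohormone_pathway", "sulfur_catabolism")) {
    p <- file.path(input_dir, sprintf("trait_calls_%s.tsv", cat))
    if (file.exists(p)) calls[[cat]] <- read_trait_calls(p, cat)
  }
  int_path <- file.path(input_dir, "interaction_traits.txt")
  interaction_traits <- if (file.exists(int_path)) readLines(int_path) else character()
  tags_path <- file.path(input_dir, "trait_tags.tsv")
  trait_tags <- if (file.exists(tags_path)) read_tsv(tags_path) else NULL

  modules <- stage("module_reconstruction",
                   call_all(defs, ko, genome_ids = genomes$genome_id,
                            strict = cfg$strict_modules))
  write_tsv(modules$calls, file.path(out_dir, "module_calls.tsv"))

  tm <- stage("assemble_matrix",
              assemble_trait_matrix(modules$matrix, calls,
                                    interaction_traits, trait_tags))
  write_trait_matrix(tm, file.path(out_dir, "trait_matrix.tsv"))

  # genomes x genomes similarity on the full matrix; negative genome
  # correlations pass through but are logged
  sim_g <- stage("genome_similarity",
                 suppressWarnings(build_similarity(tm, "genome",
                                                   alpha = cfg$fdr_alpha)))
  if (sim_g$n_negative > 0) {
    note("genome similarity: %d negative correlations passed through",
         sim_g$n_negative)
  }
  gfc_res <- stage("gfc_clustering",
                   affinity_propagation(set_preference(sim_g$S, cfg$q_preference),
                                        damping = cfg$ap_damping,
                                        maxit = cfg$ap_maxit,
                                        convits = cfg$ap_convits,
                                        jitter = cfg$ap_jitter,
                                        seed = cfg$seed))
  gfc <- gfc_res$cluster
  write_tsv(data.frame(genome_id = names(gfc), gfc_id = unname(gfc),
                       exemplar_id = gfc_res$exemplars[as.character(gfc)]),
            file.path(out_dir, "clusters_gfc.tsv"))

  # traits: prevalence prefilter, then phi with negative zeroing and FDR
  pf <- stage("prevalence_filter",
              prevalence_filter(tm, cfg$prevalence_min, cfg$min_count))
  if (length(pf$removed)) {
    note("prevalence filter removed %d trait(s)", length(pf$removed))
  }
  sim_t <- stage("trait_similarity",
                 suppressWarnings(build_similarity(pf$matrix, "trait",
                                                   alpha = cfg$fdr_alpha)))
  write_tsv(sim_t$pairs, file.path(out_dir, "trait_pairs.tsv"))
  ltc_res <- stage("ltc_clustering",
                   affinity_propagation(set_preference(sim_t$S, cfg$q_preference),
                                        damping = cfg$ap_damping,
                                        maxit = cfg$ap_maxit,
                                        convits = cfg$ap_convits,
                                        jitter = cfg$ap_jitter,
                                        seed = cfg$seed))
  ltc <- ltc_res$cluster
  write_tsv(data.frame(trait_id = names(ltc), ltc_id = unname(ltc),
                       exemplar_id = ltc_res$exemplars[as.character(ltc)]),
            file.path(out_dir, "clusters_ltc.tsv"))

  coherence <- stage("coherence", classify_coherence(gfc, genomes))
  write_tsv(coherence, file.path(out_dir, "coherence.tsv"))

  ltcs <- stage("ltc_presence",
                ltc_presence(pf$matrix, ltc, gfc, cfg, phi_raw = sim_t$phi_raw))
  write_tsv(ltcs$summary, file.path(out_dir, "ltc_summary.tsv"))
  write_tsv(data.frame(genome_id = rownames(ltcs$by_genome),
                       ltcs$by_genome, check.names = FALSE),
            file.path(out_dir, "ltc_by_genome.tsv"))
  write_tsv(data.frame(gfc_id = rownames(ltcs$by_gfc),
                       ltcs$by_gfc, check.names = FALSE),
            file.path(out_dir, "ltc_by_gfc.tsv"))

  vitamins <- stage("vitamins", classify_vitamins(tm))
  write_tsv(vitamins, file.path(out_dir, "vitamin_profiles.tsv"))
  configs <- stage("configurations", enumerate_configurations(vitamins))
  write_tsv(configs, file.path(out_dir, "configurations.tsv"))

  icounts <- stage("interaction_counts",
                   count_interaction_traits(tm, genomes))
  write_tsv(icounts, file.path(out_dir, "interaction_counts.tsv"))
  sizes <- stage("size_expectation",
                 size_expectation(icounts, genomes,
                                  n_permutations = cfg$n_permutations,
                                  seed = cfg$seed))
  write_tsv(sizes$per_genome, file.path(out_dir, "size_residuals.tsv"))
  write_tsv(sizes$per_taxon, file.path(out_dir, "size_residuals_taxon.tsv"))
  enrich <- stage("enrichment",
                  enrichment_test(tm, gfc, n_permutations = cfg$n_permutations,
                                  seed = cfg$seed))
  write_tsv(enrich, file.path(out_dir, "enrichment.tsv"))

  sens <- NULL
  if (run_sensitivity) {
    sens <- stage("sensitivity", sensitivity_analysis(tm, genomes, cfg))
    jsonlite::write_json(sens, file.path(out_dir, "sensitivity.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  env_summary <- NULL
  hits_path <- file.path(input_dir, "hits.tsv")
  if (file.exists(hits_path)) {
    hits <- stage("read_hits", read_hits(hits_path))
    pairs <- read_tsv(file.path(input_dir, "pair_scores.tsv"))
    abund_path <- file.path(input_dir, "otu_abundances.tsv")
    abund <- if (file.exists(abund_path)) read_tsv(abund_path) else NULL
    env_summary <- list()
    for (thr in cfg$identity_thresholds) {
      mapping <- stage("map_otus", map_otus(hits, gfc, thr, cfg$max_hits))
      write_tsv(mapping, file.path(out_dir, sprintf("otu_mapping_%s.tsv", thr)))
      lab <- label_pairs(pairs, mapping)
      syn <- if (length(unique(lab$group)) == 2L) {
        stage("synchrony", synchrony_test(lab, cfg$n_permutations, cfg$seed))
      } else NULL
      cf <- if (!is.null(abund)) community_fraction(abund, mapping) else NULL
      env_summary[[as.character(thr)]] <- list(
        threshold = thr,
        n_mapped = sum(mapping$mapped),
        n_otus = nrow(mapping),
        community_fraction_mean = if (!is.null(cf)) cf$mean else NA,
        synchrony = if (!is.null(syn)) unclass(syn) else NULL)
    }
    jsonlite::write_json(env_summary, file.path(out_dir, "synchrony_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  summary <- list(
    n_genomes = nrow(genomes),
    n_traits = ncol(tm$values),
    n_traits_clustered = ncol(pf$matrix$values),
    n_gfcs = length(gfc_res$exemplars),
    n_ltcs = length(ltc_res$exemplars),
    gfc_converged = gfc_res$converged,
    ltc_converged = ltc_res$converged,
    coherence = as.list(table(coherence$label)),
    ltc_categories = as.list(table(ltcs$summary$category)),
    n_unclustered_traits = length(ltcs$unclustered_traits),
    background_mean_r = ltcs$background_mean_r,
    vitamin_configurations_observed = attr(configs, "n_observed"),
    settings_used = list(q = cfg$q_preference, fdr_alpha = cfg$fdr_alpha,
                         prevalence_rule = "count/n >= min_frac (exact)",
                         module_rule = if (cfg$strict_modules) "strict"
                           else "one missing reaction allowed at >=3 reactions",
                         t_test = "Welch one-sided primary",
                         fdr_method = "BH"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    config = unclass(cfg),
    inputs = list(dir = input_dir,
                  files = list.files(input_dir)),
    outputs = list.files(out_dir),
    warnings = warnings_log,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(manifest, list(summary = summary, gfc = gfc, ltc = ltc,
                             trait_matrix = tm, env = env_summary)))
}

#' Human-readable run report
#'
#' Composes a markdown summary (cluster counts, coherence breakdown,
#' vitamin strategy table, LTC categories) strictly from the result tables
#' written by [run_all()]. Regeneration is idempotent; the environmental
#' section is omitted when that stage did not run.
#'
#' @param out_dir directory written by [run_all()].
#' @return the report text (character), invisibly written to
#'   `report.md`.
#' @export
report <- function(out_dir) {
  need <- function(f) {
    p <- file.path(out_dir, f)
    if (!file.exists(p)) ta_stop("missing result table: %s", f)
    p
  }
  gfc <- read_tsv(need("clusters_gfc.tsv"))
  ltc <- read_tsv(need("clusters_ltc.tsv"))
  coh <- read_tsv(need("coherence.tsv"))
  ltcs <- read_tsv(need("ltc_summary.tsv"))
  vit <- read_tsv(need("vitamin_profiles.tsv"))
  lines <- c(
    "# Trait atlas run report", "",
    sprintf("- genomes: %d in %d GFCs", length(unique(gfc$genome_id)),
            length(unique(gfc$gfc_id))),
    sprintf("- clustered traits: %d in %d LTCs", length(unique(ltc$trait_id)),
            length(unique(ltc$ltc_id))),
    "", "## Taxonomic coherence of GFCs", "")
  for (lb in c("monophyletic", "paraphyletic", "polyphyletic")) {
    lines <- c(lines, sprintf("- %s: %d", lb, sum(coh$label == lb)))
  }
  lines <- c(lines, "", "## LTC categories", "")
  for (ct in c("core", "common", "ancillary")) {
    lines <- c(lines, sprintf("- %s: %d", ct, sum(ltcs$category == ct)))
  }
  lines <- c(lines, sprintf("- unclustered LTCs: %d", sum(ltcs$unclustered)),
             "", "## B-vitamin strategies (genomes per strategy)", "")
  tab <- table(vit$vitamin, vit$strategy)
  for (v in rownames(tab)) {
    lines <- c(lines, sprintf("- %s: %s", v,
                              paste(sprintf("%s=%d", colnames(tab), tab[v, ]),
                                    collapse = ", ")))
  }
  syn_path <- file.path(out_dir, "synchrony_report.json")
  if (file.exists(syn_path)) {
    env <- jsonlite::read_json(syn_path)
    lines <- c(lines, "", "## Environmental mapping", "")
    for (thr in names(env)) {
      e <- env[[thr]]
      lines <- c(lines, sprintf(
        "- identity >= %s%%: %d/%d OTUs mapped%s%s", thr,
        e$n_mapped, e$n_otus,
        if (!is.null(e$community_fraction_mean) && !is.na(e$community_fraction_mean))
          sprintf(", mean mapped read fraction %.3f", e$community_fraction_mean)
        else "",
        if (length(e$synchrony))
          sprintf(", synchrony one-sided p = %.3g", e$synchrony$p_one_sided)
        else ""))
    }
  }
  text <- paste(lines, collapse = "\n")
  writeLines(text, file.path(out_dir, "report.md"))
  invisible(text)
}
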