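# Seeded synthetic-data generator. It emulates the statistical structure
# the pipeline assumes — genome blocks with shared trait repertoires
# (recoverable as GFCs), trait blocks with correlated presence
# (recoverable as LTCs), KO annotations with Bernoulli dropout, taxonomy
# with controllable cluster/taxon concordance, amplicon hit tables with
# controllable specificity, and OTU-pair synchrony scores with a planted
# same-GFC shift — so every downstream stage can be validated against a
# known planted truth.

#' Specification of a synthetic dataset
#'
#' Defaults correspond to the desk-scale validation conditions used
#' throughout the package: 150 genomes, 300 traits, 5 genome blocks, 6
#' linked-trait blocks, within-block trait occupancy 0.9 against a 0.05
#' background, KO annotation dropout 0.1, and genus labels agreeing with
#' the planted block 90% of the time.
#'
#' @param n_genomes,n_traits,n_gfc_blocks,n_ltc_blocks counts (>= 1).
#' @param block_trait_occupancy probability a genome carries a trait of a
#'   block it belongs to.
#' @param background_occupancy probability a genome carries an unrelated
#'   trait (noise).
#' @param annotation_dropout probability a truly present KO is unreported.
#' @param taxon_concordance probability a genome's genus label matches its
#'   planted block.
#' @param seed integer RNG seed; identical seeds give bit-identical data.
#' @return validated object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genomes = 150L, n_traits = 300L,
                           n_gfc_blocks = 5L, n_ltc_blocks = 6L,
                           block_trait_occupancy = 0.9,
                           background_occupancy = 0.05,
                           annotation_dropout = 0.1,
                           taxon_concordance = 0.9,
                           seed = 1L) {
  spec <- list(n_genomes = as.integer(n_genomes),
               n_traits = as.integer(n_traits),
               n_gfc_blocks = as.integer(n_gfc_blocks),
               n_ltc_blocks = as.integer(n_ltc_blocks),
               block_trait_occupancy = block_trait_occupancy,
               background_occupancy = background_occupancy,
               annotation_dropout = annotation_dropout,
               taxon_concordance = taxon_concordance,
               seed = as.integer(seed))
  for (f in c("n_genomes", "n_traits", "n_gfc_blocks", "n_ltc_blocks")) {
    if (is.na(spec[[f]]) || spec[[f]] < 1L) {
      ta_stop("synthetic spec field '%s' must be a count >= 1", f)
    }
  }
  for (f in c("block_trait_occupancy", "background_occupancy",
              "annotation_dropout", "taxon_concordance")) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      ta_stop("synthetic spec field '%s' must be a probability in [0,1]", f)
    }
  }
  if (spec$n_gfc_blocks > spec$n_genomes) {
    ta_stop("synthetic spec field 'n_gfc_blocks' exceeds n_genomes")
  }
  if (spec$n_ltc_blocks > spec$n_traits) {
    ta_stop("synthetic spec field 'n_ltc_blocks' exceeds n_traits")
  }
  structure(spec, class = "synthetic_spec")
}

# distinct carrier sets of GFC blocks per LTC block: singletons first,
# then pairs, so every trait block has a distinguishable genome support
ltc_carrier_sets <- function(n_ltc, n_gfc) {
  sets <- lapply(seq_len(n_gfc), identity)
  if (n_ltc > n_gfc) {
    prs <- utils::combn(n_gfc, min(2L, n_gfc), simplify = FALSE)
    sets <- c(sets, prs)
  }
  if (length(sets) < n_ltc) {
    ta_stop("cannot build %d distinct LTC carrier sets from %d GFC blocks",
            n_ltc, n_gfc)
  }
  sets[seq_len(n_ltc)]
}

#' Generate a planted-block trait matrix
#'
#' Genomes are assigned to `n_gfc_blocks` blocks and traits to
#' `n_ltc_blocks` linkage blocks; each linkage block is carried by a
#' distinct set of genome blocks. A genome carries a trait with
#' probability `block_trait_occupancy` when its block carries the trait's
#' linkage block, else `background_occupancy`. Six B-vitamin traits
#' (synthesis + transport for B1/B7/B12, drawn independently per genome)
#' are appended, and the traits of the first linkage block plus the
#' vitamin traits are flagged as interaction traits. The returned planted
#' truth records every assignment for recovery testing.
#'
#' @param spec a [synthetic_spec()].
#' @return list: `matrix` (a [trait_matrix()]), `truth` (list with
#'   `genome_block`, `trait_block`, `ltc_carriers`, `vitamin_states`,
#'   `interaction_block`, and a slot for `annotation_gaps`).
#' @export
gen_trait_matrix <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  set.seed(spec$seed)
  g_ids <- sprintf("G%03d", seq_len(spec$n_genomes))
  t_ids <- sprintf("T%03d", seq_len(spec$n_traits))
  genome_block <- setNames(rep(seq_len(spec$n_gfc_blocks),
                               length.out = spec$n_genomes), g_ids)
  trait_block <- setNames(rep(seq_len(spec$n_ltc_blocks),
                              length.out = spec$n_traits), t_ids)
  carriers <- ltc_carrier_sets(spec$n_ltc_blocks, spec$n_gfc_blocks)
  # carried[b, l]: does genome block b carry trait block l
  carried <- matrix(FALSE, spec$n_gfc_blocks, spec$n_ltc_blocks)
  for (l in seq_len(spec$n_ltc_blocks)) carried[carriers[[l]], l] <- TRUE
  p <- matrix(spec$background_occupancy, spec$n_genomes, spec$n_traits)
  in_block <- carried[genome_block, trait_block]   # n_genomes x n_traits
  p[in_block] <- spec$block_trait_occupancy
  values <- matrix(rbinom(length(p), 1L, p), nrow(p), ncol(p),
                   dimnames = list(g_ids, t_ids))
  # categories cycle through the five sources; kegg_module traits get KO
  # definitions in gen_ko_tables, the rest travel via call tables
  cats <- rep(c("kegg_module", "secondary_metabolite", "transporter",
                "phytohormone_pathway", "sulfur_catabolism"),
              length.out = spec$n_traits)
  # B-vitamin traits: synthesis (modules) and transport (transporters)
  vit_syn <- sprintf("vit%s_synthesis", VITAMINS)
  vit_trn <- sprintf("vit%s_transport", VITAMINS)
  syn_states <- matrix(rbinom(spec$n_genomes * 3L, 1L, 0.6),
                       spec$n_genomes, 3L, dimnames = list(g_ids, vit_syn))
  trn_states <- matrix(rbinom(spec$n_genomes * 3L, 1L, 0.5),
                       spec$n_genomes, 3L, dimnames = list(g_ids, vit_trn))
  values <- cbind(values, syn_states, trn_states)
  meta <- data.frame(
    trait_id = colnames(values),
    category = c(cats, rep("kegg_module", 3L), rep("transporter", 3L)),
    interaction = c(trait_block == 1L, rep(TRUE, 6L)),
    vitamin = c(rep(NA_character_, spec$n_traits), VITAMINS, VITAMINS),
    role = c(rep(NA_character_, spec$n_traits),
             rep("synthesis", 3L), rep("transport", 3L)),
    stringsAsFactors = FALSE)
  vitamin_states <- do.call(rbind, lapply(seq_along(VITAMINS), function(i) {
    data.frame(genome_id = g_ids, vitamin = VITAMINS[i],
               synthesis = syn_states[, i] == 1L,
               transport = trn_states[, i] == 1L,
               stringsAsFactors = FALSE)
  }))
  truth <- list(genome_block = genome_block, trait_block = trait_block,
                ltc_carriers = carriers, vitamin_states = vitamin_states,
                interaction_block = 1L,
                annotation_gaps = data.frame(genome_id = character(),
                                             trait_id = character(),
                                             stringsAsFactors = FALSE))
  list(matrix = trait_matrix(values, meta), truth = truth)
}

#' Generate module definitions for the module-category traits
#'
#' Each module-category trait gets a definition with 3-8 reactions
#' (smaller modules of 1-2 reactions are included at a low rate to
#' exercise the no-tolerance path). KO ids are unique across modules;
#' most reactions have a single singleton alternative, some have two
#' alternatives, and some alternatives are two-KO AND-complexes.
#'
#' @param tm a [trait_matrix()] (module traits are taken from its meta).
#' @param seed integer seed.
#' @return named list of [module_definition()] objects, one per
#'   module-category trait.
#' @export
gen_module_defs <- function(tm, seed = 1L) {
  set.seed(seed + 1L)
  mod_traits <- tm$meta$trait_id[tm$meta$category == "kegg_module"]
  ko_counter <- 0L
  next_ko <- function(k = 1L) {
    ids <- sprintf("K%05d", ko_counter + seq_len(k))
    ko_counter <<- ko_counter + k
    ids
  }
  defs <- lapply(mod_traits, function(tr) {
    n_rx <- sample(c(1L, 2L, 3:8), 1L,
                   prob = c(0.05, 0.05, rep(0.9 / 6, 6)))
    reactions <- lapply(seq_len(n_rx), function(i) {
      kind <- sample(c("single", "two_alts", "complex"), 1L,
                     prob = c(0.6, 0.25, 0.15))
      switch(kind,
             single = list(next_ko(1L)),
             two_alts = list(next_ko(1L), next_ko(1L)),
             complex = list(next_ko(2L)))
    })
    module_definition(tr, reactions)
  })
  setNames(defs, mod_traits)
}

#' Generate KO annotation tables from planted module traits
#'
#' For each genome and each present module-category trait, the KOs of one
#' alternative per reaction are emitted, then deleted independently with
#' probability `dropout` (a simple model of incomplete functional
#' annotation). Where dropout breaks completeness beyond the
#' one-missing-reaction tolerance, the genome/trait pair is recorded in
#' the truth as a planted annotation gap. Absent traits emit no KOs.
#'
#' @param tm a [trait_matrix()].
#' @param defs module definitions from [gen_module_defs()] (every
#'   module-category trait must have one).
#' @param dropout per-KO deletion probability.
#' @param seed integer seed.
#' @return list: `ko_table` (long data frame `genome_id`, `ko`),
#'   `annotation_gaps` (data frame of pairs where reconstruction will
#'   fail).
#' @export
gen_ko_tables <- function(tm, defs, dropout = 0.1, seed = 1L) {
  mod_traits <- tm$meta$trait_id[tm$meta$category == "kegg_module"]
  missing <- setdiff(mod_traits, names(defs))
  if (length(missing)) {
    ta_stop("module trait(s) without definition: %s",
            paste(head(missing, 5L), collapse = ", "))
  }
  set.seed(seed + 2L)
  rows <- list()
  gaps <- list()
  for (g in rownames(tm$values)) {
    kos <- character()
    for (tr in mod_traits) {
      if (tm$values[g, tr] != 1L) next
      d <- defs[[tr]]
      emitted <- unlist(lapply(d$reactions, function(rx) rx[[1L]]))
      if (dropout > 0) {
        emitted <- emitted[runif(length(emitted)) >= dropout]
      }
      kos <- c(kos, emitted)
      if (!call_module(d, emitted)$complete) {
        gaps[[length(gaps) + 1L]] <- data.frame(genome_id = g, trait_id = tr,
                                                stringsAsFactors = FALSE)
      }
    }
    if (length(kos)) {
      rows[[length(rows) + 1L]] <- data.frame(genome_id = g, ko = unique(kos),
                                              stringsAsFactors = FALSE)
    }
  }
  list(ko_table = if (length(rows)) do.call(rbind, rows) else
         data.frame(genome_id = character(), ko = character()),
       annotation_gaps = if (length(gaps)) do.call(rbind, gaps) else
         data.frame(genome_id = character(), trait_id = character()))
}

#' Generate taxonomy and genome metadata from the planted truth
#'
#' Each planted genome block corresponds to a genus; a genome gets its
#' block's genus with probability `concordance`, otherwise a random other
#' genus from the pool (block genera plus two noise genera). Higher ranks
#' are synthesized by deterministic grouping of genera (families of 2
#' genera, orders of 4, classes of 8, one phylum per 16), so coherence at
#' genus level is the planted signal. Genome sizes, completeness and
#' contamination are drawn at realistic marine-isolate scales.
#'
#' @param truth planted truth from [gen_trait_matrix()].
#' @param concordance probability the genus matches the planted block.
#' @param seed integer seed.
#' @return data frame of genome records (id, six ranks, habitat,
#'   genome_size, completeness, contamination).
#' @export
gen_taxonomy <- function(truth, concordance = 0.9, seed = 1L) {
  set.seed(seed + 3L)
  g_ids <- names(truth$genome_block)
  n_blocks <- max(truth$genome_block)
  pool <- c(sprintf("Genus_%02d", seq_len(n_blocks)),
            sprintf("Genus_x%d", 1:2))
  own <- sprintf("Genus_%02d", truth$genome_block)
  match_block <- runif(length(g_ids)) < concordance
  genus <- own
  for (i in which(!match_block)) {
    genus[i] <- sample(setdiff(pool, own[i]), 1L)
  }
  gi <- match(genus, pool)
  df <- data.frame(
    genome_id = g_ids,
    domain = "Bacteria",
    phylum = sprintf("Phylum_%02d", ceiling(gi / 16)),
    class = sprintf("Class_%02d", ceiling(gi / 8)),
    order = sprintf("Order_%02d", ceiling(gi / 4)),
    family = sprintf("Family_%02d", ceiling(gi / 2)),
    genus = genus,
    habitat = sample(HABITATS, length(g_ids), replace = TRUE,
                     prob = c(0.85, 0.06, 0.03, 0.02, 0.02, 0.02)),
    genome_size = round(rnorm(length(g_ids), 4e6, 5e5)),
    completeness = round(runif(length(g_ids), 95, 100), 2),
    contamination = round(runif(length(g_ids), 0, 5), 2),
    stringsAsFactors = FALSE)
  df
}

#' Generate environmental tables: amplicon hits and OTU-pair synchrony
#' scores
#'
#' Each OTU belongs to a planted genome block. Its alignment hits (3 to
#' `max_hits`) fall in genomes of that block with probability
#' `1 - specificity_noise`, otherwise anywhere else; identities are drawn
#' in \[97, 100\]. Pair scores are Gaussian with unit standard deviation;
#' same-block pairs are shifted up by `effect_size` (in sd units). A
#' per-sample OTU read-count table is included for community-fraction
#' summaries.
#'
#' @param truth planted truth from [gen_trait_matrix()].
#' @param n_otus number of OTUs.
#' @param specificity_noise probability a hit falls outside the OTU's
#'   block.
#' @param effect_size planted same-block mean shift of the synchrony
#'   score, in units of its standard deviation.
#' @param seed integer seed.
#' @param n_samples samples in the abundance table.
#' @param max_hits cap on hits per OTU.
#' @return list: `hits`, `pairs`, `abundances`, `otu_truth`.
#' @export
gen_env_tables <- function(truth, n_otus = 60L, specificity_noise = 0,
                           effect_size = 0, seed = 1L, n_samples = 10L,
                           max_hits = 20L) {
  set.seed(seed + 4L)
  g_ids <- names(truth$genome_block)
  n_blocks <- max(truth$genome_block)
  otu_ids <- sprintf("OTU%03d", seq_len(n_otus))
  otu_block <- setNames(rep(seq_len(n_blocks), length.out = n_otus), otu_ids)
  hits <- list()
  for (o in otu_ids) {
    n_h <- sample(3:max_hits, 1L)
    own <- g_ids[truth$genome_block == otu_block[o]]
    other <- g_ids[truth$genome_block != otu_block[o]]
    from_own <- runif(n_h) >= specificity_noise
    genome <- ifelse(from_own,
                     sample(own, n_h, replace = TRUE),
                     sample(other, n_h, replace = TRUE))
    hits[[o]] <- data.frame(otu_id = o, genome_id = genome,
                            percent_identity = round(runif(n_h, 97, 100), 2),
                            bit_rank = seq_len(n_h), stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, hits)
  cmb <- utils::combn(otu_ids, 2L)
  same <- otu_block[cmb[1L, ]] == otu_block[cmb[2L, ]]
  pairs <- data.frame(otu_a = cmb[1L, ], otu_b = cmb[2L, ],
                      score = rnorm(ncol(cmb)) + effect_size * same,
                      stringsAsFactors = FALSE)
  abundances <- expand.grid(otu_id = otu_ids,
                            sample_id = sprintf("S%02d", seq_len(n_samples)),
                            stringsAsFactors = FALSE)
  abundances$reads <- rpois(nrow(abundances), 100)
  list(hits = hits, pairs = pairs, abundances = abundances,
       otu_truth = data.frame(otu_id = otu_ids, block = unname(otu_block),
                              stringsAsFactors = FALSE))
}

#' Write a complete synthetic input directory
#'
#' Generates one coherent dataset from a [synthetic_spec()] and writes the
#' exact files [run_all()] reads: `genomes.tsv`, `ko_annotations.tsv`,
#' `module_definitions.json`, `trait_calls_<category>.tsv` for the
#' non-module categories, `trait_tags.tsv`, `interaction_traits.txt`,
#' `hits.tsv`, `pair_scores.tsv`, `otu_abundances.tsv`, `config.json`, and
#' the planted `truth.json`.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @param cfg a [ta_config()] written alongside the inputs.
#' @param env_effect_size planted same-GFC synchrony shift.
#' @param env_specificity_noise hit-table specificity noise.
#' @return invisibly, a list with the in-memory dataset (`matrix`,
#'   `truth`, `defs`, `ko`, `genomes`, `env`).
#' @export
write_synthetic_inputs <- function(spec, dir, cfg = ta_config(seed = spec$seed),
                                   env_effect_size = 3, env_specificity_noise = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- gen_trait_matrix(spec)
  tm <- gen$matrix
  defs <- gen_module_defs(tm, seed = spec$seed)
  ko <- gen_ko_tables(tm, defs, dropout = spec$annotation_dropout,
                      seed = spec$seed)
  gen$truth$annotation_gaps <- ko$annotation_gaps
  genomes <- gen_taxonomy(gen$truth, concordance = spec$taxon_concordance,
                          seed = spec$seed)
  env <- gen_env_tables(gen$truth, specificity_noise = env_specificity_noise,
                        effect_size = env_effect_size, seed = spec$seed)
  write_tsv(genomes, file.path(dir, "genomes.tsv"))
  write_tsv(ko$ko_table, file.path(dir, "ko_annotations.tsv"))
  write_module_defs(defs, file.path(dir, "module_definitions.json"))
  for (cat in c("secondary_metabolite", "transporter",
                "phytohormone_pathway", "sulfur_catabolism")) {
    tr <- tm$meta$trait_id[tm$meta$category == cat]
    df <- data.frame(genome_id = rownames(tm$values),
                     tm$values[, tr, drop = FALSE],
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, file.path(dir, sprintf("trait_calls_%s.tsv", cat)))
  }
  tags <- tm$meta[!is.na(tm$meta$vitamin),
                  c("trait_id", "category", "vitamin", "role")]
  tags$trait_id <- paste0(CATEGORY_PREFIX[tags$category], ":", tags$trait_id)
  write_tsv(tags[, c("trait_id", "vitamin", "role")],
            file.path(dir, "trait_tags.tsv"))
  int_ids <- tm$meta$trait_id[tm$meta$interaction]
  int_pref <- paste0(CATEGORY_PREFIX[tm$meta$category[match(int_ids, tm$meta$trait_id)]],
                     ":", int_ids)
  writeLines(int_pref, file.path(dir, "interaction_traits.txt"))
  write_tsv(env$hits, file.path(dir, "hits.tsv"))
  write_tsv(env$pairs, file.path(dir, "pair_scores.tsv"))
  write_tsv(env$abundances, file.path(dir, "otu_abundances.tsv"))
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  truth_json <- list(
    genome_block = as.list(gen$truth$genome_block),
    trait_block = as.list(gen$truth$trait_block),
    ltc_carriers = gen$truth$ltc_carriers,
    interaction_block = gen$truth$interaction_block,
    vitamin_states = gen$truth$vitamin_states,
    annotation_gaps = gen$truth$annotation_gaps,
    otu_block = setNames(as.list(env$otu_truth$block), env$otu_truth$otu_id))
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(list(matrix = tm, truth = gen$truth, defs = defs,
                 ko = ko$ko_table, genomes = genomes, env = env))
}
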