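# Interpretation of the raw clusterings in GFC/LTC terms: taxonomic
# coherence of genome clusters, presence and categories of linked trait
# clusters, interaction-trait enrichment, genome-size expectation
# residuals, and the q / down-sampling sensitivity analysis.

#' Taxonomic coherence of genome functional clusters
#'
#' A GFC is monophyletic (taxonomically coherent) when all grouped genomes
#' belong to the same taxon at the evaluated rank AND all genomes of that
#' taxon fall in that GFC. With more than one contained taxon the GFC is
#' polyphyletic; with exactly one taxon but further genomes of that taxon
#' elsewhere it is paraphyletic. Genomes lacking a taxon label are excluded
#' with a warning.
#'
#' @param gfc named integer vector, genome_id -> GFC id.
#' @param taxonomy data frame with `genome_id` and rank columns.
#' @param rank taxonomic rank to evaluate (default "genus").
#' @return data frame: `gfc_id`, `rank`, `label`, `n_genomes`,
#'   `taxa_contained` (comma-joined), `n_taxon_elsewhere`.
#' @export
classify_coherence <- function(gfc, taxonomy, rank = "genus") {
  if (!rank %in% names(taxonomy)) ta_stop("rank '%s' not in taxonomy table", rank)
  taxon <- setNames(as.character(taxonomy[[rank]]), taxonomy$genome_id)
  tax <- taxon[names(gfc)]
  if (anyNA(tax)) {
    ta_warn("excluding %d genome(s) without a '%s' label", sum(is.na(tax)), rank)
    gfc <- gfc[!is.na(tax)]
    tax <- tax[names(gfc)]
  }
  out <- lapply(sort(unique(gfc)), function(cl) {
    members <- names(gfc)[gfc == cl]
    taxa <- unique(tax[members])
    if (length(taxa) > 1L) {
      label <- "polyphyletic"
      elsewhere <- NA_integer_
    } else {
      same_taxon <- names(tax)[tax == taxa]
      elsewhere <- length(setdiff(same_taxon, members))
      label <- if (elsewhere == 0L) "monophyletic" else "paraphyletic"
    }
    data.frame(gfc_id = cl, rank = rank, label = label,
               n_genomes = length(members),
               taxa_contained = paste(sort(taxa), collapse = ","),
               n_taxon_elsewhere = elsewhere, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Presence, categories and within-cluster correlation of linked trait
#' clusters
#'
#' An LTC is present in a genome when strictly more than `ltc_genome_frac`
#' (default 50%) of its traits are present, and present in a GFC when it is
#' present in strictly more than `ltc_gfc_frac` of the grouped genomes.
#' Genome-wide presence classifies the LTC as core (> `core_frac`),
#' ancillary (<= `ancillary_frac`) or common (otherwise). Traits of LTCs
#' present in no GFC are flagged unclustered. `mean_within_r` is the mean
#' raw (pre-threshold) phi over the LTC's trait pairs, comparable against
#' the background mean over all trait pairs.
#'
#' @param tm a [trait_matrix()].
#' @param ltc named integer vector, trait_id -> LTC id.
#' @param gfc named integer vector, genome_id -> GFC id.
#' @param cfg a [ta_config()].
#' @param phi_raw optional pre-threshold trait phi matrix (from
#'   [build_similarity()]); without it `mean_within_r` is NA.
#' @return list: `summary` (per-LTC data frame), `by_genome` (logical
#'   genomes x LTCs), `by_gfc` (logical GFCs x LTCs), `unclustered_traits`,
#'   `background_mean_r`.
#' @export
ltc_presence <- function(tm, ltc, gfc, cfg = ta_config(), phi_raw = NULL) {
  ltc_ids <- sort(unique(ltc))
  if (!length(ltc_ids)) ta_stop("empty LTC assignment")
  genomes <- rownames(tm$values)
  by_genome <- matrix(FALSE, length(genomes), length(ltc_ids),
                      dimnames = list(genomes, as.character(ltc_ids)))
  gfc_ids <- sort(unique(gfc))
  by_gfc <- matrix(FALSE, length(gfc_ids), length(ltc_ids),
                   dimnames = list(as.character(gfc_ids), as.character(ltc_ids)))
  bg_r <- if (!is.null(phi_raw))
    mean(phi_raw[upper.tri(phi_raw)]) else NA_real_
  rows <- lapply(seq_along(ltc_ids), function(j) {
    l <- ltc_ids[j]
    traits <- names(ltc)[ltc == l]
    if (!length(traits)) ta_stop("LTC %s has no traits", l)
    frac <- rowMeans(tm$values[, traits, drop = FALSE])
    present_g <- frac > cfg$ltc_genome_frac
    by_genome[, j] <<- present_g
    for (cl in gfc_ids) {
      members <- names(gfc)[gfc == cl]
      members <- intersect(members, genomes)
      by_gfc[as.character(cl), j] <<-
        mean(present_g[members]) > cfg$ltc_gfc_frac
    }
    gp <- mean(present_g)
    category <- if (gp > cfg$core_frac) "core"
      else if (gp <= cfg$ancillary_frac) "ancillary" else "common"
    mwr <- if (!is.null(phi_raw) && length(traits) > 1L) {
      sub <- phi_raw[traits, traits]
      mean(sub[upper.tri(sub)])
    } else NA_real_
    data.frame(ltc_id = l, n_traits = length(traits),
               mean_within_r = mwr, genome_presence = gp,
               category = category,
               n_gfcs_present = sum(by_gfc[, j]),
               unclustered = !any(by_gfc[, j]),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  unclustered_traits <- names(ltc)[ltc %in% summary$ltc_id[summary$unclustered]]
  list(summary = summary, by_genome = by_genome, by_gfc = by_gfc,
       unclustered_traits = unclustered_traits, background_mean_r = bg_r)
}

#' Interaction-trait enrichment of GFCs
#'
#' Permutation test: the statistic is each GFC's mean interaction-trait
#' count; the null shuffles genome labels across GFCs (preserving GFC
#' sizes). Empirical one-sided p-values carry the +1 correction
#' (p = (1 + #null >= observed) / (1 + B)) and are BH-adjusted across
#' GFCs. Singleton GFCs are flagged low-power.
#'
#' @param tm a [trait_matrix()] with interaction flags.
#' @param gfc named integer vector, genome_id -> GFC id.
#' @param n_permutations number of label shuffles (>= 100).
#' @param seed integer seed.
#' @return data frame: `gfc_id`, `n_genomes`, `mean_interaction_traits`,
#'   `p`, `p_adj`, `low_power`.
#' @export
enrichment_test <- function(tm, gfc, n_permutations = 999L, seed = 1L) {
  if (n_permutations < 100L) ta_stop("n_permutations must be >= 100")
  counts <- count_interaction_traits(tm)
  x <- setNames(counts$n_interaction_traits, counts$genome_id)[names(gfc)]
  gfc_ids <- sort(unique(gfc))
  obs <- vapply(gfc_ids, function(cl) mean(x[gfc == cl]), 0)
  set.seed(seed)
  ge <- integer(length(gfc_ids))
  f <- factor(gfc, levels = gfc_ids)
  for (b in seq_len(n_permutations)) {
    xs <- sample(x)
    null_means <- tapply(xs, f, mean)
    ge <- ge + as.integer(null_means >= obs - 1e-12)
  }
  p <- (1 + ge) / (1 + n_permutations)
  data.frame(gfc_id = gfc_ids,
             n_genomes = as.integer(table(f)),
             mean_interaction_traits = obs,
             p = p, p_adj = bh_adjust(p),
             low_power = as.integer(table(f)) < 2L,
             stringsAsFactors = FALSE)
}

#' Interaction-trait load relative to genome size
#'
#' Fits the least-squares line of interaction-trait count on genome size,
#' reports per-genome residuals ("more interaction traits than expected by
#' genome size" = positive residual), and per-taxon mean residuals with a
#' permutation p-value (residuals shuffled across genomes).
#'
#' @param profiles data frame from [count_interaction_traits()] including
#'   `genome_size`.
#' @param taxonomy data frame with `genome_id` and rank columns.
#' @param rank rank at which taxa are summarized.
#' @param n_permutations permutations for the per-taxon test.
#' @param seed integer seed.
#' @return list: `model` (intercept, slope), `per_genome`, `per_taxon`.
#' @export
size_expectation <- function(profiles, taxonomy, rank = "genus",
                             n_permutations = 999L, seed = 1L) {
  if (nrow(profiles) < 3L) ta_stop("need >= 3 genomes with sizes")
  if (anyNA(profiles$genome_size)) ta_stop("missing genome_size values")
  if (var(profiles$genome_size) == 0) ta_stop("zero genome-size variance")
  fit <- lm(n_interaction_traits ~ genome_size, data = profiles)
  per_genome <- data.frame(genome_id = profiles$genome_id,
                           n_interaction_traits = profiles$n_interaction_traits,
                           genome_size = profiles$genome_size,
                           residual = unname(residuals(fit)),
                           stringsAsFactors = FALSE)
  taxon <- setNames(as.character(taxonomy[[rank]]), taxonomy$genome_id)
  per_genome$taxon <- taxon[per_genome$genome_id]
  known <- !is.na(per_genome$taxon)
  f <- factor(per_genome$taxon[known])
  obs <- tapply(per_genome$residual[known], f, mean)
  set.seed(seed)
  ge <- numeric(nlevels(f))
  res <- per_genome$residual[known]
  for (b in seq_len(n_permutations)) {
    null_means <- tapply(sample(res), f, mean)
    ge <- ge + as.numeric(abs(null_means) >= abs(obs) - 1e-12)
  }
  per_taxon <- data.frame(taxon = levels(f),
                          n_genomes = as.integer(table(f)),
                          mean_residual = as.numeric(obs),
                          p = (1 + ge) / (1 + n_permutations),
                          stringsAsFactors = FALSE)
  list(model = coef(fit), per_genome = per_genome, per_taxon = per_taxon)
}

# cluster the genomes of a trait matrix at a given preference quantile
cluster_genomes <- function(tm, cfg, q = cfg$q_preference) {
  sim <- suppressWarnings(build_similarity(tm, kind = "genome",
                                           alpha = cfg$fdr_alpha))
  S <- set_preference(sim$S, q)
  affinity_propagation(S, damping = cfg$ap_damping, maxit = cfg$ap_maxit,
                       convits = cfg$ap_convits, jitter = cfg$ap_jitter,
                       seed = cfg$seed)
}

#' Sensitivity analysis of the clustering
#'
#' Re-runs the genome clustering (a) over a grid of preference quantiles
#' q, reporting the cluster count per q, and (b) after down-sampling
#' overrepresented taxa (taxa holding more than `overrep_frac` of genomes)
#' to 80 / 60 / 40% of their genome coverage (sampling without
#' replacement, seeded), reporting the adjusted Rand index of each
#' replicate against the full-data clustering restricted to the retained
#' genomes.
#'
#' @param tm a [trait_matrix()].
#' @param taxonomy data frame with `genome_id` and rank columns.
#' @param cfg a [ta_config()]; uses `downsample_fracs`, `overrep_frac`.
#' @param q_grid preference quantiles to scan.
#' @param rank rank defining "taxon" for down-sampling.
#' @param n_reps down-sampling replicates per fraction.
#' @return list: `q_scan` (q, n_clusters), `downsampling` (frac, rep,
#'   n_genomes, ari).
#' @export
sensitivity_analysis <- function(tm, taxonomy, cfg = ta_config(),
                                 q_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                 rank = "genus", n_reps = 2L) {
  full <- cluster_genomes(tm, cfg)
  q_scan <- data.frame(q = q_grid, n_clusters = NA_integer_)
  for (i in seq_along(q_grid)) {
    r <- cluster_genomes(tm, cfg, q = q_grid[i])
    q_scan$n_clusters[i] <- length(r$exemplars)
  }
  taxon <- setNames(as.character(taxonomy[[rank]]), taxonomy$genome_id)
  tab <- table(taxon[rownames(tm$values)])
  overrep <- names(tab)[tab > cfg$overrep_frac * nrow(tm$values)]
  rows <- list()
  set.seed(cfg$seed)
  for (frac in cfg$downsample_fracs) {
    for (rep in seq_len(n_reps)) {
      keep <- rownames(tm$values)
      for (tx in overrep) {
        members <- names(taxon)[!is.na(taxon) & taxon == tx]
        members <- intersect(members, rownames(tm$values))
        n_keep <- max(1L, floor(frac * length(members)))
        drop <- setdiff(members, sample(members, n_keep))
        keep <- setdiff(keep, drop)
      }
      if (length(keep) < 2L) {
        ta_warn("down-sampling at %.0f%% left <2 genomes; replicate skipped",
                100 * frac)
        next
      }
      sub <- tm_subset(tm, genomes = keep)
      r <- tryCatch(cluster_genomes(sub, cfg),
                    error = function(e) NULL)
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        frac = frac, rep = rep, n_genomes = length(keep),
        ari = ari(r$cluster, full$cluster[keep]))
    }
  }
  list(q_scan = q_scan,
       downsampling = if (length(rows)) do.call(rbind, rows) else
         data.frame(frac = numeric(), rep = integer(),
                    n_genomes = integer(), ari = numeric()),
       overrepresented_taxa = overrep,
       full_n_clusters = length(full$exemplars))
}
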