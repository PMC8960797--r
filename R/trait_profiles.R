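# Per-genome trait summaries: prevalence prefiltering, B-vitamin
# acquisition strategies, vitamin configuration enumeration, and
# interaction-trait counts.

#' Filter traits by prevalence
#'
#' Keeps traits present in at least `min_frac` of genomes, evaluated as
#' count / n_genomes >= min_frac with no rounding. `min_count` overrides
#' the fractional rule with an absolute genome count.
#'
#' @param tm a [trait_matrix()].
#' @param min_frac minimum prevalence fraction in \[0, 1\].
#' @param min_count optional absolute count override.
#' @return list with `matrix` (filtered [trait_matrix()]) and `removed`
#'   (dropped trait ids).
#' @export
prevalence_filter <- function(tm, min_frac = 0.03, min_count = NULL) {
  if (min_frac < 0 || min_frac > 1) ta_stop("min_frac must lie in [0,1]")
  n <- nrow(tm$values)
  counts <- colSums(tm$values)
  keep <- if (!is.null(min_count)) counts >= min_count else
    counts / n >= min_frac - 1e-12
  if (!any(keep)) ta_stop("prevalence filter removed every trait; nothing to cluster")
  list(matrix = tm_subset(tm, traits = colnames(tm$values)[keep]),
       removed = colnames(tm$values)[!keep])
}

VITAMINS <- c("B1", "B7", "B12")
STRATEGIES <- c("none", "consumer", "independent", "flexible")

# (synthesis, transport) -> strategy; the four states are exhaustive and
# mutually exclusive
vitamin_strategy <- function(synthesis, transport) {
  ifelse(synthesis & transport, "flexible",
         ifelse(synthesis, "independent",
                ifelse(transport, "consumer", "none")))
}

#' Classify B-vitamin acquisition strategies
#'
#' For each genome and each vitamin (B1, B7, B12): synthesis is the OR over
#' that vitamin's biosynthesis traits, transport the OR over its
#' transporter traits (transporters are assumed to mediate uptake). The
#' strategy follows the published scheme: "consumer" = transporter without
#' biosynthesis, "independent" = biosynthesis without transporter,
#' "flexible" = both, "none" = neither. Vitamin tagging comes from the
#' trait metadata columns `vitamin` and `role`.
#'
#' @param tm a [trait_matrix()] whose meta tags at least one trait per
#'   vitamin.
#' @param vitamins vitamins to classify.
#' @return data frame: `genome_id`, `vitamin`, `synthesis`, `transport`,
#'   `strategy`.
#' @export
classify_vitamins <- function(tm, vitamins = VITAMINS) {
  meta <- tm$meta
  out <- list()
  for (v in vitamins) {
    syn_tr <- meta$trait_id[!is.na(meta$vitamin) & meta$vitamin == v &
                              !is.na(meta$role) & meta$role == "synthesis"]
    trn_tr <- meta$trait_id[!is.na(meta$vitamin) & meta$vitamin == v &
                              !is.na(meta$role) & meta$role == "transport"]
    if (!length(syn_tr) && !length(trn_tr)) {
      ta_stop("no trait tagged for vitamin %s", v)
    }
    if (!length(syn_tr)) ta_warn("vitamin %s: no synthesis trait tagged; synthesis = FALSE", v)
    if (!length(trn_tr)) ta_warn("vitamin %s: no transport trait tagged; transport = FALSE", v)
    syn <- if (length(syn_tr))
      rowSums(tm$values[, syn_tr, drop = FALSE]) > 0 else
      rep(FALSE, nrow(tm$values))
    trn <- if (length(trn_tr))
      rowSums(tm$values[, trn_tr, drop = FALSE]) > 0 else
      rep(FALSE, nrow(tm$values))
    out[[v]] <- data.frame(genome_id = rownames(tm$values), vitamin = v,
                           synthesis = unname(syn), transport = unname(trn),
                           strategy = vitamin_strategy(unname(syn), unname(trn)),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Enumerate three-vitamin strategy configurations
#'
#' Tabulates genomes over the full configuration space of one strategy per
#' vitamin — 4 strategies ^ 3 vitamins = 64 cells — and reports how many
#' cells are realized.
#'
#' @param profiles output of [classify_vitamins()] covering B1, B7, B12.
#' @return data frame with one row per cell (columns `B1`, `B7`, `B12`,
#'   `n_genomes`), 64 rows; attribute `n_observed` holds the number of
#'   occupied cells.
#' @export
enumerate_configurations <- function(profiles) {
  if (!nrow(profiles)) ta_stop("empty vitamin profiles")
  wide <- stats::reshape(profiles[, c("genome_id", "vitamin", "strategy")],
                         idvar = "genome_id", timevar = "vitamin",
                         direction = "wide")
  names(wide) <- sub("^strategy\\.", "", names(wide))
  if (!all(VITAMINS %in% names(wide))) {
    ta_stop("profiles must cover all of: %s", paste(VITAMINS, collapse = ", "))
  }
  space <- expand.grid(B1 = STRATEGIES, B7 = STRATEGIES, B12 = STRATEGIES,
                       stringsAsFactors = FALSE)
  key <- function(d) paste(d$B1, d$B7, d$B12, sep = "|")
  counts <- table(key(wide))
  space$n_genomes <- as.integer(counts[key(space)])
  space$n_genomes[is.na(space$n_genomes)] <- 0L
  attr(space, "n_observed") <- sum(space$n_genomes > 0L)
  space
}

#' Count interaction traits per genome
#'
#' Sums the flagged (curated interaction) trait presences per genome;
#' genome sizes are attached when supplied so the counts can be regressed
#' on size downstream.
#'
#' @param tm a [trait_matrix()] with interaction flags set.
#' @param genomes optional genome metadata table (for `genome_size`).
#' @return data frame: `genome_id`, `n_interaction_traits`, and
#'   `genome_size` when available.
#' @export
count_interaction_traits <- function(tm, genomes = NULL) {
  flagged <- tm$meta$trait_id[tm$meta$interaction]
  counts <- if (length(flagged))
    rowSums(tm$values[, flagged, drop = FALSE]) else
    rep(0L, nrow(tm$values))
  out <- data.frame(genome_id = rownames(tm$values),
                    n_interaction_traits = as.integer(counts),
                    stringsAsFactors = FALSE)
  if (!is.null(genomes)) {
    out$genome_size <- genomes$genome_size[match(out$genome_id, genomes$genome_id)]
  }
  out
}
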