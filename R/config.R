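#' Pipeline configuration
#'
#' Collects every tunable threshold of the atlas pipeline in one validated
#' object. The defaults reproduce the published analysis settings: exemplar
#' clustering preference quantile `q = 0.5`, FDR level 0.05 (chi-square test
#' with 1 df on the phi coefficient), trait prevalence prefilter at 3% of
#' genomes, strict `>50%` presence rules for linked trait clusters (LTCs) in
#' genomes and genome functional clusters (GFCs), LTC category cuts at 90%
#' (core) and 30% (ancillary), amplicon identity thresholds
#' 100 / 97 / 94.5 / 86.5%, at most 20 alignment hits per OTU, and taxon
#' down-sampling fractions 0.8 / 0.6 / 0.4 for the sensitivity analysis.
#'
#' @param q_preference quantile of off-diagonal similarities used as the
#'   affinity-propagation preference (granularity knob), in \[0, 1\].
#' @param fdr_alpha FDR level for retaining trait-pair correlations.
#' @param prevalence_min minimum trait prevalence (fraction of genomes).
#' @param min_count optional integer override of the prevalence cut, applied
#'   as an absolute genome count instead of the fraction.
#' @param ltc_genome_frac fraction of an LTC's traits a genome must carry
#'   (strictly more than) for the LTC to be present in the genome.
#' @param ltc_gfc_frac fraction of a GFC's genomes that must carry an LTC
#'   (strictly more than) for the LTC to be present in the GFC.
#' @param core_frac,ancillary_frac LTC category bounds: core if genome
#'   presence > `core_frac`, ancillary if <= `ancillary_frac`, else common.
#' @param identity_thresholds percent-identity cutoffs for amplicon mapping,
#'   descending.
#' @param max_hits cap on alignment hits inspected per OTU.
#' @param downsample_fracs genome-coverage fractions for taxon down-sampling.
#' @param overrep_frac a taxon is "overrepresented" (and down-sampled) when
#'   it holds more than this fraction of all genomes.
#' @param ap_damping,ap_maxit,ap_convits,ap_jitter affinity-propagation
#'   message damping, iteration cap, convergence window, and relative
#'   magnitude of the seeded degeneracy-breaking jitter.
#' @param strict_modules if TRUE, disable the one-missing-reaction tolerance
#'   in module completeness calls (sensitivity switch).
#' @param n_permutations permutations / randomizations for empirical tests.
#' @param seed integer seed governing all stochastic steps.
#' @return an object of class `ta_config` (a validated list).
#' @export
ta_config <- function(q_preference = 0.5,
                      fdr_alpha = 0.05,
                      prevalence_min = 0.03,
                      min_count = NULL,
                      ltc_genome_frac = 0.5,
                      ltc_gfc_frac = 0.5,
                      core_frac = 0.9,
                      ancillary_frac = 0.3,
                      identity_thresholds = c(100, 97, 94.5, 86.5),
                      max_hits = 20L,
                      downsample_fracs = c(0.8, 0.6, 0.4),
                      overrep_frac = 0.05,
                      ap_damping = 0.9,
                      ap_maxit = 1000L,
                      ap_convits = 100L,
                      ap_jitter = 1e-9,
                      strict_modules = FALSE,
                      n_permutations = 999L,
                      seed = 1L) {
  cfg <- list(
    q_preference = q_preference, fdr_alpha = fdr_alpha,
    prevalence_min = prevalence_min, min_count = min_count,
    ltc_genome_frac = ltc_genome_frac, ltc_gfc_frac = ltc_gfc_frac,
    core_frac = core_frac, ancillary_frac = ancillary_frac,
    identity_thresholds = identity_thresholds, max_hits = as.integer(max_hits),
    downsample_fracs = downsample_fracs, overrep_frac = overrep_frac,
    ap_damping = ap_damping, ap_maxit = as.integer(ap_maxit),
    ap_convits = as.integer(ap_convits), ap_jitter = ap_jitter,
    strict_modules = isTRUE(strict_modules),
    n_permutations = as.integer(n_permutations), seed = as.integer(seed)
  )
  fracs <- c("q_preference", "fdr_alpha", "prevalence_min", "ltc_genome_frac",
             "ltc_gfc_frac", "core_frac", "ancillary_frac", "overrep_frac")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      ta_stop("config field '%s' must be a single fraction in [0,1]", f)
    }
  }
  if (any(cfg$downsample_fracs <= 0) || any(cfg$downsample_fracs > 1)) {
    ta_stop("config field 'downsample_fracs' must lie in (0,1]")
  }
  if (is.unsorted(rev(cfg$identity_thresholds), strictly = TRUE)) {
    ta_stop("config field 'identity_thresholds' must be strictly descending")
  }
  if (any(cfg$identity_thresholds < 0 | cfg$identity_thresholds > 100)) {
    ta_stop("config field 'identity_thresholds' must lie in [0,100]")
  }
  if (cfg$ap_damping < 0.5 || cfg$ap_damping >= 1) {
    ta_stop("config field 'ap_damping' must lie in [0.5, 1)")
  }
  for (f in c("max_hits", "ap_maxit", "ap_convits", "n_permutations")) {
    if (cfg[[f]] < 1L) ta_stop("config field '%s' must be a positive count", f)
  }
  if (!is.null(cfg$min_count) && (cfg$min_count < 0)) {
    ta_stop("config field 'min_count' must be a non-negative count")
  }
  structure(cfg, class = "ta_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file whose keys are
#'   arguments of [ta_config()].
#' @return a `ta_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) ta_stop("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      ta_stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(ta_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) ta_stop("unknown config field(s): %s", paste(bad, collapse = ", "))
  do.call(ta_config, vals)
}

#' @export
print.ta_config <- function(x, ...) {
  cat("trait-atlas pipeline configuration\n")
  for (f in names(x)) {
    cat(sprintf("  %-20s %s\n", f, paste(format(x[[f]]), collapse = ", ")))
  }
  invisible(x)
}
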