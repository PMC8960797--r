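# Environmental stage: mapping amplicon OTUs onto genome functional
# clusters through identity-thresholded alignment hit tables with a
# specificity index, and testing whether OTU pairs mapped to the same GFC
# are more temporally synchronous than pairs mapped to different GFCs.

#' Read an alignment hit table
#'
#' Accepts either the standard 12-column tabular alignment format (qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore; no header) or a headered TSV with columns `otu_id`,
#' `genome_id`, `percent_identity` and optionally `bit_rank`. Hits are
#' ranked per OTU by descending bitscore (or the given `bit_rank`).
#'
#' @param path hit table file.
#' @return data frame: `otu_id`, `genome_id`, `percent_identity`,
#'   `bit_rank`.
#' @export
read_hits <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("otu_id", first, fixed = TRUE)) {
    df <- read_tsv(path)
    need <- c("otu_id", "genome_id", "percent_identity")
    miss <- setdiff(need, names(df))
    if (length(miss)) ta_stop("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
    if (!"bit_rank" %in% names(df)) {
      df <- df[order(df$otu_id), ]
      df$bit_rank <- ave(seq_len(nrow(df)), df$otu_id, FUN = seq_along)
    }
  } else {
    raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 12L) ta_stop("%s: expected 12 tabular alignment columns", path)
    df <- data.frame(otu_id = as.character(raw[[1L]]),
                     genome_id = as.character(raw[[2L]]),
                     percent_identity = as.numeric(raw[[3L]]),
                     bitscore = as.numeric(raw[[12L]]),
                     stringsAsFactors = FALSE)
    df <- df[order(df$otu_id, -df$bitscore), ]
    df$bit_rank <- ave(seq_len(nrow(df)), df$otu_id, FUN = seq_along)
    df$bitscore <- NULL
  }
  if (any(df$percent_identity < 0 | df$percent_identity > 100)) {
    ta_stop("%s: percent_identity outside [0,100]", path)
  }
  df
}

#' Map OTUs to genome functional clusters
#'
#' Per OTU: hits are filtered to percent identity >= `threshold`, the top
#' `max_hits` by rank are retained, and the specificity index is the
#' fraction of retained hits whose genome belongs to the modal GFC. The
#' OTU is mapped to that GFC only when the index equals 1 (every retained
#' hit in one GFC); otherwise it stays unmapped. OTUs with no retained hit
#' get a null index.
#'
#' @param hits data frame from [read_hits()].
#' @param gfc named integer vector, genome_id -> GFC id.
#' @param threshold percent-identity cutoff.
#' @param max_hits cap on hits inspected per OTU.
#' @return data frame: `otu_id`, `n_hits`, `specificity_index`, `gfc_id`
#'   (NA when unmapped), `mapped`.
#' @export
map_otus <- function(hits, gfc, threshold, max_hits = 20L) {
  if (threshold < 0 || threshold > 100) ta_stop("threshold must lie in [0,100]")
  keep <- hits$percent_identity >= threshold
  retained <- hits[keep, , drop = FALSE]
  retained <- retained[order(retained$otu_id, retained$bit_rank), , drop = FALSE]
  out <- lapply(unique(hits$otu_id), function(otu) {
    h <- retained[retained$otu_id == otu, , drop = FALSE]
    h <- head(h, max_hits)
    if (!nrow(h)) {
      return(data.frame(otu_id = otu, n_hits = 0L,
                        specificity_index = NA_real_,
                        gfc_id = NA_integer_, mapped = FALSE,
                        stringsAsFactors = FALSE))
    }
    gfcs <- gfc[h$genome_id]
    tab <- sort(table(gfcs), decreasing = TRUE)
    idx <- as.numeric(tab[1L]) / nrow(h)   # unlabelled genomes dilute the index
    mapped <- isTRUE(all.equal(idx, 1))
    data.frame(otu_id = otu, n_hits = nrow(h), specificity_index = idx,
               gfc_id = if (mapped) as.integer(names(tab)[1L]) else NA_integer_,
               mapped = mapped, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fraction of community reads mapped to GFCs
#'
#' @param abundances data frame: `otu_id`, `sample_id`, `reads`.
#' @param mapping data frame from [map_otus()].
#' @return list: `per_sample` (sample_id, fraction_mapped; NA for
#'   zero-read samples), `mean`, `range`.
#' @export
community_fraction <- function(abundances, mapping) {
  mapped_otus <- mapping$otu_id[mapping$mapped]
  per_sample <- do.call(rbind, lapply(unique(abundances$sample_id), function(s) {
    a <- abundances[abundances$sample_id == s, , drop = FALSE]
    tot <- sum(a$reads)
    frac <- if (tot == 0) NA_real_ else
      sum(a$reads[a$otu_id %in% mapped_otus]) / tot
    data.frame(sample_id = s, fraction_mapped = frac, stringsAsFactors = FALSE)
  }))
  ok <- per_sample$fraction_mapped[!is.na(per_sample$fraction_mapped)]
  list(per_sample = per_sample,
       mean = if (length(ok)) mean(ok) else NA_real_,
       range = if (length(ok)) range(ok) else c(NA_real_, NA_real_))
}

#' Label OTU pairs by shared GFC membership
#'
#' Keeps only pairs where at least one OTU is GFC-mapped (pairs of two
#' unmapped OTUs might share an unknown GFC and are excluded). A pair is
#' `same_gfc` when both OTUs map to the same GFC, otherwise
#' `different_gfc`.
#'
#' @param pairs data frame: `otu_a`, `otu_b`, `score`.
#' @param mapping data frame from [map_otus()].
#' @return the pairs kept, with a `group` column added.
#' @export
label_pairs <- function(pairs, mapping) {
  g <- setNames(mapping$gfc_id, mapping$otu_id)
  ga <- g[pairs$otu_a]
  gb <- g[pairs$otu_b]
  keep <- !is.na(ga) | !is.na(gb)
  pairs <- pairs[keep, , drop = FALSE]
  same <- !is.na(ga[keep]) & !is.na(gb[keep]) & ga[keep] == gb[keep]
  pairs$group <- ifelse(same, "same_gfc", "different_gfc")
  pairs
}

#' Synchrony test of within-GFC OTU pairs
#'
#' Compares the frequency interaction score (temporal synchrony) of
#' same-GFC OTU pairs against different-GFC pairs. Normality per group is
#' checked with the Shapiro test (skipped and flagged below 3
#' observations); the primary test is a one-sided Welch t-test (same-GFC
#' mean greater), with the two-sided p and a one-sided Wilcoxon rank test
#' reported alongside. Two seeded randomization controls re-run the Welch
#' test after (a) shuffling pair labels keeping the original group sizes
#' and (b) splitting all pairs into two equal-size groups; each control
#' reports the +1-corrected empirical p of the observed t statistic
#' against its randomized distribution and the fraction of randomizations
#' significant at 0.05.
#'
#' @param pairs labelled pairs from [label_pairs()] (columns `score`,
#'   `group`).
#' @param n_randomizations randomizations per control; 0 skips the
#'   randomization controls (e.g. inside replicate studies).
#' @param seed integer seed.
#' @return list report (class `synchrony_report`).
#' @export
synchrony_test <- function(pairs, n_randomizations = 999L, seed = 1L) {
  x <- pairs$score[pairs$group == "same_gfc"]
  y <- pairs$score[pairs$group == "different_gfc"]
  if (!length(x) || !length(y)) ta_stop("both pair groups must be non-empty")
  shapiro_p <- function(v) {
    if (length(v) < 3L || length(v) > 5000L) return(NA_real_)
    if (var(v) == 0) return(NA_real_)
    shapiro.test(v)$p.value
  }
  tt <- t.test(x, y, alternative = "greater")
  tt2 <- t.test(x, y, alternative = "two.sided")
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "greater"))
  t_obs <- unname(tt$statistic)
  all_scores <- c(x, y)
  nx <- length(x); ny <- length(y)
  n_half <- floor(length(all_scores) / 2)
  if (n_randomizations >= 1L) set.seed(seed)
  t_of <- function(a, b) {
    suppressWarnings(unname(t.test(a, b, alternative = "greater")$statistic))
  }
  run_control <- function(draw) {
    if (n_randomizations < 1L) return(NULL)
    t_null <- numeric(n_randomizations)
    sig <- 0L
    for (b in seq_len(n_randomizations)) {
      g <- draw()
      tb <- t_of(g$a, g$b)
      t_null[b] <- tb
      p_b <- suppressWarnings(t.test(g$a, g$b, alternative = "greater")$p.value)
      if (p_b < 0.05) sig <- sig + 1L
    }
    list(empirical_p = (1 + sum(t_null >= t_obs)) / (1 + n_randomizations),
         frac_significant = sig / n_randomizations)
  }
  ctrl_sizes <- run_control(function() {
    i <- sample.int(nx + ny, nx)
    list(a = all_scores[i], b = all_scores[-i])
  })
  ctrl_equal <- run_control(function() {
    i <- sample.int(length(all_scores), n_half)
    list(a = all_scores[i], b = all_scores[-i])
  })
  structure(list(
    n_same = nx, n_different = ny,
    mean_same = mean(x), mean_different = mean(y),
    shapiro_p_same = shapiro_p(x), shapiro_p_different = shapiro_p(y),
    shapiro_skipped = length(x) < 3L || length(y) < 3L,
    t_statistic = t_obs,
    p_one_sided = tt$p.value, p_two_sided = tt2$p.value,
    wilcoxon_p_one_sided = wt$p.value,
    control_same_sizes = ctrl_sizes,
    control_equal_sizes = ctrl_equal,
    n_randomizations = n_randomizations
  ), class = "synchrony_report")
}

#' @export
print.synchrony_report <- function(x, ...) {
  cat(sprintf("synchrony test: %d same-GFC vs %d different-GFC pairs\n",
              x$n_same, x$n_different))
  cat(sprintf("  means %.3f vs %.3f; Welch t = %.3f, one-sided p = %.3g (two-sided %.3g)\n",
              x$mean_same, x$mean_different, x$t_statistic,
              x$p_one_sided, x$p_two_sided))
  cat(sprintf("  Wilcoxon one-sided p = %.3g\n", x$wilcoxon_p_one_sided))
  cat(sprintf("  randomization controls (B = %d): same-sizes empirical p = %.3g, equal-sizes %.3g\n",
              x$n_randomizations, x$control_same_sizes$empirical_p,
              x$control_equal_sizes$empirical_p))
  invisible(x)
}
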