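coherence_fixture <- function() {
  data.frame(
    genome_id = sprintf("G%02d", 1:8),
    domain = "Bacteria", phylum = "P1", class = "C1", order = "O1",
    family = "F1",
    genus = c("X", "X", "X", "Y", "Y", "Z", "Z", "Y"),
    stringsAsFactors = FALSE)
}

test_that("coherence labels follow the all-and-only definition", {
  tax <- coherence_fixture()
  # GFC1 = all and only genus X; GFC2 holds 2 of Y's 3 genomes; GFC3 mixes
  gfc <- setNames(c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L), tax$genome_id)
  res <- classify_coherence(gfc, tax, rank = "genus")
  expect_equal(res$label[res$gfc_id == 1], "monophyletic")
  expect_equal(res$label[res$gfc_id == 2], "paraphyletic")
  expect_equal(res$label[res$gfc_id == 3], "polyphyletic")
  # labels partition the GFCs
  expect_equal(nrow(res), length(unique(gfc)))
  # consistent relabeling of taxa leaves labels invariant
  tax2 <- tax
  tax2$genus <- paste0("genus_", tax2$genus)
  expect_equal(classify_coherence(gfc, tax2, "genus")$label, res$label)
})

test_that("genomes without a taxon label are excluded with a warning", {
  tax <- coherence_fixture()
  tax$genus[1] <- NA
  gfc <- setNames(rep(1L, 8), tax$genome_id)
  expect_warning(res <- classify_coherence(gfc, tax), "without")
  expect_equal(res$n_genomes, 7L)
})

ltc_fixture <- function() {
  # 8 genomes, LTC A = 4 traits, LTC B = 2 traits
  v <- matrix(0L, 8, 6,
              dimnames = list(sprintf("G%02d", 1:8),
                              c("a1", "a2", "a3", "a4", "b1", "b2")))
  v[1, c("a1", "a2", "a3")] <- 1L          # 3/4 -> present
  v[2, c("a1", "a2")] <- 1L                # 2/4 -> absent (50% not > 50%)
  v[3:8, c("a1", "a2", "a3", "a4")] <- 1L  # present
  v[1:2, c("b1", "b2")] <- 1L              # B present in G1, G2 only
  trait_matrix(v)
}

test_that("LTC presence uses strict >50% rules in genomes and GFCs", {
  tm <- ltc_fixture()
  ltc <- setNames(c(1L, 1L, 1L, 1L, 2L, 2L), colnames(tm$values))
  # GFC1 = G1..G5 (A present in G1, G3, G4, G5 -> 4/5 > 50%); GFC2 = G6..G8
  gfc <- setNames(c(rep(1L, 5), rep(2L, 3)), rownames(tm$values))
  res <- ltc_presence(tm, ltc, gfc)
  expect_true(res$by_genome["G01", "1"])    # 3 of 4 traits -> 75% > 50%
  expect_false(res$by_genome["G02", "1"])   # 2 of 4 traits -> exactly 50%
  expect_true(res$by_gfc["1", "1"])         # 4 of 5 genomes
  expect_true(res$by_gfc["2", "1"])
  # LTC B present in 2/8 genomes -> ancillary, and in no GFC -> unclustered
  s2 <- res$summary[res$summary$ltc_id == 2, ]
  expect_equal(s2$category, "ancillary")
  expect_true(s2$unclustered)
  expect_setequal(res$unclustered_traits, c("b1", "b2"))
})

test_that("LTC category boundaries put 0.9 in common and 0.3 in ancillary", {
  # 10 genomes; LTC present in exactly 9 (0.9) and 3 (0.3)
  v <- matrix(0L, 10, 2, dimnames = list(sprintf("G%02d", 1:10), c("x", "y")))
  v[1:9, "x"] <- 1L
  v[1:3, "y"] <- 1L
  tm <- trait_matrix(v)
  ltc <- setNames(c(1L, 2L), c("x", "y"))
  gfc <- setNames(rep(1L, 10), rownames(v))
  res <- ltc_presence(tm, ltc, gfc)
  expect_equal(res$summary$genome_presence, c(0.9, 0.3))
  expect_equal(res$summary$category[1], "common")     # 0.9 is not > 0.9
  expect_equal(res$summary$category[2], "ancillary")  # 0.3 is <= 0.3
})

test_that("mean within-LTC phi is computed on pre-threshold values", {
  set.seed(7)
  base <- rbinom(60, 1, 0.5)
  v <- cbind(p1 = base, p2 = base, q1 = 1L - base, q2 = rbinom(60, 1, 0.5))
  rownames(v) <- sprintf("G%02d", 1:60)
  tm <- trait_matrix(v)
  sim <- build_similarity(tm, "trait")
  ltc <- setNames(c(1L, 1L, 2L, 2L), colnames(v))
  gfc <- setNames(rep(1L, 60), rownames(v))
  res <- ltc_presence(tm, ltc, gfc, phi_raw = sim$phi_raw)
  expect_equal(res$summary$mean_within_r[1], 1)   # identical traits
  # LTC 2 contains the anti-associated pair: raw phi can be negative even
  # though the parsed similarity was thresholded
  expect_lt(res$summary$mean_within_r[2], 0.5)
  expect_false(is.na(res$background_mean_r))
})

test_that("enrichment p-values carry the +1 correction and detect a maximal planted signal", {
  set.seed(9)
  n <- 40
  v <- matrix(0L, n, 6, dimnames = list(sprintf("G%02d", 1:n),
                                        sprintf("t%d", 1:6)))
  meta <- data.frame(trait_id = colnames(v), category = "kegg_module",
                     interaction = TRUE, vitamin = NA, role = NA)
  # GFC 1 (10 genomes) carries every flagged trait; the rest carry none
  v[1:10, ] <- 1L
  tm <- trait_matrix(v, meta)
  gfc <- setNames(c(rep(1L, 10), rep(2L, 30)), rownames(v))
  res <- enrichment_test(tm, gfc, n_permutations = 999, seed = 1)
  expect_equal(res$p[res$gfc_id == 1], 1 / 1000)
  expect_true(all(res$p > 0))
  # identical genomes -> all p near 1
  v2 <- matrix(1L, n, 6, dimnames = dimnames(v))
  res2 <- enrichment_test(trait_matrix(v2, meta), gfc,
                          n_permutations = 199, seed = 1)
  expect_true(all(res2$p == 1))
})

test_that("size expectation recovers a planted taxon offset and a zero-residual line", {
  set.seed(13)
  n <- 50
  size <- runif(n, 2e6, 6e6)
  counts <- round(2 + 4e-6 * size)            # exactly linear (rounded)
  profiles <- data.frame(genome_id = sprintf("G%02d", 1:n),
                         n_interaction_traits = counts, genome_size = size)
  tax <- data.frame(genome_id = profiles$genome_id,
                    genus = rep(c("A", "B"), length.out = n))
  res <- size_expectation(profiles, tax, n_permutations = 199, seed = 1)
  expect_lt(max(abs(res$per_genome$residual)), 1)   # rounding only
  # plant a +3 offset on taxon B
  profiles2 <- profiles
  isB <- tax$genus == "B"
  profiles2$n_interaction_traits <- counts + ifelse(isB, 3L, 0L)
  res2 <- size_expectation(profiles2, tax, n_permutations = 199, seed = 1)
  offB <- res2$per_taxon$mean_residual[res2$per_taxon$taxon == "B"]
  expect_gt(offB, 1)                                # +3 split across the fit
  expect_lt(res2$per_taxon$p[res2$per_taxon$taxon == "B"], 0.05)
  # recovered slope within 2 SE of the planted 4e-6 (per added count/bp)
  fit <- lm(n_interaction_traits ~ genome_size, data = profiles)
  se <- summary(fit)$coefficients["genome_size", "Std. Error"]
  expect_lt(abs(unname(res$model["genome_size"]) - 4e-6), 2 * se + 1e-7)
  expect_error(size_expectation(profiles[1:2, ], tax), ">= 3")
})

test_that("sensitivity analysis keeps ARI 1 on noiseless blocks and scans q upward", {
  spec <- synthetic_spec(n_genomes = 48, n_traits = 60, n_gfc_blocks = 4,
                         n_ltc_blocks = 5, block_trait_occupancy = 1,
                         background_occupancy = 0, annotation_dropout = 0,
                         taxon_concordance = 1, seed = 3)
  gen <- gen_trait_matrix(spec)
  tax <- gen_taxonomy(gen$truth, concordance = 1, seed = 3)
  cfg <- ta_config(seed = 3, n_permutations = 199)
  res <- sensitivity_analysis(gen$matrix, tax, cfg, q_grid = c(0.1, 0.9),
                              n_reps = 1)
  expect_equal(res$downsampling$frac, cfg$downsample_fracs)
  expect_true(all(res$downsampling$ari == 1))
  expect_lte(res$q_scan$n_clusters[res$q_scan$q == 0.1],
             res$q_scan$n_clusters[res$q_scan$q == 0.9])
})
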