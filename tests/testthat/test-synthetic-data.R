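test_that("spec validation names the offending field", {
  expect_error(synthetic_spec(n_genomes = 0), "n_genomes")
  expect_error(synthetic_spec(block_trait_occupancy = 1.2),
               "block_trait_occupancy")
  expect_error(synthetic_spec(annotation_dropout = -0.1), "annotation_dropout")
  expect_error(synthetic_spec(n_gfc_blocks = 10, n_genomes = 5), "n_gfc_blocks")
})

test_that("identical seeds give bit-identical outputs across all generators", {
  spec <- synthetic_spec(n_genomes = 40, n_traits = 50, n_gfc_blocks = 3,
                         n_ltc_blocks = 4, seed = 7)
  a <- gen_trait_matrix(spec)
  b <- gen_trait_matrix(spec)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$genome_block, b$truth$genome_block)
  defs_a <- gen_module_defs(a$matrix, seed = 7)
  defs_b <- gen_module_defs(b$matrix, seed = 7)
  expect_identical(defs_a, defs_b)
  ko_a <- gen_ko_tables(a$matrix, defs_a, dropout = 0.2, seed = 7)
  ko_b <- gen_ko_tables(b$matrix, defs_b, dropout = 0.2, seed = 7)
  expect_identical(ko_a$ko_table, ko_b$ko_table)
  expect_identical(gen_taxonomy(a$truth, 0.8, seed = 7),
                   gen_taxonomy(b$truth, 0.8, seed = 7))
  expect_identical(gen_env_tables(a$truth, seed = 7),
                   gen_env_tables(b$truth, seed = 7))
})

test_that("degenerate occupancies give an exactly block-structured matrix", {
  spec <- synthetic_spec(n_genomes = 30, n_traits = 40, n_gfc_blocks = 3,
                         n_ltc_blocks = 3, block_trait_occupancy = 1,
                         background_occupancy = 0, seed = 2)
  gen <- gen_trait_matrix(spec)
  tr <- names(gen$truth$trait_block)
  carried <- sapply(seq_len(3), function(b) {
    sapply(seq_len(3), function(l) b %in% gen$truth$ltc_carriers[[l]])
  })  # carried[l, b]
  for (g in names(gen$truth$genome_block)) {
    b <- gen$truth$genome_block[[g]]
    for (t in tr) {
      l <- gen$truth$trait_block[[t]]
      expect_equal(gen$matrix$values[g, t], as.integer(carried[l, b]))
    }
  }
})

test_that("within-block trait prevalence converges to the occupancy probability", {
  spec <- synthetic_spec(n_genomes = 200, n_traits = 60, n_gfc_blocks = 2,
                         n_ltc_blocks = 2, block_trait_occupancy = 0.9,
                         background_occupancy = 0.05, seed = 5)
  gen <- gen_trait_matrix(spec)
  carriers <- gen$truth$ltc_carriers
  in_prev <- out_prev <- c()
  for (t in names(gen$truth$trait_block)) {
    l <- gen$truth$trait_block[[t]]
    carrier_genomes <- names(gen$truth$genome_block)[
      gen$truth$genome_block %in% carriers[[l]]]
    other <- setdiff(names(gen$truth$genome_block), carrier_genomes)
    in_prev <- c(in_prev, mean(gen$matrix$values[carrier_genomes, t]))
    out_prev <- c(out_prev, mean(gen$matrix$values[other, t]))
  }
  expect_lt(abs(mean(in_prev) - 0.9), 0.05)
  expect_lt(abs(mean(out_prev) - 0.05), 0.05)
})

test_that("noiseless KO tables round-trip through module reconstruction", {
  spec <- synthetic_spec(n_genomes = 25, n_traits = 30, n_gfc_blocks = 3,
                         n_ltc_blocks = 3, annotation_dropout = 0, seed = 9)
  gen <- gen_trait_matrix(spec)
  defs <- gen_module_defs(gen$matrix, seed = 9)
  ko <- gen_ko_tables(gen$matrix, defs, dropout = 0, seed = 9)
  expect_equal(nrow(ko$annotation_gaps), 0L)
  res <- call_all(defs, ko$ko_table, genome_ids = rownames(gen$matrix$values))
  mod_traits <- gen$matrix$meta$trait_id[gen$matrix$meta$category == "kegg_module"]
  expect_identical(res$matrix[rownames(gen$matrix$values), mod_traits],
                   gen$matrix$values[, mod_traits])
})

test_that("total dropout erases every module and gaps are recorded otherwise", {
  spec <- synthetic_spec(n_genomes = 20, n_traits = 20, n_gfc_blocks = 2,
                         n_ltc_blocks = 2, seed = 11)
  gen <- gen_trait_matrix(spec)
  defs <- gen_module_defs(gen$matrix, seed = 11)
  ko1 <- gen_ko_tables(gen$matrix, defs, dropout = 1, seed = 11)
  expect_equal(nrow(ko1$ko_table), 0L)
  res <- call_all(defs, ko1$ko_table,
                  genome_ids = rownames(gen$matrix$values))
  expect_true(all(res$matrix == 0L))
  # planted gaps = exactly the present traits whose module is no longer
  # complete after dropout
  ko <- gen_ko_tables(gen$matrix, defs, dropout = 0.3, seed = 11)
  res2 <- call_all(defs, ko$ko_table, genome_ids = rownames(gen$matrix$values))
  mod_traits <- gen$matrix$meta$trait_id[gen$matrix$meta$category == "kegg_module"]
  for (g in rownames(gen$matrix$values)) {
    for (t in mod_traits) {
      planted <- gen$matrix$values[g, t] == 1L
      gap <- any(ko$annotation_gaps$genome_id == g & ko$annotation_gaps$trait_id == t)
      expect_equal(res2$matrix[g, t] == 1L, planted && !gap,
                   info = paste(g, t))
    }
  }
})

test_that("reconstructed prevalence respects the dropout survival bound", {
  # an 8-reaction module of singleton KO alternatives stays complete when
  # at most 1 of its 8 emitted KOs is dropped; with per-KO dropout 0.1 the
  # survival probability is P(Binom(8, 0.1) <= 1)
  n <- 100
  v <- matrix(1L, n, 1, dimnames = list(sprintf("G%03d", 1:n), "mod1"))
  tm <- trait_matrix(v)
  defs <- list(mod1 = module_definition(
    "mod1", lapply(1:8, function(i) list(sprintf("K%05d", i)))))
  ko <- gen_ko_tables(tm, defs, dropout = 0.1, seed = 13)
  res <- call_all(defs, ko$ko_table, genome_ids = rownames(v))
  p_keep <- pbinom(1, 8, 0.1)
  prev <- mean(res$matrix[, 1])
  expect_gte(prev, p_keep - 3 * sqrt(p_keep * (1 - p_keep) / n))
})

test_that("taxonomy concordance controls the genus match fraction", {
  spec <- synthetic_spec(n_genomes = 200, n_traits = 10, n_gfc_blocks = 4,
                         n_ltc_blocks = 4, seed = 17)
  gen <- gen_trait_matrix(spec)
  tax <- gen_taxonomy(gen$truth, concordance = 0.5, seed = 17)
  own <- sprintf("Genus_%02d", gen$truth$genome_block)
  match_frac <- mean(tax$genus == own)
  expect_gte(match_frac, 0.4)
  expect_lte(match_frac, 0.6)
  # perfect concordance -> noiseless clusters are monophyletic
  spec1 <- synthetic_spec(n_genomes = 40, n_traits = 40, n_gfc_blocks = 4,
                          n_ltc_blocks = 4, block_trait_occupancy = 1,
                          background_occupancy = 0, taxon_concordance = 1,
                          seed = 19)
  gen1 <- gen_trait_matrix(spec1)
  tax1 <- gen_taxonomy(gen1$truth, concordance = 1, seed = 19)
  coh <- classify_coherence(gen1$truth$genome_block, tax1, "genus")
  expect_true(all(coh$label == "monophyletic"))
  # ranks are ordered: one genus never spans two families
  expect_equal(nrow(unique(tax1[, c("family", "genus")])),
               length(unique(tax1$genus)))
})

test_that("hit specificity and planted synchrony effect behave as dialled", {
  spec <- synthetic_spec(n_genomes = 40, n_traits = 10, n_gfc_blocks = 4,
                         n_ltc_blocks = 4, seed = 23)
  gen <- gen_trait_matrix(spec)
  env0 <- gen_env_tables(gen$truth, n_otus = 30, specificity_noise = 0,
                         effect_size = 0, seed = 23)
  m <- map_otus(env0$hits, gen$truth$genome_block, threshold = 97)
  expect_true(all(m$specificity_index == 1))
  # with noise, some OTUs lose specificity
  env1 <- gen_env_tables(gen$truth, n_otus = 30, specificity_noise = 0.4,
                         effect_size = 0, seed = 23)
  m1 <- map_otus(env1$hits, gen$truth$genome_block, threshold = 97)
  expect_lt(mean(m1$mapped), 1)
  # planted effect shows up in the labelled pair scores
  env2 <- gen_env_tables(gen$truth, n_otus = 40, specificity_noise = 0,
                         effect_size = 3, seed = 23)
  lab <- label_pairs(env2$pairs, map_otus(env2$hits, gen$truth$genome_block, 97))
  expect_gt(mean(lab$score[lab$group == "same_gfc"]),
            mean(lab$score[lab$group == "different_gfc"]) + 2)
})
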