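hits_fixture <- function(gfcs_of_hits, pident = 99) {
  data.frame(otu_id = "OTU1",
             genome_id = names(gfcs_of_hits),
             percent_identity = pident,
             bit_rank = seq_along(gfcs_of_hits),
             stringsAsFactors = FALSE)
}

test_that("specificity index is the modal-GFC fraction and mapping requires index 1", {
  gfc <- setNames(c(1L, 1L, 1L, 2L), c("gA1", "gA2", "gA3", "gB1"))
  # three hits all in GFC 1 -> index 1, mapped
  h <- hits_fixture(setNames(c(1, 1, 1), c("gA1", "gA2", "gA3")))
  m <- map_otus(h, gfc, threshold = 97)
  expect_equal(m$specificity_index, 1)
  expect_true(m$mapped)
  expect_equal(m$gfc_id, 1L)
  # hits in (A, A, B) -> index 2/3, unmapped
  h2 <- hits_fixture(setNames(c(1, 1, 2), c("gA1", "gA2", "gB1")))
  m2 <- map_otus(h2, gfc, threshold = 97)
  expect_equal(m2$specificity_index, 2 / 3)
  expect_false(m2$mapped)
  expect_true(is.na(m2$gfc_id))
})

test_that("identity filtering is a hard boundary and zero-hit OTUs get a null index", {
  gfc <- setNames(1L, "gA1")
  h <- hits_fixture(setNames(1, "gA1"), pident = 96.9)
  m <- map_otus(h, gfc, threshold = 97)
  expect_equal(m$n_hits, 0L)
  expect_true(is.na(m$specificity_index))
  expect_false(m$mapped)
  # exactly at the threshold the hit is retained
  h2 <- hits_fixture(setNames(1, "gA1"), pident = 97)
  expect_true(map_otus(h2, gfc, threshold = 97)$mapped)
})

test_that("raising the identity threshold never increases retained hits", {
  set.seed(17)
  gfc <- setNames(rep(1:3, each = 5), sprintf("g%02d", 1:15))
  hits <- data.frame(otu_id = rep(sprintf("OTU%d", 1:10), each = 8),
                     genome_id = sample(names(gfc), 80, replace = TRUE),
                     percent_identity = runif(80, 85, 100),
                     bit_rank = rep(1:8, 10), stringsAsFactors = FALSE)
  prev <- NULL
  for (thr in c(86.5, 94.5, 97, 100)) {
    m <- map_otus(hits, gfc, thr)
    if (!is.null(prev)) expect_true(all(m$n_hits <= prev$n_hits))
    expect_true(all(m$specificity_index >= 0 | is.na(m$specificity_index)))
    expect_true(all(m$specificity_index <= 1, na.rm = TRUE))
    # index 1 iff mapped
    expect_equal(m$mapped, !is.na(m$specificity_index) & m$specificity_index == 1)
    prev <- m
  }
  # the hit cap is honoured
  mcap <- map_otus(hits, gfc, 0, max_hits = 3)
  expect_true(all(mcap$n_hits <= 3))
})

test_that("community fraction is exact on a hand-built abundance fixture", {
  mapping <- data.frame(otu_id = c("O1", "O2", "O3"),
                        n_hits = 3L, specificity_index = 1,
                        gfc_id = c(1L, 2L, NA), mapped = c(TRUE, TRUE, FALSE))
  ab <- data.frame(otu_id = rep(c("O1", "O2", "O3"), 2),
                   sample_id = rep(c("S1", "S2"), each = 3),
                   reads = c(10, 30, 60, 0, 0, 0))
  cf <- community_fraction(ab, mapping)
  expect_equal(cf$per_sample$fraction_mapped[1], 0.4)   # (10+30)/100
  expect_true(is.na(cf$per_sample$fraction_mapped[2]))  # zero-read sample
  expect_equal(cf$mean, 0.4)
  # all mapped -> 1; none mapped -> 0
  all_m <- mapping; all_m$mapped <- TRUE
  expect_equal(community_fraction(ab[1:3, ], all_m)$mean, 1)
  none <- mapping; none$mapped <- FALSE
  expect_equal(community_fraction(ab[1:3, ], none)$mean, 0)
})

test_that("pairs with no mapped member are excluded and groups assigned after mapping", {
  mapping <- data.frame(otu_id = c("O1", "O2", "O3", "O4"),
                        n_hits = 1L, specificity_index = c(1, 1, 1, 0.5),
                        gfc_id = c(1L, 1L, 2L, NA),
                        mapped = c(TRUE, TRUE, TRUE, FALSE))
  pairs <- data.frame(otu_a = c("O1", "O1", "O1", "O4"),
                      otu_b = c("O2", "O3", "O4", "O4"),
                      score = 1:4)
  lab <- label_pairs(pairs, mapping)
  expect_equal(nrow(lab), 3L)                  # O4-O4 dropped (neither mapped)
  expect_equal(lab$group, c("same_gfc", "different_gfc", "different_gfc"))
})

test_that("a planted +3 sd same-GFC shift is detected and randomization controls are null", {
  set.seed(23)
  pairs <- data.frame(
    otu_a = "x", otu_b = "y",
    score = c(rnorm(50, 3), rnorm(50, 0)),
    group = rep(c("same_gfc", "different_gfc"), each = 50))
  rep_ <- synchrony_test(pairs, n_randomizations = 199, seed = 1)
  expect_lt(rep_$p_one_sided, 0.001)
  expect_lt(rep_$wilcoxon_p_one_sided, 0.001)       # rank test agrees in direction
  expect_gt(rep_$t_statistic, 0)
  # the observed statistic is far outside both randomized distributions
  expect_lt(rep_$control_same_sizes$empirical_p, 0.05)
  expect_lt(rep_$control_equal_sizes$empirical_p, 0.05)
  # and the randomized groupings themselves are null: few significant
  expect_lt(rep_$control_same_sizes$frac_significant, 0.2)
  expect_lt(rep_$control_equal_sizes$frac_significant, 0.2)
  expect_false(is.na(rep_$shapiro_p_same))
})

test_that("type-I error of the synchrony test is near nominal under the null", {
  set.seed(29)
  hits <- replicate(200, {
    pairs <- data.frame(otu_a = "x", otu_b = "y", score = rnorm(100),
                        group = rep(c("same_gfc", "different_gfc"), each = 50))
    synchrony_test(pairs, n_randomizations = 0)$p_one_sided < 0.05
  })
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.08)
})

test_that("tiny groups skip the Shapiro check with a flag", {
  pairs <- data.frame(otu_a = "x", otu_b = "y",
                      score = c(5, 6, 0, 1, 2),
                      group = c("same_gfc", "same_gfc", rep("different_gfc", 3)))
  rep_ <- synchrony_test(pairs, n_randomizations = 0)
  expect_true(rep_$shapiro_skipped)
  expect_true(is.na(rep_$shapiro_p_same))
})

test_that("tabular 12-column alignment files parse and rank by bitscore", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- c("OTU1\tgA\t99.5\t250\t1\t0\t1\t250\t1\t250\t1e-50\t450",
            "OTU1\tgB\t98.0\t250\t5\t0\t1\t250\t1\t250\t1e-40\t400",
            "OTU2\tgC\t96.0\t250\t9\t0\t1\t250\t1\t250\t1e-30\t350")
  writeLines(rows, path)
  h <- read_hits(path)
  expect_equal(nrow(h), 3L)
  expect_equal(h$bit_rank[h$otu_id == "OTU1"], c(1L, 2L))
  expect_equal(h$genome_id[h$otu_id == "OTU1" & h$bit_rank == 1L], "gA")
})
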