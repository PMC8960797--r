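# Shared fixture builders. Everything is generated in code; no files.

# tiny hand-specified trait matrix with metadata covering all categories
tiny_trait_matrix <- function() {
  v <- rbind(
    G1 = c(1, 1, 0, 1, 1, 0),
    G2 = c(1, 0, 1, 0, 1, 0),
    G3 = c(0, 1, 1, 1, 0, 1),
    G4 = c(1, 1, 1, 0, 0, 1),
    G5 = c(0, 0, 1, 1, 1, 1))
  colnames(v) <- c("km:m1", "km:m2", "sm:s1", "tr:t1", "tr:t2", "su:u1")
  meta <- data.frame(
    trait_id = colnames(v),
    category = c("kegg_module", "kegg_module", "secondary_metabolite",
                 "transporter", "transporter", "sulfur_catabolism"),
    interaction = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    vitamin = NA_character_, role = NA_character_,
    stringsAsFactors = FALSE)
  trait_matrix(v, meta)
}

# trait matrix carrying vitamin tags for one vitamin per role combination
vitamin_fixture <- function(states) {
  # states: data.frame(synthesis, transport) one row per genome
  n <- nrow(states)
  v <- cbind(vitB1_syn = as.integer(states$synthesis),
             vitB1_trn = as.integer(states$transport),
             vitB7_syn = rep(1L, n), vitB7_trn = rep(0L, n),
             vitB12_syn = rep(0L, n), vitB12_trn = rep(1L, n))
  rownames(v) <- sprintf("G%02d", seq_len(n))
  meta <- data.frame(
    trait_id = colnames(v),
    category = rep(c("kegg_module", "transporter"), 3L),
    interaction = TRUE,
    vitamin = rep(c("B1", "B7", "B12"), each = 2L),
    role = rep(c("synthesis", "transport"), 3L),
    stringsAsFactors = FALSE)
  trait_matrix(v, meta)
}

# block-structured similarity matrix with planted clusters
planted_similarity <- function(n, n_blocks, within = 0.8, between = 0.1,
                               noise = 0.05, seed = 1) {
  set.seed(seed)
  blocks <- rep(seq_len(n_blocks), length.out = n)
  S <- matrix(between, n, n) + matrix(runif(n * n, -noise, noise), n, n)
  same <- outer(blocks, blocks, "==")
  S[same] <- within + runif(sum(same), -noise, noise)
  S <- (S + t(S)) / 2
  rownames(S) <- colnames(S) <- sprintf("i%03d", seq_len(n))
  list(S = S, blocks = setNames(blocks, rownames(S)))
}

# random module definition + KO-set instances for oracle comparisons
random_module_instance <- function(seed) {
  set.seed(seed)
  n_rx <- sample(1:10, 1)
  kos <- sprintf("K%05d", 1:10)
  reactions <- lapply(seq_len(n_rx), function(i) {
    n_alt <- sample(1:3, 1)
    lapply(seq_len(n_alt), function(j) sample(kos, sample(1:2, 1)))
  })
  defn <- module_definition(sprintf("M%04d", seed), reactions)
  ko_set <- sample(kos, sample(0:10, 1))
  list(defn = defn, ko_set = ko_set)
}

# independent brute-force completeness oracle: re-evaluates the module
# rule with plain loops, no shared code with call_module
oracle_module_complete <- function(defn, ko_set, strict = FALSE) {
  n_ok <- 0L
  for (rx in defn$reactions) {
    satisfied <- FALSE
    for (alt in rx) {
      present <- TRUE
      for (k in alt) if (!(k %in% ko_set)) present <- FALSE
      if (present) satisfied <- TRUE
    }
    if (satisfied) n_ok <- n_ok + 1L
  }
  n_rx <- length(defn$reactions)
  if (n_ok == n_rx) return(TRUE)
  if (!strict && n_rx >= 3L && n_rx - n_ok == 1L) return(TRUE)
  FALSE
}

# closed-form BH adjustment, written independently of stats::p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
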