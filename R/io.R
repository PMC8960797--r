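# Readers and writers for every table the pipeline exchanges. All tabular
# files are UTF-8 TSV with a header row; nested structures (module
# definitions, planted truth, reports) are JSON.

HABITATS <- c("marine_pelagic", "extreme", "sediment", "human", "plant", "other")
TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Read the genome metadata table
#'
#' Expects columns `genome_id`, the six taxonomy ranks domain..genus
#' (species optional), `habitat`, `genome_size`, `completeness`,
#' `contamination`. Extra columns are preserved untouched.
#'
#' @param path TSV file.
#' @return data frame of genome records, one row per genome.
#' @export
read_genomes <- function(path) {
  df <- read_tsv(path)
  need <- c("genome_id", TAX_RANKS, "habitat", "genome_size",
            "completeness", "contamination")
  miss <- setdiff(need, names(df))
  if (length(miss)) ta_stop("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  dup <- df$genome_id[duplicated(df$genome_id)]
  if (length(dup)) ta_stop("%s: duplicate genome_id: %s", path, paste(unique(dup), collapse = ", "))
  if (!all(df$habitat %in% HABITATS)) {
    bad <- which(!df$habitat %in% HABITATS)[1L]
    ta_stop("%s: line %d, field 'habitat': invalid value '%s'",
            path, bad + 1L, df$habitat[bad])
  }
  for (f in c("completeness", "contamination")) {
    v <- df[[f]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 100)) {
      ta_stop("%s: field '%s' must be a percent in [0,100]", path, f)
    }
  }
  df
}

#' Read a long-format KO annotation table
#'
#' Two columns: `genome_id`, `ko` (identifiers of the form `K#####`). An
#' empty table (header only) is valid and yields an empty annotation set.
#'
#' @param path TSV file.
#' @return data frame with columns `genome_id` and `ko`.
#' @export
read_ko_table <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  if (!all(c("genome_id", "ko") %in% names(df))) {
    ta_stop("%s: KO table needs columns genome_id, ko", path)
  }
  if (nrow(df)) {
    bad <- which(!grepl("^K[0-9]{5}$", df$ko))
    if (length(bad)) {
      ta_stop("%s: line %d, field 'ko': invalid KO id '%s'",
              path, bad[1L] + 1L, df$ko[bad[1L]])
    }
  }
  df[, c("genome_id", "ko")]
}

# collapse a long KO table into a named list of per-genome KO sets
ko_sets <- function(ko_table, genome_ids = NULL) {
  sets <- split(ko_table$ko, ko_table$genome_id)
  sets <- lapply(sets, unique)
  if (!is.null(genome_ids)) {
    out <- setNames(vector("list", length(genome_ids)), genome_ids)
    out[names(sets)[names(sets) %in% genome_ids]] <-
      sets[names(sets) %in% genome_ids]
    out[vapply(out, is.null, TRUE)] <- list(character())
    return(out)
  }
  sets
}

#' Read a per-category trait-call table
#'
#' Wide binary table: `genome_id` plus one 0/1 column per trait. Trait ids
#' are prefixed with a category code (`km:`, `sm:`, `ph:`, `tr:`, `su:`) on
#' assembly, so raw call tables may use bare names.
#'
#' @param path TSV file.
#' @param category one of the five trait categories.
#' @return list with elements `calls` (data frame) and `category`.
#' @export
read_trait_calls <- function(path, category) {
  category <- match.arg(category, c("kegg_module", "secondary_metabolite",
                                    "phytohormone_pathway", "transporter",
                                    "sulfur_catabolism"))
  df <- read_tsv(path)
  if (!"genome_id" %in% names(df)) ta_stop("%s: missing column 'genome_id'", path)
  dup <- df$genome_id[duplicated(df$genome_id)]
  if (length(dup)) ta_stop("%s: duplicate genome_id: %s", path, paste(unique(dup), collapse = ", "))
  for (tr in setdiff(names(df), "genome_id")) {
    v <- df[[tr]]
    if (anyNA(v) || !all(v %in% c(0, 1))) {
      ta_stop("%s: field '%s' must be binary 0/1 with no missing values", path, tr)
    }
  }
  list(calls = df, category = category)
}

CATEGORY_PREFIX <- c(kegg_module = "km", secondary_metabolite = "sm",
                     phytohormone_pathway = "ph", transporter = "tr",
                     sulfur_catabolism = "su")

#' Assemble the genome-by-trait matrix from completeness calls and
#' per-category trait-call tables
#'
#' Trait columns are the union over all sources, each id prefixed with its
#' category code so ids are globally unique. Genomes absent from a call
#' table get 0s for that table's traits (annotation silence is absence).
#' Interaction flags are set for exactly the ids in `interaction_traits`;
#' listed ids that match no assembled trait raise a warning and are
#' reported in the `missing_interaction_ids` attribute.
#'
#' @param module_matrix binary genomes-by-modules matrix as produced by
#'   [call_all()] (may be NULL if there are no module traits).
#' @param call_tables list of objects from [read_trait_calls()].
#' @param interaction_traits character vector of prefixed trait ids curated
#'   as interaction traits.
#' @param trait_tags optional data frame (`trait_id`, `vitamin`, `role`)
#'   tagging B-vitamin synthesis and transport traits.
#' @return a [trait_matrix()].
#' @export
assemble_trait_matrix <- function(module_matrix = NULL, call_tables = list(),
                                  interaction_traits = character(),
                                  trait_tags = NULL) {
  blocks <- list()
  cats <- character()
  if (!is.null(module_matrix)) {
    mm <- as.matrix(module_matrix)
    colnames(mm) <- paste0(CATEGORY_PREFIX[["kegg_module"]], ":", colnames(mm))
    blocks <- c(blocks, list(mm))
    cats <- c(cats, rep("kegg_module", ncol(mm)))
  }
  for (ct in call_tables) {
    df <- ct$calls
    m <- as.matrix(df[, setdiff(names(df), "genome_id"), drop = FALSE])
    rownames(m) <- df$genome_id
    colnames(m) <- paste0(CATEGORY_PREFIX[[ct$category]], ":", colnames(m))
    blocks <- c(blocks, list(m))
    cats <- c(cats, rep(ct$category, ncol(m)))
  }
  if (!length(blocks)) ta_stop("no trait sources supplied")
  all_traits <- unlist(lapply(blocks, colnames))
  dup <- all_traits[duplicated(all_traits)]
  if (length(dup)) ta_stop("trait id collides across sources: %s", paste(unique(dup), collapse = ", "))
  genomes <- sort(unique(unlist(lapply(blocks, rownames))))
  values <- matrix(0L, length(genomes), length(all_traits),
                   dimnames = list(genomes, all_traits))
  for (b in blocks) values[rownames(b), colnames(b)] <- as.integer(b)
  meta <- data.frame(trait_id = all_traits, category = cats,
                     interaction = all_traits %in% interaction_traits,
                     vitamin = NA_character_, role = NA_character_,
                     stringsAsFactors = FALSE)
  missing_int <- setdiff(interaction_traits, all_traits)
  if (length(missing_int)) {
    ta_warn("interaction-trait id(s) absent from matrix: %s",
            paste(missing_int, collapse = ", "))
  }
  if (!is.null(trait_tags)) {
    i <- match(meta$trait_id, trait_tags$trait_id)
    meta$vitamin <- trait_tags$vitamin[i]
    meta$role <- trait_tags$role[i]
  }
  tm <- trait_matrix(values, meta)
  attr(tm, "missing_interaction_ids") <- missing_int
  tm
}

#' Write / read a trait matrix (wide TSV plus a meta sidecar)
#'
#' `write_trait_matrix` writes `<path>` (genome_id + one column per trait)
#' and `<path>.meta.tsv`; `read_trait_matrix` reverses it bit-exactly.
#'
#' @param tm a [trait_matrix()].
#' @param path TSV file path.
#' @return the path (write) or a `trait_matrix` (read).
#' @export
write_trait_matrix <- function(tm, path) {
  df <- data.frame(genome_id = rownames(tm$values), tm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  write_tsv(tm$meta, paste0(path, ".meta.tsv"))
  invisible(path)
}

#' @rdname write_trait_matrix
#' @export
read_trait_matrix <- function(path) {
  df <- read_tsv(path)
  v <- as.matrix(df[, setdiff(names(df), "genome_id"), drop = FALSE])
  rownames(v) <- df$genome_id
  meta_path <- paste0(path, ".meta.tsv")
  meta <- if (file.exists(meta_path)) {
    m <- read_tsv(meta_path)
    m$interaction <- as.logical(m$interaction)
    m$vitamin <- as.character(m$vitamin)
    m$role <- as.character(m$role)
    m
  } else NULL
  trait_matrix(v, meta)
}
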