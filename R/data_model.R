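#' Binary genome-by-trait matrix with per-trait metadata
#'
#' The central container of the pipeline: a strictly binary matrix with
#' genomes as rows and genetic traits as columns, plus one metadata row per
#' trait giving its category (KEGG-style module, secondary metabolite,
#' phytohormone pathway, transporter, sulfur catabolism), whether it is a
#' curated interaction trait, and — where applicable — the B vitamin it
#' relates to and its role (synthesis or transport).
#'
#' @param values binary matrix (or data frame) with genome row names and
#'   trait column names.
#' @param meta data frame with columns `trait_id`, `category`, `interaction`
#'   and optionally `vitamin`, `role`. Defaults to category "kegg_module",
#'   no interaction flags, no vitamin tags.
#' @return an object of class `trait_matrix`.
#' @export
trait_matrix <- function(values, meta = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    ta_stop("trait matrix needs genome row names and trait column names")
  }
  if (anyDuplicated(rownames(values))) ta_stop("duplicate genome_id in trait matrix")
  if (anyDuplicated(colnames(values))) ta_stop("duplicate trait_id in trait matrix")
  storage.mode(values) <- "integer"
  check_binary(values, "trait matrix values")
  if (is.null(meta)) {
    meta <- data.frame(trait_id = colnames(values),
                       category = "kegg_module",
                       interaction = FALSE,
                       vitamin = NA_character_,
                       role = NA_character_,
                       stringsAsFactors = FALSE)
  }
  need <- c("trait_id", "category", "interaction")
  if (!all(need %in% names(meta))) {
    ta_stop("trait meta must have columns: %s", paste(need, collapse = ", "))
  }
  if (!"vitamin" %in% names(meta)) meta$vitamin <- NA_character_
  if (!"role" %in% names(meta)) meta$role <- NA_character_
  if (!setequal(meta$trait_id, colnames(values))) {
    ta_stop("trait meta ids do not match trait matrix columns")
  }
  meta <- meta[match(colnames(values), meta$trait_id), , drop = FALSE]
  rownames(meta) <- NULL
  ok_cat <- c("kegg_module", "secondary_metabolite", "phytohormone_pathway",
              "transporter", "sulfur_catabolism")
  if (!all(meta$category %in% ok_cat)) {
    ta_stop("unknown trait category: %s",
            paste(setdiff(meta$category, ok_cat), collapse = ", "))
  }
  structure(list(values = values, meta = meta), class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d genomes x %d traits (%d interaction traits)\n",
              nrow(x$values), ncol(x$values), sum(x$meta$interaction)))
  cat("categories:", paste(sprintf("%s=%d", names(table(x$meta$category)),
                                   table(x$meta$category)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

genome_ids <- function(tm) rownames(tm$values)
trait_ids <- function(tm) colnames(tm$values)

# subset a trait_matrix keeping metadata in step
tm_subset <- function(tm, genomes = NULL, traits = NULL) {
  v <- tm$values
  if (!is.null(genomes)) v <- v[genomes, , drop = FALSE]
  if (!is.null(traits)) v <- v[, traits, drop = FALSE]
  trait_matrix(v, tm$meta[match(colnames(v), tm$meta$trait_id), , drop = FALSE])
}
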