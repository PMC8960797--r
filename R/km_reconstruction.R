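# KEGG-style module completeness reconstruction. A module definition is an
# ordered list of reactions; each reaction is an OR-set of alternatives;
# each alternative is an AND-set of KO ids (a multi-subunit complex counts
# only when every subunit is annotated). A module is complete when every
# reaction has at least one satisfied alternative, with one missing
# reaction tolerated in modules of >= 3 reactions.

#' Construct a module definition
#'
#' @param module_id module identifier.
#' @param reactions list of reactions; each reaction is a list of character
#'   vectors, each vector one alternative whose KOs must all be present.
#'   A plain character vector is accepted as a reaction of singleton
#'   alternatives.
#' @return object of class `module_definition`.
#' @export
module_definition <- function(module_id, reactions) {
  if (!length(reactions)) ta_stop("module '%s' has no reactions", module_id)
  reactions <- lapply(reactions, function(rx) {
    if (is.character(rx)) rx <- as.list(rx)
    if (!length(rx)) ta_stop("module '%s': reaction with no alternatives", module_id)
    rx <- lapply(rx, as.character)
    if (any(!lengths(rx))) ta_stop("module '%s': empty alternative", module_id)
    rx
  })
  structure(list(module_id = module_id, reactions = reactions),
            class = "module_definition")
}

#' Is a single reaction satisfied by a KO set?
#'
#' TRUE iff some alternative of the reaction has all of its KOs in
#' `ko_set`.
#'
#' @param reaction list of character vectors (alternatives).
#' @param ko_set character vector of annotated KO ids.
#' @return logical scalar.
#' @export
reaction_satisfied <- function(reaction, ko_set) {
  if (is.character(reaction)) reaction <- as.list(reaction)
  any(vapply(reaction, function(alt) all(alt %in% ko_set), TRUE))
}

#' Call completeness of one module in one genome
#'
#' Counts the reactions with at least one satisfied alternative. The module
#' is complete when all reactions are annotated, or when exactly one is
#' missing in a module of at least three reactions (`strict = TRUE`
#' disables that tolerance). So a module with 7 of 8 reactions annotated is
#' complete; 2 of 3 is complete; 1 of 2 is not.
#'
#' @param defn a [module_definition()].
#' @param ko_set character vector of annotated KO ids.
#' @param strict disable the one-missing-reaction tolerance.
#' @return list with `module_id`, `n_reactions`, `n_annotated`, `complete`.
#' @export
call_module <- function(defn, ko_set, strict = FALSE) {
  n_rx <- length(defn$reactions)
  n_ok <- sum(vapply(defn$reactions, reaction_satisfied, TRUE, ko_set = ko_set))
  complete <- (n_ok == n_rx) ||
    (!strict && n_rx >= 3L && (n_rx - n_ok) == 1L)
  list(module_id = defn$module_id, n_reactions = n_rx,
       n_annotated = n_ok, complete = complete)
}

#' Call all modules across all genomes
#'
#' @param defs list of [module_definition()] objects (unique ids).
#' @param ko_table long KO table (`genome_id`, `ko`) or a named list of KO
#'   sets.
#' @param genome_ids optional genome universe; genomes without annotations
#'   get empty KO sets.
#' @param strict see [call_module()].
#' @return list with `calls` (long data frame, one row per genome x module)
#'   and `matrix` (binary genomes-by-modules completeness matrix).
#' @export
call_all <- function(defs, ko_table, genome_ids = NULL, strict = FALSE) {
  if (!length(defs)) ta_stop("no module definitions supplied")
  ids <- vapply(defs, `[[`, "", "module_id")
  if (anyDuplicated(ids)) {
    ta_stop("duplicate module_id: %s", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sets <- if (is.data.frame(ko_table)) ko_sets(ko_table, genome_ids) else ko_table
  if (!length(sets)) sets <- setNames(list(), character())
  rows <- vector("list", length(sets) * length(defs))
  k <- 0L
  for (g in names(sets)) {
    for (d in defs) {
      k <- k + 1L
      cl <- call_module(d, sets[[g]], strict = strict)
      rows[[k]] <- data.frame(genome_id = g, module_id = cl$module_id,
                              n_reactions = cl$n_reactions,
                              n_annotated = cl$n_annotated,
                              complete = cl$complete,
                              stringsAsFactors = FALSE)
    }
  }
  calls <- if (k) do.call(rbind, rows) else
    data.frame(genome_id = character(), module_id = character(),
               n_reactions = integer(), n_annotated = integer(),
               complete = logical())
  m <- matrix(0L, length(sets), length(defs),
              dimnames = list(names(sets), ids))
  if (nrow(calls)) {
    m[cbind(calls$genome_id, calls$module_id)] <- as.integer(calls$complete)
  }
  list(calls = calls, matrix = m)
}

#' Write / read module definitions as JSON
#'
#' Schema: an array of objects `{"module_id": ..., "reactions": [[["K.."],
#' ["K..","K.."]], ...]}` — reactions are arrays of alternatives, each
#' alternative an array of KO ids (AND-complex).
#'
#' @param defs list of [module_definition()] objects.
#' @param path JSON file.
#' @return the path (write) or a list of definitions (read).
#' @export
write_module_defs <- function(defs, path) {
  payload <- lapply(defs, function(d) list(module_id = d$module_id,
                                           reactions = d$reactions))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_module_defs
#' @export
read_module_defs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(d) {
    module_definition(d$module_id,
                      lapply(d$reactions, function(rx) lapply(rx, unlist)))
  })
}
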