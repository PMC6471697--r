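#' In-memory representation of a CellDesigner map
#'
#' A `map_document` holds the layout-relevant content of a
#' CellDesigner-flavoured SBML map: entities (species), their visual aliases
#' with geometry, reactions with their participant aliases, and the canvas
#' dimensions. An *entity* is the unique representation of a molecule; each
#' visual copy on the canvas is an *alias* of that entity, carrying its own
#' bounding box. Coordinates follow the CellDesigner convention: origin at the
#' top-left corner of the canvas, y increasing downward, and an alias position
#' given by the top-left corner of its box.
#'
#' @param entities data.frame with columns `entity_id`, `name`,
#'   `entity_class` (one of `"PROTEIN"`, `"METABOLITE"`, `"OTHER"`), and a
#'   list-column `annotation` of annotation lists (see [annotation_sections]).
#' @param aliases data.frame with columns `alias_id`, `entity_id`, `x`, `y`,
#'   `width`, `height`.
#' @param reactions named list (names are reaction ids); each element a list
#'   with character vectors `reactants`, `products`, `modifiers` (alias ids)
#'   and an `annotation` list.
#' @param canvas list with numeric `width` and `height`.
#'
#' @return An object of class `map_document`.
#' @export
map_document <- function(entities, aliases, reactions, canvas) {
  if (is.null(entities$annotation)) entities$annotation <- rep(list(list()), nrow(entities))
  doc <- structure(
    list(
      entities = entities,
      aliases = aliases,
      reactions = reactions,
      canvas = canvas
    ),
    class = "map_document"
  )
  validate_map(doc)
  doc
}

#' Section names allowed in entity and reaction annotations
#'
#' Annotations follow the NaviCell annotation vocabulary: free-text values
#' grouped under a fixed set of section names.
#'
#' @format Character vector of the four permitted section names.
#' @export
annotation_sections <- c("Identifiers", "Maps_Modules", "References", "Confidence")

check_annotation <- function(ann, where) {
  if (length(ann) == 0L) return(invisible(TRUE))
  bad <- setdiff(names(ann), annotation_sections)
  if (length(bad) > 0L) {
    stop("integrity error: ", where, " has unknown annotation section(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (s in names(ann)) {
    v <- ann[[s]]
    if (!is.character(v) || any(!nzchar(v))) {
      stop("integrity error: ", where, " annotation section '", s,
           "' must contain non-empty strings", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Validate a map document's invariants
#'
#' Checks referential integrity (aliases reference existing entities, reaction
#' participants reference existing aliases), id uniqueness, presence of at
#' least one alias per entity and one reactant and product per reaction,
#' positive box dimensions, canvas containment of every alias box, and
#' annotation section vocabulary. Called by every operation that constructs or
#' serialises a document.
#'
#' @param doc A [map_document].
#' @return `doc`, invisibly; stops with an integrity error otherwise.
#' @export
validate_map <- function(doc) {
  ent <- doc$entities; al <- doc$aliases; rx <- doc$reactions; cv <- doc$canvas
  if (!is.numeric(cv$width) || !is.numeric(cv$height) || cv$width <= 0 || cv$height <= 0)
    stop("integrity error: canvas dimensions must be positive", call. = FALSE)
  if (anyDuplicated(ent$entity_id))
    stop("integrity error: duplicate entity_id: ",
         paste(unique(ent$entity_id[duplicated(ent$entity_id)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(al$alias_id))
    stop("integrity error: duplicate alias_id: ",
         paste(unique(al$alias_id[duplicated(al$alias_id)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(names(rx)))
    stop("integrity error: duplicate reaction id", call. = FALSE)
  bad_class <- setdiff(ent$entity_class, c("PROTEIN", "METABOLITE", "OTHER"))
  if (length(bad_class) > 0L)
    stop("integrity error: unknown entity_class: ", paste(bad_class, collapse = ", "), call. = FALSE)
  dangling <- setdiff(al$entity_id, ent$entity_id)
  if (length(dangling) > 0L)
    stop("integrity error: alias references unknown entity: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  orphan <- setdiff(ent$entity_id, al$entity_id)
  if (length(orphan) > 0L)
    stop("integrity error: entity without any alias: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  if (nrow(al) > 0L) {
    if (any(!is.finite(al$x)) || any(!is.finite(al$y)) ||
        any(al$width <= 0) || any(al$height <= 0))
      stop("integrity error: alias geometry must be finite with positive width/height",
           call. = FALSE)
    outside <- al$x < 0 | al$y < 0 |
      al$x + al$width > cv$width | al$y + al$height > cv$height
    if (any(outside))
      stop("integrity error: alias box outside canvas: ",
           paste(al$alias_id[outside], collapse = ", "), call. = FALSE)
  }
  for (rid in names(rx)) {
    r <- rx[[rid]]
    if (length(r$reactants) < 1L || length(r$products) < 1L)
      stop("integrity error: reaction ", rid, " needs >=1 reactant and >=1 product",
           call. = FALSE)
    refs <- c(r$reactants, r$products, r$modifiers)
    missing_al <- setdiff(refs, al$alias_id)
    if (length(missing_al) > 0L)
      stop("integrity error: reaction ", rid, " references unknown alias(es): ",
           paste(missing_al, collapse = ", "), call. = FALSE)
    check_annotation(r$annotation, paste0("reaction ", rid))
  }
  for (i in seq_len(nrow(ent)))
    check_annotation(ent$annotation[[i]], paste0("entity ", ent$entity_id[i]))
  invisible(doc)
}

#' @export
print.map_document <- function(x, ...) {
  cat("CellDesigner map document\n")
  cat(sprintf("  canvas:    %g x %g\n", x$canvas$width, x$canvas$height))
  cat(sprintf("  entities:  %d  (proteins %d, metabolites %d, other %d)\n",
              nrow(x$entities),
              sum(x$entities$entity_class == "PROTEIN"),
              sum(x$entities$entity_class == "METABOLITE"),
              sum(x$entities$entity_class == "OTHER")))
  cat(sprintf("  aliases:   %d\n", nrow(x$aliases)))
  cat(sprintf("  reactions: %d\n", length(x$reactions)))
  invisible(x)
}

# centre of an alias box (alias position is its top-left corner)
alias_centre <- function(aliases, alias_id) {
  i <- match(alias_id, aliases$alias_id)
  c(x = aliases$x[i] + aliases$width[i] / 2,
    y = aliases$y[i] + aliases$height[i] / 2)
}
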