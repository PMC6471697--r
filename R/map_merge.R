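#' Merge two CellDesigner map layers
#'
#' Combines a base map and an overlay map (same canvas) into one document,
#' with the merge semantics of the classical BiNoM merging function: every
#' entity, alias and reaction of both inputs is kept (no deduplication of
#' same-named species -- layers are linked by name downstream, not by merged
#' identity), each gets a fresh identifier, and names, coordinates (bit-exact)
#' and annotations are preserved unchanged.
#'
#' Fresh ids follow the CellDesigner convention `s<N>` (species), `sa<N>`
#' (species aliases) and `re<N>` (reactions), numbered sequentially over the
#' base document first, then the overlay.
#'
#' @param base,overlay Valid [map_document]s with identical canvas dimensions.
#' @return List with `doc` (the merged [map_document]) and `report` (a
#'   `merge_report`: per-source `id_remapping` and before/after counts).
#' @export
merge_maps <- function(base, overlay) {
  validate_map(base)
  validate_map(overlay)
  if (!isTRUE(all.equal(base$canvas$width, overlay$canvas$width)) ||
      !isTRUE(all.equal(base$canvas$height, overlay$canvas$height)))
    stop("merge_maps: canvas dimensions differ (",
         base$canvas$width, "x", base$canvas$height, " vs ",
         overlay$canvas$width, "x", overlay$canvas$height, ")", call. = FALSE)

  n_ent <- c(nrow(base$entities), nrow(overlay$entities))
  n_al <- c(nrow(base$aliases), nrow(overlay$aliases))
  n_rx <- c(length(base$reactions), length(overlay$reactions))

  remap_one <- function(doc, ent_off, al_off, rx_off) {
    ent_map <- setNames(sprintf("s%d", ent_off + seq_len(nrow(doc$entities))),
                        doc$entities$entity_id)
    al_map <- setNames(sprintf("sa%d", al_off + seq_len(nrow(doc$aliases))),
                       doc$aliases$alias_id)
    rx_map <- setNames(sprintf("re%d", rx_off + seq_along(doc$reactions)),
                       names(doc$reactions))
    ent <- doc$entities
    ent$entity_id <- unname(ent_map[ent$entity_id])
    al <- doc$aliases
    al$alias_id <- unname(al_map[al$alias_id])
    al$entity_id <- unname(ent_map[al$entity_id])
    rx <- lapply(doc$reactions, function(r) {
      list(reactants = unname(al_map[r$reactants]),
           products = unname(al_map[r$products]),
           modifiers = if (length(r$modifiers)) unname(al_map[r$modifiers]) else character(0),
           annotation = r$annotation)
    })
    names(rx) <- unname(rx_map[names(doc$reactions)])
    list(entities = ent, aliases = al, reactions = rx,
         remap = c(ent_map, al_map, rx_map))
  }

  b <- remap_one(base, 0L, 0L, 0L)
  o <- remap_one(overlay, n_ent[1], n_al[1], n_rx[1])

  merged <- map_document(
    entities = rbind(b$entities, o$entities),
    aliases = rbind(b$aliases, o$aliases),
    reactions = c(b$reactions, o$reactions),
    canvas = base$canvas
  )

  report <- structure(list(
    id_remapping = list(base = b$remap, overlay = o$remap),
    counts = list(
      before = list(entities = n_ent, aliases = n_al, reactions = n_rx),
      after = list(entities = nrow(merged$entities),
                   aliases = nrow(merged$aliases),
                   reactions = length(merged$reactions))
    )
  ), class = "merge_report")

  list(doc = merged, report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat("map merge report\n")
  b <- x$counts$before; a <- x$counts$after
  cat(sprintf("  entities:  %d + %d -> %d\n", b$entities[1], b$entities[2], a$entities))
  cat(sprintf("  aliases:   %d + %d -> %d\n", b$aliases[1], b$aliases[2], a$aliases))
  cat(sprintf("  reactions: %d + %d -> %d\n", b$reactions[1], b$reactions[2], a$reactions))
  invisible(x)
}
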