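#' @importFrom stats kmeans phyper runif setNames
#' @importFrom utils read.delim write.table
NULL

SBML_NS <- "http://www.sbml.org/sbml/level2/version4"
CD_NS <- "http://www.sbml.org/2001/ns/celldesigner"
XHTML_NS <- "http://www.w3.org/1999/xhtml"

# CellDesigner species classes <-> our entity classes
cd_class_of <- function(entity_class) {
  switch(entity_class,
         PROTEIN = "PROTEIN",
         METABOLITE = "SIMPLE_MOLECULE",
         "UNKNOWN")
}
entity_class_of <- function(cd_class) {
  switch(cd_class,
         PROTEIN = "PROTEIN",
         SIMPLE_MOLECULE = "METABOLITE",
         "OTHER")
}

num_attr <- function(x) sprintf("%.17g", x)

# --- annotation <-> notes body -------------------------------------------
# Annotations are carried in the SBML <notes> body as one line per section:
#   "Identifiers: GCK,HK1". Values must not contain tabs or newlines; commas
# separate values within a section.
annotation_to_lines <- function(ann) {
  if (length(ann) == 0L) return(character(0))
  vapply(names(ann), function(s) paste0(s, ": ", paste(ann[[s]], collapse = ",")),
         character(1))
}

lines_to_annotation <- function(lines) {
  ann <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    m <- regexec("^([A-Za-z_]+):\\s*(.*)$", ln)
    parts <- regmatches(ln, m)[[1]]
    if (length(parts) != 3L || !(parts[2] %in% annotation_sections)) next
    vals <- trimws(strsplit(parts[3], ",", fixed = TRUE)[[1]])
    vals <- vals[nzchar(vals)]
    if (length(vals) > 0L) ann[[parts[2]]] <- c(ann[[parts[2]]], vals)
  }
  ann
}

#' Parse a CellDesigner SBML map
#'
#' Reads a CellDesigner-flavoured SBML level 2 document into a
#' [map_document]: species become entities, `celldesigner:speciesAlias`
#' elements (with their `bounds` geometry) become aliases, and reactions keep
#' ordered base-reactant / base-product / modifier alias references. NaviCell
#' style annotations are recovered from the notes body of each species and
#' reaction. The canvas size is taken from `celldesigner:modelDisplay`.
#'
#' @param xml Path to an XML file, or a single string containing the document.
#' @return A validated [map_document].
#' @export
parse_map <- function(xml) {
  doc <- tryCatch(
    xml2::read_xml(xml),
    error = function(e) stop("XML parse error: ", conditionMessage(e), call. = FALSE)
  )
  xml2::xml_ns_strip(doc)
  ns <- c(cd = CD_NS)

  display <- xml2::xml_find_first(
    doc, "/sbml/model/annotation/cd:extension/cd:modelDisplay", ns)
  if (inherits(display, "xml_missing"))
    stop("integrity error: missing celldesigner modelDisplay (canvas size)", call. = FALSE)
  canvas <- list(width = as.numeric(xml2::xml_attr(display, "sizeX")),
                 height = as.numeric(xml2::xml_attr(display, "sizeY")))

  sp_nodes <- xml2::xml_find_all(doc, "/sbml/model/listOfSpecies/species")
  entities <- data.frame(
    entity_id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name"),
    stringsAsFactors = FALSE
  )
  entities$entity_class <- vapply(sp_nodes, function(n) {
    cls <- xml2::xml_find_first(n, "./annotation/cd:extension/cd:speciesIdentity/cd:class", ns)
    if (inherits(cls, "xml_missing")) "OTHER" else entity_class_of(xml2::xml_text(cls))
  }, character(1))
  entities$annotation <- lapply(sp_nodes, function(n) {
    body <- xml2::xml_find_first(n, "./notes/html/body")
    if (inherits(body, "xml_missing")) return(list())
    lines_to_annotation(strsplit(xml2::xml_text(body), "\n", fixed = TRUE)[[1]])
  })

  al_nodes <- xml2::xml_find_all(
    doc, "/sbml/model/annotation/cd:extension/cd:listOfSpeciesAliases/cd:speciesAlias", ns)
  al_geom <- lapply(al_nodes, function(n) {
    b <- xml2::xml_find_first(n, "./cd:bounds", ns)
    if (inherits(b, "xml_missing"))
      stop("integrity error: alias without geometry: ", xml2::xml_attr(n, "id"),
           call. = FALSE)
    as.numeric(c(xml2::xml_attr(b, "x"), xml2::xml_attr(b, "y"),
                 xml2::xml_attr(b, "w"), xml2::xml_attr(b, "h")))
  })
  aliases <- data.frame(
    alias_id = xml2::xml_attr(al_nodes, "id"),
    entity_id = xml2::xml_attr(al_nodes, "species"),
    x = vapply(al_geom, `[`, numeric(1), 1L),
    y = vapply(al_geom, `[`, numeric(1), 2L),
    width = vapply(al_geom, `[`, numeric(1), 3L),
    height = vapply(al_geom, `[`, numeric(1), 4L),
    stringsAsFactors = FALSE
  )

  rx_nodes <- xml2::xml_find_all(doc, "/sbml/model/listOfReactions/reaction")
  reactions <- list()
  for (n in rx_nodes) {
    rid <- xml2::xml_attr(n, "id")
    ext <- xml2::xml_find_first(n, "./annotation/cd:extension", ns)
    reactants <- xml2::xml_attr(
      xml2::xml_find_all(ext, "./cd:baseReactants/cd:baseReactant", ns), "alias")
    products <- xml2::xml_attr(
      xml2::xml_find_all(ext, "./cd:baseProducts/cd:baseProduct", ns), "alias")
    modifiers <- xml2::xml_attr(
      xml2::xml_find_all(ext, "./cd:listOfModification/cd:modification", ns), "aliases")
    body <- xml2::xml_find_first(n, "./notes/html/body")
    ann <- if (inherits(body, "xml_missing")) list() else
      lines_to_annotation(strsplit(xml2::xml_text(body), "\n", fixed = TRUE)[[1]])
    reactions[[rid]] <- list(reactants = reactants, products = products,
                             modifiers = modifiers, annotation = ann)
  }

  map_document(entities, aliases, reactions, canvas)
}

add_notes <- function(parent, ann) {
  lines <- annotation_to_lines(ann)
  if (length(lines) == 0L) return(invisible(NULL))
  notes <- xml2::xml_add_child(parent, "notes")
  html <- xml2::xml_add_child(notes, "html", xmlns = XHTML_NS)
  xml2::xml_add_child(html, "head")
  body <- xml2::xml_add_child(html, "body")
  xml2::xml_text(body) <- paste(lines, collapse = "\n")
  invisible(NULL)
}

#' Serialise a map document to CellDesigner SBML
#'
#' Emits an SBML level 2 document with the CellDesigner extension carrying the
#' alias geometry, so that [parse_map()] recovers a field-identical
#' [map_document] (coordinates are written with full double precision and
#' round-trip bit-exactly). Refuses to serialise a document that violates the
#' map invariants.
#'
#' @param doc A [map_document].
#' @param path Optional file path; if `NULL` the XML is returned as a string.
#' @return The XML text (invisibly when written to `path`).
#' @export
write_map <- function(doc, path = NULL) {
  validate_map(doc)
  root <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_NS, "xmlns:celldesigner" = CD_NS,
    level = "2", version = "4"
  )
  model <- xml2::xml_add_child(root, "model", id = "integrated_map")
  mann <- xml2::xml_add_child(model, "annotation")
  ext <- xml2::xml_add_child(mann, "celldesigner:extension")
  xml2::xml_add_child(ext, "celldesigner:modelVersion", "4.0")
  xml2::xml_add_child(ext, "celldesigner:modelDisplay",
                      sizeX = num_attr(doc$canvas$width),
                      sizeY = num_attr(doc$canvas$height))
  loa <- xml2::xml_add_child(ext, "celldesigner:listOfSpeciesAliases")
  for (i in seq_len(nrow(doc$aliases))) {
    a <- doc$aliases[i, ]
    sa <- xml2::xml_add_child(loa, "celldesigner:speciesAlias",
                              id = a$alias_id, species = a$entity_id)
    xml2::xml_add_child(sa, "celldesigner:bounds",
                        x = num_attr(a$x), y = num_attr(a$y),
                        w = num_attr(a$width), h = num_attr(a$height))
  }

  comp <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comp, "compartment", id = "default", size = "1")

  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(doc$entities))) {
    e <- doc$entities[i, ]
    sp <- xml2::xml_add_child(los, "species",
                              id = e$entity_id, name = e$name,
                              compartment = "default", initialAmount = "0")
    add_notes(sp, doc$entities$annotation[[i]])
    sann <- xml2::xml_add_child(sp, "annotation")
    sext <- xml2::xml_add_child(sann, "celldesigner:extension")
    ident <- xml2::xml_add_child(sext, "celldesigner:speciesIdentity")
    xml2::xml_add_child(ident, "celldesigner:class", cd_class_of(e$entity_class))
  }

  if (length(doc$reactions) > 0L) {
    lor <- xml2::xml_add_child(model, "listOfReactions")
    alias2entity <- setNames(doc$aliases$entity_id, doc$aliases$alias_id)
    for (rid in names(doc$reactions)) {
      r <- doc$reactions[[rid]]
      rn <- xml2::xml_add_child(lor, "reaction", id = rid, reversible = "false")
      add_notes(rn, r$annotation)
      rann <- xml2::xml_add_child(rn, "annotation")
      rext <- xml2::xml_add_child(rann, "celldesigner:extension")
      xml2::xml_add_child(rext, "celldesigner:reactionType", "STATE_TRANSITION")
      br <- xml2::xml_add_child(rext, "celldesigner:baseReactants")
      for (a in r$reactants)
        xml2::xml_add_child(br, "celldesigner:baseReactant",
                            species = alias2entity[[a]], alias = a)
      bp <- xml2::xml_add_child(rext, "celldesigner:baseProducts")
      for (a in r$products)
        xml2::xml_add_child(bp, "celldesigner:baseProduct",
                            species = alias2entity[[a]], alias = a)
      if (length(r$modifiers) > 0L) {
        lm <- xml2::xml_add_child(rext, "celldesigner:listOfModification")
        for (a in r$modifiers)
          xml2::xml_add_child(lm, "celldesigner:modification",
                              type = "CATALYSIS", modifiers = alias2entity[[a]],
                              aliases = a)
      }
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (a in r$reactants)
        xml2::xml_add_child(lre, "speciesReference", species = alias2entity[[a]])
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (a in r$products)
        xml2::xml_add_child(lpr, "speciesReference", species = alias2entity[[a]])
    }
  }

  txt <- as.character(root)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Coordinates of a reaction's central glyph
#'
#' CellDesigner draws a small square glyph at the middle of each reaction; its
#' position is not stored in the XML. It is computed here as the midpoint of
#' the segment joining the centre of the first base reactant's alias box and
#' the centre of the first base product's alias box, matching CellDesigner's
#' default glyph placement for two-anchor reactions.
#'
#' @param doc A [map_document].
#' @param reaction_id Reaction identifier.
#' @return Named numeric vector `c(x = , y = )`.
#' @export
reaction_glyph_position <- function(doc, reaction_id) {
  r <- doc$reactions[[reaction_id]]
  if (is.null(r))
    stop("lookup error: unknown reaction_id: ", reaction_id, call. = FALSE)
  p1 <- alias_centre(doc$aliases, r$reactants[1])
  p2 <- alias_centre(doc$aliases, r$products[1])
  (p1 + p2) / 2
}

#' Table of central-glyph coordinates for every reaction
#'
#' @param doc A [map_document].
#' @param path Optional path; when given, the table is written as a 3-column
#'   TSV (`reaction_id`, `x`, `y`).
#' @return data.frame with columns `reaction_id`, `x`, `y`.
#' @export
glyph_table <- function(doc, path = NULL) {
  rids <- names(doc$reactions)
  pos <- vapply(rids, function(r) reaction_glyph_position(doc, r), numeric(2))
  out <- data.frame(reaction_id = rids,
                    x = if (length(rids)) pos["x", ] else numeric(0),
                    y = if (length(rids)) pos["y", ] else numeric(0),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Extract catalyst gene symbols from reaction annotations
#'
#' Returns, for every reaction whose annotation carries an `Identifiers`
#' section, the HUGO symbols listed there, deduplicated in first-seen order.
#' Symbols are matched case-sensitively; reactions without gene annotations
#' are omitted.
#'
#' @param doc A [map_document].
#' @return Named list mapping reaction_id to a character vector of symbols.
#' @export
extract_reaction_genes <- function(doc) {
  out <- list()
  for (rid in names(doc$reactions)) {
    ids <- doc$reactions[[rid]]$annotation[["Identifiers"]]
    if (length(ids) > 0L) {
      ids <- ids[!duplicated(ids)]
      out[[rid]] <- ids
    }
  }
  out
}
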