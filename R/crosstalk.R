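#' Read a gene-set collection from a GMT file
#'
#' Gene Matrix Transposed format: one gene set per line, tab-separated fields
#' `name`, `description`, then one or more gene symbols. Duplicate genes
#' within a line are removed; a line with fewer than three fields is a parse
#' error reported with its line number.
#'
#' @param path File path (or a character vector of lines via `text =`).
#' @param layer_label Free label naming the map layer the collection belongs
#'   to (e.g. `"module"` for a signalling layer, `"subsystem"` for a
#'   metabolic layer).
#' @param text Optional character vector of GMT lines instead of a file.
#' @return Object of class `gene_set_collection`: `sets` (named list of
#'   character vectors), `descriptions`, `layer_label`.
#' @export
read_gmt <- function(path = NULL, layer_label = "layer", text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT parse error at line ", i, ": expected >= 3 tab-separated fields",
           call. = FALSE)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    genes <- genes[!duplicated(genes)]
    if (f[1] %in% names(sets))
      stop("GMT parse error at line ", i, ": duplicate set name '", f[1], "'",
           call. = FALSE)
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  structure(list(sets = sets, descriptions = desc, layer_label = layer_label),
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path File path; if `NULL`, the lines are returned.
#' @return Character vector of GMT lines (invisibly when written).
#' @export
write_gmt <- function(collection, path = NULL) {
  lines <- vapply(names(collection$sets), function(nm) {
    d <- collection$descriptions[nm]
    if (is.na(d)) d <- ""
    paste(c(nm, d, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene-set collection (%s): %d sets, %d distinct genes\n",
              x$layer_label, length(x$sets), length(unique(unlist(x$sets)))))
  invisible(x)
}

#' Proteins shared between two map layers
#'
#' Intersects the union of all gene sets of one layer with the union of the
#' other: the common players through which the two map layers are linked.
#'
#' @param a,b `gene_set_collection`s.
#' @return Sorted character vector of shared symbols.
#' @export
shared_proteins <- function(a, b) {
  sort(intersect(unique(unlist(a$sets, use.names = FALSE)),
                 unique(unlist(b$sets, use.names = FALSE))))
}

#' Hypergeometric enrichment of a query in a gene-set collection
#'
#' For each set with at least `min_size` genes (after intersection with the
#' universe), computes the upper-tail hypergeometric probability of observing
#' at least the actual overlap with the query when `query_size` draws are
#' taken without replacement from a universe of `universe_size` genes of
#' which `set_size` belong to the set:
#' `P[X >= overlap]` with `X ~ Hypergeometric(universe, set, query)`.
#' P-values are Bonferroni-adjusted over the number of sets actually tested
#' in this collection.
#'
#' @param sets A `gene_set_collection`.
#' @param query Character vector of symbols; must be a subset of `universe`.
#' @param universe Character vector of symbols defining the population
#'   (typically the union of the proteins of both map layers).
#' @param min_size Minimum set size (within the universe) for a set to be
#'   tested; defaults to 10.
#' @param alpha Significance level applied to the adjusted p-values.
#' @return data.frame with one row per tested set: `set_name`,
#'   `overlap_count`, `set_size`, `query_size`, `universe_size`, `p_value`,
#'   `p_adjusted`, `significant`; sorted by `p_value`.
#' @export
enrich <- function(sets, query, universe, min_size = 10L, alpha = 0.05) {
  query <- unique(query)
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L)
    stop("enrich: query symbols outside the universe: ",
         paste(outside, collapse = ", "), call. = FALSE)
  N <- length(universe)
  q <- length(query)
  kept <- list()
  for (nm in names(sets$sets)) {
    s <- intersect(sets$sets[[nm]], universe)
    if (length(s) >= min_size) kept[[nm]] <- s
  }
  n_tested <- length(kept)
  rows <- lapply(names(kept), function(nm) {
    m <- length(kept[[nm]])
    ov <- length(intersect(kept[[nm]], query))
    p <- phyper(ov - 1L, m, N - m, q, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = ov, set_size = m,
               query_size = q, universe_size = N,
               p_value = p, p_adjusted = min(1, p * n_tested),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set_name = character(0), overlap_count = integer(0),
               set_size = integer(0), query_size = integer(0),
               universe_size = integer(0), p_value = numeric(0),
               p_adjusted = numeric(0), stringsAsFactors = FALSE)
  out$significant <- out$p_adjusted <= alpha
  out[order(out$p_value, out$set_name), , drop = FALSE]
}

#' Build the module-subsystem crosstalk network
#'
#' A bipartite weighted network between the gene-set hierarchies of the two
#' map layers: one node per module (layer a) and per subsystem (layer b),
#' connected by an edge whenever they have at least one shared protein in
#' common, with edge weight equal to the size of that intersection (edge
#' widths drawn proportional to this weight reproduce the published network
#' figure). Nodes carry enrichment flags when enrichment tables are supplied.
#'
#' @param a,b `gene_set_collection`s for the two layers.
#' @param shared Character vector of shared proteins (see
#'   [shared_proteins()]); intersections are restricted to it.
#' @param enrich_a,enrich_b Optional data.frames from [enrich()] used to flag
#'   enriched nodes.
#' @return Object of class `crosstalk_network` with `nodes` (`name`, `layer`,
#'   `enriched`) and `edges` (`source`, `target`, `weight`,
#'   `shared_symbols` comma-separated).
#' @export
build_crosstalk_network <- function(a, b, shared, enrich_a = NULL, enrich_b = NULL) {
  stopifnot(all(shared %in% unlist(a$sets, use.names = FALSE)),
            all(shared %in% unlist(b$sets, use.names = FALSE)))
  flag <- function(enr, nm) {
    if (is.null(enr)) return(FALSE)
    nm %in% enr$set_name[enr$significant]
  }
  nodes <- data.frame(
    name = c(names(a$sets), names(b$sets)),
    layer = c(rep(a$layer_label, length(a$sets)),
              rep(b$layer_label, length(b$sets))),
    stringsAsFactors = FALSE
  )
  nodes$enriched <- c(vapply(names(a$sets), function(n) flag(enrich_a, n), logical(1)),
                      vapply(names(b$sets), function(n) flag(enrich_b, n), logical(1)))
  rows <- list()
  for (m in names(a$sets)) {
    am <- intersect(a$sets[[m]], shared)
    if (length(am) == 0L) next
    for (s in names(b$sets)) {
      common <- intersect(am, b$sets[[s]])
      if (length(common) >= 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          source = m, target = s, weight = length(common),
          shared_symbols = paste(sort(common), collapse = ","),
          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(0), target = character(0),
               weight = integer(0), shared_symbols = character(0),
               stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "crosstalk_network")
}

#' @export
print.crosstalk_network <- function(x, ...) {
  cat(sprintf("crosstalk network: %d nodes (%s), %d edges, total weight %d\n",
              nrow(x$nodes),
              paste(sprintf("%d %s", table(x$nodes$layer)[unique(x$nodes$layer)],
                            unique(x$nodes$layer)), collapse = " + "),
              nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Convert a crosstalk network to an igraph object
#'
#' Useful for graph measures such as node degree or component analysis.
#'
#' @param net A `crosstalk_network`.
#' @return An [igraph::igraph] with `layer` and `enriched` vertex attributes
#'   and `weight` edge attributes.
#' @export
crosstalk_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("source", "target", "weight")],
                                directed = FALSE, vertices = net$nodes)
}

#' Export a crosstalk network as TXT and SIF
#'
#' The TXT export has the columns `source`, `target`, `interaction type`
#' (constant `crosstalk`) and `number of intersection proteins`; the SIF
#' export is the standard 3-column simple-interaction format.
#'
#' @param net A `crosstalk_network`.
#' @param path Output path.
#' @param format `"txt"` or `"sif"`.
#' @export
write_crosstalk_network <- function(net, path, format = c("txt", "sif")) {
  format <- match.arg(format)
  if (format == "txt") {
    out <- data.frame(source = net$edges$source, target = net$edges$target,
                      `interaction type` = rep("crosstalk", nrow(net$edges)),
                      `number of intersection proteins` = net$edges$weight,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(sprintf("%s\tcrosstalk\t%s", net$edges$source, net$edges$target), path)
  }
  invisible(path)
}

#' Read a reaction-to-subsystem assignment table
#'
#' Two-column TSV (`reaction_id`, `subsystem`), header optional. Each
#' reaction must be assigned to exactly one subsystem; multiple assignments
#' would double-count reactions and are rejected.
#'
#' @param path File path.
#' @return data.frame with columns `reaction_id`, `subsystem`.
#' @export
read_subsystem_assignment <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (tolower(df[1, 1]) %in% c("reaction_id", "reaction")) df <- df[-1, , drop = FALSE]
  out <- data.frame(reaction_id = df[[1]], subsystem = df[[2]],
                    stringsAsFactors = FALSE, row.names = NULL)
  dup <- duplicated(out$reaction_id)
  if (any(dup))
    stop("subsystem assignment: reaction(s) assigned more than once: ",
         paste(unique(out$reaction_id[dup]), collapse = ", "), call. = FALSE)
  out
}

#' Count reactions regulated by each module-subsystem pair
#'
#' For every (module, subsystem) pair, counts the distinct reactions of the
#' subsystem that have at least one catalyst belonging to both the module and
#' the shared-protein list. A reaction with several qualifying catalysts is
#' counted once. Reactions in the catalysis map without a subsystem
#' assignment are excluded with a diagnostic.
#'
#' @param prmap A `protein_reaction_map`.
#' @param assignment data.frame (`reaction_id`, `subsystem`) from
#'   [read_subsystem_assignment()].
#' @param modules A `gene_set_collection` (the signalling layer).
#' @param shared Character vector of shared proteins.
#' @return data.frame (`module`, `subsystem`, `n_reactions`) with
#'   `n_reactions >= 1`, sorted by module then subsystem.
#' @export
reaction_regulation_counts <- function(prmap, assignment, modules, shared) {
  rids <- names(prmap$by_reaction)
  sub_of <- setNames(assignment$subsystem, assignment$reaction_id)
  unassigned <- setdiff(rids, names(sub_of))
  if (length(unassigned) > 0L) {
    warning("reaction_regulation_counts: ", length(unassigned),
            " reaction(s) without subsystem assignment excluded: ",
            paste(unassigned, collapse = ", "), call. = FALSE)
    rids <- setdiff(rids, unassigned)
  }
  rows <- list()
  for (m in names(modules$sets)) {
    mod_shared <- intersect(modules$sets[[m]], shared)
    if (length(mod_shared) == 0L) next
    hit <- rids[vapply(rids, function(r)
      any(prmap$by_reaction[[r]] %in% mod_shared), logical(1))]
    if (length(hit) == 0L) next
    tab <- table(sub_of[hit])
    for (s in names(tab))
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, subsystem = s, n_reactions = as.integer(tab[[s]]),
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module = character(0), subsystem = character(0),
               n_reactions = integer(0), stringsAsFactors = FALSE)
  out[order(out$module, out$subsystem), , drop = FALSE]
}
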