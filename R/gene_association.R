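#' Flatten a gene-protein-reaction (GPR) rule to its gene identifiers
#'
#' Genome-scale metabolic models attach to each reaction a boolean gene rule
#' over Entrez gene ids (tokens optionally carry a transcript suffix `.N`),
#' combined with `and` / `or` and parentheses. Following the simplifying
#' assumption that any gene appearing in the rule encodes a potential
#' catalyst, the boolean structure is discarded: the rule is flattened to the
#' deduplicated list of gene ids in order of first appearance, with transcript
#' suffixes stripped. Consequently the result is invariant under any boolean
#' restructuring that preserves the token multiset.
#'
#' @param rule_text A single GPR string; the empty string yields an empty
#'   result.
#' @return Integer vector of Entrez gene ids.
#' @export
parse_gpr <- function(rule_text) {
  stopifnot(is.character(rule_text), length(rule_text) == 1L)
  if (!nzchar(trimws(rule_text))) return(integer(0))

  # tokenize, tracking character positions for error reporting
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, rule_text)[[1]]
  toks <- regmatches(rule_text, gregexpr(pat, rule_text))[[1]]
  pos <- as.integer(m)

  depth <- 0L
  genes <- integer(0)
  for (i in seq_along(toks)) {
    tk <- toks[i]
    if (tk == "(") {
      depth <- depth + 1L
    } else if (tk == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("GPR parse error at position ", pos[i], ": unbalanced ')'", call. = FALSE)
    } else if (tolower(tk) %in% c("and", "or")) {
      # connective, no gene
    } else if (grepl("^[0-9]+(\\.[0-9]+)?$", tk)) {
      genes <- c(genes, as.integer(sub("\\..*$", "", tk)))
    } else {
      stop("GPR parse error at position ", pos[i], ": unknown token '", tk, "'",
           call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("GPR parse error at position ", nchar(rule_text),
         ": unbalanced '(' (", depth, " unclosed)", call. = FALSE)
  unique(genes)
}

#' Translate Entrez gene ids to HUGO symbols
#'
#' Order-preserving translation through a single-valued Entrez-to-HUGO table.
#' Unmapped ids are never silently dropped: they are returned as a diagnostic
#' alongside the mapped symbols.
#'
#' @param entrez_ids Integer (or coercible) vector of Entrez ids.
#' @param mapping Named character vector (names = Entrez ids, values = HUGO
#'   symbols), e.g. from [read_id_mapping()].
#' @return List with `symbols` (character) and `unmapped` (integer).
#' @export
to_hugo <- function(entrez_ids, mapping) {
  ids <- as.integer(entrez_ids)
  hit <- as.character(ids) %in% names(mapping)
  list(symbols = unname(mapping[as.character(ids[hit])]),
       unmapped = ids[!hit])
}

#' Read an Entrez-to-HUGO mapping table
#'
#' Two-column TSV (`entrez`, `symbol`), header optional. The mapping must be
#' single-valued: an Entrez id mapped to two different symbols is a conflict
#' and raises an error (rather than being resolved silently).
#'
#' @param path File path.
#' @return Named character vector suitable for [to_hugo()].
#' @export
read_id_mapping <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("id mapping must have two tab-separated columns: ", path, call. = FALSE)
  if (tolower(df[1, 1]) %in% c("entrez", "entrez_id")) df <- df[-1, , drop = FALSE]
  df <- unique(df[, 1:2])
  dup <- duplicated(df[[1]])
  if (any(dup))
    stop("conflicting id mapping: Entrez id(s) ",
         paste(unique(df[[1]][dup]), collapse = ", "),
         " map to more than one symbol", call. = FALSE)
  if (any(!nzchar(df[[2]])))
    stop("id mapping contains empty HUGO symbols", call. = FALSE)
  setNames(df[[2]], df[[1]])
}

#' Read a model's reaction-to-gene-rule table
#'
#' Two-column TSV export of a genome-scale model: `reaction_id`, `rule_text`
#' (a GPR boolean expression, possibly empty). Header optional.
#'
#' @param path File path.
#' @return data.frame with columns `reaction_id` and `rule_text`.
#' @export
read_gene_rules <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character",
                   stringsAsFactors = FALSE, quote = "", na.strings = NULL)
  if (ncol(df) == 1L) df$V2 <- ""
  if (tolower(df[1, 1]) %in% c("reaction_id", "reaction")) df <- df[-1, , drop = FALSE]
  data.frame(reaction_id = df[[1]], rule_text = df[[2]],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the protein-reaction catalysis map
#'
#' Flattens every reaction's GPR rule ([parse_gpr()]), translates genes to
#' HUGO symbols ([to_hugo()]), and assembles the two-way association:
#' `by_reaction` (reaction id to ordered catalyst symbols, reactions with no
#' mapped gene omitted) and its exact transpose `by_protein` (symbol to
#' ordered reaction ids). The discarded boolean structure (complex vs isozyme
#' semantics) is a deliberate simplification; a note is emitted once per call
#' when any rule contains a connective.
#'
#' @param rules data.frame as returned by [read_gene_rules()].
#' @param mapping Named character vector from [read_id_mapping()].
#' @return Object of class `protein_reaction_map` with elements `by_reaction`,
#'   `by_protein`, and `unmapped` (named list of unmapped Entrez ids per
#'   reaction).
#' @export
build_protein_reaction_map <- function(rules, mapping) {
  by_reaction <- list()
  unmapped <- list()
  any_bool <- FALSE
  for (i in seq_len(nrow(rules))) {
    rid <- rules$reaction_id[i]
    txt <- rules$rule_text[i]
    if (grepl("\\b(and|or)\\b", txt, ignore.case = TRUE)) any_bool <- TRUE
    genes <- tryCatch(parse_gpr(txt), error = function(e)
      stop("reaction ", rid, ": ", conditionMessage(e), call. = FALSE))
    tr <- to_hugo(genes, mapping)
    if (length(tr$unmapped) > 0L) unmapped[[rid]] <- tr$unmapped
    syms <- tr$symbols[!duplicated(tr$symbols)]
    if (length(syms) > 0L) by_reaction[[rid]] <- syms
  }
  if (any_bool)
    message("note: boolean GPR structure (and/or) is flattened; ",
            "complex vs isozyme semantics are not preserved")

  by_protein <- list()
  for (rid in names(by_reaction)) {
    for (p in by_reaction[[rid]]) by_protein[[p]] <- c(by_protein[[p]], rid)
  }
  structure(list(by_reaction = by_reaction, by_protein = by_protein,
                 unmapped = unmapped),
            class = "protein_reaction_map")
}

#' @export
print.protein_reaction_map <- function(x, ...) {
  cat("protein-reaction catalysis map\n")
  cat(sprintf("  reactions with catalysts: %d\n", length(x$by_reaction)))
  cat(sprintf("  distinct proteins:        %d\n", length(x$by_protein)))
  if (length(x$unmapped) > 0L)
    cat(sprintf("  reactions with unmapped Entrez ids: %d\n", length(x$unmapped)))
  invisible(x)
}

#' Write a protein-reaction map as TSV
#'
#' One line per reaction: reaction id, tab, comma-separated catalyst symbols.
#'
#' @param prmap A `protein_reaction_map`.
#' @param path File path.
#' @export
write_protein_reaction_map <- function(prmap, path) {
  lines <- vapply(names(prmap$by_reaction), function(r)
    paste0(r, "\t", paste(prmap$by_reaction[[r]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}
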