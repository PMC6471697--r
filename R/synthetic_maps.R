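#' Specification for a synthetic map/model/gene-set bundle
#'
#' Defines a miniature but fully-specified test world: a CellDesigner-style
#' metabolic map with laid-out metabolite aliases and annotated reactions, a
#' matching gene-rule table and Entrez-to-HUGO mapping, and a pair of
#' gene-set collections (a signalling "module" layer and a metabolic
#' "subsystem" layer) with a controllable fraction of shared proteins.
#' Everything downstream of the generator is deterministic in `rng_seed`.
#'
#' Synthetic Entrez ids are drawn from a reserved range (9,000,000+ for
#' metabolic catalysts, 9,500,000+ for signalling-only genes) so they can
#' never collide with real gene ids.
#'
#' @param n_metabolites Number of metabolite species (>= 2), laid out on a
#'   jittered grid so seeds are distinct by construction.
#' @param n_reactions Number of reactions (>= 1), each joining two distinct
#'   metabolites.
#' @param catalysts_min,catalysts_max Range of catalyst counts per reaction.
#' @param canvas_width,canvas_height Canvas size in canvas units.
#' @param rng_seed Integer seed.
#' @param shared_fraction Fraction (0..1) of the catalyst proteins that are
#'   also placed into the signalling layer's gene sets.
#' @param n_modules,n_subsystems Number of gene sets per layer.
#' @param gene_pool_size Size of the catalyst gene pool; defaults to
#'   `n_reactions * catalysts_max`. Must be >= `catalysts_max`.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(n_metabolites = 8L, n_reactions = 5L,
                       catalysts_min = 1L, catalysts_max = 3L,
                       canvas_width = 1000, canvas_height = 800,
                       rng_seed = 0L, shared_fraction = 0.5,
                       n_modules = 3L, n_subsystems = 2L,
                       gene_pool_size = NULL) {
  if (n_metabolites < 2L) stop("synth_spec: n_metabolites must be >= 2", call. = FALSE)
  if (n_reactions < 1L) stop("synth_spec: n_reactions must be >= 1", call. = FALSE)
  if (catalysts_min < 1L || catalysts_max < catalysts_min)
    stop("synth_spec: catalyst range is empty", call. = FALSE)
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("synth_spec: shared_fraction must be in [0,1]", call. = FALSE)
  if (is.null(gene_pool_size)) gene_pool_size <- n_reactions * catalysts_max
  if (gene_pool_size < catalysts_max)
    stop("synth_spec: infeasible - gene pool smaller than catalysts_max", call. = FALSE)
  structure(list(
    n_metabolites = as.integer(n_metabolites), n_reactions = as.integer(n_reactions),
    catalysts_min = as.integer(catalysts_min), catalysts_max = as.integer(catalysts_max),
    canvas_width = canvas_width, canvas_height = canvas_height,
    rng_seed = as.integer(rng_seed), shared_fraction = shared_fraction,
    n_modules = as.integer(n_modules), n_subsystems = as.integer(n_subsystems),
    gene_pool_size = as.integer(gene_pool_size)
  ), class = "synth_spec")
}

#' Named synthetic presets
#'
#' `"small"`: 8 metabolites, 5 reactions with 1-3 catalysts on a 1000x800
#' canvas. `"dense"`: 16 metabolites, 20 reactions with 1-5 catalysts on a
#' 1600x1200 canvas.
#'
#' @param name `"small"` or `"dense"`.
#' @param rng_seed Integer seed.
#' @return A [synth_spec()].
#' @export
synth_preset <- function(name = c("small", "dense"), rng_seed = 0L) {
  name <- match.arg(name)
  switch(name,
    small = synth_spec(n_metabolites = 8L, n_reactions = 5L,
                       catalysts_min = 1L, catalysts_max = 3L,
                       rng_seed = rng_seed),
    dense = synth_spec(n_metabolites = 16L, n_reactions = 20L,
                       catalysts_min = 1L, catalysts_max = 5L,
                       canvas_width = 1600, canvas_height = 1200,
                       rng_seed = rng_seed, n_modules = 4L, n_subsystems = 3L)
  )
}

resample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Generate a synthetic bundle with known ground truth
#'
#' Produces every input the integration pipeline needs, plus the ground-truth
#' tables a test can check the pipeline against: per-reaction catalyst lists,
#' central-glyph positions (computed directly from the generated geometry),
#' the shared-protein list, and the expected crosstalk edge weights (computed
#' by an exhaustive double loop over module-subsystem pairs).
#'
#' @param spec A [synth_spec()].
#' @return List of class `synth_bundle` with elements `map`
#'   ([map_document]), `rules` (data.frame `reaction_id`, `rule_text`),
#'   `idmap` (named character vector), `gmt_a` / `gmt_b`
#'   (`gene_set_collection`s: signalling modules / metabolic subsystems),
#'   `assignment` (reaction to subsystem), and `truth` (list: `catalysts`,
#'   `glyphs`, `shared`, `expected_edges`).
#' @export
generate_synthetic_bundle <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$rng_seed)

  pool_entrez <- 9000000L + seq_len(spec$gene_pool_size)
  pool_hugo <- sprintf("SYNP%03d", seq_len(spec$gene_pool_size))
  hugo_of <- setNames(pool_hugo, pool_entrez)

  # metabolites on a jittered grid (distinct seeds by construction)
  nm <- spec$n_metabolites
  ncol_ <- ceiling(sqrt(nm))
  nrow_ <- ceiling(nm / ncol_)
  bw <- 70; bh <- 25
  cw <- spec$canvas_width / ncol_
  ch <- spec$canvas_height / nrow_
  idx <- seq_len(nm) - 1L
  cx <- (idx %% ncol_) * cw + cw / 2 + runif(nm, -5, 5)
  cy <- (idx %/% ncol_) * ch + ch / 2 + runif(nm, -5, 5)
  x <- pmin(pmax(cx - bw / 2, 0), spec$canvas_width - bw)
  y <- pmin(pmax(cy - bh / 2, 0), spec$canvas_height - bh)

  entities <- data.frame(
    entity_id = sprintf("s%d", seq_len(nm)),
    name = sprintf("MET%d", seq_len(nm)),
    entity_class = rep("METABOLITE", nm),
    stringsAsFactors = FALSE
  )
  entities$annotation <- rep(list(list()), nm)
  aliases <- data.frame(
    alias_id = sprintf("sa%d", seq_len(nm)),
    entity_id = entities$entity_id,
    x = x, y = y, width = bw, height = bh,
    stringsAsFactors = FALSE
  )

  reactions <- list()
  catalysts <- list()
  rules <- character(spec$n_reactions)
  glyph_x <- numeric(spec$n_reactions)
  glyph_y <- numeric(spec$n_reactions)
  for (i in seq_len(spec$n_reactions)) {
    rid <- sprintf("re%d", i)
    mets <- sample.int(nm, 2L)
    k <- resample1(spec$catalysts_min:spec$catalysts_max)
    genes <- sort(pool_entrez[sample.int(length(pool_entrez), k)])
    syms <- unname(hugo_of[as.character(genes)])
    reactions[[rid]] <- list(
      reactants = aliases$alias_id[mets[1]],
      products = aliases$alias_id[mets[2]],
      modifiers = character(0),
      annotation = list(Identifiers = syms)
    )
    catalysts[[rid]] <- syms
    toks <- paste0(genes, ".1")
    rules[i] <- if (k == 1L) toks else if (k == 2L)
      paste(toks, collapse = " and ") else
      paste0("(", toks[1], " and ", toks[2], ") or ",
             paste(toks[-(1:2)], collapse = " or "))
    # glyph position derived straight from the generated geometry
    glyph_x[i] <- ((x[mets[1]] + bw / 2) + (x[mets[2]] + bw / 2)) / 2
    glyph_y[i] <- ((y[mets[1]] + bh / 2) + (y[mets[2]] + bh / 2)) / 2
  }

  doc <- map_document(entities, aliases, reactions,
                      list(width = spec$canvas_width, height = spec$canvas_height))

  rules_df <- data.frame(reaction_id = names(reactions), rule_text = rules,
                         stringsAsFactors = FALSE)

  # metabolic subsystems: round-robin reaction assignment
  sub_names <- sprintf("SUBSYS%d", seq_len(spec$n_subsystems))
  assignment <- data.frame(
    reaction_id = names(reactions),
    subsystem = sub_names[((seq_len(spec$n_reactions) - 1L) %% spec$n_subsystems) + 1L],
    stringsAsFactors = FALSE
  )
  sub_sets <- lapply(sub_names, function(s) {
    rs <- assignment$reaction_id[assignment$subsystem == s]
    sort(unique(unlist(catalysts[rs], use.names = FALSE)))
  })
  names(sub_sets) <- sub_names
  sub_sets <- sub_sets[vapply(sub_sets, length, integer(1)) > 0L]
  gmt_b <- structure(list(sets = sub_sets,
                          descriptions = setNames(rep("synthetic metabolic subsystem",
                                                      length(sub_sets)), names(sub_sets)),
                          layer_label = "subsystem"),
                     class = "gene_set_collection")

  # signalling modules: a chosen fraction of the catalysts plus private genes
  used <- sort(unique(unlist(catalysts, use.names = FALSE)))
  n_shared <- round(spec$shared_fraction * length(used))
  shared <- sort(if (n_shared > 0L) used[sample.int(length(used), n_shared)] else character(0))
  priv_per_module <- 2L
  priv <- sprintf("SYNS%03d", seq_len(spec$n_modules * priv_per_module))
  mod_names <- sprintf("MODULE%d", seq_len(spec$n_modules))
  mod_sets <- lapply(seq_len(spec$n_modules), function(j) {
    sh <- shared[seq_along(shared) %% spec$n_modules == (j - 1L)]
    sort(c(sh, priv[(j - 1L) * priv_per_module + seq_len(priv_per_module)]))
  })
  names(mod_sets) <- mod_names
  gmt_a <- structure(list(sets = mod_sets,
                          descriptions = setNames(rep("synthetic signalling module",
                                                      length(mod_sets)), mod_names),
                          layer_label = "module"),
                     class = "gene_set_collection")

  # expected crosstalk edges by exhaustive double loop
  erows <- list()
  for (m in names(mod_sets)) {
    for (s in names(sub_sets)) {
      w <- length(intersect(intersect(mod_sets[[m]], sub_sets[[s]]), shared))
      if (w >= 1L)
        erows[[length(erows) + 1L]] <- data.frame(
          source = m, target = s, weight = w, stringsAsFactors = FALSE)
    }
  }
  expected_edges <- if (length(erows)) do.call(rbind, erows) else
    data.frame(source = character(0), target = character(0), weight = integer(0),
               stringsAsFactors = FALSE)

  idmap <- hugo_of

  structure(list(
    map = doc, rules = rules_df, idmap = idmap,
    gmt_a = gmt_a, gmt_b = gmt_b, assignment = assignment,
    truth = list(
      catalysts = catalysts,
      glyphs = data.frame(reaction_id = names(reactions),
                          x = glyph_x, y = glyph_y, stringsAsFactors = FALSE),
      shared = shared,
      expected_edges = expected_edges
    ),
    spec = spec
  ), class = "synth_bundle")
}

#' Write a synthetic bundle to a directory
#'
#' Emits `map.xml`, `rules.tsv`, `idmap.tsv`, `modules.gmt`,
#' `subsystems.gmt`, `assignment.tsv` and ground-truth tables
#' (`truth_catalysts.tsv`, `truth_glyphs.tsv`, `truth_shared.txt`,
#' `truth_edges.tsv`).
#'
#' @param bundle A `synth_bundle`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synth_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(
    map = file.path(dir, "map.xml"),
    rules = file.path(dir, "rules.tsv"),
    idmap = file.path(dir, "idmap.tsv"),
    gmt_a = file.path(dir, "modules.gmt"),
    gmt_b = file.path(dir, "subsystems.gmt"),
    assignment = file.path(dir, "assignment.tsv"),
    truth_catalysts = file.path(dir, "truth_catalysts.tsv"),
    truth_glyphs = file.path(dir, "truth_glyphs.tsv"),
    truth_shared = file.path(dir, "truth_shared.txt"),
    truth_edges = file.path(dir, "truth_edges.tsv")
  )
  write_map(bundle$map, p[["map"]])
  write.table(bundle$rules, p[["rules"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(entrez = names(bundle$idmap), symbol = unname(bundle$idmap)),
              p[["idmap"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(bundle$gmt_a, p[["gmt_a"]])
  write_gmt(bundle$gmt_b, p[["gmt_b"]])
  write.table(bundle$assignment, p[["assignment"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(vapply(names(bundle$truth$catalysts), function(r)
    paste0(r, "\t", paste(bundle$truth$catalysts[[r]], collapse = ",")),
    character(1)), p[["truth_catalysts"]])
  write.table(bundle$truth$glyphs, p[["truth_glyphs"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(bundle$truth$shared, p[["truth_shared"]])
  write.table(bundle$truth$expected_edges, p[["truth_edges"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(p)
}
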