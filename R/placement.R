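#' Placement algorithm parameters
#'
#' @param n_points Number of random points drawn inside each reaction's
#'   Voronoi cell before clustering; 100 is sufficient in practice for the
#'   catalyst counts seen on genome-scale maps.
#' @param rng_seed Integer seed; a single generator is consumed in
#'   deterministic reaction-id order, so identical inputs give bit-identical
#'   placements.
#' @param protein_width,protein_height Box dimensions (canvas units) of the
#'   created protein nodes.
#' @param max_resample When a reaction has more catalysts than sampled points,
#'   the point count is doubled up to this many times before failing.
#' @return List of class `placement_config`.
#' @export
placement_config <- function(n_points = 100L, rng_seed = 0L,
                             protein_width = 80, protein_height = 40,
                             max_resample = 10L) {
  stopifnot(n_points >= 1L, max_resample >= 1L,
            protein_width > 0, protein_height > 0)
  structure(list(n_points = as.integer(n_points), rng_seed = as.integer(rng_seed),
                 protein_width = protein_width, protein_height = protein_height,
                 max_resample = as.integer(max_resample)),
            class = "placement_config")
}

# ---- convex polygon primitives -------------------------------------------
# polygons are n x 2 matrices of vertices in order; all cells here are convex
# (intersections of half-planes with the canvas rectangle)

rect_polygon <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

polygon_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_centroid <- function(poly) {
  n <- nrow(poly)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1L)
  cross <- x * y[j] - x[j] * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps) return(c(x = mean(x), y = mean(y)))
  c(x = sum((x + x[j]) * cross) / (6 * a),
    y = sum((y + y[j]) * cross) / (6 * a))
}

# Sutherland-Hodgman clip of a convex polygon against half-plane
# a*x + b*y + c <= 0
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (is.null(n) || n == 0L) return(poly)
  out <- matrix(numeric(0), ncol = 2)
  d <- a * poly[, 1] + b * poly[, 2] + c
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    pi <- poly[i, ]; pj <- poly[j, ]
    di <- d[i]; dj <- d[j]
    if (di <= 0) out <- rbind(out, pi)
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      t <- di / (di - dj)
      out <- rbind(out, pi + t * (pj - pi))
    }
  }
  out
}

#' Seeds for the Voronoi tessellation of a map
#'
#' Every visual element of the map becomes a seed: one `ALIAS` seed per
#' species alias (at its box centre) and one `REACTION_GLYPH` seed per
#' reaction (at its central-glyph position). Coincident seed locations are
#' separated by a deterministic spiral jitter of 1e-3 canvas units (the
#' tessellation requires distinct sites); a message reports how many seeds
#' were moved.
#'
#' @param doc A [map_document].
#' @return data.frame with columns `owner_id`, `owner_kind`, `x`, `y`.
#' @export
build_seeds <- function(doc) {
  rids <- names(doc$reactions)
  gl <- if (length(rids)) vapply(rids, function(r) reaction_glyph_position(doc, r),
                                 numeric(2)) else matrix(numeric(0), nrow = 2)
  seeds <- data.frame(
    owner_id = c(doc$aliases$alias_id, rids),
    owner_kind = c(rep("ALIAS", nrow(doc$aliases)),
                   rep("REACTION_GLYPH", length(rids))),
    x = c(doc$aliases$x + doc$aliases$width / 2,
          if (length(rids)) gl["x", ] else numeric(0)),
    y = c(doc$aliases$y + doc$aliases$height / 2,
          if (length(rids)) gl["y", ] else numeric(0)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  # deterministic golden-angle spiral jitter for coincident locations
  jittered <- 0L
  repeat {
    key <- paste(seeds$x, seeds$y)
    dup <- duplicated(key)
    if (!any(dup)) break
    k <- which(dup)
    ang <- 2.39996322972865332 * seq_along(k)
    r <- 1e-3 * seq_along(k)
    seeds$x[k] <- seeds$x[k] + r * cos(ang)
    seeds$y[k] <- seeds$y[k] + r * sin(ang)
    jittered <- jittered + length(k)
  }
  if (jittered > 0L)
    message("build_seeds: jittered ", jittered, " coincident seed location(s)")
  seeds
}

#' Voronoi tessellation clipped to the canvas
#'
#' Computes, for each seed, the region of the canvas closer to it than to any
#' other seed. Each cell is built by clipping the canvas rectangle against the
#' perpendicular-bisector half-plane towards every other seed, so cells are
#' convex, tile the canvas exactly, and unbounded regions are truncated at the
#' canvas edges.
#'
#' @param seeds data.frame from [build_seeds()] (columns `owner_id`, `x`, `y`).
#' @param canvas List with `width` and `height`.
#' @return Named list (by `owner_id`) of cells; each cell is a list with
#'   `owner_id` and `polygon` (matrix of vertices).
#' @export
clipped_voronoi <- function(seeds, canvas) {
  n <- nrow(seeds)
  if (is.null(n) || n < 1L) stop("clipped_voronoi: need at least one seed", call. = FALSE)
  if (any(seeds$x < 0 | seeds$x > canvas$width |
          seeds$y < 0 | seeds$y > canvas$height))
    stop("clipped_voronoi: seed outside canvas", call. = FALSE)
  rect <- rect_polygon(0, 0, canvas$width, canvas$height)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    poly <- rect
    xi <- seeds$x[i]; yi <- seeds$y[i]
    for (j in seq_len(n)) {
      if (j == i) next
      # half-plane of points at least as close to seed i as to seed j:
      # (p - m) . (sj - si) <= 0 with m the midpoint
      a <- seeds$x[j] - xi; b <- seeds$y[j] - yi
      mx <- (seeds$x[j] + xi) / 2; my <- (seeds$y[j] + yi) / 2
      poly <- clip_halfplane(poly, a, b, -(a * mx + b * my))
      if (nrow(poly) < 3L) break
    }
    cells[[i]] <- list(owner_id = seeds$owner_id[i], polygon = poly)
  }
  names(cells) <- seeds$owner_id
  cells
}

#' Uniform random points inside a convex cell
#'
#' Fan-triangulates the (convex) polygon, picks triangles with probability
#' proportional to area, and samples uniformly within each triangle. Consumes
#' the R random number generator, so results are reproducible under
#' `set.seed()`.
#'
#' @param cell A cell from [clipped_voronoi()].
#' @param n Number of points.
#' @return `n` x 2 matrix of points.
#' @export
sample_cell <- function(cell, n) {
  stopifnot(n >= 1L)
  poly <- cell$polygon
  if (is.null(nrow(poly)) || nrow(poly) < 3L || polygon_area(poly) <= 0)
    stop("sample_cell: degenerate (zero-area) cell for owner ", cell$owner_id,
         call. = FALSE)
  nv <- nrow(poly)
  # fan triangulation from vertex 1
  tri <- lapply(2:(nv - 1L), function(i) poly[c(1L, i, i + 1L), , drop = FALSE])
  areas <- vapply(tri, polygon_area, numeric(1))
  pick <- sample.int(length(tri), n, replace = TRUE, prob = areas)
  u1 <- runif(n); u2 <- runif(n)
  s <- sqrt(u1)
  pts <- t(vapply(seq_len(n), function(k) {
    tg <- tri[[pick[k]]]
    (1 - s[k]) * tg[1, ] + s[k] * (1 - u2[k]) * tg[2, ] + s[k] * u2[k] * tg[3, ]
  }, numeric(2)))
  colnames(pts) <- c("x", "y")
  pts
}

# k-means++ seeding, consuming the R RNG
kmeanspp_init <- function(points, k) {
  n <- nrow(points)
  centers <- matrix(NA_real_, k, 2)
  idx <- sample.int(n, 1L)
  centers[1, ] <- points[idx, ]
  if (k > 1L) {
    d2 <- (points[, 1] - centers[1, 1])^2 + (points[, 2] - centers[1, 2])^2
    for (j in 2:k) {
      if (sum(d2) <= 0) idx <- sample.int(n, 1L)
      else idx <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- points[idx, ]
      d2 <- pmin(d2, (points[, 1] - centers[j, 1])^2 + (points[, 2] - centers[j, 2])^2)
    }
  }
  centers
}

#' Cluster points and return the K cluster centroids
#'
#' K-means with k-means++ initialisation (10 restarts, best within-cluster sum
#' of squares kept, ties broken by first found); Lloyd iterations are run by
#' [stats::kmeans()]. Each returned centroid is the arithmetic mean of its
#' assigned points. The degenerate ends are exact: `k = 1` returns the mean of
#' all points, `k = nrow(points)` returns the points themselves.
#'
#' @param points n x 2 matrix.
#' @param k Number of clusters, `1 <= k <= nrow(points)`.
#' @param nstart Number of k-means++ restarts.
#' @return `k` x 2 matrix of centroids.
#' @export
cluster_centroids <- function(points, k, nstart = 10L) {
  n <- nrow(points)
  if (k < 1L || k > n)
    stop("cluster_centroids: k must be in [1, ", n, "], got ", k, call. = FALSE)
  if (k == 1L) return(matrix(colMeans(points), 1, 2,
                             dimnames = list(NULL, c("x", "y"))))
  if (k == n) {
    out <- points
    colnames(out) <- c("x", "y")
    return(out)
  }
  best <- NULL
  best_wcss <- Inf
  for (s in seq_len(nstart)) {
    init <- kmeanspp_init(points, k)
    fit <- tryCatch(
      suppressWarnings(kmeans(points, centers = init, iter.max = 100L,
                              algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit) || nrow(fit$centers) != k) next
    if (fit$tot.withinss < best_wcss) {
      best_wcss <- fit$tot.withinss
      best <- fit$centers
    }
  }
  if (is.null(best))
    stop("cluster_centroids: clustering failed for k = ", k, call. = FALSE)
  dimnames(best) <- list(NULL, c("x", "y"))
  best
}

#' Place catalyst protein nodes in the vicinity of their reactions
#'
#' Implements the automatic protein-placement procedure: (1) every alias
#' centre and reaction glyph becomes a Voronoi seed and the canvas is
#' tessellated into clipped cells; (2) inside each catalysed reaction's cell,
#' `n_points` random points are drawn (doubled, up to `max_resample` times,
#' if a reaction has more catalysts than points); (3) the points are grouped
#' into K clusters, K being the number of catalyst proteins of the reaction,
#' and each cluster centroid becomes the centre of one placed protein node.
#' Because the cells are convex and contain only their own seed's territory,
#' placed centres never collide with existing map elements.
#'
#' The sampling region is additionally inset from the canvas edge by half the
#' protein box size, so created boxes always fit the canvas; if that inset
#' empties a cell, the full cell is used and the box clamped.
#'
#' Repeated symbols across the whole result are disambiguated by the
#' CellDesigner apostrophe convention: the k-th occurrence (k >= 2) of a
#' symbol carries k-1 trailing apostrophes. Reactions are processed in sorted
#' reaction-id order with a single seeded generator, so the result is
#' deterministic.
#'
#' @param doc A [map_document] (the metabolic layer).
#' @param prmap A `protein_reaction_map` from [build_protein_reaction_map()].
#' @param config A [placement_config()].
#' @return Object of class `placement_result`: `placed` data.frame
#'   (`symbol`, `display_name`, `reaction_id`, `x`, `y` centre coordinates,
#'   `width`, `height`) and `stats` (proteins placed, aliases created,
#'   reactions processed / skipped).
#' @export
place_proteins <- function(doc, prmap, config = placement_config()) {
  rids <- sort(names(prmap$by_reaction))
  missing_rx <- setdiff(rids, names(doc$reactions))
  if (length(missing_rx) > 0L)
    stop("place_proteins: reaction(s) not on the map: ",
         paste(missing_rx, collapse = ", "), call. = FALSE)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$rng_seed)

  seeds <- build_seeds(doc)
  cells <- clipped_voronoi(seeds, doc$canvas)
  # sampling region inset: keep protein box centres >= half a box from edges
  ix0 <- config$protein_width / 2
  iy0 <- config$protein_height / 2
  ix1 <- doc$canvas$width - ix0
  iy1 <- doc$canvas$height - iy0

  rows <- vector("list", length(rids))
  skipped <- 0L
  for (ii in seq_along(rids)) {
    rid <- rids[ii]
    syms <- prmap$by_reaction[[rid]]
    k <- length(syms)
    cell <- cells[[rid]]
    # inset the sampling region so protein boxes stay on-canvas
    poly <- cell$polygon
    poly <- clip_halfplane(poly, -1, 0, ix0)   # x >= ix0
    poly <- clip_halfplane(poly, 1, 0, -ix1)   # x <= ix1
    poly <- clip_halfplane(poly, 0, -1, iy0)   # y >= iy0
    poly <- clip_halfplane(poly, 0, 1, -iy1)   # y <= iy1
    use_cell <- if (nrow(poly) >= 3L && polygon_area(poly) > 0)
      list(owner_id = rid, polygon = poly) else cell

    n <- config$n_points
    tries <- 0L
    while (n < k && tries < config$max_resample) {
      n <- n * 2L
      tries <- tries + 1L
    }
    if (n < k) {
      stop("place_proteins: reaction ", rid, " has ", k,
           " catalysts but only ", n, " sample points after ",
           config$max_resample, " doublings", call. = FALSE)
    }
    pts <- sample_cell(use_cell, n)
    centers <- cluster_centroids(pts, k)
    rows[[ii]] <- data.frame(
      symbol = syms, display_name = NA_character_, reaction_id = rid,
      x = centers[, 1], y = centers[, 2],
      width = config$protein_width, height = config$protein_height,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  placed <- do.call(rbind, rows)
  if (is.null(placed))
    placed <- data.frame(symbol = character(0), display_name = character(0),
                         reaction_id = character(0), x = numeric(0), y = numeric(0),
                         width = numeric(0), height = numeric(0),
                         stringsAsFactors = FALSE)

  # apostrophe disambiguation, global, in reaction-id then symbol order
  if (nrow(placed) > 0L) {
    occ <- stats::ave(seq_len(nrow(placed)), placed$symbol, FUN = seq_along)
    placed$display_name <- paste0(placed$symbol,
                                  vapply(occ - 1L, function(k)
                                    paste(rep("'", k), collapse = ""), character(1)))
  }

  structure(list(
    placed = placed,
    stats = list(
      proteins_placed = length(unique(placed$symbol)),
      aliases_created = nrow(placed),
      reactions_processed = length(rids),
      reactions_skipped = skipped
    )
  ), class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat("protein placement result\n")
  cat(sprintf("  proteins placed:     %d\n", x$stats$proteins_placed))
  cat(sprintf("  aliases created:     %d\n", x$stats$aliases_created))
  cat(sprintf("  reactions processed: %d\n", x$stats$reactions_processed))
  invisible(x)
}

#' Convert a placement result into a proteins-only overlay map
#'
#' Each placed protein instance becomes one species (named with its
#' apostrophe-suffixed display name, carrying the base symbol in its
#' `Identifiers` annotation) with a single alias whose box is centred on the
#' cluster centroid. The overlay shares the base map's canvas and can be
#' merged back with [merge_maps()].
#'
#' @param result A `placement_result`.
#' @param canvas Canvas of the base map (list with `width`, `height`).
#' @return A [map_document] containing only the placed protein nodes.
#' @export
placement_to_map <- function(result, canvas) {
  p <- result$placed
  n <- nrow(p)
  ent <- data.frame(
    entity_id = sprintf("p_s%d", seq_len(n)),
    name = p$display_name,
    entity_class = rep("PROTEIN", n),
    stringsAsFactors = FALSE
  )
  ent$annotation <- lapply(seq_len(n), function(i) list(Identifiers = p$symbol[i]))
  x <- pmin(pmax(p$x - p$width / 2, 0), canvas$width - p$width)
  y <- pmin(pmax(p$y - p$height / 2, 0), canvas$height - p$height)
  al <- data.frame(
    alias_id = sprintf("p_sa%d", seq_len(n)),
    entity_id = ent$entity_id,
    x = x, y = y, width = p$width, height = p$height,
    stringsAsFactors = FALSE
  )
  map_document(ent, al, list(), canvas)
}

#' Write the placement table
#'
#' Intermediate tabular form of a placement (the role the BiNoM reaction
#' format plays in the original workflow): one row per placed node with
#' display name, base symbol, owning reaction, centre coordinates and box
#' size.
#'
#' @param result A `placement_result`.
#' @param path File path (TSV).
#' @export
write_placement_table <- function(result, path) {
  write.table(result$placed[, c("display_name", "symbol", "reaction_id",
                                "x", "y", "width", "height")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
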