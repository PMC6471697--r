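test_that("build_seeds emits one seed per alias and per reaction", {
  doc <- make_toy_map()
  seeds <- build_seeds(doc)
  expect_equal(nrow(seeds), 3 + 1)
  expect_equal(sum(seeds$owner_kind == "ALIAS"), 3)
  expect_equal(sum(seeds$owner_kind == "REACTION_GLYPH"), 1)
  # alias seeds at box centres
  expect_equal(seeds$x[seeds$owner_id == "sa1"], 30)
  expect_equal(seeds$y[seeds$owner_id == "sa1"], 20)
  # empty map -> no seeds
  empty <- make_two_alias_map()
  expect_equal(nrow(build_seeds(empty)), 2)
})

test_that("coincident seed locations are jittered apart, count preserved", {
  doc <- make_two_alias_map()
  doc$aliases[2, c("x", "y", "width", "height")] <-
    doc$aliases[1, c("x", "y", "width", "height")]
  doc <- map_document(doc$entities, doc$aliases, doc$reactions, doc$canvas)
  seeds <- suppressMessages(build_seeds(doc))
  expect_equal(nrow(seeds), 2)
  expect_false(seeds$x[1] == seeds$x[2] && seeds$y[1] == seeds$y[2])
  # jitter magnitude is tiny
  expect_lt(abs(seeds$x[2] - seeds$x[1]), 0.01)
})

test_that("two seeds split the canvas along the perpendicular bisector", {
  seeds <- data.frame(owner_id = c("a", "b"), x = c(25, 75), y = c(50, 50),
                      stringsAsFactors = FALSE)
  cells <- clipped_voronoi(seeds, list(width = 100, height = 100))
  expect_equal(shoelace(cells$a$polygon), 5000)
  expect_equal(shoelace(cells$b$polygon), 5000)
  expect_lte(max(cells$a$polygon[, 1]), 50)
  expect_gte(min(cells$b$polygon[, 1]), 50)
})

test_that("a single seed owns the whole canvas; zero seeds error", {
  seeds <- data.frame(owner_id = "a", x = 10, y = 90, stringsAsFactors = FALSE)
  cells <- clipped_voronoi(seeds, list(width = 40, height = 120))
  expect_equal(shoelace(cells$a$polygon), 40 * 120)
  expect_error(clipped_voronoi(seeds[0, ], list(width = 10, height = 10)),
               "at least one seed")
})

test_that("voronoi cells tile the canvas and match a Monte-Carlo point oracle", {
  set.seed(42)
  canvas <- list(width = 300, height = 200)
  seeds <- data.frame(owner_id = paste0("s", 1:10),
                      x = runif(10, 0, 300), y = runif(10, 0, 200),
                      stringsAsFactors = FALSE)
  cells <- clipped_voronoi(seeds, canvas)
  areas <- vapply(cells, function(c) shoelace(c$polygon), numeric(1))
  expect_equal(sum(areas), 300 * 200, tolerance = 1e-6)

  # classify 1e5 uniform points by nearest seed; area fractions must agree
  n <- 1e5
  px <- runif(n, 0, 300); py <- runif(n, 0, 200)
  d2 <- outer(px, seeds$x, function(a, b) (a - b)^2) +
    outer(py, seeds$y, function(a, b) (a - b)^2)
  owner <- seeds$owner_id[max.col(-d2)]
  frac_mc <- table(factor(owner, levels = seeds$owner_id)) / n
  frac_poly <- areas[seeds$owner_id] / sum(areas)
  expect_equal(as.numeric(frac_mc), as.numeric(frac_poly), tolerance = 0.02)
})

test_that("sample_cell stays inside the polygon and is RNG-reproducible", {
  cell <- list(owner_id = "u",
               polygon = cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)))
  set.seed(1); p1 <- sample_cell(cell, 100)
  expect_equal(nrow(p1), 100)
  expect_true(all(p1[, 1] > 0 & p1[, 1] < 1 & p1[, 2] > 0 & p1[, 2] < 1))
  set.seed(1); p2 <- sample_cell(cell, 100)
  expect_identical(p1, p2)
  # degenerate cell errors with its owner id
  flat <- list(owner_id = "bad",
               polygon = cbind(x = c(0, 1, 2), y = c(0, 0, 0)))
  expect_error(sample_cell(flat, 5), "degenerate.*bad")
})

test_that("empirical centroid of triangle samples matches the analytic centroid", {
  tri <- cbind(x = c(0, 4, 1), y = c(0, 0, 3))
  cell <- list(owner_id = "t", polygon = tri)
  set.seed(7)
  pts <- sample_cell(cell, 1e4)
  truth <- poly_centroid(tri)  # (5/3, 1)
  expect_equal(truth, c(5 / 3, 1))
  expect_lt(abs(mean(pts[, 1]) - truth[1]), 0.03)
  expect_lt(abs(mean(pts[, 2]) - truth[2]), 0.03)
})

test_that("cluster_centroids honours the exact degenerate forms", {
  set.seed(3)
  pts <- cbind(x = runif(40), y = runif(40))
  expect_equal(cluster_centroids(pts, 1), matrix(colMeans(pts), 1, 2,
                                                 dimnames = list(NULL, c("x", "y"))))
  out <- cluster_centroids(pts, nrow(pts))
  expect_equal(out[order(out[, 1]), ], pts[order(pts[, 1]), ], ignore_attr = TRUE)
  expect_error(cluster_centroids(pts, 41), "k must be in")
  expect_error(cluster_centroids(pts, 0), "k must be in")
})

test_that("k-means recovers two well-separated blobs", {
  set.seed(11)
  mu <- rbind(c(2, 2), c(8, 9))
  pts <- rbind(cbind(rnorm(50, mu[1, 1], 0.01), rnorm(50, mu[1, 2], 0.01)),
               cbind(rnorm(50, mu[2, 1], 0.01), rnorm(50, mu[2, 2], 0.01)))
  ctr <- cluster_centroids(pts, 2)
  ctr <- ctr[order(ctr[, 1]), ]
  expect_lt(max(abs(ctr - mu)), 0.05)
})

test_that("place_proteins: counts, containment and determinism on the toy map", {
  doc <- make_toy_map()
  prmap <- structure(list(by_reaction = list(re1 = c("HK1", "GCK")),
                          by_protein = list(HK1 = "re1", GCK = "re1"),
                          unmapped = list()),
                     class = "protein_reaction_map")
  cfg <- placement_config(n_points = 50, rng_seed = 4,
                          protein_width = 20, protein_height = 10)
  res <- place_proteins(doc, prmap, cfg)
  expect_equal(nrow(res$placed), 2)
  expect_equal(res$stats$aliases_created, 2)
  expect_equal(res$stats$proteins_placed, 2)
  # nearest seed of each placed centre is the owning reaction's glyph
  seeds <- build_seeds(doc)
  for (i in 1:2) {
    expect_equal(nearest_seed(c(res$placed$x[i], res$placed$y[i]), seeds), "re1")
  }
  res2 <- place_proteins(doc, prmap, cfg)
  expect_identical(res, res2)
  # unknown reaction in the association map is an error listing the id
  bad <- prmap; bad$by_reaction$reX <- "A"
  expect_error(place_proteins(doc, bad, cfg), "reX")
})

test_that("apostrophe naming numbers repeated symbols in deterministic order", {
  b <- generate_synthetic_bundle(synth_spec(n_metabolites = 6, n_reactions = 3,
                                            catalysts_min = 1, catalysts_max = 1,
                                            rng_seed = 5, gene_pool_size = 1))
  # single-gene pool: all 3 reactions catalysed by the same protein
  prmap <- suppressMessages(build_protein_reaction_map(b$rules, b$idmap))
  res <- place_proteins(b$map, prmap, placement_config(n_points = 30, rng_seed = 0))
  sym <- unique(res$placed$symbol)
  expect_length(sym, 1)
  expect_equal(res$placed$display_name,
               c(sym, paste0(sym, "'"), paste0(sym, "''")))
  expect_equal(res$placed$reaction_id, sort(res$placed$reaction_id))
  expect_equal(res$stats$proteins_placed, 1)
  expect_equal(res$stats$aliases_created, 3)
})

test_that("dense synthetic placement satisfies counts and the nearest-seed oracle", {
  b <- generate_synthetic_bundle(synth_preset("dense", 2))
  prmap <- suppressMessages(build_protein_reaction_map(b$rules, b$idmap))
  res <- place_proteins(b$map, prmap, placement_config(rng_seed = 2))
  # conservation: per-reaction placed counts equal association counts
  placed_by_rx <- table(res$placed$reaction_id)
  for (r in names(prmap$by_reaction)) {
    expect_equal(unname(placed_by_rx[r]), length(prmap$by_reaction[[r]]),
                 ignore_attr = TRUE)
  }
  expect_equal(nrow(res$placed), sum(lengths(prmap$by_reaction)))
  # exhaustive nearest-seed check against ALL seeds
  seeds <- build_seeds(b$map)
  owners <- vapply(seq_len(nrow(res$placed)), function(i)
    nearest_seed(c(res$placed$x[i], res$placed$y[i]), seeds), character(1))
  expect_equal(owners, res$placed$reaction_id)
  # overlay map conversion respects canvas containment
  ov <- placement_to_map(res, b$map$canvas)
  expect_s3_class(validate_map(ov), "map_document")
})

test_that("placement resamples when a reaction has more catalysts than points", {
  doc <- make_toy_map()
  syms <- paste0("P", 1:12)
  prmap <- structure(list(by_reaction = list(re1 = syms),
                          by_protein = setNames(as.list(rep("re1", 12)), syms),
                          unmapped = list()),
                     class = "protein_reaction_map")
  res <- place_proteins(doc, prmap, placement_config(n_points = 5, rng_seed = 0,
                                                     protein_width = 10,
                                                     protein_height = 6))
  expect_equal(nrow(res$placed), 12)
  # but an impossible config fails loudly
  expect_error(
    place_proteins(doc, prmap, placement_config(n_points = 5, rng_seed = 0,
                                                max_resample = 1)),
    "re1")
})
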