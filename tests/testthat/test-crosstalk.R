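test_that("GMT parsing deduplicates genes and round-trips", {
  col <- read_gmt(text = "M1\tdesc\tA\tB\tA", layer_label = "module")
  expect_equal(col$sets, list(M1 = c("A", "B")))
  rt <- read_gmt(text = write_gmt(col), layer_label = "module")
  expect_equal(rt$sets, col$sets)
  expect_equal(rt$descriptions, col$descriptions)
  # empty input -> empty collection
  expect_length(read_gmt(text = character(0))$sets, 0)
  # malformed line reported with its number
  expect_error(read_gmt(text = c("M1\td\tA", "M2\tonlytwo")), "line 2")
})

test_that("shared_proteins intersects the layer unions, symmetrically", {
  a <- read_gmt(text = c("M1\td\tA\tB", "M2\td\tC"))
  b <- read_gmt(text = c("S1\td\tB\tC", "S2\td\tD"))
  expect_equal(shared_proteins(a, b), c("B", "C"))
  expect_equal(shared_proteins(a, b), shared_proteins(b, a))
  disj <- read_gmt(text = "S1\td\tZ")
  expect_length(shared_proteins(a, disj), 0)
})

test_that("enrichment p-values match the exact combinatorial sum", {
  # universe 20, set 6, query 10, overlap 5:
  # p = sum_{i=5..6} C(6,i) C(14,10-i) / C(20,10)
  universe <- paste0("g", 1:20)
  query <- universe[1:10]
  set5 <- c(universe[6:10], universe[11])       # overlap 5, size 6
  col <- structure(list(sets = list(S = set5),
                        descriptions = c(S = ""), layer_label = "x"),
                   class = "gene_set_collection")
  res <- enrich(col, query, universe, min_size = 1)
  manual <- (choose(6, 5) * choose(14, 5) + choose(6, 6) * choose(14, 4)) / choose(20, 10)
  expect_equal(res$p_value, manual, tolerance = 1e-12)
  expect_equal(res$overlap_count, 5)
  expect_equal(hyper_upper_oracle(20, 6, 10, 5), manual)
})

test_that("zero overlap gives p exactly 1; p is monotone in overlap", {
  universe <- paste0("g", 1:15)
  query <- universe[1:5]
  col <- structure(list(sets = list(S0 = universe[6:11]),
                        descriptions = c(S0 = ""), layer_label = "x"),
                   class = "gene_set_collection")
  expect_identical(enrich(col, query, universe, min_size = 1)$p_value, 1)
  # monotonicity for fixed sizes: p non-increasing as overlap grows
  p <- vapply(0:5, function(ov) hyper_upper_oracle(15, 6, 5, ov), numeric(1))
  expect_true(all(diff(p) <= 0))
  pv <- vapply(0:5, function(ov) {
    s <- c(query[seq_len(ov)], universe[6:(11 - ov)])
    cc <- structure(list(sets = list(S = s), descriptions = c(S = ""),
                         layer_label = "x"), class = "gene_set_collection")
    enrich(cc, query, universe, min_size = 1)$p_value
  }, numeric(1))
  expect_equal(pv, p, tolerance = 1e-12)
})

test_that("min-size filter, Bonferroni and query-universe guard behave", {
  universe <- paste0("g", 1:30)
  query <- universe[1:8]
  col <- structure(list(sets = list(big1 = universe[1:12], big2 = universe[13:25],
                                    small = universe[1:9]),
                        descriptions = c(big1 = "", big2 = "", small = ""),
                        layer_label = "x"),
                   class = "gene_set_collection")
  res <- enrich(col, query, universe, min_size = 10)
  expect_setequal(res$set_name, c("big1", "big2"))   # 'small' (9 genes) filtered
  expect_equal(res$p_adjusted, pmin(1, res$p_value * 2))
  expect_error(enrich(col, c(query, "NOT_THERE"), universe), "NOT_THERE")
})

test_that("crosstalk network edges carry exact intersection weights", {
  a <- read_gmt(text = c("M1\td\tA\tB"), layer_label = "module")
  b <- read_gmt(text = c("S1\td\tB", "S2\td\tC"), layer_label = "subsystem")
  net <- build_crosstalk_network(a, b, shared = "B")
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$source, "M1")
  expect_equal(net$edges$target, "S1")
  expect_equal(net$edges$weight, 1)
  # empty shared set -> edgeless network, nodes retained
  net0 <- build_crosstalk_network(a, b, shared = character(0))
  expect_equal(nrow(net0$edges), 0)
  expect_equal(nrow(net0$nodes), 3)
})

test_that("edge weights conserve the brute-force pairwise intersections", {
  b <- generate_synthetic_bundle(synth_preset("dense", 13))
  shared <- shared_proteins(b$gmt_a, b$gmt_b)
  expect_equal(shared, b$truth$shared)
  net <- build_crosstalk_network(b$gmt_a, b$gmt_b, shared)
  brute <- 0L
  for (m in names(b$gmt_a$sets)) {
    for (s in names(b$gmt_b$sets)) {
      brute <- brute + length(intersect(intersect(b$gmt_a$sets[[m]],
                                                  b$gmt_b$sets[[s]]), shared))
    }
  }
  expect_equal(sum(net$edges$weight), brute)
  # and the generator's own expectation agrees
  got <- net$edges[order(net$edges$source, net$edges$target),
                   c("source", "target", "weight")]
  want <- b$truth$expected_edges[order(b$truth$expected_edges$source,
                                       b$truth$expected_edges$target), ]
  expect_equal(got, want, ignore_attr = TRUE)
  # igraph view: degrees and bipartite structure
  g <- crosstalk_igraph(net)
  expect_equal(igraph::gsize(g), nrow(net$edges))
  expect_equal(sort(unique(igraph::V(g)$layer)), c("module", "subsystem"))
})

test_that("network TXT and SIF exports have the documented columns", {
  a <- read_gmt(text = "M1\td\tA\tB", layer_label = "module")
  b <- read_gmt(text = "S1\td\tA\tB", layer_label = "subsystem")
  net <- build_crosstalk_network(a, b, shared = c("A", "B"))
  tf <- tempfile()
  write_crosstalk_network(net, tf, "txt")
  tab <- read.delim(tf, check.names = FALSE)
  expect_equal(names(tab), c("source", "target", "interaction type",
                             "number of intersection proteins"))
  expect_equal(tab[["number of intersection proteins"]], 2)
  write_crosstalk_network(net, tf, "sif")
  expect_equal(readLines(tf), "M1\tcrosstalk\tS1")
})

test_that("reaction regulation counts equal an exhaustive double loop", {
  b <- generate_synthetic_bundle(synth_preset("dense", 21))
  prmap <- suppressMessages(build_protein_reaction_map(b$rules, b$idmap))
  shared <- shared_proteins(b$gmt_a, b$gmt_b)
  tab <- reaction_regulation_counts(prmap, b$assignment, b$gmt_a, shared)
  sub_of <- setNames(b$assignment$subsystem, b$assignment$reaction_id)
  for (m in names(b$gmt_a$sets)) {
    for (s in unique(b$assignment$subsystem)) {
      n <- 0L
      for (r in names(prmap$by_reaction)) {
        if (sub_of[[r]] == s &&
            any(prmap$by_reaction[[r]] %in% intersect(b$gmt_a$sets[[m]], shared)))
          n <- n + 1L
      }
      row <- tab[tab$module == m & tab$subsystem == s, ]
      expect_equal(nrow(row), as.integer(n > 0))
      if (n > 0) expect_equal(row$n_reactions, n)
    }
  }
})

test_that("a reaction counts once even with several qualifying catalysts", {
  prmap <- structure(list(by_reaction = list(r1 = c("A", "B", "C")),
                          by_protein = list(A = "r1", B = "r1", C = "r1"),
                          unmapped = list()),
                     class = "protein_reaction_map")
  assignment <- data.frame(reaction_id = "r1", subsystem = "S1",
                           stringsAsFactors = FALSE)
  modules <- read_gmt(text = "M1\td\tA\tB\tC", layer_label = "module")
  tab <- reaction_regulation_counts(prmap, assignment, modules,
                                    shared = c("A", "B", "C"))
  expect_equal(tab, data.frame(module = "M1", subsystem = "S1", n_reactions = 1L,
                               stringsAsFactors = FALSE), ignore_attr = TRUE)
  # unassigned reactions excluded with a diagnostic
  prmap$by_reaction$r2 <- "A"
  prmap$by_protein$A <- c("r1", "r2")
  expect_warning(reaction_regulation_counts(prmap, assignment, modules, "A"),
                 "without subsystem assignment")
  # multi-assignment rejected at load
  tf <- tempfile()
  writeLines(c("r1\tS1", "r1\tS2"), tf)
  expect_error(read_subsystem_assignment(tf), "more than once")
})
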