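# Fixtures and independent oracles shared by the test files.

# toy map: 2 metabolites + 1 protein, one catalysed reaction, 200x100 canvas
make_toy_map <- function() {
  entities <- data.frame(
    entity_id = c("s1", "s2", "s3"),
    name = c("METB", "METC", "GCK"),
    entity_class = c("METABOLITE", "METABOLITE", "PROTEIN"),
    stringsAsFactors = FALSE
  )
  entities$annotation <- list(list(), list(),
                              list(Identifiers = "GCK", References = "PMID:1"))
  aliases <- data.frame(
    alias_id = c("sa1", "sa2", "sa3"),
    entity_id = c("s1", "s2", "s3"),
    x = c(10, 150, 80), y = c(10, 70, 10),
    width = c(40, 40, 40), height = c(20, 20, 20),
    stringsAsFactors = FALSE
  )
  reactions <- list(
    re1 = list(reactants = "sa1", products = "sa2", modifiers = "sa3",
               annotation = list(Identifiers = c("GCK", "HK1", "GCK")))
  )
  map_document(entities, aliases, reactions, list(width = 200, height = 100))
}

# map with one entity shown twice (two aliases)
make_two_alias_map <- function() {
  entities <- data.frame(entity_id = "s1", name = "MET1",
                         entity_class = "METABOLITE", stringsAsFactors = FALSE)
  entities$annotation <- list(list())
  aliases <- data.frame(
    alias_id = c("sa1", "sa2"), entity_id = c("s1", "s1"),
    x = c(5, 100), y = c(5, 50), width = c(30, 30), height = c(10, 10),
    stringsAsFactors = FALSE
  )
  map_document(entities, aliases, list(), list(width = 200, height = 100))
}

# exhaustive nearest-seed classification (the brute-force containment oracle)
nearest_seed <- function(pt, seeds) {
  d2 <- (seeds$x - pt[1])^2 + (seeds$y - pt[2])^2
  seeds$owner_id[which.min(d2)]
}

# exact upper-tail hypergeometric probability by direct combinatorial sum:
# P[X >= ov] for X ~ Hypergeom(population N, successes m, draws q)
hyper_upper_oracle <- function(N, m, q, ov) {
  hi <- min(m, q)
  if (ov > hi) return(0)
  if (ov <= max(0, m + q - N)) return(1)
  i <- ov:hi
  sum(choose(m, i) * choose(N - m, q - i)) / choose(N, q)
}

# shoelace area, independent of the package's internal helper
shoelace <- function(poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  abs(sum(poly[j, 1] * poly[, 2] - poly[, 1] * poly[j, 2])) / 2
}

# analytic centroid of a simple polygon
poly_centroid <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  cr <- poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2]
  a <- sum(cr) / 2
  c(sum((poly[, 1] + poly[j, 1]) * cr) / (6 * a),
    sum((poly[, 2] + poly[j, 2]) * cr) / (6 * a))
}
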