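test_that("overlap coefficient is intersection over smaller set", {
  a <- reference_network(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
  b <- reference_network(c("g1", "g8"), c("g2", "g9"))
  expect_equal(overlap_coefficient(a, b), 0.5)   # 1 / min(3, 2)
  expect_equal(overlap_coefficient(a, a), 1)
  disj <- reference_network("x1", "x2")
  expect_equal(overlap_coefficient(a, disj), 0)
  # symmetry and containment
  sub <- reference_network(c("g1", "g2"), c("g2", "g3"))
  expect_equal(overlap_coefficient(a, sub), overlap_coefficient(sub, a))
  expect_equal(overlap_coefficient(a, sub), 1)
  # symbol matching is case-sensitive
  up <- reference_network("G1", "G2")
  expect_equal(overlap_coefficient(a, up), 0)
  expect_error(overlap_coefficient(a, character(0)), "empty")
})

test_that("exact power-law degree counts give an exact fit", {
  degrees <- rep(1:4, times = c(144, 36, 16, 9))   # 144 / k^2 nodes
  fit <- scale_free_fit(degrees)
  expect_equal(fit$gamma, 2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_error(scale_free_fit(rep(3, 50)), "distinct")
  # duplicating every node leaves P(k), hence the fit, unchanged
  fit2 <- scale_free_fit(c(degrees, degrees))
  expect_equal(fit2$gamma, fit$gamma, tolerance = 1e-12)
  expect_equal(fit2$r_squared, fit$r_squared, tolerance = 1e-12)
})

test_that("sampled power-law degrees recover the exponent", {
  k <- 1:50
  p <- k^-1.5 / sum(k^-1.5)
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    d <- sample(k, 10000, replace = TRUE, prob = p)
    g <- scale_free_fit(d)$gamma
    if (abs(g - 1.5) <= 0.15) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("scale matching picks the highest-confidence edges deterministically", {
  ref <- reference_network(c("a", "a", "b"), c("b", "c", "c"))
  conf <- c(0.9, 0.5, 0.1)
  names(conf) <- paste(ref$edges$a, ref$edges$b, sep = "\r")
  expect_identical(nrow(match_network_scale(3, ref, conf)$edges), 3L)
  top2 <- match_network_scale(2, ref, conf)
  expect_identical(paste(top2$edges$a, top2$edges$b),
                   c("a b", "a c"))
  # tie at the cut: lexicographically smaller edge kept
  conf_tie <- c(0.9, 0.5, 0.5)
  names(conf_tie) <- names(conf)   # a\rc and b\rc tied
  t2 <- match_network_scale(2, ref, conf_tie)
  expect_identical(paste(t2$edges$a, t2$edges$b), c("a b", "a c"))
  expect_error(match_network_scale(4, ref, conf), "between 1 and")
})

test_that("hubs are the top-degree quarter with ties included", {
  expect_identical(hubs(1:8), c(7L, 8L))
  expect_identical(hubs(rep(5, 6)), 1:6)
  expect_identical(hubs(c(0, 0, 0, 10)), 4L)
  expect_identical(hubs(c(3, 7, 7, 1, 2, 0, 0, 0)), c(2L, 3L))
})

test_that("Fisher enrichment matches the hypergeometric oracle on a table sweep", {
  fg <- sinum:::fisher_greater
  r <- fg(10, 2, 3, 15)
  expect_equal(r$odds_ratio, (10 * 15) / (2 * 3))
  expect_equal(r$p_value, oracle_fisher_greater_p(10, 2, 3, 15),
               tolerance = 1e-10)
  expect_equal(fg(0, 5, 4, 6)$odds_ratio, 0)
  expect_equal(fg(0, 5, 4, 6)$p_value, 1, tolerance = 1e-12)
  expect_identical(fg(3, 2, 0, 4)$odds_ratio, Inf)
  set.seed(8)
  for (rep in 1:60) {
    tb <- sample(0:12, 4, replace = TRUE)
    expect_equal(fg(tb[1], tb[2], tb[3], tb[4])$p_value,
                 oracle_fisher_greater_p(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-10)
  }
})

test_that("hub and edge enrichment build the right 2x2 tables", {
  # 6 cells, 4 genes; gene g1 is high-degree only in type A cells
  edges <- rbind(
    expand.grid(cell = 1:3, gene_i = 1, gene_j = 2:4),
    data.frame(cell = 4:6, gene_i = 3, gene_j = 4))
  edges$z <- 1
  scns <- manual_scn_set(edges[order(edges$cell), ],
                         gene_ids = paste0("g", 1:4),
                         cell_ids = paste0("c", 1:6))
  labels <- c(rep("A", 3), rep("B", 3))
  he <- hub_enrichment("g1", scns, labels, "A")
  expect_equal(he$table["target", "event"], 3)
  expect_equal(he$table["other", "event"], 0)
  expect_identical(he$odds_ratio, Inf)
  expect_equal(he$p_value, oracle_fisher_greater_p(3, 0, 0, 3),
               tolerance = 1e-12)

  ee <- edge_enrichment(c("g1", "g2"), scns, labels, "A")
  expect_identical(ee$odds_ratio, Inf)
  expect_equal(ee$p_value, 1 / choose(6, 3), tolerance = 1e-12)
  # an edge present nowhere is uninformative
  ee0 <- edge_enrichment(c("g2", "g3"), scns, labels, "A")
  expect_equal(ee0$p_value, 1)
  expect_error(edge_enrichment(c("g1", "g2"), scns, labels, "Z"),
               "not present")
})

test_that("a gene that is a hub everywhere is uninformative (p = 1)", {
  edges <- data.frame(cell = 1:6, gene_i = 1L, gene_j = 2L, z = 1)
  scns <- manual_scn_set(edges, paste0("g", 1:8), paste0("c", 1:6))
  labels <- rep(c("A", "B"), each = 3)
  he <- hub_enrichment("g1", scns, labels, "A")
  expect_equal(he$p_value, 1, tolerance = 1e-12)
})

test_that("marker screen excludes genes with expression differences", {
  set.seed(21)
  n <- 60
  labels <- rep(c("A", "B"), each = n / 2)
  # gene 1: degree-different AND expression-different -> filtered out
  # gene 2: degree-different only -> marker
  m <- 6
  deg <- matrix(rpois(m * n, 2), m, n)
  deg[1, labels == "A"] <- deg[1, labels == "A"] + 8
  deg[2, labels == "A"] <- deg[2, labels == "A"] + 8
  expr <- matrix(rnorm(m * n, 5), m, n)
  expr[1, labels == "A"] <- expr[1, labels == "A"] + 10
  ids <- paste0("g", 1:m)
  cells <- paste0("c", 1:n)
  dm <- structure(list(values = deg, gene_ids = ids, cell_ids = cells,
                       transform = "raw"), class = "degree_matrix")
  dimnames(dm$values) <- list(ids, cells)
  gem <- expression_matrix(expr - min(expr), gene_ids = ids,
                           cell_ids = cells, is_log_transformed = TRUE)
  res <- marker_screen(dm, gem, labels, "A")
  mk <- attr(res, "markers")
  expect_true("g2" %in% mk)
  expect_false("g1" %in% mk)
  expect_lt(res$p_hub_adj[res$gene == "g2"], 0.05)
  expect_lt(res$p_expr[res$gene == "g1"], 0.05)
})

test_that("aggregate networks use a strict frequency threshold and are monotone", {
  edges <- rbind(
    data.frame(cell = 1:8, gene_i = 1L, gene_j = 2L, z = 1),   # 8/10
    data.frame(cell = 1:7, gene_i = 1L, gene_j = 3L, z = 1),   # 7/10
    data.frame(cell = 1:2, gene_i = 2L, gene_j = 3L, z = 1))   # 2/10
  scns <- manual_scn_set(edges, paste0("g", 1:3), paste0("c", 1:10))
  labels <- rep("t0", 10)
  agg <- aggregate_network(scns, labels, "t0", min_fraction = 0.7)
  expect_identical(paste(agg$edges$gene_a, agg$edges$gene_b), "g1 g2")
  expect_equal(agg$edges$frequency, 0.8)
  all_edges <- aggregate_network(scns, labels, "t0", min_fraction = 0)
  expect_identical(nrow(all_edges$edges), 3L)
  # monotone: higher threshold gives a subset
  for (f in c(0.1, 0.5, 0.75)) {
    lo <- aggregate_network(scns, labels, "t0", min_fraction = f)$edges
    expect_true(all(paste(lo$gene_a, lo$gene_b) %in%
                      paste(all_edges$edges$gene_a, all_edges$edges$gene_b)))
  }
  expect_error(aggregate_network(scns, labels, "t1"), "not present")
})

test_that("degree trajectories report per-label means and peak labels", {
  vals <- rbind(a = c(0, 0, 4, 6), b = c(1, 3, 1, 3), zero = c(0, 0, 0, 0))
  dm <- structure(list(values = vals, gene_ids = rownames(vals),
                       cell_ids = paste0("c", 1:4), transform = "raw"),
                  class = "degree_matrix")
  labels <- c("t1", "t1", "t2", "t2")
  tr <- degree_trajectory(dm, labels)
  expect_equal(tr$means["a", ], c(t1 = 0, t2 = 5))
  expect_identical(tr$argmax$label[tr$argmax$gene == "a"], "t2")
  expect_identical(tr$argmax$label[tr$argmax$gene == "zero"], "t1")
  expect_true(tr$argmax$tied[tr$argmax$gene == "zero"])
  single <- degree_trajectory(dm, rep("all", 4), genes = "b")
  expect_equal(single$means["b", "all"], mean(vals["b", ]))
  expect_error(degree_trajectory(dm, labels, genes = "nope"), "unknown gene")
})
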