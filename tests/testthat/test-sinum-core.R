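test_that("symmetric 4-cell configuration is hand-computable and yields no edges", {
  gem <- symmetric_gem()
  # literal entropy-difference form: every cell scores (1/2) ln 2
  for (cell in 1:4) {
    expect_equal(local_mi(gem, NULL, "x", "y", cell, box_size = 0.5,
                          statistic = "entropy_diff"),
                 log(2) / 2, tolerance = 1e-13)
  }
  ppe <- pair_profile(gem, gene_x = "x", gene_y = "y", box_size = 0.5,
                      statistic = "entropy_diff")
  expect_equal(ppe$sd, 0)
  expect_equal(ppe$z_per_cell, rep(0, 4))
  # default restricted-MI form: symmetric too, hence sigma = 0, no edges
  ppr <- pair_profile(gem, gene_x = "x", gene_y = "y", box_size = 0.5)
  expect_equal(ppr$sd, 0)
  for (st in c("restricted_mi", "entropy_diff")) {
    scns <- infer_scns(gem, box_size = 0.5, z_threshold = 0, statistic = st)
    expect_identical(nrow(scns$edges), 0L)
  }
})

test_that("vectorized local MI matches the explicit-loop oracle", {
  for (seed in 1:4) {
    gem <- random_log_gem(10, 30, seed)
    grid <- build_grid(gem)
    set.seed(seed + 100)
    for (rep in 1:6) {
      gx <- sample(10, 1)
      gy <- sample(setdiff(1:10, gx), 1)
      cell <- sample(30, 1)
      for (st in c("restricted_mi", "entropy_diff")) {
        expect_equal(
          local_mi(gem, grid, gx, gy, cell, box_size = 0.2, statistic = st),
          oracle_local_mi(gem$values, gx, gy, cell, 0.2, st),
          tolerance = 1e-13)
      }
    }
  }
})

test_that("restricted MI over the full grid equals the global entropy difference", {
  # with box_size = 1 every neighborhood spans the full axis, and the
  # restricted sum collapses to H(X) + H(Y) - H(X, Y) >= 0
  for (seed in 1:3) {
    gem <- random_log_gem(6, 40, seed)
    grid <- build_grid(gem)
    for (cell in c(1, 20)) {
      a <- local_mi(gem, grid, 1, 2, cell, box_size = 1)
      b <- local_mi(gem, grid, 1, 2, cell, box_size = 1,
                    statistic = "entropy_diff")
      expect_equal(a, b, tolerance = 1e-12)
      expect_gte(a, -1e-12)
    }
  }
})

test_that("pair profiles standardize to mean 0 / population sd 1 and are symmetric", {
  gem <- random_log_gem(8, 50, 7)
  grid <- build_grid(gem)
  for (pr in list(c(1, 2), c(3, 8))) {
    pp <- pair_profile(gem, grid, gene_x = pr[1], gene_y = pr[2])
    expect_gt(pp$sd, 0)
    expect_equal(mean(pp$z_per_cell), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(pp$z_per_cell^2)), 1, tolerance = 1e-9)
    rev <- pair_profile(gem, grid, gene_x = pr[2], gene_y = pr[1])
    expect_equal(pp$mi_per_cell, rev$mi_per_cell)
    expect_equal(pp$z_per_cell, rev$z_per_cell)
  }
  expect_error(pair_profile(gem, grid, gene_x = 3, gene_y = 3), "self-pair")
  # explicit standardization example: scores (1, 2, 3)
  mi <- c(1, 2, 3)
  z <- (mi - mean(mi)) / sqrt(mean((mi - mean(mi))^2))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
})

test_that("z-scores and edge sets are invariant to the entropy log base", {
  gem <- random_log_gem(6, 45, 11)
  grid <- build_grid(gem)
  pp_e <- pair_profile(gem, grid, gene_x = 1, gene_y = 4)
  pp_2 <- pair_profile(gem, grid, gene_x = 1, gene_y = 4, log_base = 2)
  expect_equal(pp_e$z_per_cell, pp_2$z_per_cell, tolerance = 1e-9)
  expect_equal(pp_2$mi_per_cell, pp_e$mi_per_cell / log(2), tolerance = 1e-12)
  s_e <- infer_scns(gem)
  s_2 <- infer_scns(gem, log_base = 2)
  expect_identical(s_e$edges[c("cell", "gene_i", "gene_j")],
                   s_2$edges[c("cell", "gene_i", "gene_j")])
})

test_that("edge calls are strict and monotone in the z threshold", {
  gem <- random_log_gem(8, 40, 3)
  s0 <- infer_scns(gem, z_threshold = 0)
  expect_true(all(s0$edges$z > 0))
  s1 <- infer_scns(gem, z_threshold = 1)
  expect_true(all(s1$edges$z > 1))
  key <- function(s) paste(s$edges$cell, s$edges$gene_i, s$edges$gene_j)
  expect_true(all(key(s1) %in% key(s0)))       # raising never adds an edge
  # a threshold equal to an attained z excludes exactly that edge
  zstar <- s0$edges$z[1]
  sstar <- infer_scns(gem, z_threshold = zstar)
  expect_false(any(abs(sstar$edges$z - zstar) < 1e-15))
  expect_identical(nrow(infer_scns(gem, z_threshold = Inf)$edges), 0L)
})

test_that("inference is deterministic and restriction limits evaluated pairs", {
  gem <- random_log_gem(8, 40, 5)
  a <- infer_scns(gem)
  b <- infer_scns(gem, threads = 4)
  expect_identical(a$edges, b$edges)
  expect_identical(a$n_pairs_evaluated, 28L)

  restr <- cbind(c("g01", "g02", "g01", "zzz"), c("g03", "g04", "g03", "g05"))
  expect_message(r <- infer_scns(gem, pair_restriction = restr), "dropped")
  expect_identical(r$n_pairs_evaluated, 2L)    # duplicate + unmatched removed
  expect_true(all(paste(r$edges$gene_i, r$edges$gene_j) %in%
                    c("1 3", "2 4")))
  expect_error(infer_scns(gem, pair_restriction = cbind("nope", "nada")),
               "no restriction pair")
})

test_that("degenerate genes never produce edges", {
  vals <- rbind(a = runif(20), b = runif(20), c = rep(2, 20))
  gem <- expression_matrix(vals, is_log_transformed = TRUE)
  scns <- infer_scns(gem)
  expect_true(scns$degenerate["c"])
  expect_false(any(scns$edges$gene_i == 3 | scns$edges$gene_j == 3))
})

test_that("degree matrix obeys the handshake identity and transforms", {
  gem <- random_log_gem(8, 40, 9)
  scns <- infer_scns(gem)
  dm <- degree_matrix(scns, gem)
  expect_identical(dim(dm), dim(gem))
  expect_identical(dm$gene_ids, gem$gene_ids)
  edge_count <- table(factor(scns$edges$cell, levels = 1:40))
  expect_equal(unname(colSums(dm$values)), as.numeric(edge_count) * 2)

  empty <- infer_scns(gem, z_threshold = Inf)
  expect_true(all(degree_matrix(empty)$values == 0))

  one <- manual_scn_set(
    data.frame(cell = 1L, gene_i = 1L, gene_j = 2L, z = 3),
    gene_ids = paste0("g", 1:3), cell_ids = paste0("c", 1:2))
  d1 <- degree_matrix(one)
  expect_equal(d1$values, matrix(c(1, 1, 0, 0, 0, 0), 3, 2,
                                 dimnames = list(paste0("g", 1:3),
                                                 paste0("c", 1:2))))
  nine <- manual_scn_set(
    data.frame(cell = 1L, gene_i = rep(1L, 9), gene_j = 2:10, z = 1),
    gene_ids = paste0("g", 1:10), cell_ids = "c1")
  expect_equal(degree_matrix(nine, transform = "log10p1")$values["g1", "c1"], 1)

  other <- expression_matrix(matrix(runif(8 * 40), 8, 40))
  expect_error(degree_matrix(scns, other), "not aligned")
})

test_that("dropout-strict mode suppresses edges at zero-expression cells", {
  set.seed(4)
  vals <- matrix(rpois(6 * 40, 6), 6, 40)
  vals[1, 1:10] <- 0
  gem <- log_transform(expression_matrix(vals))
  s <- infer_scns(gem, drop_zero_edges = TRUE)
  bad <- s$edges$cell %in% 1:10 & (s$edges$gene_i == 1 | s$edges$gene_j == 1)
  expect_false(any(bad))
})
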