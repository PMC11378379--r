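test_that("generation is reproducible and validates its specification", {
  spec <- synthetic_spec(n_cells = 50, n_genes = 10, n_types = 2,
                         modules = list(list(genes = 1:3, active_types = 1,
                                             rho = 0.7)),
                         seed = 99)
  a <- synthetic_generate(spec)
  b <- synthetic_generate(spec)
  expect_identical(a$gem$values, b$gem$values)
  expect_identical(a$truth$cell_labels, b$truth$cell_labels)
  expect_identical(dim(a$gem), c(10L, 50L))
  expect_identical(a$truth$dark_genes, 1:3)
  expect_identical(nrow(a$truth$dependent_pairs_per_type$type1), 3L)
  expect_identical(nrow(a$truth$dependent_pairs_per_type$type2), 0L)

  expect_error(synthetic_spec(50, 10, modules = list(
    list(genes = 1:3, active_types = 1, rho = 0.5),
    list(genes = 3:5, active_types = 1, rho = 0.5))), "disjoint")
  expect_error(synthetic_spec(50, 10, n_types = 2,
                              type_proportions = c(0.6, 0.6)), "sum to 1")
  expect_error(synthetic_spec(50, 10, dropout_rate = 1), "dropout_rate")
})

test_that("planted modules realize their nominal correlation within active types", {
  hits_dep <- 0L
  hits_other <- 0L
  for (seed in 1:5) {
    spec <- synthetic_spec(n_cells = 1000, n_genes = 4, n_types = 2,
                           modules = list(list(genes = 1:2, active_types = 1,
                                               rho = 0.9)),
                           seed = seed)
    sim <- synthetic_generate(spec)
    act <- sim$truth$cell_labels == "type1"
    r_in <- cor(sim$gem$values[1, act], sim$gem$values[2, act])
    r_out <- cor(sim$gem$values[1, !act], sim$gem$values[2, !act])
    if (r_in > 0.6) hits_dep <- hits_dep + 1L
    if (abs(r_out) < 0.2) hits_other <- hits_other + 1L
  }
  expect_gte(hits_dep, 4L)
  expect_gte(hits_other, 4L)
})

test_that("null matrices have uncorrelated genes", {
  ok <- 0L
  for (seed in 1:5) {
    gem <- synthetic_null_matrix(n_cells = 500, n_genes = 4, seed = seed)
    rs <- c(cor(gem$values[1, ], gem$values[2, ]),
            cor(gem$values[3, ], gem$values[4, ]))
    if (all(abs(rs) < 0.1)) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("dark-module genes keep identical expression marginals across types", {
  ps <- vapply(1:8, function(seed) {
    sim <- synthetic_generate(synthetic_marker_spec(seed = seed))
    act <- sim$truth$cell_labels == "type1"
    g <- sim$truth$dark_genes[1]
    stats::wilcox.test(sim$gem$values[g, act],
                       sim$gem$values[g, !act], exact = FALSE)$p.value
  }, 0)
  expect_gte(sum(ps >= 0.05), 7L)
})

test_that("mean factors shift expression of active module genes only", {
  sim <- synthetic_generate(synthetic_modules_spec(seed = 3, mean_factor = 3))
  act <- sim$truth$cell_labels == "type1"
  g_mod <- 1        # module of type1
  g_bg <- 40        # background gene
  expect_gt(mean(sim$gem$values[g_mod, act]),
            2 * mean(sim$gem$values[g_mod, !act]))
  p_bg <- stats::wilcox.test(sim$gem$values[g_bg, act],
                             sim$gem$values[g_bg, !act],
                             exact = FALSE)$p.value
  expect_gte(p_bg, 0.01)
})

test_that("planted dependence raises edge z-scores monotonically with rho", {
  mean_dep_z <- vapply(c(0.3, 0.6, 0.9), function(rho) {
    spec <- synthetic_spec(n_cells = 200, n_genes = 6, n_types = 2,
                           modules = list(list(genes = 1:2, active_types = 1,
                                               rho = rho)),
                           seed = 42)
    sim <- synthetic_generate(spec)
    gem <- log_transform(sim$gem)
    act <- sim$truth$cell_labels == "type1"
    pp <- pair_profile(gem, gene_x = 1, gene_y = 2)
    mean(pp$z_per_cell[act])
  }, 0)
  expect_true(all(diff(mean_dep_z) > 0))
  expect_gt(mean_dep_z[3], 0)
})

test_that("null data produce few strong edges and no markers", {
  strong <- vapply(1:4, function(seed) {
    gem <- log_transform(synthetic_null_matrix(n_cells = 200, n_genes = 20,
                                               seed = seed))
    scns <- infer_scns(gem, z_threshold = 2)
    nrow(scns$edges) / (200 * choose(20, 2))
  }, 0)
  expect_lt(mean(strong), 0.08)

  empties <- vapply(1:4, function(seed) {
    gem_raw <- synthetic_null_matrix(n_cells = 150, n_genes = 20,
                                     seed = seed + 50)
    gem <- log_transform(gem_raw)
    dm <- degree_matrix(infer_scns(gem), gem)
    set.seed(seed)
    labels <- sample(rep(c("A", "B"), length.out = 150))
    length(attr(marker_screen(dm, gem, labels, "A"), "markers")) == 0L
  }, NA)
  expect_gte(sum(empties), 3L)
})

test_that("synthetic datasets round-trip through the disk format", {
  dir <- withr::local_tempdir()
  sim <- synthetic_generate(synthetic_spec(n_cells = 30, n_genes = 8,
                                           n_types = 2, seed = 5))
  write_synthetic(sim, dir)
  gem <- load_expression_matrix(file.path(dir, "gem.tsv"))
  expect_equal(gem$values, sim$gem$values)
  labels <- load_cell_labels(file.path(dir, "labels.tsv"))
  expect_identical(unname(labels), unname(sim$truth$cell_labels))
  expect_true(file.exists(file.path(dir, "truth.json")))
})
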