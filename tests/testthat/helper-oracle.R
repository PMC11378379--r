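# Independent oracles used throughout the suite. They share nothing with
# the package internals: explicit loops, direct distance sorting, direct
# combinatorial sums.

# Brute-force local MI for one (pair, cell): explicit binning loop,
# nearest-k selection by sorting distances, term-by-term summation.
oracle_local_mi <- function(vals, gx, gy, cell, box_size,
                            statistic = "restricted_mi",
                            log_base = exp(1)) {
  n <- ncol(vals)
  gr <- max(1L, floor(sqrt(n) + 0.5))
  k <- ceiling(box_size * n)
  axis <- function(g) {
    v <- vals[g, ]
    rng <- range(v)
    edges <- seq(rng[1L], rng[2L], length.out = gr + 1L)
    bin_of <- function(x) {
      for (b in seq_len(gr)) {
        if (x >= edges[b] && (b == gr || x < edges[b + 1L])) return(b)
      }
      gr
    }
    bins <- vapply(v, bin_of, 0L)
    d <- abs(v - v[cell])
    sel <- order(d, v, seq_len(n))[seq_len(k)]
    iv <- range(v[sel])
    list(bins = bins, lo = bin_of(iv[1L]), hi = bin_of(iv[2L]))
  }
  X <- axis(gx)
  Y <- axis(gy)
  nx <- vapply(seq_len(gr), function(b) sum(X$bins == b), 0)
  ny <- vapply(seq_len(gr), function(b) sum(Y$bins == b), 0)
  lb <- log(log_base)
  if (statistic == "restricted_mi") {
    s <- 0
    for (bx in X$lo:X$hi) {
      for (by in Y$lo:Y$hi) {
        nxy <- sum(X$bins == bx & Y$bins == by)
        if (nxy > 0) {
          s <- s + (nxy / n) * (log(n * nxy / (nx[bx] * ny[by])) / lb)
        }
      }
    }
    return(s)
  }
  ent <- function(cnt) {
    p <- cnt[cnt > 0] / n
    -sum(p * (log(p) / lb))
  }
  nxy <- c()
  for (bx in X$lo:X$hi) {
    for (by in Y$lo:Y$hi) {
      nxy <- c(nxy, sum(X$bins == bx & Y$bins == by))
    }
  }
  ent(nx[X$lo:X$hi]) + ent(ny[Y$lo:Y$hi]) - ent(nxy)
}

# One-sided (greater) Fisher p-value by direct hypergeometric summation
# with choose(); no phyper/dhyper.
oracle_fisher_greater_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b        # target cells
  c1 <- a + c        # event count
  amax <- min(r1, c1)
  tot <- choose(n, c1)
  s <- 0
  for (x in a:amax) {
    s <- s + choose(r1, x) * choose(n - r1, c1 - x)
  }
  s / tot
}

# Continuous random expression matrix already on the log scale (no ties,
# so grid-edge coincidences have probability zero).
random_log_gem <- function(m, n, seed) {
  set.seed(seed)
  vals <- matrix(runif(m * n, 0, 6), m, n)
  expression_matrix(vals,
                    gene_ids = sprintf("g%02d", seq_len(m)),
                    cell_ids = sprintf("c%02d", seq_len(n)),
                    is_log_transformed = TRUE)
}

# The hand-checkable symmetric 4-cell, 2-gene configuration:
# cells at (1,1), (1,2), (2,1), (2,2).
symmetric_gem <- function() {
  expression_matrix(rbind(x = c(1, 1, 2, 2), y = c(1, 2, 1, 2)),
                    is_log_transformed = TRUE)
}

# Tiny scn_set built by hand for fixture-level tests.
manual_scn_set <- function(edges, gene_ids, cell_ids) {
  structure(list(edges = edges, gene_ids = gene_ids, cell_ids = cell_ids,
                 params = list(box_size = 0.2, z_threshold = 0,
                               neighborhood = "nearest",
                               statistic = "restricted_mi",
                               log_base = exp(1), drop_zero_edges = FALSE),
                 n_pairs_evaluated = NA_integer_,
                 degenerate = logical(length(gene_ids))),
            class = "scn_set")
}
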