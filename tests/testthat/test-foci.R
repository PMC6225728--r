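test_that("aggregation counting follows the half-diameter rule", {
  dia <- 200
  ## all pairwise distances > dia/2: no aggregates
  far <- rbind(c(0, 0, 0), c(500, 0, 0), c(0, 500, 0))
  expect_identical(count_aggregations(far, dia)$n_aggregates, 0L)
  ## one pair at 0.4*dia (80 nm <= 100 nm threshold), rest isolated
  one <- rbind(c(0, 0, 0), c(80, 0, 0), c(2000, 0, 0), c(0, 2000, 0))
  r <- count_aggregations(one, dia)
  expect_identical(r$n_aggregates, 1L)
  expect_identical(r$cluster_sizes, 2L)
  ## chain: consecutive gaps 80 nm, ends 160 nm apart -> single linkage
  ## joins all three; complete linkage does not
  chain <- rbind(c(0, 0, 0), c(80, 0, 0), c(160, 0, 0))
  expect_identical(count_aggregations(chain, dia)$cluster_sizes, 3L)
  expect_identical(count_aggregations(chain, dia,
                                      linkage = "complete")$n_aggregates, 1L)
  expect_identical(count_aggregations(chain, dia,
                                      linkage = "complete")$cluster_sizes, 2L)
  ## 0 or 1 focus
  expect_identical(count_aggregations(matrix(numeric(0), 0, 3), dia)$n_aggregates, 0L)
  expect_identical(count_aggregations(matrix(0, 1, 3), dia)$n_aggregates, 0L)
})

test_that("single linkage equals the union-find oracle on random instances up to n = 50", {
  set.seed(50)
  for (rep in 1:40) {
    n <- sample(2:50, 1)
    pos <- matrix(runif(3 * n, 0, 1200), n, 3)
    thr <- runif(1, 50, 400)
    r <- count_aggregations(pos, 2 * thr)
    memb <- uf_clusters(pos, thr)
    sizes <- as.integer(table(memb))
    expect_identical(r$n_aggregates, sum(sizes >= 2))
    expect_identical(r$cluster_sizes, sort(sizes[sizes >= 2],
                                           decreasing = TRUE))
  }
})

test_that("aggregate count is monotone in the threshold and rigid-motion invariant", {
  set.seed(51)
  pos <- matrix(runif(90, 0, 1000), 30, 3)
  ## as the cutoff grows clusters only grow or merge, so the number of foci
  ## living in aggregates is monotone (the aggregate COUNT itself can drop
  ## when two aggregates merge, so it is not a valid invariant)
  mass <- vapply(c(50, 100, 200, 400, 800, 1600), function(dia)
    sum(count_aggregations(pos, dia)$cluster_sizes), integer(1))
  expect_true(all(diff(mass) >= 0))
  ## translation + rotation leave counts unchanged
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- pos %*% Rz + matrix(c(1e4, -2e3, 500), 30, 3, byrow = TRUE)
  a <- count_aggregations(pos, 300); b <- count_aggregations(moved, 300)
  expect_identical(a$n_aggregates, b$n_aggregates)
  expect_identical(a$cluster_sizes, b$cluster_sizes)
})

test_that("colocalization matching is one-to-one, symmetric in matched count", {
  A <- rbind(c(0, 0, 0), c(1000, 0, 0), c(0, 1000, 0))
  expect_equal(colocalize(A, A, 50)$fraction, 1)
  B_far <- A + 5000
  expect_equal(colocalize(A, B_far, 50)$fraction, 0)
  ## two A foci near one B focus: only one match
  A2 <- rbind(c(0, 0, 0), c(60, 0, 0))
  B2 <- rbind(c(30, 0, 0))
  r <- colocalize(A2, B2, 100)
  expect_identical(r$n_coloc, 1L)
  expect_equal(r$fraction, 0.5)
  ## matched-pair count is symmetric under channel swap
  set.seed(52)
  X <- matrix(runif(60, 0, 800), 20, 3)
  Y <- matrix(runif(45, 0, 800), 15, 3)
  expect_identical(colocalize(X, Y, 250)$n_coloc,
                   colocalize(Y, X, 250)$n_coloc)
  ## empty channel A: fraction undefined
  expect_true(is.na(colocalize(matrix(numeric(0), 0, 3), Y, 100)$fraction))
})

test_that("planted nucleus fixtures drive aggregation and colocalization to their truth", {
  dia <- 300
  sim <- make_nucleus_foci(40, nucleus_radius = 4000,
                           aggregate_spec = list(pairs = 3,
                                                 distance = 0.3 * dia),
                           seed = 53)
  ## planted pairs sit at 0.3*dia < dia/2; random foci could add clusters,
  ## so assert at least the planted count and exactly 3 for this seed
  r <- count_aggregations(sim$channel_a, dia)
  expect_identical(r$n_aggregates, 3L)
  ## 100% colocalization at zero offset
  co <- make_nucleus_foci(30, coloc_spec = list(fraction = 1, offset = 0),
                          seed = 54)
  expect_equal(colocalize(co$channel_a, co$channel_b, 100)$fraction, 1)
  ## infeasible plant
  expect_error(make_nucleus_foci(3, aggregate_spec = list(pairs = 2,
                                                          distance = 100)),
               "plants")
})

test_that("50% planted colocalization is recovered within binomial 3 SE over 100 seeds", {
  thr <- 200
  fracs <- vapply(1:100, function(s) {
    sim <- make_nucleus_foci(200, nucleus_radius = 4000,
                             coloc_spec = list(fraction = 0.5,
                                               offset = 0.5 * thr),
                             seed = 100 + s)
    colocalize(sim$channel_a, sim$channel_b, thr)$fraction
  }, numeric(1))
  ## random B foci occasionally land near an A focus, so the measured mean
  ## can only exceed 0.5; allow binomial 3 SE plus that one-sided excess
  se <- sqrt(0.5 * 0.5 / 200) / sqrt(100)
  expect_gt(mean(fracs), 0.5 - 3 * se)
  expect_lt(mean(fracs), 0.5 + 0.1)
})

test_that("foci count histograms bin per-nucleus counts as specified", {
  expect_identical(foci_count_histogram(12, c(0, 10, 20)), c(0L, 1L))
  expect_identical(foci_count_histogram(c(0, 0, 0), c(0, 10, 20)),
                   c(3L, 0L))
  set.seed(55)
  counts <- rpois(500, 20)
  h <- foci_count_histogram(counts, seq(0, 60, by = 5))
  expect_identical(sum(h), 500L)
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 500))
})
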