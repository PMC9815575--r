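test_that("histogram densities integrate to one and center correctly", {
  set.seed(50)
  x <- rnorm(10000)
  d <- estimate_density(x, bin_width = 0.1)
  expect_equal(sum(d$density) * d$bin_width, 1, tolerance = 1e-9)
  expect_equal(sum(d$mids * d$density) * d$bin_width, 0,
               tolerance = 0.05)
  expect_true(all(d$density > 0))

  # all mass in one bin in the vanishing-pseudocount limit
  one <- estimate_density(rep(2, 100), bin_width = 0.5,
                          support = c(0, 5), pseudocount = 1e-12)
  expect_equal(max(one$density), 1 / 0.5, tolerance = 1e-6)
  expect_warning(estimate_density(rnorm(10)), "fewer than 50")
  expect_error(estimate_density(x, support = c(1, 1)), "zero-width")
  expect_error(estimate_density(x, support = c(0, 1)),
               "does not cover")
})

test_that("PRE is zero for identical densities, symmetric, and guarded", {
  set.seed(51)
  x <- rnorm(5000)
  d <- estimate_density(x, 0.1)
  expect_equal(pre_score(d$density, d$density, 0.1), 0)

  y <- rnorm(5000, mean = 0.6)
  sup <- range(c(x, y)) + c(-0.1, 0.1)
  dx <- estimate_density(x, 0.1, sup)
  dy <- estimate_density(y, 0.1, sup)
  expect_equal(pre_score(dx$density, dy$density, 0.1),
               pre_score(dy$density, dx$density, 0.1))
  expect_gt(pre_score(dx$density, dy$density, 0.1), 0)

  bad <- dx$density; bad[1] <- 0
  expect_error(pre_score(bad, dy$density, 0.1), "pseudocount")
})

test_that("histogram PRE matches the Gaussian closed form", {
  # N(0,1) vs N(1,1): symmetrized KL = (mu1-mu2)^2 / (2 sigma^2) = 0.5
  set.seed(52)
  n <- 40000
  a <- rnorm(n)
  b <- rnorm(n, mean = 1)
  sup <- range(c(a, b)) + c(-0.05, 0.05)
  da <- estimate_density(a, 0.05, sup)
  db <- estimate_density(b, 0.05, sup)
  expect_equal(pre_score(da$density, db$density, 0.05), 0.5,
               tolerance = 0.1)
})

test_that("contact graph edges require persistent sub-cutoff distance", {
  # residues 1-2 close, 1-3/2-3 always beyond 10 A
  coords <- rbind(c(0, 0, 0), c(5, 0, 0), c(20, 0, 0))
  ens <- mini_ensemble(lapply(1:60, function(i) coords +
                                matrix(rnorm(9, sd = 0.05), 3)))
  set.seed(53)
  ens2 <- mini_ensemble(lapply(1:60, function(i) coords +
                                 matrix(rnorm(9, sd = 0.05), 3)))
  g <- suppressWarnings(build_pre_graph(ens, ens2))
  expect_equal(nrow(g$edges), 1)
  expect_equal(c(g$edges$res_i, g$edges$res_j), c(1, 2))
  expect_true(all(g$edges$weight > 0 & is.finite(g$edges$weight)))
})

test_that("identical systems give near-floor PRE on every edge", {
  set.seed(54)
  base <- build_ideal_helix(8)
  frames <- lapply(1:1200, function(i) base + matrix(rnorm(24, sd = 0.3), 8))
  ens1 <- mini_ensemble(frames[1:600])
  ens2 <- mini_ensemble(frames[601:1200])
  g <- build_pre_graph(ens1, ens2)
  expect_gt(nrow(g$edges), 5)
  expect_lt(max(g$edges$pre), 0.2)
})

test_that("graph PRE values are independent of system order", {
  spec <- quick_spec(n_frames = 250, replicas = 1, seed = 55)
  gen <- generate_ensembles(spec)
  res <- spec$path_residues[1:6]
  g_ab <- build_pre_graph(gen$A, gen$B, residues = res)
  g_ba <- build_pre_graph(gen$B, gen$A, residues = res)
  expect_equal(g_ab$edges$pre, g_ba$edges$pre, tolerance = 1e-12)
})

test_that("Dijkstra equals brute-force enumeration on small graphs", {
  set.seed(56)
  for (trial in 1:12) {
    n <- sample(4:8, 1)
    full <- expand.grid(res_i = 1:n, res_j = 1:n)
    full <- full[full$res_i < full$res_j, ]
    keep <- runif(nrow(full)) < 0.6
    edges <- full[keep, , drop = FALSE]
    if (!nrow(edges)) next
    edges$pre <- runif(nrow(edges), 0.1, 5)
    edges$weight <- 1 / edges$pre
    g <- structure(list(edges = edges, residues = 1:n,
                        pre_floor = 1e-6), class = "pre_graph")
    ig <- igraph::graph_from_data_frame(
      data.frame(from = edges$res_i, to = edges$res_j,
                 weight = edges$weight), directed = FALSE,
      vertices = data.frame(name = 1:n))
    comp <- igraph::components(ig)$membership
    tgt <- which(comp == comp[1])
    tgt <- tgt[tgt != 1]
    if (!length(tgt)) next
    t <- max(tgt)
    got <- shortest_allosteric_path(g, 1, t)[[1]]
    want <- brute_force_path(edges, 1, t)
    expect_equal(got$total_weight, want$weight, tolerance = 1e-9)
    # and agrees with an independent library implementation
    ig_w <- igraph::distances(ig, v = "1", to = as.character(t))
    expect_equal(got$total_weight, as.numeric(ig_w), tolerance = 1e-9)
  }
})

test_that("single-edge graphs and unreachable targets are handled", {
  edges <- data.frame(res_i = 1L, res_j = 2L, pre = 2, weight = 0.5)
  g <- structure(list(edges = edges, residues = 1:2, pre_floor = 1e-6),
                 class = "pre_graph")
  p <- shortest_allosteric_path(g, 1, 2)[[1]]
  expect_equal(p$residues, c(1L, 2L))
  expect_equal(p$total_weight, 0.5)
  expect_equal(p$edge_pre, 2)

  edges2 <- rbind(edges, data.frame(res_i = 3L, res_j = 4L, pre = 1,
                                    weight = 1))
  g2 <- structure(list(edges = edges2, residues = 1:4,
                       pre_floor = 1e-6), class = "pre_graph")
  expect_error(shortest_allosteric_path(g2, 1, 4), "disconnected")
  expect_error(shortest_allosteric_path(g2, 1, 9), "no contact edges")
})

test_that("the planted path carries the highest PRE edges", {
  spec <- quick_spec(n_frames = 1200, replicas = 2, seed = 57)
  gen <- generate_ensembles(spec)
  g <- build_pre_graph(gen$A, gen$B, stride = 2)
  path <- spec$path_residues
  on_path <- g$edges$res_i %in% path & g$edges$res_j %in% path &
    abs(g$edges$res_i - g$edges$res_j) == 1
  expect_gt(min(g$edges$pre[on_path]),
            quantile(g$edges$pre[!on_path], 0.99))
  p <- shortest_allosteric_path(g, path[1], path[length(path)])[[1]]
  expect_gte(mean(path %in% p$residues), 0.8)
})
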