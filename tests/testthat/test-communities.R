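test_that("eigenvector centrality matches closed forms and a dense solver", {
  K4 <- toy_network(4, combn(4, 2, simplify = FALSE))
  expect_equal(centralities(K4)$eigenvector, rep(1, 4))
  star <- toy_network(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  cs <- centralities(star)
  expect_equal(cs$eigenvector, c(1, 0.5, 0.5, 0.5, 0.5), tolerance = 1e-8)
  expect_equal(attr(cs, "eigenvalue"), 2, tolerance = 1e-8)
  # random 8-node graph against eigen()
  set.seed(31)
  A <- matrix(0, 8, 8)
  idx <- sample(which(upper.tri(A)), 12)
  A[idx] <- 1
  A <- A + t(A)
  Th <- -A * 0.3
  diag(Th) <- 4
  net <- build_network(Th)
  got <- centralities(net)
  eg <- eigen(net$adjacency, symmetric = TRUE)
  want <- abs(eg$vectors[, 1])
  want <- want / max(want)
  expect_equal(got$eigenvector, want, tolerance = 1e-8)
  # eigen-equation residual at the returned pair
  x <- got$eigenvector
  expect_lt(max(abs(net$adjacency %*% x - attr(got, "eigenvalue") * x)),
            1e-6)
  expect_error(centralities(build_network(diag(3))), "edgeless")
})

test_that("top_hubs ranks by measure with lexicographic ties", {
  star <- toy_network(5, list(c(1, 2), c(1, 3), c(1, 4), c(1, 5)),
                      labels = c("hub", "b", "a", "d", "c"))
  cs <- centralities(star)
  expect_equal(top_hubs(cs, 1, "degree"), "hub")
  expect_equal(top_hubs(cs, 3, "degree"), c("hub", "a", "b"))
  expect_warning(all5 <- top_hubs(cs, 10, "eigenvector"), "all")
  expect_length(all5, 5)
})

test_that("a planted hub ranks first under both measures", {
  edges <- c(lapply(2:6, function(j) c(1, j)), list(c(7, 8)))
  net <- toy_network(8, edges, labels = c("hub", letters[1:7]))
  cs <- centralities(net)
  expect_equal(top_hubs(cs, 1, "degree"), "hub")
  expect_equal(top_hubs(cs, 1, "eigenvector"), "hub")
})

test_that("modularity_score reproduces hand-computed values", {
  tri <- toy_network(3, list(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(modularity_score(tri, rep(1, 3)), 0)
  expect_equal(modularity_score(tri, 1:3), -1 / 3)
  two_tri <- toy_network(6, list(c(1, 2), c(2, 3), c(1, 3),
                                 c(4, 5), c(5, 6), c(4, 6)))
  expect_equal(modularity_score(two_tri, c(1, 1, 1, 2, 2, 2)), 0.5)
  # invariant under module relabeling
  expect_equal(modularity_score(two_tri, c(2, 2, 2, 7, 7, 7)), 0.5)
  # agreement with the igraph implementation at resolution 1
  set.seed(5)
  A <- matrix(0, 7, 7); A[upper.tri(A)] <- rbinom(21, 1, 0.4)
  A <- A + t(A); diag(A) <- 0
  Th <- -A * 0.2; diag(Th) <- 3
  net <- build_network(Th)
  memb <- rep(1:2, c(3, 4))
  expect_equal(modularity_score(net, memb),
               igraph::modularity(net$graph, memb))
  expect_error(modularity_score(tri, c(1, 1, NA)), "cover")
})

test_that("louvain recovers planted cliques with the hand modularity", {
  cl <- c(combn(1:5, 2, simplify = FALSE),
          lapply(combn(6:10, 2, simplify = FALSE), identity),
          list(c(5, 6)))
  net <- toy_network(10, cl)
  part <- louvain(net, seed = 0)
  expect_length(part$sizes, 2)
  expect_equal(unname(part$assignment[1:5]),
               rep(part$assignment[[1]], 5))
  expect_equal(unname(part$assignment[6:10]),
               rep(part$assignment[[6]], 5))
  expect_equal(part$modularity, 2 * (10 / 21 - (21 / 42)^2),
               tolerance = 1e-10)
  # deterministic under a fixed seed
  expect_identical(part$assignment, louvain(net, seed = 0)$assignment)
  # single triangle collapses to one module
  tri <- toy_network(3, list(c(1, 2), c(2, 3), c(1, 3)))
  expect_length(louvain(tri)$sizes, 1)
})

test_that("modularity never falls below the singleton partition", {
  set.seed(41)
  for (rep in 1:3) {
    A <- matrix(0, 9, 9); A[upper.tri(A)] <- rbinom(36, 1, 0.3)
    A <- A + t(A); diag(A) <- 0
    if (sum(A) == 0) next
    Th <- -A * 0.2; diag(Th) <- 3
    net <- build_network(Th)
    part <- louvain(net, seed = rep)
    expect_gte(part$modularity,
               modularity_score(net, seq_len(net$n)) - 1e-12)
    expect_gte(part$modularity, 0 - 1e-12)   # all-in-one partition has Q=0
  }
})

test_that("resolution controls module granularity on a hierarchical fixture", {
  # two loose super-groups, each of two tight 4-cliques joined by a bridge
  cliq <- function(off) combn(off + 1:4, 2, simplify = FALSE)
  edges <- c(cliq(0), cliq(4), cliq(8), cliq(12),
             list(c(4, 5), c(12, 13), c(8, 9)))
  net <- toy_network(16, edges)
  lo <- louvain(net, resolution = 0.5, seed = 0)
  hi <- louvain(net, resolution = 1.0, seed = 0)
  expect_lte(length(lo$sizes), length(hi$sizes))
})

test_that("small modules are flagged omitted, nodes retained", {
  cl <- c(combn(1:5, 2, simplify = FALSE), list(c(6, 7)))
  net <- toy_network(7, cl)
  part <- louvain(net, seed = 0)
  expect_equal(sort(part$sizes), c(2, 5))
  flt <- filter_small_modules(part, 3)
  expect_equal(sum(flt$omitted), 1)
  expect_length(flt$assignment, 7)
  expect_identical(filter_small_modules(part, 1)$omitted,
                   rep(FALSE, 2))
})

test_that("module shares reproduce the printed node percentages", {
  # sizes 26 / 21 / 4 over 51 nodes
  fake <- structure(list(assignment = stats::setNames(
    rep(1:3, c(26, 21, 4)), sprintf("kw%02d", 1:51)),
    modularity = 0.337, resolution = 1, seed = 0,
    sizes = c(26L, 21L, 4L), omitted = rep(FALSE, 3)),
    class = "module_partition")
  sh <- module_shares(fake)
  expect_equal(round(sh$share_pct, 2), c(50.98, 41.18, 7.84))
  expect_equal(sum(sh$share_pct), 100)
  flt <- filter_small_modules(fake, 3)
  expect_false(any(flt$omitted))
})
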