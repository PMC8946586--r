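test_that("overlapping degree sums the per-layer degrees", {
  st <- stack_with_degrees(c(2, 1, 1, 0))
  expect_equal(overlap_degree(st, 1), 4)
  expect_equal(layer_degrees(st)[1, ], c(layer1 = 2, layer2 = 1,
                                         layer3 = 1, layer4 = 0))
  empty <- layer_stack(list(matrix(0, 3, 3), matrix(0, 3, 3)))
  expect_equal(overlap_degree(empty), c(0, 0, 0))
  # M identical layers: overlap = M * single-layer degree
  set.seed(41)
  g <- rand_adj(7, 0.5)
  st3 <- layer_stack(list(g, g, g))
  expect_equal(overlap_degree(st3), 3 * rowSums(g))
})

test_that("EMD matches direct evaluation of the entropy formula", {
  even <- stack_with_degrees(c(2, 2, 2, 2))
  expect_equal(node_emd(even, 1), log(4))
  concentrated <- stack_with_degrees(c(3, 0, 0, 0))
  expect_equal(node_emd(concentrated, 1), 0)
  mixed <- stack_with_degrees(c(2, 1, 1, 0))
  expect_equal(node_emd(mixed, 1),
               -(0.5 * log(0.5) + 0.25 * log(0.25) + 0.25 * log(0.25)))
  isolated <- layer_stack(list(matrix(0, 3, 3), matrix(0, 3, 3)))
  expect_equal(node_emd(isolated), c(0, 0, 0))
})

test_that("EMD is bounded by [0, ln M] with equality at the extremes", {
  set.seed(42)
  for (rep in 1:200) {
    m <- sample(2:4, 1)
    degs <- sample(0:5, m, replace = TRUE)
    if (all(degs == 0)) degs[1] <- 1
    e <- node_emd(stack_with_degrees(degs), 1)
    expect_gte(e, 0)
    expect_lte(e, log(m) + 1e-12)
    if (sum(degs > 0) == 1) expect_equal(e, 0)
    if (length(unique(degs)) == 1) expect_equal(e, log(m))
  }
})

test_that("MCC reproduces the hand-enumerated small stacks", {
  # two identical K4 layers: literal MCC = M x single-layer clustering = 2
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(node_mcc(layer_stack(list(k4, k4))), rep(2, 4))

  # 3 nodes; layer 1 edges {12, 13}, layer 2 edge {23}: the denominator
  # constrains i-incident edge pairs across distinct layers, so node 1
  # (both edges in layer 1) has denominator 0 and MCC 0 by convention
  l1 <- matrix(0, 3, 3); l1[1, 2] <- l1[2, 1] <- l1[1, 3] <- l1[3, 1] <- 1
  l2 <- matrix(0, 3, 3); l2[2, 3] <- l2[3, 2] <- 1
  st <- layer_stack(list(l1, l2))
  expect_equal(node_mcc(st, 2), 0.5)
  expect_equal(node_mcc(st, 1), 0)

  empty <- layer_stack(list(matrix(0, 4, 4), matrix(0, 4, 4)))
  expect_equal(node_mcc(empty), rep(0, 4))
  expect_error(node_mcc(layer_stack(list(k4))), "2 layers")
})

test_that("matrix-accelerated MCC equals the brute-force oracle", {
  set.seed(43)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    m <- sample(2:4, 1)
    st <- rand_stack(n, m, runif(1, 0.2, 0.6))
    for (conv in c("literal", "strict_three_layer")) {
      fast <- node_mcc(st, convention = conv)
      slow <- vapply(seq_len(n), mcc_bruteforce_oracle, numeric(1),
                     stack = st, convention = conv)
      expect_identical(fast, slow)
    }
  }
})

test_that("M identical layers reduce to M x single-layer clustering", {
  set.seed(44)
  for (m in 2:4) {
    g <- rand_adj(8, 0.5)
    st <- layer_stack(replicate(m, g, simplify = FALSE))
    expect_equal(node_mcc(st), m * clustering_coefficient(g),
                 tolerance = 1e-12)
    nz <- rowSums(g) > 0
    expect_equal(node_emd(st)[nz], rep(log(m), sum(nz)))
  }
})

test_that("strict three-layer MCC never exceeds the literal MCC", {
  set.seed(45)
  for (rep in 1:30) {
    st <- rand_stack(sample(5:9, 1), sample(3:4, 1), 0.5)
    expect_true(all(node_mcc(st, convention = "strict_three_layer") <=
                      node_mcc(st, convention = "literal") + 1e-12))
  }
})

test_that("multiplex metrics are equivariant under node relabeling", {
  set.seed(46)
  st <- rand_stack(8, 3, 0.5)
  perm <- sample(8)
  pst <- layer_stack(lapply(st$layers, function(a) a[perm, perm]))
  expect_equal(node_mcc(pst), node_mcc(st)[perm])
  expect_equal(node_emd(pst), node_emd(st)[perm])
  expect_equal(overlap_degree(pst), overlap_degree(st)[perm])
})

test_that("network summary is the mean of the node values", {
  set.seed(47)
  st <- rand_stack(10, 3, 0.4)
  s <- network_summary(st)
  expect_equal(s$mean_mcc, mean(node_mcc(st)))
  expect_equal(s$mean_emd, mean(node_emd(st)))
  empty <- layer_stack(list(matrix(0, 4, 4), matrix(0, 4, 4)))
  expect_equal(network_summary(empty), list(mean_mcc = 0, mean_emd = 0))
  # vertex-transitive stack: every node equals the mean
  ring <- matrix(0, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; ring[i, j] <- ring[j, i] <- 1 }
  rs <- layer_stack(list(ring, ring))
  expect_equal(node_mcc(rs), rep(network_summary(rs)$mean_mcc, 5))
})
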