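fix <- example1_fixture()

test_that("ancestor arcs are found by reverse reachability", {
  expect_equal(nrow(ancestor_arcs(fix, character(0))), 0)
  a4 <- ancestor_arcs(fix, "x4")
  expect_equal(nrow(a4), 1)
  expect_equal(a4$parent, "r")
  a2 <- ancestor_arcs(fix, "x2")
  expect_equal(nrow(a2), 6)
  expect_equal(sum(a2$weight), 6)
  expect_setequal(paste(a2$parent, a2$child),
                  c("r s", "s p", "s q", "p H", "q H", "H x2"))
  # the full leaf set recovers every arc
  for (s in 1:5) {
    net <- random_level_k(6, k = 2, d = 2, seed = s)
    expect_equal(sum(ancestor_arcs(net, net$leaves)$weight),
                 total_weight(net))
  }
  expect_error(ancestor_arcs(fix, "nope"), "unknown leaf")
})

test_that("clusters collect descendant leaves", {
  expect_equal(node_cluster(fix, "x1"), "x1")
  expect_equal(node_cluster(fix, "H"), "x2")
  expect_equal(node_cluster(fix, "s"), c("x1", "x2", "x3"))
  expect_equal(node_cluster(fix, "r"), fix$leaves)
  expect_error(node_cluster(fix, "zz"), "unknown node")
})

test_that("blob decomposition identifies split nodes and exit reticulations", {
  expect_length(network_blobs(random_tree(8, seed = 1)), 0)
  b <- network_blobs(fix)
  expect_length(b, 1)
  expect_setequal(b[[1]]$nodes, c("s", "p", "q", "H"))
  expect_equal(b[[1]]$split_node, "s")
  expect_equal(b[[1]]$exit_reticulations, "H")
  expect_length(b[[1]]$internal_reticulations, 0)

  e2 <- example2_network(3)
  b2 <- network_blobs(e2)
  expect_length(b2, 1)
  expect_setequal(c(b2[[1]]$exit_reticulations, b2[[1]]$internal_reticulations),
                  c("H1", "H2", "H3"))
  expect_equal(b2[[1]]$exit_reticulations, "H3")

  # every blob node has a descendant exit reticulation
  for (s in 1:8) {
    net <- random_level_k(7, k = 2, d = 3, seed = 40 + s)
    for (blob in network_blobs(net)) {
      for (v in blob$nodes) {
        desc <- c(v, netdiv:::.descendant_nodes(net, v))
        expect_true(length(intersect(desc, blob$exit_reticulations)) > 0)
      }
    }
  }
})

test_that("igraph biconnectivity agrees with the node-removal definition", {
  nets <- c(lapply(1:4, function(s) random_galled_tree(5, seed = 60 + s)),
            lapply(1:4, function(s) random_level_k(5, k = 2, d = 2,
                                                   seed = 70 + s)),
            list(fix, example2_network(2)))
  for (net in nets) {
    if (length(net$nodes) > 12) next
    ours <- netdiv:::.bicomponents(net)
    ours_part <- integer(length(net$parent))
    for (ci in seq_along(ours)) ours_part[ours[[ci]]] <- ci
    brute <- oracle_bicomp(net)
    # same partition up to renaming
    expect_equal(length(unique(ours_part)), length(unique(brute)))
    expect_true(all(tapply(brute, ours_part,
                           function(v) length(unique(v)) == 1)))
  }
})

test_that("level counts reticulations per biconnected component", {
  expect_equal(network_level(random_tree(6, seed = 2)), 0L)
  expect_equal(network_level(fix), 1L)
  for (k in 2:4) expect_equal(network_level(example2_network(k)), k)
})

test_that("classification reports level, arity and class flags", {
  p <- classify_network(fix)
  expect_equal(p$level, 1L)
  expect_equal(p$arity, 2L)
  expect_true(p$is_galled_tree)
  expect_false(p$is_tree)

  star <- phylo_network(rep("r", 5), paste0("t", 1:5))
  ps <- classify_network(star)
  expect_equal(ps$level, 0L)
  expect_equal(ps$arity, 0L)
  expect_true(ps$is_tree)
  expect_false(ps$is_binary)
  expect_true(is_semi_d_ary(star, 2))  # vacuously semi-d-ary

  p2 <- classify_network(example2_network(2))
  expect_equal(p2$level, 2L)
  expect_true(p2$is_semibinary)
  expect_false(p2$is_galled_tree)

  # level 0 <=> no reticulations <=> tree flag
  for (s in 1:6) {
    net <- random_level_k(6, k = 1, d = 2, seed = 80 + s)
    expect_equal(network_level(net) == 0, length(reticulations(net)) == 0)
    expect_equal(classify_network(net)$is_tree, network_level(net) == 0)
  }
})
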