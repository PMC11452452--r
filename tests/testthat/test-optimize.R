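fix <- example1_fixture()
f12 <- swap_family("skd", k = 1, d = 2)

test_that("brute force returns exact maxima and all argmax sets", {
  o0 <- brute_force_opt(fix, 0)
  expect_equal(o0$value, 0)
  expect_equal(o0$sets, list(character(0)))
  o2 <- brute_force_opt(fix, 2)
  expect_equal(o2$value, 10)
  expect_equal(o2$sets, list(c("x2", "x4")))
  o3 <- brute_force_opt(fix, 3)
  expect_equal(o3$value, 13)
  expect_equal(o3$sets, list(c("x1", "x3", "x4")))
  o4 <- brute_force_opt(fix, 4)
  expect_equal(o4$value, 14)
  expect_equal(o4$sets, list(fix$leaves))
  expect_error(brute_force_opt(fix, 5), "between")
  # ties are all reported: a star with equal weights
  star <- phylo_network(rep("r", 3), c("a", "b", "c"), weight = 2)
  expect_length(brute_force_opt(star, 1)$sets, 3)
})

test_that("optimal tau-expansion and contraction scan the family", {
  ex <- opt_tau_expand(fix, c("x2", "x4"), 1, f12)
  expect_equal(ex$value, 13)
  expect_equal(ex$sets, list(c("x1", "x3", "x4")))
  ct <- opt_tau_contract(fix, c("x1", "x3", "x4"), 1, f12)
  expect_equal(ct$value, 10)
  expect_equal(ct$sets, list(c("x2", "x4")))
  e0 <- opt_tau_expand(fix, character(0), 1, swap_family("s0"))
  expect_equal(e0$value, 6)
  expect_equal(e0$sets, list("x2"))
  # only candidate: completing to the full leaf set
  full <- opt_tau_expand(fix, c("x1", "x2", "x3"), 1, swap_family("s0"))
  expect_equal(full$sets, list(fix$leaves))
  expect_error(opt_tau_expand(fix, "x1", 3, swap_family("s0")), "candidate")
})

test_that("tau expansion and contraction are dual", {
  for (s in 1:4) {
    net <- random_galled_tree(6, seed = 600 + s)
    n <- length(net$leaves)
    by_size <- netdiv:::.masks_by_size(n)
    for (Xm in sample(0:(2^n - 1), 8)) {
      for (j in 1:2) {
        fwd <- netdiv:::.tau_candidate_masks(Xm, j, f12, n, by_size, TRUE)
        for (Ym in fwd) {
          back <- netdiv:::.tau_candidate_masks(Ym, j, f12, n, by_size, FALSE)
          expect_true(Xm %in% back)
        }
      }
    }
  }
})

test_that("greedy on trees equals brute force for every cardinality", {
  star <- phylo_network(rep("r", 3), c("a", "b", "c"), weight = c(3, 1, 2))
  expect_equal(greedy_tree(star)[[2]]$sets, list("a"))
  for (s in 1:20) {
    wt <- if (s %% 2) "int" else "decimal"
    tr <- random_tree(5 + s %% 5, seed = 700 + s, weights = wt)
    tab <- rpsd_table(tr)
    gr <- greedy_tree(tr)
    for (m in 0:length(tr$leaves)) {
      bf <- brute_force_opt(tr, m, tab)
      expect_equal(fam_key(gr[[m + 1]]), fam_key(bf))
      expect_equal(gr[[m + 1]]$value, bf$value)
    }
  }
  expect_error(greedy_tree(fix), "tree")
})

test_that("greedy on galled trees equals brute force, full and representative", {
  gg <- greedy_galled(fix)
  expect_equal(vapply(gg, `[[`, numeric(1), "value"), c(0, 6, 10, 13, 14))
  expect_equal(gg[[2]]$sets, list("x2"))
  expect_equal(gg[[3]]$sets, list(c("x2", "x4")))
  expect_equal(gg[[4]]$sets, list(c("x1", "x3", "x4")))
  for (s in 1:20) {
    wt <- if (s %% 2) "int" else "decimal"
    net <- random_galled_tree(5 + s %% 5, seed = 800 + s, weights = wt)
    tab <- rpsd_table(net)
    gr <- greedy_galled(net)
    rep_mode <- greedy_galled(net, mode = "representative")
    for (m in 0:length(net$leaves)) {
      bf <- brute_force_opt(net, m, tab)
      expect_equal(fam_key(gr[[m + 1]]), fam_key(bf))
      # the representative is a member of the true optimal family
      expect_true(paste(rep_mode[[m + 1]]$sets[[1]], collapse = ",") %in%
                    fam_key(bf))
    }
  }
  # trees are galled trees too, and the two greedies agree
  tr <- random_tree(7, seed = 1)
  expect_equal(lapply(greedy_galled(tr), fam_key),
               lapply(greedy_tree(tr), fam_key))
  expect_error(greedy_galled(example2_network(2)), "galled")
})

test_that("optimal sets of consecutive sizes need not nest, greedy still exact", {
  gg <- greedy_galled(fix)
  # the optimal pair {x2,x4} is not inside the optimal triple {x1,x3,x4}
  expect_false(all(gg[[3]]$sets[[1]] %in% gg[[4]]$sets[[1]]))
})

test_that("level-2 greedy equals brute force on both covered classes", {
  # the worked example is also a valid input for this class
  g2 <- greedy_level2(fix)
  expect_equal(lapply(g2, fam_key), lapply(greedy_galled(fix), fam_key))
  for (s in 1:12) {
    wt <- if (s %% 2) "int" else "decimal"
    net <- random_level_k(5 + s %% 4, k = 2, d = 2, seed = 900 + s,
                          weights = wt)
    tab <- rpsd_table(net)
    gr <- greedy_level2(net)
    for (m in 0:length(net$leaves))
      expect_equal(fam_key(gr[[m + 1]]), fam_key(brute_force_opt(net, m, tab)))
    net <- random_level_k(5 + s %% 4, k = 1, d = 3, seed = 950 + s,
                          weights = wt)
    tab <- rpsd_table(net)
    gr <- greedy_level2(net)
    for (m in 0:length(net$leaves))
      expect_equal(fam_key(gr[[m + 1]]), fam_key(brute_force_opt(net, m, tab)))
  }
  expect_error(greedy_level2(example2_network(3)), "level")
})

test_that("optimal values are nondecreasing in cardinality", {
  for (s in 1:6) {
    net <- random_level_k(7, k = 3, d = 2, seed = 1100 + s)
    vals <- vapply(optimize_rpsd(net, method = "brute"), `[[`, numeric(1),
                   "value")
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("galled-tree optima are recovered downward by contraction", {
  for (s in 1:6) {
    net <- random_galled_tree(7, seed = 1200 + s, weights = "decimal")
    tab <- rpsd_table(net)
    n <- length(net$leaves)
    fams <- lapply(0:n, function(m) brute_force_opt(net, m, tab))
    for (m in 1:(n - 1)) {
      down <- unique(unlist(lapply(fams[[m + 2]]$sets, function(Y) {
        sets_key(opt_tau_contract(net, Y, 1, f12, values = tab)$sets)
      })))
      expect_setequal(down, fam_key(fams[[m + 1]]))
    }
  }
})

test_that("dispatch routes by network class and falls back to brute force", {
  auto <- optimize_rpsd(fix)
  expect_equal(attr(auto, "method"), "greedy_galled")
  expect_warning(seq3 <- optimize_rpsd(example2_network(3)), "NP-hard")
  expect_equal(attr(seq3, "method"), "brute_force")
  tr <- random_tree(6, seed = 5)
  expect_equal(lapply(optimize_rpsd(tr, method = "brute"), fam_key),
               lapply(optimize_rpsd(tr, method = "auto"), fam_key))
  o2 <- optimize_rpsd(fix, m = 2)
  expect_s3_class(o2, "opt_family")
  expect_equal(o2$sets, list(c("x2", "x4")))
  expect_error(optimize_rpsd(example2_network(3), method = "greedy"),
               "no exact greedy")
})

test_that("chain steps realize the improving-pair relation", {
  Y <- optimize_rpsd(fix, method = "brute")
  cs <- chain_step(fix, Y, 3, 2, f12)
  expect_equal(cs$j, 1)
  expect_equal(cs$pair$A, c("x1", "x3"))
  expect_equal(cs$pair$B, "x2")
  cs10 <- chain_step(fix, Y, 1, 0, f12)
  expect_equal(cs10$j, 1)
  expect_equal(cs10$pair$B, character(0))
  # on galled trees the chain always closes in a single step
  for (s in 1:5) {
    net <- random_galled_tree(6, seed = 1300 + s)
    tab <- rpsd_table(net)
    Y <- optimize_rpsd(net, method = "brute")
    for (p in 2:length(net$leaves)) {
      cs <- chain_step(net, Y, p, p - 1, f12, values = tab)
      expect_equal(cs$j, 1)
    }
  }
})

test_that("gap scan validates the proven classes and reports certificates", {
  r1 <- gap_scan(random_galled_tree(7, seed = 11), J = 1, k = 1, d = 2)
  expect_true(all(r1$per_m$ok))
  expect_length(r1$counterexamples, 0)
  r2 <- gap_scan(random_level_k(7, k = 2, d = 2, seed = 12), J = 2,
                 k = 2, d = 2)
  expect_true(all(r2$per_m$ok))
  out <- gap_scan_sample("level3-semibinary", n_leaves = 6, reps = 3,
                         seed = 99, J = 3)
  expect_equal(out$n_scanned, 3)
  expect_type(out$violations, "list")
})
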