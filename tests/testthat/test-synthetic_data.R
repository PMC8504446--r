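test_that("Yule trees are reproducible, unit-height and bifurcating", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_equal(unname(t2$edge.length), c(1, 1))
  expect_identical(write_newick(simulate_tree(20, seed = 9)),
                   write_newick(simulate_tree(20, seed = 9)))
  t100 <- simulate_tree(100, seed = 2)
  expect_equal(t100$Nnode, 99)
  expect_equal(max(ape::node.depth.edgelength(t100)), 1, tolerance = 1e-12)
})

test_that("Mk simulation is stationary at high rates and frozen at mu = 0", {
  tr <- simulate_tree(10, seed = 3)
  sim0 <- simulate_mk(tr, mu = 0, k = 3, n_chars = 20, seed = 4)
  root_states <- sim0$node_states[11, ]
  for (j in 1:20)
    expect_true(all(sim0$tips[, j] == root_states[j]))
  # high rate: tip state frequencies indistinguishable from uniform
  simh <- simulate_mk(tr, mu = 50, k = 4, n_chars = 2000, seed = 5)
  tab <- table(factor(simh$tips, levels = 0:3))
  p <- stats::chisq.test(tab, p = rep(1 / 4, 4))$p.value
  expect_gt(p, 0.01)
})

test_that("per-branch transition frequencies follow the equal-rates kernel", {
  # one long branch: parent-child transitions are Bernoulli draws from P(t)
  tr <- read_newick("(A:2,B:0.1);")
  sim <- simulate_mk(tr, mu = 0.4, k = 2, n_chars = 4000, seed = 6)
  root <- sim$node_states[3, ]
  tipA <- sim$tips["A", ]
  p_change <- mean(tipA != root)
  expected <- 1 / 2 - 1 / 2 * exp(-2 * 0.4 * 2)
  ci <- stats::binom.test(sum(tipA != root), 4000, expected)$p.value
  expect_gt(ci, 0.001)
  expect_equal(p_change, expected, tolerance = 0.05)
})

test_that("Dollo simulation respects the single-origin constraint", {
  tr <- simulate_tree(12, seed = 7)
  sim0 <- simulate_dollo(tr, p_origin_branch = 0, p_reversal = 0.3,
                         n_chars = 30, seed = 8)
  expect_true(all(sim0$tips == 0L))
  sim <- simulate_dollo(tr, p_origin_branch = 0.1, p_reversal = 0.15,
                        n_chars = 200, seed = 9)
  for (ch in seq_len(200)) {
    ev <- sim$events[[ch]]
    # at most one origin, and states replay from the event script
    expect_lte(length(ev$origin_node[!is.na(ev$origin_node)]), 1)
  }
  # without reversals, reconstruction recovers the true origin exactly
  sim2 <- simulate_dollo(tr, p_origin_branch = 0.08, p_reversal = 0,
                         n_chars = 100, seed = 10)
  for (ch in seq_len(100)) {
    if (sum(sim2$tips[, ch]) == 0) next
    res <- dollo_reconstruct(tr, sim2$tips[, ch])
    derived <- unname(which(sim2$tips[, ch] == 1))
    true_mrca <- if (length(derived) == 1) derived else
      ape::getMRCA(tr, derived)
    expect_equal(res$origin_node, true_mrca)
    expect_length(res$reversal_nodes, 0)
  }
})

test_that("synthesized plastomes satisfy the partition invariants", {
  tmpl <- plastome_template("III",
                            region_lengths = c(LSC = 20000, IR = 16000,
                                               SSC = 14500))
  syn <- synthesize_plastome(tmpl, seed = 30)
  part <- syn$truth$partition
  rec <- syn$record
  L <- nchar(rec$sequence)
  lens <- vapply(part$regions, `[`, 0L, 2)
  expect_equal(sum(lens), L)
  expect_identical(region_sequence(rec, part, "IRa"),
                   revcomp(region_sequence(rec, part, "IRb")))
  expect_gte(part$regions$LSC[2], part$regions$SSC[2])
  # same seed reproduces byte-identical output
  syn2 <- synthesize_plastome(tmpl, seed = 30)
  expect_identical(syn2$record$sequence, rec$sequence)
  # region GC tracks the template targets
  st <- region_stats(rec, part)
  targets <- syn$truth$region_gc[c("LSC", "IR", "SSC", "IR")]
  expect_true(all(abs(st$gc[1:4] - targets) < 0.005))
})

test_that("scripted edits set the expected truth states", {
  cds <- plastdeg:::random_cds(300, 0.4)
  stopped <- apply_edit(cds, list(op = "premature_stop", at = 0.5))
  expect_equal(nchar(stopped), 300)
  expect_gte(length(conceptual_translate(stopped)$internal_stops), 1)
  trunc <- apply_edit(cds, list(op = "truncate", fraction = 0.4, end = "3'"))
  expect_equal(nchar(trunc), 180)
  expect_identical(substr(trunc, 1, 3), substr(cds, 1, 3))
  expect_identical(apply_edit(cds, list(op = "delete_all")), "")
  fs <- apply_edit(cds, list(op = "frameshift", at = 0.5))
  expect_equal(nchar(fs), 299)
  expect_error(apply_edit(cds, list(op = "explode")), "unknown")
})

test_that("the packaged state matrix matches the printed table", {
  fx <- fixture_table1()
  m <- fx$states
  expect_equal(dim(m), c(22, 13))
  expect_true(all(m %in% 0:3))
  expect_equal(m["P_cyathophylla_1", "ndhE"], 3L)
  expect_equal(m["P_cyathophylla_1", "ndhH"], 1L)
  expect_equal(m["P_cyathophylloides_1", "ndhJ"], 2L)
  expect_true(all(m["P_tongolensis", paste0("ndh", LETTERS[1:11])] == 0L))
  expect_equal(m["P_tongolensis", "ccsA"], 1L)
  # ndhF is truncated in every section Cyathophora sample
  expect_true(all(m[fixture_groups()$cyathophora, "ndhF"] == 2L))
  # outgroups fully functional
  expect_true(all(m[fixture_groups()$outgroup, ] == 0L))
  # region table spot checks
  rg <- fx$regions
  expect_equal(rg$genome_bp[rg$taxon == "P_przewalskii"], 146480)
  expect_equal(rg$ir_gc[rg$taxon == "P_cyathophylla_1"], 40.7)
  expect_equal(nrow(rg), 22)
  expect_true(length(fx$errata) >= 2)
})

test_that("the packaged tree matches the matrix taxa and clade structure", {
  tr <- fixture_tree()
  fx <- fixture_table1()
  expect_equal(ape::Ntip(tr), 22)
  expect_setequal(tr$tip.label, rownames(fx$states))
  expect_true(ape::is.rooted(tr))
  cy <- fixture_groups()$cyathophora
  node <- mrca_node(tr, cy)
  below <- plastdeg:::node_descendant_tips(tr)[[node]]
  expect_setequal(tr$tip.label[below], cy)   # the section is monophyletic
  # (P. insignis, P. przewalskii) form a clade sister to the section
  sis <- mrca_node(tr, c("P_insignis", "P_przewalskii"))
  below_sis <- plastdeg:::node_descendant_tips(tr)[[sis]]
  expect_setequal(tr$tip.label[below_sis], c("P_insignis", "P_przewalskii"))
})
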