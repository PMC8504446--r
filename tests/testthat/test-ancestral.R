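test_that("binarization schemes map the four states as defined", {
  m <- matrix(0:3, 2, 2, dimnames = list(c("a", "b"), c("g1", "g2")))
  expect_equal(as.vector(binarize(m, "functional")), c(0L, 1L, 1L, 1L))
  expect_equal(as.vector(binarize(m, "complete")), c(0L, 0L, 1L, 1L))
  expect_equal(as.vector(binarize(m, "existing")), c(0L, 0L, 0L, 1L))
  z <- matrix(0L, 2, 2)
  for (s in c("functional", "complete", "existing"))
    expect_true(all(binarize(z, s) == 0L))
  expect_error(binarize(m, "nonsense"))
  expect_error(binarize(matrix(4L, 1, 1), "functional"), "0,1,2,3")
})

test_that("equal-rates pruning likelihood has its closed-form limits", {
  tr <- read_newick("((A:0,B:0):0,(C:0,D:0):0);")
  for (k in 2:4) {
    x <- setNames(rep(1L, 4), c("A", "B", "C", "D"))
    expect_equal(mk_er_loglik(tr, x, mu = 0.7, k = k), log(1 / k))
  }
  # large-mu limit: tips become independent uniform draws
  tr2 <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  x2 <- setNames(c(0L, 1L, 0L, 1L), c("A", "B", "C", "D"))
  expect_equal(mk_er_loglik(tr2, x2, mu = 500, k = 2), 4 * log(1 / 2),
               tolerance = 1e-6)
  expect_error(mk_er_loglik(tr2, x2, mu = -1), "positive")
  expect_error(mk_er_loglik(tr2, setNames(0:1, c("A", "Z")), 1), "match")
})

test_that("pruning equals exhaustive enumeration on random small trees", {
  set.seed(10)
  for (i in 1:30) {
    n <- sample(3:5, 1); k <- sample(2:4, 1)
    tr <- random_small_tree(n)
    x <- setNames(sample(0:(k - 1), n, replace = TRUE), tr$tip.label)
    mu <- runif(1, 0.05, 3)
    expect_equal(mk_er_loglik(tr, x, mu, k), brute_mk_loglik(tr, x, mu, k),
                 tolerance = 1e-10)
  }
})

test_that("equal-rates likelihood agrees with an independent implementation", {
  tr <- simulate_tree(12, seed = 77)
  x <- simulate_mk(tr, mu = 0.8, k = 2, n_chars = 1, seed = 78)$tips[, 1]
  xf <- factor(x, levels = 0:1)
  names(xf) <- names(x)
  mu <- 0.8
  Q <- matrix(c(-mu, mu, mu, -mu), 2, dimnames = list(0:1, 0:1))
  fit <- phytools::fitMk(tr, xf, fixedQ = Q, pi = "equal")
  expect_equal(mk_er_loglik(tr, x, mu, k = 2), unclass(logLik(fit)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("marginal reconstruction matches enumeration and sums to one", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(3:5, 1); k <- sample(2:3, 1)
    tr <- random_small_tree(n)
    x <- setNames(sample(0:(k - 1), n, replace = TRUE), tr$tip.label)
    mu <- runif(1, 0.1, 2)
    m <- marginal_ancestral(tr, x, mu, k)
    expect_equal(unname(rowSums(m$prob)), rep(1, nrow(m$prob)),
                 tolerance = 1e-9)
    for (node in (n + 1):(n + tr$Nnode)) {
      expect_equal(unname(m$prob[as.character(node), ]),
                   brute_mk_marginal(tr, x, mu, k, node), tolerance = 1e-10)
    }
  }
  # star-like data dominance: all tips derived pulls the root above 1/k
  tr <- read_newick("((((A:1,B:1):1,C:1):1,D:1):1,E:1);")
  x <- setNames(rep(1L, 5), LETTERS[1:5])
  m <- marginal_ancestral(tr, x, mu = 0.3, k = 2)
  expect_gt(m$prob["6", "1"], 0.5)
})

test_that("rate fitting recovers the simulating rate and flags boundaries", {
  tr <- simulate_tree(48, seed = 12)
  sim <- simulate_mk(tr, mu = 0.5, k = 2, n_chars = 40, seed = 13)
  mus <- suppressWarnings(vapply(seq_len(40), function(j)
    fit_mk_er(tr, sim$tips[, j], k = 2)$mu, 0))
  expect_gt(median(mus), 0.2)
  expect_lt(median(mus), 1.1)
  # optimality on a grid
  x <- sim$tips[, 1]
  fit <- fit_mk_er(tr, x, k = 2)
  grid <- exp(seq(log(1e-4), log(50), length.out = 100))
  ll <- vapply(grid, function(m) mk_er_loglik(tr, x, m, 2), 0)
  expect_gte(fit$loglik + 1e-6, max(ll))
  # invariant character sits at the lower bound with a warning
  inv <- setNames(rep(0L, 48), tr$tip.label)
  expect_warning(f2 <- fit_mk_er(tr, inv, k = 2), "invariant")
  expect_true(f2$boundary)
})

test_that("Dollo reconstruction is minimal among single-origin histories", {
  set.seed(14)
  for (i in 1:40) {
    tr <- random_small_tree(6)
    x <- setNames(sample(0:1, 6, replace = TRUE), tr$tip.label)
    res <- dollo_reconstruct(tr, x)
    expect_equal(res$n_events, brute_dollo_min_events(tr, x))
    # tip-permutation invariance
    res2 <- dollo_reconstruct(tr, x[sample(names(x))])
    expect_identical(res$node_states, res2$node_states)
  }
  # all-ancestral character: no events
  tr <- random_small_tree(5)
  res0 <- dollo_reconstruct(tr, setNames(rep(0L, 5), tr$tip.label))
  expect_equal(res0$n_events, 0L)
  expect_true(is.na(res0$origin_node))
  expect_error(dollo_reconstruct(tr, setNames(rep(2L, 5), tr$tip.label)),
               "binary")
})

test_that("reconstructed Dollo event scripts replay to the observed tips", {
  fx <- fixture_table1()
  tr <- fixture_tree()
  for (scheme in c("functional", "complete", "existing")) {
    bm <- binarize(fx$states, scheme)
    for (gene in colnames(bm)) {
      res <- dollo_reconstruct(tr, bm[, gene])
      # forward-simulate the event script: derived below the origin except
      # under reversal stems
      ntip <- length(tr$tip.label)
      replay <- rep(0L, ntip + tr$Nnode)
      if (!is.na(res$origin_node)) {
        desc <- function(node) {
          out <- node
          for (kid in tr$edge[tr$edge[, 1] == node, 2]) out <- c(out, desc(kid))
          out
        }
        replay[desc(res$origin_node)] <- 1L
        for (rv in res$reversal_nodes) replay[desc(rv)] <- 0L
      }
      expect_equal(setNames(replay[seq_len(ntip)], tr$tip.label),
                   bm[tr$tip.label, gene], label = paste(scheme, gene))
    }
  }
})

test_that("fixture reconstruction reproduces the reported loss history", {
  fx <- fixture_table1()
  tr <- fixture_tree()
  bm <- binarize(fx$states, "functional")
  # ndhG: three reversal branches within series Reges
  res <- dollo_reconstruct(tr, bm[, "ndhG"])
  expect_equal(length(res$reversal_nodes), 3)
  tipsets <- lapply(res$reversal_nodes, function(n) {
    idx <- plastdeg:::node_descendant_tips(tr)[[n]]
    sort(tr$tip.label[idx])
  })
  expect_true(list(sort(c("P_thamnophila", "P_aff_thamnophila"))) %in% tipsets ||
                any(vapply(tipsets, identical,
                           TRUE, sort(c("P_thamnophila", "P_aff_thamnophila")))))
  expect_true(any(vapply(tipsets, identical, TRUE, "P_rex_var_rex")))
  expect_true(any(vapply(tipsets, identical, TRUE, "P_rex_var_rockii")))
  # ccsA regains function within clade III under the ER model: the MRCA of
  # (P. cyathophylloides 1/2, P. superba 1/2/3) carries a localized,
  # many-fold elevated functional-state probability relative to the derived
  # background at the section's ancestor (the absolute support depends on
  # branch lengths, which the packaged tree sets to 1)
  x <- bm[, "ccsA"]
  fit <- fit_mk_er(tr, x, k = 2)
  m <- marginal_ancestral(tr, x, fit$mu, k = 2)
  node <- mrca_node(tr, c("P_cyathophylloides_1", "P_cyathophylloides_2",
                          "P_superba_1", "P_superba_2", "P_superba_3"))
  cy <- mrca_node(tr, fixture_groups()$cyathophora)
  p_here <- m$prob[as.character(node), "0"]
  p_background <- m$prob[as.character(cy), "0"]
  expect_gt(p_here, 0.4)
  expect_gt(p_here, 5 * p_background)
})
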