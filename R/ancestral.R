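# Ancestral reconstruction of gene functional loss on a rooted phylogeny:
# (a) equal-rates Mk likelihood (Felsenstein pruning, closed-form kernel)
#     with two-pass marginal ancestral states, and
# (b) Dollo parsimony (single origin of the derived state, reversions
#     allowed and minimized) with per-branch origin/reversal events.
#
# Characters are named integer vectors over 0..k-1 (tip label -> state);
# state matrices are integer matrices with taxa rows and gene columns.

#' Recode a 4-state degradation matrix to binary
#'
#' Schemes: "functional" maps state 0 -> 0 and 1/2/3 -> 1 (functional vs
#' non-functional); "complete" maps 0/1 -> 0 and 2/3 -> 1 (full-length vs
#' truncated/lost); "existing" maps 0/1/2 -> 0 and 3 -> 1 (present vs
#' physically lost).
#'
#' @param matrix integer matrix over {0,1,2,3} (taxa x genes).
#' @param scheme one of "functional", "complete", "existing".
#' @return binary integer matrix of the same shape.
#' @export
binarize <- function(matrix, scheme = c("functional", "complete", "existing")) {
  scheme <- match.arg(scheme)
  if (!all(matrix %in% 0:3)) stop("matrix values must be in {0,1,2,3}")
  cut <- switch(scheme, functional = 1L, complete = 2L, existing = 3L)
  out <- ifelse(matrix >= cut, 1L, 0L)
  mode(out) <- "integer"
  dimnames(out) <- dimnames(matrix)
  out
}

# equal-rates transition kernel: P_ii(t) = 1/k + (k-1)/k e^{-k mu t},
# P_ij(t) = 1/k - 1/k e^{-k mu t} (off-diagonal rate mu)
mk_er_kernel <- function(t, mu, k) {
  e <- exp(-k * mu * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (k - 1) * e / k
  P
}

check_character <- function(tree, character, k) {
  if (is.null(names(character))) stop("character must be named by tip label")
  if (!setequal(names(character), tree$tip.label))
    stop("tip labels and character taxa do not match")
  if (!all(character %in% 0:(k - 1)))
    stop("character states must lie in 0..k-1")
  character[tree$tip.label]
}

# conditional (downward) likelihoods for every node; rows = nodes in ape
# numbering (1..ntip tips, ntip+1.. internals), cols = states
mk_down_likelihoods <- function(tree, character, mu, k) {
  tree <- ensure_branch_lengths(tree)
  x <- check_character(tree, character, k)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  Lmat <- matrix(0, ntip + nnode, k)
  Lmat[cbind(seq_len(ntip), x + 1L)] <- 1
  ord <- reorder(tree, "postorder")
  scale_log <- 0
  # accumulate child contributions into parents in postorder
  contrib <- matrix(1, ntip + nnode, k)
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    if (child > ntip) {
      Lmat[child, ] <- contrib[child, ]
      m <- max(Lmat[child, ])
      if (m > 0 && m < 1e-150) {        # guard underflow on deep trees
        Lmat[child, ] <- Lmat[child, ] / m
        scale_log <- scale_log + log(m)
      }
    }
    P <- mk_er_kernel(ord$edge.length[e], mu, k)
    contrib[parent, ] <- contrib[parent, ] * as.vector(P %*% Lmat[child, ])
  }
  root <- ntip + 1L
  Lmat[root, ] <- contrib[root, ]
  list(L = Lmat, scale_log = scale_log, tree = ord, ntip = ntip)
}

#' Log-likelihood of a character under the equal-rates Mk model
#'
#' Felsenstein pruning with the closed-form equal-rates kernel
#' P_ii(t) = 1/k + (k-1)/k exp(-k mu t), P_ij(t) = 1/k (1 - exp(-k mu t)),
#' combined with a uniform 1/k root prior. Branches without lengths are
#' treated as length 1 (with a warning).
#'
#' @param tree rooted "phylo" object.
#' @param character named integer vector (tip label -> state in 0..k-1).
#' @param mu transition rate (> 0) per unit branch length.
#' @param k number of states.
#' @return log-likelihood (numeric scalar).
#' @export
mk_er_loglik <- function(tree, character, mu, k = 2) {
  if (mu <= 0) stop("mu must be positive")
  d <- mk_down_likelihoods(tree, character, mu, k)
  root <- d$ntip + 1L
  log(sum(d$L[root, ] / k)) + d$scale_log
}

#' Maximum-likelihood fit of the equal-rates Mk rate
#'
#' One-dimensional bounded likelihood maximization of mu on [1e-8, 1e3],
#' searched on the log scale (the likelihood is flat over most of the linear
#' range) to a relative tolerance of about 1e-8. For an invariant character
#' the optimum sits at the lower bound; this is flagged with a warning and
#' `boundary = TRUE`.
#'
#' @inheritParams mk_er_loglik
#' @return list with `mu`, `loglik`, `boundary`.
#' @export
fit_mk_er <- function(tree, character, k = 2) {
  tree <- suppressWarnings(ensure_branch_lengths(tree))
  f <- function(log_mu) mk_er_loglik(tree, character, exp(log_mu), k)
  opt <- stats::optimize(f, interval = log(c(1e-8, 1e3)), maximum = TRUE,
                         tol = 1e-9)
  opt$maximum <- exp(opt$maximum)
  if (!is.finite(opt$objective)) stop("non-finite likelihood")
  boundary <- opt$maximum < 1e-6
  if (length(unique(character)) == 1) {
    boundary <- TRUE
    warning("invariant character: rate estimate at lower bound")
  }
  list(mu = opt$maximum, loglik = opt$objective, boundary = boundary)
}

#' Marginal ancestral state probabilities under the equal-rates Mk model
#'
#' Standard two-pass (inside/outside) computation: for each internal node
#' the posterior probability of each state conditional on all tip data, a
#' uniform root prior and the given rate.
#'
#' @inheritParams mk_er_loglik
#' @return list with `prob` (matrix, internal nodes in ape numbering x
#'   states; rows sum to 1), `loglik`, `mu`.
#' @export
marginal_ancestral <- function(tree, character, mu, k = 2) {
  if (mu <= 0) stop("mu must be positive")
  d <- mk_down_likelihoods(tree, character, mu, k)
  tr <- d$tree
  ntip <- d$ntip
  nnode <- tr$Nnode
  root <- ntip + 1L
  Dn <- d$L

  # outside pass (preorder): U_root = prior; for child v of u,
  # U_v(s) = sum_su U_u(su) * prod_{w sib} (P tw Dw)(su) * P(tv)[su, s]
  U <- matrix(0, ntip + nnode, k)
  U[root, ] <- rep(1 / k, k)
  edges <- tr$edge
  # precompute per-edge P %*% D_child
  PD <- matrix(0, nrow(edges), k)
  Plist <- vector("list", nrow(edges))
  for (e in seq_len(nrow(edges))) {
    Plist[[e]] <- mk_er_kernel(tr$edge.length[e], mu, k)
    PD[e, ] <- as.vector(Plist[[e]] %*% Dn[edges[e, 2], ])
  }
  children_of <- split(seq_len(nrow(edges)), edges[, 1])
  preorder <- rev(seq_len(nrow(edges)))      # reverse postorder
  for (e in preorder) {
    u <- edges[e, 1]; v <- edges[e, 2]
    sibs <- setdiff(children_of[[as.character(u)]], e)
    acc <- U[u, ]
    for (se in sibs) acc <- acc * PD[se, ]
    U[v, ] <- as.vector(t(Plist[[e]]) %*% acc)
  }

  post <- U * Dn
  post <- post / rowSums(post)
  internal <- (ntip + 1L):(ntip + nnode)
  prob <- post[internal, , drop = FALSE]
  rownames(prob) <- internal
  colnames(prob) <- 0:(k - 1)
  list(prob = prob, loglik = log(sum(Dn[root, ] / k)) + d$scale_log, mu = mu)
}

#' MRCA node of a set of tips
#' @param tree rooted "phylo" object.
#' @param tips character vector of tip labels.
#' @return ape node number of the most recent common ancestor.
#' @export
mrca_node <- function(tree, tips) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) stop("unknown tips: ", paste(unknown, collapse = ", "))
  idx <- match(tips, tree$tip.label)
  if (length(idx) == 1) return(idx)
  ape::getMRCA(tree, idx)
}

# descendants (all nodes incl. tips) of each node, as logical matrix helpers
node_descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  below <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  ord <- reorder(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]; c_ <- ord$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[c_]])
  }
  below
}

#' Dollo parsimony reconstruction of a binary character
#'
#' The derived state (1) arises exactly once: on the branch subtending the
#' MRCA of all derived tips (on the root itself when that MRCA is the root).
#' Inside the origin clade, each maximal subtree whose tips are all ancestral
#' (0) receives one reversal on its stem branch; this minimizes the number
#' of reversals subject to the single-origin constraint. A character with no
#' derived tip yields zero events.
#'
#' @param tree rooted "phylo" object.
#' @param binary_character named integer vector over {0,1} (tip label ->
#'   state).
#' @return list with `node_states` (integer vector over all nodes, ape
#'   numbering), `origin_node` (node whose subtending branch carries the
#'   origin; `NA` if no derived tip), `origin_at_root`, `reversal_nodes`
#'   (nodes whose stem branch carries a reversal), `n_events`.
#' @export
dollo_reconstruct <- function(tree, binary_character) {
  if (!all(binary_character %in% 0:1)) stop("character must be binary over {0,1}")
  x <- check_character(tree, binary_character, 2)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  n_all <- ntip + nnode
  root <- ntip + 1L

  derived_tips <- which(x == 1L)
  states <- rep(0L, n_all)
  if (length(derived_tips) == 0) {
    return(list(node_states = states, origin_node = NA_integer_,
                origin_at_root = FALSE, reversal_nodes = integer(0),
                n_events = 0L))
  }
  origin <- if (length(derived_tips) == 1) derived_tips else
    ape::getMRCA(tree, derived_tips)

  below <- node_descendant_tips(tree)
  all0 <- vapply(seq_len(n_all), function(n) all(x[below[[n]]] == 0L), TRUE)

  # membership of the origin clade
  in_clade <- rep(FALSE, n_all)
  desc_nodes <- function(node) {
    out <- node
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    for (kk in kids) out <- c(out, desc_nodes(kk))
    out
  }
  clade_nodes <- desc_nodes(origin)
  in_clade[clade_nodes] <- TRUE

  parent <- rep(NA_integer_, n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  # reversal stems: all-0 node whose parent (inside the clade) is not all-0
  reversal <- integer(0)
  for (n in clade_nodes) {
    if (!all0[n]) next
    p <- parent[n]
    if (is.na(p) || !in_clade[p] || n == origin) next
    if (!all0[p]) reversal <- c(reversal, n)
  }
  reversal <- sort(unique(reversal))

  # node states: derived inside the origin clade unless under a reversal stem
  under_reversal <- rep(FALSE, n_all)
  for (rv in reversal) under_reversal[desc_nodes(rv)] <- TRUE
  states[in_clade & !under_reversal] <- 1L
  states[seq_len(ntip)] <- x                 # tips keep observed states

  list(node_states = states,
       origin_node = as.integer(origin),
       origin_at_root = origin == root,
       reversal_nodes = as.integer(reversal),
       n_events = 1L + length(reversal))
}

#' Count genes with derived (lost) state at a selected ancestral node
#'
#' @param dollo_results named list of [dollo_reconstruct()] results, one per
#'   gene.
#' @param tree the tree the reconstructions were computed on.
#' @param tips tip labels whose MRCA is the node of interest.
#' @return list with `node`, `count` and `genes` (character vector of genes
#'   whose reconstructed state at the node is derived).
#' @export
summarize_losses <- function(dollo_results, tree, tips) {
  node <- mrca_node(tree, tips)
  derived <- vapply(dollo_results, function(res) res$node_states[node] == 1L, TRUE)
  list(node = node, count = sum(derived), genes = names(derived)[derived])
}
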