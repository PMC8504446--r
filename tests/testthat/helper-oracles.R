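# Independent brute-force oracles used across tests. These deliberately use
# naive enumeration, never the package's own algorithms.

# likelihood by exhaustive summation over all internal-node state assignments
brute_mk_loglik <- function(tree, x, mu, k) {
  tree <- suppressWarnings(ensure_branch_lengths(tree))
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  x <- x[tree$tip.label]
  kernel <- function(t) {
    e <- exp(-k * mu * t)
    P <- matrix((1 - e) / k, k, k)
    diag(P) <- 1 / k + (k - 1) * e / k
    P
  }
  P <- lapply(tree$edge.length, kernel)
  grid <- expand.grid(rep(list(0:(k - 1)), nn))
  tot <- 0
  for (gi in seq_len(nrow(grid))) {
    full <- c(unname(x), unlist(grid[gi, ]))
    pr <- 1 / k
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P[[e]][full[tree$edge[e, 1]] + 1, full[tree$edge[e, 2]] + 1]
    tot <- tot + pr
  }
  log(tot)
}

# marginal posterior at one internal node by conditioning the same sum
brute_mk_marginal <- function(tree, x, mu, k, node) {
  tree <- suppressWarnings(ensure_branch_lengths(tree))
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  x <- x[tree$tip.label]
  kernel <- function(t) {
    e <- exp(-k * mu * t)
    P <- matrix((1 - e) / k, k, k)
    diag(P) <- 1 / k + (k - 1) * e / k
    P
  }
  P <- lapply(tree$edge.length, kernel)
  grid <- expand.grid(rep(list(0:(k - 1)), nn))
  mass <- numeric(k)
  for (gi in seq_len(nrow(grid))) {
    full <- c(unname(x), unlist(grid[gi, ]))
    pr <- 1 / k
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P[[e]][full[tree$edge[e, 1]] + 1, full[tree$edge[e, 2]] + 1]
    mass[full[node] + 1] <- mass[full[node] + 1] + pr
  }
  mass / sum(mass)
}

# minimum number of events (1 origin + R reversals) over all internal-node
# assignments satisfying the single-origin constraint; Inf when impossible
brute_dollo_min_events <- function(tree, x) {
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  x <- x[tree$tip.label]
  if (sum(x) == 0) return(0L)
  grid <- expand.grid(rep(list(0:1), nn))
  parent <- rep(NA_integer_, ntip + nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  best <- Inf
  for (gi in seq_len(nrow(grid))) {
    full <- c(unname(x), unlist(grid[gi, ]))
    gains <- 0L; losses <- 0L
    root_state <- full[ntip + 1L]
    if (root_state == 1L) gains <- gains + 1L   # origin on the root stem
    for (e in seq_len(nrow(tree$edge))) {
      u <- full[tree$edge[e, 1]]; v <- full[tree$edge[e, 2]]
      if (u == 0 && v == 1) gains <- gains + 1L
      if (u == 1 && v == 0) losses <- losses + 1L
    }
    if (gains != 1L) next
    best <- min(best, 1L + losses)
  }
  best
}

# exact two-sided rank-sum p by full enumeration of group assignments
brute_u_pvalue <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  obs <- u_of(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  p <- 2 * min(mean(us <= obs + 1e-12), mean(us >= obs - 1e-12))
  min(1, p)
}

brute_u_stat <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# NG86 pathway oracle: recursive enumeration of all stop-free substitution
# orders between two codons
brute_ng86_codon <- function(c1, c2, code, allow_stops = FALSE) {
  walk <- function(cur) {
    diffs <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(diffs) == 0)
      return(list(list(s = 0, n = 0)))
    paths <- list()
    for (pos in diffs) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (!allow_stops && code[[nxt]] == "*") next
      syn <- code[[nxt]] == code[[cur]]
      for (rest in walk(nxt))
        paths[[length(paths) + 1]] <- list(s = rest$s + syn, n = rest$n + !syn)
    }
    paths
  }
  paths <- walk(c1)
  if (length(paths) == 0) return(brute_ng86_codon(c1, c2, code, allow_stops = TRUE))
  c(Sd = mean(vapply(paths, function(p) p$s, 0)),
    Nd = mean(vapply(paths, function(p) p$n, 0)))
}

# random stop-free codon (table 11)
random_sense_codon <- function(code) {
  repeat {
    cod <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
    if (code[[cod]] != "*") return(cod)
  }
}

# small random rooted tree with branch lengths, unique labels
random_small_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}
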