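# Generators for every input the pipeline consumes: random trees, discrete
# characters under equal-rates Mk and Dollo regimes, and fully annotated
# circular plastomes with a configurable quadripartite architecture and
# scripted pseudogenization edits. Every generator is seeded and returns its
# ground truth alongside the data.

#' Simulate a Yule (pure-birth) tree
#'
#' Branch lengths are rescaled so the tree height is 1.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed.
#' @return rooted bifurcating "phylo" object with tips t1..tn.
#' @export
simulate_tree <- function(n_tips, seed = 1) {
  stopifnot(n_tips >= 2)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  tree$tip.label <- paste0("t", seq_len(n_tips))
  tree
}

#' Simulate discrete characters under the equal-rates Mk model
#'
#' Root states are drawn uniformly over k states; states evolve along each
#' branch with the closed-form equal-rates kernel. The true states of all
#' internal nodes are retained.
#'
#' @param tree rooted "phylo" object with branch lengths.
#' @param mu transition rate (>= 0; 0 keeps every character at its root state).
#' @param k number of states.
#' @param n_chars number of independent characters.
#' @param seed integer seed.
#' @return list with `tips` (matrix n_tips x n_chars over 0..k-1, rownames =
#'   tip labels) and `node_states` (matrix over all nodes, ape numbering).
#' @export
simulate_mk <- function(tree, mu, k = 2, n_chars = 1, seed = 1) {
  stopifnot(mu >= 0)
  set.seed(seed)
  tree <- suppressWarnings(ensure_branch_lengths(tree))
  ntip <- length(tree$tip.label)
  n_all <- ntip + tree$Nnode
  root <- ntip + 1L
  edges <- reorder(tree, "postorder")$edge
  elen <- reorder(tree, "postorder")$edge.length
  preorder <- rev(seq_len(nrow(edges)))
  states <- matrix(NA_integer_, n_all, n_chars)
  states[root, ] <- sample.int(k, n_chars, replace = TRUE) - 1L
  for (e in preorder) {
    P <- if (mu == 0) diag(k) else mk_er_kernel(elen[e], mu, k)
    parent_states <- states[edges[e, 1], ]
    states[edges[e, 2], ] <- vapply(parent_states, function(s)
      sample.int(k, 1, prob = P[s + 1L, ]) - 1L, 0L)
  }
  tips <- states[seq_len(ntip), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  list(tips = tips, node_states = states)
}

#' Simulate binary characters under a Dollo regime
#'
#' Each character gains the derived state (1) on at most one branch: an
#' origin occurs with probability 1 - prod(1 - p) over branch probabilities
#' p, on a branch sampled proportionally to p. Below the origin, each branch
#' independently reverts to the ancestral state with probability
#' `p_reversal`; descendants of a reverted branch stay ancestral (no
#' re-origin).
#'
#' @param tree rooted "phylo" object.
#' @param p_origin_branch per-branch origin probability (scalar recycled over
#'   branches, or vector of length nbranch), in [0, 1].
#' @param p_reversal per-branch reversal probability in [0, 1].
#' @param n_chars number of characters.
#' @param seed integer seed.
#' @return list with `tips` (binary matrix n_tips x n_chars), `events`
#'   (per-character list: origin edge child node or NA, reversal edge child
#'   nodes) and `node_states`.
#' @export
simulate_dollo <- function(tree, p_origin_branch, p_reversal, n_chars = 1, seed = 1) {
  stopifnot(all(p_origin_branch >= 0), all(p_origin_branch <= 1),
            p_reversal >= 0, p_reversal <= 1)
  set.seed(seed)
  ntip <- length(tree$tip.label)
  n_all <- ntip + tree$Nnode
  edges <- tree$edge
  nb <- nrow(edges)
  p <- rep_len(p_origin_branch, nb)
  tips <- matrix(0L, ntip, n_chars, dimnames = list(tree$tip.label, NULL))
  node_states <- matrix(0L, n_all, n_chars)
  events <- vector("list", n_chars)
  post <- reorder(tree, "postorder")$edge
  preorder_edges <- rev(seq_len(nrow(post)))
  parent_of <- rep(NA_integer_, n_all)
  parent_of[edges[, 2]] <- edges[, 1]
  for (ch in seq_len(n_chars)) {
    origin_edge <- NA_integer_
    if (stats::runif(1) < 1 - prod(1 - p) && any(p > 0)) {
      origin_edge <- sample.int(nb, 1, prob = p)
    }
    st <- rep(0L, n_all)
    reversals <- integer(0)
    if (!is.na(origin_edge)) {
      origin_node <- edges[origin_edge, 2]
      # walk edges in preorder, propagating states below the origin
      st[origin_node] <- 1L
      for (pe in preorder_edges) {
        u <- post[pe, 1]; v <- post[pe, 2]
        if (v == origin_node) next
        if (st[u] == 1L) {
          if (stats::runif(1) < p_reversal) {
            st[v] <- 0L
            reversals <- c(reversals, v)
          } else st[v] <- 1L
        }
      }
    }
    node_states[, ch] <- st
    tips[, ch] <- st[seq_len(ntip)]
    events[[ch]] <- list(origin_node = if (is.na(origin_edge)) NA_integer_
                                       else edges[origin_edge, 2],
                         reversal_nodes = reversals)
  }
  list(tips = tips, events = events, node_states = node_states)
}

# ---- synthetic plastomes ---------------------------------------------------

#' Default synthetic plastome template
#'
#' Describes the gene table (symbol, kind, length, home region, strand,
#' order), per-region length and GC targets and the IR boundary type. Gene
#' lengths follow typical plastid values (ycf1 ~5 kb, ndhF ~2.2 kb, most
#' others 0.3-1.5 kb); landmark genes rps19, rpl2, trnH-GUG, ycf1, ndhF,
#' ndhH and ndhA are always present. For IR types II-IV the corresponding
#' prefix of the SSC gene order (ycf1, ndhH, ndhA[, ndhF]) is captured into
#' the inverted repeat; type IV additionally inverts ndhA within the SSC.
#'
#' @param ir_type one of "I", "II", "III", "IV".
#' @param ycf1_ir_overlap for type I, bases of ycf1 inside IRb (default 1000;
#'   observed plastomes range from a few hundred to ~1.6 kb).
#' @param region_lengths named vector of target lengths (LSC, IR, SSC) for
#'   the uncaptured (type I) layout.
#' @param region_gc named vector of target GC fractions per region.
#' @return a `plastome_template` list.
#' @export
plastome_template <- function(ir_type = c("I", "II", "III", "IV"),
                              ycf1_ir_overlap = 1000L,
                              region_lengths = c(LSC = 83000, IR = 25600, SSC = 17600),
                              region_gc = c(LSC = 0.365, IR = 0.43, SSC = 0.325)) {
  ir_type <- match.arg(ir_type)
  genes <- rbind(
    data.frame(gene = "trnH-GUG", kind = "tRNA", length = 72,  region = "LSC", strand = "-"),
    data.frame(gene = "psbA",   kind = "CDS", length = 1062, region = "LSC", strand = "-"),
    data.frame(gene = "matK",   kind = "CDS", length = 1530, region = "LSC", strand = "-"),
    data.frame(gene = "atpA",   kind = "CDS", length = 1524, region = "LSC", strand = "-"),
    data.frame(gene = "rpoB",   kind = "CDS", length = 3213, region = "LSC", strand = "-"),
    data.frame(gene = "ndhJ",   kind = "CDS", length = 477,  region = "LSC", strand = "-"),
    data.frame(gene = "ndhK",   kind = "CDS", length = 678,  region = "LSC", strand = "+"),
    data.frame(gene = "ndhC",   kind = "CDS", length = 363,  region = "LSC", strand = "+"),
    data.frame(gene = "psaA",   kind = "CDS", length = 2253, region = "LSC", strand = "+"),
    data.frame(gene = "psbB",   kind = "CDS", length = 1527, region = "LSC", strand = "+"),
    data.frame(gene = "petA",   kind = "CDS", length = 963,  region = "LSC", strand = "+"),
    data.frame(gene = "accD",   kind = "CDS", length = 1491, region = "LSC", strand = "+"),
    data.frame(gene = "rbcL",   kind = "CDS", length = 1428, region = "LSC", strand = "+"),
    data.frame(gene = "rpl16",  kind = "CDS", length = 408,  region = "LSC", strand = "-"),
    data.frame(gene = "rps19",  kind = "CDS", length = 279,  region = "LSC", strand = "-"),
    data.frame(gene = "rpl2",   kind = "CDS", length = 1485, region = "IR",  strand = "-"),
    data.frame(gene = "rpl23",  kind = "CDS", length = 282,  region = "IR",  strand = "-"),
    data.frame(gene = "ycf2",   kind = "CDS", length = 6846, region = "IR",  strand = "+"),
    data.frame(gene = "ndhB",   kind = "CDS", length = 1533, region = "IR",  strand = "-"),
    data.frame(gene = "rps7",   kind = "CDS", length = 468,  region = "IR",  strand = "-"),
    data.frame(gene = "rrn16",  kind = "rRNA", length = 1491, region = "IR", strand = "+"),
    data.frame(gene = "rrn23",  kind = "rRNA", length = 2810, region = "IR", strand = "+"),
    data.frame(gene = "rrn4.5", kind = "rRNA", length = 103,  region = "IR", strand = "+"),
    data.frame(gene = "rrn5",   kind = "rRNA", length = 121,  region = "IR", strand = "+"),
    data.frame(gene = "trnN-GUU", kind = "tRNA", length = 72, region = "IR", strand = "-"),
    data.frame(gene = "ycf1",   kind = "CDS", length = 5301, region = "SSC", strand = "+"),
    data.frame(gene = "ndhH",   kind = "CDS", length = 1182, region = "SSC", strand = "-"),
    data.frame(gene = "ndhA",   kind = "CDS", length = 1092, region = "SSC", strand = "-"),
    data.frame(gene = "ndhF",   kind = "CDS", length = 2241, region = "SSC", strand = "-"),
    data.frame(gene = "ndhG",   kind = "CDS", length = 531,  region = "SSC", strand = "-"),
    data.frame(gene = "ndhE",   kind = "CDS", length = 306,  region = "SSC", strand = "-"),
    data.frame(gene = "ndhD",   kind = "CDS", length = 1503, region = "SSC", strand = "-"),
    data.frame(gene = "ccsA",   kind = "CDS", length = 963,  region = "SSC", strand = "+"),
    data.frame(gene = "ndhI",   kind = "CDS", length = 501,  region = "SSC", strand = "-"),
    data.frame(gene = "rps15",  kind = "CDS", length = 273,  region = "SSC", strand = "-")
  )
  genes$order <- stats::ave(rep(1L, nrow(genes)), genes$region, FUN = seq_along)
  captured <- switch(ir_type, I = character(0),
                     II = c("ycf1", "ndhH", "ndhA", "ndhF"),
                     III = c("ycf1", "ndhH", "ndhA"),
                     IV = c("ycf1", "ndhH"))
  structure(list(genes = genes, ir_type = ir_type, captured = captured,
                 ycf1_ir_overlap = as.integer(ycf1_ir_overlap),
                 region_lengths = region_lengths, region_gc = region_gc),
            class = "plastome_template")
}

# random DNA with an (almost) exact GC count, as a character vector
random_dna_chars <- function(len, gc) {
  if (len == 0) return(character(0))
  n_gc <- round(gc * len)
  n_g <- round(n_gc / 2)
  n_a <- round((len - n_gc) / 2)
  pool <- c(rep("G", n_g), rep("C", n_gc - n_g),
            rep("A", n_a), rep("T", len - n_gc - n_a))
  sample(pool)
}

# random stop-free CDS with ATG start and TAA stop at a GC target
random_cds <- function(len, gc) {
  stopifnot(len %% 3 == 0, len >= 6)
  x <- random_dna_chars(len, gc)
  x[1:3] <- c("A", "T", "G")
  x[(len - 2):len] <- c("T", "A", "A")
  s <- chars_to_seq(x)
  cods <- codon_split(s)
  internal <- cods[-length(cods)]
  bad <- which(internal %in% c("TAA", "TAG", "TGA"))
  # composition-preserving permutations of the stop codons (Ile/Asp/Val)
  swap <- c(TAA = "ATA", TAG = "GAT", TGA = "GTA")
  for (b in bad)
    substr(s, (b - 1) * 3 + 1, b * 3) <- swap[[substr(s, (b - 1) * 3 + 1, b * 3)]]
  s
}

# split a total spacer budget over n gaps, roughly evenly with jitter
split_spacers <- function(total, n) {
  if (n == 0) return(integer(0))
  w <- stats::runif(n, 0.5, 1.5)
  out <- floor(total * w / sum(w))
  out[1] <- out[1] + (total - sum(out))
  as.integer(out)
}

#' Apply one pseudogenization edit to a CDS sequence
#'
#' Operations: `premature_stop` replaces the codon at relative position `at`
#' with TAA (expected state 1); `frameshift` deletes one base at `at`
#' (expected state 1); `truncate` removes `fraction` of the sequence from
#' the 5' or 3' `end` (expected state 2); `delete_all` removes the gene
#' (expected state 3).
#'
#' @param cds CDS string.
#' @param edit list with `op` and its parameters (`at`, `fraction`, `end`).
#' @return edited sequence ("" for delete_all).
#' @export
apply_edit <- function(cds, edit) {
  op <- edit$op
  if (op == "delete_all") return("")
  n <- nchar(cds)
  if (op == "premature_stop") {
    at <- edit$at %||% 0.5
    n_codon <- n %/% 3L
    idx <- min(max(2L, round(at * n_codon)), n_codon - 1L)
    substr(cds, (idx - 1L) * 3L + 1L, idx * 3L) <- "TAA"
    return(cds)
  }
  if (op == "frameshift") {
    at <- edit$at %||% 0.5
    pos <- min(max(4L, round(at * n)), n - 3L)
    return(paste0(substr(cds, 1, pos - 1L), substr(cds, pos + 1L, n)))
  }
  if (op == "truncate") {
    fraction <- edit$fraction %||% 0.5
    end <- edit$end %||% "3'"
    keep <- n - round(fraction * n)
    if (end == "3'") return(substr(cds, 1, keep))
    return(substr(cds, n - keep + 1L, n))
  }
  stop("unknown edit op: ", op)
}

expected_state_of_edit <- function(op) {
  switch(op, premature_stop = 1L, frameshift = 1L, truncate = 2L,
         delete_all = 3L, stop("unknown edit op: ", op))
}

#' Synthesize an annotated circular plastome with known ground truth
#'
#' Assembles LSC + IRb + SSC + IRa (IRa the exact reverse complement of IRb)
#' from the template: stop-free CDS with ATG starts and TAA stops, random
#' spacers at per-region GC targets, IR-captured genes duplicated and
#' mirrored in IRa, and (for type I) ycf1 laid across the IRb/SSC junction.
#' Bases flanking the IR are forced to break reverse complementarity so that
#' the planted IR is exactly maximal. Edits from `edit_script` are applied
#' to the named genes before assembly.
#'
#' @param template a [plastome_template()].
#' @param edit_script list of edits, each a list(gene =, op =, ...) as in
#'   [apply_edit()].
#' @param seed integer seed.
#' @param taxon record id / display name.
#' @param gene_sequences optional named list of unedited transcribed gene
#'   sequences to reuse (so that several cohort members share homologous
#'   genes); generated from the template when `NULL`.
#' @return list with `record` (annotated [plastome_record()]) and `truth`
#'   (partition, ir_type, per-gene expected states, applied edits, and the
#'   unedited `gene_sequences`).
#' @export
synthesize_plastome <- function(template, edit_script = list(), seed = 1,
                                taxon = "synthetic", gene_sequences = NULL) {
  set.seed(seed)
  g <- template$genes
  edits_by_gene <- list()
  for (e in edit_script) edits_by_gene[[e$gene]] <- e

  # generate transcribed sequences, apply edits
  seqs <- stats::setNames(vector("list", nrow(g)), g$gene)
  base_seqs <- stats::setNames(vector("list", nrow(g)), g$gene)
  states <- stats::setNames(rep(0L, nrow(g)), g$gene)
  for (i in seq_len(nrow(g))) {
    # genes captured into the IR are generated at the IR's GC target
    placed <- if (g$gene[i] %in% template$captured) "IR" else g$region[i]
    gc_t <- template$region_gc[[placed]]
    s <- gene_sequences[[g$gene[i]]] %||%
      (if (g$kind[i] == "CDS") random_cds(g$length[i], gc_t)
       else chars_to_seq(random_dna_chars(g$length[i], gc_t)))
    base_seqs[[g$gene[i]]] <- s
    ed <- edits_by_gene[[g$gene[i]]]
    if (!is.null(ed)) {
      s <- apply_edit(s, ed)
      states[g$gene[i]] <- expected_state_of_edit(ed$op)
    }
    seqs[[g$gene[i]]] <- s
  }

  # region item lists: genes in template order, captured SSC prefix moved to
  # the IRb tail; type IV inverts ndhA in place
  strand_of <- stats::setNames(g$strand, g$gene)
  if (template$ir_type == "IV")
    strand_of[["ndhA"]] <- if (strand_of[["ndhA"]] == "+") "-" else "+"
  lsc_genes <- g$gene[g$region == "LSC"]
  ir_genes <- c(g$gene[g$region == "IR"], template$captured)
  ssc_genes <- setdiff(g$gene[g$region == "SSC"], template$captured)
  present <- names(seqs)[nchar(unlist(seqs)) > 0]
  lsc_genes <- intersect(lsc_genes, present)
  ir_genes <- intersect(ir_genes, present)
  ssc_genes <- intersect(ssc_genes, present)

  type1_overlap <- template$ir_type == "I" && "ycf1" %in% ssc_genes &&
    states[["ycf1"]] == 0L
  ov <- if (type1_overlap) min(template$ycf1_ir_overlap,
                               nchar(seqs[["ycf1"]]) - 3L) else 0L

  gene_len <- vapply(seqs, nchar, 0L)
  captured_extra <- sum(gene_len[intersect(template$captured, present)])
  target <- template$region_lengths
  spacer_budget <- c(
    LSC = max(0, round(target[["LSC"]]) - sum(gene_len[lsc_genes])),
    IR = max(0, round(target[["IR"]]) - sum(gene_len[setdiff(ir_genes, template$captured)])),
    SSC = max(0, round(target[["SSC"]]) - captured_extra - sum(gene_len[ssc_genes])))

  build_region <- function(genes_in, budget, gc_t, lead_spacer = TRUE,
                           trail_spacer = TRUE) {
    n_gap <- length(genes_in) - 1L + lead_spacer + trail_spacer
    gaps <- split_spacers(budget, n_gap)
    pieces <- character(0)
    feats <- list()
    pos <- 0L
    gi <- 1L
    if (lead_spacer) {
      pieces <- c(pieces, chars_to_seq(random_dna_chars(gaps[gi], gc_t)))
      pos <- pos + gaps[gi]; gi <- gi + 1L
    }
    for (j in seq_along(genes_in)) {
      gene <- genes_in[j]
      s <- seqs[[gene]]
      fwd <- if (strand_of[[gene]] == "+") s else revcomp(s)
      feats[[length(feats) + 1]] <- list(gene = gene,
                                         kind = g$kind[g$gene == gene],
                                         strand = strand_of[[gene]],
                                         start = pos, end = pos + nchar(fwd),
                                         pseudo = states[[gene]] > 0L)
      pieces <- c(pieces, fwd)
      pos <- pos + nchar(fwd)
      if (j < length(genes_in) || trail_spacer) {
        pieces <- c(pieces, chars_to_seq(random_dna_chars(gaps[gi], gc_t)))
        pos <- pos + gaps[gi]; gi <- gi + 1L
      }
    }
    list(seq = paste(pieces, collapse = ""), feats = feats)
  }

  lsc <- build_region(lsc_genes, spacer_budget[["LSC"]], template$region_gc[["LSC"]])
  irb <- build_region(ir_genes, spacer_budget[["IR"]], template$region_gc[["IR"]],
                      trail_spacer = !type1_overlap || length(ir_genes) == 0)
  ssc <- build_region(ssc_genes, spacer_budget[["SSC"]], template$region_gc[["SSC"]],
                      lead_spacer = !type1_overlap)

  # type I: slide the first `ov` bases of the SSC (the ycf1 5' end) into IRb
  if (type1_overlap) {
    irb$seq <- paste0(irb$seq, substr(ssc$seq, 1L, ov))
    ssc$seq <- substr(ssc$seq, ov + 1L, nchar(ssc$seq))
    irb_len0 <- nchar(irb$seq)
    ssc$feats <- lapply(ssc$feats, function(f) {
      f$start <- f$start - ov; f$end <- f$end - ov; f
    })
  }

  l_lsc <- nchar(lsc$seq); l_ir <- nchar(irb$seq); l_ssc <- nchar(ssc$seq)
  L <- l_lsc + 2L * l_ir + l_ssc

  fix_boundary <- function(chars, i_fix, partner) {
    # force chars[i_fix] to not complement `partner`
    if (chars[i_fix] == .COMP[[partner]]) {
      alt <- setdiff(c("A", "C", "G", "T"), .COMP[[partner]])
      chars[i_fix] <- sample(alt, 1)
    }
    chars
  }
  lsc_chars <- seq_chars(lsc$seq)
  ssc_chars <- seq_chars(ssc$seq)
  # IR maximality: last LSC base must not pair with first LSC base, and
  # first SSC base must not pair with last SSC base
  lsc_chars <- fix_boundary(lsc_chars, length(lsc_chars), lsc_chars[1])
  ssc_chars <- fix_boundary(ssc_chars, length(ssc_chars), ssc_chars[1])
  lsc$seq <- chars_to_seq(lsc_chars)
  ssc$seq <- chars_to_seq(ssc_chars)

  ira_seq <- revcomp(irb$seq)
  sequence <- paste0(lsc$seq, irb$seq, ssc$seq, ira_seq)

  features <- list()
  add_feats <- function(feats, offset) {
    for (f in feats) {
      if (f$start < 0) {                  # ycf1 sliding across the junction
        features[[length(features) + 1]] <<-
          gene_feature(f$gene, f$kind, f$strand,
                       matrix(c(offset + f$start, offset + f$end), 1),
                       pseudo = f$pseudo)
        next
      }
      features[[length(features) + 1]] <<-
        gene_feature(f$gene, f$kind, f$strand,
                     matrix(c(offset + f$start, offset + f$end), 1),
                     pseudo = f$pseudo)
    }
  }
  add_feats(lsc$feats, 0L)
  add_feats(irb$feats, l_lsc)
  add_feats(ssc$feats, l_lsc + l_ir)
  # mirrored IRa copies of the IR genes
  ira_off <- l_lsc + l_ir + l_ssc
  for (f in irb$feats) {
    features[[length(features) + 1]] <-
      gene_feature(f$gene, f$kind, if (f$strand == "+") "-" else "+",
                   matrix(c(ira_off + l_ir - f$end, ira_off + l_ir - f$start), 1),
                   pseudo = f$pseudo)
  }

  record <- plastome_record(id = taxon, sequence = sequence, taxon = taxon,
                            circular = TRUE, features = features)
  partition <- region_partition(list(LSC = c(0L, l_lsc),
                                     IRb = c(l_lsc, l_ir),
                                     SSC = c(l_lsc + l_ir, l_ssc),
                                     IRa = c(ira_off, l_ir)), L)
  list(record = record,
       truth = list(partition = partition, ir_type = template$ir_type,
                    states = states, edits = edit_script,
                    region_gc = template$region_gc,
                    gene_sequences = base_seqs))
}

#' Synthesize a cohort of plastomes sharing homologous genes
#'
#' Generates one set of unedited gene sequences from the template, then one
#' plastome per taxon with its own spacers and scripted edits. The first
#' cohort member listed with an empty edit script is a natural reference for
#' [build_state_matrix()].
#'
#' @param template a [plastome_template()] (or named list of templates, one
#'   per taxon, sharing the same gene table).
#' @param edit_scripts named list (taxon -> list of edits); taxa with no
#'   entry receive no edits.
#' @param taxa character vector of taxon ids (default: names of
#'   `edit_scripts`).
#' @param seed integer seed.
#' @return list with `records` (named list of [plastome_record()]),
#'   `truth` (named list of per-taxon truth bundles) and `gene_sequences`.
#' @export
synthesize_cohort <- function(template, edit_scripts = list(),
                              taxa = names(edit_scripts), seed = 1) {
  set.seed(seed)
  templates <- if (inherits(template, "plastome_template"))
    stats::setNames(rep(list(template), length(taxa)), taxa) else template
  base <- synthesize_plastome(templates[[1]], seed = seed, taxon = "base")
  gene_seqs <- base$truth$gene_sequences
  records <- list(); truth <- list()
  sub_seeds <- sample.int(.Machine$integer.max, length(taxa))
  for (i in seq_along(taxa)) {
    tx <- taxa[i]
    syn <- synthesize_plastome(templates[[tx]],
                               edit_script = edit_scripts[[tx]] %||% list(),
                               seed = sub_seeds[i], taxon = tx,
                               gene_sequences = gene_seqs)
    records[[tx]] <- syn$record
    truth[[tx]] <- syn$truth
  }
  list(records = records, truth = truth, gene_sequences = gene_seqs)
}
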