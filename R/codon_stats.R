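# Relative synonymous codon usage and GC statistics.

#' Relative synonymous codon usage (RSCU)
#'
#' Pools codon counts over a collection of CDS sequences and computes, for
#' each sense codon, RSCU(c) = count(c) * family_size / sum of counts over
#' c's synonymous family (genetic code table 11). Stop codons are excluded.
#' Single-codon families (Met ATG, Trp TGG) are reported with RSCU fixed at 1
#' and flagged uninformative. A family with zero total count yields missing
#' RSCU values.
#'
#' @param cds_collection character vector of CDS sequences, each with length
#'   a multiple of 3 (names used in error messages).
#' @return data frame (codon, aa, count, rscu, informative) with one row per
#'   sense codon.
#' @export
rscu <- function(cds_collection) {
  lens <- nchar(cds_collection)
  bad <- which(lens %% 3L != 0L)
  if (length(bad)) {
    nm <- names(cds_collection)[bad[1]] %||% as.character(bad[1])
    stop("CDS length not a multiple of 3: ", nm)
  }
  code <- genetic_code_11()
  sense <- names(code)[code != "*"]
  counts <- stats::setNames(integer(length(sense)), sense)
  for (s in cds_collection) {
    cods <- codon_split(toupper(s))
    cods <- cods[cods %in% sense]
    t <- table(cods)
    counts[names(t)] <- counts[names(t)] + as.integer(t)
  }
  aa <- unname(code[sense])
  fam_size <- ave(rep(1L, length(sense)), aa, FUN = sum)
  fam_total <- ave(as.numeric(counts), aa, FUN = sum)
  val <- ifelse(fam_total > 0, counts * fam_size / fam_total, NA_real_)
  val[fam_size == 1] <- 1
  out <- data.frame(codon = sense, aa = aa, count = as.integer(counts),
                    rscu = val, informative = fam_size > 1, row.names = NULL)
  out[order(out$aa, out$codon), ]
}

#' GC content of a sequence
#'
#' (#G + #C) / (#A + #C + #G + #T); N bases are excluded from numerator and
#' denominator. Optionally restricted to one codon position.
#'
#' @param sequence DNA string.
#' @param codon_position "all" (default) or 1, 2, 3 to use only that codon
#'   position (the sequence is then read as consecutive codons from base 1).
#' @return GC fraction in [0, 1].
#' @export
gc_content <- function(sequence, codon_position = "all") {
  sequence <- toupper(sequence)
  if (!identical(codon_position, "all")) {
    pos <- as.integer(codon_position)
    stopifnot(pos %in% 1:3)
    ch <- seq_chars(sequence)
    idx <- seq(pos, length(ch), by = 3L)
    sequence <- chars_to_seq(ch[idx])
  }
  gc_fraction(sequence)
}

#' Default grouping of plastid gene symbols into functional groups
#'
#' Genes are grouped by symbol prefix (atp, ndh, pet, psa, psb, rpl, rps,
#' rpo, clp, ycf); any other symbol forms its own single-gene group.
#'
#' @param genes character vector of gene symbols.
#' @return character vector of group labels, same length as `genes`.
#' @export
default_gene_groups <- function(genes) {
  prefixes <- c("atp", "ndh", "pet", "psa", "psb", "rpl", "rps", "rpo", "clp", "ycf")
  out <- genes
  for (p in prefixes) out[startsWith(genes, p)] <- p
  out
}

#' GC content by gene group across samples, with deviations from the mean
#'
#' Pools the CDS bases of each gene group within each sample and computes
#' the group GC fraction; the deviation matrix subtracts each group's mean
#' over samples (so deviation columns are centred on zero).
#'
#' @param records list of annotated [plastome_record()] objects.
#' @param grouping function mapping gene symbols to group labels
#'   (default [default_gene_groups()]).
#' @return list with matrices `gc` and `deviation` (samples x groups); cells
#'   for empty groups are `NA`.
#' @export
gc_group_matrix <- function(records, grouping = default_gene_groups) {
  ids <- vapply(records, function(r) r$id, "")
  all_groups <- sort(unique(unlist(lapply(records, function(r)
    grouping(vapply(r$features, function(f) f$gene, ""))))))
  gc <- matrix(NA_real_, length(records), length(all_groups),
               dimnames = list(ids, all_groups))
  for (i in seq_along(records)) {
    r <- records[[i]]
    genes <- vapply(r$features, function(f) f$gene, "")
    grp <- grouping(genes)
    for (g in unique(grp)) {
      seqs <- vapply(r$features[grp == g], function(f) feature_sequence(r, f), "")
      pooled <- paste(seqs, collapse = "")
      if (nchar(pooled) > 0) gc[i, g] <- gc_fraction(pooled)
    }
  }
  dev <- sweep(gc, 2, colMeans(gc, na.rm = TRUE), "-")
  list(gc = gc, deviation = dev)
}
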