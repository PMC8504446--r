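# Quadripartite structure: detection of the inverted repeat, per-region
# statistics, IR/SSC boundary typing and the junction-gene report.
#
# A region partition stores each region as (start, length) in original
# genome coordinates (0-based start on the circle), in canonical order
# LSC -> IRb -> SSC -> IRa on the forward strand. IRb is the IR copy that is
# followed by the SSC. The canonical rotation offset is the LSC start.

region_partition <- function(regions, L) {
  stopifnot(setequal(names(regions), c("LSC", "IRb", "SSC", "IRa")))
  structure(list(regions = regions, genome_length = L,
                 offset = regions$LSC[1]),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition>", format(x$genome_length, big.mark = ","), "bp\n")
  for (r in c("LSC", "IRb", "SSC", "IRa")) {
    iv <- x$regions[[r]]
    cat(sprintf("  %-3s start %7d  length %7d\n", r, iv[1], iv[2]))
  }
  invisible(x)
}

#' Sequence of one region of a partition
#' @param record a [plastome_record()].
#' @param partition a partition from [detect_inverted_repeat()].
#' @param region one of "LSC", "IRb", "SSC", "IRa".
#' @return character DNA string (forward strand).
#' @export
region_sequence <- function(record, partition, region) {
  iv <- partition$regions[[match.arg(region, c("LSC", "IRb", "SSC", "IRa"))]]
  circ_substr(record$sequence, iv[1], iv[2])
}

#' Detect the inverted repeat and partition a circular plastome
#'
#' Finds the maximal-length pair of disjoint, exactly reverse-complementary
#' substrings of length >= `min_len` on the circular sequence, extended
#' maximally (no mismatch tolerance). The two single-copy gaps become LSC
#' (longer) and SSC (shorter); IRb is the IR copy followed by the SSC on the
#' forward strand in canonical rotation. Ties among co-maximal repeat pairs
#' are broken by the smallest canonical start coordinate.
#'
#' @param sequence DNA string (assumed circular), length >= 4 * `min_len`.
#' @param min_len minimum IR core length to report (default 1000 bp).
#' @return a `region_partition`.
#' @export
detect_inverted_repeat <- function(sequence, min_len = 1000) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 4 * min_len)
    stop(sprintf("sequence length %d < 4 * min_len (%d)", L, 4 * min_len))
  x <- seq_chars(sequence)
  cx <- unname(.COMP[x])

  # seed k-mers sampled from the doubled sequence so that any circular
  # occurrence of a >= min_len repeat contains at least one whole seed
  k <- min(24L, min_len)
  stride <- max(1L, min_len - k + 1L)
  S2 <- paste0(sequence, sequence)
  R2 <- revcomp(S2)
  R2d <- Biostrings::DNAString(R2)
  L2 <- 2L * L

  cand <- new.env(parent = emptyenv())
  for (p in seq(1L, L, by = stride)) {
    pat <- substr(S2, p, p + k - 1L)
    if (grepl("N", pat, fixed = TRUE)) next
    hits <- Biostrings::start(Biostrings::matchPattern(pat, R2d))
    for (q in hits) {
      # R2[q..q+k-1] is the reverse complement of S2[a2..b2]
      a2 <- L2 + 2L - q - k
      b2 <- L2 + 1L - q
      s1 <- (p - 1L) %% L          # 0-based starts on the circle
      s2 <- (a2 - 1L) %% L
      if (s1 == s2) next           # self-palindrome, not a repeat pair
      pair <- extend_ir_pair(x, cx, L, s1, s2, k)
      if (is.null(pair) || pair$len < min_len) next
      key <- paste(min(pair$s1, pair$s2), max(pair$s1, pair$s2), pair$len)
      if (!exists(key, envir = cand)) assign(key, pair, envir = cand)
    }
  }
  pairs <- as.list(cand)
  if (length(pairs) == 0)
    stop(sprintf("no inverted repeat of length >= %d found", min_len))
  lens <- vapply(pairs, function(p) p$len, 0L)
  best <- pairs[lens == max(lens)]
  starts <- vapply(best, function(p) min(p$s1, p$s2), 0L)
  pair <- best[[which.min(starts)]]

  build_partition(L, pair)
}

# maximal mismatch-free extension of an exact seed; s1, s2 are 0-based starts
# of the two copies (copy2 coordinates refer to the segment whose reverse
# complement matches copy1), len the current exact length
extend_ir_pair <- function(x, cx, L, s1, s2, len) {
  # seed invariant: x[s1 .. s1+len) == revcomp(x[s2-len+1+? ...]) -- here the
  # pairing is x[s1 + i] == comp(x[s2 + len - 1 - i]). Work with copy2 as the
  # interval [s2, s2+len) whose last base pairs with copy1's first base.
  gap_a <- (s2 - (s1 + len)) %% L          # forward gap: copy1 end -> copy2 start
  gap_b <- (s1 - (s2 + len)) %% L          # forward gap: copy2 end -> copy1 start
  if (gap_a == 0 && gap_b == 0 && len == 0) return(NULL)

  # extend copy1 rightwards / copy2 leftwards into gap_a
  t_max <- gap_a %/% 2L
  if (t_max > 0) {
    i1 <- circ_index(s1 + len + seq_len(t_max), L)
    i2 <- circ_index(s2 - seq_len(t_max) + 1L, L)
    ok <- x[i1] == cx[i2]
    ext <- if (all(ok)) t_max else which(!ok)[1] - 1L
    if (ext > 0) {
      len <- len + ext
      s2 <- (s2 - ext) %% L
    }
  }
  # extend copy1 leftwards / copy2 rightwards into gap_b
  gap_b <- (s1 - (s2 + len)) %% L
  t_max <- gap_b %/% 2L
  if (t_max > 0) {
    i1 <- circ_index(s1 - seq_len(t_max) + 1L, L)
    i2 <- circ_index(s2 + len + seq_len(t_max), L)
    ok <- x[i1] == cx[i2]
    ext <- if (all(ok)) t_max else which(!ok)[1] - 1L
    if (ext > 0) {
      len <- len + ext
      s1 <- (s1 - ext) %% L
    }
  }
  # disjointness on the circle
  if ((s2 - (s1 + len)) %% L + (s1 - (s2 + len)) %% L + 2L * len != L) return(NULL)
  list(s1 = as.integer(s1 %% L), s2 = as.integer(s2 %% L), len = as.integer(len))
}

build_partition <- function(L, pair) {
  s1 <- pair$s1; s2 <- pair$s2; len <- pair$len
  gap_a <- (s2 - (s1 + len)) %% L          # between copy1 and copy2
  gap_b <- (s1 - (s2 + len)) %% L          # between copy2 and copy1
  if (gap_a >= gap_b) {
    lsc <- c((s1 + len) %% L, gap_a); irb <- c(s2, len)
    ssc <- c((s2 + len) %% L, gap_b); ira <- c(s1, len)
  } else {
    lsc <- c((s2 + len) %% L, gap_b); irb <- c(s1, len)
    ssc <- c((s1 + len) %% L, gap_a); ira <- c(s2, len)
  }
  region_partition(list(LSC = as.integer(lsc), IRb = as.integer(irb),
                        SSC = as.integer(ssc), IRa = as.integer(ira)), L)
}

#' Per-region length and GC statistics
#'
#' @param record a [plastome_record()].
#' @param partition a `region_partition` covering the record.
#' @return data frame with one row per region plus a "genome" row: length in
#'   bp and GC fraction (N bases excluded from numerator and denominator).
#' @export
region_stats <- function(record, partition) {
  L <- nchar(record$sequence)
  if (partition$genome_length != L)
    stop("partition genome length does not match record")
  regions <- c("LSC", "IRb", "SSC", "IRa")
  lens <- vapply(regions, function(r) partition$regions[[r]][2], 0L)
  if (sum(lens) != L) stop("partition does not cover the genome")
  gc <- vapply(regions, function(r) gc_fraction(region_sequence(record, partition, r)), 0)
  out <- data.frame(region = c(regions, "genome"),
                    length = c(lens, L),
                    gc = c(gc, gc_fraction(record$sequence)),
                    row.names = NULL)
  out
}

# bases of a feature falling inside a region interval, on the circle
feature_region_overlap <- function(feature, iv, L) {
  if (iv[2] == 0) return(0L)
  reg_start <- iv[1]
  total <- 0L
  for (r in seq_len(nrow(feature$location))) {
    fs <- feature$location[r, 1]; fe <- feature$location[r, 2]
    # shift both to coordinates relative to region start
    rel_s <- (fs - reg_start) %% L
    rel_e <- rel_s + (fe - fs)
    # feature interval [rel_s, rel_e) vs region [0, iv[2]) on a line of length L
    total <- total + max(0L, min(rel_e, iv[2]) - rel_s)
    # wrapped tail of the feature interval
    if (rel_e > L) total <- total + max(0L, min(rel_e - L, iv[2]))
  }
  as.integer(total)
}

feature_placement <- function(feature, partition) {
  L <- partition$genome_length
  len <- feature_length(feature)
  in_irb <- feature_region_overlap(feature, partition$regions$IRb, L)
  in_ira <- feature_region_overlap(feature, partition$regions$IRa, L)
  in_ssc <- feature_region_overlap(feature, partition$regions$SSC, L)
  in_lsc <- feature_region_overlap(feature, partition$regions$LSC, L)
  frac_ir <- (in_irb + in_ira) / len
  list(len = len, in_irb = in_irb, in_ira = in_ira, in_ssc = in_ssc,
       in_lsc = in_lsc, frac_ir = frac_ir, frac_ssc = in_ssc / len)
}

# placement call for one landmark gene; a gene duplicated in the IR is judged
# by its best-placed copy
landmark_placement <- function(record, partition, gene, ir_frac = 0.95,
                               span_frac = 0.05) {
  feats <- find_features(record, gene)
  if (length(feats) == 0) return(NULL)
  pls <- lapply(feats, feature_placement, partition = partition)
  frac_ir <- vapply(pls, function(p) p$frac_ir, 0)
  best <- pls[[which.max(frac_ir)]]
  call <- if (best$frac_ir >= ir_frac) "in_IR"
          else if (best$frac_ssc >= ir_frac) "in_SSC"
          else if (best$frac_ir >= span_frac && best$frac_ssc >= span_frac) "spans_junction"
          else "other"
  list(gene = gene, call = call, placement = best,
       strand = feats[[which.max(frac_ir)]]$strand,
       pseudo = any(vapply(feats, function(f) f$pseudo, TRUE)))
}

#' Classify the IR/SSC junction architecture (types I-IV)
#'
#' Types are defined by the placement of the landmark genes ycf1, ndhF, ndhH
#' and ndhA relative to the inverted repeat. Type I: ycf1 spans the SSC/IRb
#' junction while ndhF, ndhH and ndhA lie fully in the SSC. Type II: all four
#' landmarks lie within the IR. Type III: ycf1, ndhH and ndhA in the IR, ndhF
#' not. Type IV: ycf1 and ndhH in the IR, ndhA fully in the SSC with its
#' orientation inverted (annotated strand opposite to ndhF's strand, the
#' configuration in which the two genes share a strand being the ancestral
#' one). Annotated pseudogene remnants count as landmarks. A gene is "in the
#' IR" when at least 95% of its span lies inside the IR and "spans" a
#' junction when both sides hold at least 5%.
#'
#' @param record annotated [plastome_record()].
#' @param partition `region_partition` of the record.
#' @return list with `type` ("I", "II", "III", "IV" or "unclassified"),
#'   `evidence` data frame (gene, placement, strand, pseudo) and
#'   `ycf1_overlap_bp`, the bases of ycf1 inside IRb.
#' @export
classify_ir_type <- function(record, partition) {
  landmarks <- c("ycf1", "ndhF", "ndhH", "ndhA")
  pls <- lapply(landmarks, landmark_placement, record = record,
                partition = partition)
  names(pls) <- landmarks
  present <- !vapply(pls, is.null, TRUE)
  evidence <- do.call(rbind, lapply(pls[present], function(p)
    data.frame(gene = p$gene, placement = p$call, strand = p$strand,
               pseudo = p$pseudo)))
  if (is.null(evidence))
    evidence <- data.frame(gene = character(0), placement = character(0),
                           strand = character(0), pseudo = logical(0))
  rownames(evidence) <- NULL
  ycf1_overlap <- if (present[["ycf1"]]) pls$ycf1$placement$in_irb else 0L

  call_of <- function(g) if (present[[g]]) pls[[g]]$call else NA_character_
  type <- "unclassified"
  if (all(present)) {
    ndha_inverted <- pls$ndhA$strand != pls$ndhF$strand
    if (identical(call_of("ycf1"), "spans_junction") &&
        identical(call_of("ndhF"), "in_SSC") &&
        identical(call_of("ndhH"), "in_SSC") &&
        identical(call_of("ndhA"), "in_SSC") &&
        ycf1_overlap > 0) {
      type <- "I"
    } else if (identical(call_of("ycf1"), "in_IR") &&
               identical(call_of("ndhF"), "in_IR") &&
               identical(call_of("ndhH"), "in_IR") &&
               identical(call_of("ndhA"), "in_IR")) {
      type <- "II"
    } else if (identical(call_of("ycf1"), "in_IR") &&
               identical(call_of("ndhH"), "in_IR") &&
               identical(call_of("ndhA"), "in_IR") &&
               !identical(call_of("ndhF"), "in_IR")) {
      type <- "III"
    } else if (identical(call_of("ycf1"), "in_IR") &&
               identical(call_of("ndhH"), "in_IR") &&
               identical(call_of("ndhA"), "in_SSC") &&
               ndha_inverted) {
      type <- "IV"
    }
  }
  list(type = type, evidence = evidence,
       ycf1_overlap_bp = as.integer(ycf1_overlap))
}

#' Genes flanking and spanning the four region junctions
#'
#' For each junction (LSC/IRb, IRb/SSC, SSC/IRa, IRa/LSC) reports the nearest
#' gene on each side and any gene spanning it, with distances in bp. A gene
#' exactly abutting a junction is reported with distance 0 on its side, not
#' as spanning (half-open boundary convention).
#'
#' @param record annotated [plastome_record()].
#' @param partition `region_partition` of the record.
#' @return data frame (junction, side, gene, distance); side is "left",
#'   "right" or "spanning". Empty annotation gives an empty report.
#' @export
junction_genes <- function(record, partition) {
  L <- partition$genome_length
  r <- partition$regions
  junctions <- c(LSC_IRb = (r$LSC[1] + r$LSC[2]) %% L,
                 IRb_SSC = (r$IRb[1] + r$IRb[2]) %% L,
                 SSC_IRa = (r$SSC[1] + r$SSC[2]) %% L,
                 IRa_LSC = (r$IRa[1] + r$IRa[2]) %% L)
  out <- list()
  for (jn in names(junctions)) {
    jpos <- junctions[[jn]]
    left_best <- NULL; right_best <- NULL
    for (f in record$features) {
      for (row in seq_len(nrow(f$location))) {
        fs <- f$location[row, 1]; fe <- f$location[row, 2]
        rel_s <- (fs - jpos) %% L            # distance ahead of the junction
        rel_e <- rel_s + (fe - fs)
        if (rel_e > L) {                     # interval spans the junction
          out[[length(out) + 1]] <- data.frame(
            junction = jn, side = "spanning", gene = f$gene, distance = 0L)
          next
        }
        d_right <- rel_s                     # gap from junction to interval start
        d_left <- L - rel_e                  # gap from interval end back to junction
        if (is.null(right_best) || d_right < right_best$distance)
          right_best <- list(gene = f$gene, distance = d_right)
        if (is.null(left_best) || d_left < left_best$distance)
          left_best <- list(gene = f$gene, distance = d_left)
      }
    }
    if (!is.null(left_best))
      out[[length(out) + 1]] <- data.frame(junction = jn, side = "left",
                                           gene = left_best$gene,
                                           distance = left_best$distance)
    if (!is.null(right_best))
      out[[length(out) + 1]] <- data.frame(junction = jn, side = "right",
                                           gene = right_best$gene,
                                           distance = right_best$distance)
  }
  if (length(out) == 0)
    return(data.frame(junction = character(0), side = character(0),
                      gene = character(0), distance = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
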