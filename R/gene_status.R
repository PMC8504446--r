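# Four-state gene functionality calling.
#
# States follow the degradation code used throughout the package:
#   0 functional; 1 full-length sequence with a premature stop codon (or a
#   frame-disrupting indel); 2 truncated gene; 3 complete loss.
# A remnant is located against the intact reference CDS by k-mer seeding and
# local alignment, then classified from coverage, internal stops and
# frameshifts.

.START_CODONS <- c("ATG", "GTG", "TTG")   # plastid CDS convention (table 11)

#' Conceptual codon-by-codon translation (genetic code table 11)
#'
#' @param cds_sequence DNA string over A,C,G,T,N, length >= 3.
#' @return list with `protein` (character string, stops as "*"),
#'   `internal_stops` (1-based codon indices of stop codons strictly before
#'   the final complete codon) and `incomplete_tail` (TRUE when the length is
#'   not a multiple of 3).
#' @export
conceptual_translate <- function(cds_sequence) {
  cds_sequence <- toupper(cds_sequence)
  if (nchar(cds_sequence) < 3) stop("sequence shorter than one codon")
  code <- genetic_code_11()
  codons <- codon_split(cds_sequence)
  aa <- ifelse(codons %in% names(code), unname(code[codons]), "X")
  n <- length(aa)
  internal <- which(aa[-n] == "*")
  list(protein = paste(aa, collapse = ""),
       internal_stops = as.integer(internal),
       incomplete_tail = (nchar(cds_sequence) %% 3L) != 0L)
}

# ---- locating a gene against a reference CDS -------------------------------

# seed positions of `ref` k-mers in `subject`; returns implied 1-based start
# positions of the gene in subject coordinates
seed_hits <- function(ref, subject_dna, k = 15L, n_seeds = 24L) {
  L <- nchar(ref)
  if (L < k) return(integer(0))
  offs <- unique(as.integer(round(seq(1L, L - k + 1L, length.out = min(n_seeds, L - k + 1L)))))
  implied <- integer(0)
  for (o in offs) {
    pat <- substr(ref, o, o + k - 1L)
    if (grepl("N", pat, fixed = TRUE)) next
    st <- Biostrings::start(Biostrings::matchPattern(pat, subject_dna))
    implied <- c(implied, st - o + 1L)
  }
  implied
}

#' Locate a (possibly degraded) gene in a plastome
#'
#' Seeded local search of the intact reference CDS against both strands of
#' the genome (k-mer seeds, then gapped local alignment of the best seed
#' cluster window). Returns coverage and identity fractions together with
#' internal-stop and frameshift counts computed on the induced alignment, or
#' `NULL` when no match with identity >= `min_identity` over >=
#' `min_span` bp exists (complete loss).
#'
#' @param record a [plastome_record()].
#' @param reference_cds intact reference CDS (character DNA string), given in
#'   transcription orientation with start and stop codons.
#' @param min_identity identity floor for accepting a hit (default 0.6).
#' @param min_span minimum aligned reference span in bp (default 50).
#' @return a `gene_hit` list (coverage, identity, internal_stops,
#'   frameshifts, has_start, has_stop, strand, subject window) or `NULL`.
#' @export
locate_gene <- function(record, reference_cds, min_identity = 0.6, min_span = 50L) {
  reference_cds <- toupper(reference_cds)
  if (nchar(reference_cds) == 0) stop("empty reference CDS")
  L <- nchar(record$sequence)
  genome <- if (record$circular) paste0(record$sequence, record$sequence) else record$sequence
  strands <- list(`+` = genome, `-` = revcomp(genome))
  Lref <- nchar(reference_cds)

  best <- NULL
  for (sname in names(strands)) {
    subj <- strands[[sname]]
    subj_dna <- Biostrings::DNAString(subj)
    hits <- seed_hits(reference_cds, subj_dna)
    if (record$circular) hits <- hits[hits <= L + Lref]   # dedupe doubled copy
    if (length(hits) == 0) next
    # cluster implied starts; take the modal cluster
    hits <- sort(hits)
    cl <- cumsum(c(1L, diff(hits) > as.integer(0.5 * Lref + 200L)))
    top <- which.max(tabulate(cl))
    centre <- as.integer(round(stats::median(hits[cl == top])))
    win_s <- max(1L, centre - 400L)
    win_e <- min(nchar(subj), centre + Lref + 400L)
    window <- substr(subj, win_s, win_e)
    pa <- Biostrings::pairwiseAlignment(
      pattern = reference_cds, subject = window, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = FALSE, type = "DNA"),
      gapOpening = 6, gapExtension = 2)
    if (is.null(best) || Biostrings::score(pa) > best$score)
      best <- list(pa = pa, strand = sname, score = Biostrings::score(pa),
                   win_s = win_s)
  }
  if (is.null(best)) return(NULL)

  pa <- best$pa
  pat_rng <- c(Biostrings::start(Biostrings::pattern(pa)),
               Biostrings::end(Biostrings::pattern(pa)))
  aligned_ref_span <- pat_rng[2] - pat_rng[1] + 1L
  identity <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
  if (aligned_ref_span < min_span || identity < min_identity) return(NULL)

  coverage <- aligned_ref_span / Lref

  # frameshift-inducing indels: aligned gap runs with length not 0 mod 3
  ins_w <- unlist(Biostrings::width(Biostrings::insertion(pa)))
  del_w <- unlist(Biostrings::width(Biostrings::deletion(pa)))
  frameshifts <- sum(c(ins_w, del_w) %% 3L != 0L)

  # internal stops: translate the matched genomic segment in the reading
  # frame implied by the reference alignment start
  subj_seg <- gsub("-", "", as.character(Biostrings::alignedSubject(pa)), fixed = TRUE)
  skip <- (3L - ((pat_rng[1] - 1L) %% 3L)) %% 3L
  internal_stops <- 0L
  if (nchar(subj_seg) - skip >= 3) {
    tr <- conceptual_translate(substr(subj_seg, skip + 1L, nchar(subj_seg)))
    stops <- tr$internal_stops
    # a stop in the final reference codon is the genuine terminator
    reaches_end <- pat_rng[2] >= Lref - 2L
    internal_stops <- length(stops)
    if (!reaches_end && length(stops) > 0) internal_stops <- length(stops)
  }

  has_start <- pat_rng[1] == 1L && substr(subj_seg, 1L, 3L) %in% .START_CODONS
  last_codon <- substr(subj_seg, nchar(subj_seg) - 2L, nchar(subj_seg))
  has_stop <- pat_rng[2] == Lref &&
    isTRUE(unname(genetic_code_11()[last_codon]) == "*")

  structure(list(coverage = coverage, identity = identity,
                 internal_stops = as.integer(internal_stops),
                 frameshifts = as.integer(frameshifts),
                 has_start = has_start, has_stop = has_stop,
                 strand = best$strand, score = best$score,
                 ref_span = c(pat_rng[1], pat_rng[2])),
            class = "gene_hit")
}

#' Classify a gene's degradation state from a located hit
#'
#' Mapping: no hit -> 3 (complete loss); coverage below `t_trunc` -> 2
#' (truncated); coverage at or above `t_trunc` with at least one internal
#' stop or frameshift -> 1 (full-length pseudogene); coverage at or above
#' `t_full` with no internal stop, no frameshift and intact start and stop
#' codons -> 0 (functional). A defect-free hit with coverage in
#' `[t_trunc, t_full)` is called 0 with a "borderline" warning; a full-length
#' defect-free hit whose start or stop codon is broken is called 1 (the
#' reading frame no longer yields the reference protein).
#'
#' @param hit result of [locate_gene()] (or `NULL`).
#' @param thresholds list with `t_trunc` (default 0.90) and `t_full`
#'   (default 0.95), both in (0, 1].
#' @return integer state in 0:3.
#' @export
classify_gene_state <- function(hit, thresholds = list(t_trunc = 0.90, t_full = 0.95)) {
  t_trunc <- thresholds$t_trunc %||% 0.90
  t_full <- thresholds$t_full %||% 0.95
  if (any(c(t_trunc, t_full) <= 0) || any(c(t_trunc, t_full) > 1))
    stop("thresholds must lie in (0, 1]")
  if (is.null(hit)) return(3L)
  if (hit$coverage < t_trunc) return(2L)
  if (hit$internal_stops > 0 || hit$frameshifts > 0) return(1L)
  if (hit$coverage >= t_full) {
    if (hit$has_start && hit$has_stop) return(0L)
    return(1L)
  }
  warning("borderline coverage ", signif(hit$coverage, 3),
          " without defects; calling functional")
  0L
}

#' Build the taxa x gene degradation-state matrix
#'
#' Calls [locate_gene()] and [classify_gene_state()] for every (record, gene)
#' pair against reference CDS sequences taken from a designated all-functional
#' reference record.
#'
#' @param records list of [plastome_record()] objects (unique ids).
#' @param reference a [plastome_record()] in which every gene of `gene_list`
#'   is annotated and functional.
#' @param gene_list character vector of gene symbols; defaults to the 11 NDH
#'   genes plus accD and ccsA.
#' @param thresholds passed to [classify_gene_state()].
#' @return integer matrix (taxa rows in input order, gene columns) over
#'   {0,1,2,3}, with per-call evidence in `attr(, "evidence")`.
#' @export
build_state_matrix <- function(records, reference, gene_list = default_gene_list(),
                               thresholds = list(t_trunc = 0.90, t_full = 0.95)) {
  ids <- vapply(records, function(r) r$id, "")
  if (anyDuplicated(ids)) stop("duplicate taxon ids")
  refs <- lapply(gene_list, function(g) {
    fs <- find_features(reference, g)
    if (length(fs) == 0)
      stop("gene ", g, " is not annotated in the reference record")
    feature_sequence(reference, fs[[1]])
  })
  names(refs) <- gene_list
  m <- matrix(NA_integer_, nrow = length(records), ncol = length(gene_list),
              dimnames = list(ids, gene_list))
  evidence <- list()
  for (i in seq_along(records)) {
    for (g in gene_list) {
      hit <- locate_gene(records[[i]], refs[[g]])
      state <- suppressWarnings(classify_gene_state(hit, thresholds))
      m[i, g] <- state
      evidence[[paste(ids[i], g, sep = "|")]] <-
        list(taxon = ids[i], gene = g, state = state,
             coverage = if (is.null(hit)) 0 else hit$coverage,
             identity = if (is.null(hit)) NA_real_ else hit$identity,
             internal_stops = if (is.null(hit)) NA_integer_ else hit$internal_stops,
             frameshifts = if (is.null(hit)) NA_integer_ else hit$frameshifts)
    }
  }
  attr(m, "evidence") <- evidence
  m
}

#' Default gene list for degradation calling
#'
#' The 11 plastid NDH genes (ndhA-ndhK) plus accD and ccsA.
#' @return character vector of 13 gene symbols.
#' @export
default_gene_list <- function() {
  c(paste0("ndh", LETTERS[1:11]), "accD", "ccsA")
}
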