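#' Construct a gene feature
#'
#' A gene feature is one annotated gene on a plastome: a CDS, tRNA or rRNA
#' with a strand and one or more exon intervals. Intervals are 0-based
#' half-open and are listed in transcription order: ascending genomic
#' coordinates on the plus strand, descending on the minus strand. A feature
#' crossing the origin of a circular genome is represented by two (or more)
#' intervals, never by coordinates beyond the sequence length.
#'
#' @param gene gene symbol, e.g. "ndhF", "ycf1".
#' @param kind one of "CDS", "tRNA", "rRNA".
#' @param strand "+" or "-".
#' @param location integer matrix with columns `start`, `end` (0-based
#'   half-open), one row per exon, in transcription order.
#' @param pseudo logical; `TRUE` if annotated as a pseudogene.
#' @return an object of class `gene_feature`.
#' @export
gene_feature <- function(gene, kind = "CDS", strand = "+", location, pseudo = FALSE) {
  if (!is.character(gene) || nchar(gene) == 0) stop("gene symbol must be non-empty")
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA"))
  strand <- match.arg(strand, c("+", "-"))
  location <- matrix(as.integer(location), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
  if (any(location[, 2] <= location[, 1])) stop("feature intervals must be non-empty")
  structure(list(gene = gene, kind = kind, strand = strand,
                 location = location, pseudo = isTRUE(pseudo)),
            class = "gene_feature")
}

#' Construct a plastome record
#'
#' The central sequence container: one circular (or linear) annotated plastid
#' genome with its gene features.
#'
#' @param id accession-like identifier, unique within a collection.
#' @param sequence upper-case DNA string over A, C, G, T, N.
#' @param taxon display name of the organism.
#' @param circular logical; circular molecule?
#' @param features list of [gene_feature()] objects.
#' @return an object of class `plastome_record`.
#' @export
plastome_record <- function(id, sequence, taxon = id, circular = TRUE,
                            features = list()) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence)) stop("sequence must be over {A,C,G,T,N}")
  rec <- structure(list(id = id, taxon = taxon, circular = isTRUE(circular),
                        sequence = sequence, features = features),
                   class = "plastome_record")
  validate_plastome_record(rec)
  rec
}

validate_plastome_record <- function(rec) {
  L <- nchar(rec$sequence)
  for (f in rec$features) {
    if (!inherits(f, "gene_feature")) stop("features must be gene_feature objects")
    if (any(f$location < 0L) || any(f$location > L))
      stop(sprintf("feature %s lies outside [0, %d)", f$gene, L))
  }
  invisible(rec)
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s (%s), %s bp, %s, %d features\n",
              x$id, x$taxon, format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear", length(x$features)))
  invisible(x)
}

#' @export
print.gene_feature <- function(x, ...) {
  cat(sprintf("<gene_feature> %s [%s, %s] %s%s\n", x$gene, x$kind, x$strand,
              paste(sprintf("%d..%d", x$location[, 1], x$location[, 2]),
                    collapse = ","),
              if (x$pseudo) " (pseudo)" else ""))
  invisible(x)
}

#' Total length of a feature in bases
#' @param feature a [gene_feature()].
#' @return integer number of bases covered.
#' @export
feature_length <- function(feature) {
  sum(feature$location[, 2] - feature$location[, 1])
}

#' Extract the transcribed sequence of a feature
#'
#' Concatenates the exon intervals in transcription order; minus-strand
#' features are reverse-complemented, matching the GenBank
#' `complement(join(...))` convention.
#'
#' @param record a [plastome_record()].
#' @param feature a [gene_feature()] on that record.
#' @return character DNA string in transcription orientation.
#' @export
feature_sequence <- function(record, feature) {
  pieces <- apply(feature$location, 1, function(iv) {
    substr(record$sequence, iv[1] + 1L, iv[2])
  })
  if (feature$strand == "+") {
    paste(pieces, collapse = "")
  } else {
    # intervals are stored in transcription order (descending); each piece is
    # reverse-complemented individually, then concatenated
    paste(vapply(pieces, revcomp, ""), collapse = "")
  }
}

#' Find features of a record by gene symbol
#' @param record a [plastome_record()].
#' @param gene gene symbol.
#' @return list of matching [gene_feature()] objects (possibly empty).
#' @export
find_features <- function(record, gene) {
  Filter(function(f) identical(f$gene, gene), record$features)
}
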