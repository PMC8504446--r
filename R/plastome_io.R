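# GenBank flat-file, FASTA and newick I/O.
#
# GenBank coordinates are 1-based inclusive; the internal model is 0-based
# half-open. The conversion (a..b) <-> [a-1, b) is applied only here.

.GB_FEATURE_KINDS <- c("CDS", "tRNA", "rRNA")

#' Read a GenBank flat file
#'
#' Parses one or more LOCUS records (DDBJ/ENA/GenBank feature-table dialect)
#' into [plastome_record()] objects. `join()` locations become multi-interval
#' features; `complement()` sets the minus strand with intervals stored in
#' transcription order; `/pseudo` and `/pseudogene` qualifiers set the pseudo
#' flag. Only CDS, tRNA and rRNA features are retained.
#'
#' @param path path to a GenBank flat file with at least one LOCUS record.
#' @return list of [plastome_record()] objects, one per LOCUS.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0) stop("no LOCUS record found in ", path)
  ends <- grep("^//", lines)
  if (length(ends) < length(starts))
    stop("unterminated LOCUS record in ", path)
  records <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:ends[ends > starts[i]][1]]
    records[[i]] <- parse_genbank_record(block, starts[i])
  }
  ids <- vapply(records, function(r) r$id, "")
  if (anyDuplicated(ids)) stop("duplicate record ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  records
}

parse_genbank_record <- function(block, offset_line) {
  locus <- block[1]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  if (length(toks) < 3 || is.na(suppressWarnings(as.integer(toks[3]))))
    stop(sprintf("malformed LOCUS line at line %d: %s", offset_line, locus))
  id <- toks[2]
  declared_len <- as.integer(toks[3])
  circular <- any(grepl("circular", locus, ignore.case = TRUE))

  taxon <- id
  org <- grep("^\\s{2}ORGANISM", block, value = TRUE)
  if (length(org) >= 1) taxon <- trimws(sub("^\\s{2}ORGANISM\\s*", "", org[1]))

  # ---- sequence ----
  ori <- grep("^ORIGIN", block)
  if (length(ori) != 1)
    stop(sprintf("record %s: missing ORIGIN block (near line %d)", id, offset_line))
  seq_lines <- block[(ori + 1):length(block)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) != declared_len)
    stop(sprintf("record %s: sequence length %d does not match LOCUS length %d",
                 id, nchar(sequence), declared_len))

  # ---- features ----
  feat_start <- grep("^FEATURES", block)
  features <- list()
  if (length(feat_start) == 1) {
    flines <- block[(feat_start + 1):(ori - 1)]
    key_idx <- grep("^\\s{5}\\S", flines)
    for (j in seq_along(key_idx)) {
      from <- key_idx[j]
      to <- if (j < length(key_idx)) key_idx[j + 1] - 1 else length(flines)
      chunk <- flines[from:to]
      key <- sub("^\\s{5}(\\S+).*$", "\\1", chunk[1])
      if (!key %in% .GB_FEATURE_KINDS) next
      features[[length(features) + 1]] <-
        parse_genbank_feature(key, chunk, id, offset_line + feat_start + from - 1,
                              declared_len, circular)
    }
  }
  features <- Filter(Negate(is.null), features)
  plastome_record(id = id, sequence = sequence, taxon = taxon,
                  circular = circular, features = features)
}

parse_genbank_feature <- function(key, chunk, id, line_no, L, circular) {
  # location may continue over several lines until the first qualifier
  qual_idx <- grep("^\\s{21}/", chunk)
  loc_end <- if (length(qual_idx)) qual_idx[1] - 1 else length(chunk)
  loc_text <- paste(sub("^\\s{5}\\S+\\s*", "", chunk[1]),
                    paste(trimws(chunk[seq_len(loc_end)[-1]]), collapse = ""),
                    sep = "")
  loc_text <- gsub("\\s", "", loc_text)
  parsed <- parse_gb_location(loc_text, id, line_no)
  if (any(parsed$intervals[, 2] > L))
    stop(sprintf("record %s (line %d): feature end %d beyond sequence length %d",
                 id, line_no, max(parsed$intervals[, 2]), L))

  quals <- trimws(chunk[qual_idx])
  gene <- NA_character_
  g <- grep("^/gene=", quals, value = TRUE)
  if (length(g)) gene <- gsub('^/gene="?|"?$', "", g[1])
  pseudo <- any(grepl("^/pseudo(gene)?\\b", quals) | quals %in% c("/pseudo"))
  if (is.na(gene)) return(NULL)          # unnamed features are not modeled

  ivs <- parsed$intervals
  if (parsed$strand == "-") ivs <- ivs[rev(seq_len(nrow(ivs))), , drop = FALSE]
  gene_feature(gene = gene, kind = key, strand = parsed$strand,
               location = ivs, pseudo = pseudo)
}

# "complement(join(1000..2000,3000..3100))" -> strand + 0-based intervals
parse_gb_location <- function(text, id = "?", line_no = NA) {
  strand <- "+"
  if (grepl("^complement\\(", text)) {
    strand <- "-"
    text <- sub("^complement\\((.*)\\)$", "\\1", text)
  }
  if (grepl("^join\\(", text)) text <- sub("^join\\((.*)\\)$", "\\1", text)
  if (grepl("[()]", text) || !grepl("^[<>0-9.,]+$", text))
    stop(sprintf("record %s (line %s): cannot parse location '%s'",
                 id, line_no, text))
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  ivs <- t(vapply(parts, function(p) {
    p <- gsub("[<>]", "", p)
    if (grepl("\\.\\.", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else {
      ab <- rep(as.integer(p), 2)
    }
    if (anyNA(ab) || ab[2] < ab[1])
      stop(sprintf("record %s (line %s): bad interval '%s'", id, line_no, p))
    c(ab[1] - 1L, ab[2])               # 1-based inclusive -> 0-based half-open
  }, integer(2)))
  dimnames(ivs) <- list(NULL, c("start", "end"))
  list(strand = strand, intervals = ivs)
}

format_gb_location <- function(feature) {
  ivs <- feature$location
  if (feature$strand == "-") ivs <- ivs[rev(seq_len(nrow(ivs))), , drop = FALSE]
  body <- paste(sprintf("%d..%d", ivs[, 1] + 1L, ivs[, 2]), collapse = ",")
  if (nrow(ivs) > 1) body <- sprintf("join(%s)", body)
  if (feature$strand == "-") body <- sprintf("complement(%s)", body)
  body
}

#' Write a GenBank flat file
#'
#' Emits a standard GenBank flat file re-readable by [read_genbank()];
#' internal 0-based half-open coordinates are restored to 1-based inclusive.
#'
#' @param record a [plastome_record()] (or list of them).
#' @param path output path.
#' @export
write_genbank <- function(record, path) {
  records <- if (inherits(record, "plastome_record")) list(record) else record
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    L <- nchar(rec$sequence)
    writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s PLN 01-JAN-2000",
                       rec$id, L, if (rec$circular) "circular" else "linear"), con)
    writeLines(sprintf("DEFINITION  %s plastid genome.", rec$taxon), con)
    writeLines("SOURCE      plastid", con)
    writeLines(sprintf("  ORGANISM  %s", rec$taxon), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", L), con)
    writeLines(sprintf('                     /organism="%s"', rec$taxon), con)
    for (f in rec$features) {
      writeLines(sprintf("     %-15s %s", f$kind, format_gb_location(f)), con)
      writeLines(sprintf('                     /gene="%s"', f$gene), con)
      if (f$pseudo) writeLines("                     /pseudo", con)
    }
    writeLines("ORIGIN", con)
    s <- tolower(rec$sequence)
    for (pos in seq(1L, L, by = 60L)) {
      line_chunk <- substr(s, pos, min(pos + 59L, L))
      tens <- substring(line_chunk,
                        seq(1L, nchar(line_chunk), by = 10L),
                        pmin(seq(10L, nchar(line_chunk) + 9L, by = 10L),
                             nchar(line_chunk)))
      writeLines(sprintf("%9d %s", pos, paste(tens, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(NULL)
}

#' Read a rooted tree from a newick string or file
#'
#' @param text newick string (or path to a file containing one).
#' @return an [ape::read.tree()] "phylo" object. Missing branch lengths are
#'   left absent; operations that require lengths substitute 1.0 with a
#'   warning (see [ensure_branch_lengths()]).
#' @export
read_newick <- function(text) {
  if (length(text) == 1 && !grepl("\\(", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  open_n <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  close_n <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (open_n != close_n) stop("unbalanced parentheses in newick string")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("cannot parse newick string")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  tree
}

#' Write a tree as newick
#' @param tree a "phylo" object.
#' @param path optional output path; if omitted the newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Fill in absent branch lengths
#'
#' Branch lengths absent in the input newick are treated as 1.0 when an
#' operation requires lengths; a warning records the substitution.
#'
#' @param tree a "phylo" object.
#' @return the tree with a complete `edge.length` vector.
#' @export
ensure_branch_lengths <- function(tree) {
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; using 1.0 for every branch")
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("tree has missing branch lengths; using 1.0 where absent")
    tree$edge.length[is.na(tree$edge.length)] <- 1
  }
  tree
}

#' Read sequences from a FASTA file
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(NULL)
}
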