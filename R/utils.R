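# Internal sequence helpers shared across modules.
# All genome coordinates inside the package are 0-based half-open; file I/O
# converts at the boundary.

.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

chars_to_seq <- function(x) paste(x, collapse = "")

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# circular 1-based index into a genome of length L
circ_index <- function(i, L) ((i - 1L) %% L) + 1L

# extract the circular substring [start, start+len) (0-based start)
circ_substr <- function(s, start, len) {
  L <- nchar(s)
  stopifnot(len >= 0, len <= L)
  if (len == 0) return("")
  a <- (start %% L) + 1L        # 1-based
  b <- a + len - 1L
  if (b <= L) {
    substr(s, a, b)
  } else {
    paste0(substr(s, a, L), substr(s, 1L, b - L))
  }
}

gc_fraction <- function(s) {
  if (nchar(s) == 0) stop("empty sequence")
  counts <- table(factor(seq_chars(s), levels = c("A", "C", "G", "T", "N")))
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0) stop("GC content undefined: no unambiguous bases")
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

# genetic code used throughout: bacterial/plastid table 11
genetic_code_11 <- function() Biostrings::getGeneticCode("11")

codon_split <- function(s) {
  n <- nchar(s)
  n_codon <- n %/% 3L
  if (n_codon == 0) return(character(0))
  substring(s, seq(1L, by = 3L, length.out = n_codon),
            seq(3L, by = 3L, length.out = n_codon))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
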