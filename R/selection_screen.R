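# Pairwise dN/dS screen by the Nei-Gojobori (1986) counting method with
# Jukes-Cantor correction. This is a lightweight per-gene screen for
# elevated or depressed nonsynonymous divergence between two aligned coding
# sequences; it is not a branch-site codon-model analysis.

ng86_codon_sites <- function(codon, code) {
  bases <- c("A", "C", "G", "T")
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    for (b in setdiff(bases, orig)) {
      mut <- codon
      substr(mut, pos, pos) <- b
      # changes to stop codons count as nonsynonymous
      if (code[[mut]] != "*" && code[[mut]] == aa) s <- s + 1 / 3
    }
  }
  c(S = s, N = 3 - s)
}

#' Synonymous and nonsynonymous site counts (Nei-Gojobori 1986)
#'
#' Each of the three positions of every codon contributes the fraction of
#' its three possible point changes that are synonymous to S and the
#' remainder to N (genetic code table 11); changes to stop codons count as
#' nonsynonymous. S + N = 3 x codon count.
#'
#' @param codon_sequence gap-free, stop-free coding sequence, length a
#'   multiple of 3.
#' @return named numeric vector c(S, N).
#' @export
ng86_site_counts <- function(codon_sequence) {
  codon_sequence <- toupper(codon_sequence)
  if (nchar(codon_sequence) %% 3L != 0L) stop("length must be a multiple of 3")
  code <- genetic_code_11()
  codons <- codon_split(codon_sequence)
  aa <- unname(code[codons])
  if (any(aa[-length(aa)] == "*")) stop("internal stop codon in sequence")
  sites <- vapply(codons, ng86_codon_sites, numeric(2), code = code)
  c(S = sum(sites["S", ]), N = sum(sites["N", ]))
}

# all mutational pathways between two codons differing at positions `diffs`;
# returns average (Sd, Nd) over pathways not passing through stop codons
ng86_codon_diffs <- function(c1, c2, code, exclude_stop_paths = TRUE) {
  diffs <- which(seq_chars(c1) != seq_chars(c2))
  d <- length(diffs)
  if (d == 0) return(c(Sd = 0, Nd = 0))
  perms <- switch(d,
                  `1` = list(diffs),
                  `2` = list(diffs, rev(diffs)),
                  `3` = {
                    p <- list()
                    for (i in 1:3) for (j in 1:3) for (l in 1:3)
                      if (length(unique(c(i, j, l))) == 3)
                        p[[length(p) + 1]] <- diffs[c(i, j, l)]
                    p
                  })
  acc_s <- 0; acc_n <- 0; n_path <- 0
  for (ord in perms) {
    cur <- c1
    s <- 0; n <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (exclude_stop_paths && code[[nxt]] == "*") { ok <- FALSE; break }
      if (code[[nxt]] == code[[cur]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    if (ok) { acc_s <- acc_s + s; acc_n <- acc_n + n; n_path <- n_path + 1 }
  }
  if (n_path == 0) {
    # every pathway crosses a stop codon; fall back to including them
    return(ng86_codon_diffs(c1, c2, code, exclude_stop_paths = FALSE))
  }
  c(Sd = acc_s / n_path, Nd = acc_n / n_path)
}

#' Pairwise dN/dS by the Nei-Gojobori (1986) method
#'
#' Codons differing at d positions distribute their d changes over all d!
#' mutational pathways (pathways through stop codons excluded unless every
#' pathway crosses one); site counts are averaged between the two sequences;
#' proportions are Jukes-Cantor corrected, dX = -3/4 ln(1 - 4/3 pX).
#'
#' @param seq_a,seq_b equal-length, codon-aligned, gap-free coding sequences.
#' @return list with S, N (average sites), Sd, Nd (differences), pS, pN,
#'   dS, dN and omega = dN/dS (`NA` when dS = 0).
#' @export
ng86_pairwise <- function(seq_a, seq_b) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must have equal length")
  code <- genetic_code_11()
  sa <- ng86_site_counts(seq_a)
  sb <- ng86_site_counts(seq_b)
  S <- (sa[["S"]] + sb[["S"]]) / 2
  N <- (sa[["N"]] + sb[["N"]]) / 2
  ca <- codon_split(seq_a); cb <- codon_split(seq_b)
  dmat <- mapply(function(x, y) ng86_codon_diffs(x, y, code), ca, cb)
  Sd <- sum(dmat["Sd", ]); Nd <- sum(dmat["Nd", ])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p, what) {
    if (p >= 3 / 4) {
      warning(what, " proportion ", signif(p, 3),
              " >= 3/4: Jukes-Cantor distance saturated")
      return(NA_real_)
    }
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  dS <- jc(pS, "synonymous"); dN <- jc(pN, "nonsynonymous")
  omega <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = dS, dN = dN, omega = omega)
}

#' dN/dS screen over a per-gene codon alignment
#'
#' Applies [ng86_pairwise()] to every sequence pair of a codon alignment
#' (e.g. read with [read_fasta()]).
#'
#' @param alignment named character vector of equal-length codon-aligned
#'   sequences (gap columns removed upstream).
#' @return data frame (seq_a, seq_b, dN, dS, omega).
#' @export
dnds_screen <- function(alignment) {
  nms <- names(alignment) %||% as.character(seq_along(alignment))
  out <- list()
  for (i in seq_along(alignment)) for (j in seq_along(alignment)) {
    if (j <= i) next
    res <- ng86_pairwise(alignment[[i]], alignment[[j]])
    out[[length(out) + 1]] <- data.frame(seq_a = nms[i], seq_b = nms[j],
                                         dN = res$dN, dS = res$dS,
                                         omega = res$omega)
  }
  do.call(rbind, out)
}
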