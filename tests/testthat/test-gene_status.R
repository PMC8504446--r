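test_that("conceptual translation finds internal stops under table 11", {
  expect_equal(conceptual_translate("ATGTAA")$protein, "M*")
  expect_equal(conceptual_translate("ATGTAA")$internal_stops, integer(0))
  # TGA is a stop in the plastid/bacterial code
  tr <- conceptual_translate("ATGTGAAAATAA")
  expect_equal(tr$internal_stops, 2L)
  expect_error(conceptual_translate("AT"), "codon")
  expect_true(conceptual_translate("ATGAAAA")$incomplete_tail)
  # a generated stop-free CDS translates without internal stops
  set.seed(3)
  cds <- plastdeg:::random_cds(900, 0.38)
  expect_equal(conceptual_translate(cds)$internal_stops, integer(0))
})

make_host <- function(gene_seq, seed = 1, strand = "+") {
  # embed a gene in a random 12 kb circular host genome
  set.seed(seed)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  fwd <- if (strand == "+") gene_seq else revcomp(gene_seq)
  plastome_record("host", paste0(rand(5000), fwd, rand(7000)))
}

test_that("locate_gene recovers exact, mutated and deleted copies", {
  set.seed(11)
  ref <- plastdeg:::random_cds(1200, 0.38)

  hit <- locate_gene(make_host(ref, seed = 2), ref)
  expect_equal(hit$coverage, 1.0)
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$internal_stops, 0L)
  expect_equal(hit$frameshifts, 0L)
  expect_true(hit$has_start && hit$has_stop)

  # minus-strand copy is found as well
  hitm <- locate_gene(make_host(ref, seed = 3, strand = "-"), ref)
  expect_equal(hitm$coverage, 1.0)
  expect_equal(hitm$strand, "-")

  # planted 1-bp deletion at the midpoint: one frameshift, downstream stops
  mid <- nchar(ref) %/% 2
  del <- paste0(substr(ref, 1, mid - 1), substr(ref, mid + 1, nchar(ref)))
  hd <- locate_gene(make_host(del, seed = 4), ref)
  expect_equal(hd$frameshifts, 1L)
  expect_gte(hd$internal_stops, 1L)

  # absent gene
  expect_null(locate_gene(make_host("", seed = 5), ref))
  expect_error(locate_gene(make_host(ref, seed = 2), ""), "empty")
})

test_that("state classification implements the four-state code", {
  hit <- function(cov, stops = 0, fs = 0, start = TRUE, stop = TRUE)
    structure(list(coverage = cov, identity = 0.99, internal_stops = stops,
                   frameshifts = fs, has_start = start, has_stop = stop),
              class = "gene_hit")
  expect_equal(classify_gene_state(NULL), 3L)
  expect_equal(classify_gene_state(hit(0.40)), 2L)
  expect_equal(classify_gene_state(hit(0.99, stops = 1)), 1L)
  expect_equal(classify_gene_state(hit(0.99, fs = 1)), 1L)
  expect_equal(classify_gene_state(hit(0.99)), 0L)
  expect_equal(classify_gene_state(hit(0.99, start = FALSE)), 1L)
  expect_warning(s <- classify_gene_state(hit(0.92)), "borderline")
  expect_equal(s, 0L)
  expect_error(classify_gene_state(hit(0.99), list(t_trunc = 0, t_full = 2)),
               "thresholds")
  # monotonicity: increasing coverage never moves a defective remnant
  # from 1 toward 3
  states <- vapply(seq(0.2, 1, by = 0.05), function(cv)
    classify_gene_state(hit(cv, stops = 1)), 0L)
  expect_true(all(diff(states) <= 0))
  expect_setequal(unique(states), c(2L, 1L))
})

test_that("state matrix matches scripted-edit ground truth on a cohort", {
  tmpl <- plastome_template("I",
                            region_lengths = c(LSC = 20000, IR = 16000,
                                               SSC = 14500))
  edits <- list(
    tax1 = list(list(gene = "ndhH", op = "premature_stop", at = 0.5),
                list(gene = "ndhE", op = "delete_all")),
    tax2 = list(list(gene = "ndhA", op = "truncate", fraction = 0.6, end = "3'"),
                list(gene = "ccsA", op = "frameshift", at = 0.4),
                list(gene = "ndhB", op = "premature_stop", at = 0.3)),
    tax3 = list())
  coh <- synthesize_cohort(tmpl, edits, seed = 31)
  m <- suppressWarnings(build_state_matrix(coh$records, coh$records$tax3))
  genes <- default_gene_list()
  for (tx in names(edits))
    expect_equal(unname(m[tx, genes]), unname(coh$truth[[tx]]$states[genes]),
                 label = tx)
  # all-functional taxon gives an all-zero row
  expect_true(all(m["tax3", ] == 0L))
  expect_error(build_state_matrix(coh$records[c(1, 1)], coh$records$tax3),
               "duplicate")
})
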