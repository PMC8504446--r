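# A compact template keeps these structural tests fast; region sizes are
# config-exposed template parameters and do not change the detection logic.
small_template <- function(type = "I") {
  plastome_template(type,
                    region_lengths = c(LSC = 20000, IR = 16000, SSC = 14500))
}

test_that("planted inverted repeat is recovered exactly", {
  set.seed(7)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  lsc <- rand(20000); ir <- rand(8000); ssc <- rand(4000)
  seq <- paste0(lsc, ir, ssc, revcomp(ir))
  # force maximal extension to stop at the planted boundaries
  part <- detect_inverted_repeat(seq, min_len = 1000)
  expect_equal(part$regions$IRb[2], part$regions$IRa[2])
  expect_gte(part$regions$IRb[2], 8000)           # at least the planted block
  expect_lte(part$regions$IRb[2] - 8000, 2)       # chance 1-bp extensions only
  expect_equal(part$regions$LSC[2] + part$regions$IRb[2] +
                 part$regions$SSC[2] + part$regions$IRa[2], nchar(seq))
  expect_identical(region_sequence(list(sequence = seq), part, "IRa"),
                   revcomp(region_sequence(list(sequence = seq), part, "IRb")))
  expect_gte(part$regions$LSC[2], part$regions$SSC[2])
})

test_that("random sequence without a repeat raises the no-IR error", {
  set.seed(8)
  seq <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
               collapse = "")
  expect_error(detect_inverted_repeat(seq, min_len = 1000),
               "no inverted repeat")
  expect_error(detect_inverted_repeat(substr(seq, 1, 3000), min_len = 1000),
               "min_len")
})

test_that("detection is rotation-invariant and strand-covariant", {
  syn <- synthesize_plastome(small_template("I"), seed = 21)
  seq <- syn$record$sequence
  L <- nchar(seq)
  part0 <- detect_inverted_repeat(seq)
  for (shift in c(1234L, L %/% 3)) {
    rot <- paste0(substr(seq, shift + 1, L), substr(seq, 1, shift))
    part <- detect_inverted_repeat(rot)
    # same canonical regions, shifted starts
    for (r in c("LSC", "IRb", "SSC", "IRa")) {
      expect_equal(part$regions[[r]][2], part0$regions[[r]][2])
      expect_equal(part$regions[[r]][1],
                   (part0$regions[[r]][1] - shift) %% L)
    }
  }
  # reverse complement preserves region lengths and swaps the IR labels
  partrc <- detect_inverted_repeat(revcomp(seq))
  expect_equal(partrc$regions$LSC[2], part0$regions$LSC[2])
  expect_equal(partrc$regions$SSC[2], part0$regions$SSC[2])
  expect_equal(partrc$regions$IRb[2], part0$regions$IRa[2])
})

test_that("region statistics follow the partition", {
  rec <- plastome_record("G", strrep("G", 4000))
  part <- plastdeg:::region_partition(
    list(LSC = c(0L, 2000L), IRb = c(2000L, 700L), SSC = c(2700L, 600L),
         IRa = c(3300L, 700L)), 4000L)
  st <- region_stats(rec, part)
  expect_equal(st$gc, rep(1, 5))
  expect_equal(sum(st$length[1:4]), 4000)
  rec2 <- plastome_record("H", strrep("ATGC", 1000))
  st2 <- region_stats(rec2, part)
  expect_equal(st2$gc, rep(0.5, 5))
  expect_error(region_stats(plastome_record("I", "ACGT"), part), "length")
})

test_that("IR type rules classify hand-built annotations", {
  # skeleton: LSC [0,2e4), IRb [2e4,3e4), SSC [3e4,34e3), IRa [34e3,44e3)
  set.seed(9)
  seq <- paste(sample(c("A", "C", "G", "T"), 44000, replace = TRUE), collapse = "")
  part <- plastdeg:::region_partition(
    list(LSC = c(0L, 20000L), IRb = c(20000L, 10000L), SSC = c(30000L, 4000L),
         IRa = c(34000L, 10000L)), 44000L)
  mk_rec <- function(feats) plastome_record("T", seq, features = feats)
  iv <- function(a, b) matrix(c(a, b), 1)

  # type I: ycf1 straddles the IRb/SSC junction with 1000 bp inside IRb
  rec <- mk_rec(list(
    gene_feature("ycf1", "CDS", "+", iv(29000, 33000)),
    gene_feature("ndhF", "CDS", "-", iv(33050, 33350)),
    gene_feature("ndhH", "CDS", "-", iv(33400, 33600)),
    gene_feature("ndhA", "CDS", "-", iv(33650, 33850))))
  res <- classify_ir_type(rec, part)
  expect_equal(res$type, "I")
  expect_equal(res$ycf1_overlap_bp, 1000L)

  # type II: all four landmarks inside the IR
  rec2 <- mk_rec(list(
    gene_feature("ycf1", "CDS", "+", iv(21000, 24000)),
    gene_feature("ndhF", "CDS", "-", iv(24100, 24900)),
    gene_feature("ndhH", "CDS", "-", iv(25000, 25500)),
    gene_feature("ndhA", "CDS", "-", iv(25600, 26100))))
  expect_equal(classify_ir_type(rec2, part)$type, "II")

  # type III: ndhF released to the SSC
  rec3 <- mk_rec(list(
    gene_feature("ycf1", "CDS", "+", iv(21000, 24000)),
    gene_feature("ndhF", "CDS", "-", iv(31000, 31800)),
    gene_feature("ndhH", "CDS", "-", iv(25000, 25500)),
    gene_feature("ndhA", "CDS", "-", iv(25600, 26100))))
  expect_equal(classify_ir_type(rec3, part)$type, "III")

  # type IV: ndhA back in the SSC with inverted orientation
  rec4 <- mk_rec(list(
    gene_feature("ycf1", "CDS", "+", iv(21000, 24000)),
    gene_feature("ndhF", "CDS", "-", iv(31000, 31800)),
    gene_feature("ndhH", "CDS", "-", iv(25000, 25500)),
    gene_feature("ndhA", "CDS", "+", iv(30200, 30700))))
  expect_equal(classify_ir_type(rec4, part)$type, "IV")
  # same placement but ancestral orientation is not type IV
  rec4b <- mk_rec(list(
    gene_feature("ycf1", "CDS", "+", iv(21000, 24000)),
    gene_feature("ndhF", "CDS", "-", iv(31000, 31800)),
    gene_feature("ndhH", "CDS", "-", iv(25000, 25500)),
    gene_feature("ndhA", "CDS", "-", iv(30200, 30700))))
  expect_equal(classify_ir_type(rec4b, part)$type, "unclassified")

  # missing ycf1 entirely -> unclassified, no error
  rec5 <- mk_rec(list(gene_feature("ndhF", "CDS", "-", iv(31000, 31800))))
  res5 <- classify_ir_type(rec5, part)
  expect_equal(res5$type, "unclassified")
  expect_false("ycf1" %in% res5$evidence$gene)

  # classification is a pure function of placements: permuting feature order
  # never changes the call
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1))) {
    recp <- mk_rec(rec4$features[perm])
    expect_equal(classify_ir_type(recp, part)$type, "IV")
  }
})

test_that("junction report names flanking genes and spanning genes", {
  syn <- synthesize_plastome(small_template("I"), seed = 22)
  part <- detect_inverted_repeat(syn$record$sequence)
  jg <- junction_genes(syn$record, part)
  lsc_irb <- jg[jg$junction == "LSC_IRb", ]
  expect_equal(lsc_irb$gene[lsc_irb$side == "left"], "rps19")
  expect_equal(lsc_irb$gene[lsc_irb$side == "right"], "rpl2")
  ira_lsc <- jg[jg$junction == "IRa_LSC", ]
  expect_equal(ira_lsc$gene[ira_lsc$side == "left"], "rpl2")
  expect_equal(ira_lsc$gene[ira_lsc$side == "right"], "trnH-GUG")
  # type I: ycf1 spans the IRb/SSC junction
  expect_true("ycf1" %in% jg$gene[jg$junction == "IRb_SSC" &
                                    jg$side == "spanning"])

  # a gene exactly abutting a junction has distance 0 and is not spanning
  seq <- strrep("ACGT", 1000)
  part2 <- plastdeg:::region_partition(
    list(LSC = c(0L, 2000L), IRb = c(2000L, 700L), SSC = c(2700L, 600L),
         IRa = c(3300L, 700L)), 4000L)
  rec <- plastome_record("A", seq, features = list(
    gene_feature("rps19", "CDS", "+", matrix(c(1900, 2000), 1))))
  jg2 <- junction_genes(rec, part2)
  row <- jg2[jg2$junction == "LSC_IRb" & jg2$side == "left", ]
  expect_equal(row$distance, 0L)
  expect_false(any(jg2$side == "spanning" & jg2$junction == "LSC_IRb"))
})
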