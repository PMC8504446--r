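# Packaged study fixtures: the published 22-taxon x 13-gene degradation
# state matrix, the region size/GC table, and the study tree topology
# (assembled from the reported clade structure, unit branch lengths).
#
# Machine-safe taxon labels are used throughout; display names are returned
# alongside.

.FIXTURE_TAXA <- c(
  P_cyathophylla_1      = "P. cyathophylla 1",
  P_cyathophylla_2      = "P. cyathophylla 2",
  P_cyathophylloides_1  = "P. cyathophylloides 1",
  P_cyathophylloides_2  = "P. cyathophylloides 2",
  P_rex_var_rex         = "P. rex var. rex",
  P_rex_var_purpurea    = "P. rex var. purpurea",
  P_rex_var_rockii      = "P. rex var. rockii",
  P_aff_thamnophila     = "P. aff. thamnophila",
  P_thamnophila         = "P. thamnophila",
  P_connata             = "P. connata",
  P_superba_1           = "P. superba 1",
  P_superba_2           = "P. superba 2",
  P_superba_3           = "P. superba 3",
  P_przewalskii         = "P. przewalskii",
  P_insignis            = "P. insignis",
  P_lyrata              = "P. lyrata",
  P_tongolensis         = "P. tongolensis",
  P_kangdingensis       = "P. kangdingensis",
  Phtheirospermum_japonicum = "Phtheirospermum japonicum",
  Lindenbergia_muraria  = "Lindenbergia muraria",
  Paulownia_tomentosa   = "Paulownia tomentosa",
  Rehmannia_glutinosa   = "Rehmannia glutinosa")

.CYATHOPHORA_TAXA <- names(.FIXTURE_TAXA)[1:13]

#' Taxon groups of the packaged study fixture
#'
#' @return list with `cyathophora` (the 13 section Cyathophora samples),
#'   `other_pedicularis` (5 samples) and `outgroup` (4 non-Pedicularis
#'   samples), as machine-safe labels.
#' @export
fixture_groups <- function() {
  list(cyathophora = .CYATHOPHORA_TAXA,
       other_pedicularis = names(.FIXTURE_TAXA)[14:18],
       outgroup = names(.FIXTURE_TAXA)[19:22])
}

#' Packaged degradation-state matrix and region table
#'
#' The published 22-sample survey: per-taxon states of the 11 NDH genes,
#' accD and ccsA (0 functional, 1 premature stop, 2 truncated, 3 lost; a
#' gene absent from a sample's pseudogene list is functional), and the
#' genome/region size and GC table. Known transcription inconsistencies in
#' the source table are kept as printed and listed under `errata`, except
#' ndhG in P. rex var. rex, which is recorded as functional following the
#' study's text and reconstruction results.
#'
#' @return list with `states` (22 x 13 integer matrix), `regions` (data
#'   frame: taxon, group, sizes in bp and GC percentages, gene counts),
#'   `display_names` and `errata`.
#' @export
fixture_table1 <- function() {
  genes <- default_gene_list()
  taxa <- names(.FIXTURE_TAXA)
  m <- matrix(0L, length(taxa), length(genes), dimnames = list(taxa, genes))
  set_states <- function(taxon, ...) {
    st <- c(...)
    m[taxon, names(st)] <<- as.integer(st)
  }
  set_states("P_cyathophylla_1", ndhA = 2, ndhD = 2, ndhE = 3, ndhF = 2, ndhG = 3,
             ndhH = 1, ndhI = 3, ndhJ = 1, ndhK = 1, accD = 1, ccsA = 1)
  set_states("P_cyathophylla_2", ndhA = 2, ndhD = 2, ndhE = 3, ndhF = 2, ndhG = 3,
             ndhH = 1, ndhI = 3, ndhJ = 1, ndhK = 1, accD = 1, ccsA = 1)
  set_states("P_cyathophylloides_1", ndhA = 2, ndhD = 1, ndhE = 3, ndhF = 2,
             ndhG = 3, ndhH = 1, ndhI = 3, ndhJ = 2, ndhK = 2, accD = 1)
  set_states("P_cyathophylloides_2", ndhA = 2, ndhD = 1, ndhE = 3, ndhF = 2,
             ndhG = 3, ndhH = 1, ndhI = 3, ndhJ = 1, ndhK = 1, accD = 2)
  set_states("P_rex_var_rex", ndhA = 2, ndhD = 1, ndhE = 1, ndhF = 2,
             ndhH = 1, ndhI = 3, ndhJ = 1, accD = 1, ccsA = 1)
  set_states("P_rex_var_purpurea", ndhA = 2, ndhD = 1, ndhE = 1, ndhF = 2,
             ndhG = 2, ndhH = 1, ndhI = 3, ndhJ = 1, accD = 1, ccsA = 1)
  set_states("P_rex_var_rockii", ndhA = 2, ndhD = 1, ndhE = 1, ndhF = 2,
             ndhH = 1, ndhI = 1, ndhJ = 1, accD = 1, ccsA = 1)
  set_states("P_aff_thamnophila", ndhA = 3, ndhD = 1, ndhE = 1, ndhF = 2,
             ndhH = 2, ndhI = 3, ndhJ = 1, accD = 1, ccsA = 1)
  set_states("P_thamnophila", ndhA = 3, ndhD = 1, ndhE = 1, ndhF = 2,
             ndhH = 2, ndhI = 3, ndhJ = 1, accD = 1, ccsA = 1)
  set_states("P_connata", ndhA = 2, ndhD = 2, ndhE = 3, ndhF = 2, ndhG = 3,
             ndhH = 1, ndhI = 3, ndhJ = 1, ndhK = 1, accD = 1, ccsA = 1)
  set_states("P_superba_1", ndhA = 1, ndhD = 1, ndhE = 1, ndhF = 2, ndhG = 1,
             ndhH = 1, ndhI = 1, ndhJ = 1, ndhK = 1, accD = 1, ccsA = 1)
  set_states("P_superba_2", ndhA = 1, ndhD = 1, ndhE = 1, ndhF = 2, ndhG = 1,
             ndhH = 1, ndhI = 1, ndhJ = 1, ndhK = 1, accD = 1)
  set_states("P_superba_3", ndhA = 1, ndhD = 1, ndhE = 1, ndhF = 2, ndhG = 1,
             ndhH = 1, ndhI = 1, ndhJ = 1, ndhK = 1, accD = 1)
  set_states("P_przewalskii", ndhA = 2, ndhB = 1, ndhC = 2, ndhD = 1, ndhF = 3,
             ndhG = 2, ndhH = 1, ndhI = 1, ndhK = 2, accD = 1, ccsA = 1)
  set_states("P_insignis", ndhA = 2, ndhB = 1, ndhC = 1, ndhD = 2, ndhE = 1,
             ndhF = 2, ndhG = 1, ndhH = 1, ndhI = 1, ndhJ = 1, ndhK = 1,
             accD = 2, ccsA = 2)
  set_states("P_lyrata", ndhA = 1, ndhD = 2, ndhE = 1, ndhF = 2, ndhG = 1,
             ndhH = 1, ndhI = 1, accD = 2, ccsA = 1)
  set_states("P_tongolensis", ccsA = 1)
  set_states("P_kangdingensis", ccsA = 1)
  # outgroup rows remain all-functional

  groups <- fixture_groups()
  group_of <- rep("outgroup", length(taxa))
  group_of[taxa %in% groups$cyathophora] <- "cyathophora"
  group_of[taxa %in% groups$other_pedicularis] <- "other_pedicularis"

  regions <- data.frame(
    taxon = taxa, group = group_of,
    genome_bp = c(154426, 154412, 154238, 154238, 153415, 153512, 156819,
                  153446, 153612, 153908, 157028, 156942, 156947,
                  146480, 147267, 148379, 151850, 151577,
                  153372, 154122, 154798, 153777),
    genome_gc = c(38.3, 38.3, 38.3, 38.3, 38.3, 38.3, 38.2, 38.3, 38.3, 38.4,
                  38.2, 38.2, 38.2, 38.5, 38.6, 38.4, 38.3, 38.3,
                  38.3, 37.7, 38.0, 37.9),
    lsc_bp = c(82962, 82972, 82342, 83342, 82950, 82999, 82920, 82999, 82972,
               82533, 83056, 83061, 83065, 82246, 82213, 82471, 83240, 82805,
               84478, 85029, 85438, 84669),
    lsc_gc = c(36.6, 36.6, 36.6, 36.6, 36.6, 36.6, 36.6, 36.6, 36.6, 36.6,
               36.6, 36.6, 36.6, 36.6, 36.7, 36.6, 36.4, 36.4,
               36.4, 35.7, 36.0, 36.0),
    ir_bp = c(33821, 33861, 33833, 33833, 31421, 31819, 33957, 31416, 31411,
              33800, 33148, 33079, 33148, 24759, 24936, 26227, 25729, 25743,
              25608, 25832, 25814, 25759),
    ir_gc = c(40.7, 40.7, 40.7, 40.7, 41.1, 41.1, 40.6, 41.1, 41.1, 40.7,
              40.9, 40.9, 40.9, 43.5, 43.5, 43.0, 43.3, 43.3,
              43.4, 43.2, 43.2, 43.1),
    ssc_bp = c(3822, 3718, 4230, 4230, 7623, 6875, 5985, 7615, 7818, 3775,
               7676, 7723, 7586, 14716, 15181, 13456, 17251, 17286,
               17678, 17429, 17732, 17590),
    ssc_gc = c(33.9, 33.6, 34.3, 34.3, 34.2, 34.0, 33.8, 34.2, 34.3, 33.9,
               33.2, 33.2, 33.4, 32.8, 32.7, 31.9, 32.5, 32.4,
               32.3, 31.5, 32.4, 32.2),
    cds = c(69, 69, 70, 70, 70, 70, 71, 71, 71, 69, 69, 70, 70,
            69, 67, 71, 79, 79, 80, 80, 80, 80),
    trna = rep(4L, 22), rrna = rep(30L, 22),
    row.names = NULL)

  errata <- c(
    paste("P. cyathophylloides 2 prints LSC 83,342 bp next to a genome size",
          "identical to sample 1 (LSC 82,342 bp); both printed values are",
          "stored unresolved."),
    paste("ndhG in P. rex var. rex: the printed pseudogene list includes",
          "ndhG (truncated) but the study's text and reconstruction treat it",
          "as functional; the matrix records state 0."),
    paste("ndhG is absent from the printed pseudogene list of",
          "P. aff. thamnophila (functional); the matrix follows the table."),
    paste("ccsA is absent from the printed lists of P. cyathophylloides 1/2",
          "and P. superba 2/3 (functional); the matrix follows the table."))

  list(states = m, regions = regions, display_names = .FIXTURE_TAXA,
       errata = errata)
}

#' Packaged study tree topology
#'
#' The rooted 22-tip topology assembled from the reported clade structure:
#' section Cyathophora = (clade III (P. cyathophylloides + P. superba),
#' (clade II (P. cyathophylla + P. connata), clade I (series Reges with
#' P. rex var. rockii sister to the rest))); (P. insignis, P. przewalskii)
#' sister to the section; then successively P. lyrata, P. kangdingensis and
#' P. tongolensis; outgroups Phtheirospermum, Lindenbergia, Rehmannia and
#' Paulownia. All branch lengths are 1 (the source tree's branch lengths are
#' unpublished).
#'
#' @return rooted "phylo" object with 22 tips.
#' @export
fixture_tree <- function() {
  clade3 <- "((P_cyathophylloides_1:1,P_cyathophylloides_2:1):1,(P_superba_1:1,(P_superba_2:1,P_superba_3:1):1):1)"
  clade2 <- "((P_cyathophylla_1:1,P_cyathophylla_2:1):1,P_connata:1)"
  clade1 <- "(P_rex_var_rockii:1,((P_rex_var_rex:1,P_rex_var_purpurea:1):1,(P_thamnophila:1,P_aff_thamnophila:1):1):1)"
  cyatho <- sprintf("(%s:1,(%s:1,%s:1):1)", clade3, clade2, clade1)
  core <- sprintf("((P_insignis:1,P_przewalskii:1):1,%s:1)", cyatho)
  nwk <- sprintf(
    "(Paulownia_tomentosa:1,(Rehmannia_glutinosa:1,(Lindenbergia_muraria:1,(Phtheirospermum_japonicum:1,(P_tongolensis:1,(P_kangdingensis:1,(P_lyrata:1,%s:1):1):1):1):1):1):1);",
    core)
  read_newick(nwk)
}
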