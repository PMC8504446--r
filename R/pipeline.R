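# Orchestration: one call that runs partition -> IR typing -> gene states ->
# codon/GC statistics -> rank statistics -> ancestral reconstruction and
# writes TSV reports plus a run manifest. Stages are plain package functions;
# the composite is deterministic given the config and seed.

#' Write / read a degradation-state matrix as TSV
#'
#' Taxa as rows (first column `taxon`), genes as columns, integer states.
#' @param matrix integer matrix (taxa x genes).
#' @param path TSV path.
#' @export
write_state_matrix <- function(matrix, path) {
  df <- data.frame(taxon = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state_matrix
#' @export
read_state_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- df$taxon
  m
}

#' Run the full comparative degradation pipeline
#'
#' Input modes (combinable): a directory of annotated GenBank plastomes
#' (`plastome_dir` + `reference_taxon`), and/or a precomputed state matrix +
#' tree (`state_matrix`, `tree` paths, or `use_fixture = TRUE` for the
#' packaged study data). Sequence inputs drive partition/IR-type/gene-state/
#' codon statistics; the matrix + tree drive the ancestral reconstructions.
#'
#' @param config list with fields: `out_dir` (required); optional
#'   `plastome_dir`, `reference_taxon`, `gene_list`, `thresholds`,
#'   `state_matrix`, `tree`, `use_fixture`, `schemes` (default all three
#'   binarizations), `summary_tips` (named list of tip sets whose MRCA loss
#'   counts are reported), `seed`.
#' @return invisible list of stage outputs (paths and in-memory results);
#'   the run manifest is written to `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  has_seq <- !is.null(config$plastome_dir)
  has_fixture <- isTRUE(config$use_fixture)
  has_matrix <- has_fixture || !is.null(config$state_matrix)
  if (!has_seq && !has_matrix)
    stop("config must provide plastome_dir and/or a state matrix (or use_fixture)")
  if (has_seq && !dir.exists(config$plastome_dir))
    stop("plastome_dir does not exist: ", config$plastome_dir)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed %||% 1L)
  out <- list()
  manifest <- list(package = "plastdeg",
                   version = as.character(utils::packageVersion("plastdeg")),
                   seed = config$seed %||% 1L,
                   config = config[setdiff(names(config), "summary_tips")],
                   stages = list())
  path_of <- function(f) file.path(config$out_dir, f)
  tsv <- function(df, f) {
    utils::write.table(df, path_of(f), sep = "\t", quote = FALSE, row.names = FALSE)
    path_of(f)
  }

  records <- NULL
  if (has_seq) {
    files <- list.files(config$plastome_dir, pattern = "\\.(gb|gbk|genbank)$",
                        full.names = TRUE)
    if (length(files) == 0) stop("no GenBank files in ", config$plastome_dir)
    records <- unlist(lapply(files, read_genbank), recursive = FALSE)
    manifest$stages$load <- list(n_records = length(records))

    # --- partition + IR typing -------------------------------------------
    region_rows <- list(); ir_rows <- list(); junction_rows <- list()
    partitions <- list()
    for (rec in records) {
      part <- detect_inverted_repeat(rec$sequence)
      partitions[[rec$id]] <- part
      st <- region_stats(rec, part)
      st$sample <- rec$id
      st$start <- c(vapply(c("LSC", "IRb", "SSC", "IRa"),
                           function(r) part$regions[[r]][1], 0L), NA)
      region_rows[[rec$id]] <- st
      ir <- classify_ir_type(rec, part)
      ir_rows[[rec$id]] <- data.frame(sample = rec$id, type = ir$type,
                                      ycf1_overlap_bp = ir$ycf1_overlap_bp)
      jg <- junction_genes(rec, part)
      if (nrow(jg)) { jg$sample <- rec$id; junction_rows[[rec$id]] <- jg }
    }
    out$regions <- do.call(rbind, region_rows)
    out$ir_types <- do.call(rbind, ir_rows)
    tsv(out$regions, "regions.tsv")
    tsv(out$ir_types, "ir_types.tsv")
    if (length(junction_rows)) tsv(do.call(rbind, junction_rows), "junctions.tsv")
    manifest$stages$partition <- list(n = length(partitions))

    # --- gene states ------------------------------------------------------
    ref_id <- config$reference_taxon
    if (!is.null(ref_id)) {
      ref <- records[[which(vapply(records, function(r) r$id, "") == ref_id)]]
      gene_list <- config$gene_list %||% default_gene_list()
      gene_list <- intersect(gene_list,
                             vapply(ref$features, function(f) f$gene, ""))
      out$states <- build_state_matrix(records, ref, gene_list,
                                       thresholds = config$thresholds %||%
                                         list(t_trunc = 0.90, t_full = 0.95))
      write_state_matrix(out$states, path_of("state_matrix.tsv"))
      manifest$stages$gene_states <- list(genes = gene_list)
    }

    # --- codon / GC statistics -------------------------------------------
    cds_of <- function(rec) {
      feats <- Filter(function(f) f$kind == "CDS" && !f$pseudo, rec$features)
      feats <- feats[!duplicated(vapply(feats, function(f) f$gene, ""))]
      s <- vapply(feats, function(f) feature_sequence(rec, f), "")
      stats::setNames(s, vapply(feats, function(f) f$gene, ""))
    }
    rscu_rows <- lapply(records, function(rec) {
      cds <- cds_of(rec)
      cds <- cds[nchar(cds) %% 3 == 0]
      r <- rscu(cds); r$sample <- rec$id; r
    })
    out$rscu <- do.call(rbind, rscu_rows)
    tsv(out$rscu, "rscu.tsv")
    gcm <- gc_group_matrix(records)
    tsv(data.frame(sample = rownames(gcm$gc), gcm$gc, check.names = FALSE),
        "gc_groups.tsv")
    tsv(data.frame(sample = rownames(gcm$deviation), gcm$deviation,
                   check.names = FALSE), "gc_deviation.tsv")

    # --- rank statistics on region characteristics -----------------------
    wide <- stats::reshape(out$regions[, c("sample", "region", "length", "gc")],
                           direction = "wide", idvar = "sample",
                           timevar = "region")
    num <- wide[, setdiff(names(wide), "sample")]
    out$correlations <- correlation_table(num)
    tsv(out$correlations, "correlations.tsv")
  }

  # --- ancestral reconstruction -------------------------------------------
  states <- NULL; tree <- NULL
  if (has_fixture) {
    states <- fixture_table1()$states
    tree <- fixture_tree()
  }
  if (!is.null(config$state_matrix)) states <- read_state_matrix(config$state_matrix)
  if (!is.null(config$tree)) tree <- read_newick(config$tree)
  if (is.null(states) && !is.null(out$states)) states <- out$states
  if (!is.null(states) && !is.null(tree)) {
    states <- states[intersect(rownames(states), tree$tip.label), , drop = FALSE]
    schemes <- config$schemes %||% c("functional", "complete", "existing")
    event_rows <- list()
    dollo_all <- list()
    for (scheme in schemes) {
      bm <- binarize(states, scheme)
      dollo_all[[scheme]] <- list()
      for (gene in colnames(bm)) {
        res <- dollo_reconstruct(tree, bm[, gene])
        dollo_all[[scheme]][[gene]] <- res
        event_rows[[paste(scheme, gene)]] <- data.frame(
          scheme = scheme, gene = gene,
          origin_node = res$origin_node,
          n_reversals = length(res$reversal_nodes),
          n_events = res$n_events)
      }
    }
    out$dollo <- dollo_all
    out$events <- do.call(rbind, event_rows)
    tsv(out$events, "dollo_events.tsv")

    # equal-rates likelihood fits on the binarized characters
    er_rows <- list()
    for (gene in colnames(states)) {
      bm <- binarize(states, "functional")[, gene]
      if (length(unique(bm)) > 1) {
        fit <- fit_mk_er(tree, bm, k = 2)
        er_rows[[gene]] <- data.frame(gene = gene, mu = fit$mu,
                                      loglik = fit$loglik)
      }
    }
    if (length(er_rows)) {
      out$er_fits <- do.call(rbind, er_rows)
      tsv(out$er_fits, "mk_er_fits.tsv")
    }

    # loss counts at selected ancestral nodes
    summary_tips <- config$summary_tips
    if (is.null(summary_tips) && all(.CYATHOPHORA_TAXA %in% tree$tip.label))
      summary_tips <- list(cyathophora_ancestor = .CYATHOPHORA_TAXA)
    if (!is.null(summary_tips)) {
      ndh <- grep("^ndh", colnames(states), value = TRUE)
      summaries <- lapply(summary_tips, function(tips)
        summarize_losses(dollo_all$functional[ndh], tree, tips))
      out$node_summaries <- summaries
      jsonlite::write_json(
        lapply(summaries, function(s) list(node = s$node, n_ndh_lost = s$count,
                                           genes = s$genes)),
        path_of("node_summaries.json"), auto_unbox = TRUE)
    }
    manifest$stages$ancestral <- list(schemes = schemes,
                                      n_genes = ncol(states))
  }

  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, path_of("manifest.json"), auto_unbox = TRUE,
                       null = "null", force = TRUE)
  invisible(out)
}
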