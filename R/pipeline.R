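#' Build a pipeline configuration
#'
#' Collects the input paths and stage parameters of a full family
#' characterization run. Any parameter can also be set in a flat
#' `key = value` text file read by [read_pipeline_config()].
#'
#' @param proteins,pspg_seeds,gff3,msa,counts,library_sizes,references
#'   Input file paths (proteins FASTA, gap-free 44-column seed FASTA,
#'   gene models GFF3, aligned family FASTA, counts TSV, library-size
#'   TSV, reference-label TSV with `id` and `group` columns).
#' @param outdir Output directory for report tables.
#' @param min_score Motif-scan threshold in bits (`NULL` = model
#'   default).
#' @param c_term_window C-terminal search window (residues).
#' @param pseudocount Pseudocount for the seed model.
#' @param tolerance Event-clustering column tolerance.
#' @param min_overlap Minimum pairwise-complete columns for p-distances.
#' @param threshold Detection floor in RPKM.
#' @param distance,linkage Heatmap clustering choices.
#' @param pka_set pKa table for pI computation.
#' @param log_level `"INFO"` or `"DEBUG"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(proteins, pspg_seeds, gff3, msa, counts,
                            library_sizes, references, outdir,
                            min_score = NULL, c_term_window = 150L,
                            pseudocount = 1, tolerance = 0L,
                            min_overlap = 30L, threshold = 1,
                            distance = "correlation", linkage = "average",
                            pka_set = "bjellqvist", log_level = "INFO") {
  cfg <- list(proteins = proteins, pspg_seeds = pspg_seeds, gff3 = gff3,
              msa = msa, counts = counts, library_sizes = library_sizes,
              references = references, outdir = outdir,
              min_score = min_score, c_term_window = c_term_window,
              pseudocount = pseudocount, tolerance = tolerance,
              min_overlap = min_overlap, threshold = threshold,
              distance = distance, linkage = linkage, pka_set = pka_set,
              log_level = log_level)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a key = value file
#'
#' Blank lines and `#` comments are ignored; numeric-looking values are
#' converted.
#'
#' @param path Path to the config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[lines != ""]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "), call. = FALSE)
  vals <- lapply(kv, function(x) {
    v <- x[[2L]]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1L)
  do.call(pipeline_config, vals)
}

pipe_log <- function(cfg, level, ...) {
  levels <- c(DEBUG = 1L, INFO = 2L)
  if (levels[[level]] >= levels[[cfg$log_level %||% "INFO"]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
}

stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full family characterization pipeline
#'
#' Orchestrates identify (motif scan + protein statistics), structure
#' (introns, phases, alignment projection, insertion events), phylo
#' (p-distances, neighbor joining, group assignment) and express (RPKM,
#' Venn partition, clustered z-scores, peak summary), writes every report
#' table to `config$outdir` as TSV (plus the tree as newick and the
#' effective configuration), and returns the in-memory results. Stage
#' failures abort with the failing stage named.
#'
#' @param config A [pipeline_config()] or path to a key = value file.
#' @return Invisibly, a list with `catalog`, `introns`, `events`,
#'   `intron_summary`, `tree`, `assignment`, `rpkm`, `venn`, `clustered`,
#'   `peaks`, `report_tables`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("proteins", "pspg_seeds", "gff3", "msa", "counts",
              "library_sizes", "references")) {
    if (!file.exists(config[[f]])) {
      stop("pipeline stage '", stage_of_input(f), "' failed: input file '",
           config[[f]], "' (", f, ") not found", call. = FALSE)
    }
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  ## -- identify ------------------------------------------------------------
  res <- list()
  stage("identify", {
    pipe_log(config, "INFO", "identify: scanning proteins for the PSPG box")
    proteins <- read_fasta(config$proteins)
    seeds <- read_fasta(config$pspg_seeds)
    model <- build_pspg_model(seeds, pseudocount = config$pseudocount)
    models <- read_gff3(config$gff3)
    chrom_map <- models %>% select("gene_id", "chromosome")
    res$catalog <- identify_family(
      proteins, model, chromosome_map = chrom_map,
      c_term_window = config$c_term_window, min_score = config$min_score,
      pka_set = config$pka_set)
    res$gene_models <- models
    pipe_log(config, "INFO", "identify: ", nrow(res$catalog), " of ",
             nrow(proteins), " proteins carry the motif (window = ",
             config$c_term_window, ")")
  })

  ## -- structure -----------------------------------------------------------
  stage("structure", {
    pipe_log(config, "INFO", "structure: extracting introns")
    msa <- read_fasta(config$msa, aligned = TRUE)
    members <- res$gene_models %>%
      filter(.data$gene_id %in% res$catalog$protein_id)
    introns <- extract_introns(members) %>%
      add_alignment_columns(msa)
    res$events <- cluster_insertion_events(introns,
                                            tolerance = config$tolerance)
    res$introns <- res$events$introns
    res$msa <- msa
    pipe_log(config, "INFO", "structure: ", nrow(res$introns),
             " introns in ", nrow(res$events$events), " events (tolerance = ",
             config$tolerance, ")")
  })

  ## -- phylo ---------------------------------------------------------------
  stage("phylo", {
    pipe_log(config, "INFO", "phylo: neighbor joining on p-distances")
    refs <- readr::read_tsv(config$references, show_col_types = FALSE)
    fam_msa <- res$msa %>% filter(.data$id %in% res$catalog$protein_id)
    d <- p_distance_matrix(fam_msa, min_overlap = config$min_overlap)
    res$tree <- nj_tree(d)
    res$assignment <- assign_groups(res$tree, refs)
    res$catalog <- add_group_labels(res$catalog, res$assignment)
    res$intron_summary <- intron_summary_tables(res$catalog, res$introns,
                                                 res$events)
    pipe_log(config, "INFO", "phylo: ", nrow(fam_msa), " leaves, ",
             length(unique(res$assignment$group)), " groups assigned")
  })

  ## -- express -------------------------------------------------------------
  stage("express", {
    pipe_log(config, "INFO", "express: RPKM, Venn and clustering")
    counts <- read_counts_table(config$counts, config$library_sizes)
    counts <- counts %>% filter(.data$gene_id %in% res$catalog$protein_id)
    res$rpkm <- rpkm_matrix(counts)
    res$venn <- venn_partition(res$rpkm, threshold = config$threshold)
    res$clustered <- zscore_and_cluster(res$rpkm,
                                         distance = config$distance,
                                         linkage = config$linkage)
    res$peaks <- peak_summary(res$rpkm)
    pipe_log(config, "INFO", "express: ", length(unique(res$rpkm$gene_id)),
             " genes profiled at threshold ", config$threshold, " RPKM")
  })

  ## -- report --------------------------------------------------------------
  stage("report", {
    out <- config$outdir
    w <- function(x, f) readr::write_tsv(x, file.path(out, f))
    w(res$catalog, "catalog.tsv")
    w(res$introns, "introns.tsv")
    w(res$events$events, "events.tsv")
    w(res$intron_summary$by_group_count, "intron_summary_by_group.tsv")
    w(res$intron_summary$phase_counts, "phase_totals.tsv")
    w(res$intron_summary$event_membership, "event_membership.tsv")
    write_newick(res$tree, file.path(out, "tree.nwk"))
    w(res$assignment, "group_assignments.tsv")
    w(res$rpkm, "rpkm.tsv")
    w(tidy(res$venn), "venn.tsv")
    zs <- res$clustered$zscores
    zs <- zs[match(res$clustered$leaf_order, zs$gene_id), ]
    w(zs, "zscores.tsv")
    w(res$peaks$genes, "peaks.tsv")
    per_group <- count(res$catalog, .data$group, name = "n_genes")
    per_chrom <- count(res$catalog, .data$chromosome, name = "n_genes")
    w(per_group, "per_group_counts.tsv")
    w(per_chrom, "per_chromosome_counts.tsv")
    w(res$peaks$tissue_counts, "peak_tissue_counts.tsv")
    writeLines(effective_config_lines(config),
               file.path(out, "effective_config.txt"))
    res$report_tables <- c("catalog.tsv", "introns.tsv", "events.tsv",
                            "intron_summary_by_group.tsv", "phase_totals.tsv",
                            "event_membership.tsv", "tree.nwk",
                            "group_assignments.tsv", "rpkm.tsv", "venn.tsv",
                            "zscores.tsv", "peaks.tsv",
                            "per_group_counts.tsv",
                            "per_chromosome_counts.tsv",
                            "peak_tissue_counts.tsv",
                            "effective_config.txt")
    pipe_log(config, "INFO", "report: ", length(res$report_tables),
             " files written to ", out)
  })
  invisible(res)
}

stage_of_input <- function(field) {
  switch(field,
         proteins = "identify", pspg_seeds = "identify",
         gff3 = "structure", msa = "structure",
         references = "phylo",
         counts = "express", library_sizes = "express",
         "identify")
}

effective_config_lines <- function(cfg) {
  flat <- cfg[!vapply(cfg, is.null, logical(1))]
  vapply(names(flat), function(k) paste0(k, " = ", flat[[k]]),
         character(1))
}
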