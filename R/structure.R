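#' Map a coding-nucleotide offset to intron phase and protein residue
#'
#' `cds_offset` counts coding nucleotides 5' of a splice site in the
#' mRNA. Phase 0 introns fall between two codons, phase 1 after the first
#' base of a codon, phase 2 after the second. The reported residue is the
#' one whose codon contains the splice (phases 1-2) or immediately
#' precedes it (phase 0).
#'
#' @param cds_offset Positive integer vector of coding-nucleotide offsets.
#' @return A tibble with columns `cds_offset`, `phase`, `residue`.
#' @export
map_intron_to_protein <- function(cds_offset) {
  if (length(cds_offset) == 0L) {
    return(tibble(cds_offset = integer(), phase = integer(),
                  residue = integer()))
  }
  if (any(is.na(cds_offset)) || any(cds_offset < 1) ||
      any(cds_offset != round(cds_offset))) {
    stop("cds_offset must be a positive integer", call. = FALSE)
  }
  cds_offset <- as.integer(cds_offset)
  phase <- cds_offset %% 3L
  residue <- ifelse(phase == 0L, cds_offset %/% 3L,
                    cds_offset %/% 3L + 1L)
  tibble(cds_offset = cds_offset, phase = phase,
         residue = as.integer(residue))
}

#' Extract introns from gene models
#'
#' Introns are the gaps between consecutive CDS segments, numbered 5' to
#' 3' in transcript orientation (the segment list is walked right-to-left
#' on the minus strand). Genomic bounds stay in genome orientation;
#' `cds_offset`, phase and residue are transcript-relative.
#'
#' @param models Nested gene-model tibble from [read_gff3()].
#' @return A tibble with columns `gene_id`, `intron_index`,
#'   `genomic_start`, `genomic_end`, `cds_offset`, `phase`, `residue`.
#' @export
extract_introns <- function(models) {
  rows <- purrr::pmap(models[c("gene_id", "strand", "cds")],
                      function(gene_id, strand, cds) {
    segs <- arrange(cds, .data$start)
    k <- nrow(segs)
    if (k < 2L) return(NULL)
    gap_start <- segs$end[-k] + 1L
    gap_end <- segs$start[-1L] - 1L
    if (any(gap_end < gap_start)) {
      stop("touching CDS segments (zero-length intron) in gene '",
           gene_id, "'", call. = FALSE)
    }
    seg_len <- segs$end - segs$start + 1L
    if (strand == "-") {
      ## transcript runs right-to-left: intron i in transcript order is
      ## genomic gap k-i; coding offset accumulates from the right
      tx_order <- rev(seq_len(k - 1L))
      offsets <- cumsum(rev(seg_len))[seq_len(k - 1L)]
      gap_start <- gap_start[tx_order]
      gap_end <- gap_end[tx_order]
    } else {
      offsets <- cumsum(seg_len)[seq_len(k - 1L)]
    }
    mapped <- map_intron_to_protein(offsets)
    tibble(gene_id = gene_id, intron_index = seq_len(k - 1L),
           genomic_start = as.integer(gap_start),
           genomic_end = as.integer(gap_end),
           cds_offset = mapped$cds_offset, phase = mapped$phase,
           residue = mapped$residue)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(gene_id = character(), intron_index = integer(),
                  genomic_start = integer(), genomic_end = integer(),
                  cds_offset = integer(), phase = integer(),
                  residue = integer())
  }
  out
}

#' Project a protein residue onto its alignment column
#'
#' @param aligned_seq A single gapped sequence (gaps are `-`).
#' @param residue 1-based residue indices (vectorized).
#' @return Integer vector of 1-based alignment columns.
#' @export
project_to_alignment <- function(aligned_seq, residue) {
  stopifnot(length(aligned_seq) == 1L)
  chars <- strsplit(aligned_seq, "")[[1]]
  cols <- which(chars != "-")
  if (any(residue < 1) || any(residue != round(residue))) {
    stop("residue indices must be positive integers", call. = FALSE)
  }
  if (any(residue > length(cols))) {
    stop("residue index exceeds ungapped length (", length(cols), ")",
         call. = FALSE)
  }
  cols[residue]
}

#' Attach alignment columns to intron records
#'
#' Looks up each gene's row of the family alignment and projects every
#' intron's residue to its 1-based alignment column.
#'
#' @param introns Intron tibble from [extract_introns()].
#' @param msa Aligned sequences (tibble with `id`, `residues`) covering
#'   every gene in `introns`.
#' @return `introns` with an added integer `column`.
#' @export
add_alignment_columns <- function(introns, msa) {
  missing <- setdiff(unique(introns$gene_id), msa$id)
  if (length(missing) > 0L) {
    stop("gene(s) absent from the alignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  aligned <- setNames(msa$residues, msa$id)
  introns %>%
    group_by(.data$gene_id) %>%
    mutate(column = project_to_alignment(aligned[[first(.data$gene_id)]],
                                         .data$residue)) %>%
    ungroup()
}

#' Cluster introns into homologous insertion events
#'
#' Two introns belong to the same insertion event when they map to
#' alignment columns at most `tolerance` apart AND share the same phase
#' (single linkage within that rule); a phase change implies an
#' independent insertion. Events are ordered by their median alignment
#' column and labeled `I-1`, `I-2`, ... One gene never contributes two
#' introns to the same event: chains that would, are split greedily in
#' column order.
#'
#' @param introns Intron tibble with `column` and `phase` (see
#'   [add_alignment_columns()]).
#' @param tolerance Maximum column difference within an event.
#' @return An object of class `insertion_events`: a list with `events`
#'   (tibble `event_id`, `column`, `phase`, `n_members`) and `introns`
#'   (the input with an `event_id` column).
#' @export
cluster_insertion_events <- function(introns, tolerance = 0L) {
  stopifnot(tolerance >= 0)
  if (nrow(introns) == 0L) {
    out <- list(events = tibble(event_id = character(), column = numeric(),
                                phase = integer(), n_members = integer()),
                introns = mutate(introns, event_id = character(0)))
    class(out) <- "insertion_events"
    return(out)
  }
  stopifnot(all(c("column", "phase", "gene_id") %in% names(introns)))
  recs <- introns %>%
    mutate(.row = row_number()) %>%
    arrange(.data$phase, .data$column, .data$gene_id, .data$intron_index)
  ## single-linkage chains within phase, then split same-gene collisions
  cluster <- integer(nrow(recs))
  cl <- 0L
  genes_in_cl <- character(0)
  for (i in seq_len(nrow(recs))) {
    new_chain <- i == 1L ||
      recs$phase[i] != recs$phase[i - 1L] ||
      (recs$column[i] - recs$column[i - 1L]) > tolerance
    if (new_chain || recs$gene_id[i] %in% genes_in_cl) {
      cl <- cl + 1L
      genes_in_cl <- character(0)
    }
    cluster[i] <- cl
    genes_in_cl <- c(genes_in_cl, recs$gene_id[i])
  }
  recs$.cluster <- cluster
  events <- recs %>%
    group_by(.data$.cluster) %>%
    summarise(column = median(.data$column), phase = first(.data$phase),
              n_members = n(), .groups = "drop") %>%
    arrange(.data$column, .data$phase) %>%
    mutate(event_id = paste0("I-", row_number()))
  recs <- recs %>%
    left_join(select(events, ".cluster", "event_id"), by = ".cluster") %>%
    arrange(.data$.row) %>%
    select(-".cluster", -".row")
  out <- list(
    events = select(events, "event_id", "column", "phase", "n_members"),
    introns = recs
  )
  class(out) <- "insertion_events"
  out
}

#' @export
print.insertion_events <- function(x, ...) {
  cat("insertion events:", nrow(x$events), "events over",
      nrow(x$introns), "introns\n")
  print(x$events, ...)
  invisible(x)
}

#' @method tidy insertion_events
#' @export
tidy.insertion_events <- function(x, ...) x$introns

#' @method glance insertion_events
#' @export
glance.insertion_events <- function(x, ...) {
  tibble(n_events = nrow(x$events), n_introns = nrow(x$introns))
}

#' Summarise intron content of a family catalog
#'
#' Builds the group-by-intron-count table (intron-count classes are the
#' observed distinct counts), phase totals, and per-event group
#' membership counts.
#'
#' @param catalog A `family_catalog` with `group` filled in.
#' @param introns Intron tibble (any gene absent from the catalog is an
#'   error).
#' @param events Optional `insertion_events` object for the per-event
#'   membership table.
#' @return A list of class `intron_summary` with elements
#'   `by_group_count` (wide tibble with a `total` column),
#'   `phase_counts`, `event_membership` (or `NULL`), `total_genes`,
#'   `total_introns`.
#' @export
intron_summary_tables <- function(catalog, introns, events = NULL) {
  stray <- setdiff(unique(introns$gene_id), catalog$protein_id)
  if (length(stray) > 0L) {
    stop("intron record(s) for gene(s) not in the catalog: ",
         paste(stray, collapse = ", "), call. = FALSE)
  }
  per_gene <- catalog %>%
    select("protein_id", "group") %>%
    left_join(count(introns, .data$gene_id, name = "n_introns"),
              by = c(protein_id = "gene_id")) %>%
    mutate(n_introns = dplyr::coalesce(.data$n_introns, 0L),
           group = dplyr::coalesce(.data$group, "unassigned"))
  classes <- sort(unique(per_gene$n_introns))
  by_group <- per_gene %>%
    count(.data$group, .data$n_introns) %>%
    tidyr::pivot_wider(names_from = "n_introns", values_from = "n",
                       values_fill = 0L) %>%
    arrange(.data$group) %>%
    select("group", all_of(as.character(classes)))   # numeric class order
  by_group$total <- rowSums(by_group[as.character(classes)])
  phase_counts <- introns %>%
    count(.data$phase, name = "n_introns") %>%
    tidyr::complete(phase = 0:2, fill = list(n_introns = 0L))
  event_membership <- NULL
  if (!is.null(events)) {
    event_membership <- events$introns %>%
      left_join(select(catalog, "protein_id", "group"),
                by = c(gene_id = "protein_id")) %>%
      count(.data$event_id, .data$group, name = "n_introns")
  }
  out <- list(
    by_group_count = by_group,
    phase_counts = phase_counts,
    event_membership = event_membership,
    total_genes = nrow(per_gene),
    total_introns = nrow(introns)
  )
  class(out) <- "intron_summary"
  out
}

#' @export
print.intron_summary <- function(x, ...) {
  cat("intron summary:", x$total_genes, "genes,", x$total_introns,
      "introns\n")
  print(x$by_group_count, ...)
  invisible(x)
}

#' The published pomelo UGT group-by-intron-count distribution
#'
#' Genes per phylogenetic group (A-P) and intron-count class for the
#' pomelo (*Citrus grandis*) UDP-glycosyltransferase family, shipped as
#' plain text with the package.
#'
#' @return A tibble with a `group` column and `introns_<k>` class
#'   columns.
#' @export
ugt_intron_distribution <- function() {
  path <- system.file("extdata", "ugt_group_intron_distribution.tsv",
                      package = "famscan", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Marginal totals of a published group-by-intron-count distribution
#'
#' Takes a distribution table with a `group` column and per-class columns
#' named `introns_<k>` (genes in that group carrying `k` introns) and
#' recomputes its marginals: genes per group, genes per intron-count
#' class, intron-bearing and intron-less gene counts, and the total
#' intron count (sum of class times genes).
#'
#' @param dist_tbl The distribution tibble.
#' @return A list with `group_totals`, `class_totals`, `total_genes`,
#'   `intronless_genes`, `intron_bearing_genes`, `total_introns`.
#' @export
summarize_intron_distribution <- function(dist_tbl) {
  stopifnot("group" %in% names(dist_tbl))
  class_cols <- grep("^introns_\\d+$", names(dist_tbl), value = TRUE)
  if (length(class_cols) == 0L) {
    stop("no 'introns_<k>' class columns found", call. = FALSE)
  }
  k <- as.integer(sub("^introns_", "", class_cols))
  counts <- as.matrix(dist_tbl[class_cols])
  group_totals <- tibble(group = dist_tbl$group,
                         n_genes = unname(rowSums(counts)))
  class_totals <- tibble(n_introns = k, n_genes = unname(colSums(counts)))
  list(
    group_totals = group_totals,
    class_totals = class_totals,
    total_genes = sum(counts),
    intronless_genes = sum(class_totals$n_genes[class_totals$n_introns == 0L]),
    intron_bearing_genes = sum(class_totals$n_genes[class_totals$n_introns > 0L]),
    total_introns = sum(class_totals$n_introns * class_totals$n_genes)
  )
}
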