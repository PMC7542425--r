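## Canonical sample ordering: tissues in TISSUE_LEVELS order, stages in
## STAGE_LEVELS order within tissue; unknown labels go last, alphabetically.
order_samples <- function(tissue, stage) {
  t_rank <- match(tissue, TISSUE_LEVELS)
  s_rank <- match(stage, STAGE_LEVELS)
  order(ifelse(is.na(t_rank), length(TISSUE_LEVELS) + 1L, t_rank),
        tissue, ifelse(is.na(s_rank), length(STAGE_LEVELS) + 1L, s_rank),
        stage)
}

#' Convert a count table to RPKM
#'
#' `rpkm = count * 1e9 / (gene_length_bp * library_size)` — reads per
#' kilobase of coding sequence per million mapped reads.
#'
#' @param counts A `count_table` tibble (see [read_counts_table()]).
#' @return A tibble with columns `gene_id`, `sample_id`, `tissue`,
#'   `stage`, `rpkm`.
#' @export
rpkm_matrix <- function(counts) {
  validate_count_table(counts)
  counts %>%
    mutate(rpkm = .data$count * 1e9 /
             (.data$gene_length * .data$library_size)) %>%
    select("gene_id", "sample_id", "tissue", "stage", "rpkm") %>%
    as_tibble()
}

#' Partition genes by the set of tissues in which they are detected
#'
#' A gene is detected in a tissue when its maximum RPKM over that
#' tissue's stages reaches `threshold`. Every gene falls in exactly one
#' of the 15 non-empty tissue subsets or the `none` (undetected) class,
#' so region counts always sum to the gene count.
#'
#' @param expr RPKM tibble from [rpkm_matrix()].
#' @param threshold Detection floor in RPKM units.
#' @param tissues The tissues defining the partition (all must be
#'   present in `expr`).
#' @return An object of class `venn_partition`: a tibble with `region`
#'   (tissue names joined by `+`, or `"none"`), `n_genes` and a
#'   `gene_ids` list-column, covering all 16 classes.
#' @export
venn_partition <- function(expr, threshold = 1,
                           tissues = TISSUE_LEVELS) {
  missing <- setdiff(tissues, unique(expr$tissue))
  if (length(missing) > 0L) {
    stop("tissue(s) missing from expression data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  detected <- expr %>%
    filter(.data$tissue %in% tissues) %>%
    group_by(.data$gene_id, .data$tissue) %>%
    summarise(detected = max(.data$rpkm) >= threshold, .groups = "drop")
  regions <- detected %>%
    filter(.data$detected) %>%
    mutate(tissue = factor(.data$tissue, levels = tissues)) %>%
    arrange(.data$tissue) %>%
    group_by(.data$gene_id) %>%
    summarise(region = paste(.data$tissue, collapse = "+"),
              .groups = "drop")
  per_gene <- tibble(gene_id = unique(expr$gene_id)) %>%
    left_join(regions, by = "gene_id") %>%
    mutate(region = dplyr::coalesce(.data$region, "none"))
  ## enumerate all 15 subsets in canonical order, plus "none"
  subsets <- unlist(purrr::map(seq_along(tissues), function(k) {
    utils::combn(tissues, k, FUN = paste, collapse = "+", simplify = FALSE)
  }))
  all_regions <- c(unlist(subsets), "none")
  out <- tibble(region = all_regions) %>%
    left_join(per_gene %>%
                group_by(.data$region) %>%
                summarise(n_genes = n(),
                          gene_ids = list(sort(.data$gene_id)),
                          .groups = "drop"),
              by = "region") %>%
    mutate(n_genes = dplyr::coalesce(.data$n_genes, 0L),
           gene_ids = purrr::map(.data$gene_ids,
                                 function(g) g %||% character(0)))
  attr(out, "threshold") <- threshold
  attr(out, "tissues") <- tissues
  class(out) <- c("venn_partition", class(out))
  out
}

#' @method tidy venn_partition
#' @export
tidy.venn_partition <- function(x, ...) {
  tibble(region = x$region, n_genes = x$n_genes)
}

#' Z-score expression rows and cluster genes hierarchically
#'
#' Each gene's RPKM profile is standardized to mean 0, unit (n-1)
#' standard deviation; constant profiles become all-zero rows. Genes are
#' clustered by average linkage on 1 - Pearson correlation (or Euclidean
#' distance on the z-scores). The reported leaf order comes from a
#' deterministic dendrogram traversal: at every merge, the subtree
#' containing the earlier input row comes first. The `[-2, 2]` display
#' clip is metadata for plotting; stored z-scores are never clipped.
#'
#' @param expr RPKM tibble from [rpkm_matrix()].
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An object of class `clustered_matrix`: list with `zscores`
#'   (wide tibble, genes x samples), `leaf_order` (character),
#'   `hclust`, `samples`, `display_clip`.
#' @export
zscore_and_cluster <- function(expr, distance = c("correlation", "euclidean"),
                               linkage = "average") {
  distance <- match.arg(distance)
  samp <- expr %>% distinct(.data$sample_id, .data$tissue, .data$stage)
  samp <- samp[order_samples(samp$tissue, samp$stage), ]
  if (nrow(samp) < 2L) stop("need at least two samples", call. = FALSE)
  wide <- expr %>%
    select("gene_id", "sample_id", "rpkm") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "rpkm") %>%
    select("gene_id", all_of(samp$sample_id))
  if (nrow(wide) < 2L) stop("need at least two genes", call. = FALSE)
  m <- as.matrix(wide[-1L])
  rownames(m) <- wide$gene_id
  mu <- rowMeans(m)
  sdev <- apply(m, 1L, sd)
  z <- (m - mu) / ifelse(sdev == 0, 1, sdev)
  z[sdev == 0, ] <- 0
  constant <- sdev == 0
  if (distance == "correlation") {
    dm <- matrix(1, nrow(z), nrow(z))
    nc <- !constant
    if (sum(nc) >= 2L) dm[nc, nc] <- 1 - cor(t(z[nc, , drop = FALSE]))
    dm[constant, constant] <- 0    # identical flat profiles
    diag(dm) <- 0
    dd <- as.dist(dm)
  } else {
    dd <- stats::dist(z)
  }
  hc <- hclust(dd, method = linkage)
  leaf_order <- rownames(z)[deterministic_leaf_order(hc$merge)]
  out <- list(
    zscores = bind_cols(tibble(gene_id = rownames(z)), as_tibble(z)),
    leaf_order = leaf_order,
    hclust = hc,
    samples = samp,
    display_clip = c(-2, 2)
  )
  class(out) <- "clustered_matrix"
  out
}

## Traverse an hclust merge matrix putting, at every internal node, the
## child subtree containing the smallest original row index first.
deterministic_leaf_order <- function(merge) {
  leaves <- function(node) {
    if (node < 0) return(-node)
    kids <- merge[node, ]
    a <- leaves(kids[1L]); b <- leaves(kids[2L])
    if (min(a) <= min(b)) c(a, b) else c(b, a)
  }
  leaves(nrow(merge))
}

#' @export
print.clustered_matrix <- function(x, ...) {
  cat("clustered expression matrix:", nrow(x$zscores), "genes x",
      nrow(x$samples), "samples\n")
  cat("leaf order starts:", paste(head(x$leaf_order, 5L), collapse = ", "),
      "...\n")
  invisible(x)
}

#' @method tidy clustered_matrix
#' @export
tidy.clustered_matrix <- function(x, ...) {
  x$zscores %>%
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "z") %>%
    left_join(x$samples, by = "sample_id")
}

#' Peak sample per gene and aggregate peak counts
#'
#' Reports each gene's maximum-RPKM sample; ties are resolved by the
#' canonical sample order (flavedo < albedo < SM < JS, then stage
#' 80 < 140 < 200 DAB). All-zero genes form a separate `no_peak` class
#' excluded from the aggregates.
#'
#' @param expr RPKM tibble from [rpkm_matrix()].
#' @return An object of class `peak_summary`: list with `genes` (per-gene
#'   peak tibble), `tissue_counts`, `stage_counts` (stage within peak
#'   tissue).
#' @export
peak_summary <- function(expr) {
  samp <- expr %>% distinct(.data$sample_id, .data$tissue, .data$stage)
  samp <- samp[order_samples(samp$tissue, samp$stage), ]
  rank <- setNames(seq_len(nrow(samp)), samp$sample_id)
  genes <- expr %>%
    mutate(.rank = rank[.data$sample_id]) %>%
    group_by(.data$gene_id) %>%
    arrange(.data$.rank, .by_group = TRUE) %>%
    summarise(no_peak = all(.data$rpkm == 0),
              peak_idx = which.max(.data$rpkm),
              peak_tissue = .data$tissue[peak_idx],
              peak_stage = .data$stage[peak_idx],
              peak_rpkm = .data$rpkm[peak_idx],
              .groups = "drop") %>%
    mutate(peak_tissue = if_else(.data$no_peak, NA_character_,
                                 .data$peak_tissue),
           peak_stage = if_else(.data$no_peak, NA_character_,
                                .data$peak_stage)) %>%
    select(-"peak_idx")
  with_peak <- filter(genes, !.data$no_peak)
  out <- list(
    genes = genes,
    tissue_counts = count(with_peak, tissue = .data$peak_tissue,
                          name = "n_genes"),
    stage_counts = count(with_peak, tissue = .data$peak_tissue,
                         stage = .data$peak_stage, name = "n_genes")
  )
  class(out) <- "peak_summary"
  out
}

#' @export
print.peak_summary <- function(x, ...) {
  cat("peak expression summary over", nrow(x$genes), "genes\n")
  print(x$tissue_counts, ...)
  invisible(x)
}

#' @method tidy peak_summary
#' @export
tidy.peak_summary <- function(x, ...) x$genes
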