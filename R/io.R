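#' Read sequences from a FASTA file
#'
#' Parses plain or aligned FASTA into a tibble with one row per record.
#' Residues are uppercased. In aligned mode the `-` gap character is kept;
#' `.` is rejected so that only one gap dialect circulates downstream.
#'
#' @param path Path to a FASTA file.
#' @param aligned Logical; if `TRUE` the file is an alignment and `-` gap
#'   characters are preserved. In plain mode any gap character is an error.
#' @return A tibble with columns `id`, `description`, `residues`.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  residues <- toupper(as.character(set))
  if (any(residues == "")) {
    stop("empty sequence for id(s): ",
         paste(ids[residues == ""], collapse = ", "), call. = FALSE)
  }
  if (any(grepl("\\.", residues))) {
    stop("'.' gap characters are not supported; use '-' gaps", call. = FALSE)
  }
  if (!aligned && any(grepl("-", residues, fixed = TRUE))) {
    stop("gap characters found; read with aligned = TRUE if this is an alignment",
         call. = FALSE)
  }
  tibble(id = unname(ids), description = unname(desc),
         residues = unname(residues))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) seqs$description else
    rep("", nrow(seqs))
  header <- ifelse(desc == "" | is.na(desc), paste0(">", seqs$id),
                   paste0(">", seqs$id, " ", desc))
  wrap <- function(s) {
    starts <- seq(1L, nchar(s), by = width)
    substring(s, starts, pmin(starts + width - 1L, nchar(s)))
  }
  lines <- unlist(purrr::map2(header, seqs$residues,
                              function(h, s) c(h, wrap(s))))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Extracts CDS features, grouped per parent gene, as nested gene models.
#' All coordinates are GFF3 convention: 1-based, inclusive. Non-CDS
#' features are ignored; strand is recorded but transcript orientation is
#' applied only when introns are extracted.
#'
#' @param path Path to a GFF3 file with CDS features carrying `Parent`
#'   (or `ID`) attributes.
#' @return A tibble with columns `gene_id`, `chromosome`, `strand` and a
#'   list-column `cds` of tibbles `(start, end)` sorted by start.
#' @export
read_gff3 <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(cds) == 0L) {
    stop("no CDS features found in '", path, "'", call. = FALSE)
  }
  parents <- cds$Parent
  parent_chr <- vapply(seq_along(cds), function(i) {
    p <- parents[[i]]
    if (length(p) >= 1L) as.character(p[[1]]) else NA_character_
  }, character(1))
  if (anyNA(parent_chr)) {
    stop("CDS feature without a Parent attribute at row(s): ",
         paste(which(is.na(parent_chr)), collapse = ", "), call. = FALSE)
  }
  df <- tibble(
    gene_id = parent_chr,
    chromosome = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(BiocGenerics::strand(cds)),
    start = BiocGenerics::start(cds),
    end = BiocGenerics::end(cds)
  )
  models <- df %>%
    group_by(.data$gene_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    tidyr::nest(cds = c("start", "end")) %>%
    ungroup()
  ## one chromosome/strand per gene; validate and flag overlapping segments
  purrr::pwalk(models, function(gene_id, chromosome, strand, cds) {
    if (length(unique(chromosome)) > 1L || length(unique(strand)) > 1L) {
      stop("gene '", gene_id, "' has CDS on multiple chromosomes or strands",
           call. = FALSE)
    }
    if (nrow(cds) > 1L && any(cds$start[-1L] <= cds$end[-nrow(cds)])) {
      stop("overlapping CDS segments within gene '", gene_id, "'",
           call. = FALSE)
    }
    if (any(cds$end < cds$start)) {
      stop("CDS segment with end < start in gene '", gene_id, "'",
           call. = FALSE)
    }
  })
  models
}

#' Write gene models to a GFF3 file
#'
#' Emits one `gene` feature and its `CDS` children per gene model, in the
#' same nested-tibble shape [read_gff3()] returns.
#'
#' @param models Nested gene-model tibble (`gene_id`, `chromosome`,
#'   `strand`, `cds` list-column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(models))) {
    g <- models$gene_id[i]
    chr <- models$chromosome[i]
    strand <- models$strand[i]
    segs <- models$cds[[i]]
    lines <- c(lines,
      sprintf("%s\tfamscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              chr, min(segs$start), max(segs$end), strand, g),
      sprintf("%s\tfamscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
              chr, segs$start, segs$end, strand, g, seq_len(nrow(segs)), g))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a count table with gene lengths and library sizes
#'
#' The counts file is a TSV with columns `gene_id`, `length` (coding
#' length in bp) and one column per sample named `<tissue>_<stage>`
#' (e.g. `flavedo_80`). Library sizes (total mapped reads per sample) come
#' from a two-column sidecar TSV (`sample_id`, `library_size`).
#'
#' @param counts_path Path to the counts TSV.
#' @param library_sizes_path Path to the library-size TSV.
#' @return A long tibble of class `count_table` with columns `gene_id`,
#'   `sample_id`, `tissue`, `stage`, `count`, `gene_length`,
#'   `library_size`.
#' @export
read_counts_table <- function(counts_path, library_sizes_path) {
  wide <- readr::read_tsv(counts_path, show_col_types = FALSE,
                          na = character())
  libs <- readr::read_tsv(library_sizes_path, show_col_types = FALSE,
                          na = character())
  if (!all(c("gene_id", "length") %in% names(wide))) {
    stop("counts TSV must have 'gene_id' and 'length' columns", call. = FALSE)
  }
  sample_cols <- setdiff(names(wide), c("gene_id", "length"))
  if (length(sample_cols) == 0L) stop("counts TSV has no sample columns",
                                      call. = FALSE)
  if (!setequal(sample_cols, libs$sample_id)) {
    stop("sample columns and library-size sample_ids do not match",
         call. = FALSE)
  }
  long <- wide %>%
    tidyr::pivot_longer(all_of(sample_cols), names_to = "sample_id",
                        values_to = "count") %>%
    rename(gene_length = "length") %>%
    left_join(libs, by = "sample_id") %>%
    mutate(tissue = sub("_[^_]+$", "", .data$sample_id),
           stage = sub("^.*_", "", .data$sample_id)) %>%
    select("gene_id", "sample_id", "tissue", "stage", "count",
           "gene_length", "library_size")
  validate_count_table(long)
  class(long) <- c("count_table", class(long))
  long
}

validate_count_table <- function(x) {
  if (!is.numeric(x$count) || any(is.na(x$count)) || any(x$count < 0) ||
      any(x$count != round(x$count))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (!is.numeric(x$gene_length) || any(is.na(x$gene_length)) ||
      any(x$gene_length <= 0)) {
    stop("every gene needs a strictly positive numeric length",
         call. = FALSE)
  }
  if (!is.numeric(x$library_size) || any(is.na(x$library_size)) ||
      any(x$library_size <= 0)) {
    stop("library sizes must be strictly positive", call. = FALSE)
  }
  invisible(x)
}

#' Write a count table (and its library-size sidecar) to TSV
#'
#' @param counts A `count_table` tibble (see [read_counts_table()]).
#' @param counts_path,library_sizes_path Output paths.
#' @return `counts_path`, invisibly.
#' @export
write_counts_table <- function(counts, counts_path, library_sizes_path) {
  wide <- counts %>%
    select("gene_id", length = "gene_length", "sample_id", "count") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count")
  readr::write_tsv(wide, counts_path)
  libs <- counts %>% distinct(.data$sample_id, .data$library_size)
  readr::write_tsv(libs, library_sizes_path)
  invisible(counts_path)
}

#' Serialize a phylogenetic tree to newick
#'
#' @param tree An `ape::phylo` tree with labeled leaves and non-negative
#'   branch lengths.
#' @param path Optional output path; when `NULL` the newick string is
#'   returned.
#' @return The newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(tree$tip.label == "")) {
    stop("all leaves must carry a non-empty label", call. = FALSE)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths are not serializable here", call. = FALSE)
  }
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a newick tree
#'
#' @param x A path to a newick file, or a newick string.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(x) {
  tr <- if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
  if (is.null(tr)) stop("could not parse newick input", call. = FALSE)
  tr
}
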