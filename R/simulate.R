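## A PSPG-like 44-residue consensus used as the simulator's default motif;
## the hallmark HCGWNS core sits mid-motif as in real plant UGTs.
PSPG_CONSENSUS <- "WAPQVEVLAHPAVGCFVTHCGWNSTLESLSLGVPMVAMPQWTDQ"

## Fixed codon per amino acid for back-translation; intron phases depend
## only on codon boundaries, so one deterministic codon per residue is
## sufficient.
CODON_TABLE <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTT", M = "ATG", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
  W = "TGG", Y = "TAT"
)

#' Default planted insertion-event table
#'
#' Ten events at distinct root-protein positions. Phases follow the
#' pattern seen in plant UGT families: predominantly phase 1, a few
#' phase 0, one phase 2. One event (the sixth by position) is carried by
#' most groups and plays the role of the family's deeply conserved
#' intron.
#'
#' @param n_groups Number of groups in the simulated family.
#' @return Tibble with `root_pos`, `phase`, `carrier_groups`
#'   (list-column of group indices), `fraction`.
#' @export
default_event_spec <- function(n_groups = 16L) {
  g <- function(idx) list(idx[idx <= n_groups])
  tibble(
    root_pos = c(40L, 80L, 120L, 160L, 200L, 240L, 280L, 320L, 350L, 380L),
    phase = c(1L, 1L, 0L, 0L, 1L, 1L, 1L, 2L, 0L, 1L),
    carrier_groups = c(g(1:3), g(2:5), g(4:6), g(7:9), g(10:12),
                       g(4:16), g(8:10), g(11:13), g(13:16), g(14:16)),
    fraction = c(0.6, 0.6, 0.7, 0.6, 0.6, 0.8, 0.5, 0.5, 0.6, 0.7)
  )
}

#' Build a simulation configuration
#'
#' Defaults describe a plant UGT-like multigene family: 16 phylogenetic
#' groups of 5-10 genes each (about 120 genes), a 459-residue root
#' protein carrying the 44-residue PSPG consensus 31 residues before the
#' C-terminus, strong between-group and mild within-group divergence
#' with a conserved motif (reduced substitution rate inside it), ten
#' planted intron insertion events, nine chromosomes plus a small
#' unplaced (`chrUn`) fraction, and a 4-tissue x 3-stage expression
#' design with mostly ubiquitous genes, a flavedo-biased peak-tissue
#' distribution and negative-binomial counts.
#'
#' @param seed Integer seed; the simulation is deterministic given it.
#' @param n_groups,genes_per_group Family layout (`genes_per_group` is an
#'   inclusive range).
#' @param root_length,motif_consensus,motif_offset_from_cterm Root
#'   protein geometry.
#' @param between_group_divergence,within_group_divergence Expected
#'   substitutions per site on group-ancestor and gene branches.
#' @param motif_rate_factor Multiplier on the substitution rate inside
#'   the motif (conserved motif).
#' @param group_indel_mean,gene_indel_mean,mean_indel_length Poisson
#'   means for indel counts per branch and the mean indel length.
#' @param event_spec Planted insertion events (see
#'   [default_event_spec()]).
#' @param n_chromosomes,chrun_fraction,intergenic_range,intron_length_range
#'   Genome layout.
#' @param expression Expression-design parameters (class fractions,
#'   peak-tissue probabilities, negative-binomial dispersion, library
#'   sizes, RPKM scales).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_groups = 16L,
                              genes_per_group = c(5L, 10L),
                              root_length = 459L,
                              motif_consensus = PSPG_CONSENSUS,
                              motif_offset_from_cterm = 31L,
                              between_group_divergence = 0.35,
                              within_group_divergence = 0.05,
                              motif_rate_factor = 0.05,
                              group_indel_mean = 1.5,
                              gene_indel_mean = 0.4,
                              mean_indel_length = 3,
                              event_spec = default_event_spec(n_groups),
                              n_chromosomes = 9L,
                              chrun_fraction = 0.04,
                              intergenic_range = c(500L, 2000L),
                              intron_length_range = c(80L, 400L),
                              expression = list()) {
  stopifnot(n_groups >= 1L, length(genes_per_group) == 2L,
            between_group_divergence > 0, between_group_divergence < 1,
            within_group_divergence > 0, within_group_divergence < 1,
            nchar(motif_consensus) == PSPG_LENGTH)
  if (any(event_spec$root_pos > root_length)) {
    stop("event root_pos beyond the root protein length", call. = FALSE)
  }
  expr_defaults <- list(
    tissue_specific = 0.12, silent = 0.04,
    specific_tissue_probs = setNames(rep(0.25, 4), TISSUE_LEVELS),
    peak_tissue_probs = setNames(c(0.49, 0.17, 0.17, 0.17), TISSUE_LEVELS),
    flavedo_stage_probs = setNames(c(0.41, 0.32, 0.27), STAGE_LEVELS),
    dispersion = 8,
    libsize_range = c(8e6, 1.2e7),
    base_rpkm_meanlog = log(20), base_rpkm_sdlog = 0.8,
    specific_rpkm_meanlog = log(50), specific_rpkm_sdlog = 0.6,
    off_tissue_rpkm = 0.001,
    peak_boost = 3, stage_boost = 2
  )
  expr <- utils::modifyList(expr_defaults, expression)
  stopifnot(expr$dispersion > 0,
            expr$tissue_specific + expr$silent <= 1)
  cfg <- list(
    seed = as.integer(seed), n_groups = as.integer(n_groups),
    genes_per_group = as.integer(genes_per_group),
    root_length = as.integer(root_length),
    motif_consensus = motif_consensus,
    motif_offset_from_cterm = as.integer(motif_offset_from_cterm),
    between_group_divergence = between_group_divergence,
    within_group_divergence = within_group_divergence,
    motif_rate_factor = motif_rate_factor,
    group_indel_mean = group_indel_mean,
    gene_indel_mean = gene_indel_mean,
    mean_indel_length = mean_indel_length,
    event_spec = event_spec,
    n_chromosomes = as.integer(n_chromosomes),
    chrun_fraction = chrun_fraction,
    intergenic_range = as.integer(intergenic_range),
    intron_length_range = as.integer(intron_length_range),
    expression = expr
  )
  class(cfg) <- "simulation_config"
  cfg
}

## --- alignment-aware lineage evolution ------------------------------------

## The growing alignment is a named list of equal-length character
## vectors plus col_origin, mapping current columns to root positions
## (NA for inserted columns). Insertions pad every existing row.
aln_new <- function(root_chars) {
  list(rows = list(root = root_chars),
       col_origin = seq_along(root_chars))
}

aln_motif_cols <- function(aln, motif_root_cols) {
  which(aln$col_origin %in% motif_root_cols)
}

aln_insert_gap_block <- function(aln, after, len, row_name, residues) {
  pre <- seq_len(after)
  post <- setdiff(seq_along(aln$col_origin), pre)
  aln$rows <- lapply(aln$rows, function(r) {
    c(r[pre], rep("-", len), r[post])
  })
  aln$rows[[row_name]][after + seq_len(len)] <- residues
  aln$col_origin <- c(aln$col_origin[pre], rep(NA_integer_, len),
                      aln$col_origin[post])
  aln
}

## Derive child from parent: substitutions at non-gap columns (reduced
## rate in the motif), then indels that never touch motif columns.
derive_lineage <- function(aln, parent, child, rate, n_indel_mean, cfg,
                           motif_root_cols) {
  row <- aln$rows[[parent]]
  motif_cols <- aln_motif_cols(aln, motif_root_cols)
  nongap <- which(row != "-")
  p_sub <- 1 - exp(-rate)
  p <- rep(p_sub, length(nongap))
  p[nongap %in% motif_cols] <- 1 - exp(-rate * cfg$motif_rate_factor)
  hit <- nongap[runif(length(nongap)) < p]
  if (length(hit) > 0L) {
    row[hit] <- vapply(row[hit], function(a) {
      sample(setdiff(AMINO_ACIDS, a), 1L)
    }, character(1))
  }
  aln$rows[[child]] <- row
  n_indels <- rpois(1L, n_indel_mean)
  for (k in seq_len(n_indels)) {
    len <- 1L + rpois(1L, max(cfg$mean_indel_length - 1, 0))
    motif_cols <- aln_motif_cols(aln, motif_root_cols)
    if (runif(1) < 0.5) {
      ## deletion: a run of the child's non-gap, non-motif columns
      cand <- setdiff(which(aln$rows[[child]] != "-"), motif_cols)
      cand <- cand[cand > 5L & cand < length(aln$col_origin) - 5L]
      if (length(cand) == 0L) next
      start <- sample(cand, 1L)
      run <- head(cand[cand >= start], len)
      if (length(run) > 0L) aln$rows[[child]][run] <- "-"
    } else {
      ## insertion: new columns outside the motif span
      span <- range(motif_cols)
      cand <- setdiff(5L:(length(aln$col_origin) - 5L),
                      (span[1L]):(span[2L] - 1L))
      if (length(cand) == 0L) next
      after <- sample(cand, 1L)
      aln <- aln_insert_gap_block(aln, after, len, child,
                                  sample(AMINO_ACIDS, len, replace = TRUE))
    }
  }
  aln
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

## --- the family simulator --------------------------------------------------

#' Simulate a multigene family with planted ground truth
#'
#' Evolves group ancestors from a motif-carrying root protein and genes
#' from their group ancestor (substitutions and indels applied in
#' alignment space, so the true MSA exists by construction), assigns
#' planted intron insertion events with fixed phases, back-translates
#' each protein to a CDS, interrupts it at the planted splice sites and
#' places the resulting gene models on chromosomes (both strands, plus a
#' `chrUn` fraction), and assigns each gene an expression class and peak
#' sample. Deterministic for a fixed `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return An object of class `family_simulation`: list with `proteins`,
#'   `msa`, `gene_models`, `genome` (named character vector of
#'   chromosome sequences), `pspg_seeds`, and `truth` (gene table,
#'   intron table, event table, true tree, skipped carriers).
#' @export
simulate_family <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_family_impl(config))
}

simulate_family_impl <- function(cfg) {
  L <- cfg$root_length
  motif_end <- L - cfg$motif_offset_from_cterm
  motif_start <- motif_end - PSPG_LENGTH + 1L
  stopifnot(motif_start > max(cfg$event_spec$root_pos))
  root <- sample(AMINO_ACIDS, L, replace = TRUE)
  root[motif_start:motif_end] <- strsplit(cfg$motif_consensus, "")[[1]]
  motif_root_cols <- motif_start:motif_end

  aln <- aln_new(root)
  groups <- LETTERS[seq_len(cfg$n_groups)]
  for (g in groups) {
    aln <- derive_lineage(aln, "root", paste0("anc_", g),
                          cfg$between_group_divergence,
                          cfg$group_indel_mean, cfg, motif_root_cols)
  }
  sizes <- sample(cfg$genes_per_group[1L]:cfg$genes_per_group[2L],
                  cfg$n_groups, replace = TRUE)
  gene_ids <- character(0)
  gene_group <- character(0)
  for (gi in seq_along(groups)) {
    for (k in seq_len(sizes[gi])) {
      id <- sprintf("g%s%02d", groups[gi], k)
      aln <- derive_lineage(aln, paste0("anc_", groups[gi]), id,
                            cfg$within_group_divergence,
                            cfg$gene_indel_mean, cfg, motif_root_cols)
      gene_ids <- c(gene_ids, id)
      gene_group <- c(gene_group, groups[gi])
    }
  }

  ## final MSA: gene rows only, all-gap columns dropped
  gene_rows <- aln$rows[gene_ids]
  occupied <- Reduce(`|`, lapply(gene_rows, function(r) r != "-"))
  col_origin <- aln$col_origin[occupied]
  gene_rows <- lapply(gene_rows, function(r) r[occupied])
  msa <- tibble(id = gene_ids,
                residues = vapply(gene_rows, paste, character(1),
                                  collapse = ""))
  proteins <- tibble(id = gene_ids,
                     description = paste0("group ", gene_group),
                     residues = gsub("-", "", msa$residues, fixed = TRUE))

  ## planted introns: for each event, each carrier-group gene joins with
  ## probability `fraction`, provided its row has a residue at the
  ## event's column (lost residues are recorded as skipped carriers)
  events_cfg <- cfg$event_spec
  intron_rows <- list()
  skipped <- list()
  event_column <- integer(nrow(events_cfg))
  for (e in seq_len(nrow(events_cfg))) {
    ev <- events_cfg[e, ]
    col <- match(ev$root_pos, col_origin)
    event_column[e] <- col %||% NA_integer_
    carrier_groups <- groups[ev$carrier_groups[[1L]]]
    for (i in seq_along(gene_ids)) {
      if (!(gene_group[i] %in% carrier_groups)) next
      if (runif(1) > ev$fraction) next
      if (is.na(col) || gene_rows[[i]][col] == "-") {
        skipped[[length(skipped) + 1L]] <-
          tibble(gene_id = gene_ids[i], planted_event = e)
        next
      }
      r <- sum(gene_rows[[i]][seq_len(col)] != "-")
      offset <- if (ev$phase == 0L) 3L * r else 3L * (r - 1L) + ev$phase
      intron_rows[[length(intron_rows) + 1L]] <-
        tibble(gene_id = gene_ids[i], planted_event = e,
               cds_offset = offset, phase = ev$phase,
               residue = r, column = col)
    }
  }
  true_introns <- bind_rows(intron_rows)
  if (nrow(true_introns) == 0L) {
    true_introns <- tibble(gene_id = character(), planted_event = integer(),
                           cds_offset = integer(), phase = integer(),
                           residue = integer(), column = integer())
  }
  realized <- sort(unique(true_introns$planted_event))
  ## event ids ordered by alignment column, as the analysis numbers them
  realized <- realized[order(event_column[realized])]
  event_label <- setNames(paste0("I-", seq_along(realized)), realized)
  true_introns$event_id <- unname(event_label[as.character(true_introns$planted_event)])
  true_events <- true_introns %>%
    group_by(.data$event_id) %>%
    summarise(column = first(.data$column), phase = first(.data$phase),
              n_members = n(), .groups = "drop") %>%
    arrange(.data$column)

  ## expression classes and peak samples
  expr <- cfg$expression
  cls_probs <- c(tissue_specific = expr$tissue_specific,
                 silent = expr$silent,
                 ubiquitous = 1 - expr$tissue_specific - expr$silent)
  classes <- sample(names(cls_probs), length(gene_ids), replace = TRUE,
                    prob = cls_probs)
  peak_tissue <- character(length(gene_ids))
  peak_stage <- character(length(gene_ids))
  for (i in seq_along(gene_ids)) {
    if (classes[i] == "silent") {
      peak_tissue[i] <- NA_character_; peak_stage[i] <- NA_character_
    } else if (classes[i] == "tissue_specific") {
      peak_tissue[i] <- sample(TISSUE_LEVELS, 1L,
                               prob = expr$specific_tissue_probs)
      peak_stage[i] <- sample(STAGE_LEVELS, 1L)
    } else {
      peak_tissue[i] <- sample(TISSUE_LEVELS, 1L,
                               prob = expr$peak_tissue_probs)
      peak_stage[i] <- if (peak_tissue[i] == "flavedo") {
        sample(STAGE_LEVELS, 1L, prob = expr$flavedo_stage_probs)
      } else sample(STAGE_LEVELS, 1L)
    }
  }

  ## chromosomes, strands, gene models, genome sequences
  chromo <- ifelse(runif(length(gene_ids)) < cfg$chrun_fraction, "chrUn",
                   paste0("chr", sample.int(cfg$n_chromosomes,
                                            length(gene_ids),
                                            replace = TRUE)))
  strand <- sample(c("+", "-"), length(gene_ids), replace = TRUE)
  chrom_seq <- setNames(vector("list", cfg$n_chromosomes + 1L),
                        c(paste0("chr", seq_len(cfg$n_chromosomes)), "chrUn"))
  chrom_pos <- setNames(rep(0L, length(chrom_seq)), names(chrom_seq))
  for (nm in names(chrom_seq)) chrom_seq[[nm]] <- character(0)
  model_rows <- list()
  gene_cds_len <- integer(length(gene_ids))
  for (i in seq_along(gene_ids)) {
    prot <- proteins$residues[i]
    cds <- paste(CODON_TABLE[strsplit(prot, "")[[1]]], collapse = "")
    cds_len <- nchar(cds)
    gene_cds_len[i] <- cds_len
    offs <- sort(true_introns$cds_offset[true_introns$gene_id == gene_ids[i]])
    exon_len <- diff(c(0L, offs, cds_len))
    n_introns <- length(offs)
    intron_len <- integer(0)
    pieces <- character(0)
    cut <- c(0L, offs, cds_len)
    for (k in seq_len(n_introns + 1L)) {
      pieces <- c(pieces, substr(cds, cut[k] + 1L, cut[k + 1L]))
      if (k <= n_introns) {
        il <- sample(cfg$intron_length_range[1L]:cfg$intron_length_range[2L], 1L)
        intron_len <- c(intron_len, il)
        pieces <- c(pieces, paste0("GT",
          paste(sample(c("A", "C", "G", "T"), il - 4L, replace = TRUE),
                collapse = ""), "AG"))
      }
    }
    tx_seq <- paste(pieces, collapse = "")
    tot <- nchar(tx_seq)
    chr <- chromo[i]
    spacer <- sample(cfg$intergenic_range[1L]:cfg$intergenic_range[2L], 1L)
    start_pos <- chrom_pos[[chr]] + spacer + 1L
    locus_seq <- if (strand[i] == "+") tx_seq else revcomp(tx_seq)
    chrom_seq[[chr]] <- c(chrom_seq[[chr]],
                          paste(sample(c("A", "C", "G", "T"), spacer,
                                       replace = TRUE), collapse = ""),
                          locus_seq)
    chrom_pos[[chr]] <- start_pos + tot - 1L
    ## transcript-order piece lengths -> genomic CDS segments
    piece_len <- nchar(pieces)
    is_exon <- rep(c(TRUE, FALSE), length.out = length(pieces))
    if (strand[i] == "+") {
      ends <- start_pos - 1L + cumsum(piece_len)
      starts <- ends - piece_len + 1L
    } else {
      e0 <- start_pos + tot - 1L
      starts_rev <- e0 - cumsum(piece_len) + 1L
      ends <- e0 - c(0L, cumsum(piece_len)[-length(piece_len)])
      starts <- starts_rev
    }
    segs <- tibble(start = starts[is_exon], end = ends[is_exon]) %>%
      arrange(.data$start)
    model_rows[[i]] <- tibble(gene_id = gene_ids[i], chromosome = chr,
                              strand = strand[i], cds = list(segs))
  }
  gene_models <- bind_rows(model_rows)
  genome <- vapply(chrom_seq, paste, character(1), collapse = "")
  genome <- genome[nchar(genome) > 0L]

  ## true tree: star-of-stars with divergences as branch lengths
  grp_clades <- vapply(seq_along(groups), function(gi) {
    tips <- gene_ids[gene_group == groups[gi]]
    paste0("(", paste0(tips, ":", cfg$within_group_divergence,
                       collapse = ","), "):", cfg$between_group_divergence)
  }, character(1))
  true_tree <- read_newick(paste0("(", paste(grp_clades, collapse = ","),
                                  ");"))

  ## per-gene motif start in protein coordinates
  motif_first_col <- match(motif_start, col_origin)
  gene_motif_start <- unname(vapply(gene_rows, function(r) {
    sum(r[seq_len(motif_first_col)] != "-")
  }, integer(1)))

  is_reference <- !duplicated(gene_group)
  truth <- list(
    genes = tibble(gene_id = gene_ids, group = gene_group,
                   chromosome = chromo, strand = strand,
                   motif_start = gene_motif_start,
                   protein_length = nchar(proteins$residues),
                   gene_length = gene_cds_len,
                   expression_class = classes,
                   peak_tissue = peak_tissue, peak_stage = peak_stage,
                   is_reference = is_reference),
    introns = select(true_introns, "gene_id", "cds_offset", "phase",
                     "residue", "column", "event_id"),
    events = true_events,
    tree = true_tree,
    skipped_carriers = bind_rows(skipped)
  )
  out <- list(config = cfg, proteins = proteins, msa = msa,
              gene_models = gene_models, genome = genome,
              pspg_seeds = simulate_pspg_seeds_impl(cfg$motif_consensus,
                                                    n = 12L,
                                                    divergence = 0.08),
              truth = truth)
  class(out) <- "family_simulation"
  out
}

#' @export
print.family_simulation <- function(x, ...) {
  cat("simulated family:", nrow(x$proteins), "genes in",
      length(unique(x$truth$genes$group)), "groups;",
      nrow(x$truth$introns), "introns across",
      nrow(x$truth$events), "events\n")
  invisible(x)
}

simulate_pspg_seeds_impl <- function(consensus, n, divergence) {
  chars <- strsplit(consensus, "")[[1]]
  p <- 1 - exp(-divergence)
  seqs <- vapply(seq_len(n), function(i) {
    s <- chars
    hit <- which(runif(length(s)) < p)
    s[hit] <- vapply(s[hit], function(a) sample(setdiff(AMINO_ACIDS, a), 1L),
                     character(1))
    paste(s, collapse = "")
  }, character(1))
  tibble(id = sprintf("seed%02d", seq_len(n)), description = "",
         residues = seqs)
}

#' Simulate a PSPG seed alignment
#'
#' Generates `n` gap-free variants of a 44-residue consensus at the given
#' per-site divergence, suitable as input to [build_pspg_model()].
#'
#' @param consensus 44-residue motif consensus.
#' @param n Number of seed sequences.
#' @param divergence Expected substitutions per site from the consensus.
#' @param seed Integer seed.
#' @return Tibble with `id`, `description`, `residues`.
#' @export
simulate_pspg_seeds <- function(consensus = PSPG_CONSENSUS, n = 12L,
                                divergence = 0.08, seed = 1L) {
  with_seed(seed, simulate_pspg_seeds_impl(consensus, n, divergence))
}

#' Simulate background (non-family) proteins
#'
#' Uniform-random amino-acid sequences without the motif, for estimating
#' the motif scan's false-positive behavior.
#'
#' @param n Number of proteins.
#' @param length_range Inclusive protein-length range.
#' @param seed Integer seed.
#' @return Tibble with `id`, `description`, `residues`.
#' @export
simulate_background_proteins <- function(n, length_range = c(150L, 600L),
                                         seed = 1L) {
  with_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
    tibble(
      id = sprintf("bg%03d", seq_len(n)),
      description = "",
      residues = vapply(lens, function(l) {
        paste(sample(AMINO_ACIDS, l, replace = TRUE), collapse = "")
      }, character(1))
    )
  })
}

#' Simulate an expression count table for a simulated family
#'
#' Draws negative-binomial counts for the 4-tissue x 3-stage design.
#' Expression is planted in RPKM space per the truth manifest's class
#' and peak-sample assignments (tissue-specific genes: high in their
#' tissue, essentially zero elsewhere; ubiquitous genes: a lognormal
#' baseline boosted at the peak sample; silent genes: zero), then
#' converted to count means through each gene's coding length and the
#' sample's library size.
#'
#' @param sim A `family_simulation` (or its `truth` list).
#' @param config Optional `simulation_config`; defaults to the
#'   simulation's own.
#' @return A `count_table` tibble (see [read_counts_table()]).
#' @export
simulate_expression <- function(sim, config = NULL) {
  truth <- if (inherits(sim, "family_simulation")) sim$truth else sim
  cfg <- config %||%
    (if (inherits(sim, "family_simulation")) sim$config else
       simulation_config())
  expr <- cfg$expression
  stopifnot(expr$dispersion > 0)
  with_seed(cfg$seed + 1L, {
    genes <- truth$genes
    samples <- tidyr::expand_grid(tissue = TISSUE_LEVELS,
                                  stage = STAGE_LEVELS) %>%
      mutate(sample_id = paste(.data$tissue, .data$stage, sep = "_"))
    libs <- tibble(sample_id = samples$sample_id,
                   library_size = round(runif(nrow(samples),
                                              expr$libsize_range[1L],
                                              expr$libsize_range[2L])))
    rows <- purrr::map(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      rpkm <- numeric(nrow(samples))
      if (g$expression_class == "ubiquitous") {
        base <- rlnorm(1L, expr$base_rpkm_meanlog, expr$base_rpkm_sdlog)
        rpkm[] <- base
        peak <- samples$tissue == g$peak_tissue &
          samples$stage == g$peak_stage
        rpkm[peak] <- base * expr$peak_boost
      } else if (g$expression_class == "tissue_specific") {
        hi <- rlnorm(1L, expr$specific_rpkm_meanlog, expr$specific_rpkm_sdlog)
        rpkm[] <- expr$off_tissue_rpkm
        in_tissue <- samples$tissue == g$peak_tissue
        rpkm[in_tissue] <- hi
        rpkm[in_tissue & samples$stage == g$peak_stage] <-
          hi * expr$stage_boost
      }
      tibble(gene_id = g$gene_id, sample_id = samples$sample_id,
             tissue = samples$tissue, stage = samples$stage,
             mean_rpkm = rpkm, gene_length = g$gene_length)
    })
    tab <- bind_rows(rows) %>%
      left_join(libs, by = "sample_id") %>%
      mutate(mu = .data$mean_rpkm * .data$gene_length *
               .data$library_size / 1e9,
             count = rnbinom(n(), mu = .data$mu, size = expr$dispersion)) %>%
      select("gene_id", "sample_id", "tissue", "stage", "count",
             "gene_length", "library_size")
    class(tab) <- c("count_table", class(tab))
    tab
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the files the pipeline consumes: `genome.fa`, `models.gff3`,
#' `proteins.fa`, `msa.afa`, `pspg_seeds.fa`, `counts.tsv`,
#' `library_sizes.tsv`, `references.tsv` (one labeled reference per
#' group) and `truth.json`.
#'
#' @param sim A `family_simulation`.
#' @param dir Output directory (created if needed).
#' @param counts Optional pre-simulated `count_table`; by default
#'   [simulate_expression()] is called.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, counts = NULL) {
  stopifnot(inherits(sim, "family_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(tibble(id = names(sim$genome), description = "",
                     residues = sim$genome),
              file.path(dir, "genome.fa"))
  write_gff3(sim$gene_models, file.path(dir, "models.gff3"))
  write_fasta(sim$proteins, file.path(dir, "proteins.fa"))
  write_fasta(sim$msa, file.path(dir, "msa.afa"))
  write_fasta(sim$pspg_seeds, file.path(dir, "pspg_seeds.fa"))
  if (is.null(counts)) counts <- simulate_expression(sim)
  write_counts_table(counts, file.path(dir, "counts.tsv"),
                     file.path(dir, "library_sizes.tsv"))
  refs <- sim$truth$genes %>%
    filter(.data$is_reference) %>%
    select(id = "gene_id", "group")
  readr::write_tsv(refs, file.path(dir, "references.tsv"))
  truth_json <- list(
    genes = sim$truth$genes,
    introns = sim$truth$introns,
    events = sim$truth$events,
    tree = write_newick(sim$truth$tree),
    skipped_carriers = sim$truth$skipped_carriers
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
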