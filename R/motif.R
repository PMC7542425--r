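## Average (not monoisotopic) residue masses in daltons; adding one water
## per chain gives the average molecular weight reported by standard
## proteomics calculators.
AVG_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

## Bjellqvist pKa values (the set behind the classic ExPASy pI tool):
## side chains, free C-terminus, and residue-specific free N-terminus.
PKA_SETS <- list(
  bjellqvist = list(
    cterm = 3.55,
    nterm_default = 7.5,
    nterm = c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
              E = 7.7),
    acidic = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0),
    basic = c(H = 5.98, K = 10.0, R = 12.0)
  ),
  emboss = list(
    cterm = 3.6,
    nterm_default = 8.6,
    nterm = c(),
    acidic = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1),
    basic = c(H = 6.5, K = 10.8, R = 12.5)
  )
)

#' Compute average protein molecular weight
#'
#' Sums average residue masses and adds one water (18.01524 Da). `X`
#' (unknown residue) contributes the mean residue mass.
#'
#' @param residues Character vector of amino-acid sequences.
#' @return Numeric vector of molecular weights in daltons.
#' @export
compute_mw <- function(residues) {
  masses <- c(AVG_RESIDUE_MASS, X = mean(AVG_RESIDUE_MASS))
  vapply(residues, function(s) {
    if (is.na(s) || nchar(s) == 0L) {
      stop("cannot compute Mw of an empty sequence", call. = FALSE)
    }
    aa <- strsplit(s, "")[[1]]
    bad <- setdiff(unique(aa), names(masses))
    if (length(bad) > 0L) {
      stop("non-amino-acid character(s) in sequence: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    sum(masses[aa]) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

## Net charge of a peptide at a given pH under a pKa set.
## Positive groups: free N-terminus, H, K, R. Negative: free C-terminus,
## D, E, C, Y. X residues are not ionizable.
peptide_charge <- function(ph, counts, nterm_pka, pka) {
  pos <- 1 / (1 + 10^(ph - nterm_pka))
  for (a in names(pka$basic)) {
    pos <- pos + counts[[a]] / (1 + 10^(ph - pka$basic[[a]]))
  }
  neg <- 1 / (1 + 10^(pka$cterm - ph))
  for (a in names(pka$acidic)) {
    neg <- neg + counts[[a]] / (1 + 10^(pka$acidic[[a]] - ph))
  }
  pos - neg
}

#' Compute protein isoelectric point
#'
#' Finds the pH at which the peptide's net charge vanishes, by bisection
#' on \[0, 14\]. The charge model counts side chains of D, E, C, Y
#' (acidic) and H, K, R (basic) plus the free termini; the net charge is
#' strictly decreasing in pH so the root is unique.
#'
#' @param residues Character vector of amino-acid sequences.
#' @param pka_set Name of the bundled pKa table: `"bjellqvist"` (default,
#'   the set behind the classic ExPASy tool) or `"emboss"`.
#' @param tol Charge tolerance at the returned pH.
#' @return Numeric vector of pI values (pH units).
#' @export
compute_pi <- function(residues, pka_set = "bjellqvist", tol = 1e-4) {
  pka <- PKA_SETS[[match.arg(pka_set, names(PKA_SETS))]]
  vapply(residues, function(s) {
    if (is.na(s) || nchar(s) == 0L) {
      stop("cannot compute pI of an empty sequence", call. = FALSE)
    }
    aa <- strsplit(s, "")[[1]]
    bad <- setdiff(unique(aa), c(AMINO_ACIDS, "X"))
    if (length(bad) > 0L) {
      stop("non-amino-acid character(s) in sequence: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    counts <- as.list(table(factor(aa, levels = AMINO_ACIDS)))
    nt <- aa[1L]
    nterm_pka <- if (nt %in% names(pka$nterm)) pka$nterm[[nt]] else
      pka$nterm_default
    ## bisect to a pH width where the residual charge is below tol for
    ## any realistic peptide (slope of charge in pH is bounded)
    lo <- 0; hi <- 14
    while ((hi - lo) > 1e-7) {
      mid <- (lo + hi) / 2
      if (peptide_charge(mid, counts, nterm_pka, pka) > 0) lo <- mid
      else hi <- mid
    }
    mid <- (lo + hi) / 2
    if (abs(peptide_charge(mid, counts, nterm_pka, pka)) >= tol) {
      stop("bisection did not reach the charge tolerance", call. = FALSE)
    }
    mid
  }, numeric(1), USE.NAMES = FALSE)
}

#' Build a PSPG-box scoring model from a seed alignment
#'
#' Converts a gap-free alignment of 44-residue PSPG boxes into a
#' position-specific log-odds matrix (bits):
#' `log2(((count + pc * bg) / (N + pc)) / bg)` per column and residue,
#' with pseudocount `pc` and background frequencies `bg`.
#'
#' The model's default acceptance threshold is a fraction of the score of
#' its own consensus (the column-wise log-odds maxima summed), so the
#' threshold adapts to the information content of the seed set.
#'
#' @param seeds Character vector (or tibble with a `residues` column) of
#'   aligned 44-residue motif sequences without gaps.
#' @param pseudocount Positive pseudocount mass.
#' @param min_score_frac Fraction of the consensus score used as the
#'   default hit threshold.
#' @param background Named 20-vector of background frequencies summing to
#'   1; defaults to uniform.
#' @return An object of class `pspg_model`.
#' @export
build_pspg_model <- function(seeds, pseudocount = 1,
                             min_score_frac = 0.6, background = NULL) {
  if (is.data.frame(seeds)) seeds <- seeds$residues
  if (length(seeds) == 0L) stop("empty seed set", call. = FALSE)
  if (any(nchar(seeds) != PSPG_LENGTH)) {
    stop("every seed must be exactly ", PSPG_LENGTH, " residues",
         call. = FALSE)
  }
  if (any(grepl("[-.]", seeds))) {
    stop("seed sequences must be gap-free", call. = FALSE)
  }
  stopifnot(pseudocount > 0)
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), AMINO_ACIDS)
  }
  stopifnot(all(background > 0), abs(sum(background) - 1) < 1e-8,
            setequal(names(background), AMINO_ACIDS))
  background <- background[AMINO_ACIDS]
  mat <- do.call(rbind, strsplit(toupper(seeds), ""))
  bad <- setdiff(unique(as.vector(mat)), AMINO_ACIDS)
  if (length(bad) > 0L) {
    stop("non-standard residue(s) in seeds: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(mat)
  counts <- t(apply(mat, 2L, function(col) {
    table(factor(col, levels = AMINO_ACIDS))
  }))
  log_odds <- log2(t((t(counts) + pseudocount * background) / (n + pseudocount)) /
                     matrix(background, PSPG_LENGTH, 20, byrow = TRUE))
  dimnames(log_odds) <- list(NULL, AMINO_ACIDS)
  consensus_score <- sum(apply(log_odds, 1L, max))
  model <- list(
    log_odds = log_odds,
    background = background,
    pseudocount = pseudocount,
    n_seeds = n,
    consensus_score = consensus_score,
    min_score_frac = min_score_frac,
    min_score = min_score_frac * consensus_score
  )
  class(model) <- "pspg_model"
  model
}

#' @export
print.pspg_model <- function(x, ...) {
  cat("PSPG-box log-odds model (", PSPG_LENGTH, " columns, ",
      x$n_seeds, " seeds)\n", sep = "")
  cat("consensus score:", format(x$consensus_score, digits = 5),
      "bits; hit threshold:", format(x$min_score, digits = 5), "bits\n")
  invisible(x)
}

#' @method tidy pspg_model
#' @export
tidy.pspg_model <- function(x, ...) {
  tibble(
    column = rep(seq_len(PSPG_LENGTH), times = 20L),
    residue = rep(AMINO_ACIDS, each = PSPG_LENGTH),
    log_odds = as.vector(x$log_odds)
  ) %>% arrange(.data$column, .data$residue)
}

#' @method glance pspg_model
#' @export
glance.pspg_model <- function(x, ...) {
  tibble(n_seeds = x$n_seeds, motif_length = PSPG_LENGTH,
         consensus_score = x$consensus_score, min_score = x$min_score)
}

## Score every admissible 44-residue window of one protein; residues
## outside the standard alphabet score 0 (background odds).
score_windows <- function(residues, model, c_term_window) {
  len <- nchar(residues)
  if (len < PSPG_LENGTH) return(NULL)
  first_start <- max(1L, len - c_term_window + 1L)
  starts <- first_start:(len - PSPG_LENGTH + 1L)
  aa <- strsplit(residues, "")[[1]]
  idx <- match(aa, AMINO_ACIDS)   # NA for non-standard residues
  scores <- vapply(starts, function(s) {
    pos <- s:(s + PSPG_LENGTH - 1L)
    ok <- !is.na(idx[pos])
    sum(model$log_odds[cbind(which(ok), idx[pos][ok])])
  }, numeric(1))
  tibble(start = starts, score = scores)
}

#' Scan proteins for the PSPG box near the C-terminus
#'
#' Slides a 44-residue window over the last `c_term_window` residues of
#' each protein and keeps the maximum-scoring window when it reaches the
#' model threshold; ties go to the most C-terminal start. Proteins shorter
#' than 44 residues simply yield no hit.
#'
#' @param proteins Tibble with columns `id` and `residues` (as returned by
#'   [read_fasta()]), or a named character vector of sequences.
#' @param model A [build_pspg_model()] object.
#' @param c_term_window Number of C-terminal residues searched.
#' @param min_score Score threshold in bits; defaults to the model's.
#' @return A tibble with one row per hit: `protein_id`, `start` (1-based
#'   residue position of the motif), `score` (bits), `distance_to_cterm`
#'   (residues between motif end and sequence end).
#' @export
scan_pspg <- function(proteins, model, c_term_window = 150L,
                      min_score = NULL) {
  stopifnot(inherits(model, "pspg_model"))
  if (is.character(proteins)) {
    proteins <- tibble(id = names(proteins) %||% as.character(seq_along(proteins)),
                       residues = unname(proteins))
  }
  if (is.null(min_score)) min_score <- model$min_score
  hits <- purrr::map2(proteins$id, proteins$residues, function(id, res) {
    sc <- score_windows(res, model, c_term_window)
    if (is.null(sc)) return(NULL)
    best <- sc %>% filter(.data$score == max(.data$score)) %>%
      slice(n())                       # most C-terminal on ties
    if (best$score < min_score) return(NULL)
    tibble(protein_id = id, start = best$start, score = best$score,
           distance_to_cterm = nchar(res) - (best$start + PSPG_LENGTH - 1L))
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0L) {
    out <- tibble(protein_id = character(), start = integer(),
                  score = numeric(), distance_to_cterm = integer())
  }
  out
}

#' Identify family members and compute their protein statistics
#'
#' Runs the PSPG scan over a protein set and assembles the family catalog:
#' every protein with a motif hit, together with its length, average
#' molecular weight, isoelectric point and chromosome. Proteins absent
#' from `chromosome_map` are reported on `"chrUn"`, the placeholder for
#' unplaced scaffolds. The `group` column is filled later by
#' [assign_groups()].
#'
#' @param proteins Tibble with `id` and `residues` columns.
#' @param model A `pspg_model`.
#' @param chromosome_map Optional tibble mapping `gene_id` to
#'   `chromosome`.
#' @param c_term_window,min_score Passed to [scan_pspg()].
#' @param pka_set Passed to [compute_pi()].
#' @return A tibble (class `family_catalog`) with columns `protein_id`,
#'   `motif_start`, `motif_score`, `distance_to_cterm`, `length`, `mw`,
#'   `pi`, `chromosome`, `group`.
#' @export
identify_family <- function(proteins, model, chromosome_map = NULL,
                            c_term_window = 150L, min_score = NULL,
                            pka_set = "bjellqvist") {
  hits <- scan_pspg(proteins, model, c_term_window, min_score)
  if (nrow(hits) == 0L) {
    out <- tibble(protein_id = character(), motif_start = integer(),
                  motif_score = numeric(), distance_to_cterm = integer(),
                  length = integer(), mw = numeric(), pi = numeric(),
                  chromosome = character(), group = character())
    class(out) <- c("family_catalog", class(out))
    return(out)
  }
  members <- proteins %>%
    rename(protein_id = "id") %>%
    inner_join(hits, by = "protein_id") %>%
    mutate(length = nchar(.data$residues),
           mw = compute_mw(.data$residues),
           pi = compute_pi(.data$residues, pka_set = pka_set))
  if (is.null(chromosome_map)) {
    members$chromosome <- "chrUn"
  } else {
    members <- members %>%
      left_join(rename(chromosome_map, protein_id = "gene_id"),
                by = "protein_id") %>%
      mutate(chromosome = dplyr::coalesce(.data$chromosome, "chrUn"))
  }
  out <- members %>%
    mutate(group = NA_character_) %>%
    select("protein_id", motif_start = "start", motif_score = "score",
           "distance_to_cterm", "length", "mw", "pi", "chromosome", "group")
  class(out) <- c("family_catalog", class(out))
  out
}
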