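#' p-distance matrix from a protein alignment
#'
#' For each pair of sequences, the fraction of mismatched residues over
#' the columns where both carry a residue (pairwise-complete columns).
#' Optionally Poisson-corrected (`-log(1 - p)`).
#'
#' @param msa Tibble with `id` and `residues` (all the same aligned
#'   length).
#' @param min_overlap Minimum number of pairwise-complete columns; pairs
#'   below this are an error (the distance would be meaningless).
#' @param correction `"none"` (uncorrected p-distance, default) or
#'   `"poisson"`.
#' @return A symmetric numeric matrix with sequence ids as dimnames.
#' @export
p_distance_matrix <- function(msa, min_overlap = 30L,
                              correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  stopifnot(is.data.frame(msa), nrow(msa) >= 2L)
  lens <- nchar(msa$residues)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must all have the same length", call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(msa$residues, ""))
  present <- chars != "-"
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(msa$id, msa$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- present[i, ] & present[j, ]
      m <- sum(ok)
      if (m < min_overlap) {
        stop("sequences '", msa$id[i], "' and '", msa$id[j],
             "' share only ", m, " aligned columns (min_overlap = ",
             min_overlap, ")", call. = FALSE)
      }
      p <- sum(chars[i, ok] != chars[j, ok]) / m
      if (correction == "poisson") {
        if (p >= 1) stop("saturated pair '", msa$id[i], "'/'", msa$id[j],
                         "' cannot be Poisson-corrected", call. = FALSE)
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

## Q-criterion minimum with deterministic tie-breaking: smallest (i, j)
## pair under the current node ordering.
nj_pick_pair <- function(d, r, n_active) {
  q <- (n_active - 2) * d - outer(r, r, "+")
  diag(q) <- Inf
  m <- min(q)
  cand <- which(q <= m + 1e-12 & upper.tri(q), arr.ind = TRUE)
  cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
  cand[1L, ]
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining: at each step the pair
#' minimizing `Q(i,j) = (n-2) d(i,j) - R(i) - R(j)` is joined, pendant
#' branch lengths follow the two-point formulas, and distances to the new
#' node are `(d(i,k) + d(j,k) - d(i,j)) / 2`. Ties in Q are broken by the
#' smallest index pair, so the result is deterministic. The unrooted
#' result is stored rooted at the final join (a trifurcation for n > 3).
#'
#' Negative pendant branch lengths (possible on non-additive input) are
#' clipped to zero with the deficit moved to the sibling branch, the
#' common normalization for display and patristic distances.
#'
#' @param d Symmetric non-negative distance matrix with labeled rows.
#' @param clip_negative Clip negative branch lengths (default `TRUE`).
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(d, clip_negative = TRUE) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d))) stop("distance matrix must have row names",
                                 call. = FALSE)
  if (any(d < 0) || any(abs(d - t(d)) > 1e-9) || any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must be symmetric, non-negative, zero-diagonal",
         call. = FALSE)
  }
  n <- nrow(d)
  if (n < 2L) stop("need at least two taxa", call. = FALSE)
  fmt <- function(x) sprintf("%.12g", x)
  sub <- rownames(d)            # newick fragment per active node
  if (n == 2L) {
    return(read_newick(paste0("(", sub[1L], ":", fmt(d[1, 2] / 2), ",",
                              sub[2L], ":", fmt(d[1, 2] / 2), ");")))
  }
  active <- d
  while (nrow(active) > 3L) {
    m <- nrow(active)
    r <- rowSums(active)
    ij <- nj_pick_pair(active, r, m)
    i <- ij[1L]; j <- ij[2L]
    dij <- active[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (clip_negative) {
      if (li < 0) { lj <- lj + li; li <- 0 }
      if (lj < 0) { li <- li + lj; lj <- 0 }
      li <- max(li, 0); lj <- max(lj, 0)
    }
    new_sub <- paste0("(", sub[i], ":", fmt(li), ",", sub[j], ":",
                      fmt(lj), ")")
    dk <- (active[i, ] + active[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    nxt <- rbind(cbind(active[keep, keep, drop = FALSE], dk[keep]),
                 c(dk[keep], 0))
    active <- nxt
    sub <- c(sub[keep], new_sub)
  }
  ## resolve the last three nodes by the three-point formulas
  d12 <- active[1, 2]; d13 <- active[1, 3]; d23 <- active[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  if (clip_negative) { l1 <- max(l1, 0); l2 <- max(l2, 0); l3 <- max(l3, 0) }
  read_newick(paste0("(", sub[1L], ":", fmt(l1), ",", sub[2L], ":",
                     fmt(l2), ",", sub[3L], ":", fmt(l3), ");"))
}

#' Patristic distances between all leaves of a tree
#'
#' Sums branch lengths along the path between every pair of leaves.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return Symmetric matrix of patristic distances (leaf labels as
#'   dimnames).
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  stats::cophenetic(tree)
}

#' Assign phylogenetic groups by nearest labeled reference
#'
#' Every non-reference leaf receives the group of the reference leaf at
#' minimal patristic distance; ties are broken by the lexicographically
#' smallest group label. Reference leaves keep their own label at
#' distance zero. This reads group membership off tree proximity rather
#' than strict clade monophyly, which makes the assignment deterministic
#' and robust to reference placement.
#'
#' @param tree An `ape::phylo` tree containing all reference leaves.
#' @param references Tibble with columns `id` (leaf label) and `group`.
#' @return A tibble with `id`, `group`, `reference_id`, `distance`,
#'   `is_reference`.
#' @export
assign_groups <- function(tree, references) {
  stopifnot(is.data.frame(references),
            all(c("id", "group") %in% names(references)))
  missing <- setdiff(references$id, tree$tip.label)
  if (length(missing) > 0L) {
    stop("reference leaf/leaves missing from tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pd <- patristic_distances(tree)
  refs <- references %>% arrange(.data$group, .data$id)
  queries <- tree$tip.label
  rows <- purrr::map(queries, function(q) {
    if (q %in% refs$id) {
      g <- refs$group[match(q, refs$id)]
      return(tibble(id = q, group = g, reference_id = q, distance = 0,
                    is_reference = TRUE))
    }
    dists <- pd[q, refs$id]
    best <- which(dists <= min(dists) + 1e-12)
    ## refs are sorted by group then id, so the first hit is the
    ## lexicographically smallest group label among the tied references
    pick <- best[1L]
    tibble(id = q, group = refs$group[pick], reference_id = refs$id[pick],
           distance = unname(dists[pick]), is_reference = FALSE)
  })
  bind_rows(rows)
}

#' Fill the catalog's group column from a group assignment
#'
#' @param catalog A `family_catalog`.
#' @param assignment Output of [assign_groups()].
#' @return The catalog with `group` filled (members absent from the
#'   assignment stay `NA`, i.e. unassigned).
#' @export
add_group_labels <- function(catalog, assignment) {
  catalog %>%
    select(-"group") %>%
    left_join(select(assignment, protein_id = "id", "group"),
              by = "protein_id")
}
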