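make_count_table <- function(df) {
  # df: gene_id, sample_id (tissue_stage), count, gene_length, library_size
  df$tissue <- sub("_[^_]+$", "", df$sample_id)
  df$stage <- sub("^.*_", "", df$sample_id)
  df <- df[c("gene_id", "sample_id", "tissue", "stage", "count",
             "gene_length", "library_size")]
  class(df) <- c("count_table", class(df))
  df
}

test_that("RPKM follows its definition and scaling invariance", {
  tab <- make_count_table(tibble::tibble(
    gene_id = "g1", sample_id = "flavedo_80", count = 10L,
    gene_length = 1000L, library_size = 1e6
  ))
  expect_equal(rpkm_matrix(tab)$rpkm, 10)

  tab$count <- 0L
  expect_equal(rpkm_matrix(tab)$rpkm, 0)

  tab$gene_length <- 0L
  expect_error(rpkm_matrix(tab), "length")

  counts <- random_count_table(10, seed = 2)
  r1 <- rpkm_matrix(counts)
  doubled <- counts
  doubled$count <- doubled$count * 2L
  doubled$library_size <- doubled$library_size * 2
  expect_equal(rpkm_matrix(doubled)$rpkm, r1$rpkm)
})

test_that("Venn partition classifies detection patterns and conserves genes", {
  expr <- rpkm_matrix(random_count_table(2, seed = 3))
  expr$rpkm <- 0
  expr$rpkm[expr$gene_id == "g001" & expr$sample_id == "flavedo_140"] <- 5
  vp <- venn_partition(expr)
  expect_equal(vp$n_genes[vp$region == "flavedo"], 1L)
  expect_equal(vp$gene_ids[[which(vp$region == "flavedo")]], "g001")
  expect_equal(vp$n_genes[vp$region == "none"], 1L)
  expect_equal(sum(vp$n_genes), 2L)

  expr$rpkm <- 2
  vp2 <- venn_partition(expr)
  expect_equal(vp2$n_genes[vp2$region == "flavedo+albedo+SM+JS"], 2L)

  expect_error(venn_partition(dplyr::filter(expr, tissue != "JS")), "JS")
})

test_that("Venn counts conserve genes and shrink monotonically in threshold", {
  for (seed in 1:100) {
    expr <- rpkm_matrix(random_count_table(8, seed = 1000 + seed))
    vp <- venn_partition(expr, threshold = 1)
    expect_equal(sum(vp$n_genes), 8L)
    # region sizes (number of tissues in a gene's region) never grow
    # when the threshold rises
    region_size <- function(v) {
      sizes <- lengths(strsplit(v$region, "+", fixed = TRUE))
      sizes[v$region == "none"] <- 0L
      per_gene <- rep(sizes, v$n_genes)
      names(per_gene) <- unlist(v$gene_ids)
      per_gene
    }
    lo <- region_size(vp)
    hi <- region_size(venn_partition(expr, threshold = 5))
    expect_true(all(hi[names(lo)] <= lo))
  }
})

test_that("z-scoring standardizes rows and clustering is deterministic", {
  expr <- rpkm_matrix(random_count_table(5, seed = 8))
  base <- c(1, 2, 3, rep(2, 9))
  for (g in unique(expr$gene_id)) {
    expr$rpkm[expr$gene_id == g] <- base + as.integer(substr(g, 2, 4))
  }
  # two identical profiles merge first and sit adjacent in leaf order
  expr$rpkm[expr$gene_id == "g002"] <- expr$rpkm[expr$gene_id == "g001"]
  cm <- zscore_and_cluster(expr)
  z <- as.matrix(cm$zscores[-1])
  expect_true(all(abs(rowMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-9))
  expect_equal(sort(match(c("g001", "g002"), cm$leaf_order)),
               c(1, 2) + min(match(c("g001", "g002"), cm$leaf_order)) - 1)
  expect_setequal(cm$leaf_order, unique(expr$gene_id))

  # first three samples of the canonical order are the flavedo stages
  expect_equal(cm$samples$sample_id[1:3],
               c("flavedo_80", "flavedo_140", "flavedo_200"))

  # explicit small check: profile (1, 2, 3) standardizes to (-1, 0, 1)
  small <- make_count_table(tibble::tibble(
    gene_id = rep(c("a", "b"), each = 3),
    sample_id = rep(c("flavedo_80", "flavedo_140", "flavedo_200"), 2),
    count = c(1L, 2L, 3L, 9L, 6L, 3L),
    gene_length = 1000L, library_size = 1e9
  ))
  zs <- zscore_and_cluster(rpkm_matrix(small))
  expect_equal(unlist(zs$zscores[zs$zscores$gene_id == "a", -1],
                      use.names = FALSE), c(-1, 0, 1))

  # constant rows become zero vectors
  const <- make_count_table(tibble::tibble(
    gene_id = rep(c("a", "b"), each = 3),
    sample_id = rep(c("flavedo_80", "flavedo_140", "flavedo_200"), 2),
    count = c(4L, 4L, 4L, 1L, 5L, 9L),
    gene_length = 1000L, library_size = 1e9
  ))
  zc <- zscore_and_cluster(rpkm_matrix(const))
  expect_equal(unlist(zc$zscores[zc$zscores$gene_id == "a", -1],
                      use.names = FALSE), c(0, 0, 0))

  single <- make_count_table(tibble::tibble(
    gene_id = c("a", "b"), sample_id = "flavedo_80", count = 1L,
    gene_length = 1000L, library_size = 1e6
  ))
  expect_error(zscore_and_cluster(rpkm_matrix(single)), "two samples")
})

test_that("z-scores are idempotent and leaf order survives row permutation", {
  expr <- rpkm_matrix(random_count_table(12, seed = 14))
  cm1 <- zscore_and_cluster(expr)
  # feeding standardized values back yields the same z-scores
  again <- tidy(cm1)
  again$rpkm <- again$z
  cm2 <- zscore_and_cluster(again[c("gene_id", "sample_id", "tissue",
                                    "stage", "rpkm")])
  expect_equal(as.matrix(cm2$zscores[-1]), as.matrix(cm1$zscores[-1]),
               tolerance = 1e-9)

  perm <- expr[order(rev(expr$gene_id), expr$sample_id), ]
  cm3 <- zscore_and_cluster(perm)
  # same dendrogram: adjacency structure is preserved up to relabeling
  expect_setequal(cm3$leaf_order, cm1$leaf_order)
  expect_equal(cm3$hclust$height, cm1$hclust$height, tolerance = 1e-12)
})

test_that("peak summary picks the argmax sample with canonical tie-breaks", {
  df <- rpkm_matrix(random_count_table(3, seed = 4))
  df$rpkm <- 1
  df$rpkm[df$gene_id == "g001" & df$sample_id == "flavedo_80"] <- 9
  # g002 ties between flavedo_80 and albedo_80 at the max
  df$rpkm[df$gene_id == "g002" & df$sample_id %in%
            c("flavedo_80", "albedo_80")] <- 7
  df$rpkm[df$gene_id == "g003"] <- 0
  ps <- peak_summary(df)
  g <- ps$genes
  expect_equal(g$peak_tissue[g$gene_id == "g001"], "flavedo")
  expect_equal(g$peak_stage[g$gene_id == "g001"], "80")
  expect_equal(g$peak_tissue[g$gene_id == "g002"], "flavedo")
  expect_true(g$no_peak[g$gene_id == "g003"])
  expect_equal(sum(ps$tissue_counts$n_genes), 2L)
})

test_that("planted peak-tissue fractions are recovered from counts", {
  sim <- benchmark_sim()
  counts <- simulate_expression(sim)
  ps <- peak_summary(rpkm_matrix(counts))
  truth <- sim$truth$genes
  active <- dplyr::filter(truth, expression_class != "silent")
  planted <- mean(active$peak_tissue == "flavedo")
  got <- ps$tissue_counts$n_genes[ps$tissue_counts$tissue == "flavedo"] /
    sum(ps$tissue_counts$n_genes)
  expect_lt(abs(got - planted), 0.05)
})
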