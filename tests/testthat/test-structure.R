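test_that("phase and residue mapping agrees with a codon-walk oracle", {
  expect_equal(as.list(map_intron_to_protein(300))[c("phase", "residue")],
               list(phase = 0L, residue = 100L))
  expect_equal(as.list(map_intron_to_protein(301))[c("phase", "residue")],
               list(phase = 1L, residue = 101L))
  expect_equal(as.list(map_intron_to_protein(302))[c("phase", "residue")],
               list(phase = 2L, residue = 101L))
  expect_error(map_intron_to_protein(0), "positive")

  # oracle: lay residues out three bases each and walk to the base
  # preceding the splice; its residue owns (or precedes) the splice
  codon_of_base <- rep(seq_len(1000), each = 3)
  got <- map_intron_to_protein(1:3000)
  expect_equal(got$phase, (1:3000) %% 3L)
  expect_equal(got$residue, codon_of_base[1:3000])
})

test_that("introns are extracted in transcript orientation on both strands", {
  plus <- tibble::tibble(
    gene_id = "gp", chromosome = "chr1", strand = "+",
    cds = list(tibble::tibble(start = c(101L, 301L), end = c(200L, 400L)))
  )
  ip <- extract_introns(plus)
  expect_equal(ip$genomic_start, 201L)
  expect_equal(ip$genomic_end, 300L)
  expect_equal(ip$cds_offset, 100L)
  expect_equal(ip$phase, 1L)
  expect_equal(ip$residue, 34L)

  minus <- plus
  minus$strand <- "-"
  im <- extract_introns(minus)
  # transcript starts at the 301-400 segment: offset counts its 100 bases
  expect_equal(im$cds_offset, 100L)
  expect_equal(im$genomic_start, 201L)
  expect_equal(im$intron_index, 1L)

  single <- plus
  single$cds <- list(tibble::tibble(start = 101L, end = 400L))
  expect_equal(nrow(extract_introns(single)), 0L)

  touching <- plus
  touching$cds <- list(tibble::tibble(start = c(101L, 201L),
                                      end = c(200L, 300L)))
  expect_error(extract_introns(touching), "touching")
})

test_that("mirroring a gene model leaves protein-relative coordinates fixed", {
  set.seed(21)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    len <- sample(30:300, k) * 3L
    gaps <- sample(50:500, k - 1)
    starts <- integer(k); ends <- integer(k)
    pos <- sample(1000:5000, 1)
    for (i in seq_len(k)) {
      starts[i] <- pos
      ends[i] <- pos + len[i] - 1L
      if (i < k) pos <- ends[i] + gaps[i] + 1L
    }
    model <- tibble::tibble(
      gene_id = "g", chromosome = "chr1",
      strand = sample(c("+", "-"), 1),
      cds = list(tibble::tibble(start = starts, end = ends))
    )
    span <- c(min(starts), max(ends))
    mirrored <- model
    mirrored$strand <- setdiff(c("+", "-"), model$strand)
    mirrored$cds <- list(tibble::tibble(
      start = sort(span[1] + span[2] - ends),
      end = sort(span[1] + span[2] - starts)
    ))
    a <- extract_introns(model)
    b <- extract_introns(mirrored)
    expect_equal(b[c("cds_offset", "phase", "residue", "intron_index")],
                 a[c("cds_offset", "phase", "residue", "intron_index")])
    # conservation: introns = segments - 1
    expect_equal(nrow(a), k - 1L)
  }
})

test_that("residues project onto alignment columns through gaps", {
  expect_equal(project_to_alignment("A-CD", 1), 1L)
  expect_equal(project_to_alignment("A-CD", 2), 3L)
  expect_error(project_to_alignment("A-CD", 4), "ungapped")

  msa <- tibble::tibble(id = c("x", "y"),
                        residues = c("A-CD", "ABCD"))
  introns <- tibble::tibble(gene_id = c("x", "y"), intron_index = 1L,
                            cds_offset = c(4L, 4L), phase = 1L,
                            residue = c(2L, 2L))
  cols <- add_alignment_columns(introns, msa)
  expect_equal(cols$column, c(3L, 2L))
  expect_error(add_alignment_columns(dplyr::mutate(introns, gene_id = "z"),
                                     msa), "absent")
})

test_that("event clustering groups by column and phase", {
  recs <- tibble::tibble(gene_id = c("a", "b", "c"), intron_index = 1L,
                         column = 120, phase = 1L)
  ev <- cluster_insertion_events(recs)
  expect_equal(nrow(ev$events), 1L)
  expect_equal(ev$events$event_id, "I-1")
  expect_equal(ev$events$n_members, 3L)

  recs2 <- tibble::tibble(gene_id = c("a", "b"), intron_index = 1L,
                          column = 120, phase = c(1L, 0L))
  ev2 <- cluster_insertion_events(recs2)
  expect_equal(nrow(ev2$events), 2L)

  # one gene never contributes two introns to one event
  recs3 <- tibble::tibble(gene_id = c("a", "a", "b"),
                          intron_index = c(1L, 2L, 1L),
                          column = c(120, 121, 120), phase = 1L)
  ev3 <- cluster_insertion_events(recs3, tolerance = 2L)
  members <- ev3$introns |>
    dplyr::count(event_id, gene_id)
  expect_true(all(members$n == 1L))

  expect_equal(nrow(cluster_insertion_events(recs[0, ])$events), 0L)
})

test_that("planted insertion events are recovered exactly at tolerance 0", {
  sim <- benchmark_sim()
  introns <- extract_introns(sim$gene_models) |>
    add_alignment_columns(sim$msa)
  ev <- cluster_insertion_events(introns, tolerance = 0L)
  expect_equal(nrow(ev$events), nrow(sim$truth$events))
  got <- dplyr::inner_join(ev$introns, sim$truth$introns,
                           by = c("gene_id", "cds_offset"))
  expect_equal(nrow(got), nrow(sim$truth$introns))
  # identical partitions: the two labelings are a bijection
  tab <- table(got$event_id.x, got$event_id.y)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("intron summaries respect conservation invariants", {
  catalog <- tibble::tibble(
    protein_id = c("a", "b", "c", "d"),
    group = c("A", "A", "B", "B")
  )
  introns <- tibble::tibble(
    gene_id = c("a", "a", "c"), intron_index = c(1L, 2L, 1L),
    phase = c(1L, 0L, 1L)
  )
  s <- intron_summary_tables(catalog, introns)
  expect_equal(s$total_genes, 4L)
  expect_equal(s$total_introns, 3L)
  # row sums equal group sizes
  expect_equal(s$by_group_count$total, c(2, 2))
  # one gene with two introns occupies exactly one cell of its class
  expect_equal(s$by_group_count$`2`[s$by_group_count$group == "A"], 1L)
  expect_equal(sum(s$phase_counts$n_introns), 3L)
  expect_error(
    intron_summary_tables(catalog, dplyr::mutate(introns, gene_id = "zz")),
    "zz")

  empty <- intron_summary_tables(catalog[0, ], introns[0, ])
  expect_equal(empty$total_genes, 0L)
})

test_that("published distribution marginals reproduce the family totals", {
  dist <- ugt_intron_distribution()
  s <- summarize_intron_distribution(dist)
  expect_equal(sum(s$group_totals$n_genes), s$total_genes)
  expect_equal(s$intronless_genes + s$intron_bearing_genes, s$total_genes)
  expect_equal(sum(s$class_totals$n_genes * s$class_totals$n_introns),
               s$total_introns)
})
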