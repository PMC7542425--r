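test_that("molecular weight matches the average-mass table and is additive", {
  expect_equal(compute_mw("G"), 57.0519 + 18.01524, tolerance = 1e-6)
  expect_equal(compute_mw("GG"), 2 * 57.0519 + 18.01524, tolerance = 1e-6)
  expect_error(compute_mw(""), "empty")
  expect_error(compute_mw("GZ"), "Z")

  set.seed(5)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (i in 1:20) {
    a <- paste(sample(aas, sample(1:30, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(1:30, 1), replace = TRUE), collapse = "")
    expect_equal(compute_mw(paste0(a, b)),
                 compute_mw(a) + compute_mw(b) - 18.01524,
                 tolerance = 1e-9)
  }
})

test_that("pI bisection agrees with a fine grid-search oracle", {
  expect_lt(compute_pi("DDDD"), 4.5)
  expect_equal(compute_pi("DDDD"), pi_grid_oracle("DDDD"), tolerance = 2e-4)
  expect_gt(compute_pi("KKKK"), 9.0)
  expect_equal(compute_pi("KKKK"), pi_grid_oracle("KKKK"), tolerance = 2e-4)

  set.seed(17)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  peptides <- vapply(1:100, function(i) {
    paste(sample(aas, sample(5:80, 1), replace = TRUE), collapse = "")
  }, character(1))
  got <- compute_pi(peptides)
  want <- vapply(peptides, pi_grid_oracle, numeric(1))
  expect_true(all(abs(got - want) < 2e-4))
  expect_true(all(got > 0 & got < 14))
})

test_that("the log-odds model follows the stated formula", {
  base <- strrep("A", 43)
  seeds <- paste0(c("A", "A", "A", "C"), base)   # column 1: A,A,A,C
  model <- build_pspg_model(seeds, pseudocount = 0.05)
  bg <- 1 / 20
  expect_equal(unname(model$log_odds[1, "A"]),
               log2(((3 + 0.05 * bg) / (4 + 0.05)) / bg))
  expect_equal(unname(model$log_odds[1, "C"]),
               log2(((1 + 0.05 * bg) / (4 + 0.05)) / bg))
  expect_equal(unname(model$log_odds[2, "A"]),
               log2(((4 + 0.05 * bg) / (4 + 0.05)) / bg))

  # identical seeds: every column's argmax is the seed residue
  consensus <- paste(rep(c("W", "Q", "H", "N"), 11), collapse = "")
  model2 <- build_pspg_model(rep(consensus, 10))
  argmax <- colnames(model2$log_odds)[apply(model2$log_odds, 1, which.max)]
  expect_equal(paste(argmax, collapse = ""), consensus)

  expect_error(build_pspg_model(character(0)), "empty")
  expect_error(build_pspg_model(strrep("A", 40)), "44")
  expect_error(build_pspg_model(paste0("-", strrep("A", 43))), "gap")
})

test_that("PSPG scan recovers planted motifs at their true offsets", {
  sim <- benchmark_sim()
  model <- build_pspg_model(sim$pspg_seeds)
  hits <- scan_pspg(sim$proteins, model)
  expect_equal(nrow(hits), nrow(sim$proteins))
  truth <- sim$truth$genes
  expect_equal(hits$start[match(truth$gene_id, hits$protein_id)],
               truth$motif_start)
  expect_true(all(hits$distance_to_cterm >= 0))

  # the consensus scores the column-maximum sum, the global maximum
  consensus <- paste(colnames(model$log_odds)[apply(model$log_odds, 1,
                                                    which.max)],
                     collapse = "")
  chit <- scan_pspg(tibble::tibble(id = "cons", residues = consensus), model)
  expect_equal(chit$score, model$consensus_score, tolerance = 1e-9)

  short <- scan_pspg(tibble::tibble(id = "s", residues = strrep("A", 40)),
                     model)
  expect_equal(nrow(short), 0L)
})

test_that("shuffled proteins essentially never reach the hit threshold", {
  sim <- benchmark_sim()
  model <- build_pspg_model(sim$pspg_seeds)
  p1 <- strsplit(sim$proteins$residues[1], "")[[1]]
  set.seed(99)
  shuffled <- tibble::tibble(
    id = sprintf("shuf%04d", 1:1000),
    residues = vapply(1:1000, function(i) {
      paste(sample(p1), collapse = "")
    }, character(1))
  )
  hits <- scan_pspg(shuffled, model)
  expect_lte(nrow(hits) / 1000, 0.01)
})

test_that("identify_family separates planted members from background noise", {
  sim <- benchmark_sim()
  model <- build_pspg_model(sim$pspg_seeds)
  members <- sim$proteins[1:60, ]
  negatives <- simulate_background_proteins(40, seed = 7)
  pool <- dplyr::bind_rows(members, negatives)
  catalog <- identify_family(pool, model)
  expect_setequal(catalog$protein_id, members$id)
  expect_true(all(catalog$chromosome == "chrUn"))
  expect_true(all(catalog$length >= 1))
  expect_true(all(catalog$mw > 0))
  expect_true(all(catalog$pi > 0 & catalog$pi < 14))

  # permutation invariance of membership and statistics
  perm <- pool[sample(nrow(pool)), ]
  catalog2 <- identify_family(perm, model)
  key <- function(x) dplyr::arrange(tibble::as_tibble(x), protein_id)
  expect_equal(key(catalog2), key(catalog))

  cmap <- tibble::tibble(gene_id = members$id[1], chromosome = "chr3")
  catalog3 <- identify_family(members[1:2, ], model, chromosome_map = cmap)
  expect_equal(catalog3$chromosome[match(members$id[1:2],
                                         catalog3$protein_id)],
               c("chr3", "chrUn"))

  empty <- identify_family(sim$proteins[0, ], model)
  expect_equal(nrow(empty), 0L)
})
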