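# The benchmark simulation (16 groups, ~120 genes, 10 planted events,
# seed 42) and its pipeline run are computed once and shared across test
# files.
.benchmark_cache <- new.env(parent = emptyenv())

benchmark_sim <- function() {
  if (is.null(.benchmark_cache$sim)) {
    .benchmark_cache$sim <- simulate_family(simulation_config(seed = 42))
  }
  .benchmark_cache$sim
}

benchmark_dir <- function() {
  if (is.null(.benchmark_cache$dir)) {
    dir <- file.path(tempdir(), "famscan-benchmark")
    write_simulation(benchmark_sim(), dir)
    .benchmark_cache$dir <- dir
  }
  .benchmark_cache$dir
}

benchmark_pipeline_config <- function(outdir = file.path(benchmark_dir(), "out")) {
  dir <- benchmark_dir()
  pipeline_config(
    proteins = file.path(dir, "proteins.fa"),
    pspg_seeds = file.path(dir, "pspg_seeds.fa"),
    gff3 = file.path(dir, "models.gff3"),
    msa = file.path(dir, "msa.afa"),
    counts = file.path(dir, "counts.tsv"),
    library_sizes = file.path(dir, "library_sizes.tsv"),
    references = file.path(dir, "references.tsv"),
    outdir = outdir
  )
}

benchmark_pipeline <- function() {
  if (is.null(.benchmark_cache$pipeline)) {
    .benchmark_cache$pipeline <- suppressMessages(
      run_pipeline(benchmark_pipeline_config()))
  }
  .benchmark_cache$pipeline
}

# Random count_table fixtures for expression property tests.
random_count_table <- function(n_genes, seed) {
  set.seed(seed)
  samples <- tidyr::expand_grid(tissue = c("flavedo", "albedo", "SM", "JS"),
                                stage = c("80", "140", "200"))
  samples$sample_id <- paste(samples$tissue, samples$stage, sep = "_")
  genes <- sprintf("g%03d", seq_len(n_genes))
  tab <- tidyr::expand_grid(gene_id = genes, sample_id = samples$sample_id)
  tab <- dplyr::left_join(tab, samples, by = "sample_id")
  tab$count <- rnbinom(nrow(tab), mu = 30, size = 0.4)
  tab$gene_length <- rep(sample(600:2400, n_genes, replace = TRUE),
                         each = nrow(samples))
  tab$library_size <- rep(1e7, nrow(tab))
  class(tab) <- c("count_table", class(tab))
  tab
}
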