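test_that("simulation is deterministic for a fixed seed", {
  cfg <- sim_config(list(sim_species("s", 1, list(
    list(type = "WGD", age = 30, retention = 0.7, label = "w")))),
    n_chrom = 1, genes_per_chrom = 60, codons_per_gene = 20, seed = 8)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$gene_sets, s2$gene_sets)
  expect_identical(s1$cds, s2$cds)
  expect_identical(s1$pairs, s2$pairs)
  expect_identical(s1$truth$pairs, s2$truth$pairs)
})

test_that("a no-event species reproduces the ancestor gene order", {
  cfg <- sim_config(list(sim_species("s", 1, list())),
                    n_chrom = 2, genes_per_chrom = 30,
                    emit_sequences = FALSE, seed = 9)
  sim <- simulate_dataset(cfg)
  gs <- sim$gene_sets$s
  expect_equal(nrow(gs), 60L)
  expect_null(sim$truth$pairs)
  # order along each chromosome follows ancestral rank
  anc <- sim$truth$ancestor_of[gs$gene_id[gs$chromosome == "s_c1"]]
  expect_equal(anc[order(gs$rank[gs$chromosome == "s_c1"])], sort(anc))
})

test_that("a lossless WGD gives exactly one homoeolog per gene, depth 2", {
  cfg <- sim_config(list(
    sim_species("ref", 1, list()),
    sim_species("tgt", 1, list(list(type = "WGD", age = 30, retention = 1,
                                    label = "w")))),
    n_chrom = 1, genes_per_chrom = 50, emit_sequences = FALSE, seed = 10)
  sim <- simulate_dataset(cfg)
  tp <- sim$truth$pairs[sim$truth$pairs$species == "tgt", ]
  expect_equal(nrow(tp), 50L)     # one homoeologous pair per ancestral gene
  blocks <- detect_blocks(sim$cross_pairs[["ref|tgt"]], sim$gene_sets$ref,
                          sim$gene_sets$tgt, collinearity_params())
  tab <- build_homology_table(sim$gene_sets$ref, list(tgt = blocks),
                              c(tgt = 2L))
  hd <- homology_depth(tab, "tgt")
  expect_equal(hd$modal_depth, 2L)
  expect_gt(hd$histogram[["2"]] / 50, 0.9)
})

test_that("truth record is consistent with the emitted gene sets", {
  cfg <- sim_config(list(sim_species("s", 1.1, list(
    list(type = "WGT", age = 80, retention = 0.6, label = "tri"),
    list(type = "WGD", age = 30, retention = 0.8, label = "w")))),
    n_chrom = 2, genes_per_chrom = 50, emit_sequences = FALSE, seed = 11)
  sim <- simulate_dataset(cfg)
  ids <- sim$gene_sets$s$gene_id
  tp <- sim$truth$pairs
  expect_true(all(c(tp$gene_a, tp$gene_b) %in% ids))
  expect_true(all(tp$event %in% c("tri", "w")))
  # dS bookkeeping: 2 x r x rate x age
  expect_equal(unique(tp$true_ds[tp$event == "w"]),
               2 * cfg$clock_rate * 1.1 * 30 * 1e6)
})

test_that("realized deletion runs recover the configured extension parameter", {
  cfg <- sim_config(list(sim_species("s", 1, list(
    list(type = "WGD", age = 30, retention = 0.5, label = "w")))),
    n_chrom = 1, genes_per_chrom = 3000, emit_sequences = FALSE,
    fractionation_p = 0.6, seed = 12)
  sim <- simulate_dataset(cfg)
  runs <- sim$truth$runs$length
  expect_gt(length(runs), 1000)
  h <- structure(list(counts = table(runs)), class = "run_histogram")
  expect_lt(abs(fit_geometric(h)$p - 0.6), 0.03)
})

test_that("evolve_pair respects the zero-divergence boundary", {
  anc <- random_cds(100)
  pr <- evolve_pair(anc, 0, seed = 1)
  expect_equal(pr$cds_a, anc)
  expect_equal(pr$cds_b, anc)
  expect_error(evolve_pair(strrep("ATG", 20), 0.5, seed = 1), "impossible")
})

test_that("rearrangement scripts relocate genes between chromosomes", {
  cfg <- sim_config(list(sim_species("s", 1, list(
    list(type = "WGD", age = 30, retention = 1, label = "w"),
    list(type = "script", lines = "EJ c1a c2a -> fused")))),
    n_chrom = 2, genes_per_chrom = 20, emit_sequences = FALSE, seed = 13)
  sim <- simulate_dataset(cfg)
  chroms <- unique(sim$gene_sets$s$chromosome)
  expect_setequal(chroms, c("s_fused", "s_c1b", "s_c2b"))
  expect_equal(sum(sim$gene_sets$s$chromosome == "s_fused"), 40L)
})

test_that("karyotype-derived gene sets keep ids unique and traceable", {
  k <- new_ancestral_karyotype(c("c1", "c2"), 25)
  tip <- replay_script(k, c("WGD", "EJ c1a c1b -> m +S1", "LOSS S1",
                            "NODE t"))$snapshots$t
  tg <- karyotype_to_gene_set(tip, "sp")
  expect_false(any(duplicated(tg$gene_set$gene_id)))
  expect_equal(nrow(tg$gene_set), 100L)  # content conserved
  expect_true(all(grepl("^c[12]\\.g\\d+$", tg$ancestor_of)))
})

test_that("written datasets are re-readable through genome_io", {
  cfg <- sim_config(list(sim_species("s", 1, list(
    list(type = "WGD", age = 30, retention = 0.8, label = "w")))),
    n_chrom = 1, genes_per_chrom = 30, codons_per_gene = 10, seed = 14)
  sim <- simulate_dataset(cfg)
  d <- tempfile()
  write_simulated_dataset(sim, d)
  gs <- read_gene_loci(file.path(d, "s.loci.tsv"), "bed-tsv")
  expect_equal(as.data.frame(gs), as.data.frame(sim$gene_sets$s))
  cds <- read_cds(file.path(d, "cds.fasta"))
  expect_equal(cds[names(sim$cds)], sim$cds)
  expect_true(file.exists(file.path(d, "truth.json")))
})
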