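ref10 <- function() toy_gene_set("ref", list(r1 = sprintf("r%02d", 1:10)))

block_df <- function(id, ref_genes, tgt_genes, ranks_a, ranks_b,
                     genome_b = "tgt", chr_b = "t1") {
  data.frame(block_id = id, genome_a = "ref", chr_a = "r1", gene_a = ref_genes,
             rank_a = ranks_a, genome_b = genome_b, chr_b = chr_b,
             gene_b = tgt_genes, rank_b = ranks_b, orientation = "parallel",
             stringsAsFactors = FALSE)
}

test_that("a single block fills one column, the rest stay dots", {
  ref <- ref10()
  blk <- block_df(1, sprintf("r%02d", 1:6), sprintf("t%02d", 1:6), 0:5, 0:5)
  tab <- build_homology_table(ref, list(tgt = blk), c(tgt = 2L))
  expect_equal(sum(tab$tgt.1 != "."), 6L)
  expect_equal(sum(tab$tgt.1 == "."), 4L)
  expect_true(all(tab$tgt.2 == "."))
  # conservation: dots + non-dots = rows x multiplicity
  cells <- as.matrix(tab[, c("tgt.1", "tgt.2")])
  expect_equal(sum(cells == ".") + sum(cells != "."), 10L * 2L)
})

test_that("overlapping blocks land in distinct columns as laid out by hand", {
  ref <- ref10()
  b1 <- block_df(1, sprintf("r%02d", 1:6), sprintf("t%02d", 1:6), 0:5, 0:5)
  b2 <- block_df(2, sprintf("r%02d", 4:9), sprintf("u%02d", 4:9), 3:8, 0:5,
                 chr_b = "t2")
  tab <- build_homology_table(ref, list(tgt = rbind(b1, b2)), c(tgt = 2L))
  expect_equal(tab$tgt.1[1:6], sprintf("t%02d", 1:6))
  expect_equal(tab$tgt.2[4:9], sprintf("u%02d", 4:9))
  expect_equal(tab$tgt.1[7:10], rep(".", 4))
})

test_that("no blocks means all dots; unknown genes are errors", {
  ref <- ref10()
  tab <- build_homology_table(ref, list(tgt = wgdkit:::empty_anchor_df()),
                              c(tgt = 3L))
  expect_true(all(as.matrix(tab[, paste0("tgt.", 1:3)]) == "."))
  expect_equal(homology_depth(tab, "tgt")$modal_depth, 0L)
  bad <- block_df(1, "nope", "t01", 0, 0)
  expect_error(build_homology_table(ref, list(tgt = bad), c(tgt = 2L)),
               "unknown reference gene")
})

test_that("loss rate is the dot fraction and survives relabeling", {
  ref <- ref10()
  blk <- block_df(1, sprintf("r%02d", 1:6), sprintf("t%02d", 1:6), 0:5, 0:5)
  tab <- build_homology_table(ref, list(tgt = blk), c(tgt = 4L))
  expect_equal(loss_rate(tab, "tgt"), (40 - 6) / 40)
  expect_error(loss_rate(tab, "nope"), "unknown genome")
  # relabeling reference chromosomes does not change the rate
  tab2 <- tab
  tab2$chromosome <- paste0("renamed_", tab2$chromosome)
  expect_equal(loss_rate(tab2, "tgt"), loss_rate(tab, "tgt"))
})

test_that("homology depth matches the binomial expectation under random loss", {
  set.seed(13)
  n <- 2000
  ref <- toy_gene_set("ref", list(r1 = sprintf("r%04d", 1:n)))
  keep <- matrix(runif(n * 4) < 0.5, n, 4)
  blocks <- do.call(rbind, lapply(1:4, function(ci) {
    rows <- which(keep[, ci])
    block_df(ci, sprintf("r%04d", rows), sprintf("t%d_%04d", ci, rows),
             rows - 1L, seq_along(rows) - 1L, chr_b = paste0("t", ci))
  }))
  tab <- build_homology_table(ref, list(tgt = blocks), c(tgt = 4L))
  hd <- homology_depth(tab, "tgt")
  expected <- dbinom(0:4, 4, 0.5) * n
  expect_true(all(abs(hd$histogram - expected) < 4 * sqrt(expected + 1)))
  expect_equal(sum(hd$histogram), n)
})

test_that("translocation fraction counts best hits outside all columns", {
  ref <- ref10()
  blk <- block_df(1, sprintf("r%02d", 1:8), sprintf("t%02d", 1:8), 0:7, 0:7)
  tab <- build_homology_table(ref, list(tgt = blk), c(tgt = 2L))
  bh <- data.frame(gene_a = sprintf("r%02d", 1:10),
                   gene_b = c(sprintf("t%02d", 1:8), "x1", "x2"))
  expect_equal(translocation_fraction(bh, tab, "tgt"), 0.2)
  bh_all <- bh[1:8, ]
  expect_equal(translocation_fraction(bh_all, tab, "tgt"), 0)
})

test_that("deletion runs follow the bordered-run definition", {
  ref <- ref10()
  # pattern along r1: G . G . . G G G G G  (gene, dot, ...)
  pat <- c("t1", ".", "t3", ".", ".", "t6", "t7", "t8", "t9", "t10")
  blk <- block_df(1, sprintf("r%02d", which(pat != ".")),
                  pat[pat != "."], which(pat != ".") - 1L,
                  seq_len(sum(pat != ".")) - 1L)
  tab <- build_homology_table(ref, list(tgt = blk), c(tgt = 1L))
  rh <- deletion_run_histogram(tab, "tgt", 1)
  expect_equal(rh$counts, c(`1` = 1L, `2` = 1L))
  expect_equal(rh$genes_in_runs, 3L)
  expect_equal(rh$short_run_gene_fraction, 1.0)
  expect_equal(rh$end_runs, 0L)
})

test_that("an all-dot column has no bordered runs, one end run", {
  ref <- ref10()
  tab <- build_homology_table(ref, list(tgt = wgdkit:::empty_anchor_df()),
                              c(tgt = 1L))
  rh <- deletion_run_histogram(tab, "tgt", 1)
  expect_equal(rh$n_runs, 0L)
  expect_equal(rh$end_runs, 1L)
})

test_that("run finding equals a regex oracle on random patterns", {
  set.seed(17)
  for (rep in 1:20) {
    n <- 60
    is_dot <- runif(n) < 0.4
    ids <- sprintf("r%03d", 1:n)
    ref <- toy_gene_set("ref", list(r1 = ids))
    kept <- which(!is_dot)
    if (length(kept) < 2) next
    blk <- block_df(1, ids[kept], sprintf("t%03d", kept), kept - 1L,
                    seq_along(kept) - 1L)
    tab <- build_homology_table(ref, list(tgt = blk), c(tgt = 1L))
    rh <- deletion_run_histogram(tab, "tgt", 1)
    want <- oracle_bordered_runs(paste(ifelse(is_dot, ".", "G"), collapse = ""))
    got <- rep(as.integer(names(rh$counts)), rh$counts)
    expect_equal(sort(got), sort(as.integer(want)))
  }
})

test_that("geometric MLE closed form: boundaries and simple cases", {
  h1 <- structure(list(counts = c(`1` = 5L)), class = "run_histogram")
  expect_equal(fit_geometric(h1)$p, 0)
  h2 <- structure(list(counts = c(`2` = 2L)), class = "run_histogram")
  expect_equal(fit_geometric(h2)$p, 0.5)
  expect_error(fit_geometric(list(counts = integer(0))), "no runs")
})

test_that("geometric MLE matches grid-search likelihood maximisation", {
  set.seed(19)
  lens <- 1L + rgeom(2000, 1 - 0.6)
  h <- structure(list(counts = table(lens)), class = "run_histogram")
  fit <- fit_geometric(h)
  expect_lt(abs(fit$p - 0.6), 0.03)
  expect_lt(abs(fit$p - oracle_geometric_mle(lens)), 1e-4)
  # MLE identity p = 1 - 1/mean
  expect_equal(fit$p, 1 - 1 / fit$mean_length)
})

test_that("pooling run histograms preserves totals", {
  h1 <- structure(list(counts = c(`1` = 2L, `3` = 1L), n_runs = 3L,
                       genes_in_runs = 5L, short_run_gene_fraction = 0.4,
                       end_runs = 1L), class = "run_histogram")
  h2 <- structure(list(counts = c(`2` = 2L), n_runs = 2L, genes_in_runs = 4L,
                       short_run_gene_fraction = 1, end_runs = 0L),
                  class = "run_histogram")
  pooled <- pool_run_histograms(h1, h2)
  expect_equal(pooled$n_runs, 5L)
  expect_equal(pooled$genes_in_runs, 9L)
  expect_equal(pooled$end_runs, 1L)
})
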