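test_that("the 10-codon glycine worked case gives the classic NG86 numbers", {
  a <- strrep("GGG", 10)
  b <- paste0(strrep("GGG", 9), "GGA")
  est <- ng86_estimate(list(seq_a = a, seq_b = b))
  expect_equal(est$S, 10)
  expect_equal(est$N, 20)
  expect_equal(est$sd, 1)
  expect_equal(est$nd, 0)
  expect_equal(est$pS, 0.1)
  expect_equal(est$Ks, 0.1073256, tolerance = 1e-4)  # -(3/4) log(1 - 4/30)
  expect_equal(est$Ka, 0)
  expect_false(est$saturated)
})

test_that("NG86 matches the Biopython reference implementation", {
  set.seed(9)
  cases <- list(
    list(a = strrep("GGG", 10), b = paste0(strrep("GGG", 9), "GGA")))
  for (d in c(0.1, 0.4)) {
    pr <- evolve_pair(random_cds(300), d, seed = 9)
    cases[[length(cases) + 1]] <- list(a = pr$cds_a, b = pr$cds_b)
  }
  # a pair with nonsynonymous differences as well
  pr <- evolve_pair(random_cds(200), 0.3, seed = 10)
  mut <- pr$cds_b
  substr(mut, 4, 4) <- "A"; substr(mut, 31, 31) <- "A"  # A-initial codons are never stops
  cases[[length(cases) + 1]] <- list(a = pr$cds_a, b = mut)
  for (cs in cases) {
    est <- ng86_estimate(list(seq_a = cs$a, seq_b = cs$b))
    ref <- oracle_ng86_biopython(cs$a, cs$b)
    expect_equal(est$Ks, ref$ks, tolerance = 1e-4)
    expect_equal(est$Ka, ref$ka, tolerance = 1e-4)
  }
})

test_that("NG86 basics: zero distance, saturation, symmetry, site conservation", {
  a <- "ATGGCTAAGCTTGGAACCGTT"
  expect_equal(ng86_estimate(list(seq_a = a, seq_b = a))$Ks, 0)
  expect_equal(ng86_estimate(list(seq_a = a, seq_b = a))$Ka, 0)

  # every codon differs at a synonymous third position: pS = 1 >= 3/4
  sat <- ng86_estimate(list(seq_a = strrep("GGG", 10), seq_b = strrep("GGA", 10)))
  expect_true(sat$saturated)
  expect_true(is.na(sat$Ks))

  set.seed(31)
  for (i in 1:10) {
    anc <- random_cds(50)
    pr <- evolve_pair(anc, runif(1, 0, 0.6), seed = i)
    e1 <- ng86_estimate(list(seq_a = pr$cds_a, seq_b = pr$cds_b))
    e2 <- ng86_estimate(list(seq_a = pr$cds_b, seq_b = pr$cds_a))
    expect_equal(e1$Ks, e2$Ks)
    expect_equal(e1$Ka, e2$Ka)
    expect_equal(e1$S + e1$N, 3 * e1$n_codons, tolerance = 1e-6)
  }
})

test_that("codon alignment handles identity, insertions and stops", {
  a <- "ATGGCTAAGCTTGGAACCGTTGCTGCTTAA"   # 10 codons, terminal stop
  aln <- build_codon_alignment(a, a)
  expect_equal(aln$n_codons, 9L)            # stop trimmed
  expect_equal(aln$seq_a, aln$seq_b)

  # one extra in-frame codon in b: the gapped column is dropped
  b <- "ATGGCTAAGCACCACCACCTTGGAACCGTTGCTGCT"
  a2 <- "ATGGCTAAGCTTGGAACCGTTGCTGCT"
  aln2 <- build_codon_alignment(a2, b)
  expect_equal(aln2$n_codons, 9L)

  expect_error(build_codon_alignment("ATGTAAGCT", "ATGTAAGCT"), "stop")

  # codons containing ambiguous bases are removed
  aln3 <- build_codon_alignment("ATGGCTAANCTT", "ATGGCTAAGCTT")
  expect_equal(aln3$n_codons, 3L)
})

test_that("alignment length matches the protein mapping on mismatched pairs", {
  set.seed(5)
  anc <- random_cds(200)
  pr <- evolve_pair(anc, 0.1, seed = 5)
  aln <- build_codon_alignment(pr$cds_a, pr$cds_b)
  expect_equal(aln$n_codons, 200L)   # no indels: every column survives
})

test_that("block median Ks follows the median conventions", {
  est <- data.frame(gene_a = c("a1", "a2", "a3", "a4"),
                    gene_b = c("b1", "b2", "b3", "b4"),
                    Ks = c(0.1, 0.3, 0.5, NA), saturated = c(F, F, F, TRUE))
  blk3 <- data.frame(gene_a = c("a1", "a2", "a3"), gene_b = c("b1", "b2", "b3"))
  expect_equal(block_median_ks(blk3, est), 0.3)
  blk2 <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"))
  expect_equal(block_median_ks(blk2, est), 0.2)
  blk_sat <- data.frame(gene_a = "a4", gene_b = "b4")
  expect_warning(res <- block_median_ks(blk_sat, est), "no usable")
  expect_true(is.na(res))
})

test_that("median of many anchors equals the sorting oracle", {
  set.seed(77)
  n <- 1000
  ks <- rlnorm(n, -1, 0.5)
  est <- data.frame(gene_a = sprintf("a%04d", 1:n),
                    gene_b = sprintf("b%04d", 1:n), Ks = ks, saturated = FALSE)
  blk <- est[, c("gene_a", "gene_b")]
  s <- sort(ks)
  expect_equal(block_median_ks(blk, est), (s[n / 2] + s[n / 2 + 1]) / 2)
})

test_that("simulated synonymous divergence is recovered within 10%", {
  anc <- random_cds(30000)
  for (d in c(0.1, 0.5, 1.0)) {
    pr <- evolve_pair(anc, d, seed = 3)
    est <- ng86_estimate(build_codon_alignment(pr$cds_a, pr$cds_b))
    expect_lt(abs(est$Ks - d) / d, 0.10)
    expect_lt(est$Ka, 0.01)
  }
})
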