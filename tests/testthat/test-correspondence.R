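test_that("a single block yields a single-member profile", {
  inst <- toy_anchor_instance(0:5, 0:5)
  blocks <- detect_blocks(inst$pairs, inst$loci_a, inst$loci_b,
                          collinearity_params())
  prof <- correspondence_profile(blocks)
  expect_equal(prof$by_target, list(chrB = "chrA"))
  expect_equal(prof$combinations$combination, "chrA")
  expect_equal(prof$combinations$count, 1L)
})

test_that("a hand-built dot plot is tabulated correctly", {
  # target t1 shows A and B; t2 shows A and B; t3 shows only A
  ga <- sprintf("a%02d", 1:20); gb <- sprintf("b%02d", 1:20)
  loci_ref <- toy_gene_set("ref", list(A = ga, B = gb))
  t1 <- sprintf("t1_%02d", 1:12); t2 <- sprintf("t2_%02d", 1:12)
  t3 <- sprintf("t3_%02d", 1:6)
  loci_tgt <- toy_gene_set("tgt", list(t1 = t1, t2 = t2, t3 = t3))
  pairs <- rbind(
    data.frame(gene_a = ga[1:6], gene_b = t1[1:6], score = 1),
    data.frame(gene_a = gb[1:6], gene_b = t1[7:12], score = 1),
    data.frame(gene_a = ga[7:12], gene_b = t2[1:6], score = 1),
    data.frame(gene_a = gb[7:12], gene_b = t2[7:12], score = 1),
    data.frame(gene_a = ga[13:18], gene_b = t3[1:6], score = 1))
  blocks <- detect_blocks(pairs, loci_ref, loci_tgt, collinearity_params())
  prof <- correspondence_profile(blocks, min_anchors = 5)
  cmb <- prof$combinations
  expect_equal(cmb$count[cmb$combination == "A+B"], 2L)
  expect_equal(cmb$count[cmb$combination == "A"], 3L)
  # t1 and t2 show A and B, t3 only A: no target exhibits exactly {B}
  expect_false("B" %in% cmb$combination)
  expect_equal(prof$by_target, list(t1 = c("A", "B"), t2 = c("A", "B"),
                                    t3 = "A"))
})

test_that("two WGDs without rearrangement give every combination count 4", {
  k <- new_ancestral_karyotype(c("c1", "c2"), 40, node_label = "anc")
  tip <- replay_script(k, c("WGD", "WGD", "NODE tip"))$snapshots$tip
  tg <- karyotype_to_gene_set(tip, "tgt")
  rg <- karyotype_to_gene_set(k, "ref")
  pairs <- pairs_from_ancestry(c(rg$ancestor_of, tg$ancestor_of))
  pairs <- pairs[xor(grepl("^ref", pairs$gene_a), grepl("^ref", pairs$gene_b)), ]
  swap <- grepl("^tgt", pairs$gene_a)
  tmp <- pairs$gene_a[swap]
  pairs$gene_a[swap] <- pairs$gene_b[swap]
  pairs$gene_b[swap] <- tmp
  blocks <- detect_blocks(pairs, rg$gene_set, tg$gene_set,
                          collinearity_params())
  prof <- correspondence_profile(blocks, min_anchors = 5)
  expect_true(all(prof$combinations$count == 4L))
})

test_that("merge timing follows the 4/2/1 parsimony rule", {
  prof <- structure(list(
    by_target = list(),
    combinations = data.frame(
      combination = c("A+B", "C+D", "E+F", "G+H", "A"),
      size = c(2L, 2L, 2L, 2L, 1L),
      count = c(4L, 2L, 1L, 3L, 4L))), class = "correspondence_profile")
  tm <- infer_merge_timing(prof)
  expect_equal(tm$timing[tm$combination == "A+B"], "pre-omega")
  expect_equal(tm$timing[tm$combination == "C+D"], "post-omega/pre-alpha")
  expect_equal(tm$timing[tm$combination == "E+F"], "post-alpha")
  expect_equal(tm$timing[tm$combination == "G+H"], "ambiguous")
  expect_equal(tm$timing[tm$combination == "A"], "single")
})

test_that("simulated fusions at all three epochs are classified exactly", {
  anc <- new_ancestral_karyotype(paste0("c", 1:6), 60, node_label = "anc")
  lines <- c("EJ c1 c2 -> f12 +S1", "LOSS S1", "WGD",
             "EJ c3a c4a -> f34 +S2", "LOSS S2", "WGD",
             "EJ c5aa c6aa -> f56 +S3", "LOSS S3", "NODE tip")
  tip <- replay_script(anc, lines)$snapshots$tip
  tg <- karyotype_to_gene_set(tip, "tgt")
  rg <- karyotype_to_gene_set(anc, "ref")
  pairs <- pairs_from_ancestry(c(rg$ancestor_of, tg$ancestor_of))
  pairs <- pairs[xor(grepl("^ref", pairs$gene_a), grepl("^ref", pairs$gene_b)), ]
  swap <- grepl("^tgt", pairs$gene_a)
  tmp <- pairs$gene_a[swap]
  pairs$gene_a[swap] <- pairs$gene_b[swap]
  pairs$gene_b[swap] <- tmp
  blocks <- detect_blocks(pairs, rg$gene_set, tg$gene_set,
                          collinearity_params())
  tm <- infer_merge_timing(correspondence_profile(blocks, min_anchors = 5))
  tm2 <- tm[tm$size == 2, ]
  expect_equal(tm2$timing[tm2$combination == "ref_c1+ref_c2"], "pre-omega")
  expect_equal(tm2$timing[tm2$combination == "ref_c3+ref_c4"],
               "post-omega/pre-alpha")
  expect_equal(tm2$timing[tm2$combination == "ref_c5+ref_c6"], "post-alpha")
  expect_equal(nrow(tm2), 3L)
})
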