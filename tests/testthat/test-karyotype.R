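test_that("WGT triples and WGD doubles the non-satellite count", {
  k <- new_ancestral_karyotype(paste0("E", 1:7), 50)
  k3 <- apply_event(k, karyotype_event("WGT"))
  expect_equal(chromosome_count(k3), 21L)
  expect_true(all(c("E1a", "E1b", "E1c") %in% names(k3$chromosomes)))
  k2 <- apply_event(k, karyotype_event("WGD"))
  expect_equal(chromosome_count(k2), 14L)
})

test_that("end-to-end joining conserves content and emits a satellite", {
  k <- new_ancestral_karyotype(c("c1", "c2", "c3"), c(10, 20, 30))
  ej <- karyotype_event("EJ", operands = c("c1", "c2"), products = "f",
                        satellite = "S1")
  k2 <- apply_event(k, ej)
  expect_equal(chromosome_count(k2), 2L)   # -2 +1, satellite not counted
  expect_true(k2$chromosomes$S1$is_satellite)
  expect_equal(segment_content(k2)[c("c1", "c2", "c3")],
               segment_content(k)[c("c1", "c2", "c3")])
  expect_equal(wgdkit:::chrom_length(k2$chromosomes$f), 30L)
})

test_that("nested fusion inserts the whole chromosome at the breakpoint", {
  k <- new_ancestral_karyotype(c("c1", "c2"), c(10, 20))
  k2 <- apply_event(k, karyotype_event("NCF", operands = c("c1", "c2"),
                                       breakpoints = 5, products = "n",
                                       satellite = "S1"))
  segs <- k2$chromosomes$n$segments
  expect_equal(segs$source, c("c2", "c1", "c2"))
  expect_equal(segs$start, c(1L, 1L, 6L))
  expect_equal(segs$end, c(5L, 10L, 20L))
})

test_that("crossover swaps distal arms at the breakpoints", {
  k <- new_ancestral_karyotype(c("c1", "c2"), c(10, 20))
  k2 <- apply_event(k, karyotype_event("X", operands = c("c1", "c2"),
                                       breakpoints = c(4, 15),
                                       products = c("p1", "p2")))
  expect_equal(wgdkit:::chrom_length(k2$chromosomes$p1), 4L + 5L)
  expect_equal(wgdkit:::chrom_length(k2$chromosomes$p2), 15L + 6L)
  expect_equal(segment_content(k2), segment_content(k))
})

test_that("inversion is an involution", {
  k <- new_ancestral_karyotype("c1", 20)
  inv <- karyotype_event("Inv", operands = "c1", breakpoints = c(4, 9))
  k1 <- apply_event(k, inv)
  trav <- function(kk) wgdkit:::segment_traversal(kk$chromosomes$c1)
  expect_false(identical(trav(k1), trav(k)))
  k2 <- apply_event(k1, inv)
  expect_equal(trav(k2), trav(k))   # gene-order traversal restored
  expect_equal(segment_content(k1), segment_content(k))
})

test_that("event preconditions are enforced", {
  k <- new_ancestral_karyotype("c1", 10)
  expect_error(apply_event(k, karyotype_event("SatLoss", operands = "c1")),
               "non-satellite")
  expect_error(apply_event(k, karyotype_event("EJ", operands = c("c1", "zz"),
                                              products = "f")), "unknown")
  expect_error(apply_event(k, karyotype_event("X", operands = c("c1", "c1"),
                                              breakpoints = c(99, 1))),
               "out of range")
})

test_that("the event DSL round-trips through parse and format", {
  lines <- c("NODE E", "WGT", "X c1@12 c2@30 -> n1 n2",
             "EJ c3 c4 -> c5 +S1", "NCF c6 c7@15 -> c8 +S2",
             "INV c5 4..9", "LOSS S1", "REN old new")
  script <- parse_event_script(lines)
  expect_equal(format_event_script(script), lines)
  expect_error(parse_event_script("FROB c1"), "line 1")
})

test_that("an empty script replays to a single snapshot of the initial state", {
  k <- new_ancestral_karyotype(c("c1", "c2"), 10, node_label = "root")
  rep <- replay_script(k, character(0))
  expect_equal(names(rep$snapshots), "root")
  expect_equal(chromosome_count(rep$snapshots$root), 2L)
})

test_that("the packaged trajectory reproduces the published node counts", {
  rep <- replay_script(eudicot_ancestor(100), apiaceae_trajectory_script())
  counts <- setNames(rep$summary$n_chromosomes, rep$summary$node)
  expect_equal(counts[["E"]], 7L)
  expect_equal(counts[["H"]], 21L)
  expect_equal(counts[["P"]], 8L)
  expect_equal(counts[["Q"]], 10L)
  expect_equal(counts[["R"]], 11L)
  expect_equal(rep$summary$n_satellites, rep(0L, 5))  # all satellites lost
})

test_that("segment content is conserved through the full trajectory", {
  k0 <- eudicot_ancestor(100)
  rep <- replay_script(k0, apiaceae_trajectory_script())
  # after WGT + 2 WGDs every ancestral unit is present 12 times
  content <- segment_content(rep$final)
  expect_setequal(names(content), paste0("E", 1:7))
  for (src in names(content))
    expect_equal(as.vector(table(content[[src]])), rep(12L, 100))
})

test_that("random event sequences conserve content up to satellite loss", {
  set.seed(29)
  for (rep_i in 1:10) {
    k <- new_ancestral_karyotype(paste0("c", 1:4), sample(20:40, 4))
    base <- segment_content(k)
    for (step in 1:6) {
      ids <- names(k$chromosomes)[!vapply(k$chromosomes, `[[`, logical(1),
                                          "is_satellite")]
      kind <- sample(c("EJ", "X", "Inv"), 1)
      if (kind == "EJ" && length(ids) >= 2) {
        ops <- sample(ids, 2)
        k <- apply_event(k, karyotype_event("EJ", operands = ops,
                                            products = paste0("m", step),
                                            satellite = paste0("S", step)))
        k <- apply_event(k, karyotype_event("SatLoss",
                                            operands = paste0("S", step)))
      } else if (kind == "X" && length(ids) >= 2) {
        ops <- sample(ids, 2)
        l1 <- wgdkit:::chrom_length(k$chromosomes[[ops[1]]])
        l2 <- wgdkit:::chrom_length(k$chromosomes[[ops[2]]])
        k <- apply_event(k, karyotype_event(
          "X", operands = ops, breakpoints = c(sample(l1 - 1, 1),
                                               sample(l2 - 1, 1)),
          products = paste0("x", step, c("a", "b"))))
      } else {
        ch <- sample(ids, 1)
        l <- wgdkit:::chrom_length(k$chromosomes[[ch]])
        if (l < 3) next
        ab <- sort(sample(l, 2))
        k <- apply_event(k, karyotype_event("Inv", operands = ch,
                                            breakpoints = ab))
      }
    }
    expect_equal(segment_content(k)[names(base)], base)
  }
})
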