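#' Chromosome correspondence profile from collinear blocks
#'
#' For each target chromosome, the set of reference chromosomes it shows
#' homology to (blocks with at least `min_anchors` anchors), and for every
#' observed reference-chromosome combination the number of distinct target
#' chromosomes containing all of its members. Repeated co-occurrence of the
#' same ancestral combination across target chromosomes carries the timing
#' signal of chromosome fusions relative to the polyploidies.
#'
#' @param blocks anchor data.frame from [detect_blocks()] (reference as side
#'   `a`, target as side `b`).
#' @param min_anchors minimal anchors for a block to count.
#' @return list of class `correspondence_profile`: `by_target` (named list,
#'   target chromosome -> character vector of reference chromosomes) and
#'   `combinations` (data.frame `combination`, `size`, `count`).
#' @export
correspondence_profile <- function(blocks, min_anchors = 1L) {
  bs <- block_summary(blocks)
  bs <- bs[bs$n_anchors >= min_anchors, , drop = FALSE]
  by_target <- lapply(split(bs$chr_a, bs$chr_b), function(x) sort(unique(x)))
  combos <- unique(unname(vapply(by_target, paste, character(1), collapse = "+")))
  counts <- vapply(combos, function(cb) {
    members <- strsplit(cb, "+", fixed = TRUE)[[1]]
    sum(vapply(by_target, function(s) all(members %in% s), logical(1)))
  }, integer(1))
  combinations <- data.frame(
    combination = combos,
    size = lengths(strsplit(combos, "+", fixed = TRUE)),
    count = unname(counts), stringsAsFactors = FALSE)
  combinations <- combinations[order(-combinations$size,
                                     combinations$combination), , drop = FALSE]
  rownames(combinations) <- NULL
  structure(list(by_target = by_target, combinations = combinations),
            class = "correspondence_profile")
}

#' Parsimony timing of chromosome mergers relative to two WGDs
#'
#' With two rounds of doubling after the mergers in question, a
#' reference-chromosome combination present on 4 target chromosomes merged
#' before the first WGD; one present twice merged between the two WGDs; one
#' present once merged after the second. Other counts are flagged ambiguous.
#' The expected counts generalise to the running product of the configured
#' ploidy multipliers.
#'
#' @param profile a [correspondence_profile()].
#' @param ploidy_series ordered event multipliers after the candidate
#'   mergers (default `c(2, 2)`: two WGDs).
#' @param labels class labels, oldest first; length
#'   `length(ploidy_series) + 1`.
#' @return data.frame `combination`, `size`, `count`, `timing`.
#' @export
infer_merge_timing <- function(profile, ploidy_series = c(2L, 2L),
                               labels = c("pre-omega", "post-omega/pre-alpha",
                                          "post-alpha")) {
  stopifnot(length(labels) == length(ploidy_series) + 1L)
  expected <- rev(cumprod(rev(ploidy_series)))   # oldest first, e.g. 4, 2
  expected <- c(expected, 1L)                    # ... then 1 = after all WGDs
  cmb <- profile$combinations
  timing <- vapply(cmb$count, function(ct) {
    hit <- which(expected == ct)
    if (length(hit)) labels[hit[1]] else "ambiguous"
  }, character(1))
  timing[cmb$size < 2] <- "single"   # not a merger
  out <- cmb
  out$timing <- timing
  out
}
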