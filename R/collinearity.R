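#' Collinearity detection parameters
#'
#' Defaults follow common practice for plant paleogenomics: a maximal gap of
#' 50 intervening genes between neighbouring anchors, removal of homologous
#' families larger than 30 genes before chaining, and acceptance of chains
#' with at least 5 anchors.
#'
#' @param max_gap maximal number of intervening gene ranks between
#'   consecutive anchors, on each chromosome separately.
#' @param max_family_size families (connected components of the pair graph)
#'   larger than this are removed before chaining.
#' @param min_anchors minimal anchors per emitted block.
#' @param orientation chain orientation(s) to consider.
#' @return list of class `collinearity_params`.
#' @export
collinearity_params <- function(max_gap = 50L, max_family_size = 30L,
                                min_anchors = 5L,
                                orientation = c("both", "parallel", "antiparallel")) {
  orientation <- match.arg(orientation)
  stopifnot(max_gap >= 1, min_anchors >= 2, max_family_size >= 1)
  structure(list(max_gap = as.integer(max_gap),
                 max_family_size = as.integer(max_family_size),
                 min_anchors = as.integer(min_anchors),
                 orientation = orientation),
            class = "collinearity_params")
}

#' Remove pairs belonging to oversized gene families
#'
#' A family is a connected component of the homolog-pair graph. All pairs
#' touching a component with more than `max_family_size` genes are removed;
#' large families (tandem arrays, transposon-derived genes) otherwise swamp
#' the chaining with spurious anchors.
#'
#' @param pairs homolog pair data.frame (`gene_a`, `gene_b`, ...).
#' @param max_family_size size threshold in genes.
#' @return filtered pair data.frame.
#' @export
filter_families <- function(pairs, max_family_size = 30L) {
  if (!nrow(pairs)) return(pairs)
  g <- igraph::graph_from_data_frame(pairs[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  big <- which(comp$csize > max_family_size)
  if (!length(big)) return(pairs)
  bad_genes <- names(comp$membership)[comp$membership %in% big]
  keep <- !(pairs$gene_a %in% bad_genes | pairs$gene_b %in% bad_genes)
  wgd_log("filter_families: removed %d of %d pairs in %d oversized families",
          sum(!keep), nrow(pairs), length(big))
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Longest gap-constrained chain by dynamic programming.
# ra, rb: anchor ranks sorted by (ra, rb). Returns indices of the best chain,
# ties broken by smaller start rank. anti = TRUE chains strictly decreasing rb.
chain_dp <- function(ra, rb, max_gap, anti = FALSE) {
  n <- length(ra)
  if (!n) return(integer(0))
  score <- rep(1L, n)
  prev <- rep(0L, n)
  for (j in seq_len(n)) {
    if (j == 1L) next
    i <- seq_len(j - 1L)
    da <- ra[j] - ra[i]
    db <- if (anti) rb[i] - rb[j] else rb[j] - rb[i]
    ok <- da > 0L & (da - 1L) <= max_gap & db > 0L & (db - 1L) <= max_gap
    if (any(ok)) {
      cand <- score[i][ok]
      best <- max(cand)
      if (best + 1L > score[j]) {
        score[j] <- best + 1L
        # among equal-score predecessors prefer the earliest (smallest ra)
        prev[j] <- i[ok][which.max(cand)]
      }
    }
  }
  top <- max(score)
  ends <- which(score == top)
  # tie-break: chain with smallest start rank
  chains <- lapply(ends, function(e) {
    idx <- integer(0)
    while (e != 0L) { idx <- c(e, idx); e <- prev[e] }
    idx
  })
  starts <- vapply(chains, function(ch) ra[ch[1]], numeric(1))
  chains[[which.min(starts)]]
}

#' Detect collinear blocks between two gene sets
#'
#' Per chromosome pair, maximal gap-constrained chains of anchors are
#' extracted greedily by descending anchor count (ties: smaller start rank);
#' anchors of an emitted block are removed before re-chaining. Chains run
#' strictly increasing in both ranks (parallel) or increasing/decreasing
#' (antiparallel); consecutive anchors may skip at most `max_gap` intervening
#' gene ranks on either chromosome.
#'
#' @param pairs homolog pair data.frame.
#' @param loci_a,loci_b [gene_set()]s the pairs refer to. For intra-genome
#'   comparison pass the same object twice.
#' @param params a [collinearity_params()].
#' @return anchor data.frame, one row per anchor, columns
#'   `block_id genome_a chr_a gene_a rank_a genome_b chr_b gene_b rank_b
#'   orientation`, ordered by (chr_a, chr_b, block, rank_a).
#' @export
detect_blocks <- function(pairs, loci_a, loci_b, params = collinearity_params()) {
  stopifnot(inherits(params, "collinearity_params"))
  if (!nrow(pairs)) return(empty_anchor_df())
  ia <- match(pairs$gene_a, loci_a$gene_id)
  ib <- match(pairs$gene_b, loci_b$gene_id)
  known <- !is.na(ia) & !is.na(ib)
  if (any(!known))
    wgd_log("detect_blocks: skipped %d pairs with unknown gene ids", sum(!known))
  pairs <- pairs[known, , drop = FALSE]
  ia <- ia[known]; ib <- ib[known]
  if (!nrow(pairs)) return(empty_anchor_df())
  an <- data.frame(gene_a = pairs$gene_a, chr_a = loci_a$chromosome[ia],
                   rank_a = loci_a$rank[ia],
                   gene_b = pairs$gene_b, chr_b = loci_b$chromosome[ib],
                   rank_b = loci_b$rank[ib], stringsAsFactors = FALSE)
  an <- an[!duplicated(an[, c("gene_a", "gene_b")]), , drop = FALSE]
  out <- list()
  for (grp in split(an, list(an$chr_a, an$chr_b), drop = TRUE)) {
    grp <- grp[order(grp$rank_a, grp$rank_b), , drop = FALSE]
    repeat {
      if (nrow(grp) < params$min_anchors) break
      ch_par <- if (params$orientation %in% c("both", "parallel"))
        chain_dp(grp$rank_a, grp$rank_b, params$max_gap, anti = FALSE) else integer(0)
      ch_anti <- if (params$orientation %in% c("both", "antiparallel"))
        chain_dp(grp$rank_a, grp$rank_b, params$max_gap, anti = TRUE) else integer(0)
      if (length(ch_par) >= length(ch_anti)) {
        ch <- ch_par; orient <- "parallel"
      } else {
        ch <- ch_anti; orient <- "antiparallel"
      }
      if (length(ch) < params$min_anchors) break
      blk <- grp[ch, , drop = FALSE]
      blk$orientation <- orient
      out[[length(out) + 1L]] <- blk
      grp <- grp[-ch, , drop = FALSE]
    }
  }
  if (!length(out)) return(empty_anchor_df())
  # deterministic block order: chrom pair, then start rank
  starts <- vapply(out, function(b) b$rank_a[1], numeric(1))
  keys <- vapply(out, function(b) paste(b$chr_a[1], b$chr_b[1]), character(1))
  ord <- order(keys, starts)
  out <- out[ord]
  res <- do.call(rbind, lapply(seq_along(out), function(i) {
    b <- out[[i]]
    data.frame(block_id = i, genome_a = loci_a$genome[1], chr_a = b$chr_a,
               gene_a = b$gene_a, rank_a = b$rank_a,
               genome_b = loci_b$genome[1], chr_b = b$chr_b,
               gene_b = b$gene_b, rank_b = b$rank_b,
               orientation = b$orientation, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Summarise blocks (one row per block)
#' @param blocks anchor data.frame from [detect_blocks()].
#' @return data.frame with per-block anchor counts and spans.
#' @export
block_summary <- function(blocks) {
  if (!nrow(blocks))
    return(data.frame(block_id = integer(0), chr_a = character(0),
                      chr_b = character(0), n_anchors = integer(0),
                      orientation = character(0)))
  sp <- split(blocks, blocks$block_id)
  do.call(rbind, lapply(sp, function(b) data.frame(
    block_id = b$block_id[1], chr_a = b$chr_a[1], chr_b = b$chr_b[1],
    n_anchors = nrow(b),
    start_a = min(b$rank_a), end_a = max(b$rank_a),
    start_b = min(b$rank_b), end_b = max(b$rank_b),
    orientation = b$orientation[1], stringsAsFactors = FALSE)))
}
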