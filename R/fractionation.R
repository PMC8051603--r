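#' Build a reference-anchored homology table
#'
#' Rows are the reference genes in chromosome-then-rank order; each compared
#' genome contributes as many columns as its declared homology multiplicity
#' (2 extra paralog columns for a triplicated reference's own duplicates, 3
#' for a triplicated genome, 4 for a doubly-duplicated one). Collinear
#' partners are filled in from blocks; column identity is kept consistent
#' along a block (all anchors of one block occupy one column). Blocks are
#' placed by descending anchor count; a block that fits no free column is
#' dropped and counted. Missing cells hold the dot marker `"."`.
#'
#' @param reference a [gene_set()] (the reference genome).
#' @param blocks_by_genome named list: genome -> anchor data.frame from
#'   [detect_blocks()] computed with the reference as side `a`.
#' @param multiplicities named integer vector: genome -> column count.
#' @return data.frame of class `homology_table`: `gene_id`, `chromosome`,
#'   then columns `<genome>.<i>`; attributes `reference`, `multiplicities`,
#'   `dropped_blocks`.
#' @export
build_homology_table <- function(reference, blocks_by_genome, multiplicities) {
  stopifnot(is.list(blocks_by_genome), !is.null(names(blocks_by_genome)))
  if (!all(names(blocks_by_genome) %in% names(multiplicities)))
    stop("multiplicities missing for: ",
         paste(setdiff(names(blocks_by_genome), names(multiplicities)),
               collapse = ", "))
  ref <- reference[order(reference$chromosome, reference$rank), , drop = FALSE]
  n <- nrow(ref)
  row_of <- stats::setNames(seq_len(n), ref$gene_id)
  tab <- data.frame(gene_id = ref$gene_id, chromosome = ref$chromosome,
                    stringsAsFactors = FALSE)
  dropped <- stats::setNames(integer(length(blocks_by_genome)),
                             names(blocks_by_genome))
  for (g in names(blocks_by_genome)) {
    m <- as.integer(multiplicities[[g]])
    stopifnot(m >= 1)
    cols <- matrix(".", nrow = n, ncol = m)
    blocks <- blocks_by_genome[[g]]
    if (nrow(blocks)) {
      unknown <- setdiff(blocks$gene_a, ref$gene_id)
      if (length(unknown))
        stop("block references unknown reference gene: ", unknown[1])
      sp <- split(blocks, blocks$block_id)
      # first-fit in reference row order: fragments of one homoeologous copy
      # are disjoint intervals, so left-endpoint first-fit colours them with
      # exactly the overlap depth (classic interval-graph colouring); ties by
      # descending size keep the larger block when true overflow occurs
      starts <- vapply(sp, function(b) min(row_of[b$gene_a]), numeric(1))
      sizes <- vapply(sp, nrow, integer(1))
      sp <- sp[order(starts, -sizes)]
      for (b in sp) {
        rows <- row_of[b$gene_a]
        placed <- FALSE
        for (ci in seq_len(m)) {
          if (all(cols[rows, ci] == ".")) {
            cols[rows, ci] <- b$gene_b
            placed <- TRUE
            break
          }
        }
        if (!placed) dropped[[g]] <- dropped[[g]] + 1L
      }
    }
    colnames(cols) <- paste0(g, ".", seq_len(m))
    tab <- cbind(tab, as.data.frame(cols, stringsAsFactors = FALSE))
  }
  if (any(dropped > 0))
    wgd_log("build_homology_table: dropped blocks beyond multiplicity: %s",
            paste(names(dropped)[dropped > 0], dropped[dropped > 0],
                  sep = "=", collapse = ", "))
  structure(tab, reference = reference$genome[1],
            multiplicities = multiplicities, dropped_blocks = dropped,
            class = c("homology_table", "data.frame"))
}

table_genome_columns <- function(table, genome) {
  mm <- attr(table, "multiplicities")
  if (is.null(mm) || !genome %in% names(mm))
    stop("unknown genome in homology table: ", genome)
  paste0(genome, ".", seq_len(mm[[genome]]))
}

#' Homology depth histogram for one genome
#'
#' Per reference gene, the number of non-dot cells among that genome's
#' columns; reported as a histogram over 0..multiplicity with the modal
#' depth. The modal depth recovers the homology ratio of the best-matched
#' regions (e.g. 4 copies in a doubly-duplicated genome vs a single-copy
#' reference).
#'
#' @param table a [build_homology_table()] result.
#' @param genome genome name.
#' @return list `histogram` (named counts 0..m), `modal_depth`, `mean_depth`.
#' @export
homology_depth <- function(table, genome) {
  cols <- table_genome_columns(table, genome)
  m <- length(cols)
  depth <- rowSums(as.matrix(table[, cols, drop = FALSE]) != ".")
  hist <- vapply(0:m, function(d) sum(depth == d), integer(1))
  names(hist) <- 0:m
  list(histogram = hist, modal_depth = as.integer(names(hist)[which.max(hist)]),
       mean_depth = mean(depth))
}

#' Collinear gene loss rate for one genome
#'
#' Fraction of dot cells among the genome's columns:
#' `dots / (rows x multiplicity)`.
#'
#' @inheritParams homology_depth
#' @return loss fraction in `[0, 1]`.
#' @export
loss_rate <- function(table, genome) {
  cols <- table_genome_columns(table, genome)
  cells <- as.matrix(table[, cols, drop = FALSE])
  sum(cells == ".") / length(cells)
}

#' Fraction of best-hit genes away from their collinear locations
#'
#' Best-matched genes absent from every homology-table column of their
#' genome have left their ancestral (collinear) location, e.g. by
#' transposon-mediated relocation.
#'
#' @param best_hits data.frame of best hits with target genes in `gene_b`
#'   (reference genes in `gene_a`).
#' @param table a [build_homology_table()] result.
#' @param genome target genome name.
#' @return fraction of best-hit target genes not found in any column.
#' @export
translocation_fraction <- function(best_hits, table, genome) {
  cols <- table_genome_columns(table, genome)
  if (!nrow(best_hits)) return(0)
  collinear <- unique(unlist(table[, cols, drop = FALSE], use.names = FALSE))
  targets <- unique(best_hits$gene_b)
  mean(!(targets %in% collinear))
}

#' Histogram of deletion run lengths in one homology-table column
#'
#' A run is a maximal stretch of consecutive dot rows strictly bordered by
#' retained (non-dot) rows within one reference chromosome; runs touching a
#' chromosome end are excluded from the histogram and counted separately.
#'
#' @param table a [build_homology_table()] result.
#' @param genome genome name.
#' @param column column index within the genome (1..multiplicity).
#' @return list of class `run_histogram`: `counts` (named: run length ->
#'   runs), `n_runs`, `genes_in_runs`, `short_run_gene_fraction` (genes in
#'   runs of length <= 2 over genes in qualifying runs), `end_runs`.
#' @export
deletion_run_histogram <- function(table, genome, column = 1L) {
  cols <- table_genome_columns(table, genome)
  if (column < 1 || column > length(cols))
    stop("column out of range for genome ", genome)
  cells <- table[[cols[column]]]
  lengths_all <- integer(0)
  end_runs <- 0L
  for (chr in split(cells == ".", table$chromosome)) {
    r <- rle(chr)
    if (length(r$lengths) == 0) next
    is_dot <- r$values
    for (i in seq_along(r$lengths)) {
      if (!is_dot[i]) next
      if (i == 1L || i == length(r$lengths)) end_runs <- end_runs + 1L
      else lengths_all <- c(lengths_all, r$lengths[i])
    }
  }
  counts <- if (length(lengths_all)) table(lengths_all) else table(integer(0))
  counts <- stats::setNames(as.integer(counts), names(counts))
  genes_in_runs <- sum(lengths_all)
  short <- sum(lengths_all[lengths_all <= 2])
  structure(list(counts = counts, n_runs = length(lengths_all),
                 genes_in_runs = genes_in_runs,
                 short_run_gene_fraction =
                   if (genes_in_runs) short / genes_in_runs else NA_real_,
                 end_runs = end_runs),
            class = "run_histogram")
}

#' Pool run histograms (e.g. across columns)
#' @param ... `run_histogram` objects.
#' @return a pooled `run_histogram`.
#' @export
pool_run_histograms <- function(...) {
  hs <- list(...)
  if (length(hs) == 1 && is.list(hs[[1]]) && !inherits(hs[[1]], "run_histogram"))
    hs <- hs[[1]]
  lens <- unlist(lapply(hs, function(h)
    rep(as.integer(names(h$counts)), h$counts)))
  counts <- if (length(lens)) table(lens) else table(integer(0))
  counts <- stats::setNames(as.integer(counts), names(counts))
  genes <- sum(lens)
  structure(list(counts = counts, n_runs = length(lens), genes_in_runs = genes,
                 short_run_gene_fraction =
                   if (genes) sum(lens[lens <= 2]) / genes else NA_real_,
                 end_runs = sum(vapply(hs, function(h) h$end_runs, integer(1)))),
            class = "run_histogram")
}

#' Geometric fit to deletion run lengths
#'
#' Model `P(L = k) = (1 - p) p^(k-1)`, k >= 1, where `p` is the extension
#' parameter: the probability that a deletion run extends by one more gene.
#' The maximum-likelihood estimate is closed-form, `p = 1 - 1/mean(L)`.
#'
#' @param hist a `run_histogram` (or list with `counts`).
#' @return list of class `geometric_fit`: `p`, `mean_length`,
#'   `log_likelihood`, `n_runs`.
#' @export
fit_geometric <- function(hist) {
  lens <- rep(as.integer(names(hist$counts)), hist$counts)
  n <- length(lens)
  if (!n) stop("fit_geometric: no runs")
  mean_l <- mean(lens)
  p <- 1 - 1 / mean_l
  ll <- if (p > 0) n * log(1 - p) + sum(lens - 1) * log(p) else 0
  structure(list(p = p, mean_length = mean_l, log_likelihood = ll, n_runs = n),
            class = "geometric_fit")
}

#' Write a homology table TSV (dot = missing)
#' @param table a `homology_table`.
#' @param path output path.
#' @export
write_homology_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a homology table TSV written by [write_homology_table()]
#' @param path input path.
#' @param reference reference genome name.
#' @return a `homology_table` (multiplicities recovered from column names).
#' @export
read_homology_table <- function(path, reference = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  gcols <- grep("\\.\\d+$", names(df), value = TRUE)
  genomes <- unique(sub("\\.\\d+$", "", gcols))
  mult <- vapply(genomes, function(g)
    sum(sub("\\.\\d+$", "", gcols) == g), integer(1))
  structure(df, reference = reference, multiplicities = mult,
            dropped_blocks = NULL,
            class = c("homology_table", "data.frame"))
}
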