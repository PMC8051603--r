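#' Group homoeologous columns into subgenomes A1-A4
#'
#' For a target genome carried through two WGDs (homology multiplicity 4),
#' the four homology-table columns are labelled A1-A4 per reference
#' chromosome by descending retained-gene count; ties are broken by the
#' dominant target chromosome name (falling back to the column index), so
#' labels are stable across runs.
#'
#' @param table a [build_homology_table()] result with multiplicity 4 for
#'   `genome`.
#' @param genome target genome name.
#' @param target_loci optional [gene_set()] of the target genome, used to
#'   name each column's dominant chromosome.
#' @return data.frame `reference_chromosome, column, subgenome, retained,
#'   dominant_target, zero_coverage`.
#' @export
assign_subgenomes <- function(table, genome, target_loci = NULL) {
  cols <- table_genome_columns(table, genome)
  if (length(cols) != 4L)
    stop("assign_subgenomes requires homology multiplicity 4, got ",
         length(cols))
  out <- list()
  for (chr in unique(table$chromosome)) {
    rows <- table[table$chromosome == chr, cols, drop = FALSE]
    retained <- vapply(rows, function(x) sum(x != "."), integer(1))
    dominant <- vapply(seq_along(cols), function(ci) {
      genes <- rows[[ci]][rows[[ci]] != "."]
      if (!length(genes)) return(paste0("zzz_column", ci))
      if (!is.null(target_loci)) {
        chrom <- target_loci$chromosome[match(genes, target_loci$gene_id)]
        chrom <- chrom[!is.na(chrom)]
        if (length(chrom)) return(names(sort(table(chrom), decreasing = TRUE))[1])
      }
      sort(genes)[1]
    }, character(1))
    ord <- order(-retained, dominant, seq_along(cols))
    out[[chr]] <- data.frame(
      reference_chromosome = chr,
      column = cols[ord],
      subgenome = paste0("A", seq_along(cols)),
      retained = retained[ord],
      dominant_target = ifelse(grepl("^zzz_column", dominant[ord]),
                               NA_character_, dominant[ord]),
      zero_coverage = retained[ord] == 0L,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify expression bias between duplicated gene copies
#'
#' Per pair and condition, the log2 ratio of mean FPKM (plus a pseudocount)
#' is combined with a Welch t-test on log2-transformed replicate values;
#' p-values are Benjamini-Hochberg adjusted across all comparisons. A copy
#' is called `higher`/`lower` only when `|log2FC| > fc_threshold` and the
#' adjusted p-value is below `alpha`; otherwise `no_difference`. Thresholds
#' mirror common differential-expression cut-offs (|log2FC| > 1, adjusted
#' p < 0.05).
#'
#' @param expr FPKM matrix (genes x samples).
#' @param duplicate_pairs data.frame with `gene_a`, `gene_b`.
#' @param conditions factor/character vector mapping each sample (column of
#'   `expr`) to its condition; replicates share a condition label.
#' @param fc_threshold log2 fold-change threshold.
#' @param alpha adjusted-p threshold.
#' @param pseudocount added to FPKM before log2.
#' @return data.frame of class `bias_classification`: one row per pair x
#'   condition with `log2fc`, `p`, `p_adj`, `category` (category of
#'   `gene_a` relative to `gene_b`); attribute `fractions` (category
#'   proportions) and `skipped` (pairs without data).
#' @export
classify_bias <- function(expr, duplicate_pairs, conditions,
                          fc_threshold = 1, alpha = 0.05, pseudocount = 1) {
  stopifnot(length(conditions) == ncol(expr))
  conditions <- as.character(conditions)
  cond_cols <- split(seq_len(ncol(expr)), conditions)
  cond_cols <- cond_cols[lengths(cond_cols) >= 2]
  if (!length(cond_cols)) stop("classify_bias: need >= 2 replicates per condition")
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(duplicate_pairs))) {
    ga <- duplicate_pairs$gene_a[i]; gb <- duplicate_pairs$gene_b[i]
    if (!ga %in% rownames(expr) || !gb %in% rownames(expr)) {
      skipped <- skipped + 1L
      next
    }
    for (cn in names(cond_cols)) {
      va <- log2(as.numeric(expr[ga, cond_cols[[cn]]]) + pseudocount)
      vb <- log2(as.numeric(expr[gb, cond_cols[[cn]]]) + pseudocount)
      lfc <- log2(mean(as.numeric(expr[ga, cond_cols[[cn]]])) + pseudocount) -
        log2(mean(as.numeric(expr[gb, cond_cols[[cn]]])) + pseudocount)
      p <- if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
        if (isTRUE(all.equal(mean(va), mean(vb)))) 1 else 0
      } else {
        tryCatch(stats::t.test(va, vb)$p.value, error = function(e) 1)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = ga, gene_b = gb, condition = cn, log2fc = lfc, p = p,
        stringsAsFactors = FALSE)
    }
  }
  if (skipped) wgd_log("classify_bias: skipped %d pairs missing from matrix",
                       skipped)
  if (!length(rows)) stop("classify_bias: no classifiable pairs")
  df <- do.call(rbind, rows)
  df$p_adj <- stats::p.adjust(df$p, method = "BH")
  df$category <- ifelse(
    abs(df$log2fc) > fc_threshold & df$p_adj < alpha,
    ifelse(df$log2fc > 0, "higher", "lower"), "no_difference")
  fractions <- prop.table(table(factor(df$category,
                                       levels = c("higher", "lower",
                                                  "no_difference"))))
  structure(df, fractions = fractions, skipped = skipped,
            class = c("bias_classification", "data.frame"))
}
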