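#' Gene set constructor
#'
#' A gene set is the ordered collection of gene models of one genome:
#' one row per gene with chromosome, 0-based half-open coordinates, strand
#' and `rank`, the 0-based order index along its chromosome.
#'
#' @param df data.frame with columns `gene_id`, `genome`, `chromosome`,
#'   `start`, `end`, `strand`. Ranks are (re)assigned by ascending start,
#'   ties broken by `gene_id`.
#' @return a `gene_set` data.frame with an added `rank` column.
#' @export
gene_set <- function(df) {
  required <- c("gene_id", "genome", "chromosome", "start", "end", "strand")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("gene_set: missing columns: ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[, required]
  if (nrow(df)) {
    dup <- df$gene_id[duplicated(df$gene_id)]
    if (length(dup))
      stop("duplicate gene_id in gene set: ", paste(unique(dup), collapse = ", "))
    if (any(df$start >= df$end))
      stop("gene_set: start must be < end (0-based half-open)")
    if (!all(df$strand %in% c("+", "-")))
      stop("gene_set: strand must be '+' or '-'")
  }
  df <- assign_ranks(df)
  class(df) <- c("gene_set", "data.frame")
  df
}

# rank = 0-based order by start within chromosome, ties by gene_id
assign_ranks <- function(df) {
  if (!nrow(df)) {
    df$rank <- integer(0)
    return(df)
  }
  ord <- order(df$chromosome, df$start, df$gene_id)
  df <- df[ord, , drop = FALSE]
  df$rank <- as.integer(stats::ave(df$start, df$chromosome,
                                   FUN = function(x) seq_along(x) - 1L))
  rownames(df) <- NULL
  df
}

#' Read gene loci from GFF3 or a BED-like TSV
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention; the TSV dialect (header
#' `gene_id genome chromosome start end strand`) is already 0-based
#' half-open. Ranks are assigned by ascending start per chromosome;
#' unsorted input is accepted and sorted with a notice.
#'
#' @param path input file.
#' @param format `"gff3"` or `"bed-tsv"`.
#' @param genome genome name (required for GFF3, which does not carry one).
#' @param feature_type GFF3 feature type holding gene models.
#' @return a [gene_set()].
#' @export
read_gene_loci <- function(path, format = c("gff3", "bed-tsv"),
                           genome = NULL, feature_type = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gff3") {
    if (is.null(genome)) stop("read_gene_loci: 'genome' is required for GFF3")
    if (file.size(path) == 0) {
      warning("empty gene locus file: ", path)
      return(gene_set(data.frame(gene_id = character(0), genome = character(0),
                                 chromosome = character(0), start = integer(0),
                                 end = integer(0), strand = character(0))))
    }
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type %in% feature_type]
    if (!length(gr)) gr <- rtracklayer::import(path, format = "gff3")
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
    df <- data.frame(gene_id = ids,
                     genome = genome,
                     chromosome = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,  # 1-based -> 0-based
                     end = GenomicRanges::end(gr),           # inclusive -> half-open
                     strand = as.character(GenomicRanges::strand(gr)),
                     stringsAsFactors = FALSE)
    df$strand[!df$strand %in% c("+", "-")] <- "+"
  } else {
    if (file.size(path) == 0) {
      warning("empty gene locus file: ", path)
      df <- data.frame(gene_id = character(0), genome = character(0),
                       chromosome = character(0), start = integer(0),
                       end = integer(0), strand = character(0))
      return(gene_set(df))
    }
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!is.null(genome)) df$genome <- genome
  }
  if (nrow(df) && is.unsorted(order(df$chromosome, df$start)))
    wgd_log("input %s not sorted by position; sorting", path)
  gene_set(df)
}

#' Write gene loci as the BED-like TSV dialect
#' @param gs a [gene_set()].
#' @param path output path.
#' @export
write_gene_loci <- function(gs, path) {
  utils::write.table(gs[, c("gene_id", "genome", "chromosome", "start", "end", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read homologous gene pairs
#'
#' Accepts 12-column tabular BLAST (outfmt 6; columns 1, 2, 11, 12 used) or a
#' 3-column TSV `gene_a gene_b score`. Self-hits are removed, pairs above
#' `max_evalue` dropped, and duplicate pairs collapsed keeping the best score.
#'
#' @param path input file.
#' @param max_evalue e-value cutoff (BLAST dialect only). The default 1e-5
#'   follows common practice for homology searches feeding collinearity.
#' @return data.frame `gene_a, gene_b, score, evalue`.
#' @export
read_homolog_pairs <- function(path, max_evalue = 1e-5) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#")
  if (!length(nf))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0), evalue = numeric(0)))
  ncol_mode <- unique(nf)
  if (length(ncol_mode) > 1)
    stop("malformed homolog pair file at line ",
         which(nf != nf[1])[1], ": inconsistent column count")
  raw <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol_mode == 12) {
    df <- data.frame(gene_a = as.character(raw[[1]]), gene_b = as.character(raw[[2]]),
                     score = as.numeric(raw[[12]]), evalue = as.numeric(raw[[11]]),
                     stringsAsFactors = FALSE)
    bad <- which(is.na(df$score) | is.na(df$evalue))
    if (length(bad)) stop("malformed homolog pair row at line ", bad[1])
    df <- df[df$evalue <= max_evalue, , drop = FALSE]
  } else if (ncol_mode == 3) {
    df <- data.frame(gene_a = as.character(raw[[1]]), gene_b = as.character(raw[[2]]),
                     score = as.numeric(raw[[3]]), evalue = NA_real_,
                     stringsAsFactors = FALSE)
    bad <- which(is.na(df$score))
    if (length(bad)) stop("malformed homolog pair row at line ", bad[1])
  } else {
    stop("homolog pair file must have 12 (BLAST outfmt 6) or 3 columns, got ",
         ncol_mode)
  }
  df <- df[df$gene_a != df$gene_b, , drop = FALSE]
  if (any(df$score < 0)) stop("negative score in homolog pair file")
  # collapse duplicates (either order) keeping best score
  key <- ifelse(df$gene_a < df$gene_b,
                paste(df$gene_a, df$gene_b), paste(df$gene_b, df$gene_a))
  ord <- order(key, -df$score)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write homolog pairs as a 3-column TSV
#' @param pairs data.frame with `gene_a, gene_b, score`.
#' @param path output path.
#' @export
write_homolog_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("gene_a", "gene_b", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read coding sequences from FASTA
#' @param path FASTA file.
#' @return named character vector of CDS.
#' @export
read_cds <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write coding sequences to FASTA
#' @param cds named character vector.
#' @param path output path.
#' @export
write_cds <- function(cds, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds), path)
  invisible(path)
}

#' Read an expression matrix (genes x samples, FPKM)
#'
#' @param path TSV with a header row of sample ids and gene ids in column 1.
#' @return numeric matrix, genes in rows.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("expression matrix must be numeric")
  if (any(m < 0)) stop("expression matrix contains negative values")
  m
}

#' Write an expression matrix
#' @param m numeric matrix, genes in rows.
#' @param path output path.
#' @export
write_expression_matrix <- function(m, path) {
  utils::write.table(data.frame(gene_id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write collinear blocks (one anchor per row)
#' @param blocks anchor data.frame from [detect_blocks()].
#' @param path output path.
#' @export
write_blocks <- function(blocks, path) {
  cols <- c("block_id", "genome_a", "chr_a", "gene_a", "rank_a",
            "genome_b", "chr_b", "gene_b", "rank_b", "orientation")
  utils::write.table(blocks[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read collinear blocks written by [write_blocks()]
#' @param path block TSV.
#' @return anchor data.frame.
#' @export
read_blocks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$block_id <- as.integer(df$block_id)
  df
}

#' Read MCScanX-style collinearity text
#'
#' Parses the `## Alignment` block format of the MCScanX family of tools
#' into the package's anchor table. Ranks are resolved against the supplied
#' gene sets.
#'
#' @param path collinearity file.
#' @param loci_a,loci_b gene sets for the two genomes.
#' @return anchor data.frame as from [detect_blocks()].
#' @export
read_mcscanx <- function(path, loci_a, loci_b) {
  lines <- readLines(path)
  out <- list()
  block_id <- 0L
  orientation <- "parallel"
  for (ln in lines) {
    if (grepl("^## Alignment", ln)) {
      block_id <- block_id + 1L
      orientation <- if (grepl("minus", ln)) "antiparallel" else "parallel"
    } else if (!grepl("^#", ln) && nzchar(trimws(ln))) {
      f <- strsplit(trimws(ln), "[\t ]+")[[1]]
      # rows look like "0-  0:  geneA  geneB  evalue"
      genes <- f[f %in% c(loci_a$gene_id, loci_b$gene_id)]
      if (length(genes) >= 2)
        out[[length(out) + 1L]] <- data.frame(block_id = block_id,
                                              gene_a = genes[1], gene_b = genes[2],
                                              orientation = orientation,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_anchor_df())
  df <- do.call(rbind, out)
  ia <- match(df$gene_a, loci_a$gene_id)
  ib <- match(df$gene_b, loci_b$gene_id)
  keep <- !is.na(ia) & !is.na(ib)
  df <- df[keep, , drop = FALSE]; ia <- ia[keep]; ib <- ib[keep]
  data.frame(block_id = df$block_id,
             genome_a = loci_a$genome[ia], chr_a = loci_a$chromosome[ia],
             gene_a = df$gene_a, rank_a = loci_a$rank[ia],
             genome_b = loci_b$genome[ib], chr_b = loci_b$chromosome[ib],
             gene_b = df$gene_b, rank_b = loci_b$rank[ib],
             orientation = df$orientation, stringsAsFactors = FALSE)
}

empty_anchor_df <- function() {
  data.frame(block_id = integer(0), genome_a = character(0), chr_a = character(0),
             gene_a = character(0), rank_a = integer(0), genome_b = character(0),
             chr_b = character(0), gene_b = character(0), rank_b = integer(0),
             orientation = character(0), stringsAsFactors = FALSE)
}
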