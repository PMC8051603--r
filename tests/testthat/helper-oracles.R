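# Independent oracles used to cross-check package computations.

# union-find connected components of a pair graph
oracle_components <- function(pairs) {
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  parent <- stats::setNames(genes, genes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs$gene_a[i]); rb <- find(pairs$gene_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(genes, find, character(1))
  split(genes, roots)
}

# exhaustive longest gap-constrained chain by depth-first enumeration of all
# valid chains (both orientations); independent of the DP formulation
oracle_longest_chain <- function(ra, rb, max_gap) {
  n <- length(ra)
  if (!n) return(0L)
  best <- 0L
  for (anti in c(FALSE, TRUE)) {
    step <- function(i, len) {
      if (len > best) best <<- len
      for (j in seq_len(n)) {
        da <- ra[j] - ra[i]
        db <- if (anti) rb[i] - rb[j] else rb[j] - rb[i]
        if (da > 0 && da - 1 <= max_gap && db > 0 && db - 1 <= max_gap)
          step(j, len + 1L)
      }
    }
    for (i in seq_len(n)) step(i, 1L)
  }
  best
}

# NG86 via Biopython (reference implementation)
oracle_ng86_biopython <- function(seq_a, seq_b) {
  py <- Sys.which("python")
  if (!nzchar(py)) stop("python not on PATH")
  script <- sprintf(
    'import warnings; warnings.filterwarnings("ignore")
from Bio.codonalign.codonseq import CodonSeq, cal_dn_ds
dn, ds = cal_dn_ds(CodonSeq("%s"), CodonSeq("%s"), method="NG86")
print(repr(dn)); print(repr(ds))', seq_a, seq_b)
  out <- system2(py, "-", input = script, stdout = TRUE, stderr = FALSE)
  list(ka = as.numeric(out[1]), ks = as.numeric(out[2]))
}

# grid-search maximiser of the geometric run-length likelihood
oracle_geometric_mle <- function(lens, grid = seq(0, 0.999, by = 1e-4)) {
  ll <- vapply(grid, function(p) {
    if (p == 0) {
      if (all(lens == 1)) 0 else -Inf
    } else {
      length(lens) * log(1 - p) + sum(lens - 1) * log(p)
    }
  }, numeric(1))
  grid[which.max(ll)]
}

# regex-based bordered-run finder on a dot/gene pattern string (one chromosome)
oracle_bordered_runs <- function(pattern) {
  m <- gregexpr("(?<=G)\\.+(?=G)", pattern, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  attr(m, "match.length")
}

# toy gene set from per-chromosome gene-id vectors
toy_gene_set <- function(genome, chrom_genes) {
  rows <- do.call(rbind, Map(function(chr, ids) data.frame(
    gene_id = ids, genome = genome, chromosome = chr,
    start = (seq_along(ids) - 1L) * 100L,
    end = (seq_along(ids) - 1L) * 100L + 50L,
    strand = "+", stringsAsFactors = FALSE), names(chrom_genes), chrom_genes))
  gene_set(rows)
}

# anchors at given rank pairs, as a homolog pair table plus gene sets
toy_anchor_instance <- function(ranks_a, ranks_b, n_a = max(ranks_a) + 1L,
                                n_b = max(ranks_b) + 1L) {
  ga <- sprintf("a%03d", 0:(n_a - 1)); gb <- sprintf("b%03d", 0:(n_b - 1))
  list(loci_a = toy_gene_set("A", list(chrA = ga)),
       loci_b = toy_gene_set("B", list(chrB = gb)),
       pairs = data.frame(gene_a = ga[ranks_a + 1L], gene_b = gb[ranks_b + 1L],
                          score = 100, stringsAsFactors = FALSE))
}
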