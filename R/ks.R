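# --- NG86 lookup tables -----------------------------------------------------
#
# Precomputed once per session:
#   syn_sites[codon]  fractional synonymous site count (0/1 classification of
#                     each possible single-nucleotide change, /3 per position)
#   SD[a, b], ND[a, b] synonymous / nonsynonymous differences between codons,
#                     averaged over all minimal mutation pathways; pathways
#                     passing through a stop codon are excluded and the rest
#                     reweighted; if every pathway is excluded the observed
#                     changes are counted as nonsynonymous.
# Changes that create a stop codon are classified nonsynonymous, which keeps
# S + N = 3 x codons exact.

ng86_tables <- function() {
  if (!is.null(.wgdkit_cache$ng86)) return(.wgdkit_cache$ng86)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  aa <- unname(code)
  bases <- c("A", "C", "G", "T")
  n <- length(codons)
  idx <- stats::setNames(seq_len(n), codons)

  syn_sites <- numeric(n)
  for (k in seq_len(n)) {
    cd <- codons[k]
    if (aa[k] == "*") { syn_sites[k] <- NA_real_; next }
    s <- 0
    for (pos in 1:3) {
      ref <- substr(cd, pos, pos)
      for (b in setdiff(bases, ref)) {
        alt <- cd
        substr(alt, pos, pos) <- b
        if (code[[alt]] == aa[k]) s <- s + 1 / 3
      }
    }
    syn_sites[k] <- s
  }

  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  SD <- matrix(0, n, n, dimnames = list(codons, codons))
  ND <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || aa[i] == "*" || aa[j] == "*") next
      pos <- which(strsplit(codons[i], "")[[1]] != strsplit(codons[j], "")[[1]])
      k <- length(pos)
      paths <- perms[[as.character(k)]]
      sds <- numeric(0); nds <- numeric(0)
      for (p in paths) {
        cur <- codons[i]; s <- 0; nn <- 0; ok <- TRUE
        for (step in pos[p]) {
          nxt <- cur
          substr(nxt, step, step) <- substr(codons[j], step, step)
          if (code[[nxt]] == "*") { ok <- FALSE; break }
          if (code[[nxt]] == code[[cur]]) s <- s + 1 else nn <- nn + 1
          cur <- nxt
        }
        if (ok) { sds <- c(sds, s); nds <- c(nds, nn) }
      }
      if (length(sds)) {
        SD[i, j] <- mean(sds); ND[i, j] <- mean(nds)
      } else {
        SD[i, j] <- 0; ND[i, j] <- k
      }
    }
  }
  .wgdkit_cache$ng86 <- list(idx = idx, aa = aa, syn_sites = syn_sites,
                             SD = SD, ND = ND)
  .wgdkit_cache$ng86
}

split_codons <- function(seq) {
  L <- nchar(seq)
  substring(seq, seq(1L, L, 3L), seq(3L, L, 3L))
}

translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[codons]
  aa[is.na(aa)] <- "X"  # ambiguous bases
  unname(aa)
}

#' Build a gap-free codon alignment of two coding sequences
#'
#' Sequences are aligned at the protein level (global alignment of the
#' translations) and the alignment is mapped back to codons. Gapped codon
#' columns and codons containing ambiguous bases are removed, as are terminal
#' stop codons; trailing bases not forming a full codon are trimmed.
#'
#' @param cds_a,cds_b in-frame coding sequences (character).
#' @return list of class `codon_alignment` with gap-free aligned codon
#'   strings `seq_a`, `seq_b` (equal length, multiple of 3) and `n_codons`.
#' @export
build_codon_alignment <- function(cds_a, cds_b) {
  prep <- function(s, label) {
    s <- toupper(gsub("U", "T", s, fixed = TRUE))
    s <- substr(s, 1L, (nchar(s) %/% 3L) * 3L)
    if (!nchar(s)) stop("empty coding sequence (", label, ")")
    cods <- split_codons(s)
    aa <- translate_codons(cods)
    internal <- which(aa == "*")
    internal <- internal[internal < length(cods)]
    if (length(internal))
      stop("internal stop codon in ", label, " at codon ", internal[1])
    if (aa[length(aa)] == "*") { cods <- cods[-length(cods)]; aa <- aa[-length(aa)] }
    if (!length(cods)) stop("no codons left after trimming (", label, ")")
    list(cods = cods, aa = aa)
  }
  a <- prep(cds_a, "cds_a")
  b <- prep(cds_b, "cds_b")
  pa <- paste(a$aa, collapse = "")
  pb <- paste(b$aa, collapse = "")
  if (identical(pa, pb)) {
    map_a <- seq_along(a$cods); map_b <- seq_along(b$cods)
  } else {
    aln <- Biostrings::pairwiseAlignment(Biostrings::AAString(pa),
                                         Biostrings::AAString(pb),
                                         type = "global",
                                         substitutionMatrix = "BLOSUM62",
                                         gapOpening = 10, gapExtension = 0.5)
    sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    ia <- 0L; ib <- 0L; map_a <- integer(0); map_b <- integer(0)
    for (k in seq_along(sa)) {
      if (sa[k] != "-") ia <- ia + 1L
      if (sb[k] != "-") ib <- ib + 1L
      if (sa[k] != "-" && sb[k] != "-") {
        map_a <- c(map_a, ia); map_b <- c(map_b, ib)
      }
    }
  }
  ca <- a$cods[map_a]; cb <- b$cods[map_b]
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[clean]; cb <- cb[clean]
  if (!length(ca)) stop("no aligned codon columns left after filtering")
  structure(list(seq_a = paste(ca, collapse = ""),
                 seq_b = paste(cb, collapse = ""),
                 n_codons = length(ca)),
            class = "codon_alignment")
}

#' Nei-Gojobori (1986) Ka/Ks estimate
#'
#' Synonymous site fractions are computed per codon from the standard genetic
#' code and averaged over the two sequences; observed differences in codons
#' with multiple substitutions are averaged over all minimal mutation
#' pathways (pathways through stop codons excluded). Proportions are
#' corrected for multiple hits with the Jukes-Cantor formula
#' `K = -(3/4) log(1 - (4/3) p)`. `Ks` is undefined (`saturated = TRUE`)
#' when `pS >= 3/4`.
#'
#' @param aln a [build_codon_alignment()] result, or a list with equal-length
#'   in-frame `seq_a`, `seq_b`.
#' @return list of class `kaks_estimate` with fields `S, N, sd, nd, pS, pN,
#'   Ks, Ka, saturated, n_codons`.
#' @export
ng86_estimate <- function(aln) {
  if (!all(c("seq_a", "seq_b") %in% names(aln)))
    stop("ng86_estimate: need seq_a and seq_b")
  if (nchar(aln$seq_a) != nchar(aln$seq_b))
    stop("aligned sequences differ in length")
  if (nchar(aln$seq_a) %% 3L != 0L) stop("alignment length not a multiple of 3")
  if (!nchar(aln$seq_a)) stop("empty alignment")
  tb <- ng86_tables()
  ia <- tb$idx[split_codons(aln$seq_a)]
  ib <- tb$idx[split_codons(aln$seq_b)]
  if (anyNA(ia) || anyNA(ib)) stop("alignment contains non-ACGT codons")
  if (any(tb$aa[ia] == "*") || any(tb$aa[ib] == "*"))
    stop("alignment contains stop codons")
  nc <- length(ia)
  S <- (sum(tb$syn_sites[ia]) + sum(tb$syn_sites[ib])) / 2
  N <- 3 * nc - S
  sd_ <- sum(tb$SD[cbind(ia, ib)])
  nd_ <- sum(tb$ND[cbind(ia, ib)])
  pS <- if (S > 0) sd_ / S else 0
  pN <- if (N > 0) nd_ / N else 0
  saturated <- pS >= 3 / 4
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  structure(list(S = S, N = N, sd = sd_, nd = nd_, pS = pS, pN = pN,
                 Ks = jc(pS), Ka = jc(pN),
                 saturated = saturated, n_codons = nc),
            class = "kaks_estimate")
}

#' Ka/Ks for a table of gene pairs
#'
#' Convenience wrapper: aligns and estimates every pair, returning the Ks TSV
#' layout (`gene_a gene_b S N sd nd Ks Ka saturated`).
#'
#' @param pairs data.frame with `gene_a`, `gene_b`.
#' @param cds named character vector of coding sequences.
#' @return data.frame, one row per pair; pairs whose genes lack a CDS or fail
#'   alignment yield NA values.
#' @export
kaks_for_pairs <- function(pairs, cds) {
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    if (!ga %in% names(cds) || !gb %in% names(cds))
      return(data.frame(gene_a = ga, gene_b = gb, S = NA, N = NA, sd = NA,
                        nd = NA, Ks = NA, Ka = NA, saturated = NA))
    est <- tryCatch(ng86_estimate(build_codon_alignment(cds[[ga]], cds[[gb]])),
                    error = function(e) NULL)
    if (is.null(est))
      return(data.frame(gene_a = ga, gene_b = gb, S = NA, N = NA, sd = NA,
                        nd = NA, Ks = NA, Ka = NA, saturated = NA))
    data.frame(gene_a = ga, gene_b = gb, S = est$S, N = est$N, sd = est$sd,
               nd = est$nd, Ks = est$Ks, Ka = est$Ka, saturated = est$saturated)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Median Ks of a block's anchors
#'
#' @param block_anchors anchor rows of one block (data.frame with `gene_a`,
#'   `gene_b`).
#' @param estimates data.frame from [kaks_for_pairs()] (or any with `gene_a`,
#'   `gene_b`, `Ks`, `saturated`).
#' @return median of defined, unsaturated anchor Ks values (even counts give
#'   the mean of the central two); `NA` with a warning when no usable anchor.
#' @export
block_median_ks <- function(block_anchors, estimates) {
  key <- function(a, b) paste(a, b, sep = "\r")
  lut <- c(stats::setNames(estimates$Ks, key(estimates$gene_a, estimates$gene_b)),
           stats::setNames(estimates$Ks, key(estimates$gene_b, estimates$gene_a)))
  ks <- lut[key(block_anchors$gene_a, block_anchors$gene_b)]
  usable <- ks[is.finite(ks)]
  n_dropped <- length(ks) - length(usable)
  if (!length(usable)) {
    warning("block has no usable (unsaturated) anchor Ks")
    return(NA_real_)
  }
  if (n_dropped) wgd_log("block_median_ks: %d saturated/undefined anchors excluded",
                         n_dropped)
  stats::median(usable)
}

#' Median Ks per block for a full anchor table
#' @param blocks anchor data.frame from [detect_blocks()].
#' @param estimates Ka/Ks table from [kaks_for_pairs()].
#' @return data.frame `block_id`, `n_anchors`, `median_ks`.
#' @export
blocks_median_ks <- function(blocks, estimates) {
  sp <- split(blocks, blocks$block_id)
  out <- do.call(rbind, lapply(sp, function(b) data.frame(
    block_id = b$block_id[1], n_anchors = nrow(b),
    median_ks = suppressWarnings(block_median_ks(b, estimates)))))
  rownames(out) <- NULL
  out
}
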