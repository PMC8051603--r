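# Forward simulator of polyploid genome evolution. Gene orders descend from
# a common ancestor through whole-genome triplication/duplication events with
# per-lineage rate multipliers; duplicated copies fractionate by deleting
# geometric-length runs of genes until a retention target; optional
# rearrangements and gene transpositions; codon sequences accrue synonymous
# substitutions at a molecular-clock rate. Full ground truth is returned.

FOURFOLD_CODON_PREFIXES <- c("GC", "GG", "GT", "AC", "CC", "TC", "CT", "CG")

#' Random in-frame coding sequence from 4-fold degenerate codon families
#'
#' Restricting the codon inventory to 4-fold degenerate families makes
#' synonymous evolution at third positions exactly Jukes-Cantor, so the
#' NG86 estimator can be calibrated against the configured divergence.
#'
#' @param n_codons codon count.
#' @return a CDS string.
#' @export
random_cds <- function(n_codons) {
  pre <- sample(FOURFOLD_CODON_PREFIXES, n_codons, replace = TRUE)
  third <- sample(c("A", "C", "G", "T"), n_codons, replace = TRUE)
  paste0(paste0(pre, third), collapse = "")
}

syn_neighbors <- function() {
  if (!is.null(.wgdkit_cache$syn_nb)) return(.wgdkit_cache$syn_nb)
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  bases <- c("A", "C", "G", "T")
  nb <- lapply(codons, function(cd) {
    if (code[[cd]] == "*") return(character(0))
    out <- character(0)
    for (pos in 1:3) for (b in setdiff(bases, substr(cd, pos, pos))) {
      alt <- cd
      substr(alt, pos, pos) <- b
      if (code[[alt]] == code[[cd]]) out <- c(out, alt)
    }
    out
  })
  names(nb) <- codons
  .wgdkit_cache$syn_nb <- nb
  nb
}

# accrue synonymous substitutions: per codon, Poisson(d x syn_sites) events,
# each a uniform draw among current synonymous single-nucleotide neighbours
evolve_seq <- function(seq, d) {
  if (d <= 0) return(seq)
  tb <- ng86_tables()
  nb <- syn_neighbors()
  cods <- split_codons(seq)
  s_c <- tb$syn_sites[tb$idx[cods]]
  if (all(s_c == 0 | is.na(s_c)))
    stop("impossible substitution draw: sequence has no synonymous sites")
  nsub <- stats::rpois(length(cods), d * ifelse(is.na(s_c), 0, s_c))
  hit <- which(nsub > 0)
  for (i in hit) {
    cur <- cods[i]
    for (k in seq_len(nsub[i])) {
      opts <- nb[[cur]]
      if (!length(opts)) break
      cur <- opts[sample.int(length(opts), 1L)]
    }
    cods[i] <- cur
  }
  paste0(cods, collapse = "")
}

#' Evolve an ancestral CDS into two descendants at a target synonymous divergence
#'
#' Substitutions are synonymous only, Poisson-distributed per synonymous
#' site, with the target divergence split evenly between the two
#' descendants; no stop codons can be introduced.
#'
#' @param ancestral_cds in-frame CDS without internal stops.
#' @param target_ds expected synonymous substitutions per synonymous site
#'   between the two descendants.
#' @param seed RNG seed.
#' @return list `cds_a`, `cds_b`.
#' @export
evolve_pair <- function(ancestral_cds, target_ds, seed = 1L) {
  stopifnot(target_ds >= 0)
  with_seed(seed, list(cds_a = evolve_seq(ancestral_cds, target_ds / 2),
                       cds_b = evolve_seq(ancestral_cds, target_ds / 2)))
}

#' Describe one simulated species
#'
#' @param name species name.
#' @param rate whole-lineage synonymous-rate multiplier.
#' @param events ordered list (oldest first) of polyploidy events:
#'   `list(type = "WGD"|"WGT", age = Mya, retention = fraction kept per
#'   duplicated copy, label = event name)`; elements may also be
#'   `list(type = "script", lines = <rearrangement DSL lines>)`, applied in
#'   sequence position (EJ/X/INV/REN acting on current chromosome names).
#' @param transposed_fraction per-species override of the configuration's
#'   transposed-gene fraction (`NULL` = use the configured value).
#' @return list of class `sim_species`.
#' @export
sim_species <- function(name, rate = 1, events = list(),
                        transposed_fraction = NULL) {
  ages <- vapply(events, function(e)
    if (identical(e$type, "script")) NA_real_ else e$age, numeric(1))
  ages <- ages[!is.na(ages)]
  if (length(ages) > 1 && any(diff(ages) >= 0))
    stop("event ages must be strictly decreasing (oldest first)")
  structure(list(name = name, rate = rate, events = events,
                 transposed_fraction = transposed_fraction),
            class = "sim_species")
}

#' Simulation configuration
#'
#' @param species list of [sim_species()].
#' @param n_chrom ancestral chromosome count.
#' @param genes_per_chrom genes per ancestral chromosome.
#' @param codons_per_gene codons per gene (`emit_sequences`).
#' @param clock_rate synonymous substitutions per site per year.
#' @param fractionation_p geometric extension parameter of deletion runs.
#' @param transposed_fraction fraction of retained genes relocated to random
#'   positions.
#' @param spurious_pair_fraction spurious homolog pairs added, as a fraction
#'   of true pairs.
#' @param root_age age (Mya) of the common ancestor in sequence space;
#'   defaults to the oldest event age (or 1) across species.
#' @param emit_sequences simulate codon sequences?
#' @param cross_species_pairs emit inter-species true pairs?
#' @param seed mandatory RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(species, n_chrom = 2L, genes_per_chrom = 200L,
                       codons_per_gene = 100L, clock_rate = 4.8e-9,
                       fractionation_p = 0.6, transposed_fraction = 0,
                       spurious_pair_fraction = 0.05, root_age = NULL,
                       emit_sequences = TRUE, cross_species_pairs = TRUE,
                       seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(fractionation_p >= 0, fractionation_p < 1,
            transposed_fraction >= 0, transposed_fraction < 1)
  if (is.null(root_age)) {
    ages <- unlist(lapply(species, function(sp)
      vapply(sp$events, function(e)
        if (identical(e$type, "script")) NA_real_ else e$age, numeric(1))))
    ages <- ages[is.finite(ages)]
    root_age <- if (length(ages)) max(ages) else 1
  }
  structure(list(species = species, n_chrom = as.integer(n_chrom),
                 genes_per_chrom = as.integer(genes_per_chrom),
                 codons_per_gene = as.integer(codons_per_gene),
                 clock_rate = clock_rate, fractionation_p = fractionation_p,
                 transposed_fraction = transposed_fraction,
                 spurious_pair_fraction = spurious_pair_fraction,
                 root_age = root_age, emit_sequences = emit_sequences,
                 cross_species_pairs = cross_species_pairs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' The default multi-species scenario
#'
#' Four lineages descending from a common eudicot-like ancestor: an
#' outgroup carrying only the ancient triplication, and three ingroup
#' species sharing the triplication plus two nested WGDs (130, 70 and 36
#' Mya) with whole-lineage rate multipliers 1.0, 1.143 and 1.27 relative to
#' the slowest ingroup lineage.
#'
#' @param n_chrom,genes_per_chrom,codons_per_gene scenario size.
#' @param seed RNG seed.
#' @param ... passed on to [sim_config()].
#' @return a `sim_config`.
#' @export
paper_like_config <- function(n_chrom = 2L, genes_per_chrom = 150L,
                              codons_per_gene = 80L, seed = 1L, ...) {
  tri <- list(type = "WGT", age = 130, retention = 0.45, label = "gamma")
  w1 <- list(type = "WGD", age = 70, retention = 0.6, label = "omega")
  w2 <- list(type = "WGD", age = 36, retention = 0.7, label = "alpha")
  sim_config(
    species = list(
      sim_species("outgroup", rate = 0.9, events = list(tri)),
      sim_species("slow_ingroup", rate = 1.0, events = list(tri, w1, w2)),
      sim_species("mid_ingroup", rate = 1.143, events = list(tri, w1, w2)),
      sim_species("fast_ingroup", rate = 1.27, events = list(tri, w1, w2))),
    n_chrom = n_chrom, genes_per_chrom = genes_per_chrom,
    codons_per_gene = codons_per_gene, seed = seed, ...)
}

# delete geometric-length runs from one chromosome until the retention
# target; returns list(rows = kept row indices, runs = realized run lengths)
fractionate_chromosome <- function(n_genes, retention, p) {
  keep <- rep(TRUE, n_genes)
  runs <- integer(0)
  target <- retention * n_genes
  while (sum(keep) > target && sum(keep) > 0) {
    alive <- which(keep)
    start <- alive[sample.int(length(alive), 1L)]
    L <- 1L + stats::rgeom(1L, 1 - p)
    # delete L consecutive *retained* genes starting at `start`
    run_rows <- alive[alive >= start]
    run_rows <- run_rows[seq_len(min(L, length(run_rows)))]
    keep[run_rows] <- FALSE
    runs <- c(runs, length(run_rows))
  }
  list(keep = keep, runs = runs)
}

apply_sim_script <- function(chroms, lines) {
  script <- parse_event_script(lines)
  for (it in script) {
    if (!is.null(it$node)) next
    switch(it$kind,
           EJ = {
             a <- it$operands[1]; b <- it$operands[2]
             if (!a %in% names(chroms) || !b %in% names(chroms))
               stop("rearrangement references unknown chromosome")
             p <- if (length(it$products)) it$products[1] else paste0(a, b)
             merged <- rbind(chroms[[a]], chroms[[b]])
             chroms[[a]] <- NULL; chroms[[b]] <- NULL
             chroms[[p]] <- merged
           },
           X = {
             a <- it$operands[1]; b <- it$operands[2]
             pa <- it$breakpoints[1]; pb <- it$breakpoints[2]
             ca <- chroms[[a]]; cb <- chroms[[b]]
             if (pa > nrow(ca) || pb > nrow(cb)) stop("breakpoint out of range")
             n1 <- if (length(it$products)) it$products[1] else paste0(a, "'")
             n2 <- if (length(it$products) > 1) it$products[2] else paste0(b, "'")
             chroms[[a]] <- NULL; chroms[[b]] <- NULL
             chroms[[n1]] <- rbind(ca[seq_len(pa), , drop = FALSE],
                                   cb[seq_len(nrow(cb)) > pb, , drop = FALSE])
             chroms[[n2]] <- rbind(cb[seq_len(pb), , drop = FALSE],
                                   ca[seq_len(nrow(ca)) > pa, , drop = FALSE])
           },
           Inv = {
             a <- it$operands[1]
             rng <- it$breakpoints[1]:it$breakpoints[2]
             ca <- chroms[[a]]
             if (max(rng) > nrow(ca)) stop("inversion range out of range")
             ca[rng, ] <- ca[rev(rng), ]
             chroms[[a]] <- ca
           },
           Rename = {
             ca <- chroms[[it$operands[1]]]
             chroms[[it$operands[1]]] <- NULL
             chroms[[it$products[1]]] <- ca
           },
           stop("unsupported rearrangement in simulator: ", it$kind))
  }
  chroms
}

#' Simulate a multi-species polyploid dataset with full ground truth
#'
#' Events are executed oldest first per species; WGD/WGT duplicate gene
#' orders, fractionation deletes geometric-length runs until the per-copy
#' retention target, rearrangement scripts reshape chromosomes, and the
#' transposed fraction is relocated to random positions. Homolog-pair
#' tables contain all true pairs plus spurious ones. Identical
#' configurations and seeds give identical output.
#'
#' @param config a [sim_config()].
#' @return list of class `wgd_simulation`: `gene_sets` (per species),
#'   `pairs` (per species, plus `cross` per species pair), `cds` (named
#'   character, when sequences are emitted), and `truth` (`pairs` with event
#'   labels and true dS, `runs` of realized deletion lengths, `transposed`
#'   ids, `ancestor_of` map).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(config) {
  anc_chroms <- paste0("c", seq_len(config$n_chrom))
  anc_ids <- lapply(anc_chroms, function(ch)
    sprintf("%s.g%03d", ch, seq_len(config$genes_per_chrom)))
  names(anc_ids) <- anc_chroms
  anc_seq <- NULL
  if (config$emit_sequences)
    anc_seq <- stats::setNames(
      vapply(seq_len(config$n_chrom * config$genes_per_chrom),
             function(i) random_cds(config$codons_per_gene), character(1)),
      unlist(anc_ids))

  my_per_ds <- function(rate) 2 * config$clock_rate * rate * 1e6  # dS per Mya (pairwise)

  gene_sets <- list()
  pairs <- list()
  cds_all <- character(0)
  truth_pairs <- list()
  truth_runs <- list()
  truth_transposed <- list()
  ancestor_of <- character(0)

  for (sp in config$species) {
    chroms <- lapply(anc_chroms, function(ch)
      data.frame(anc_id = anc_ids[[ch]], copy = "", stringsAsFactors = FALSE))
    names(chroms) <- anc_chroms
    wgd_events <- list()
    for (ev in sp$events) {
      if (identical(ev$type, "script")) {
        chroms <- apply_sim_script(chroms, ev$lines)
        next
      }
      wgd_events[[length(wgd_events) + 1L]] <- ev
      suff <- if (ev$type == "WGD") c("a", "b") else c("a", "b", "c")
      new_chroms <- list()
      for (cn in names(chroms)) {
        for (s in suff) {
          cp <- chroms[[cn]]
          cp$copy <- paste0(cp$copy, s)
          new_chroms[[paste0(cn, s)]] <- cp
        }
      }
      chroms <- new_chroms
      retention <- if (is.null(ev$retention)) 1 else ev$retention
      if (retention < 1) {
        for (cn in names(chroms)) {
          fr <- fractionate_chromosome(nrow(chroms[[cn]]), retention,
                                       config$fractionation_p)
          chroms[[cn]] <- chroms[[cn]][fr$keep, , drop = FALSE]
          if (length(fr$runs))
            truth_runs[[length(truth_runs) + 1L]] <- data.frame(
              species = sp$name,
              event = if (is.null(ev$label)) ev$type else ev$label,
              length = fr$runs, stringsAsFactors = FALSE)
        }
      }
    }
    # final gene ids
    for (cn in names(chroms)) {
      cp <- chroms[[cn]]
      cp$gene_id <- sprintf("%s:%s:%s", sp$name, cp$anc_id,
                            ifelse(cp$copy == "", "0", cp$copy))
      chroms[[cn]] <- cp
    }
    # transposition
    transposed <- character(0)
    tf <- if (is.null(sp$transposed_fraction)) config$transposed_fraction
          else sp$transposed_fraction
    if (tf > 0) {
      all_genes <- do.call(rbind, Map(function(cn, df)
        data.frame(chrom = cn, row = seq_len(nrow(df)), gene_id = df$gene_id,
                   stringsAsFactors = FALSE), names(chroms), chroms))
      k <- round(tf * nrow(all_genes))
      if (k > 0) {
        pick <- all_genes[sample.int(nrow(all_genes), k), , drop = FALSE]
        transposed <- pick$gene_id
        # remove all picked genes first (indices refer to the pre-move state),
        # then reinsert each at a random position of a random chromosome
        moved <- list()
        for (cn in unique(pick$chrom)) {
          rows <- pick$row[pick$chrom == cn]
          moved[[cn]] <- chroms[[cn]][rows, , drop = FALSE]
          chroms[[cn]] <- chroms[[cn]][-rows, , drop = FALSE]
        }
        moved <- do.call(rbind, moved)
        for (j in seq_len(nrow(moved))) {
          dest <- sample(names(chroms), 1L)
          at <- sample.int(nrow(chroms[[dest]]) + 1L, 1L)
          chroms[[dest]] <- rbind(
            chroms[[dest]][seq_len(at - 1L), , drop = FALSE],
            moved[j, , drop = FALSE],
            chroms[[dest]][seq_len(nrow(chroms[[dest]])) >= at, , drop = FALSE])
        }
      }
    }
    truth_transposed[[sp$name]] <- transposed
    # gene set
    gs_rows <- do.call(rbind, Map(function(cn, df) {
      n <- nrow(df)
      if (!n) return(NULL)
      data.frame(gene_id = df$gene_id, genome = sp$name,
                 chromosome = paste0(sp$name, "_", cn),
                 start = (seq_len(n) - 1L) * 1000L,
                 end = (seq_len(n) - 1L) * 1000L + 600L,
                 strand = "+", stringsAsFactors = FALSE)
    }, names(chroms), chroms))
    gene_sets[[sp$name]] <- gene_set(gs_rows)
    flat <- do.call(rbind, chroms)
    ancestor_of <- c(ancestor_of, stats::setNames(flat$anc_id, flat$gene_id))

    # true within-species pairs
    ev_ages <- vapply(wgd_events, `[[`, numeric(1), "age")
    ev_labels <- vapply(wgd_events, function(e)
      if (is.null(e$label)) e$type else e$label, character(1))
    tp <- list()
    for (grp in split(flat$gene_id, flat$anc_id)) {
      if (length(grp) < 2) next
      cmb <- utils::combn(sort(grp), 2)
      tp[[length(tp) + 1L]] <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                                          stringsAsFactors = FALSE)
    }
    if (length(tp)) {
      tp <- do.call(rbind, tp)
      copy_of <- function(id) sub("^[^:]+:[^:]+:", "", id)
      div_event <- mapply(function(a, b) {
        ca <- strsplit(copy_of(a), "")[[1]]
        cb <- strsplit(copy_of(b), "")[[1]]
        which(ca != cb)[1]
      }, tp$gene_a, tp$gene_b)
      tp$species <- sp$name
      tp$event <- ev_labels[div_event]
      tp$age <- ev_ages[div_event]
      tp$true_ds <- my_per_ds(sp$rate) * tp$age
      truth_pairs[[length(truth_pairs) + 1L]] <- tp
      sp_pairs <- data.frame(gene_a = tp$gene_a, gene_b = tp$gene_b,
                             score = 200, stringsAsFactors = FALSE)
    } else {
      sp_pairs <- data.frame(gene_a = character(0), gene_b = character(0),
                             score = numeric(0), stringsAsFactors = FALSE)
    }
    # spurious pairs
    n_spur <- round(config$spurious_pair_fraction * nrow(sp_pairs))
    if (n_spur > 0 && nrow(flat) > 1) {
      sa <- flat$gene_id[sample.int(nrow(flat), n_spur, replace = TRUE)]
      sb <- flat$gene_id[sample.int(nrow(flat), n_spur, replace = TRUE)]
      ok <- sa != sb
      sp_pairs <- rbind(sp_pairs, data.frame(gene_a = sa[ok], gene_b = sb[ok],
                                             score = 50))
    }
    pairs[[sp$name]] <- sp_pairs

    # sequences: evolve along the duplication tree of each ancestral gene
    if (config$emit_sequences) {
      rate_my <- config$clock_rate * sp$rate * 1e6  # dS per branch per Mya
      ages <- c(config$root_age, ev_ages, 0)
      suffixes <- lapply(wgd_events, function(e)
        if (e$type == "WGD") c("a", "b") else c("a", "b", "c"))
      needed <- split(flat$gene_id, flat$anc_id)
      for (anc in names(needed)) {
        seqs <- stats::setNames(list(anc_seq[[anc]]), "")
        for (lev in seq_along(ev_ages)) {
          d_branch <- rate_my * (ages[lev] - ages[lev + 1])
          seqs <- lapply(seqs, evolve_seq, d = d_branch)
          # positional expansion: the root copy has the empty name, which
          # list name-indexing cannot address
          nm <- as.vector(t(outer(names(seqs), suffixes[[lev]], paste0)))
          seqs <- stats::setNames(
            rep(seqs, each = length(suffixes[[lev]])), nm)
        }
        # final branch: from the youngest event (or root if none) to the present
        seqs <- lapply(seqs, evolve_seq, d = rate_my * ages[length(ages) - 1])
        for (gid in needed[[anc]]) {
          cp <- sub("^[^:]+:[^:]+:", "", gid)
          if (cp == "0") cp <- ""
          cds_all[[gid]] <- seqs[[match(cp, names(seqs))]]
        }
      }
    }
  }

  # cross-species true pairs
  cross <- list()
  if (config$cross_species_pairs && length(config$species) > 1) {
    for (i in seq_along(config$species)) for (j in seq_along(config$species)) {
      if (j <= i) next
      a <- config$species[[i]]; b <- config$species[[j]]
      fa <- gene_sets[[a$name]]; fb <- gene_sets[[b$name]]
      anc_a <- split(fa$gene_id, ancestor_of[fa$gene_id])
      anc_b <- split(fb$gene_id, ancestor_of[fb$gene_id])
      shared <- intersect(names(anc_a), names(anc_b))
      cp <- do.call(rbind, lapply(shared, function(anc)
        expand.grid(gene_a = anc_a[[anc]], gene_b = anc_b[[anc]],
                    stringsAsFactors = FALSE)))
      if (is.null(cp)) next
      cp$species <- paste(a$name, b$name, sep = "|")
      cp$event <- "divergence"
      cp$age <- config$root_age
      cp$true_ds <- config$clock_rate * (a$rate + b$rate) * 1e6 * config$root_age
      truth_pairs[[length(truth_pairs) + 1L]] <-
        cp[, c("gene_a", "gene_b", "species", "event", "age", "true_ds")]
      cross[[paste(a$name, b$name, sep = "|")]] <-
        data.frame(gene_a = cp$gene_a, gene_b = cp$gene_b, score = 200,
                   stringsAsFactors = FALSE)
    }
  }

  structure(list(
    gene_sets = gene_sets,
    pairs = pairs,
    cross_pairs = cross,
    cds = if (config$emit_sequences) cds_all else NULL,
    truth = list(
      pairs = if (length(truth_pairs)) do.call(rbind, truth_pairs) else NULL,
      runs = if (length(truth_runs)) do.call(rbind, truth_runs) else NULL,
      transposed = truth_transposed,
      ancestor_of = ancestor_of),
    config = config), class = "wgd_simulation")
}

#' Write a simulated dataset in the package's external formats
#'
#' Gene loci as BED-like TSV, CDS as FASTA, homolog pairs as 3-column TSV,
#' and the truth record as JSON.
#'
#' @param sim a `wgd_simulation`.
#' @param dir output directory (created).
#' @return invisibly, the manifest of written files.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (sp in names(sim$gene_sets)) {
    f <- file.path(dir, paste0(sp, ".loci.tsv"))
    write_gene_loci(sim$gene_sets[[sp]], f)
    files <- c(files, f)
    f <- file.path(dir, paste0(sp, ".pairs.tsv"))
    write_homolog_pairs(sim$pairs[[sp]], f)
    files <- c(files, f)
  }
  for (cp in names(sim$cross_pairs)) {
    f <- file.path(dir, paste0(gsub("\\|", "_", cp), ".pairs.tsv"))
    write_homolog_pairs(sim$cross_pairs[[cp]], f)
    files <- c(files, f)
  }
  if (!is.null(sim$cds)) {
    f <- file.path(dir, "cds.fasta")
    write_cds(sim$cds, f)
    files <- c(files, f)
  }
  f <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, f, auto_unbox = TRUE, digits = NA,
                       null = "null")
  files <- c(files, f)
  invisible(files)
}

#' Lay genes on a replayed karyotype
#'
#' Each ancestral proto-chromosome carries genes at ranks `1..size`; a
#' karyotype segment `(source, start, end, orient)` contributes those genes
#' in traversal order. Gene ids are `species:source.gNNN:occurrence` so
#' multiple copies stay distinct.
#'
#' @param k a `karyotype` (e.g. a [replay_script()] snapshot).
#' @param species species name for ids.
#' @return list: `gene_set`, and `ancestor_of` (gene id -> ancestral gene).
#' @export
karyotype_to_gene_set <- function(k, species) {
  rows <- list()
  occ <- new.env(parent = emptyenv())
  for (ch in k$chromosomes) {
    if (ch$is_satellite || !nrow(ch$segments)) next
    pos <- 0L
    for (si in seq_len(nrow(ch$segments))) {
      seg <- ch$segments[si, ]
      ranks <- if (seg$orient == "+") seg$start:seg$end else seg$end:seg$start
      for (r in ranks) {
        anc <- sprintf("%s.g%03d", seg$source, r)
        n_prev <- if (is.null(occ[[anc]])) 0L else occ[[anc]]
        occ[[anc]] <- n_prev + 1L
        pos <- pos + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = sprintf("%s:%s:%d", species, anc, n_prev + 1L),
          genome = species, chromosome = paste0(species, "_", ch$id),
          start = (pos - 1L) * 1000L, end = (pos - 1L) * 1000L + 600L,
          strand = if (seg$orient == "+") "+" else "-",
          anc_id = anc, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  gs <- gene_set(df[, c("gene_id", "genome", "chromosome", "start", "end",
                        "strand")])
  list(gene_set = gs,
       ancestor_of = stats::setNames(df$anc_id, df$gene_id))
}

#' All true homolog pairs implied by an ancestor map
#' @param ancestor_of named vector gene id -> ancestral gene id (possibly
#'   concatenated across genomes).
#' @param score score to assign.
#' @return data.frame `gene_a, gene_b, score`.
#' @export
pairs_from_ancestry <- function(ancestor_of, score = 200) {
  out <- list()
  for (grp in split(names(ancestor_of), ancestor_of)) {
    if (length(grp) < 2) next
    cmb <- utils::combn(sort(grp), 2)
    out[[length(out) + 1L]] <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                                          stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0)))
  df <- do.call(rbind, out)
  df$score <- score
  rownames(df) <- NULL
  df
}

#' Simulate an FPKM expression matrix for duplicate pairs
#'
#' Baseline expression is log-normal per pair; a configured fraction of
#' pairs receives a true bias of `bias_log2fc` log2 units on copy `a`;
#' replicates get log-normal noise.
#'
#' @param n_pairs number of duplicate pairs.
#' @param n_conditions conditions (tissues/varieties).
#' @param n_reps replicates per condition.
#' @param bias_fraction fraction of pairs with true bias.
#' @param bias_log2fc true bias effect size (log2).
#' @param noise_sd replicate noise sd on the log2 scale.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters.
#' @param seed RNG seed.
#' @return list `expr` (matrix), `pairs` (data.frame `gene_a, gene_b`),
#'   `conditions` (per-column labels), `truth` (logical vector: pair biased).
#' @export
simulate_expression <- function(n_pairs, n_conditions = 3L, n_reps = 3L,
                                bias_fraction = 0, bias_log2fc = 2,
                                noise_sd = 0.25, baseline_meanlog = 3,
                                baseline_sdlog = 1, seed = 1L) {
  with_seed(seed, {
    pair_ids <- sprintf("dup%04d", seq_len(n_pairs))
    ga <- paste0(pair_ids, "_a"); gb <- paste0(pair_ids, "_b")
    biased <- seq_len(n_pairs) <= round(bias_fraction * n_pairs)
    biased <- sample(biased)
    cond <- rep(paste0("cond", seq_len(n_conditions)), each = n_reps)
    ncol_ <- n_conditions * n_reps
    base <- stats::rlnorm(n_pairs, baseline_meanlog, baseline_sdlog)
    expr <- matrix(0, nrow = 2 * n_pairs, ncol = ncol_,
                   dimnames = list(c(ga, gb),
                                   paste0(cond, "_r", rep(seq_len(n_reps),
                                                          n_conditions))))
    for (i in seq_len(n_pairs)) {
      mu_a <- base[i] * if (biased[i]) 2^bias_log2fc else 1
      mu_b <- base[i]
      expr[ga[i], ] <- mu_a * 2^stats::rnorm(ncol_, 0, noise_sd)
      expr[gb[i], ] <- mu_b * 2^stats::rnorm(ncol_, 0, noise_sd)
    }
    list(expr = expr,
         pairs = data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE),
         conditions = cond, truth = biased)
  })
}
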