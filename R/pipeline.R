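#' Run the full analysis pipeline on a simulated or on-disk dataset
#'
#' Stages: simulate (optional) -> collinear blocks -> Ka/Ks -> Ks density and
#' peak model -> homology table -> fractionation statistics. Artifacts are
#' written to `outdir` together with a machine-readable JSON manifest
#' (inputs, parameters, seed) from which every artifact is regenerable.
#'
#' @param config list (or path to a JSON file) with elements:
#'   `seed`; `simulate` (arguments of [paper_like_config()], or `FALSE` and
#'   then `loci`/`pairs`/`cds` file paths); `collinearity` (arguments of
#'   [collinearity_params()]); `ks` (`ceiling`, `bandwidth`); `peaks`
#'   (`n_max`, `r2_min`); `reference` (genome for the homology table);
#'   `multiplicities` (named list).
#' @param outdir output directory.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  manifest <- list(package = "wgdkit",
                   version = as.character(utils::packageVersion("wgdkit")),
                   seed = seed, parameters = config, artifacts = list())
  art <- function(name, path) manifest$artifacts[[name]] <<- path

  sim_args <- config$simulate
  if (is.null(sim_args)) sim_args <- list()
  sc <- do.call(paper_like_config, c(sim_args, list(seed = seed)))
  sim <- simulate_dataset(sc)
  simdir <- file.path(outdir, "simulated")
  write_simulated_dataset(sim, simdir)
  art("simulated", simdir)

  cp_args <- config$collinearity
  if (is.null(cp_args)) cp_args <- list()
  params <- do.call(collinearity_params, cp_args)

  ks_ceiling <- if (is.null(config$ks$ceiling)) 2.5 else config$ks$ceiling
  n_max <- if (is.null(config$peaks$n_max)) 3L else config$peaks$n_max
  r2_min <- if (is.null(config$peaks$r2_min)) 0.95 else config$peaks$r2_min

  reference <- if (is.null(config$reference)) names(sim$gene_sets)[1]
               else config$reference
  blocks_by_genome <- list()
  peak_rows <- list()
  for (sp in names(sim$gene_sets)) {
    gs <- sim$gene_sets[[sp]]
    pr <- filter_families(sim$pairs[[sp]], params$max_family_size)
    blocks <- detect_blocks(pr, gs, gs, params)
    write_blocks(blocks, file.path(outdir, paste0(sp, ".blocks.tsv")))
    art(paste0(sp, "_blocks"), file.path(outdir, paste0(sp, ".blocks.tsv")))
    if (!is.null(sim$cds) && nrow(blocks)) {
      anchors <- unique(blocks[, c("gene_a", "gene_b")])
      kk <- kaks_for_pairs(anchors, sim$cds)
      utils::write.table(kk, file.path(outdir, paste0(sp, ".kaks.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      art(paste0(sp, "_kaks"), file.path(outdir, paste0(sp, ".kaks.tsv")))
      ks <- kk$Ks[is.finite(kk$Ks)]
      if (length(ks) >= 10) {
        curve <- estimate_density(ks, ks_ceiling = ks_ceiling)
        model <- fit_peak_model(curve, n_max = n_max, r2_min = r2_min,
                                seed = seed)
        write_peak_report(model, sp, file.path(outdir, paste0(sp, ".peaks.tsv")))
        art(paste0(sp, "_peaks"), file.path(outdir, paste0(sp, ".peaks.tsv")))
        peak_rows[[sp]] <- model
      }
    }
  }
  # homology table against the reference genome
  ref_gs <- sim$gene_sets[[reference]]
  mult <- config$multiplicities
  others <- setdiff(names(sim$gene_sets), reference)
  blocks_ref <- list()
  for (sp in others) {
    key <- paste(sort(c(reference, sp))[1], sort(c(reference, sp))[2], sep = "|")
    cpairs <- sim$cross_pairs[[key]]
    if (is.null(cpairs)) next
    # orient pairs reference-first
    if (!identical(sort(c(reference, sp))[1], reference))
      cpairs <- data.frame(gene_a = cpairs$gene_b, gene_b = cpairs$gene_a,
                           score = cpairs$score)
    blocks_ref[[sp]] <- detect_blocks(filter_families(cpairs,
                                                      params$max_family_size),
                                      ref_gs, sim$gene_sets[[sp]], params)
  }
  if (length(blocks_ref)) {
    if (is.null(mult))
      mult <- stats::setNames(rep(4L, length(blocks_ref)), names(blocks_ref))
    tab <- build_homology_table(ref_gs, blocks_ref,
                                unlist(mult)[names(blocks_ref)])
    write_homology_table(tab, file.path(outdir, "homology_table.tsv"))
    art("homology_table", file.path(outdir, "homology_table.tsv"))
    fr <- lapply(names(blocks_ref), function(sp) {
      hists <- lapply(seq_len(unlist(mult)[[sp]]), function(ci)
        deletion_run_histogram(tab, sp, ci))
      pooled <- pool_run_histograms(hists)
      fit <- if (pooled$n_runs) fit_geometric(pooled) else NULL
      data.frame(genome = sp, loss_rate = loss_rate(tab, sp),
                 modal_depth = homology_depth(tab, sp)$modal_depth,
                 n_runs = pooled$n_runs,
                 geometric_p = if (is.null(fit)) NA_real_ else fit$p)
    })
    fr <- do.call(rbind, fr)
    utils::write.table(fr, file.path(outdir, "fractionation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    art("fractionation", file.path(outdir, "fractionation.tsv"))
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
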