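#' Run the end-to-end simulate -> enrich -> motif pipeline
#'
#' Demonstration pipeline over a synthetic SELEX experiment: simulates all
#' samples/replicates/cycles, counts canonical k-mers, computes fold
#' changes versus each stream's cycle 0, summarises enrichment by both
#' A/T-composition groupings, ranks top k-mers per sample, overlaps the
#' top sets of the protein samples, and builds a one-mismatch PFM around
#' the leading sample's top seed k-mers. All tables plus a machine-readable
#' manifest are written to `output_dir`; identical configurations produce
#' byte-identical outputs.
#'
#' Per-sample top lists are ranked by the mean fold change across
#' replicates at the last kept cycle; PFM windows are matched in that
#' sample's last-cycle reads pooled over replicates.
#'
#' @param output_dir output directory (created; must be empty unless
#'   `overwrite`).
#' @param config a [selex_config()].
#' @param models named list of [affinity_model()]s; default one `WT`
#'   model plus a 10x reduced-affinity `mutant`.
#' @param k k-mer length (default 6).
#' @param top_n size of the per-sample top list used for the overlap
#'   (default 100).
#' @param n_seeds number of top k-mers used as PFM seeds (default 9).
#' @param max_mismatch mismatch allowance of the PFM window search
#'   (default 1).
#' @param overwrite allow writing into an existing non-empty directory.
#' @return (invisibly) list with the written file paths, the simulation,
#'   the combined enrichment table, group summaries, top sets, overlap and
#'   PFM.
#' @export
run_pipeline <- function(output_dir, config = selex_config(),
                         models = NULL, k = 6, top_n = 100, n_seeds = 9,
                         max_mismatch = 1, overwrite = FALSE) {
  stopifnot(k >= 1, top_n >= 1, n_seeds >= 1)
  models <- models %||% list(
    WT = affinity_model(affinity_scale = 1),
    mutant = affinity_model(affinity_scale = 0.1))
  if (dir.exists(output_dir) && !overwrite &&
      length(list.files(output_dir)) > 0L) {
    stop("output directory exists and is non-empty; use overwrite = TRUE",
         call. = FALSE)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- simulate_selex(config, models,
                        output_dir = file.path(output_dir, "fastq"),
                        overwrite = overwrite)
  samples <- names(sim$manifest$models)
  is_control <- unlist(sim$manifest$is_control)
  cycles <- config$cycles_keep
  last_cycle <- max(cycles)

  # count + fold change per stream
  enr <- list()
  for (sample in samples) {
    for (rep_i in seq_len(config$replicates)) {
      zero <- count_containing_reads(
        sim$read_sets[[paste(sample, rep_i, 0, sep = "_")]], k)
      for (cyc in setdiff(cycles, 0L)) {
        tab <- count_containing_reads(
          sim$read_sets[[paste(sample, rep_i, cyc, sep = "_")]], k)
        enr[[paste(sample, rep_i, cyc, sep = "_")]] <-
          fold_change(tab, zero)
      }
    }
  }
  combined <- do.call(rbind, lapply(enr, as.data.frame))
  rownames(combined) <- NULL
  paths <- list(kmer_table = file.path(output_dir, "kmer_enrichment.tsv"))
  write_kmer_table(combined, paths$kmer_table)

  # group summaries, both groupings
  summaries <- list()
  for (grouping in c("total_at", "max_run_at")) {
    for (sample in samples) {
      for (cyc in setdiff(cycles, 0L)) {
        reps <- enr[paste(sample, seq_len(config$replicates), cyc,
                          sep = "_")]
        summaries[[paste(grouping, sample, cyc, sep = "_")]] <-
          summarise_groups(reps, grouping)
      }
    }
  }
  summary_df <- do.call(rbind, lapply(summaries, as.data.frame))
  rownames(summary_df) <- NULL
  paths$group_summary <- file.path(output_dir, "group_summary.tsv")
  write_group_summary(summary_df, paths$group_summary)

  # per-sample replicate-mean enrichment at the last cycle -> top lists
  mean_tables <- lapply(samples, function(sample) {
    reps <- enr[paste(sample, seq_len(config$replicates), last_cycle,
                      sep = "_")]
    .mean_enrichment_table(reps)
  })
  names(mean_tables) <- samples
  tops <- lapply(mean_tables, top_kmers, n = top_n)
  top_df <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample = s, rank = seq_along(tops[[s]]), kmer = tops[[s]],
               stringsAsFactors = FALSE)
  }))
  paths$top_kmers <- file.path(output_dir, "top_kmers.tsv")
  .write_tsv(top_df, paths$top_kmers)

  overlap <- NULL
  protein_samples <- samples[!is_control[samples]]
  if (length(protein_samples) %in% 2:3) {
    overlap <- overlap_sets(tops[protein_samples])
    paths$overlap <- file.path(output_dir, "overlap.tsv")
    write_overlap(overlap, paths$overlap)
  }

  # PFM around the leading protein sample's top seeds
  lead <- if (length(protein_samples)) protein_samples[1L] else samples[1L]
  seeds <- top_kmers(mean_tables[[lead]], n = n_seeds)
  pooled <- read_set(
    unlist(lapply(seq_len(config$replicates), function(rep_i) {
      sim$read_sets[[paste(lead, rep_i, last_cycle, sep = "_")]]$reads
    }), use.names = FALSE),
    sample = lead, replicate = 1L, cycle = last_cycle)
  windows <- match_windows(pooled, seeds, max_mismatch = max_mismatch)
  pfm <- build_pfm(windows)
  ppm <- to_ppm_ic(pfm)
  paths$pfm <- file.path(output_dir, "pfm.tsv")
  paths$ppm_ic <- file.path(output_dir, "ppm_ic.tsv")
  paths$jaspar <- file.path(output_dir, "pfm_jaspar.txt")
  write_pfm(pfm, paths$pfm)
  write_ppm_ic(ppm, paths$ppm_ic)
  write_jaspar(pfm, paths$jaspar, name = paste0(lead, "_top", n_seeds))

  manifest <- list(
    pipeline = list(k = k, top_n = top_n, n_seeds = n_seeds,
                    max_mismatch = max_mismatch, lead_sample = lead,
                    seeds = seeds),
    simulation = sim$manifest,
    outputs = lapply(paths, basename))
  paths$manifest <- file.path(output_dir, "run_manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(paths = paths, sim = sim, enrichment = combined,
                 group_summary = summary_df, top_kmers = tops,
                 overlap = overlap, pfm = pfm, ppm_ic = ppm,
                 manifest = manifest))
}

# average fold changes across replicate enrichment tables; a k-mer's mean
# is defined only where every replicate defines it
.mean_enrichment_table <- function(tables) {
  stopifnot(length(tables) >= 1L)
  out <- tables[[1L]]
  fc <- sapply(tables, function(t) t$fold_change)
  fc <- matrix(fc, nrow = nrow(out))
  out$fold_change <- rowMeans(fc)   # NA if any replicate undefined
  out$replicate <- NA_integer_
  out
}

#' Re-execute a pipeline run from its manifest
#'
#' The run manifest written by [run_pipeline()] records every parameter
#' and seed; this reconstructs the configuration and models from it and
#' reruns the pipeline, which reproduces the original outputs exactly.
#'
#' @param manifest_path path to a `run_manifest.json`.
#' @param output_dir directory for the re-run outputs.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return as [run_pipeline()].
#' @export
run_pipeline_from_manifest <- function(manifest_path, output_dir,
                                       overwrite = FALSE) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$simulation$config
  config <- selex_config(
    random_region_length = cfg$random_region_length,
    n_reads_per_cycle = cfg$n_reads_per_cycle,
    n_cycles = cfg$n_cycles,
    cycles_keep = cfg$cycles_keep,
    selection_strength = cfg$selection_strength,
    half_saturation = cfg$half_saturation,
    background_affinity = cfg$background_affinity,
    replicates = cfg$replicates,
    include_negative_control = cfg$include_negative_control,
    rng_seed = cfg$rng_seed)
  is_control <- unlist(man$simulation$is_control)
  models <- list()
  for (nm in names(man$simulation$models)) {
    if (isTRUE(is_control[nm])) next   # re-added by simulate_selex
    mod <- man$simulation$models[[nm]]
    models[[nm]] <- affinity_model(
      mode = mod$mode, w = mod$w, gc_penalty = mod$gc_penalty,
      beta = mod$beta, affinity_scale = mod$affinity_scale,
      energy = if (is.null(mod$energy)) NULL else {
        e <- mod$energy
        if (is.matrix(e)) e else matrix(unlist(e), nrow = 4, byrow = TRUE)
      })
  }
  run_pipeline(output_dir, config = config, models = models,
               k = man$pipeline$k, top_n = man$pipeline$top_n,
               n_seeds = man$pipeline$n_seeds,
               max_mismatch = man$pipeline$max_mismatch,
               overwrite = overwrite)
}
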