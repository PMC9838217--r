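#' Ground-truth affinity model for synthetic SELEX
#'
#' Defines the binding affinity a simulated protein assigns to an
#' oligonucleotide. In `at_energy` mode the binding energy of a length-`w`
#' window is its A/T count minus `gc_penalty` per G/C base, emulating a
#' binder that prefers AT-rich sites but tolerates a G/C at a graded cost;
#' in `pwm` mode an explicit 4 x w energy matrix is summed over the window.
#' The sequence-level affinity treats every window as a potential binding
#' site and sums their Boltzmann weights:
#' `affinity_scale * sum over windows of exp(beta * window energy)`,
#' so a partially AT-rich site contributes to binding even when a better
#' site exists elsewhere on the oligonucleotide. Affinity is
#' strand-symmetric and non-negative. `affinity_scale = 1` is the
#' wild-type-like reference; values below 1 model reduced-affinity
#' mutants; `beta = 0` makes affinity constant, which is how the
#' no-protein negative control is represented.
#'
#' @param mode `"at_energy"` or `"pwm"`.
#' @param w binding-site width in bases (default 6).
#' @param gc_penalty energy penalty per G/C base in the window (default
#'   0.5: one G/C costs half an A/T unit on top of the lost A/T, the
#'   graded single-G/C tolerance of an AT-reading binder).
#' @param beta energy-to-affinity exponent (default 1; 0 gives a constant,
#'   non-selective affinity).
#' @param affinity_scale positive multiplier on the affinity (default 1).
#' @param energy 4 x w numeric energy matrix (rows A, C, G, T), required
#'   for `pwm` mode.
#' @return object of class `affinity_model`.
#' @export
affinity_model <- function(mode = c("at_energy", "pwm"), w = 6,
                           gc_penalty = 0.5, beta = 1, affinity_scale = 1,
                           energy = NULL) {
  mode <- match.arg(mode)
  stopifnot(w >= 1, affinity_scale > 0, gc_penalty >= 0)
  if (mode == "pwm") {
    if (is.null(energy) || !is.matrix(energy) || nrow(energy) != 4L ||
        ncol(energy) != w) {
      stop("pwm mode requires a 4 x w energy matrix", call. = FALSE)
    }
    rownames(energy) <- .BASES
  }
  structure(list(mode = mode, w = as.integer(w), gc_penalty = gc_penalty,
                 beta = beta, affinity_scale = affinity_scale,
                 energy = energy),
            class = "affinity_model")
}

#' Synthetic SELEX experiment configuration
#'
#' Study conditions of the simulated experiment: fixed-length random
#' oligonucleotide libraries, iterative selection/amplification cycles, a
#' no-protein negative control and independent replicates. Selection
#' retains each sequence with occupancy probability
#' `p(s) = a(s) / (a(s) + c)` where
#' `a(s) = selection_strength * affinity(s) + background_affinity` and
#' `c = half_saturation`. The background term models nonspecific bead
#' retention: it is what the no-protein control amplifies, and it is why a
#' reduced-affinity protein, whose specific signal drops towards the
#' background, enriches less in every composition group. Amplification
#' resamples the retained pool with replacement back to
#' `n_reads_per_cycle`.
#'
#' @param random_region_length length of the random oligonucleotide region
#'   in nt (default 20).
#' @param n_reads_per_cycle reads sequenced per library (default 50000).
#' @param n_cycles number of selection cycles simulated (default 6, max 6).
#' @param cycles_keep cycles whose libraries are retained/written
#'   (default `c(0, 1, 3, 6)` capped at `n_cycles`, the cycles analysed
#'   downstream).
#' @param selection_strength multiplier on affinity in the occupancy
#'   probability (default 1).
#' @param half_saturation the half-saturation constant `c` (default 350;
#'   on the default `at_energy` scale a wild-type-like read whose best
#'   site is all-A/T sits near 60% retention).
#' @param background_affinity nonspecific retention affinity added to
#'   every sequence (default 200, i.e. a no-protein library retains about
#'   36% of molecules per cycle).
#' @param replicates number of independent replicates (default 3).
#' @param include_negative_control add a no-protein control sample
#'   (default TRUE).
#' @param rng_seed master seed; per-stream seeds are derived via
#'   [stream_seed()].
#' @return object of class `selex_config`.
#' @export
selex_config <- function(random_region_length = 20, n_reads_per_cycle = 50000,
                         n_cycles = 6, cycles_keep = NULL,
                         selection_strength = 1, half_saturation = 350,
                         background_affinity = 200,
                         replicates = 3, include_negative_control = TRUE,
                         rng_seed = 1) {
  stopifnot(random_region_length >= 1, n_reads_per_cycle >= 1,
            n_cycles >= 1, n_cycles <= 6, selection_strength > 0,
            half_saturation > 0, background_affinity >= 0, replicates >= 1)
  cycles_keep <- sort(unique(as.integer(
    cycles_keep %||% c(0, 1, 3, 6))))
  cycles_keep <- cycles_keep[cycles_keep >= 0 & cycles_keep <= n_cycles]
  structure(list(random_region_length = as.integer(random_region_length),
                 n_reads_per_cycle = as.integer(n_reads_per_cycle),
                 n_cycles = as.integer(n_cycles),
                 cycles_keep = cycles_keep,
                 selection_strength = selection_strength,
                 half_saturation = half_saturation,
                 background_affinity = background_affinity,
                 replicates = as.integer(replicates),
                 include_negative_control = isTRUE(include_negative_control),
                 rng_seed = as.integer(rng_seed)),
            class = "selex_config")
}

# ---- internal matrix-level machinery -------------------------------------

.mat_to_seqs <- function(m) {
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) .BASES[m[, j] + 1L]))
}

# summed Boltzmann site weights per row of a base-code matrix
.affinity_from_matrix <- function(m, model) {
  w <- model$w
  if (ncol(m) < w) stop("sequences shorter than site width w = ", w,
                        call. = FALSE)
  W <- ncol(m) - w + 1L
  total <- numeric(nrow(m))
  if (model$mode == "at_energy") {
    at <- (m == 0L) | (m == 3L)
    for (i in seq_len(W)) {
      s <- at[, i]
      if (w > 1L) for (j in 2:w) s <- s + at[, i + j - 1L]
      # energy = n_AT - gc_penalty * n_GC; the A/T count is
      # strand-symmetric, so each double-stranded site is summed once
      total <- total + exp(model$beta * (s - model$gc_penalty * (w - s)))
    }
  } else {
    E <- model$energy
    # the reverse-complement window scores under E what the forward
    # window scores under the complemented, column-reversed matrix
    Erc <- E[4:1, w:1, drop = FALSE]
    for (i in seq_len(W)) {
      sf <- numeric(nrow(m))
      sr <- numeric(nrow(m))
      for (j in seq_len(w)) {
        b <- m[, i + j - 1L] + 1L
        sf <- sf + E[cbind(b, j)]
        sr <- sr + Erc[cbind(b, j)]
      }
      total <- total + exp(model$beta * sf) + exp(model$beta * sr)
    }
  }
  model$affinity_scale * total
}

# ---- exported operations --------------------------------------------------

#' Affinity of sequences under a ground-truth model
#'
#' @param seqs character vector of ACGT sequences, each at least `w` long.
#' @param model an [affinity_model()].
#' @return non-negative numeric vector; strand-symmetric, i.e.
#'   `affinity(s) == affinity(reverse_complement(s))`.
#' @export
affinity <- function(seqs, model) {
  assert_dna(seqs)
  stopifnot(inherits(model, "affinity_model"))
  out <- numeric(length(seqs))
  idx <- split(seq_along(seqs), nchar(seqs))
  for (ii in idx) {
    out[ii] <- .affinity_from_matrix(seq_code_matrix(seqs[ii]), model)
  }
  out
}

#' Sample the initial random library (cycle 0)
#'
#' Draws `n_reads_per_cycle` sequences of `random_region_length` bases,
#' each base uniform over A, C, G, T; deterministic given the seed.
#'
#' @param config a [selex_config()].
#' @param sample,replicate labels recorded on the returned library and
#'   used (with `config$rng_seed`) to derive the stream seed.
#' @param seed optional explicit seed overriding the derived stream seed.
#' @return a [read_set()] at cycle 0.
#' @export
sample_initial_library <- function(config, sample = "WT", replicate = 1L,
                                   seed = NULL) {
  stopifnot(inherits(config, "selex_config"))
  seed <- seed %||% stream_seed(config$rng_seed, sample, replicate)
  m <- with_seed(seed, .sample_library_matrix(config))
  read_set(.mat_to_seqs(m), sample = sample, replicate = replicate, cycle = 0L)
}

.sample_library_matrix <- function(config) {
  matrix(sample(0:3, config$n_reads_per_cycle * config$random_region_length,
                replace = TRUE),
         nrow = config$n_reads_per_cycle,
         ncol = config$random_region_length)
}

# one selection + amplification round on a base-code matrix; uses the
# caller's RNG state
.cycle_matrix <- function(m, model, config) {
  a <- config$selection_strength * .affinity_from_matrix(m, model) +
    config$background_affinity
  p <- a / (a + config$half_saturation)
  retained <- which(stats::runif(nrow(m)) < p)
  if (length(retained) == 0L) {
    stop("selection retained no sequences; lower half_saturation or ",
         "selection stringency", call. = FALSE)
  }
  idx <- retained[sample.int(length(retained), config$n_reads_per_cycle,
                             replace = TRUE)]
  m[idx, , drop = FALSE]
}

#' Run one SELEX selection/amplification cycle
#'
#' Selection retains each sequence independently with probability
#' `p(s) = a(s) / (a(s) + c)`, where `a(s)` includes the configured
#' nonspecific background term; amplification resamples the retained pool
#' with replacement to `n_reads_per_cycle` (multinomial PCR model).
#' Uses the current RNG state; seed it for reproducibility.
#'
#' @param library a [read_set()].
#' @param model an [affinity_model()]; use `beta = 0` for the no-protein
#'   negative control (constant affinity).
#' @param config a [selex_config()].
#' @return a [read_set()] at `library$cycle + 1`.
#' @export
run_cycle <- function(library, model, config) {
  stopifnot(inherits(library, "read_set"), inherits(model, "affinity_model"),
            inherits(config, "selex_config"))
  if (length(library$reads) == 0L) stop("empty library", call. = FALSE)
  m <- seq_code_matrix(library$reads)
  m2 <- .cycle_matrix(m, model, config)
  read_set(.mat_to_seqs(m2), sample = library$sample,
           replicate = library$replicate, cycle = library$cycle + 1L)
}

#' Simulate a full SELEX experiment
#'
#' Runs the full factorial of samples x replicates x cycles with a
#' known ground truth: each (sample, replicate) stream gets its own seed
#' derived from the master seed, draws a fresh random library, and is
#' carried through `n_cycles` rounds of selection and amplification.
#' When `include_negative_control` is set, a `control` sample with
#' constant affinity (`beta = 0`) is added. Identical configurations give
#' byte-identical outputs.
#'
#' @param config a [selex_config()].
#' @param models named list of [affinity_model()]s, one per protein sample
#'   (default a single wild-type-like `WT` model).
#' @param output_dir if non-NULL, libraries for the kept cycles are written
#'   there as `sample_replicate_cycle.fastq.gz` plus a `manifest.json`.
#' @param overwrite allow writing into an existing directory.
#' @return object of class `selex_sim`: list with `read_sets` (named
#'   `sample_replicate_cycle`), `manifest`, and `config`.
#' @export
simulate_selex <- function(config, models = NULL, output_dir = NULL,
                           overwrite = FALSE) {
  stopifnot(inherits(config, "selex_config"))
  models <- models %||% list(WT = affinity_model())
  stopifnot(is.list(models), !is.null(names(models)),
            all(vapply(models, inherits, logical(1), "affinity_model")))
  is_control <- rep(FALSE, length(models))
  if (config$include_negative_control) {
    models <- c(models, list(control = affinity_model(beta = 0)))
    is_control <- c(is_control, TRUE)
  }
  names(is_control) <- names(models)

  if (!is.null(output_dir)) {
    if (dir.exists(output_dir) && !overwrite &&
        length(list.files(output_dir)) > 0L) {
      stop("output directory exists and is non-empty; use overwrite = TRUE",
           call. = FALSE)
    }
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  }

  read_sets <- list()
  streams <- data.frame(sample = character(0), replicate = integer(0),
                        seed = integer(0))
  for (sample in names(models)) {
    for (rep_i in seq_len(config$replicates)) {
      seed <- stream_seed(config$rng_seed, sample, rep_i)
      streams <- rbind(streams,
                       data.frame(sample = sample, replicate = rep_i,
                                  seed = seed))
      sets <- with_seed(seed, {
        m <- .sample_library_matrix(config)
        out <- list()
        if (0L %in% config$cycles_keep) {
          out[["0"]] <- read_set(.mat_to_seqs(m), sample, rep_i, 0L)
        }
        for (cyc in seq_len(config$n_cycles)) {
          m <- .cycle_matrix(m, models[[sample]], config)
          if (cyc %in% config$cycles_keep) {
            out[[as.character(cyc)]] <- read_set(.mat_to_seqs(m), sample,
                                                 rep_i, cyc)
          }
        }
        out
      })
      for (cyc in names(sets)) {
        key <- paste(sample, rep_i, cyc, sep = "_")
        read_sets[[key]] <- sets[[cyc]]
        if (!is.null(output_dir)) {
          write_fastq(sets[[cyc]],
                      file.path(output_dir, paste0(key, ".fastq.gz")))
        }
      }
    }
  }

  manifest <- list(
    config = unclass(config),
    models = lapply(models, function(mod) {
      mod$energy <- if (is.null(mod$energy)) NULL else unclass(mod$energy)
      unclass(mod)
    }),
    is_control = as.list(is_control),
    streams = streams)
  if (!is.null(output_dir)) {
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(read_sets = read_sets, manifest = manifest, config = config),
            class = "selex_sim")
}

#' @export
print.selex_sim <- function(x, ...) {
  cat(sprintf("<selex_sim> %d libraries (%s), %d replicate(s), cycles %s\n",
              length(x$read_sets),
              paste(names(x$manifest$models), collapse = ", "),
              x$config$replicates,
              paste(x$config$cycles_keep, collapse = ",")))
  invisible(x)
}
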