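# File parsing and table writing. FASTQ goes through Biostrings; all
# tables are plain TSV with fixed headers; reports and manifests are JSON.

#' Read a FASTQ library
#'
#' Reads a (possibly gzip-compressed) FASTQ file into a [read_set()];
#' sequences are uppercased and qualities ignored. When `sample`,
#' `replicate` or `cycle` are not given they are parsed from a file name
#' of the form `sample_replicate_cycle.fastq[.gz]`, falling back to the
#' base file name / 1 / 0.
#'
#' @param path FASTQ file path.
#' @param sample,replicate,cycle optional metadata overrides.
#' @return a [read_set()].
#' @export
read_fastq <- function(path, sample = NULL, replicate = NULL, cycle = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  # structural pre-check: 4-line records with @/+ markers, so that damaged
  # files fail with a line number instead of being silently tolerated
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty FASTQ file: ", path, call. = FALSE)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ in ", path, ": truncated record at line ",
         length(lines), call. = FALSE)
  }
  ids <- seq(1L, length(lines), by = 4L)
  bad <- ids[!startsWith(lines[ids], "@")]
  bad <- c(bad, (ids + 2L)[!startsWith(lines[ids + 2L], "+")])
  if (length(bad)) {
    stop("malformed FASTQ in ", path, ": bad record marker at line ",
         min(bad), call. = FALSE)
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      stop("malformed FASTQ in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  if (length(seqs) == 0L) stop("empty FASTQ file: ", path, call. = FALSE)
  base <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  m <- regmatches(base, regexec("^(.+)_([0-9]+)_([0-9]+)$", base))[[1]]
  if (length(m) == 4L) {
    sample <- sample %||% m[2]
    replicate <- replicate %||% as.integer(m[3])
    cycle <- cycle %||% as.integer(m[4])
  }
  message(length(seqs), " records read from ", basename(path))
  read_set(unname(toupper(as.character(seqs))),
           sample = sample %||% base,
           replicate = replicate %||% 1L,
           cycle = cycle %||% 0L)
}

#' Write a read set as FASTQ
#'
#' Constant quality string (`I`); gzip when the path ends in `.gz`.
#' Output is byte-stable: rewriting the same reads gives identical files.
#'
#' @param x a [read_set()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(x, path) {
  stopifnot(inherits(x, "read_set"))
  ids <- sprintf("%s_%d_%d:%d", x$sample, x$replicate, x$cycle,
                 seq_along(x$reads))
  seqs <- Biostrings::DNAStringSet(x$reads)
  names(seqs) <- ids
  quals <- Biostrings::BStringSet(strrep("I", nchar(x$reads)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              compress = grepl("\\.gz$", path),
                              qualities = quals)
  invisible(path)
}

#' Read a plain one-sequence-per-line file
#'
#' @param path text file with one read per line (blank lines ignored).
#' @param ... metadata passed to [read_set()].
#' @return a [read_set()].
#' @export
read_seq_lines <- function(path, ...) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- toupper(trimws(readLines(path)))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty sequence file: ", path, call. = FALSE)
  read_set(lines, ...)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write the per-k-mer enrichment table
#'
#' Columns, in fixed order: kmer, k, cycle, sample, replicate,
#' containing_reads, total_reads, fraction, fold_change, total_at,
#' max_run_at.
#'
#' @param table an `enrichment_table` or a row-bound combination of them.
#' @param path output TSV path.
#' @export
write_kmer_table <- function(table, path) {
  cols <- c("kmer", "k", "cycle", "sample", "replicate", "containing_reads",
            "total_reads", "fraction", "fold_change", "total_at",
            "max_run_at")
  stopifnot(all(cols %in% names(table)))
  .write_tsv(table[, cols], path)
}

#' Write a group summary table
#' @param summary a [summarise_groups()] result (or several row-bound).
#' @param path output TSV path.
#' @export
write_group_summary <- function(summary, path) {
  cols <- c("grouping", "group", "cycle", "sample", "n_replicates",
            "n_kmers", "mean_fc", "sd_fc")
  stopifnot(all(cols %in% names(summary)))
  .write_tsv(summary[, cols], path)
}

#' Write a Venn overlap table
#' @param overlap an [overlap_sets()] result.
#' @param path output TSV path.
#' @export
write_overlap <- function(overlap, path) {
  .write_tsv(overlap[, c("region", "count")], path)
}

#' Write a PFM as TSV
#'
#' 4 x k tab-separated matrix with row labels A, C, G, T.
#'
#' @param pfm a [build_pfm()] matrix.
#' @param path output TSV path.
#' @export
write_pfm <- function(pfm, path) {
  stopifnot(inherits(pfm, "pfm"))
  df <- data.frame(base = rownames(pfm), unclass(pfm), check.names = FALSE)
  .write_tsv(df, path)
}

#' Write a PFM as a JASPAR-style text block
#'
#' Plain-text matrix block (`>name` header, one `BASE [counts]` line per
#' base) readable by common logo tools.
#'
#' @param pfm a [build_pfm()] matrix.
#' @param path output path.
#' @param name motif name for the header line.
#' @export
write_jaspar <- function(pfm, path, name = "motif") {
  stopifnot(inherits(pfm, "pfm"))
  lines <- c(paste0(">", name),
             vapply(rownames(pfm), function(b) {
               sprintf("%s  [ %s ]", b,
                       paste(format(pfm[b, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write PPM and information content as TSV
#' @param ppm_ic a [to_ppm_ic()] result.
#' @param path output TSV path.
#' @export
write_ppm_ic <- function(ppm_ic, path) {
  stopifnot(inherits(ppm_ic, "ppm_ic"))
  df <- data.frame(base = c(rownames(ppm_ic$ppm), "IC_bits"),
                   rbind(ppm_ic$ppm, ppm_ic$ic), check.names = FALSE)
  .write_tsv(df, path)
}

#' Read an EMSA lane quantification table
#'
#' Tab-separated lane table with columns `X_uM` and `D_x`; `D_0` and
#' `D_bound` are taken from `# D_0=...` / `# D_bound=...` header comment
#' lines unless supplied as arguments.
#'
#' @param path input TSV path.
#' @param D_0,D_bound optional overrides of the header metadata.
#' @param probe_nM probe concentration metadata (default 68.1).
#' @return a `gel_quantification`.
#' @export
read_gel_table <- function(path, D_0 = NULL, D_bound = NULL, probe_nM = 68.1) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0(key, "\\s*="), meta, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    as.numeric(sub(paste0(".*", key, "\\s*=\\s*([-0-9.eE+]+).*"), "\\1",
                   hit[1]))
  }
  D_0 <- D_0 %||% get_meta("D_0")
  D_bound <- D_bound %||% get_meta("D_bound")
  if (is.null(D_0) || is.null(D_bound)) {
    stop("D_0 and D_bound must be given as arguments or '# key=value' ",
         "header lines", call. = FALSE)
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t")
  stopifnot(all(c("X_uM", "D_x") %in% names(df)))
  structure(list(lanes = df[, c("X_uM", "D_x")], D_0 = D_0,
                 D_bound = D_bound, probe_nM = probe_nM),
            class = "gel_quantification")
}

#' Write an isotherm fit report as JSON
#' @param fit an [fit_isotherm()] result.
#' @param path output JSON path.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "isotherm_fit"))
  jsonlite::write_json(
    list(Kd_uM = fit$Kd, Bmax = fit$Bmax, rss = fit$rss,
         converged = fit$converged, note = fit$note),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a protein domain annotation table
#'
#' Tab-separated columns `domain`, `start`, `end` (1-based inclusive);
#' protein name and length come from arguments or from `# protein=` /
#' `# length=` header comment lines.
#'
#' @param path input TSV path.
#' @param name,length optional overrides of the header metadata.
#' @return a [protein_annotation()].
#' @export
read_annotation <- function(path, name = NULL, length = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  if (is.null(name)) {
    hit <- grep("protein\\s*=", meta, value = TRUE)
    if (length(hit)) name <- sub(".*protein\\s*=\\s*(\\S+).*", "\\1", hit[1])
  }
  if (is.null(length)) {
    hit <- grep("length\\s*=", meta, value = TRUE)
    if (base::length(hit)) {
      length <- as.integer(sub(".*length\\s*=\\s*([0-9]+).*", "\\1", hit[1]))
    }
  }
  if (is.null(name) || is.null(length)) {
    stop("protein name and length must be given as arguments or header ",
         "lines", call. = FALSE)
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t")
  stopifnot(all(c("domain", "start", "end") %in% names(df)))
  protein_annotation(name, length,
                     data.frame(name = df$domain, start = df$start,
                                end = df$end))
}

#' Read a missense variant position table
#'
#' Tab-separated with a `position` column; optional `substitution` and
#' `label` columns are carried through.
#'
#' @param path input TSV path.
#' @return data.frame with at least a `position` column.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#")
  stopifnot("position" %in% names(df))
  df$position <- as.integer(df$position)
  df
}

#' Trim fixed-width flanks from reads
#'
#' Removes constant flanking/adapter sequence of known width before k-mer
#' counting, e.g. when libraries were sequenced with their primer arms.
#'
#' @param reads a [read_set()] or character vector.
#' @param left,right number of bases to drop from each end (default 0).
#' @return same type as the input, with shortened reads; reads shorter
#'   than `left + right` become empty strings and are dropped.
#' @export
trim_flanks <- function(reads, left = 0, right = 0) {
  stopifnot(left >= 0, right >= 0)
  rs <- inherits(reads, "read_set")
  x <- if (rs) reads$reads else reads
  out <- substr(x, left + 1L, nchar(x) - right)
  out <- out[nzchar(out)]
  if (rs) read_set(out, reads$sample, reads$replicate, reads$cycle) else out
}
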