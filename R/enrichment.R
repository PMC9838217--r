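#' A SELEX sequencing library
#'
#' Bundles the reads of one library with its experimental coordinates:
#' sample label (e.g. a protein or the no-protein negative control),
#' replicate number and SELEX cycle. Cycle 0 denotes the unselected random
#' starting library, the denominator of all fold-change calculations.
#'
#' @param reads character vector of read sequences.
#' @param sample sample label.
#' @param replicate replicate number (>= 1).
#' @param cycle SELEX cycle (>= 0).
#' @return an object of class `read_set`.
#' @export
read_set <- function(reads, sample = "sample", replicate = 1L, cycle = 0L) {
  stopifnot(is.character(reads), replicate >= 1, cycle >= 0)
  structure(
    list(reads = reads, sample = as.character(sample),
         replicate = as.integer(replicate), cycle = as.integer(cycle)),
    class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> sample=%s replicate=%d cycle=%d reads=%d\n",
              x$sample, x$replicate, x$cycle, length(x$reads)))
  invisible(x)
}

.as_read_set <- function(reads) {
  if (inherits(reads, "read_set")) reads else read_set(reads)
}

#' Count reads containing each canonical k-mer
#'
#' For every canonical k-mer, counts the number of reads in which at least
#' one length-k window canonicalises to it (presence/absence: a read
#' contributes at most 1 per k-mer regardless of how often the k-mer occurs
#' in it), and normalises by the total number of counted reads to give a
#' fraction. Windows are scanned on the read as given; reverse-complement
#' matching is achieved entirely through canonicalisation.
#'
#' Reads shorter than k are skipped with a warning and excluded from the
#' total; windows containing characters outside A,C,G,T are skipped.
#'
#' @param reads a [read_set()] or character vector of reads.
#' @param k k-mer length.
#' @return a data.frame of class `kmer_count_table` with one row per
#'   canonical k-mer (columns `kmer`, `containing_reads`, `fraction`) and
#'   attributes `k`, `total_reads`, `sample`, `replicate`, `cycle`.
#' @examples
#' tab <- count_containing_reads(c("GATATT"), k = 6)
#' tab[tab$containing_reads > 0, ] # AATATC, fraction 1
#' @export
count_containing_reads <- function(reads, k) {
  rs <- .as_read_set(reads)
  k <- as.integer(k)
  .check_table_k(k)
  if (length(rs$reads) == 0L) {
    stop("empty read set", call. = FALSE)
  }
  lens <- nchar(rs$reads)
  short <- lens < k
  if (any(short)) {
    warning(sum(short), " read(s) shorter than k = ", k,
            " skipped and excluded from total_reads", call. = FALSE)
  }
  keep <- rs$reads[!short]
  if (length(keep) == 0L) {
    stop("no reads of length >= k = ", k, call. = FALSE)
  }
  N <- 4^k
  ct <- canonical_code_table(k)
  counts <- numeric(N)
  offset <- 0L
  for (grp in split(keep, nchar(keep))) {
    m <- seq_code_matrix(grp)
    W <- window_codes(m, k)
    canon <- matrix(ct[as.vector(W) + 1], nrow = nrow(W))
    key <- (row(canon) + offset - 1) * N + canon   # read-distinct key
    v <- as.vector(canon)
    kv <- as.vector(key)
    ok <- !is.na(kv)
    first <- ok & !duplicated(kv)
    counts <- counts + tabulate(v[first] + 1, nbins = N)
    offset <- offset + length(grp)
  }
  codes <- canonical_codes(k)
  total <- length(keep)
  out <- data.frame(kmer = code_to_kmer(codes, k),
                    containing_reads = as.integer(counts[codes + 1]),
                    stringsAsFactors = FALSE)
  out$fraction <- out$containing_reads / total
  structure(out, k = k, total_reads = total, sample = rs$sample,
            replicate = rs$replicate, cycle = rs$cycle,
            class = c("kmer_count_table", "data.frame"))
}

#' Fold change of k-mer fractions versus cycle 0
#'
#' The enrichment of a canonical k-mer is the ratio of its read-containment
#' fraction at a selection cycle to its fraction in the initial random
#' library (cycle 0). K-mers with zero cycle-0 fraction get `NA` fold
#' change (flagged undefined, never infinite) and are excluded from group
#' summaries. No pseudocounts are applied unless requested.
#'
#' @param cycle_table [count_containing_reads()] table at the selection
#'   cycle.
#' @param zero_table the corresponding cycle-0 table (same k).
#' @param pseudocount reads added to both numerator and denominator counts
#'   before forming fractions (default 0; a value of 1 can stabilise tiny
#'   libraries).
#' @return a data.frame of class `enrichment_table` with columns `kmer`,
#'   `k`, `cycle`, `sample`, `replicate`, `containing_reads`,
#'   `total_reads`, `fraction`, `fold_change`, `total_at`, `max_run_at`.
#' @export
fold_change <- function(cycle_table, zero_table, pseudocount = 0) {
  stopifnot(inherits(cycle_table, "kmer_count_table"),
            inherits(zero_table, "kmer_count_table"))
  k <- attr(cycle_table, "k")
  if (k != attr(zero_table, "k")) {
    stop("mismatched k between tables (", k, " vs ",
         attr(zero_table, "k"), ")", call. = FALSE)
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  fc_num <- (cycle_table$containing_reads + pseudocount) /
    (attr(cycle_table, "total_reads") + pseudocount)
  fc_den <- (zero_table$containing_reads + pseudocount) /
    (attr(zero_table, "total_reads") + pseudocount)
  fc <- ifelse(fc_den > 0, fc_num / fc_den, NA_real_)
  anno <- canonical_annotation(k)
  out <- data.frame(kmer = cycle_table$kmer,
                    k = k,
                    cycle = attr(cycle_table, "cycle"),
                    sample = attr(cycle_table, "sample"),
                    replicate = attr(cycle_table, "replicate"),
                    containing_reads = cycle_table$containing_reads,
                    total_reads = attr(cycle_table, "total_reads"),
                    fraction = cycle_table$fraction,
                    fold_change = fc,
                    total_at = anno$total_at,
                    max_run_at = anno$max_run_at,
                    stringsAsFactors = FALSE)
  structure(out, class = c("enrichment_table", "data.frame"))
}

#' Summarise enrichment by A/T composition group
#'
#' Groups canonical k-mers by total A/T count or by longest A/T run, and
#' summarises fold changes per group. Within each replicate the group
#' statistic is the arithmetic mean fold change over that replicate's
#' defined k-mers; across replicates the reported `mean_fc` and `sd_fc`
#' are the mean and sample standard deviation (n - 1) of the per-replicate
#' means, mirroring error bars over independent replicate experiments.
#' `sd_fc` is 0 with a single replicate; a group with no defined k-mer is
#' reported with `n_kmers = 0` and missing mean.
#'
#' @param tables one `enrichment_table` or a list of them (replicates of
#'   the same sample and cycle).
#' @param grouping `"total_at"` or `"max_run_at"`.
#' @return data.frame of class `group_summary` with columns `grouping`,
#'   `group`, `cycle`, `sample`, `n_replicates`, `n_kmers`, `mean_fc`,
#'   `sd_fc`.
#' @export
summarise_groups <- function(tables, grouping = c("total_at", "max_run_at")) {
  grouping <- match.arg(grouping)
  if (inherits(tables, "enrichment_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "enrichment_table")))
  cyc <- unique(vapply(tables, function(t) t$cycle[1L], numeric(1)))
  samp <- unique(vapply(tables, function(t) t$sample[1L], character(1)))
  if (length(cyc) != 1L || length(samp) != 1L) {
    stop("all replicate tables must share one cycle and one sample",
         call. = FALSE)
  }
  k <- tables[[1L]]$k[1L]
  groups <- 0:k
  per_rep_mean <- sapply(tables, function(t) {
    def <- !is.na(t$fold_change)
    vapply(groups, function(g) {
      v <- t$fold_change[def & t[[grouping]] == g]
      if (length(v) == 0L) NA_real_ else mean(v)
    }, numeric(1))
  })
  per_rep_mean <- matrix(per_rep_mean, nrow = length(groups))
  per_rep_n <- sapply(tables, function(t) {
    def <- !is.na(t$fold_change)
    vapply(groups, function(g) sum(def & t[[grouping]] == g), integer(1))
  })
  per_rep_n <- matrix(per_rep_n, nrow = length(groups))
  n_rep <- length(tables)
  sd_fc <- if (n_rep == 1L) {
    ifelse(is.na(per_rep_mean[, 1L]), NA_real_, 0)
  } else {
    apply(per_rep_mean, 1L, stats::sd)
  }
  structure(
    data.frame(grouping = grouping,
               group = groups,
               cycle = as.integer(cyc),
               sample = samp,
               n_replicates = n_rep,
               n_kmers = apply(per_rep_n, 1L, min),
               mean_fc = rowMeans(per_rep_mean),
               sd_fc = sd_fc,
               stringsAsFactors = FALSE),
    class = c("group_summary", "data.frame"))
}

#' Top-N enriched canonical k-mers
#'
#' Returns the `n` canonical k-mers with highest defined fold change,
#' in descending order; ties are broken lexicographically.
#'
#' @param table an `enrichment_table`.
#' @param n number of k-mers to return (default 100).
#' @return character vector of canonical k-mers.
#' @export
top_kmers <- function(table, n = 100) {
  stopifnot(inherits(table, "enrichment_table"), n >= 1)
  def <- table[!is.na(table$fold_change), , drop = FALSE]
  if (nrow(def) < n) {
    warning("only ", nrow(def), " k-mers with defined fold change; ",
            "returning all of them", call. = FALSE)
    n <- nrow(def)
  }
  ord <- order(-def$fold_change, def$kmer)
  def$kmer[ord][seq_len(n)]
}

#' Overlap of top k-mer sets
#'
#' Exact Venn-region counts for two or three named sets of canonical
#' k-mers. Region labels join the member set names with `&`; regions are
#' exclusive, so each set's regions sum to its size.
#'
#' @param sets named list of 2 or 3 character vectors of canonical k-mers.
#' @return data.frame with columns `region` and `count`, one row per Venn
#'   region (including empty ones).
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% 2:3,
            !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  for (nm in names(sets)) {
    s <- sets[[nm]]
    if (any(s != canonical_kmer(s))) {
      stop("set ", nm, " contains non-canonical k-mers", call. = FALSE)
    }
  }
  all_kmers <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) all_kmers %in% s,
                   logical(length(all_kmers)))
  member <- matrix(member, ncol = length(sets))
  patterns <- apply(member, 1L, function(row) {
    paste(names(sets)[row], collapse = "&")
  })
  # enumerate all non-empty membership patterns so empty regions appear
  combos <- unlist(lapply(seq_along(sets), function(m) {
    apply(utils::combn(names(sets), m), 2L, paste, collapse = "&")
  }))
  counts <- vapply(combos, function(p) sum(patterns == p), integer(1))
  data.frame(region = combos, count = counts,
             row.names = NULL, stringsAsFactors = FALSE)
}
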