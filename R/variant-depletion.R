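#' Protein annotation for domain-level variant analysis
#'
#' @param name protein name.
#' @param length protein length in residues.
#' @param domains data.frame with columns `name`, `start`, `end`; 1-based
#'   inclusive residue coordinates, unique names,
#'   `1 <= start <= end <= length`.
#' @return object of class `protein_annotation`.
#' @export
protein_annotation <- function(name, length, domains) {
  stopifnot(is.data.frame(domains),
            all(c("name", "start", "end") %in% names(domains)))
  length <- as.integer(length)
  domains$start <- as.integer(domains$start)
  domains$end <- as.integer(domains$end)
  if (anyDuplicated(domains$name)) {
    stop("domain names must be unique", call. = FALSE)
  }
  bad <- domains$start < 1L | domains$start > domains$end |
    domains$end > length
  if (any(bad)) {
    stop("invalid domain span: ", domains$name[bad][1L], call. = FALSE)
  }
  structure(list(name = as.character(name), length = length,
                 domains = domains[, c("name", "start", "end")]),
            class = "protein_annotation")
}

.check_positions <- function(positions, annotation) {
  positions <- as.integer(positions)
  bad <- positions < 1L | positions > annotation$length | is.na(positions)
  if (any(bad)) {
    stop("variant position out of bounds: ", positions[bad][1L],
         " (protein length ", annotation$length, ")", call. = FALSE)
  }
  positions
}

#' Protein-level missense depletion score (Vp)
#'
#' The fraction of residue positions carrying at least one missense
#' variant. Low values indicate depletion of observed missense variation
#' across the protein. Note that comparing against published scores for a
#' given protein additionally requires the same variant snapshot the
#' publication used.
#'
#' @param positions integer vector of 1-based residue positions carrying a
#'   missense variant (duplicates collapse).
#' @param annotation a [protein_annotation()].
#' @return Vp in \[0, 1\].
#' @export
compute_vp <- function(positions, annotation) {
  stopifnot(inherits(annotation, "protein_annotation"))
  positions <- .check_positions(positions, annotation)
  length(unique(positions)) / annotation$length
}

#' Domain-level depletion score and ratio (Vd, Vd/Vp)
#'
#' Vd is the positional missense fraction restricted to one domain span;
#' the ratio Vd/Vp compares it with the whole protein. A ratio >= 1
#' indicates a domain not depleted of missense variants relative to the
#' full protein; ratios well below 1 flag domains under stronger
#' constraint.
#'
#' @param positions as in [compute_vp()].
#' @param annotation a [protein_annotation()].
#' @param domain_name name of a domain in the annotation.
#' @return list with elements `Vd` and `VdVp`.
#' @export
compute_vdvp <- function(positions, annotation, domain_name) {
  stopifnot(inherits(annotation, "protein_annotation"))
  d <- annotation$domains[annotation$domains$name == domain_name, ]
  if (nrow(d) != 1L) stop("unknown domain: ", domain_name, call. = FALSE)
  positions <- unique(.check_positions(positions, annotation))
  vp <- length(positions) / annotation$length
  if (vp == 0) {
    stop("Vp is 0: Vd/Vp is undefined for an empty variant set",
         call. = FALSE)
  }
  inside <- positions >= d$start & positions <= d$end
  vd <- sum(inside) / (d$end - d$start + 1L)
  list(Vd = vd, VdVp = vd / vp)
}

#' Full depletion report
#'
#' Vp for the protein plus Vd and Vd/Vp for every annotated domain. The
#' first row is the whole-protein pseudo-domain, whose Vd/Vp is 1 by
#' construction.
#'
#' @param positions as in [compute_vp()].
#' @param annotation a [protein_annotation()].
#' @return data.frame with columns `region`, `start`, `end`, `n_positions`,
#'   `score` (Vp for the protein row, Vd otherwise) and `vdvp`.
#' @export
depletion_report <- function(positions, annotation) {
  stopifnot(inherits(annotation, "protein_annotation"))
  positions <- unique(.check_positions(positions, annotation))
  vp <- length(positions) / annotation$length
  rows <- data.frame(region = annotation$name, start = 1L,
                     end = annotation$length,
                     n_positions = length(positions),
                     score = vp,
                     vdvp = if (vp > 0) 1 else NA_real_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(annotation$domains))) {
    d <- annotation$domains[i, ]
    inside <- positions >= d$start & positions <= d$end
    vd <- sum(inside) / (d$end - d$start + 1L)
    rows <- rbind(rows, data.frame(
      region = d$name, start = d$start, end = d$end,
      n_positions = sum(inside), score = vd,
      vdvp = if (vp > 0) vd / vp else NA_real_,
      stringsAsFactors = FALSE))
  }
  rows
}

#' Filter clinical variants against a population set
#'
#' Returns the clinical variant positions not present at equivalent
#' positions in the population set (exact positional set difference).
#' Positions observed in a population database that excludes severe
#' disease are unlikely to be pathogenic, so the remainder nominates
#' candidate pathogenic variants.
#'
#' @param clinical integer vector of clinical variant positions.
#' @param population integer vector of population variant positions.
#' @return sorted integer vector of retained positions.
#' @export
filter_candidates <- function(clinical, population) {
  sort(setdiff(unique(as.integer(clinical)),
               unique(as.integer(population))))
}
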