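#' Average rrn operon copy number per cell of a community
#'
#' Converts gene-copy-based relative abundances into the community-wide
#' average number of rRNA (rrn) operon copies per cell. For taxon
#' fractions f_i measured in gene copies and per-cell copy numbers n_i,
#' the average is the harmonic form `n_bar = 1 / sum(f_i / n_i)`
#' (equivalently, total gene copies over total cells), so
#' `min(n_i) <= n_bar <= max(n_i)`. Taxa with unknown copy number (`NA`)
#' are assigned the average of the known taxa; when a sample has no
#' usable profile at all, the `fallback` constant is returned.
#'
#' @param profile data.frame with columns `fraction` (relative gene
#'   abundance, renormalized to sum to 1) and `rrn_copies` (>= 1 or
#'   `NA`), or `NULL` for a missing profile.
#' @param fallback copies-per-cell constant used when no profile is
#'   available (default 2.04, a typical activated-sludge community
#'   average).
#' @return average rrn copies per cell (scalar).
#' @examples
#' average_rrn_per_cell(data.frame(fraction = c(0.5, 0.5),
#'                                 rrn_copies = c(1, 4)))  # 1.6
#' average_rrn_per_cell(NULL)  # 2.04 fallback
#' @export
average_rrn_per_cell <- function(profile, fallback = 2.04) {
  if (is.null(profile) || !nrow(profile)) return(fallback)
  stopifnot(all(c("fraction", "rrn_copies") %in% names(profile)))
  f <- profile$fraction
  n <- profile$rrn_copies
  if (any(f < 0, na.rm = TRUE)) stop("negative taxon fraction", call. = FALSE)
  if (any(n < 1, na.rm = TRUE)) {
    stop("rrn copy numbers must be >= 1", call. = FALSE)
  }
  keep <- !is.na(f) & f > 0
  f <- f[keep]
  n <- n[keep]
  if (!length(f)) return(fallback)
  if (all(is.na(n))) return(fallback)
  if (anyNA(n)) {
    known <- !is.na(n)
    fk <- f[known] / sum(f[known])
    n[!known] <- 1 / sum(fk / n[known])
  }
  f <- f / sum(f)
  1 / sum(f / n)
}

#' Clade abundance as a percentage of the total bacterial community
#'
#' Converts a clade's marker-gene copy number and the sample's 16S rRNA
#' gene copy number (both measured by qPCR on the same template mass)
#' into the clade's share of total bacterial cells:
#' `percent = 100 * marker_copies / (s16_copies / n_bar)`, assuming one
#' marker-gene copy per cell (the ppk1 case) and `n_bar` 16S copies per
#' bacterial cell.
#'
#' @param marker_copies clade marker-gene copies (>= 0; one per cell).
#' @param s16_copies total bacterial 16S rRNA gene copies (> 0).
#' @param n_bar average rrn copies per cell (>= 1), from
#'   [average_rrn_per_cell()].
#' @param gene_copies_per_cell marker-gene copies per cell (default 1).
#' @return percentage of total bacterial cells (vectorized).
#' @examples
#' clade_abundance(1e5, 2e7, 2)  # 1.0
#' @export
clade_abundance <- function(marker_copies, s16_copies, n_bar,
                            gene_copies_per_cell = 1) {
  if (any(s16_copies <= 0)) stop("s16_copies must be positive", call. = FALSE)
  if (any(n_bar < 1)) stop("n_bar must be >= 1", call. = FALSE)
  if (any(marker_copies < 0)) {
    stop("marker_copies must be non-negative", call. = FALSE)
  }
  100 * (marker_copies / gene_copies_per_cell) / (s16_copies / n_bar)
}

#' Unclassified fraction of a lineage
#'
#' The part of the lineage's total abundance (e.g. 16S-based total
#' Accumulibacter) not explained by the clade-specific assays:
#' `max(0, total - sum(clades))`. A negative raw difference (clades
#' summing above the total, possible with independent assays) is clipped
#' to zero and flagged via the `"clipped"` attribute.
#'
#' @param total_pct total lineage abundance, percent (>= 0).
#' @param clade_pcts numeric vector of per-clade percentages.
#' @return unclassified percentage with logical attribute `"clipped"`.
#' @examples
#' unclassified_fraction(10, c(1, 3))  # 6
#' @export
unclassified_fraction <- function(total_pct, clade_pcts) {
  stopifnot(total_pct >= 0)
  raw <- total_pct - sum(clade_pcts)
  structure(max(0, raw), clipped = raw < 0)
}

#' Per-sample clade abundance profiles
#'
#' Convenience wrapper assembling [clade_abundance()] and
#' [unclassified_fraction()] over a per-sample qPCR copy table.
#'
#' @param copies data.frame with columns `sample`, `clade`,
#'   `marker_copies`; one row per sample x clade assay.
#' @param s16 data.frame with columns `sample`, `s16_copies` and
#'   optionally `total_pct` (16S-based total lineage percentage).
#' @param rrn_profiles named list of community profiles (see
#'   [average_rrn_per_cell()]) keyed by sample; samples without an entry
#'   use the `fallback`.
#' @param fallback rrn copies-per-cell fallback.
#' @return data.frame with one row per sample x clade plus, when
#'   `total_pct` is supplied, one `"unclassified"` row per sample;
#'   columns `sample`, `clade`, `percent`, `n_bar`.
#' @export
abundance_profile <- function(copies, s16, rrn_profiles = list(),
                              fallback = 2.04) {
  stopifnot(all(c("sample", "clade", "marker_copies") %in% names(copies)),
            all(c("sample", "s16_copies") %in% names(s16)))
  out <- list()
  for (s in unique(copies$sample)) {
    srow <- s16[s16$sample == s, , drop = FALSE]
    if (nrow(srow) != 1L) {
      stop("need exactly one 16S row for sample '", s, "'", call. = FALSE)
    }
    n_bar <- average_rrn_per_cell(rrn_profiles[[s]], fallback = fallback)
    sub <- copies[copies$sample == s, , drop = FALSE]
    pct <- clade_abundance(sub$marker_copies, srow$s16_copies, n_bar)
    res <- data.frame(sample = s, clade = sub$clade, percent = pct,
                      n_bar = n_bar, stringsAsFactors = FALSE)
    if ("total_pct" %in% names(srow) && !is.na(srow$total_pct)) {
      un <- unclassified_fraction(srow$total_pct, pct)
      res <- rbind(res, data.frame(sample = s, clade = "unclassified",
                                   percent = as.numeric(un), n_bar = n_bar,
                                   stringsAsFactors = FALSE))
    }
    out[[s]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
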