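#' Global percent identity between two sequences
#'
#' Optimal global (Needleman-Wunsch) alignment under match +1,
#' mismatch -1, gap -2 (linear, end gaps penalized), with identity
#' defined as matched columns over total alignment columns (gaps
#' included) x 100. Cloned amplicons are primer-bounded fragments of the
#' reference region, so a global alignment avoids spurious short local
#' hits. Symmetric in its arguments.
#'
#' @param a,b non-empty DNA strings.
#' @param match,mismatch,gap alignment scores (gap is the per-base cost
#'   of a linear gap, negative).
#' @return percent identity in \[0, 100\].
#' @examples
#' global_identity("ACGTACGT", "ACGTACGT")  # 100
#' @export
global_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- normalize_dna(a, "sequence a")
  b <- normalize_dna(b, "sequence b")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = -gap)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  cols <- nchar(pat)
  matches <- sum(strsplit(pat, "")[[1L]] == strsplit(sub, "")[[1L]] &
                   strsplit(pat, "")[[1L]] != "-")
  100 * matches / cols
}

#' Assign a query sequence to a clade by nearest reference
#'
#' Computes the global identity of the query to every reference sequence
#' and reports the best hit (ties broken by lexicographically smaller
#' reference id). The query is `assigned` when the best identity reaches
#' the threshold; the default of 93% reflects the lower end of identities
#' typically observed between cloned amplicons and their clade's
#' references.
#'
#' @param query query DNA string (e.g. a cloned amplicon).
#' @param db a [ref_db] of reference sequences (non-empty).
#' @param threshold_pct minimum identity for assignment (default 93).
#' @return one-row data.frame: `best_ref_id`, `best_clade`,
#'   `percent_identity`, `assigned`.
#' @export
assign_clade <- function(query, db, threshold_pct = 93) {
  stopifnot(inherits(db, "ref_db"))
  if (!nrow(db)) stop("empty reference database", call. = FALSE)
  ids <- vapply(seq_len(nrow(db)), function(i) {
    global_identity(query, db$seq[i])
  }, numeric(1L))
  ord <- order(-ids, db$id)
  best <- ord[1L]
  data.frame(best_ref_id = db$id[best], best_clade = db$clade[best],
             percent_identity = ids[best],
             assigned = ids[best] >= threshold_pct,
             stringsAsFactors = FALSE)
}

#' Assign a clone library and summarize primer specificity
#'
#' Assigns every query to its nearest reference and reports the fraction
#' of assigned clones that fall inside the expected target clade, the
#' in-vitro specificity check applied to a primer set's clone library.
#'
#' @param queries named character vector of query sequences (names used
#'   as ids) or a `DNAStringSet`.
#' @param db a [ref_db].
#' @param target_clade expected clade for the library.
#' @param threshold_pct assignment identity threshold.
#' @return list with `assignments` (data.frame with `query_id` plus the
#'   [assign_clade()] columns) and `fraction_in_target` (assigned clones
#'   in the target clade over all clones).
#' @export
assign_library <- function(queries, db, target_clade, threshold_pct = 93) {
  if (inherits(queries, "DNAStringSet")) {
    queries <- stats::setNames(as.character(queries), names(queries))
  }
  if (is.null(names(queries))) {
    names(queries) <- sprintf("clone_%03d", seq_along(queries))
  }
  rows <- lapply(names(queries), function(id) {
    cbind(data.frame(query_id = id, stringsAsFactors = FALSE),
          assign_clade(queries[[id]], db, threshold_pct))
  })
  assignments <- do.call(rbind, rows)
  rownames(assignments) <- NULL
  in_target <- assignments$assigned & assignments$best_clade == target_clade
  list(assignments = assignments,
       fraction_in_target = sum(in_target) / nrow(assignments))
}
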