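#' Primer and primer-pair constructors
#'
#' A primer stores its sequence 5'->3', its orientation (`forward` or
#' `reverse`) and, when the name follows the `"<gene>-<pos><f|r>"`
#' convention (e.g. `"Acc-ppk1-372f"`), the 1-based reference coordinate
#' parsed from the name. For a forward primer that coordinate is the
#' 5'-most template position of the binding site; for a reverse primer it
#' is the 5'-most coordinate of the primer on the reference strand, i.e.
#' the rightmost position of the amplicon. The parsed coordinate is
#' advisory only: matching never trusts it.
#'
#' @param seq primer sequence, 5'->3', 10-40 nt over the IUPAC alphabet.
#' @param orientation `"forward"` or `"reverse"`; defaults to the value
#'   implied by a trailing `f`/`r` in `name` when one is given.
#' @param name optional primer name.
#' @return an object of class `primer`.
#' @examples
#' primer("TGAAGGCATTCGCTTCCT", name = "Acc-ppk1-372f")
#' @export
primer <- function(seq, orientation = NULL, name = NULL) {
  seq <- normalize_dna(seq, "primer sequence")
  L <- nchar(seq)
  if (L < 10L || L > 40L) {
    stop("primer length must be 10-40 nt (got ", L, ")", call. = FALSE)
  }
  parsed <- if (!is.null(name)) parse_primer_name(name) else NULL
  if (is.null(orientation)) {
    if (is.null(parsed)) {
      stop("orientation must be given when the name does not end in f/r",
           call. = FALSE)
    }
    orientation <- parsed$orientation
  }
  orientation <- match.arg(orientation, c("forward", "reverse"))
  if (!is.null(parsed) && parsed$orientation != orientation) {
    stop("primer name '", name, "' implies orientation '", parsed$orientation,
         "' but '", orientation, "' was given", call. = FALSE)
  }
  structure(list(name = if (is.null(name)) sprintf("primer-%s", orientation) else name,
                 seq = seq, orientation = orientation,
                 ref_coord = if (is.null(parsed)) NA_integer_ else parsed$coord),
            class = "primer")
}

# Parse "<gene>-<pos><f|r>"; returns NULL when the name does not conform.
parse_primer_name <- function(name) {
  m <- regmatches(name, regexec("-([0-9]+)([fr])$", name))[[1L]]
  if (length(m) != 3L) return(NULL)
  list(coord = as.integer(m[2L]),
       orientation = if (m[3L] == "f") "forward" else "reverse")
}

#' @rdname primer
#' @param forward,reverse `primer` objects with the matching orientations.
#' @param pair_name optional pair label; defaults to
#'   `"<forward name>/<reverse name>"`.
#' @export
primer_pair <- function(forward, reverse, pair_name = NULL) {
  stopifnot(inherits(forward, "primer"), inherits(reverse, "primer"))
  if (forward$orientation != "forward" || reverse$orientation != "reverse") {
    stop("primer_pair() needs one forward and one reverse primer",
         call. = FALSE)
  }
  if (is.null(pair_name)) pair_name <- paste(forward$name, reverse$name, sep = "/")
  structure(list(name = pair_name, forward = forward, reverse = reverse),
            class = "primer_pair")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("%s primer %s: 5'-%s-3' (%d nt)\n",
              x$orientation, x$name, x$seq, nchar(x$seq)))
  invisible(x)
}

#' Read primer definitions from a TSV file
#'
#' Expects tab-separated columns `name`, `sequence` and optionally
#' `orientation` (inferred from a trailing `f`/`r` in the name when
#' absent); `#` comments allowed.
#'
#' @param path input path.
#' @return list of [primer] objects, named by primer name.
#' @export
read_primers <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("name", "sequence") %in% names(tab))) {
    stop("primer TSV needs columns 'name' and 'sequence'", call. = FALSE)
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    ori <- if ("orientation" %in% names(tab)) tab$orientation[i] else NULL
    primer(tab$sequence[i], orientation = ori, name = tab$name[i])
  })
  names(out) <- tab$name
  out
}

#' qPCR primer sets for the Accumulibacter ppk1 clades
#'
#' Published clade-specific primer sets for the polyphosphate kinase 1
#' (ppk1) marker gene of "Candidatus Accumulibacter". Coordinates embedded
#' in the primer names are 1-based positions on the ppk1 reference; for a
#' forward primer the coordinate is the 5' (leftmost) binding position and
#' for a reverse primer the rightmost position of the amplicon.
#'
#' @return data.frame with columns `pair`, `target_clade`, `forward_name`,
#'   `forward_seq`, `reverse_name`, `reverse_seq`.
#' @export
accumulibacter_primers <- function() {
  data.frame(
    pair = c("Primer-IA", "Primer-IB", "Primer-IC", "Primer-ID",
             "Primer-IIE", "Primer-IIG", "Primer-IIH", "Primer-II-I"),
    target_clade = c("IA", "IB", "IC", "ID", "IIE", "IIG", "IIH", "II-I"),
    forward_name = c("Acc-ppk1-974f", "Acc-ppk1-372f", "Acc-ppk1-362f",
                     "Acc-ppk1-634f", "Acc-ppk1-757f", "Acc-ppk1-410f",
                     "Acc-ppk1-701f", "Acc-ppk1-688f"),
    forward_seq = c("TGATGCGCGACAATCTCAAATTCAA", "TGAAGGCATTCGCTTCCT",
                    "AGCTGGCGAGTGAAGGCATTCG", "TGCGACAGCGAATACAG",
                    "TTCGTGGACGAGGAAGA", "CCGAGCAACGCGAATGG",
                    "ACTCCTTCGTATTCCTCTCT", "AGTGATTATGCTTTCGTCTTTC"),
    reverse_name = c("Acc-ppk1-1113r", "Acc-ppk1-653r", "Acc-ppk1-758r",
                     "Acc-ppk1-848r", "Acc-ppk1-1129r", "Acc-ppk1-514r",
                     "Acc-ppk1-928r", "Acc-ppk1-946r"),
    reverse_seq = c("AATGATCGGATTGAAGCTCTGGTAG", "AAGCAGTATTCGCTGTC",
                    "AACAGGTTGCTGTTGCGCGTGA", "ACTTCGAGGCGGACG",
                    "ATTGTTCGAGCAACTCGATG", "TGTTGAGTACGCGCGGGA",
                    "TCATCGCTTCGGAGCA", "TGAACTGTCCGAGCAGGA"),
    stringsAsFactors = FALSE
  )
}

# Core scanning engine. site_mask: masks of the sequence as laid on the
# reference strand; dist3: per site position, distance (1-based) from the
# primer 3' end. Returns offsets (1-based template start), mismatch count
# and, per hit, the sorted distances-from-3' of the mismatched positions.
scan_site <- function(site_mask, dist3, tmask, k, w) {
  L <- length(site_mask)
  n <- length(tmask)
  empty <- list(start = integer(), n_mismatches = integer(),
                mismatch_pos = list())
  if (L > n) return(empty)
  noff <- n - L + 1L
  mm <- integer(noff)
  mmw <- integer(noff)
  prot <- dist3 <= w
  for (i in seq_len(L)) {
    bad <- bitwAnd(site_mask[i], tmask[i:(i + noff - 1L)]) == 0L
    mm <- mm + bad
    if (prot[i]) mmw <- mmw + bad
  }
  hit <- which(mm <= k & mmw == 0L)
  if (!length(hit)) return(empty)
  pos <- lapply(hit, function(o) {
    mis <- which(bitwAnd(site_mask, tmask[o:(o + L - 1L)]) == 0L)
    sort(dist3[mis])
  })
  list(start = hit, n_mismatches = mm[hit], mismatch_pos = pos)
}

#' Match a primer against a template under a MAM pattern
#'
#' Scans every template window for binding sites with at most
#' `pattern$max_mismatches` mismatches and no mismatch within the
#' 3'-protected window. A forward primer is compared directly against the
#' reference strand; a reverse primer is compared as its reverse
#' complement laid on the reference strand (so its 3' end faces left).
#' Mismatch positions are reported as 1-based distances from the primer
#' 3' end (1 = 3' terminus). Base compatibility is IUPAC-set
#' intersection, so degenerate template bases (e.g. `N`) never count as
#' mismatches.
#'
#' @param primer a [primer] object.
#' @param template template DNA string (reference strand, 5'->3'), or a
#'   single-row slice of a [ref_db].
#' @param pattern a [mam_pattern].
#' @param seq_id template identifier carried into the result (taken from
#'   a `ref_db` row automatically).
#' @return data.frame with columns `primer_name`, `seq_id`,
#'   `template_start`, `template_end`, `n_mismatches` and the list column
#'   `mismatch_pos_3prime`. Zero rows when there is no admissible site;
#'   a primer longer than the template yields zero rows, not an error.
#' @examples
#' p <- primer("ACGTACGTAC", "forward", "demo-1f")
#' match_primer(p, paste0("TT", "ACGTACGTAC", "GGA"), mam_pattern(0))
#' @export
match_primer <- function(primer, template, pattern, seq_id = NA_character_) {
  stopifnot(inherits(primer, "primer"), inherits(pattern, "mam_pattern"))
  if (inherits(template, "data.frame")) {
    stopifnot(nrow(template) == 1L)
    seq_id <- template$id
    template <- template$seq
  }
  template <- normalize_dna(template, "template")
  pmask <- encode_iupac(primer$seq)
  L <- length(pmask)
  if (pattern$protected_3prime > L) {
    stop("3'-protected window exceeds primer length", call. = FALSE)
  }
  if (primer$orientation == "forward") {
    site <- pmask
    dist3 <- rev(seq_len(L))      # last site position is the 3' terminus
  } else {
    site <- rev(mask_complement(pmask))
    dist3 <- seq_len(L)           # first site position is the 3' terminus
  }
  hits <- scan_site(site, dist3, encode_iupac(template),
                    pattern$max_mismatches, pattern$protected_3prime)
  out <- data.frame(
    primer_name = rep(primer$name, length(hits$start)),
    seq_id = rep(seq_id, length(hits$start)),
    template_start = hits$start,
    template_end = hits$start + L - 1L,
    n_mismatches = hits$n_mismatches,
    stringsAsFactors = FALSE
  )
  out$mismatch_pos_3prime <- hits$mismatch_pos
  out
}

#' Predict amplicons for a primer pair on one template
#'
#' Combines every forward and reverse binding site in convergent
#' orientation: the forward 5' (leftmost) coordinate must not exceed the
#' reverse primer's rightmost coordinate, the amplicon length
#' (`end - start + 1`, 1-based inclusive) must be at least the longer
#' primer and at most `max_len`.
#'
#' @param pair a [primer_pair].
#' @param template template DNA string or single-row `ref_db` slice.
#' @param pattern a [mam_pattern].
#' @param max_len maximum amplicon length in bp (default 450).
#' @param seq_id template identifier.
#' @return data.frame with columns `seq_id`, `start`, `end`, `length_bp`,
#'   `f_start`, `r_end`, `f_mismatches`, `r_mismatches` and list columns
#'   `f_mismatch_pos`, `r_mismatch_pos`. Zero rows is a valid outcome.
#' @export
predict_amplicons <- function(pair, template, pattern, max_len = 450L,
                              seq_id = NA_character_) {
  stopifnot(inherits(pair, "primer_pair"))
  if (inherits(template, "data.frame")) {
    stopifnot(nrow(template) == 1L)
    seq_id <- template$id
    template <- template$seq
  }
  fm <- match_primer(pair$forward, template, pattern, seq_id)
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), length_bp = integer(),
                      f_start = integer(), r_end = integer(),
                      f_mismatches = integer(), r_mismatches = integer(),
                      stringsAsFactors = FALSE)
  empty$f_mismatch_pos <- list()
  empty$r_mismatch_pos <- list()
  if (!nrow(fm)) return(empty)
  rm_ <- match_primer(pair$reverse, template, pattern, seq_id)
  if (!nrow(rm_)) return(empty)
  combos <- expand.grid(fi = seq_len(nrow(fm)), ri = seq_len(nrow(rm_)))
  start <- fm$template_start[combos$fi]
  end <- rm_$template_end[combos$ri]
  len <- end - start + 1L
  min_len_geom <- max(nchar(pair$forward$seq), nchar(pair$reverse$seq))
  keep <- len >= min_len_geom & len <= max_len
  combos <- combos[keep, , drop = FALSE]
  if (!nrow(combos)) return(empty)
  out <- data.frame(
    seq_id = rep(seq_id, nrow(combos)),
    start = start[keep], end = end[keep], length_bp = len[keep],
    f_start = fm$template_start[combos$fi],
    r_end = rm_$template_end[combos$ri],
    f_mismatches = fm$n_mismatches[combos$fi],
    r_mismatches = rm_$n_mismatches[combos$ri],
    stringsAsFactors = FALSE
  )
  out$f_mismatch_pos <- fm$mismatch_pos_3prime[combos$fi]
  out$r_mismatch_pos <- rm_$mismatch_pos_3prime[combos$ri]
  rownames(out) <- NULL
  out
}

#' Coverage of a target set by a primer pair
#'
#' Percentage of target records that yield at least one predicted
#' amplicon under the given MAM pattern; a template with several binding
#' sites still counts once. Reported to one decimal place.
#'
#' @param pair a [primer_pair].
#' @param targets a `ref_db` (or data.frame with `id`, `seq`) of target
#'   records; must be non-empty.
#' @param pattern a [mam_pattern].
#' @param max_len maximum amplicon length in bp.
#' @return coverage percentage in \[0, 100\], rounded to one decimal.
#' @export
coverage <- function(pair, targets, pattern, max_len = 450L) {
  if (!nrow(targets)) {
    stop("coverage is undefined for an empty target set", call. = FALSE)
  }
  hit <- vapply(seq_len(nrow(targets)), function(i) {
    nrow(predict_amplicons(pair, targets[i, , drop = FALSE], pattern,
                           max_len = max_len)) > 0L
  }, logical(1L))
  round(100 * sum(hit) / nrow(targets), 1L)
}

#' Per-pattern coverage/specificity report for a primer pair
#'
#' For each MAM pattern, computes the percentage of target-clade records
#' and of non-target records that are amplifiable by the pair (both
#' primers bound in convergent orientation, amplicon within `max_len`).
#' The non-target denominator is the number of non-target records.
#' Offending non-target matches are returned with per-primer mismatch
#' distances from the 3' end, which drive 3'-positional ranking of
#' candidate primers.
#'
#' @param pair a [primer_pair].
#' @param db a [ref_db].
#' @param target_clade clade label in `db`.
#' @param patterns list of [mam_pattern]s (e.g. [mam_presets()]).
#' @param max_len maximum amplicon length in bp.
#' @return object of class `specificity_report`: list with `pair_name`,
#'   `target_clade`, `summary` (data.frame: pattern, pct_targets,
#'   pct_nontargets, n_targets, n_nontargets) and `offending` (named list
#'   per pattern of data.frames with seq_id, clade and per-primer
#'   mismatch-position list columns).
#' @export
specificity_report <- function(pair, db, target_clade, patterns = mam_presets(),
                               max_len = 450L) {
  stopifnot(inherits(pair, "primer_pair"), length(patterns) > 0L)
  parts <- partition(db, target_clade)
  tg <- parts$targets
  nt <- parts$nontargets
  labs <- vapply(patterns, `[[`, character(1L), "label")
  summary <- data.frame(pattern = labs,
                        pct_targets = NA_real_, pct_nontargets = NA_real_,
                        n_targets = nrow(tg), n_nontargets = nrow(nt),
                        stringsAsFactors = FALSE)
  offending <- stats::setNames(vector("list", length(patterns)), labs)
  for (j in seq_along(patterns)) {
    pat <- patterns[[j]]
    tg_hit <- if (nrow(tg)) vapply(seq_len(nrow(tg)), function(i) {
      nrow(predict_amplicons(pair, tg[i, , drop = FALSE], pat, max_len)) > 0L
    }, logical(1L)) else logical()
    off <- list()
    nt_hit <- logical(nrow(nt))
    for (i in seq_len(nrow(nt))) {
      amp <- predict_amplicons(pair, nt[i, , drop = FALSE], pat, max_len)
      if (nrow(amp)) {
        nt_hit[i] <- TRUE
        best <- which.min(amp$f_mismatches + amp$r_mismatches)
        off[[length(off) + 1L]] <- data.frame(
          seq_id = nt$id[i], clade = nt$clade[i],
          f_mismatches = amp$f_mismatches[best],
          r_mismatches = amp$r_mismatches[best],
          stringsAsFactors = FALSE
        )
        off[[length(off)]]$f_mismatch_pos <- amp$f_mismatch_pos[best]
        off[[length(off)]]$r_mismatch_pos <- amp$r_mismatch_pos[best]
      }
    }
    summary$pct_targets[j] <-
      if (nrow(tg)) round(100 * sum(tg_hit) / nrow(tg), 1L) else NA_real_
    summary$pct_nontargets[j] <-
      if (nrow(nt)) round(100 * sum(nt_hit) / nrow(nt), 1L) else 0
    offending[[j]] <- if (length(off)) do.call(rbind, off) else
      data.frame(seq_id = character(), clade = character(),
                 f_mismatches = integer(), r_mismatches = integer(),
                 stringsAsFactors = FALSE)
  }
  structure(list(pair_name = pair$name, target_clade = target_clade,
                 summary = summary, offending = offending),
            class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("Specificity report for ", x$pair_name,
      " (target clade ", x$target_clade, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
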