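#' Primer design constraints
#'
#' Screening thresholds applied to candidate primer pairs before the
#' coverage/specificity criteria. Defaults reflect common qPCR design
#' practice for SYBR assays on short marker-gene amplicons: amplicons are
#' capped at 450 bp, degenerate primer bases are disallowed, and the
#' melting-temperature difference and inter/intra-primer complementarity
#' are controlled.
#'
#' @param primer_len_range integer length-2, allowed primer lengths (nt).
#' @param max_amplicon_bp maximum amplicon length (bp).
#' @param min_amplicon_bp minimum amplicon length (bp).
#' @param allow_degenerate allow degenerate bases in candidate primers?
#' @param max_tm_diff_C maximum |Tm(forward) - Tm(reverse)| in degrees C.
#' @param max_self_complementarity_run maximum contiguous complementary
#'   run within/between primers.
#' @param max_3prime_complementarity_run maximum complementary run
#'   anchored at a primer 3' end.
#' @return object of class `design_constraints`.
#' @export
design_constraints <- function(primer_len_range = c(17L, 25L),
                               max_amplicon_bp = 450L,
                               min_amplicon_bp = 70L,
                               allow_degenerate = FALSE,
                               max_tm_diff_C = 3.0,
                               max_self_complementarity_run = 8L,
                               max_3prime_complementarity_run = 4L) {
  stopifnot(length(primer_len_range) == 2L,
            primer_len_range[1L] <= primer_len_range[2L],
            min_amplicon_bp <= max_amplicon_bp,
            max_tm_diff_C >= 0, max_self_complementarity_run >= 0,
            max_3prime_complementarity_run >= 0)
  structure(list(primer_len_range = as.integer(primer_len_range),
                 max_amplicon_bp = as.integer(max_amplicon_bp),
                 min_amplicon_bp = as.integer(min_amplicon_bp),
                 allow_degenerate = isTRUE(allow_degenerate),
                 max_tm_diff_C = max_tm_diff_C,
                 max_self_complementarity_run = as.integer(max_self_complementarity_run),
                 max_3prime_complementarity_run = as.integer(max_3prime_complementarity_run)),
            class = "design_constraints")
}

#' Find windows conserved across all target sequences
#'
#' Enumerates windows of the requested lengths on a designated reference
#' target (the first record) and keeps those that occur with zero
#' mismatches (IUPAC-aware) in at least `min_fraction` of the targets.
#' Targets need not be aligned: conservation is verified by exact-match
#' scanning of every target.
#'
#' @param targets `ref_db` (or data.frame with `seq`) of target records;
#'   non-empty.
#' @param len_range integer length-2 window length range (nt).
#' @param min_fraction minimum fraction of targets that must contain the
#'   window exactly (default 1 = all).
#' @return data.frame with columns `start` (1-based position on the
#'   reference target), `length` and `consensus`. Zero rows is valid.
#' @export
conserved_windows <- function(targets, len_range = c(17L, 25L),
                              min_fraction = 1) {
  if (!nrow(targets)) stop("no target sequences", call. = FALSE)
  ref <- targets$seq[1L]
  others <- targets$seq[-1L]
  n_needed <- ceiling(min_fraction * nrow(targets))
  plain <- all(grepl("^[ACGT]*$", targets$seq))
  omask <- if (!plain) lapply(others, encode_iupac)
  out <- list()
  for (L in seq(len_range[1L], len_range[2L])) {
    n_win <- nchar(ref) - L + 1L
    if (n_win < 1L) next
    starts <- seq_len(n_win)
    wins <- substring(ref, starts, starts + L - 1L)
    counts <- rep(1L, n_win)  # the reference target itself
    if (length(others)) {
      if (plain) {
        for (s in others) {
          counts <- counts + vapply(wins, grepl, logical(1L), x = s,
                                    fixed = TRUE, USE.NAMES = FALSE)
        }
      } else {
        d3 <- rev(seq_len(L))
        for (tm in omask) {
          counts <- counts + vapply(starts, function(i) {
            length(scan_site(encode_iupac(wins[i]), d3, tm, 0L, 0L)$start) > 0L
          }, logical(1L))
        }
      }
    }
    keep <- counts >= n_needed
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(start = starts[keep], length = L,
                                            consensus = wins[keep],
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), length = integer(),
                      consensus = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# SantaLucia (1998) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K); keys are 5'->3' dinucleotides.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)   # per terminal base pair
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature from the unified nearest-neighbor
#' thermodynamic table (SantaLucia 1998), with initiation terms for the
#' terminal base pairs and the entropic salt correction
#' 0.368 (N-1) ln\[Na+\]. Default conditions: 50 mM monovalent salt,
#' 400 nM total primer, Tm = 1000 dH / (dS + R ln(Ct/4)) - 273.15.
#'
#' @param seq non-degenerate DNA string (>= 2 nt).
#' @param primer_conc_M total primer concentration in mol/L.
#' @param na_conc_M monovalent cation concentration in mol/L.
#' @return melting temperature in degrees Celsius.
#' @examples
#' melting_temperature("TGAAGGCATTCGCTTCCT")
#' @export
melting_temperature <- function(seq, primer_conc_M = 4e-7, na_conc_M = 0.05) {
  seq <- normalize_dna(seq, "primer sequence")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    stop("melting_temperature() requires a non-degenerate sequence",
         call. = FALSE)
  }
  L <- length(chars)
  if (L < 2L) stop("sequence too short for a nearest-neighbor model",
                   call. = FALSE)
  dinucs <- paste0(chars[-L], chars[-1L])
  dh <- sum(NN_DH[dinucs])
  ds <- sum(NN_DS[dinucs])
  ends <- ifelse(chars[c(1L, L)] %in% c("G", "C"), "GC", "AT")
  dh <- dh + sum(NN_INIT_DH[ends])
  ds <- ds + sum(NN_INIT_DS[ends])
  ds <- ds + 0.368 * (L - 1L) * log(na_conc_M)
  R <- 1.98720425864083  # cal/(mol K)
  1000 * dh / (ds + R * log(primer_conc_M / 4)) - 273.15
}

#' Inter/intra-primer complementarity scores
#'
#' Slides `a` (5'->3') against `b` (3'->5') over all ungapped offsets and
#' reports the longest contiguous Watson-Crick complementary run, plus
#' the longest run that includes either primer's 3'-terminal base
#' (the 3'-anchored run, the configuration that primes primer-dimer
#' extension). Self-complementarity is `complementarity_scores(a, a)`.
#'
#' @param a,b DNA strings, 5'->3'.
#' @return named numeric vector with `max_run` and `max_3prime_run`.
#' @export
complementarity_scores <- function(a, b) {
  am <- encode_iupac(normalize_dna(a, "sequence a"))
  bm <- rev(encode_iupac(normalize_dna(b, "sequence b")))  # b laid 3'->5'
  bcomp <- mask_complement(bm)
  la <- length(am)
  lb <- length(bm)
  max_run <- 0L
  max_3p <- 0L
  # offset: a[i] pairs b3to5[i + off]; off in (1-la)..(lb-1)
  for (off in seq(1L - la, lb - 1L)) {
    i <- seq(max(1L, 1L - off), min(la, lb - off))
    if (!length(i)) next
    comp <- bitwAnd(am[i], bcomp[i + off]) > 0L
    r <- rle(comp)
    runs <- r$lengths[r$values]
    if (length(runs)) max_run <- max(max_run, max(runs))
    # 3'-anchored: run containing a's 3' end (i == la) or b's 3' end
    # (b3to5 index 1, i.e. i + off == 1)
    ends_r <- cumsum(r$lengths)
    starts_r <- ends_r - r$lengths + 1L
    for (anchor in c(la, 1L - off)) {
      idx <- match(TRUE, anchor >= i[1L] & anchor <= i[length(i)])
      if (is.na(idx)) next
      k <- which(starts_r <= anchor - i[1L] + 1L & ends_r >= anchor - i[1L] + 1L)
      if (length(k) && r$values[k]) max_3p <- max(max_3p, r$lengths[k])
    }
  }
  c(max_run = as.integer(max_run), max_3prime_run = as.integer(max_3p))
}

#' Enumerate and rank clade-specific candidate primer pairs
#'
#' Candidate forward primers are windows conserved in all targets;
#' candidate reverse primers are reverse complements of such windows.
#' Pairs are screened against the [design_constraints()] (length,
#' amplicon size, degeneracy, Tm difference, complementarity), then
#' against the selection criteria: (i) 100% of targets and 0% of
#' non-targets matched under the stringent pattern (`0MAM`); (ii) as few
#' non-target records as possible matched under the flexible patterns
#' (`criterion2_score`, ascending); (iii) among flexible-pattern
#' non-target matches, mismatches as close to the primer 3' end as
#' possible (`criterion3_score` = smallest distance-from-3'-end of the
#' closest-to-3' mismatch, ascending; ties by mean distance). Remaining
#' ties break by amplicon length, then pair name.
#'
#' @param targets,nontargets `ref_db` partitions (see [partition()]).
#' @param constraints a [design_constraints()].
#' @param patterns named list of [mam_pattern]s; must contain a stringent
#'   `0MAM` (k = 0) pattern, all others are treated as flexible.
#' @param max_candidates cap on screened pairs (windows are paired
#'   left-to-right until the cap).
#' @return data.frame of class `candidate_ranking`, best candidate first,
#'   with per-criterion columns. When no pair passes, a zero-row frame
#'   whose `"diagnostic"` attribute names the tightest failing stage.
#' @export
rank_candidates <- function(targets, nontargets,
                            constraints = design_constraints(),
                            patterns = mam_presets(),
                            max_candidates = 5000L) {
  stopifnot(inherits(constraints, "design_constraints"))
  k0 <- vapply(patterns, function(p) p$max_mismatches == 0L, logical(1L))
  if (!any(k0)) stop("patterns must include a stringent (k = 0) pattern",
                     call. = FALSE)
  stringent <- patterns[[which(k0)[1L]]]
  flexible <- patterns[!k0]
  if (!length(flexible)) stop("patterns must include a flexible pattern",
                              call. = FALSE)

  empty <- function(reason) {
    out <- data.frame(pair_name = character(), f_name = character(),
                      r_name = character(), f_seq = character(),
                      r_seq = character(), f_start = integer(),
                      r_end = integer(), amplicon_bp = integer(),
                      tm_f = numeric(), tm_r = numeric(),
                      criterion1_pass = logical(), criterion2_score = numeric(),
                      criterion3_score = numeric(), criterion3_mean = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "diagnostic") <- reason
    class(out) <- c("candidate_ranking", "data.frame")
    out
  }

  wins <- conserved_windows(targets, constraints$primer_len_range)
  if (!constraints$allow_degenerate) {
    wins <- wins[grepl("^[ACGT]+$", wins$consensus), , drop = FALSE]
  }
  if (!nrow(wins)) return(empty("no conserved window in all targets"))
  wins$end <- wins$start + wins$length - 1L
  wins$tm <- vapply(wins$consensus, melting_temperature, numeric(1L),
                    USE.NAMES = FALSE)

  # Precompute, per window x record, every binding offset with at most
  # kmax mismatches, keeping the site-local mismatch positions. A window
  # used as a forward primer binds the reference strand as-is; used as a
  # reverse primer (sequence = reverse complement of the window) it lays
  # down the very same site, so one scan serves both orientations --
  # only the 3'-end geometry differs.
  kmax <- max(vapply(patterns, `[[`, integer(1L), "max_mismatches"))
  tg_masks <- lapply(targets$seq, encode_iupac)
  nt_masks <- lapply(nontargets$seq, encode_iupac)
  win_masks <- lapply(wins$consensus, encode_iupac)
  scan_all <- function(wmask, masks, k) {
    lapply(masks, function(tm) {
      scan_site(wmask, seq_along(wmask), tm, k, 0L)
    })
  }
  tg_hits <- lapply(win_masks, scan_all, masks = tg_masks, k = 0L)
  nt_hits <- lapply(win_masks, scan_all, masks = nt_masks, k = kmax)

  # per-window self-complementarity in both roles (forward = consensus,
  # reverse = its reverse complement)
  wins$rc <- vapply(wins$consensus, revcomp_dna, character(1L),
                    USE.NAMES = FALSE)
  self_fwd <- lapply(wins$consensus, function(s) complementarity_scores(s, s))
  self_rev <- lapply(wins$rc, function(s) complementarity_scores(s, s))

  # admissible offsets of window `hits` under (k, w) in a given role
  admissible <- function(hits, L, k, w, role) {
    keep <- hits$n_mismatches <= k
    if (w > 0L && any(keep)) {
      keep[keep] <- vapply(which(keep), function(m) {
        pos <- hits$mismatch_pos[[m]]  # site-local, 1 = leftmost
        if (!length(pos)) return(TRUE)
        if (role == "forward") all(pos <= L - w) else all(pos > w)
      }, logical(1L))
    }
    hits$start[keep]
  }
  pairable <- function(f_off, r_off, Lf, Lr, max_len) {
    if (!length(f_off) || !length(r_off)) return(FALSE)
    len <- outer(r_off + Lr - 1L, f_off, `-`) + 1L
    any(len >= max(Lf, Lr) & len <= max_len)
  }

  # candidate pairs: forward window strictly left of reverse window,
  # amplicon = r_end - f_start + 1 within bounds, Tm difference bounded
  rows <- list()
  n_pairs_geom <- 0L
  n_tm_fail <- 0L
  n_thermo_fail <- 0L
  n_c1_fail <- 0L
  n_pairs <- 0L
  max_len <- constraints$max_amplicon_bp
  for (i in seq_len(nrow(wins))) {
    amp <- wins$end - wins$start[i] + 1L
    js <- which(wins$start > wins$end[i] &
                amp >= constraints$min_amplicon_bp & amp <= max_len)
    if (!length(js)) next
    n_pairs_geom <- n_pairs_geom + length(js)
    tm_ok <- abs(wins$tm[js] - wins$tm[i]) <= constraints$max_tm_diff_C
    n_tm_fail <- n_tm_fail + sum(!tm_ok)
    js <- js[tm_ok]
    Lf <- wins$length[i]
    for (j in js) {
      if (n_pairs >= max_candidates) break
      n_pairs <- n_pairs + 1L
      Lr <- wins$length[j]
      # criterion (i): every target amplifiable and no non-target
      # amplifiable under the stringent (k = 0) pattern
      c1 <- TRUE
      for (t in seq_along(tg_masks)) {
        if (!pairable(tg_hits[[i]][[t]]$start, tg_hits[[j]][[t]]$start,
                      Lf, Lr, max_len)) { c1 <- FALSE; break }
      }
      if (c1) {
        for (t in seq_along(nt_masks)) {
          f0 <- admissible(nt_hits[[i]][[t]], Lf, 0L, 0L, "forward")
          r0 <- admissible(nt_hits[[j]][[t]], Lr, 0L, 0L, "reverse")
          if (pairable(f0, r0, Lf, Lr, max_len)) { c1 <- FALSE; break }
        }
      }
      if (!c1) { n_c1_fail <- n_c1_fail + 1L; next }
      f_seq <- wins$consensus[i]
      r_seq <- wins$rc[j]
      self_f <- self_fwd[[i]]
      self_r <- self_rev[[j]]
      cross <- complementarity_scores(f_seq, r_seq)
      if (max(self_f["max_run"], self_r["max_run"], cross["max_run"]) >
            constraints$max_self_complementarity_run ||
          max(self_f["max_3prime_run"], self_r["max_3prime_run"],
              cross["max_3prime_run"]) >
            constraints$max_3prime_complementarity_run) {
        n_thermo_fail <- n_thermo_fail + 1L
        next
      }
      # flexible patterns: count amplifiable non-targets (criterion ii)
      # and their closest-to-3' mismatch distances (criterion iii)
      c2 <- 0L
      dists <- numeric()
      for (pat in flexible) {
        k <- pat$max_mismatches
        w <- pat$protected_3prime
        for (t in seq_along(nt_masks)) {
          fh <- nt_hits[[i]][[t]]
          rh <- nt_hits[[j]][[t]]
          f_off <- admissible(fh, Lf, k, w, "forward")
          r_off <- admissible(rh, Lr, k, w, "reverse")
          if (!pairable(f_off, r_off, Lf, Lr, max_len)) next
          c2 <- c2 + 1L
          # best prediction = fewest total mismatches among admissible
          # convergent combinations; distance = closest-to-3' mismatch
          best <- NULL
          for (fo in f_off) for (ro in r_off) {
            len <- ro + Lr - 1L - fo + 1L
            if (len < max(Lf, Lr) || len > max_len) next
            fi_ <- match(fo, fh$start)
            ri_ <- match(ro, rh$start)
            tot <- fh$n_mismatches[fi_] + rh$n_mismatches[ri_]
            if (is.null(best) || tot < best$tot) {
              fpos <- fh$mismatch_pos[[fi_]]
              rpos <- rh$mismatch_pos[[ri_]]
              best <- list(tot = tot,
                           d3 = c(Lf - fpos + 1L, rpos))
            }
          }
          if (!is.null(best) && length(best$d3)) {
            dists <- c(dists, min(best$d3))
          }
        }
      }
      f_name <- sprintf("cand-%df", wins$start[i])
      r_name <- sprintf("cand-%dr", wins$end[j])
      rows[[length(rows) + 1L]] <- data.frame(
        pair_name = paste(f_name, r_name, sep = "/"),
        f_name = f_name, r_name = r_name,
        f_seq = f_seq, r_seq = r_seq,
        f_start = wins$start[i], r_end = wins$end[j],
        amplicon_bp = wins$end[j] - wins$start[i] + 1L,
        tm_f = wins$tm[i], tm_r = wins$tm[j],
        criterion1_pass = TRUE,
        criterion2_score = c2,
        criterion3_score = if (length(dists)) min(dists) else 0,
        criterion3_mean = if (length(dists)) mean(dists) else 0,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    reason <- if (n_c1_fail > 0L) {
      "no pair with 100% target / 0% non-target at the stringent pattern"
    } else if (n_thermo_fail > 0L) {
      "all pairs failed the complementarity screen"
    } else if (n_tm_fail > 0L) {
      "no window pair within the Tm-difference limit"
    } else if (n_pairs_geom == 0L) {
      "no window pair within amplicon bounds"
    } else {
      "no screened pair"
    }
    return(empty(reason))
  }
  out <- do.call(rbind, rows)
  ord <- order(out$criterion2_score, out$criterion3_score,
               out$criterion3_mean, out$amplicon_bp, out$pair_name)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_ranking", "data.frame")
  out
}
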