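# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so fixture generation never perturbs user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute the base at position i of a character vector with a
# different (uniformly chosen) base.
substitute_base <- function(chars, idx) {
  for (i in idx) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  chars
}

#' Specify a planted primer-pair site for the synthetic database
#'
#' Describes a forward/reverse primer-site pair written verbatim into
#' every sequence of one clade and corrupted in every other sequence.
#' Coordinates follow the reference-strand convention: `forward_coord`
#' is the forward primer's 5' (leftmost) template position and
#' `reverse_coord` the reverse primer's rightmost template position, so
#' the planted amplicon spans `reverse_coord - forward_coord + 1` bp.
#'
#' @param clade target clade label.
#' @param forward_coord,forward_seq forward site position and primer
#'   sequence (5'->3').
#' @param reverse_coord,reverse_seq reverse site rightmost position and
#'   reverse primer sequence (5'->3'; its reverse complement is planted
#'   on the reference strand).
#' @param min_nontarget_mismatches minimum substitutions introduced into
#'   each site of every non-target sequence (default 4).
#' @param force_3prime_mismatch when `TRUE`, one non-target substitution
#'   is placed exactly at each primer's 3'-terminal position, so the
#'   pair discriminates under a 3'-protected pattern (`1MAM`) but not
#'   under its unprotected variant (`1MAM*`) when
#'   `min_nontarget_mismatches = 1`.
#' @return a `planted_site` list.
#' @export
planted_site <- function(clade, forward_coord, forward_seq,
                         reverse_coord, reverse_seq,
                         min_nontarget_mismatches = 4L,
                         force_3prime_mismatch = FALSE) {
  forward_seq <- normalize_dna(forward_seq, "forward_seq")
  reverse_seq <- normalize_dna(reverse_seq, "reverse_seq")
  structure(list(clade = clade,
                 forward_coord = as.integer(forward_coord),
                 forward_seq = forward_seq,
                 reverse_coord = as.integer(reverse_coord),
                 reverse_seq = reverse_seq,
                 min_nontarget_mismatches = as.integer(min_nontarget_mismatches),
                 force_3prime_mismatch = isTRUE(force_3prime_mismatch)),
            class = "planted_site")
}

# reference-strand intervals and 3'-terminal positions of a planted site
site_intervals <- function(site) {
  lf <- nchar(site$forward_seq)
  lr <- nchar(site$reverse_seq)
  f <- c(site$forward_coord, site$forward_coord + lf - 1L)
  r <- c(site$reverse_coord - lr + 1L, site$reverse_coord)
  list(f = f, r = r,
       f_site = site$forward_seq,
       r_site = revcomp_dna(site$reverse_seq),
       f_3prime = f[2L],   # forward 3' end = rightmost site base
       r_3prime = r[1L])   # reverse 3' end = leftmost site base
}

#' Generate a synthetic clade-structured reference database
#'
#' Emulates a multi-clade marker-gene database with controlled
#' inter/intra-clade divergence and planted, exactly conserved primer
#' sites. Each clade receives a consensus derived from a common ancestor
#' by substitutions at clade-specific disjoint positions (guaranteeing
#' at least `inter_clade_divergence` pairwise differences between
#' consensuses); each sequence then mutates its clade consensus
#' independently at `intra_clade_substitution_rate` per position.
#' Planted sites are copied verbatim into every target-clade sequence
#' and corrupted with at least `min_nontarget_mismatches` substitutions
#' per primer site in every non-target sequence; planted regions are
#' excluded from background mutation, so the coverage/specificity
#' guarantees hold exactly. Substitutions only; no indels.
#'
#' @param n_clades number of clades (labels taken from
#'   [accumulibacter_clades()] when `clades` is `NULL`).
#' @param seqs_per_clade sequences per clade.
#' @param seq_length_bp sequence length.
#' @param intra_clade_substitution_rate per-position substitution
#'   probability within a clade (in \[0, 1\]).
#' @param inter_clade_divergence minimum pairwise substitutions between
#'   clade consensuses.
#' @param planted_sites list of [planted_site()] specifications.
#' @param seed integer seed fixing all randomness.
#' @param clades optional explicit clade labels (length `n_clades`).
#' @return a [ref_db]; ids are `"SYN-<clade>-<k>"`.
#' @examples
#' db <- generate_clade_db(n_clades = 2, seqs_per_clade = 3,
#'                         seq_length_bp = 200, seed = 1)
#' @export
generate_clade_db <- function(n_clades = 14L, seqs_per_clade = 10L,
                              seq_length_bp = 1000L,
                              intra_clade_substitution_rate = 0.02,
                              inter_clade_divergence = 10L,
                              planted_sites = list(),
                              seed = 1L, clades = NULL) {
  stopifnot(n_clades >= 1L, seqs_per_clade >= 1L, seq_length_bp >= 1L,
            intra_clade_substitution_rate >= 0,
            intra_clade_substitution_rate <= 1)
  if (is.null(clades)) {
    if (n_clades <= 14L) clades <- accumulibacter_clades()[seq_len(n_clades)]
    else clades <- sprintf("C%02d", seq_len(n_clades))
  }
  stopifnot(length(clades) == n_clades)
  if (inherits(planted_sites, "planted_site")) {
    planted_sites <- list(planted_sites)
  }
  for (s in planted_sites) {
    iv <- site_intervals(s)
    if (!s$clade %in% clades) {
      stop("planted site targets unknown clade '", s$clade, "'",
           call. = FALSE)
    }
    if (iv$f[1L] < 1L || iv$r[2L] > seq_length_bp || iv$f[2L] >= iv$r[1L]) {
      stop("planted site for clade ", s$clade,
           " does not fit the sequence length", call. = FALSE)
    }
  }
  if (n_clades * inter_clade_divergence > seq_length_bp) {
    stop("inter-clade divergence exceeds available sequence length",
         call. = FALSE)
  }

  # positions covered by any planted site: excluded from background
  # mutation and from consensus divergence
  planted_pos <- unique(unlist(lapply(planted_sites, function(s) {
    iv <- site_intervals(s)
    c(seq(iv$f[1L], iv$f[2L]), seq(iv$r[1L], iv$r[2L]))
  })))

  with_seed(seed, {
    ancestor <- strsplit(random_dna(seq_length_bp), "")[[1L]]
    free_pos <- setdiff(seq_len(seq_length_bp), planted_pos)
    if (length(free_pos) < n_clades * inter_clade_divergence) {
      stop("not enough unplanted positions for the requested divergence",
           call. = FALSE)
    }
    # disjoint clade-specific mutation blocks => pairwise divergence
    # >= 2 * inter_clade_divergence >= inter_clade_divergence
    div_pos <- sample(free_pos, n_clades * inter_clade_divergence)
    records <- list()
    for (ci in seq_len(n_clades)) {
      clade <- clades[ci]
      block <- div_pos[seq((ci - 1L) * inter_clade_divergence + 1L,
                           ci * inter_clade_divergence)]
      consensus <- substitute_base(ancestor, block)
      for (k in seq_len(seqs_per_clade)) {
        chars <- consensus
        if (intra_clade_substitution_rate > 0 && length(free_pos)) {
          mut <- free_pos[stats::runif(length(free_pos)) <
                            intra_clade_substitution_rate]
          chars <- substitute_base(chars, mut)
        }
        # write planted sites: exact in targets, corrupted in non-targets
        for (s in planted_sites) {
          iv <- site_intervals(s)
          f_chars <- strsplit(iv$f_site, "")[[1L]]
          r_chars <- strsplit(iv$r_site, "")[[1L]]
          if (clade == s$clade) {
            chars[iv$f[1L]:iv$f[2L]] <- f_chars
            chars[iv$r[1L]:iv$r[2L]] <- r_chars
          } else {
            chars[iv$f[1L]:iv$f[2L]] <-
              corrupt_site(f_chars, s$min_nontarget_mismatches,
                           if (s$force_3prime_mismatch) length(f_chars))
            chars[iv$r[1L]:iv$r[2L]] <-
              corrupt_site(r_chars, s$min_nontarget_mismatches,
                           if (s$force_3prime_mismatch) 1L)
          }
        }
        records[[length(records) + 1L]] <- list(
          id = sprintf("SYN-%s-%03d", clade, k),
          clade = clade,
          seq = paste(chars, collapse = "")
        )
      }
    }
    ref_db(vapply(records, `[[`, character(1L), "id"),
           vapply(records, `[[`, character(1L), "clade"),
           vapply(records, `[[`, character(1L), "seq"))
  })
}

# Introduce >= n_mm substitutions into a site; `forced` (site-local
# index) always receives one of them when given.
corrupt_site <- function(chars, n_mm, forced = NULL) {
  n_mm <- min(n_mm, length(chars))
  idx <- integer()
  if (!is.null(forced)) idx <- forced
  pool <- setdiff(seq_along(chars), idx)
  if (length(idx) < n_mm) {
    idx <- c(idx, sample(pool, n_mm - length(idx)))
  }
  substitute_base(chars, idx)
}

#' Simulate a qPCR dilution-series Ct table
#'
#' Generates replicate Ct values for a ten-fold (or arbitrary) dilution
#' series under the standard-curve model inverted:
#' `Ct = intercept_ct - log10(copies) / log10(1 + efficiency) + N(0, sd)`.
#' Values above the detection limit are reported as undetected
#' (`ct = NA`, `detected = FALSE`).
#'
#' @param true_efficiency amplification efficiency as a fraction (1.0 =
#'   perfect doubling).
#' @param intercept_ct Ct at one template copy.
#' @param copies vector of template copy numbers per dilution level
#'   (default `10^(3:8)`, a six-point ten-fold series).
#' @param replicates replicates per level (default 6).
#' @param ct_noise_sd Gaussian Ct noise standard deviation.
#' @param undetected_above_ct detection limit in cycles (default 40).
#' @param seed integer seed.
#' @return data.frame with columns `copies`, `log10_copies`, `replicate`,
#'   `ct` (NA when undetected), `detected`.
#' @examples
#' simulate_ct(true_efficiency = 1, ct_noise_sd = 0, seed = 1)
#' @export
simulate_ct <- function(true_efficiency = 1.0, intercept_ct = 38,
                        copies = 10^(3:8), replicates = 6L,
                        ct_noise_sd = 0.15, undetected_above_ct = 40,
                        seed = 1L) {
  stopifnot(true_efficiency > 0, ct_noise_sd >= 0, replicates >= 1L)
  with_seed(seed, {
    lg <- rep(log10(copies), each = replicates)
    ct <- intercept_ct - lg / log10(1 + true_efficiency) +
      stats::rnorm(length(lg), 0, ct_noise_sd)
    detected <- ct <= undetected_above_ct
    data.frame(copies = rep(copies, each = replicates),
               log10_copies = lg,
               replicate = rep(seq_len(replicates), times = length(copies)),
               ct = ifelse(detected, ct, NA_real_),
               detected = detected)
  })
}
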