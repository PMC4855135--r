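test_that("base compatibility equals IUPAC set intersection on all 15x15 pairs", {
  codes <- names(IUPAC_SETS)
  for (a in codes) for (b in codes) {
    expect_identical(base_compatible(a, b), ORACLE_COMPAT[a, b],
                     info = paste(a, b))
  }
  expect_error(base_compatible("A", "X"), "non-IUPAC")
})

test_that("an exactly planted primer yields one perfect match", {
  p <- primer("ACGTTGCACG", "forward", "toy-3f")
  tmpl <- paste0("GG", "ACGTTGCACG", "TTTT")
  m <- match_primer(p, tmpl, mam_pattern(0))
  expect_equal(nrow(m), 1L)
  expect_equal(m$template_start, 3L)
  expect_equal(m$n_mismatches, 0L)
  expect_length(m$mismatch_pos_3prime[[1L]], 0L)

  # a primer longer than the template is an empty result, not an error
  long <- primer(strrep("ACGT", 5L), "forward")
  expect_equal(nrow(match_primer(long, "ACGTACGT", mam_pattern(0))), 0L)
})

test_that("the 3'-protected window separates 1MAM from 1MAM*", {
  # template's only candidate site mismatches the primer at its 3' terminus
  p <- primer("ACGTTGCACG", "forward", "toy-1f")
  tmpl <- paste0("ACGTTGCACT", "AAAA")  # last primer base G vs template T
  m_protected <- match_primer(p, tmpl, mam_presets()[["1MAM"]])
  m_free <- match_primer(p, tmpl, mam_presets()[["1MAM*"]])
  expect_equal(nrow(m_protected), 0L)
  expect_equal(nrow(m_free), 1L)
  expect_equal(m_free$mismatch_pos_3prime[[1L]], 1L)

  # the same discrimination for a reverse primer (3' end faces left)
  rp <- primer("ACGTTGCACG", "reverse", "toy-20r")
  site <- revcomp_dna("ACGTTGCACG")
  site_mm <- paste0("A", substring(site, 2L))  # leftmost = reverse 3' terminus
  if (substring(site, 1L, 1L) == "A") site_mm <- paste0("G", substring(site, 2L))
  tmpl_r <- paste0("TT", site_mm, "GG")
  expect_equal(nrow(match_primer(rp, tmpl_r, mam_presets()[["1MAM"]])), 0L)
  mr <- match_primer(rp, tmpl_r, mam_presets()[["1MAM*"]])
  expect_equal(nrow(mr), 1L)
  expect_equal(mr$mismatch_pos_3prime[[1L]], 1L)
})

test_that("matcher agrees with the brute-force oracle on random instances", {
  set.seed(424L)
  for (rep in 1:300) {
    L <- sample(10:20, 1L)
    n <- sample(40:120, 1L)
    alphabet <- if (rep %% 5 == 0) names(IUPAC_SETS) else c("A", "C", "G", "T")
    pseq <- random_dna_str(L, if (rep %% 7 == 0) c("A", "C", "G", "T", "R", "N")
                              else c("A", "C", "G", "T"))
    tmpl <- random_dna_str(n, alphabet)
    ori <- sample(c("forward", "reverse"), 1L)
    k <- sample(0:3, 1L)
    w <- sample(0:2, 1L)
    got <- match_primer(primer(pseq, ori), tmpl, mam_pattern(k, w))
    want <- oracle_match(pseq, ori, tmpl, k, w)
    expect_equal(got$template_start, want$start,
                 info = sprintf("rep %d starts", rep))
    expect_equal(got$n_mismatches, want$n_mismatches,
                 info = sprintf("rep %d counts", rep))
    expect_equal(got$mismatch_pos_3prime, want$mismatch_pos,
                 ignore_attr = TRUE, info = sprintf("rep %d positions", rep))
  }
})

test_that("strand symmetry: reverse-complementing the template mirrors matches", {
  set.seed(77L)
  for (rep in 1:50) {
    L <- sample(10:16, 1L)
    n <- sample(50:100, 1L)
    pseq <- random_dna_str(L)
    tmpl <- random_dna_str(n)
    k <- sample(0:3, 1L)
    fwd <- match_primer(primer(pseq, "forward"), tmpl, mam_pattern(k))
    rev_ <- match_primer(primer(pseq, "reverse"), revcomp_dna(tmpl),
                         mam_pattern(k))
    expect_setequal(n - fwd$template_end + 1L, rev_$template_start)
    expect_equal(sort(fwd$n_mismatches), sort(rev_$n_mismatches))
  }
})

test_that("amplicon prediction applies the coordinate and orientation rules", {
  # planted convergent pair: forward 5' at 11, reverse rightmost at 52
  set.seed(9L)
  fseq <- "ACGGTTACAG"
  rseq <- "TTGACCAGTC"
  tmpl_chars <- strsplit(random_dna_str(80L), "")[[1L]]
  tmpl_chars[11:20] <- strsplit(fseq, "")[[1L]]
  tmpl_chars[43:52] <- strsplit(revcomp_dna(rseq), "")[[1L]]
  tmpl <- paste(tmpl_chars, collapse = "")
  pair <- primer_pair(primer(fseq, "forward", "t-11f"),
                      primer(rseq, "reverse", "t-52r"))
  amp <- predict_amplicons(pair, tmpl, mam_pattern(0))
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$start, 11L)
  expect_equal(amp$end, 52L)
  expect_equal(amp$length_bp, 42L)
  expect_equal(amp$length_bp, amp$end - amp$start + 1L)

  # divergent orientation (reverse site upstream of forward site) -> none
  tmpl2_chars <- strsplit(random_dna_str(80L), "")[[1L]]
  tmpl2_chars[43:52] <- strsplit(fseq, "")[[1L]]
  tmpl2_chars[11:20] <- strsplit(revcomp_dna(rseq), "")[[1L]]
  tmpl2 <- paste(tmpl2_chars, collapse = "")
  expect_equal(nrow(predict_amplicons(pair, tmpl2, mam_pattern(0))), 0L)

  # max_len filter
  expect_equal(nrow(predict_amplicons(pair, tmpl, mam_pattern(0),
                                      max_len = 41L)), 0L)
})

test_that("amplicon prediction is strand-symmetric up to mirrored coordinates", {
  fix <- make_planted_fixture(seed = 31L)
  rec <- partition(fix$db, "IA")$targets[1L, ]
  n <- nchar(rec$seq)
  amp <- predict_amplicons(fix$pair, rec$seq, mam_pattern(1))
  swapped <- primer_pair(primer(fix$rev, "forward", "sw-f"),
                         primer(fix$fwd, "reverse", "sw-r"))
  amp_rc <- predict_amplicons(swapped, revcomp_dna(rec$seq), mam_pattern(1))
  expect_equal(nrow(amp), nrow(amp_rc))
  expect_setequal(amp$length_bp, amp_rc$length_bp)
  expect_setequal(n - amp$end + 1L, amp_rc$start)
})

test_that("coverage counts templates once and respects the denominator", {
  fix <- make_planted_fixture(seed = 13L)
  parts <- partition(fix$db, "IA")
  expect_equal(coverage(fix$pair, parts$targets, mam_pattern(0)), 100)
  expect_equal(coverage(fix$pair, parts$nontargets, mam_pattern(0)), 0)
  expect_error(coverage(fix$pair, parts$targets[0, ], mam_pattern(0)),
               "empty")

  # 4 of 11 targets amplifiable -> 36.4%
  hit <- partition(fix$db, "IA")$targets$seq[1L]
  set.seed(2L)
  miss <- replicate(7L, random_dna_str(400L))
  mixed <- ref_db(sprintf("m%d", 1:11), rep("IA", 11L),
                  c(rep(hit, 4L), miss))
  expect_equal(coverage(fix$pair, mixed, mam_pattern(0)), 36.4)
})

test_that("specificity percentages use the non-target denominator", {
  fix <- make_planted_fixture(seed = 21L)
  rep_ <- specificity_report(fix$pair, fix$db, "IA")
  expect_s3_class(rep_, "specificity_report")
  expect_equal(rep_$summary$n_nontargets, rep(10L, 4L))
  expect_equal(rep_$summary$pct_targets, rep(100, 4L))
  # non-targets differ by >= 4 substitutions per site: nothing matches
  # even under 3MAM
  expect_equal(rep_$summary$pct_nontargets, rep(0, 4L))
  expect_equal(vapply(rep_$offending, nrow, integer(1L)),
               c("0MAM" = 0L, "1MAM" = 0L, "1MAM*" = 0L, "3MAM" = 0L))
})

test_that("percentages are monotone across nested MAM patterns", {
  # planted non-target corruption of 1-3 mismatches exercises the
  # intermediate patterns
  for (seed in c(3L, 14L)) {
    for (mm in 1:3) {
      fix <- make_planted_fixture(seed = seed, min_mm = mm,
                                  force_3prime = (mm == 1L))
      rep_ <- specificity_report(fix$pair, fix$db, "IA")
      pct <- rep_$summary$pct_nontargets
      names(pct) <- rep_$summary$pattern
      # 0MAM subset 1MAM subset 1MAM* subset 3MAM
      expect_true(pct[["0MAM"]] <= pct[["1MAM"]])
      expect_true(pct[["1MAM"]] <= pct[["1MAM*"]])
      expect_true(pct[["1MAM*"]] <= pct[["3MAM"]])
      expect_true(all(rep_$summary$pct_targets == 100))
    }
  }
})

test_that("a forced 3'-terminal non-target mismatch flips 1MAM vs 1MAM*", {
  fix <- make_planted_fixture(seed = 17L, min_mm = 1L, force_3prime = TRUE)
  rep_ <- specificity_report(fix$pair, fix$db, "IA")
  pct <- rep_$summary$pct_nontargets
  names(pct) <- rep_$summary$pattern
  expect_equal(pct[["0MAM"]], 0)
  expect_equal(pct[["1MAM"]], 0)      # 3'-protected window blocks the hit
  expect_equal(pct[["1MAM*"]], 100)   # unprotected single mismatch passes
})

test_that("reconstructed non-target counts reproduce the printed percentages", {
  # 561 non-targets: 24 match under (k=3,w=0), 8 under (k=1,w=0)
  expect_equal(round(100 * 24 / 561, 2L), 4.28)
  expect_equal(round(100 * 8 / 561, 2L), 1.43)
  fix <- make_planted_fixture(seed = 23L, n_clades = 2L, per = 3L)
  parts <- partition(fix$db, "IA")
  hit1 <- local({  # single mid-primer mismatch in the forward site
    chars <- strsplit(parts$targets$seq[1L], "")[[1L]]
    chars[105L] <- setdiff(c("A", "C", "G", "T"), chars[105L])[1L]
    paste(chars, collapse = "")
  })
  hit3 <- local({  # three mismatches in the forward site
    chars <- strsplit(parts$targets$seq[1L], "")[[1L]]
    for (i in c(103L, 106L, 109L)) {
      chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1L]
    }
    paste(chars, collapse = "")
  })
  set.seed(4L)
  bg <- replicate(537L, random_dna_str(60L))
  db <- ref_db(c(sprintf("t%d", 1:3), sprintf("n%d", 1:561)),
               c(rep("IA", 3L), rep("IB", 561L)),
               c(parts$targets$seq, rep(hit1, 8L), rep(hit3, 16L), bg))
  rep_ <- specificity_report(fix$pair, db, "IA",
                             parse_mam(c("0MAM", "k1w0", "k3w0")))
  pct <- rep_$summary$pct_nontargets
  names(pct) <- rep_$summary$pattern
  expect_equal(round(pct[["k1w0"]], 2L), 1.4)   # 8 / 561, one decimal
  expect_equal(round(pct[["k3w0"]], 2L), 4.3)   # 24 / 561, one decimal
  expect_equal(nrow(rep_$offending[["k1w0"]]), 8L)
  expect_equal(nrow(rep_$offending[["k3w0"]]), 24L)
})
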