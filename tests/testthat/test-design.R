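test_that("conserved windows match brute-force enumeration", {
  # identical targets: every window of each length is conserved
  tg <- ref_db(c("a", "b", "c"), rep("IA", 3L), rep(strrep("ACGTT", 12L), 3L))
  win <- conserved_windows(tg, c(17L, 18L))
  expect_equal(nrow(win), (60 - 17 + 1) + (60 - 18 + 1))

  # random targets: agree with direct checking of every window
  set.seed(55L)
  seqs <- c(random_dna_str(120L), random_dna_str(120L))
  # share a planted 20-mer
  shared <- random_dna_str(20L)
  seqs <- vapply(seqs, function(s) {
    paste0(substring(s, 1L, 50L), shared, substring(s, 71L, 120L))
  }, character(1L), USE.NAMES = FALSE)
  tg2 <- ref_db(c("x", "y"), c("IA", "IA"), seqs)
  win2 <- conserved_windows(tg2, c(17L, 19L))
  brute <- do.call(rbind, lapply(17:19, function(L) {
    starts <- seq_len(120L - L + 1L)
    wins <- substring(seqs[1L], starts, starts + L - 1L)
    keep <- vapply(wins, grepl, logical(1L), x = seqs[2L], fixed = TRUE,
                   USE.NAMES = FALSE)
    data.frame(start = starts[keep], length = L, consensus = wins[keep],
               stringsAsFactors = FALSE)
  }))
  expect_equal(win2[order(win2$length, win2$start), ],
               brute[order(brute$length, brute$start), ],
               ignore_attr = TRUE)
  # the planted shared 20-mer contributes its full complement of windows
  for (L in 17:19) {
    inside <- win2$length == L & win2$start >= 51L &
      win2$start + L - 1L <= 70L
    expect_gte(sum(inside), 20L - L + 1L)
  }
})

test_that("nearest-neighbor Tm is symmetric, monotone in GC and matches a second implementation", {
  set.seed(66L)
  for (i in 1:10) {
    s <- random_dna_str(20L)
    expect_equal(melting_temperature(s), oracle_tm(s), tolerance = 1e-8)
    expect_equal(melting_temperature(s), melting_temperature(revcomp_dna(s)),
                 tolerance = 1e-10)
  }
  # extending with G.C pairs raises Tm on fixture sequences
  base <- "ATGCATGCATGCATGCA"
  expect_gt(melting_temperature(paste0(base, "GC")),
            melting_temperature(base))
  expect_error(melting_temperature("ACGTN"), "non-degenerate")
})

test_that("complementarity scores equal brute force over all alignments", {
  a <- "ACGTACGTAC"
  sc <- complementarity_scores(a, revcomp_dna(a))
  expect_equal(unname(sc["max_run"]), 10L)

  # no complementary adjacency
  expect_lte(unname(complementarity_scores("AAAAAAAAAA", "CCCCCCCCCC")["max_run"]),
             1L)

  set.seed(88L)
  for (i in 1:40) {
    x <- random_dna_str(sample(8:16, 1L))
    y <- random_dna_str(sample(8:16, 1L))
    expect_equal(complementarity_scores(x, y), oracle_complementarity(x, y),
                 info = paste(x, y))
    expect_equal(complementarity_scores(x, x), oracle_complementarity(x, x),
                 info = paste("self", x))
  }
})

test_that("the ranker returns the planted discriminative pair first", {
  fix <- make_design_fixture()
  ranked <- rank_candidates(fix$targets, fix$nontargets,
                            design_constraints(primer_len_range = c(18L, 18L)))
  expect_equal(nrow(ranked), 1L)  # the planted pair is the only candidate
  top <- ranked[1L, ]
  expect_equal(top$f_seq, fix$fwd)
  expect_equal(top$r_seq, fix$rev)
  expect_equal(top$f_start, fix$f_start)
  expect_equal(top$r_end, fix$r_end)
  expect_equal(top$amplicon_bp, 181L)
  expect_true(top$criterion1_pass)
  expect_equal(top$criterion2_score, 0)

  # the returned pair indeed scores 100% target / 0.0% non-target at 0MAM
  db <- rbind(fix$targets, fix$nontargets)
  class(db) <- c("ref_db", "data.frame")
  pair <- primer_pair(primer(top$f_seq, "forward", "top-f"),
                      primer(top$r_seq, "reverse", "top-r"))
  expect_equal(coverage(pair, fix$targets, mam_pattern(0)), 100)
  rep_ <- specificity_report(pair, db, "IA", list(mam_pattern(0, label = "0MAM")))
  expect_equal(rep_$summary$pct_targets, 100)
  expect_equal(rep_$summary$pct_nontargets, 0)
})

test_that("criterion (iii) prefers non-target mismatches at the 3' terminus", {
  # two forward candidate sites, identical geometry, non-targets carrying
  # a single mismatch at the 3' terminus (site A) vs mid-primer (site B)
  set.seed(99L)
  siteA <- random_dna_str(18L)
  siteB <- random_dna_str(18L)
  siteR <- random_dna_str(18L)
  bg <- random_dna_str(260L)
  build <- function(a, b, r) {
    chars <- strsplit(bg, "")[[1L]]
    chars[21:38] <- strsplit(a, "")[[1L]]
    chars[61:78] <- strsplit(b, "")[[1L]]
    chars[221:238] <- strsplit(revcomp_dna(r), "")[[1L]]
    paste(chars, collapse = "")
  }
  flip <- function(s, i) {
    chars <- strsplit(s, "")[[1L]]
    chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1L]
    paste(chars, collapse = "")
  }
  targets <- ref_db(c("t1", "t2"), c("IA", "IA"),
                    rep(build(siteA, siteB, siteR), 2L))
  # non-target: site A mismatched at its 3' end (position 18), site B
  # mismatched mid-primer (position 9), reverse site intact
  nont <- ref_db("n1", "IB",
                 build(flip(siteA, 18L), flip(siteB, 9L), siteR))
  ranked <- rank_candidates(targets, nont,
                            design_constraints(primer_len_range = c(18L, 18L),
                                               max_tm_diff_C = 50,
                                               max_self_complementarity_run = 18L,
                                               max_3prime_complementarity_run = 18L),
                            patterns = parse_mam(c("0MAM", "3MAM")),
                            max_candidates = 50000L)
  a_row <- which(ranked$f_start == 21L & ranked$r_end == 238L)
  b_row <- which(ranked$f_start == 61L & ranked$r_end == 238L)
  expect_length(a_row, 1L)
  expect_length(b_row, 1L)
  expect_lt(a_row, b_row)
  expect_equal(ranked$criterion3_score[a_row], 1)
  expect_equal(ranked$criterion3_score[b_row], 10)  # 18 - 9 + 1
})

test_that("an undesignable fixture yields an empty ranking with a diagnostic", {
  # both clades share every window: no discriminative pair exists
  s <- strrep("ACGTTGCA", 30L)
  db <- ref_db(c("a", "b", "c", "d"), c("IA", "IA", "IB", "IB"), rep(s, 4L))
  parts <- partition(db, "IA")
  ranked <- rank_candidates(parts$targets, parts$nontargets,
                            design_constraints(primer_len_range = c(18L, 18L),
                                               max_tm_diff_C = 50))
  expect_equal(nrow(ranked), 0L)
  expect_match(attr(ranked, "diagnostic"), "stringent")
})

test_that("ranking output satisfies the declared constraints and is deterministic", {
  site <- planted_site("IA", 40L, "TGACACTCAAAATGAAAC", 220L,
                       "CGCGAATAAATGATAGGT", min_nontarget_mismatches = 4L)
  db <- generate_clade_db(n_clades = 2L, seqs_per_clade = 8L,
                          seq_length_bp = 260L,
                          intra_clade_substitution_rate = 0.06,
                          inter_clade_divergence = 4L,
                          planted_sites = list(site), seed = 302L)
  parts <- partition(db, "IA")
  cons <- design_constraints(primer_len_range = c(18L, 18L))
  r1 <- rank_candidates(parts$targets, parts$nontargets, cons)
  r2 <- rank_candidates(parts$targets, parts$nontargets, cons)
  expect_identical(r1, r2)
  if (nrow(r1)) {
    expect_true(all(r1$amplicon_bp <= cons$max_amplicon_bp))
    expect_true(all(abs(r1$tm_f - r1$tm_r) <= cons$max_tm_diff_C))
    expect_true(all(grepl("^[ACGT]+$", c(r1$f_seq, r1$r_seq))))
    expect_true(all(r1$criterion1_pass))
    # criterion dominance: zero-score candidates precede positive scores
    expect_true(!is.unsorted(r1$criterion2_score))
  }
})
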