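# Independent oracles used across the suite. These deliberately share no
# code with the package: IUPAC semantics are written as explicit character
# sets, matching as a per-window sliding comparison, alignment as a plain
# dynamic program.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# 15 x 15 compatibility lookup built by set intersection
ORACLE_COMPAT <- {
  codes <- names(IUPAC_SETS)
  m <- matrix(FALSE, 15L, 15L, dimnames = list(codes, codes))
  for (a in codes) for (b in codes) {
    m[a, b] <- length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0L
  }
  m
}

ORACLE_COMP_CHAR <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                      H = "D", V = "B", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(ORACLE_COMP_CHAR[strsplit(s, "")[[1L]]]), collapse = "")
}

# Brute-force sliding-window matcher: returns starts and mismatch
# distances-from-3' for every admissible window under (k, w).
oracle_match <- function(primer_seq, orientation, template, k, w) {
  site <- if (orientation == "forward") primer_seq else oracle_revcomp(primer_seq)
  sc <- strsplit(site, "")[[1L]]
  L <- length(sc)
  dist3 <- if (orientation == "forward") rev(seq_len(L)) else seq_len(L)
  tc <- strsplit(template, "")[[1L]]
  n <- length(tc)
  starts <- integer()
  nmm <- integer()
  pos <- list()
  if (L <= n) {
    for (s in seq_len(n - L + 1L)) {
      ok <- ORACLE_COMPAT[cbind(sc, tc[s:(s + L - 1L)])]
      mism <- which(!ok)
      if (length(mism) <= k && !any(dist3[mism] <= w)) {
        starts <- c(starts, s)
        nmm <- c(nmm, length(mism))
        pos <- c(pos, list(sort(dist3[mism])))
      }
    }
  }
  list(start = starts, n_mismatches = nmm, mismatch_pos = pos)
}

# Needleman-Wunsch optimal global score, linear gaps, end gaps penalized.
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ac <- strsplit(a, "")[[1L]]
  bc <- strsplit(b, "")[[1L]]
  n <- length(ac)
  m <- length(bc)
  prev <- gap * (0:m)
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- gap * i
    for (j in seq_len(m)) {
      sub <- prev[j] + if (ac[i] == bc[j]) match else mismatch
      cur[j + 1L] <- max(sub, prev[j + 1L] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev[m + 1L]
}

# Second, independently coded implementation of the unified NN Tm
# (same published table, canonical-dinucleotide lookup arrangement).
oracle_tm <- function(seq, ct = 4e-7, na = 0.05) {
  dh_tab <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
              CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  ds_tab <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
              CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  rc2 <- function(d) oracle_revcomp(d)
  chars <- strsplit(toupper(seq), "")[[1L]]
  L <- length(chars)
  dh <- 0
  ds <- 0
  for (i in seq_len(L - 1L)) {
    d <- paste0(chars[i], chars[i + 1L])
    key <- if (d %in% names(dh_tab)) d else rc2(d)
    dh <- dh + dh_tab[[key]]
    ds <- ds + ds_tab[[key]]
  }
  for (e in chars[c(1L, L)]) {
    if (e %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (L - 1L) * log(na)
  1000 * dh / (ds + 1.98720425864083 * log(ct / 4)) - 273.15
}

# Brute-force complementarity: longest WC-complementary run over all
# ungapped offsets of a (5'->3') against b (3'->5'), plus the longest
# run touching either 3' terminus.
oracle_complementarity <- function(a, b) {
  ac <- strsplit(a, "")[[1L]]
  bc <- rev(strsplit(b, "")[[1L]])
  la <- length(ac)
  lb <- length(bc)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  best <- 0L
  best3 <- 0L
  for (i in seq_len(la)) for (j in seq_len(lb)) {
    len <- 0L
    while (i + len <= la && j + len <= lb &&
           !is.na(comp[ac[i + len]]) &&
           comp[[ac[i + len]]] == bc[j + len]) {
      len <- len + 1L
    }
    if (len > best) best <- len
    if (len > 0L) {
      covers_a3 <- (i <= la) && (i + len - 1L >= la)
      covers_b3 <- (j <= 1L) && (j + len - 1L >= 1L)
      if ((covers_a3 || covers_b3) && len > best3) best3 <- len
    }
  }
  c(max_run = best, max_3prime_run = best3)
}

random_dna_str <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Deterministic design fixture in which the planted pair is the ONLY
# window pair conserved across the targets: the two targets differ at
# every 10th background position and at the positions immediately
# flanking each planted site, so any 18-mer other than the sites
# themselves covers a divergent position. Non-targets carry the target
# background with 4 substitutions inside each site.
make_design_fixture <- function() {
  fwd <- "TGACACTCAAAATGAAAC"
  rev <- "CGCGAATAAATGATAGGT"
  f_iv <- 40:57
  r_iv <- 203:220
  set.seed(777L)
  bg <- strsplit(random_dna_str(260L), "")[[1L]]
  bg[f_iv] <- strsplit(fwd, "")[[1L]]
  bg[r_iv] <- strsplit(oracle_revcomp(rev), "")[[1L]]
  flip1 <- function(chars, i) {
    chars[i] <- setdiff(c("A", "C", "G", "T"), chars[i])[1L]
    chars
  }
  d_pos <- setdiff(c(seq(10L, 260L, by = 10L), 39L, 58L, 202L, 221L),
                   c(f_iv, r_iv))
  c2 <- bg
  for (p in d_pos) c2 <- flip1(c2, p)
  corrupt <- function(chars) {
    for (p in c(f_iv[c(3L, 8L, 13L, 18L)], r_iv[c(3L, 8L, 13L, 18L)])) {
      chars <- flip1(chars, p)
    }
    chars
  }
  list(
    targets = ref_db(c("t1", "t2"), c("IA", "IA"),
                     c(paste(bg, collapse = ""), paste(c2, collapse = ""))),
    nontargets = ref_db(c("n1", "n2"), c("IB", "IB"),
                        c(paste(corrupt(bg), collapse = ""),
                          paste(corrupt(c2), collapse = ""))),
    fwd = fwd, rev = rev, f_start = 40L, r_end = 220L
  )
}

# Shared planted-site fixture: one discriminative primer pair for clade IA
make_planted_fixture <- function(seed = 101L, n_clades = 3L, per = 5L,
                                 len = 400L, min_mm = 4L,
                                 force_3prime = FALSE) {
  fwd <- "TGAAGGCATTCGCTTCCT"
  rev <- "AAGCAGTATTCGCTGTC"
  site <- planted_site("IA", 100L, fwd, 300L, rev,
                       min_nontarget_mismatches = min_mm,
                       force_3prime_mismatch = force_3prime)
  db <- generate_clade_db(n_clades = n_clades, seqs_per_clade = per,
                          seq_length_bp = len, planted_sites = list(site),
                          seed = seed)
  pair <- primer_pair(primer(fwd, "forward", "fix-100f"),
                      primer(rev, "reverse", "fix-300r"))
  list(db = db, pair = pair, fwd = fwd, rev = rev, site = site)
}
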