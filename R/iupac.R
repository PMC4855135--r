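# IUPAC nucleotide codes encoded as 4-bit masks over {A, C, G, T}.
# Two codes are compatible iff their base sets intersect (mask AND != 0).
IUPAC_MASKS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

#' Encode a DNA string as IUPAC bit masks
#'
#' Internal helper: converts a sequence to an integer vector of 4-bit masks
#' over A/C/G/T. U is treated as T; case is ignored.
#'
#' @param seq single DNA string.
#' @return integer vector, one mask per base.
#' @noRd
encode_iupac <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  m <- unname(IUPAC_MASKS[chars])
  if (anyNA(m)) {
    bad <- unique(chars[is.na(m)])
    stop("non-IUPAC nucleotide character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m
}

# Complement a mask vector: A<->T (bits 1<->8), C<->G (bits 2<->4).
mask_complement <- function(m) {
  bitwOr(
    bitwOr(bitwShiftL(bitwAnd(m, 1L), 3L), bitwShiftL(bitwAnd(m, 2L), 1L)),
    bitwOr(bitwShiftR(bitwAnd(m, 4L), 1L), bitwShiftR(bitwAnd(m, 8L), 3L))
  )
}

#' Reverse complement of a DNA string (IUPAC-aware)
#'
#' @param seq single DNA string over the IUPAC alphabet.
#' @return the reverse complement, upper case.
#' @examples
#' revcomp_dna("ACGTN")
#' @export
revcomp_dna <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Test IUPAC compatibility of a primer base with a template base
#'
#' Two IUPAC codes are compatible when the nucleotide sets they denote
#' intersect; a position with an empty intersection counts as one mismatch
#' in primer-template matching. Template `N` therefore matches every primer
#' base.
#'
#' @param primer_char,template_char single IUPAC nucleotide characters
#'   (vectors recycle element-wise).
#' @return logical vector.
#' @examples
#' base_compatible("A", "A")  # TRUE
#' base_compatible("R", "C")  # FALSE: R = {A,G}
#' @export
base_compatible <- function(primer_char, template_char) {
  p <- IUPAC_MASKS[toupper(primer_char)]
  t <- IUPAC_MASKS[toupper(template_char)]
  if (anyNA(p) || anyNA(t)) {
    stop("non-IUPAC nucleotide character", call. = FALSE)
  }
  unname(bitwAnd(p, t) > 0L)
}

# Validate that a string is non-empty IUPAC DNA; returns normalized
# (upper-case, U->T) sequence.
normalize_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop(what, " must be a non-empty DNA string", call. = FALSE)
  }
  s <- chartr("u", "T", toupper(seq))
  s <- chartr("U", "T", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% names(IUPAC_MASKS))) {
    bad <- unique(chars[!chars %in% names(IUPAC_MASKS)])
    stop(what, " contains non-IUPAC character(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  s
}
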