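#' Mismatch-allowance (MAM) patterns
#'
#' A MAM pattern specifies how many primer-template mismatches are
#' tolerated (`max_mismatches`, k) and how many 3'-terminal primer
#' positions are protected (`protected_3prime`, w): a site matches when
#' the total number of mismatches is at most k and no mismatch falls
#' within the w positions closest to the primer 3' end.
#'
#' The named presets follow the convention used for clade-specific primer
#' screening: `0MAM` = (k = 0, w = 0) (perfect match), `1MAM` = (1, 1),
#' `1MAM*` = (1, 0) and `3MAM` = (3, 0). The distinction between `1MAM`
#' and `1MAM*` isolates discrimination at the terminal 3' position: a
#' site whose single mismatch sits exactly at the 3' terminus matches
#' under `1MAM*` but not under `1MAM`.
#'
#' @param max_mismatches integer k >= 0.
#' @param protected_3prime integer w >= 0; number of 3'-terminal primer
#'   positions where no mismatch is permitted.
#' @param label optional display label; defaults to `"k<k>w<w>"`.
#' @return an object of class `mam_pattern`.
#' @examples
#' mam_pattern(1, 1)
#' mam_presets()[["1MAM*"]]
#' parse_mam(c("0MAM", "k2w3"))
#' @export
mam_pattern <- function(max_mismatches, protected_3prime = 0L, label = NULL) {
  k <- as.integer(max_mismatches)
  w <- as.integer(protected_3prime)
  if (is.na(k) || k < 0L) stop("max_mismatches must be >= 0", call. = FALSE)
  if (is.na(w) || w < 0L) stop("protected_3prime must be >= 0", call. = FALSE)
  if (is.null(label)) label <- sprintf("k%dw%d", k, w)
  structure(list(label = label, max_mismatches = k, protected_3prime = w),
            class = "mam_pattern")
}

#' @rdname mam_pattern
#' @export
mam_presets <- function() {
  list(
    "0MAM"  = mam_pattern(0L, 0L, "0MAM"),
    "1MAM"  = mam_pattern(1L, 1L, "1MAM"),
    "1MAM*" = mam_pattern(1L, 0L, "1MAM*"),
    "3MAM"  = mam_pattern(3L, 0L, "3MAM")
  )
}

#' @rdname mam_pattern
#' @param labels character vector of preset names (`"0MAM"`, `"1MAM"`,
#'   `"1MAM*"`, `"3MAM"`) and/or inline `"k<INT>w<INT>"` definitions.
#' @export
parse_mam <- function(labels) {
  presets <- mam_presets()
  out <- lapply(labels, function(lab) {
    if (lab %in% names(presets)) return(presets[[lab]])
    m <- regmatches(lab, regexec("^k([0-9]+)w([0-9]+)$", lab))[[1L]]
    if (length(m) == 3L) {
      return(mam_pattern(as.integer(m[2L]), as.integer(m[3L]), lab))
    }
    stop("unknown MAM pattern '", lab, "'; use a preset (",
         paste(names(presets), collapse = ", "),
         ") or inline 'k<INT>w<INT>'", call. = FALSE)
  })
  names(out) <- vapply(out, `[[`, character(1L), "label")
  out
}

#' @export
print.mam_pattern <- function(x, ...) {
  cat(sprintf("MAM pattern %s: <= %d mismatch(es), %d 3'-protected position(s)\n",
              x$label, x$max_mismatches, x$protected_3prime))
  invisible(x)
}
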