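#' Fit a qPCR standard curve and estimate amplification efficiency
#'
#' Ordinary least squares of Ct on log10 template copies over all
#' replicate points (replicates are not averaged, so replicate variance
#' enters R^2). Amplification efficiency is estimated from the slope as
#' `E = (10^(-1/slope) - 1) * 100`; a perfectly doubling reaction has
#' slope -1/log10(2) = -3.3219 and efficiency 100%. The curve is `valid`
#' only when R^2 exceeds 0.96 and the efficiency lies within 85-115%.
#'
#' @param points data.frame with numeric columns `log10_copies` and `ct`
#'   (one row per replicate measurement; undetected reactions must be
#'   dropped beforehand).
#' @return object of class `standard_curve`: list with `points`, `slope`,
#'   `intercept`, `r_squared`, `efficiency_pct` (NA when slope >= 0),
#'   `valid` and `diagnostic`.
#' @examples
#' pts <- data.frame(log10_copies = 3:8,
#'                   ct = 38 - (3:8) / log10(2))
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("log10_copies", "ct") %in% names(points)))
  points <- points[, c("log10_copies", "ct")]
  if (any(!is.finite(points$log10_copies)) || any(!is.finite(points$ct))) {
    stop("non-finite values in standard-curve points", call. = FALSE)
  }
  if (length(unique(points$log10_copies)) < 2L) {
    stop("a standard curve needs >= 2 distinct dilution levels",
         call. = FALSE)
  }
  fit <- stats::lm(ct ~ log10_copies, data = points)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  r2 <- stats::cor(points$log10_copies, points$ct)^2
  if (slope < 0) {
    eff <- (10^(-1 / slope) - 1) * 100
    diagnostic <- NA_character_
  } else {
    eff <- NA_real_
    diagnostic <- "non-negative slope: Ct must decrease with template copies"
  }
  valid <- !is.na(eff) && r2 > 0.96 && eff >= 85 && eff <= 115
  structure(list(points = points, slope = slope, intercept = intercept,
                 r_squared = r2, efficiency_pct = eff, valid = valid,
                 diagnostic = diagnostic),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: slope %.4f, R^2 %.3f, efficiency %s, %s\n",
              x$slope, x$r_squared,
              if (is.na(x$efficiency_pct)) "undefined"
              else sprintf("%.1f%%", x$efficiency_pct),
              if (x$valid) "valid" else "NOT valid"))
  if (!is.na(x$diagnostic)) cat("  ", x$diagnostic, "\n")
  invisible(x)
}

#' Convert a dsDNA mass to a copy number
#'
#' `copies = mass_ng * 1e-9 / (length_bp * 660 g/mol) * 6.02214e23`,
#' using the conventional 660 g/mol average molecular weight per
#' double-stranded base pair.
#'
#' @param mass_ng DNA mass in nanograms (> 0).
#' @param length_bp amplicon length in base pairs (> 0).
#' @return copy number (numeric, vectorized).
#' @examples
#' copies_from_mass(1, 1000)  # ~9.12e8 copies
#' @export
copies_from_mass <- function(mass_ng, length_bp) {
  if (any(mass_ng <= 0) || any(length_bp <= 0)) {
    stop("mass_ng and length_bp must be positive", call. = FALSE)
  }
  mass_ng * 1e-9 / (length_bp * 660) * 6.02214e23
}

#' Relative efficiency of non-specific amplification
#'
#' `RE = 2^-(ct_observed - ct_reference)`, the relative amplification
#' strength of a primer set on a non-target template compared with its
#' own target at equal copies, assuming 100% per-cycle efficiency. A
#' delay of 10 cycles corresponds to RE = 2^-10, i.e. 0.1% at one
#' decimal, the boundary between negligible and interfering.
#'
#' @param ct_observed Ct on the non-target template (finite).
#' @param ct_reference Ct of the same primer set on its own target at
#'   equal template copies.
#' @return relative efficiency (numeric, vectorized).
#' @seealso [classify_interference()]
#' @export
relative_efficiency <- function(ct_observed, ct_reference) {
  if (any(!is.finite(ct_observed)) || any(!is.finite(ct_reference))) {
    stop("Ct values must be finite; encode undetected reactions as absent",
         call. = FALSE)
  }
  2^(-(ct_observed - ct_reference))
}

#' Classify an interference measurement
#'
#' `none` when the non-target reaction is undetected, `negligible` when
#' detected with RE < 2^-10, `interfering` when RE >= 2^-10 (a delay of
#' fewer than ten cycles).
#'
#' @param re relative efficiency, or `NA` for undetected.
#' @return character vector in `c("none", "negligible", "interfering")`.
#' @export
classify_interference <- function(re) {
  ifelse(is.na(re), "none",
         ifelse(re >= 2^-10, "interfering", "negligible"))
}

#' Cross-amplification interference matrix
#'
#' From a Ct table of every primer set run against amplicon templates of
#' every clade at equal copy numbers, computes each non-target entry's
#' relative efficiency against the primer's own-target reference Ct,
#' classifies it, and accumulates per-primer sums of non-specific
#' relative efficiencies (detected non-target entries only).
#'
#' @param ct_table data.frame with columns `primer_set`, `template_clade`
#'   and `ct` (`NA` = undetected). Replicate rows are averaged.
#' @param primer_targets named character vector mapping each primer set
#'   to its own target clade.
#' @return object of class `interference_matrix`: list with `entries`
#'   (primer_set, template_clade, ct_observed, ct_reference, re,
#'   classification), `sums` (per-primer sum of non-specific RE) and
#'   `class_fractions` (percentage of non-target entries per class,
#'   one decimal).
#' @export
interference_matrix <- function(ct_table, primer_targets) {
  stopifnot(is.data.frame(ct_table),
            all(c("primer_set", "template_clade", "ct") %in% names(ct_table)))
  primers <- unique(ct_table$primer_set)
  missing_map <- setdiff(primers, names(primer_targets))
  if (length(missing_map)) {
    stop("no target clade mapped for primer set(s): ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  # average replicates; all-NA means undetected
  agg <- stats::aggregate(ct ~ primer_set + template_clade, data = ct_table,
                          FUN = function(x) mean(x, na.rm = TRUE),
                          na.action = stats::na.pass)
  agg$ct[is.nan(agg$ct)] <- NA_real_
  rows <- list()
  sums <- stats::setNames(numeric(length(primers)), primers)
  for (p in primers) {
    target <- primer_targets[[p]]
    sub <- agg[agg$primer_set == p, , drop = FALSE]
    ref_ct <- sub$ct[sub$template_clade == target]
    if (!length(ref_ct) || is.na(ref_ct)) {
      stop("missing reference Ct for primer set '", p,
           "' on its own target clade '", target, "'", call. = FALSE)
    }
    non <- sub[sub$template_clade != target, , drop = FALSE]
    re <- rep(NA_real_, nrow(non))
    det <- !is.na(non$ct)
    if (any(det)) re[det] <- relative_efficiency(non$ct[det], ref_ct)
    rows[[p]] <- data.frame(primer_set = p,
                            template_clade = non$template_clade,
                            ct_observed = non$ct,
                            ct_reference = ref_ct,
                            re = re,
                            classification = classify_interference(re),
                            stringsAsFactors = FALSE)
    sums[p] <- sum(re, na.rm = TRUE)
  }
  entries <- do.call(rbind, rows)
  rownames(entries) <- NULL
  cls <- factor(entries$classification,
                levels = c("none", "negligible", "interfering"))
  fr <- round(100 * as.numeric(table(cls)) / nrow(entries), 1L)
  structure(list(entries = entries, sums = sums,
                 class_fractions = stats::setNames(fr, levels(cls))),
            class = "interference_matrix")
}

#' @export
print.interference_matrix <- function(x, ...) {
  cat("Interference matrix:", nrow(x$entries), "non-target combinations\n")
  fr <- x$class_fractions
  cat(sprintf("  none %.1f%%, negligible %.1f%%, interfering %.1f%%\n",
              fr["none"], fr["negligible"], fr["interfering"]))
  cat("  per-primer sums of non-specific RE (log2):\n")
  s <- x$sums
  lab <- ifelse(s > 0, sprintf("2^%.1f", log2(s)), "0")
  cat(paste0("    ", names(s), ": ", lab, collapse = "\n"), "\n")
  invisible(x)
}
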