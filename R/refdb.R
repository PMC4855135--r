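#' Construct a clade-annotated reference sequence database
#'
#' A reference database is a `data.frame` with columns `id`, `clade` and
#' `seq` (one row per marker-gene sequence) and class `ref_db`. Sequences
#' are upper-cased on ingest and RNA `U` is normalized to `T`; every
#' character must be a valid IUPAC nucleotide code. Ids must be unique.
#'
#' @param id character vector of unique, non-empty sequence identifiers.
#' @param clade character vector of clade labels (free-form strings,
#'   matched exactly and case-sensitively downstream).
#' @param seq character vector of DNA sequences (5'->3', reference strand).
#' @return a `ref_db` data.frame with attribute `clades` (sorted unique
#'   clade labels).
#' @examples
#' db <- ref_db(c("s1", "s2", "s3"), c("IA", "IA", "IB"),
#'              c("ACGT", "ACGA", "TTGA"))
#' ref_clades(db)
#' @export
ref_db <- function(id, clade, seq) {
  id <- as.character(id)
  clade <- as.character(clade)
  seq <- as.character(seq)
  n <- length(id)
  if (length(clade) != n || length(seq) != n) {
    stop("id, clade and seq must have equal length", call. = FALSE)
  }
  if (n > 0L) {
    if (any(!nzchar(id))) stop("empty sequence id", call. = FALSE)
    if (anyDuplicated(id)) {
      stop("duplicate sequence id(s): ",
           paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
    }
    if (any(!nzchar(clade))) stop("empty clade label", call. = FALSE)
    seq <- vapply(seq, normalize_dna, character(1L), USE.NAMES = FALSE)
  }
  db <- data.frame(id = id, clade = clade, seq = seq,
                   stringsAsFactors = FALSE)
  class(db) <- c("ref_db", "data.frame")
  db
}

#' @rdname ref_db
#' @param db a `ref_db` object.
#' @export
ref_clades <- function(db) sort(unique(db$clade))

#' The fourteen Accumulibacter ppk1 clade labels
#'
#' Standard clade labels for the "Candidatus Accumulibacter" lineage:
#' five clades in Type I and nine in Type II.
#'
#' @return character vector of 14 clade labels.
#' @export
accumulibacter_clades <- function() {
  c("IA", "IB", "IC", "ID", "IE",
    "IIA", "IIB", "IIC", "IID", "IIE", "IIF", "IIG", "IIH", "II-I")
}

#' Read a reference database from FASTA plus a clade annotation table
#'
#' The annotation file is two-column tab-separated (`id<TAB>clade`), with
#' `#` comment lines allowed. Every FASTA record must be annotated and
#' every annotated id must have a sequence; anything else is an error.
#'
#' @param fasta_path path to a (multi-record) FASTA file; any line
#'   wrapping is accepted.
#' @param annotation_path path to the tab-separated annotation file.
#' @return a [ref_db] object, records in FASTA order.
#' @seealso [write_database()] for the inverse operation.
#' @export
read_database <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))  # id = first whitespace-delimited token
  ann <- read_annotation(annotation_path)
  missing_ann <- setdiff(ids, ann$id)
  if (length(missing_ann)) {
    stop("FASTA id(s) without clade annotation: ",
         paste(utils::head(missing_ann, 5L), collapse = ", "), call. = FALSE)
  }
  missing_seq <- setdiff(ann$id, ids)
  if (length(missing_seq)) {
    stop("annotated id(s) without sequence: ",
         paste(utils::head(missing_seq, 5L), collapse = ", "), call. = FALSE)
  }
  clade <- ann$clade[match(ids, ann$id)]
  ref_db(ids, clade, as.character(seqs))
}

read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(id = character(), clade = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("annotation line ", bad[1L], " is not two tab-separated fields",
         call. = FALSE)
  }
  ids <- trimws(vapply(parts, `[[`, character(1L), 1L))
  clades <- trimws(vapply(parts, `[[`, character(1L), 2L))
  if (anyDuplicated(ids)) {
    stop("duplicate id(s) in annotation: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  data.frame(id = ids, clade = clades, stringsAsFactors = FALSE)
}

#' Write a reference database as FASTA plus annotation TSV
#'
#' @param db a [ref_db] object.
#' @param fasta_path,annotation_path output paths.
#' @param width FASTA line-wrap width.
#' @return `db`, invisibly.
#' @export
write_database <- function(db, fasta_path, annotation_path, width = 70L) {
  stopifnot(inherits(db, "ref_db"))
  x <- Biostrings::DNAStringSet(db$seq)
  names(x) <- db$id
  Biostrings::writeXStringSet(x, fasta_path, width = width)
  writeLines(c("# id\tclade", paste(db$id, db$clade, sep = "\t")),
             annotation_path)
  invisible(db)
}

#' Partition a database into target and non-target records
#'
#' Splits the database into the records of one target clade and all
#' remaining records, the basic step of clade-specific primer screening:
#' each clade in turn is treated as the target while every other sequence
#' represents the non-target pool.
#'
#' @param db a [ref_db] object.
#' @param target_clade a clade label present in `db`.
#' @return list with elements `targets` and `nontargets`, both `ref_db`.
#' @examples
#' db <- ref_db(c("a", "b", "c"), c("IA", "IA", "IB"),
#'              c("ACGT", "ACGT", "TTAA"))
#' p <- partition(db, "IA")
#' nrow(p$targets)    # 2
#' nrow(p$nontargets) # 1
#' @export
partition <- function(db, target_clade) {
  stopifnot(inherits(db, "ref_db"))
  clades <- ref_clades(db)
  if (!target_clade %in% clades) {
    stop("unknown clade '", target_clade, "'; available clades: ",
         paste(clades, collapse = ", "), call. = FALSE)
  }
  sel <- db$clade == target_clade
  tg <- db[sel, , drop = FALSE]
  nt <- db[!sel, , drop = FALSE]
  rownames(tg) <- rownames(nt) <- NULL
  class(tg) <- class(nt) <- c("ref_db", "data.frame")
  list(targets = tg, nontargets = nt)
}

#' @export
print.ref_db <- function(x, ...) {
  cl <- ref_clades(x)
  cat("Reference database: ", nrow(x), " sequence(s), ",
      length(cl), " clade(s)\n", sep = "")
  if (length(cl)) {
    tab <- table(x$clade)
    cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
  }
  invisible(x)
}
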