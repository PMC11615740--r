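#' Construct a multiple sequence alignment object
#'
#' An `msa` object holds an ordered set of aligned protein sequences with a
#' designated query row. Sequences are canonicalized on construction:
#' letters are uppercased and any symbol outside the 20 canonical amino
#' acids and `"-"` is handled by `noncanonical` (ambiguity codes such as
#' X/B/Z/U/O cannot be one-hot encoded under a 20-letter alphabet; the
#' default maps them to the gap symbol).
#'
#' The query row defines the mutable coordinate system of the pipeline and
#' must be gap-free.
#'
#' @param ids Character vector of unique, non-empty record identifiers.
#' @param seqs Character vector of aligned sequences, all the same length.
#' @param query Index (or identifier) of the query record. Default: first.
#' @param noncanonical `"gap"` to map ambiguity codes to `"-"` (default) or
#'   `"error"` to reject them.
#' @return An object of class `msa`: a list with elements `ids`, `seqs`,
#'   `query` (integer index), `L` (alignment columns) and `depth`.
#' @examples
#' m <- msa(c("q", "h1"), c("MKV", "MK-"))
#' m$L
#' @export
msa <- function(ids, seqs, query = 1L, noncanonical = c("gap", "error")) {
  noncanonical <- match.arg(noncanonical)
  ids <- as.character(ids)
  seqs <- as.character(seqs)
  if (length(ids) != length(seqs) || length(ids) < 1L) {
    stop("ids and seqs must be non-empty vectors of equal length",
         call. = FALSE)
  }
  if (any(!nzchar(ids))) stop("empty record identifier", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate record identifier: '", ids[duplicated(ids)][1L], "'",
         call. = FALSE)
  }
  if (is.character(query)) {
    query <- match(query, ids)
    if (is.na(query)) stop("query identifier not found in alignment",
                           call. = FALSE)
  }
  query <- as.integer(query)
  if (is.na(query) || query < 1L || query > length(ids)) {
    stop("query index out of range", call. = FALSE)
  }
  seqs <- vapply(seqs, .canonicalize, "", noncanonical = noncanonical,
                 USE.NAMES = FALSE)
  L <- nchar(seqs[1L])
  if (L == 0L) stop("alignment has zero columns", call. = FALSE)
  ragged <- which(nchar(seqs) != L)
  if (length(ragged) > 0L) {
    stop("record '", ids[ragged[1L]], "' has length ",
         nchar(seqs[ragged[1L]]), ", expected ", L, call. = FALSE)
  }
  if (grepl("-", seqs[query], fixed = TRUE)) {
    stop("query record '", ids[query],
         "' contains gaps; it must define a gap-free coordinate system",
         call. = FALSE)
  }
  structure(
    list(ids = ids, seqs = seqs, query = query,
         L = L, depth = length(ids)),
    class = "msa"
  )
}

# uppercase; map non-canonical, non-gap symbols per policy; '.' -> '-'
.canonicalize <- function(s, noncanonical = "gap") {
  s <- toupper(s)
  s <- gsub(".", "-", s, fixed = TRUE)
  ok <- paste0(aa_alphabet(), collapse = "")
  bad <- gsub(paste0("[", ok, "-]"), "", s)
  if (nchar(bad) > 0L) {
    if (noncanonical == "error") {
      stop("non-canonical residue '", substr(bad, 1L, 1L), "' in sequence",
           call. = FALSE)
    }
    s <- gsub(paste0("[^", ok, "-]"), "-", s)
  }
  s
}

#' @export
print.msa <- function(x, ...) {
  cat("Multiple sequence alignment: ", x$depth, " sequences x ",
      x$L, " columns\n", sep = "")
  cat("Query: ", x$ids[x$query], " (record ", x$query, ")\n", sep = "")
  show <- utils::head(seq_len(x$depth), 5L)
  for (k in show) {
    s <- x$seqs[k]
    if (nchar(s) > 60L) s <- paste0(substr(s, 1L, 57L), "...")
    cat(sprintf("  %-20s %s\n", x$ids[k], s))
  }
  if (x$depth > 5L) cat("  ... ", x$depth - 5L, " more\n", sep = "")
  invisible(x)
}

#' Read an alignment from A3M or aligned FASTA
#'
#' The first record is taken as the query unless `query_id` names another
#' record. For A3M input, lowercase letters and `"."` are insertion states
#' relative to the query's match columns; they are deleted from every record
#' independently, after which all records must share the query's
#' match-column count (the standard A3M convention, as emitted by HHblits).
#'
#' @param path File to read.
#' @param format `"auto"` (by extension: `.a3m` vs anything else),
#'   `"a3m"`, or `"fasta"`.
#' @param query_id Optional identifier of the query record.
#' @inheritParams msa
#' @return An [msa] object.
#' @seealso [write_msa()]
#' @export
read_msa <- function(path, format = c("auto", "a3m", "fasta"),
                     query_id = NULL, noncanonical = c("gap", "error")) {
  format <- match.arg(format)
  noncanonical <- match.arg(noncanonical)
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.a3m$", path, ignore.case = TRUE)) "a3m"
              else "fasta"
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty alignment file: '", path, "'",
                              call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (format == "a3m") {
    # drop insertion states: lowercase letters and '.'
    seqs <- gsub("[a-z.]", "", seqs)
  }
  msa(ids, seqs, query = if (is.null(query_id)) 1L else query_id,
      noncanonical = noncanonical)
}

#' Write an alignment to FASTA
#'
#' Writes the canonicalized records verbatim (gaps preserved), so that
#' `read_msa(write_msa(m))` reproduces identifiers, residues, and order
#' exactly.
#'
#' @param x An [msa] object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_msa <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  set <- Biostrings::BStringSet(x$seqs)
  names(set) <- x$ids
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

# alignment as a depth x L matrix of single characters
.msa_matrix <- function(x) {
  matrix(unlist(strsplit(x$seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = x$depth, ncol = x$L, byrow = TRUE)
}

# alignment as a depth x L integer matrix, 1..20 canonical / 21 gap
.msa_codes <- function(x) {
  matrix(unlist(lapply(x$seqs, .encode21), use.names = FALSE),
         nrow = x$depth, ncol = x$L, byrow = TRUE)
}

#' Extract the query sequence of an alignment
#'
#' @param x An [msa] object.
#' @return The query sequence as a single string (gap-free by construction).
#' @export
query_sequence <- function(x) {
  stopifnot(inherits(x, "msa"))
  x$seqs[x$query]
}
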