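#' Construct an MSA object
#'
#' An `msa` is an aligned sequence collection in the A3M dialect: uppercase
#' letters and `-` are match columns, lowercase letters are insertions
#' relative to the query. The first row is the query; its own aligned form
#' (which must be gap-free) defines the number of match columns.
#'
#' @param ids character vector of unique row identifiers; the first is the
#'   query id.
#' @param seqs character vector of aligned sequences, same length as `ids`.
#'   Every row must have exactly the query's match length after removal of
#'   lowercase insertion characters.
#' @return An object of class `msa`: a list with elements `ids`, `seqs` and
#'   `match_length`.
#' @examples
#' m <- msa(c("q", "s1"), c("ACDE", "AC-E"))
#' m$match_length
#' @export
msa <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- as.character(seqs)
  if (length(ids) != length(seqs)) {
    abort_argument("`ids` and `seqs` must have the same length")
  }
  if (length(ids) < 1L) abort_argument("an msa needs at least a query row")
  if (anyDuplicated(ids)) {
    abort_format(sprintf("duplicated row id: '%s'", ids[duplicated(ids)][1L]))
  }
  qmatch <- deinsert(seqs[1L])
  if (nchar(qmatch) == 0L) abort_format("query row is empty")
  if (grepl("-", qmatch, fixed = TRUE)) {
    abort_format(sprintf("query row '%s' contains gap characters", ids[1L]))
  }
  match_length <- nchar(qmatch)
  lens <- nchar(deinsert(seqs))
  bad <- which(lens != match_length)
  if (length(bad)) {
    abort_format(sprintf(
      "row '%s' has %d match columns; expected %d",
      ids[bad[1L]], lens[bad[1L]], match_length))
  }
  structure(list(ids = ids, seqs = seqs, match_length = match_length),
            class = "msa")
}

# Remove lowercase insertion characters, leaving match columns only.
deinsert <- function(s) gsub("[a-z]", "", s)

#' Number of rows of an MSA (query included)
#' @param msa an [msa] object.
#' @return integer row count.
#' @export
n_rows <- function(msa) length(msa$ids)

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d rows (query '%s'), %d match columns\n",
              n_rows(x), x$ids[1L], x$match_length))
  invisible(x)
}

# Match-column sequences (insertions stripped) for all rows.
match_seqs <- function(msa) deinsert(msa$seqs)

# Accept either an msa or a sequence_cluster wherever an alignment is
# expected.
as_msa <- function(x) {
  if (inherits(x, "sequence_cluster")) return(x$members)
  if (inherits(x, "msa")) return(x)
  abort_argument("expected an 'msa' or 'sequence_cluster' object")
}
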