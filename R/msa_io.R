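# One-hot alphabet: 20 standard amino acids, the gap symbol, and a single
# "unknown" slot absorbing non-standard residue codes (B, J, O, U, X, Z, ...).
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                 "-", "X")

#' Read an A3M / aligned FASTA file
#'
#' Lowercase letters are kept as insertions relative to the query's match
#' columns; `-` is a gap. Record ids are taken from the FASTA header up to
#' the first whitespace. A leading ColabFold `#` length header line, if
#' present, is skipped.
#'
#' @param path path to an A3M or aligned FASTA file whose first record is
#'   the query.
#' @return An [msa] object.
#' @export
read_a3m <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort_format(sprintf("empty alignment file: %s", path))
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) abort_format(sprintf("not FASTA/A3M (no leading '>'): %s", path))
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste0, "", collapse = "")
  if (length(seqs) != length(ids) || !nzchar(seqs[1L])) {
    abort_format(sprintf("record without sequence in %s", path))
  }
  msa(ids, unname(seqs))
}

#' Write an MSA to an A3M file
#'
#' Inverse of [read_a3m()]: `read_a3m(write_a3m(m, path))` reproduces `m`
#' exactly, including lowercase insertion characters.
#'
#' @param msa an [msa] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_a3m <- function(msa, path) {
  stopifnot(inherits(msa, "msa"))
  out <- tryCatch(file(path, "wt"), condition = function(e)
    abort_io(sprintf("cannot write %s: %s", path, conditionMessage(e))))
  on.exit(close(out))
  writeLines(paste0(">", msa$ids, "\n", msa$seqs, collapse = "\n"), out, sep = "\n")
  invisible(path)
}

#' Remove gappy sequences from an MSA
#'
#' Drops every non-query row whose gap fraction over match columns strictly
#' exceeds `max_gap` ("more than 25% gaps" excluded, with the default).
#' Insertions are not alignment columns and are ignored by the count. The
#' query row is always retained and row order is preserved; the operation is
#' idempotent.
#'
#' @param msa an [msa] object.
#' @param max_gap maximum tolerated gap fraction in `[0, 1]`; default 0.25.
#' @return the filtered [msa].
#' @export
filter_by_gap_fraction <- function(msa, max_gap = 0.25) {
  stopifnot(inherits(msa, "msa"))
  if (!is.numeric(max_gap) || length(max_gap) != 1L || is.na(max_gap) ||
      max_gap < 0 || max_gap > 1) {
    abort_argument("`max_gap` must be a single value in [0, 1]")
  }
  frac <- gap_fractions(msa)
  keep <- frac <= max_gap
  keep[1L] <- TRUE
  msa(msa$ids[keep], msa$seqs[keep])
}

# Per-row gap fraction over match columns.
gap_fractions <- function(msa) {
  m <- match_seqs(msa)
  vapply(m, function(s) {
    sum(charToRaw(s) == charToRaw("-")) / nchar(s)
  }, numeric(1), USE.NAMES = FALSE)
}

#' One-hot encode MSA match columns
#'
#' Insertions are dropped; each match column maps to exactly one hot
#' position over a 22-letter alphabet (20 amino acids, gap, unknown).
#' Squared Euclidean distance between two encoded rows is twice their
#' Hamming distance over match columns, which puts DBSCAN epsilon values on
#' the AFcluster scale.
#'
#' @param msa an [msa] object.
#' @return numeric matrix, one row per MSA row (rownames = ids),
#'   `match_length * 22` columns.
#' @export
encode_onehot <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  a <- length(AA_ALPHABET)
  L <- msa$match_length
  n <- n_rows(msa)
  chars <- matrix(unlist(strsplit(match_seqs(msa), "", fixed = TRUE)),
                  nrow = n, ncol = L, byrow = TRUE)
  idx <- match(chars, AA_ALPHABET)
  idx[is.na(idx)] <- match("X", AA_ALPHABET)
  out <- matrix(0, nrow = n, ncol = L * a,
                dimnames = list(msa$ids, NULL))
  cols <- (rep(seq_len(L), each = n) - 1L) * a + idx
  out[cbind(rep(seq_len(n), times = L), cols)] <- 1
  out
}

#' Uniform random subsample of an MSA
#'
#' The query is always included; the remaining `size - 1` rows are drawn
#' uniformly without replacement from the non-query rows (all rows are
#' returned if fewer are available). Relative row order is preserved and
#' the draw is deterministic for a fixed seed.
#'
#' @param msa an [msa] object.
#' @param size total number of rows to keep, query included; `size >= 1`.
#' @param seed integer RNG seed.
#' @return the subsampled [msa].
#' @export
subsample_random <- function(msa, size, seed) {
  stopifnot(inherits(msa, "msa"))
  if (!is_count(size, min = 1L)) abort_argument("`size` must be an integer >= 1")
  n_other <- n_rows(msa) - 1L
  k <- min(size - 1L, n_other)
  pick <- if (k == n_other) seq_len(n_other) else
    with_seed(seed, sort(sample.int(n_other, k)))
  idx <- c(1L, pick + 1L)
  msa(msa$ids[idx], msa$seqs[idx])
}

#' Depth-limited two-part MSA split (max-MSA baseline)
#'
#' Emulates the depth-limiting behaviour of max-MSA subsampling: the
#' non-query rows are randomly partitioned into a cluster part of at most
#' `max_seq` rows (query first) and a disjoint extra part of at most
#' `extra_seq` rows. Conventional depth pairs are 8:16, 32:64 and
#' 64:128. The extra part carries no query row and is returned as a bare
#' list so the two parts stay disjoint.
#'
#' @param msa an [msa] object.
#' @param max_seq maximum rows of the cluster part (query included).
#' @param extra_seq maximum rows of the extra part.
#' @param seed integer RNG seed.
#' @return list with elements `cluster` (an [msa]) and `extra` (list with
#'   `ids` and `seqs`, possibly empty).
#' @export
subsample_maxmsa <- function(msa, max_seq, extra_seq, seed) {
  stopifnot(inherits(msa, "msa"))
  if (!is_count(max_seq, min = 1L)) abort_argument("`max_seq` must be an integer >= 1")
  if (!is_count(extra_seq, min = 0L)) abort_argument("`extra_seq` must be an integer >= 0")
  n_other <- n_rows(msa) - 1L
  perm <- with_seed(seed, sample.int(max(n_other, 1L), n_other))
  k1 <- min(max_seq - 1L, n_other)
  k2 <- min(extra_seq, n_other - k1)
  main <- sort(perm[seq_len(k1)])
  extra <- if (k2 > 0L) sort(perm[k1 + seq_len(k2)]) else integer(0)
  idx <- c(1L, main + 1L)
  list(
    cluster = msa(msa$ids[idx], msa$seqs[idx]),
    extra = list(ids = msa$ids[extra + 1L], seqs = msa$seqs[extra + 1L])
  )
}
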