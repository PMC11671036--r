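# complex_msa: a prediction-ready multi-chain alignment.
#   chain_specs: data.frame(chain_id, query_id, query_seq, copies, match_length)
#   ids/seqs:    rows, row 1 being the fully paired merged query
#   src:         span index per row (0 = merged query, NA = paired row)
#   boundaries:  data.frame(chain_id, copy, start, end) in match columns
new_complex_msa <- function(chain_specs, ids, seqs, src) {
  spans <- chain_specs[rep(seq_len(nrow(chain_specs)), chain_specs$copies), ,
                       drop = FALSE]
  end <- cumsum(spans$match_length)
  boundaries <- data.frame(
    chain_id = spans$chain_id,
    copy = unlist(lapply(chain_specs$copies, seq_len)),
    start = c(1L, head(end, -1L) + 1L),
    end = end
  )
  total <- sum(chain_specs$match_length * chain_specs$copies)
  lens <- nchar(deinsert(seqs))
  if (any(lens != total)) {
    abort_format(sprintf(
      "row '%s' has %d match columns; expected %d",
      ids[lens != total][1L], lens[lens != total][1L], total))
  }
  structure(list(chain_specs = chain_specs, ids = ids, seqs = seqs,
                 src = src, boundaries = boundaries,
                 total_match_length = total),
            class = "complex_msa")
}

#' @export
print.complex_msa <- function(x, ...) {
  cat(sprintf("complex_msa: %d rows, %d match columns, chains [%s]\n",
              length(x$ids), x$total_match_length,
              paste(sprintf("%s x%d (%d aa)", x$chain_specs$chain_id,
                            x$chain_specs$copies, x$chain_specs$match_length),
                    collapse = ", ")))
  invisible(x)
}

#' Unpaired receptor-ligand concatenation with diagonal padding
#'
#' Builds a complex alignment from two unpaired single-chain alignments:
#' row 1 is the fully paired concatenation of the two queries; every other
#' receptor row is padded with gaps over the ligand span and every ligand
#' row with gaps over the receptor span (no row pairing is performed).
#' Chain order is receptor then ligand; both row counts are preserved.
#'
#' @param receptor an [msa] or `sequence_cluster` (the metamorphic chain).
#' @param ligand an [msa] (the partner chain, typically at full depth).
#' @return a `complex_msa`. If `receptor` is a cluster its label is kept as
#'   attribute `"cluster_label"`.
#' @export
pad_concat_unpaired <- function(receptor, ligand) {
  rec <- as_msa(receptor)
  lig <- as_msa(ligand)
  Lr <- rec$match_length
  Ll <- lig$match_length
  chain_specs <- data.frame(
    chain_id = c("A", "B"),
    query_id = c(rec$ids[1L], lig$ids[1L]),
    query_seq = c(rec$seqs[1L], lig$seqs[1L]),
    copies = c(1L, 1L),
    match_length = c(Lr, Ll)
  )
  nr <- n_rows(rec) - 1L
  nl <- n_rows(lig) - 1L
  ids <- c(paste0(rec$ids[1L], "_", lig$ids[1L]),
           rec$ids[-1L], lig$ids[-1L])
  seqs <- c(paste0(rec$seqs[1L], lig$seqs[1L]),
            if (nr) paste0(rec$seqs[-1L], strrep("-", Ll)),
            if (nl) paste0(strrep("-", Lr), lig$seqs[-1L]))
  src <- c(0L, rep(1L, nr), rep(2L, nl))
  out <- new_complex_msa(chain_specs, ids, seqs, src)
  if (inherits(receptor, "sequence_cluster")) {
    attr(out, "cluster_label") <- receptor$label
  }
  out
}

#' Paired receptor-ligand concatenation
#'
#' Horizontally concatenates explicitly paired rows; unpaired rows are
#' excluded. This reproduces the paired-MSA baseline the unpaired protocol
#' is compared against.
#'
#' @param receptor,ligand [msa] objects.
#' @param pairing data.frame (or 2-column matrix) of
#'   `(receptor_row_id, ligand_row_id)`; may be empty.
#' @return a `complex_msa` whose rows are the merged query plus one row per
#'   pairing entry.
#' @export
pair_concat <- function(receptor, ligand, pairing) {
  rec <- as_msa(receptor)
  lig <- as_msa(ligand)
  pairing <- as.data.frame(pairing)
  if (ncol(pairing) == 0L) pairing <- data.frame(a = character(0), b = character(0))
  if (ncol(pairing) != 2L) {
    abort_argument("`pairing` must have two columns (receptor id, ligand id)")
  }
  ri <- match(as.character(pairing[[1L]]), rec$ids)
  li <- match(as.character(pairing[[2L]]), lig$ids)
  bad <- c(as.character(pairing[[1L]])[is.na(ri)],
           as.character(pairing[[2L]])[is.na(li)])
  if (length(bad)) abort_argument(sprintf("unknown row id in pairing: '%s'", bad[1L]))
  chain_specs <- data.frame(
    chain_id = c("A", "B"),
    query_id = c(rec$ids[1L], lig$ids[1L]),
    query_seq = c(rec$seqs[1L], lig$seqs[1L]),
    copies = c(1L, 1L),
    match_length = c(rec$match_length, lig$match_length)
  )
  ids <- c(paste0(rec$ids[1L], "_", lig$ids[1L]),
           if (length(ri)) paste0(rec$ids[ri], "_", lig$ids[li]))
  seqs <- c(paste0(rec$seqs[1L], lig$seqs[1L]),
            if (length(ri)) paste0(rec$seqs[ri], lig$seqs[li]))
  new_complex_msa(chain_specs, ids, seqs, c(0L, rep(NA_integer_, nrow(pairing))))
}

#' Homooligomer assembly by MSA copy duplication
#'
#' Duplicates a single-chain alignment into `copies` adjacent spans in
#' unpaired diagonal-padded form: the query row is the query sequence
#' repeated once per copy, and every non-query source row appears once per
#' copy span with gaps elsewhere. `copies = 1` reduces to the input. This
#' is the monomer-to-dimer fold-switch sampling move.
#'
#' @param unit an [msa] or `sequence_cluster`.
#' @param copies number of chain copies, `>= 1`.
#' @return a `complex_msa` with a single chain spec of `copies` copies.
#' @export
duplicate_homooligomer <- function(unit, copies) {
  m <- as_msa(unit)
  if (!is_count(copies, min = 1L)) abort_argument("`copies` must be an integer >= 1")
  copies <- as.integer(copies)
  L <- m$match_length
  chain_specs <- data.frame(
    chain_id = "A", query_id = m$ids[1L], query_seq = m$seqs[1L],
    copies = copies, match_length = L
  )
  n_other <- n_rows(m) - 1L
  ids <- m$ids[1L]
  seqs <- strrep(m$seqs[1L], copies)
  src <- 0L
  for (cp in seq_len(copies)) {
    if (!n_other) break
    ids <- c(ids, m$ids[-1L])
    seqs <- c(seqs, paste0(strrep("-", (cp - 1L) * L), m$seqs[-1L],
                           strrep("-", (copies - cp) * L)))
    src <- c(src, rep(cp, n_other))
  }
  out <- new_complex_msa(chain_specs, ids, seqs, src)
  if (inherits(unit, "sequence_cluster")) attr(out, "cluster_label") <- unit$label
  out
}

# Extract the part of an aligned row covering match columns start..end,
# keeping insertions attached to their preceding match column (a leading
# insertion attaches to column 1).
extract_span <- function(seq, start, end) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  lower <- chars %in% letters
  mcol <- cumsum(!lower)          # match-column index per character
  owner <- pmax(mcol, 1L)        # insertions follow their match column
  paste0(chars[owner >= start & owner <= end], collapse = "")
}

#' Split an unpaired complex alignment back into its chains
#'
#' Inverse of the unpaired assembly operations: each chain-copy span is cut
#' out at the recorded boundaries and reassembled into a single-chain
#' alignment headed by that chain's query. For diagonally padded rows this
#' recovers the input alignments exactly.
#'
#' @param cmsa a `complex_msa`.
#' @return named list of [msa] objects, one per chain-copy span (names
#'   `A1`, `A2`, `B1`, ...).
#' @export
split_complex_msa <- function(cmsa) {
  stopifnot(inherits(cmsa, "complex_msa"))
  b <- cmsa$boundaries
  spec_of <- match(b$chain_id, cmsa$chain_specs$chain_id)
  out <- vector("list", nrow(b))
  names(out) <- paste0(b$chain_id, b$copy)
  for (s in seq_len(nrow(b))) {
    rows <- which(cmsa$src == s)
    seqs <- vapply(cmsa$seqs[rows], extract_span, "", b$start[s], b$end[s],
                   USE.NAMES = FALSE)
    spec <- cmsa$chain_specs[spec_of[s], ]
    out[[s]] <- msa(c(spec$query_id, cmsa$ids[rows]), c(spec$query_seq, seqs))
  }
  out
}

#' Write a complex alignment as ColabFold-style A3M
#'
#' First line is the `#len1,len2...\tcopies1,copies2...` length header
#' encoding per-chain match lengths and copy counts, followed by the rows
#' (merged query first).
#'
#' @param cmsa a `complex_msa`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_complex_a3m <- function(cmsa, path) {
  stopifnot(inherits(cmsa, "complex_msa"))
  hdr <- sprintf("#%s\t%s",
                 paste(cmsa$chain_specs$match_length, collapse = ","),
                 paste(cmsa$chain_specs$copies, collapse = ","))
  out <- tryCatch(file(path, "wt"), condition = function(e)
    abort_io(sprintf("cannot write %s: %s", path, conditionMessage(e))))
  on.exit(close(out))
  writeLines(c(hdr, paste0(">", cmsa$ids, "\n", cmsa$seqs)), out)
  invisible(path)
}

#' Read a ColabFold-style complex A3M
#'
#' Parses the `#` length header back into chain specs; per-chain query
#' sequences are recovered by cutting the merged query row at the header
#' lengths, and each unpaired row is attributed to the single span it
#' covers (rows covering several spans are treated as paired).
#'
#' @param path path to a complex A3M written by [write_complex_a3m()].
#' @return a `complex_msa`.
#' @export
read_complex_a3m <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!startsWith(first, "#")) {
    abort_format(sprintf("missing '#' length header in %s", path))
  }
  parts <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1L]]
  lens <- as.integer(strsplit(parts[1L], ",", fixed = TRUE)[[1L]])
  cps <- as.integer(strsplit(parts[2L], ",", fixed = TRUE)[[1L]])
  if (anyNA(lens) || anyNA(cps) || length(lens) != length(cps)) {
    abort_format(sprintf("malformed '#' length header in %s", path))
  }
  lines <- readLines(path, warn = FALSE)[-1L]
  lines <- lines[nzchar(lines)]
  hdr <- startsWith(lines, ">")
  rec <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>\\s*", "", lines[hdr]))
  seqs <- unname(vapply(split(lines[!hdr], rec[!hdr]), paste0, "", collapse = ""))
  if (!length(seqs)) abort_format(sprintf("no records in %s", path))
  # per-chain queries from the merged query row
  qend <- cumsum(rep(lens, cps))
  qstart <- c(1L, head(qend, -1L) + 1L)
  first_spans <- cumsum(cps) - cps + 1L  # first copy span of each chain
  qseqs <- vapply(seq_along(lens), function(i)
    extract_span(seqs[1L], qstart[first_spans[i]], qend[first_spans[i]]), "")
  chain_specs <- data.frame(
    chain_id = LETTERS[seq_along(lens)],
    query_id = paste0(ids[1L], "/", LETTERS[seq_along(lens)]),
    query_seq = qseqs, copies = cps, match_length = lens
  )
  # span attribution for non-query rows
  src <- c(0L, vapply(seqs[-1L], function(s) {
    m <- deinsert(s)
    nongap <- which(strsplit(m, "", fixed = TRUE)[[1L]] != "-")
    spans <- unique(findInterval(nongap, qstart))
    if (length(spans) == 1L) spans else NA_integer_
  }, integer(1), USE.NAMES = FALSE))
  new_complex_msa(chain_specs, ids, seqs, src)
}

#' Fan out per-cluster prediction jobs
#'
#' Builds one complex alignment per sequence cluster — merged with a
#' partner alignment in unpaired mode when `partner` is given, otherwise
#' duplicated to `copies` homooligomer copies — and records a job manifest
#' with the predictor settings (defaults: a single model, three recycles).
#'
#' @param clusters list of `sequence_cluster` objects ([cluster_msa()]).
#' @param partner optional partner [msa] (full-depth ligand alignment).
#' @param copies chain copies when no partner is given; default 1.
#' @param outdir optional directory; when given, one
#'   `cluster_<label>.a3m` per job plus `manifest.json` are written there.
#' @param settings predictor settings ([predictor_settings()]).
#' @return list with `jobs` (list of `complex_msa`, each carrying its
#'   `"cluster_label"` attribute) and `manifest` (data.frame with columns
#'   `label`, `file`, `n_chains`, `chains`).
#' @export
emit_prediction_jobs <- function(clusters, partner = NULL, copies = 1L,
                                 outdir = NULL,
                                 settings = predictor_settings()) {
  if (!length(clusters)) abort_argument("no clusters to emit jobs for")
  jobs <- lapply(clusters, function(cl) {
    if (!is.null(partner)) pad_concat_unpaired(cl, partner)
    else duplicate_homooligomer(cl, copies)
  })
  labels <- vapply(clusters, `[[`, integer(1), "label")
  files <- sprintf("cluster_%03d.a3m", labels)
  manifest <- data.frame(
    label = labels,
    file = files,
    n_chains = vapply(jobs, function(j) sum(j$chain_specs$copies), integer(1)),
    chains = vapply(jobs, function(j)
      paste(sprintf("%s:%d:%d", j$chain_specs$chain_id,
                    j$chain_specs$match_length, j$chain_specs$copies),
            collapse = ","), character(1))
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(outdir)) abort_io(sprintf("cannot create %s", outdir))
    for (i in seq_along(jobs)) {
      write_complex_a3m(jobs[[i]], file.path(outdir, files[i]))
    }
    write_manifest(list(settings = settings, jobs = manifest),
                   file.path(outdir, "manifest.json"))
  }
  list(jobs = jobs, manifest = manifest, settings = settings)
}

#' Write / read a prediction-job manifest
#'
#' @param manifest list with elements `settings` and `jobs` (data.frame).
#' @param path JSON file path.
#' @return `path` (write) or the manifest list (read).
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$jobs <- as.data.frame(m$jobs)
  m
}
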