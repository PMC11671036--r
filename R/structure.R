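# structure_model: atomic coordinates plus per-residue plDDT.
#   atoms:  data.frame(chain, resno, resid, elety, x, y, z, o, b)
#   plddt:  data.frame(chain, resno, plddt) — mean B-factor per residue,
#           the AlphaFold convention for storing per-residue confidence.
new_structure_model <- function(atoms) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z", "o", "b")
  stopifnot(all(need %in% names(atoms)))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) abort_format("non-finite coordinates")
  for (ch in unique(atoms$chain)) {
    r <- atoms$resno[atoms$chain == ch]
    if (is.unsorted(unique(r), strictly = TRUE)) {
      abort_format(sprintf("residue numbers not strictly increasing in chain %s", ch))
    }
  }
  key <- paste(atoms$chain, atoms$resno)
  first <- !duplicated(key)
  plddt <- data.frame(
    chain = atoms$chain[first],
    resno = atoms$resno[first],
    plddt = as.numeric(tapply(atoms$b, factor(key, levels = key[first]), mean))
  )
  structure(list(atoms = atoms, plddt = plddt), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d residues, chains [%s]\n",
              nrow(x$atoms), nrow(x$plddt),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

#' Read a PDB structure
#'
#' Parses ATOM records through bio3d. Only the first MODEL of a
#' multi-model file is kept; for alternate locations one atom per position
#' is retained, preferring highest occupancy then the alphabetically first
#' altloc code. The B-factor column is interpreted as per-residue plDDT
#' (averaged over a residue's atoms), following the AlphaFold deposition
#' convention.
#'
#' @param path path to a PDB file.
#' @return a `structure_model`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) abort_format(
                    sprintf("cannot parse PDB %s: %s", path, conditionMessage(e))))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) abort_format(sprintf("no ATOM records in %s", path))
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  alt <- at$alt
  alt[is.na(alt)] <- ""
  pos <- paste(at$chain, at$resno, at$elety)
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(pos, levels = unique(pos))),
                        function(i) i[order(-at$o[i], alt[i])][1L]),
                 use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  at$chain[is.na(at$chain)] <- "A"
  new_structure_model(data.frame(
    chain = at$chain, resno = at$resno, resid = at$resid, elety = at$elety,
    x = at$x, y = at$y, z = at$z, o = at$o, b = at$b
  ))
}

#' Write a structure model to PDB
#'
#' Per-atom B-factors carry the plDDT values; coordinates are written at
#' PDB precision (3 decimals).
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, o = a$o, b = a$b)
  invisible(path)
}

#' Residue selection for superposition and RMSD
#'
#' @param segments data.frame with columns `chain`, `start`, `end`
#'   (inclusive residue-number ranges); segments must not overlap within a
#'   chain.
#' @param atom_subset atoms used per residue: `"CA"` (default, the
#'   convention for transmembrane-segment comparisons), `"backbone"`
#'   (N, CA, C, O) or `"all-heavy"`.
#' @return a `residue_selection` object.
#' @export
residue_selection <- function(segments,
                              atom_subset = c("CA", "backbone", "all-heavy")) {
  atom_subset <- match.arg(atom_subset)
  segments <- as.data.frame(segments)
  if (!all(c("chain", "start", "end") %in% names(segments)) || !nrow(segments)) {
    abort_argument("`segments` needs nonempty chain/start/end columns")
  }
  if (any(segments$start > segments$end)) {
    abort_argument("segment start must be <= end")
  }
  for (ch in unique(segments$chain)) {
    s <- segments[segments$chain == ch, , drop = FALSE]
    covered <- unlist(Map(seq, s$start, s$end))
    if (anyDuplicated(covered)) {
      abort_argument(sprintf("overlapping segments in chain %s", ch))
    }
  }
  structure(list(segments = segments, atom_subset = atom_subset),
            class = "residue_selection")
}

#' Read a residue selection from YAML or JSON
#'
#' Expected keys: `atom_subset` and `segments`, a list of
#' `{chain, start, end}` entries. A template ships in
#' `system.file("extdata", "selection_template.yaml", package = "confland")`.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @return a `residue_selection`.
#' @export
read_selection <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  segs <- do.call(rbind, lapply(cfg$segments, as.data.frame))
  residue_selection(segs, atom_subset = cfg$atom_subset %||% "CA")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Atoms-of-selection in deterministic order: segment order, then residue
# number, then atom name. Errors name the first unresolvable residue.
select_atoms <- function(model, selection) {
  stopifnot(inherits(model, "structure_model"),
            inherits(selection, "residue_selection"))
  subset_names <- switch(selection$atom_subset,
                         "CA" = "CA",
                         "backbone" = c("N", "CA", "C", "O"),
                         "all-heavy" = NULL)
  a <- model$atoms
  out <- list()
  for (s in seq_len(nrow(selection$segments))) {
    seg <- selection$segments[s, ]
    for (r in seq(seg$start, seg$end)) {
      rows <- which(a$chain == seg$chain & a$resno == r)
      if (!is.null(subset_names)) {
        rows <- rows[a$elety[rows] %in% subset_names]
        rows <- rows[order(match(a$elety[rows], subset_names))]
      } else {
        rows <- rows[!grepl("^H", a$elety[rows])]
        rows <- rows[order(a$elety[rows])]
      }
      if (!length(rows)) {
        abort_selection(sprintf(
          "selection cannot be resolved: chain %s residue %d (%s atoms)",
          seg$chain, r, selection$atom_subset))
      }
      out[[length(out) + 1L]] <- rows
    }
  }
  idx <- unlist(out)
  list(xyz = as.matrix(a[idx, c("x", "y", "z")]),
       atoms = a[idx, , drop = FALSE])
}

# Per-residue plDDT of the selected residues.
selection_plddt <- function(model, selection) {
  p <- model$plddt
  vals <- unlist(lapply(seq_len(nrow(selection$segments)), function(s) {
    seg <- selection$segments[s, ]
    p$plddt[p$chain == seg$chain & p$resno >= seg$start & p$resno <= seg$end]
  }))
  vals
}
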