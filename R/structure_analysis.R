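#' Segment RMSD of a model to both conformational references
#'
#' Superposes the model onto each reference over the configured residue
#' selection and returns both RMSDs. By default the superposition is
#' fitted on the selection itself; `fit = "whole"` instead fits on all
#' residues shared by the selection's chains (same atom subset) and then
#' measures RMSD over the selection without refitting.
#'
#' @param model a `structure_model` (predicted model).
#' @param ref_active,ref_inactive reference `structure_model`s.
#' @param selection a [residue_selection()] (e.g. the intracellular
#'   portions of TM5-TM6 for a GPCR), applied to the references.
#' @param selection_model optional selection applied to the model when its
#'   chain ids or numbering differ from the references; defaults to
#'   `selection`. Both must resolve to equal atom counts.
#' @param fit `"selection"` (default) or `"whole"`.
#' @return named numeric vector `c(rmsd_active = , rmsd_inactive = )`.
#' @export
rmsd_to_references <- function(model, ref_active, ref_inactive, selection,
                               selection_model = selection,
                               fit = c("selection", "whole")) {
  fit <- match.arg(fit)
  one <- function(ref) {
    mv <- select_atoms(model, selection_model)$xyz
    rv <- select_atoms(ref, selection)$xyz
    if (nrow(mv) != nrow(rv)) {
      abort_selection(sprintf(
        "selection resolves to %d atoms on the model but %d on the reference",
        nrow(mv), nrow(rv)))
    }
    if (fit == "selection") return(kabsch_rmsd(mv, rv)$rmsd)
    whole_m <- whole_chain_selection(model, selection_model)
    whole_r <- whole_chain_selection(ref, selection)
    mw <- select_atoms(model, whole_m)$xyz
    rw <- select_atoms(ref, whole_r)$xyz
    if (nrow(mw) != nrow(rw)) {
      abort_selection("whole-chain fit: model and reference atom counts differ")
    }
    k <- kabsch_rmsd(mw, rw)
    moved <- sweep(mv %*% k$rotation, 2, k$translation, `+`)
    sqrt(mean(rowSums((moved - rv)^2)))
  }
  c(rmsd_active = one(ref_active), rmsd_inactive = one(ref_inactive))
}

# Selection spanning every residue of the chains named in `selection`.
whole_chain_selection <- function(model, selection) {
  chains <- unique(selection$segments$chain)
  segs <- do.call(rbind, lapply(chains, function(ch) {
    r <- model$plddt$resno[model$plddt$chain == ch]
    data.frame(chain = ch, start = min(r), end = max(r))
  }))
  residue_selection(segs, atom_subset = selection$atom_subset)
}

#' RMSD between the two reference structures over a selection
#'
#' The conformational gap between the active and inactive references over
#' the analysed segments. This is the quantity that motivates the
#' classification threshold of the `gcgr54` rule (5.4 Angstrom for the
#' GCGR TM5-TM6 segments).
#'
#' @inheritParams rmsd_to_references
#' @return RMSD in Angstrom.
#' @export
reference_gap_rmsd <- function(ref_active, ref_inactive, selection) {
  a <- select_atoms(ref_active, selection)$xyz
  i <- select_atoms(ref_inactive, selection)$xyz
  if (nrow(a) != nrow(i)) {
    abort_selection("selection resolves to different atom counts on the two references")
  }
  kabsch_rmsd(a, i)$rmsd
}

#' Classify conformational states from reference RMSDs
#'
#' Vectorised application of one of three classification rules:
#' \describe{
#'   \item{`argmin_excl3`}{state is the reference with the lower RMSD;
#'     models with RMSD over 3 Angstrom to both conformations are
#'     `excluded`; exact ties are `ambiguous`.}
#'   \item{`thresh35`}{`active` if `rmsd_active < 3.5` and
#'     `rmsd_active <= rmsd_inactive` (inactive symmetric); equal RMSDs
#'     both under 3.5 are `ambiguous`; everything else `excluded`. Used
#'     when the references differ strongly (fold-switch dimers).}
#'   \item{`gcgr54`}{state is the argmin if the lower RMSD is at most
#'     5.4 Angstrom (the reference-gap value for the GCGR TM5-TM6
#'     segments) AND mean plDDT exceeds 70; otherwise `excluded`.}
#' }
#'
#' @param rmsd_active,rmsd_inactive numeric vectors of segment RMSDs (A).
#' @param mean_plddt numeric vector (required by `gcgr54`).
#' @param iptm numeric vector or `NA` for monomers; carried through.
#' @param rule one of `"argmin_excl3"`, `"thresh35"`, `"gcgr54"`.
#' @param model character vector of model identifiers.
#' @return data.frame of state calls: `model`, `rmsd_active`,
#'   `rmsd_inactive`, `mean_plddt`, `iptm`, `state` (one of `active`,
#'   `inactive`, `ambiguous`, `excluded`) and `rule`.
#' @export
classify_state <- function(rmsd_active, rmsd_inactive, mean_plddt = NA_real_,
                           iptm = NA_real_,
                           rule = c("argmin_excl3", "thresh35", "gcgr54"),
                           model = NULL) {
  rule <- match.arg(rule)
  n <- length(rmsd_active)
  if (length(rmsd_inactive) != n) {
    abort_argument("`rmsd_active` and `rmsd_inactive` lengths differ")
  }
  mean_plddt <- rep_len(mean_plddt, n)
  iptm <- rep_len(iptm, n)
  if (is.null(model)) model <- sprintf("model_%03d", seq_len(n))
  lo <- pmin(rmsd_active, rmsd_inactive)
  argmin <- ifelse(rmsd_active == rmsd_inactive, "ambiguous",
                   ifelse(rmsd_active < rmsd_inactive, "active", "inactive"))
  state <- switch(rule,
    argmin_excl3 = ifelse(lo > 3.0, "excluded", argmin),
    thresh35 = ifelse(lo < 3.5, argmin, "excluded"),
    gcgr54 = {
      if (anyNA(mean_plddt)) abort_argument("rule 'gcgr54' requires mean_plddt")
      ifelse(lo <= 5.4 & mean_plddt > 70, argmin, "excluded")
    })
  data.frame(model = as.character(model),
             rmsd_active = rmsd_active, rmsd_inactive = rmsd_inactive,
             mean_plddt = mean_plddt, iptm = iptm,
             state = state, rule = rule)
}

#' Top fraction of state calls by a confidence metric
#'
#' Returns the `ceiling(fraction * n)` highest-confidence calls sorted
#' descending by the metric; exact metric ties are broken by model id so
#' the result is invariant to input order.
#'
#' @param calls state-call data.frame ([classify_state()]).
#' @param metric `"plddt"` (uses `mean_plddt`) or `"iptm"`.
#' @param fraction fraction to keep, in `(0, 1]`; default 0.1 (the top-10%
#'   convention).
#' @return the selected rows of `calls`, sorted.
#' @export
rank_top_fraction <- function(calls, metric = c("plddt", "iptm"),
                              fraction = 0.1) {
  metric <- match.arg(metric)
  if (!is.data.frame(calls) || !nrow(calls)) abort_argument("`calls` is empty")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    abort_argument("`fraction` must be in (0, 1]")
  }
  vals <- if (metric == "plddt") calls$mean_plddt else calls$iptm
  if (anyNA(vals)) {
    abort_argument(sprintf("metric '%s' missing on some calls", metric))
  }
  k <- ceiling(fraction * nrow(calls))
  out <- calls[order(-vals, calls$model), , drop = FALSE][seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise a conformational landscape
#'
#' Counts and percentages per state over a set of calls. Percentages are
#' computed over all calls, excluded and ambiguous ones included, so the
#' four rows sum to 100.
#'
#' @param calls state-call data.frame ([classify_state()] or a ranked
#'   subset from [rank_top_fraction()]).
#' @return data.frame with columns `state`, `n`, `pct`, class
#'   `confland_summary`.
#' @export
landscape_summary <- function(calls) {
  if (!is.data.frame(calls) || !nrow(calls)) abort_argument("`calls` is empty")
  states <- c("active", "inactive", "ambiguous", "excluded")
  n <- vapply(states, function(s) sum(calls$state == s), integer(1))
  out <- data.frame(state = states, n = as.integer(n),
                    pct = 100 * n / nrow(calls), row.names = NULL)
  class(out) <- c("confland_summary", "data.frame")
  out
}

#' @export
print.confland_summary <- function(x, ...) {
  total <- sum(x$n)
  cat(sprintf("landscape over %d models:\n", total))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-9s %4d  (%d%%)\n", x$state[i], x$n[i], round(x$pct[i])))
  }
  invisible(x)
}
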