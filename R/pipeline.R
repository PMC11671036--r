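#' Run the clustered-MSA landscape pipeline with the mock predictor
#'
#' Closed-loop driver used by tests and the acceptance script: fans the
#' clusters out into prediction jobs ([emit_prediction_jobs()]), predicts
#' each with the deterministic mock ([mock_predict()]), classifies every
#' model against the rule set's reference structures
#' ([rmsd_to_references()], [classify_state()]), ranks the top confidence
#' fraction and summarises the landscape.
#'
#' @param clusters list of `sequence_cluster`s ([cluster_msa()]).
#' @param rules a `mock_rules` object ([make_mock_rules()]) built on these
#'   clusters' labels.
#' @param partner optional partner [msa]; when given, jobs are unpaired
#'   receptor-ligand assemblies, otherwise homooligomers of `copies`.
#' @param copies chain copies when no partner is given.
#' @param rule classification rule id (see [classify_state()]).
#' @param metric,top_fraction confidence ranking (see
#'   [rank_top_fraction()]).
#' @param selection residue selection for the RMSD analysis; defaults to
#'   the rule set's whole-chain CA selection.
#' @param fit superposition mode (see [rmsd_to_references()]).
#' @param seed integer seed; each job gets a seed derived from it and the
#'   cluster label.
#' @param outdir optional directory for job A3Ms and the manifest.
#' @return list with `calls`, `summary`, `top`, `top_summary`, `manifest`
#'   and the `planted` record carried over from `rules`.
#' @export
run_mock_landscape <- function(clusters, rules, partner = NULL, copies = 1L,
                               rule = "argmin_excl3", metric = "iptm",
                               top_fraction = 0.1, selection = NULL,
                               fit = "selection", seed = 1L, outdir = NULL) {
  stopifnot(inherits(rules, "mock_rules"))
  if (is.null(selection)) selection <- rules$structure$selection
  emitted <- emit_prediction_jobs(clusters, partner = partner,
                                  copies = copies, outdir = outdir)
  results <- lapply(emitted$jobs, function(job) {
    mock_predict(job, rules, derive_seed(seed, attr(job, "cluster_label")))
  })
  rmsds <- t(vapply(results, function(res) {
    rmsd_to_references(res$model, rules$structure$ref_active,
                       rules$structure$ref_inactive, selection, fit = fit)
  }, numeric(2)))
  calls <- classify_state(
    rmsd_active = rmsds[, 1L], rmsd_inactive = rmsds[, 2L],
    mean_plddt = vapply(results, `[[`, numeric(1), "mean_plddt"),
    iptm = vapply(results, `[[`, numeric(1), "iptm"),
    rule = rule,
    model = sprintf("cluster_%03d", emitted$manifest$label))
  top <- rank_top_fraction(calls, metric = metric, fraction = top_fraction)
  list(calls = calls, summary = landscape_summary(calls),
       top = top, top_summary = landscape_summary(top),
       manifest = emitted$manifest, planted = rules$planted)
}
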