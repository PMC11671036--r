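#' Predictor settings
#'
#' Defaults follow the landscape-sampling protocol: a single model with
#' three recycling steps per cluster.
#'
#' @param n_models number of predictor models per job.
#' @param n_recycle number of recycling steps.
#' @return list of settings.
#' @export
predictor_settings <- function(n_models = 1L, n_recycle = 3L) {
  list(n_models = as.integer(n_models), n_recycle = as.integer(n_recycle))
}

#' Predict a structure for a complex alignment job
#'
#' The predictor contract: given a `complex_msa`, return a
#' `prediction_result` holding a `structure_model` with one chain per
#' chain copy, per-residue plDDT (total residues = total match length of
#' the query), and an ipTM score iff the job has more than one chain.
#' The `"mock"` backend is deterministic and used throughout the test
#' suite; `"colabfold"` is a thin subprocess adapter around a local
#' `colabfold_batch` binary and raises a typed predictor error when the
#' binary is unavailable.
#'
#' @param job a `complex_msa`.
#' @param backend `"mock"` or `"colabfold"`.
#' @param rules mock rule table ([make_mock_rules()]); mock backend only.
#' @param seed integer seed; mock backend only.
#' @param settings [predictor_settings()].
#' @return a `prediction_result`: list with `model`, `mean_plddt`, `iptm`
#'   (`NA` for monomers) and `cluster`.
#' @export
predict_structure <- function(job, backend = c("mock", "colabfold"),
                              rules = NULL, seed = 1L,
                              settings = predictor_settings()) {
  backend <- match.arg(backend)
  stopifnot(inherits(job, "complex_msa"))
  if (backend == "mock") {
    if (is.null(rules)) abort_config("mock backend needs a `rules` table")
    return(mock_predict(job, rules, seed))
  }
  colabfold_predict(job, settings)
}

# Untested adapter: shells out to a local ColabFold. Kept out of the test
# suite (GPU dependency); only the unavailable-binary error path is
# exercised.
colabfold_predict <- function(job, settings = predictor_settings()) {
  bin <- Sys.which("colabfold_batch")
  if (!nzchar(bin)) {
    abort_predictor("predictor unavailable: 'colabfold_batch' not found on PATH")
  }
  dir <- tempfile("cf_job_")
  dir.create(dir)
  write_complex_a3m(job, file.path(dir, "job.a3m"))
  status <- system2(bin, c(file.path(dir, "job.a3m"), dir,
                           "--num-models", settings$n_models,
                           "--num-recycle", settings$n_recycle))
  if (status != 0L) abort_predictor(sprintf("colabfold_batch exited with %d", status))
  pdbs <- list.files(dir, pattern = "rank_001.*\\.pdb$", full.names = TRUE)
  if (!length(pdbs)) abort_predictor("colabfold_batch produced no ranked model")
  model <- read_structure(pdbs[1L])
  structure(list(model = model, mean_plddt = mean(model$plddt$plddt),
                 iptm = NA_real_,
                 cluster = attr(job, "cluster_label") %||% NA_integer_),
            class = "prediction_result")
}

#' Deterministic mock predictor
#'
#' Test double standing in for a neural structure predictor. The rule
#' table maps a job's cluster label to a planted conformational state and
#' to plDDT/ipTM score distributions; the mock emits the corresponding
#' fixture template (see [make_two_state_structures()]) with Gaussian
#' coordinate noise and draws the scores — all under the given seed, so
#' repeated calls are byte-identical.
#'
#' Chains are laid out one per chain copy (ids `A`, `B`, ...): copies of
#' the first (metamorphic) chain use the state template, partner chains a
#' generic helical trace of the right length.
#'
#' @param job a `complex_msa` carrying a `"cluster_label"` attribute (as
#'   emitted by [emit_prediction_jobs()]).
#' @param rules a `mock_rules` object ([make_mock_rules()]).
#' @param seed integer seed.
#' @return a `prediction_result`.
#' @export
mock_predict <- function(job, rules, seed) {
  stopifnot(inherits(job, "complex_msa"), inherits(rules, "mock_rules"))
  label <- attr(job, "cluster_label")
  row <- if (!is.null(label)) {
    rules$table[match(label, rules$table$label), , drop = FALSE]
  }
  if (is.null(label) || anyNA(row$state)) {
    if (is.null(rules$default)) {
      abort_config(sprintf("no mock rule for cluster label %s and no default rule",
                           if (is.null(label)) "<none>" else label))
    }
    row <- rules$default
  }
  st <- rules$structure
  spans <- job$boundaries
  span_len <- job$chain_specs$match_length[match(spans$chain_id,
                                                 job$chain_specs$chain_id)]
  receptor_chain <- job$chain_specs$chain_id[1L]
  with_seed(seed, {
    atoms <- do.call(rbind, lapply(seq_len(nrow(spans)), function(s) {
      L <- span_len[s]
      xyz <- if (spans$chain_id[s] == receptor_chain) {
        if (L != st$spec$n_residues) {
          abort_config(sprintf(
            "mock structure fixture has %d residues but receptor chain has %d",
            st$spec$n_residues, L))
        }
        st$templates[[row$state]]
      } else {
        helix_trace(L)
      }
      xyz <- xyz + matrix(rnorm(length(xyz), 0, rules$noise_sigma), ncol = 3)
      xyz[, 1] <- xyz[, 1] + (s - 1L) * 60   # keep chains apart
      data.frame(chain = LETTERS[s], resno = seq_len(L), resid = "GLY",
                 elety = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 o = 1, b = 0)
    }))
    model_mean <- rnorm(1, row$plddt_mean, row$plddt_sd)
    atoms$b <- clamp(rnorm(nrow(atoms), model_mean, 2), 0, 100)
    iptm <- if (nrow(spans) > 1L) {
      clamp(rnorm(1, row$iptm_mean, row$iptm_sd), 0, 1)
    } else NA_real_
    model <- new_structure_model(atoms)
    structure(list(model = model,
                   mean_plddt = mean(model$plddt$plddt),
                   iptm = iptm,
                   cluster = label %||% NA_integer_),
              class = "prediction_result")
  })
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result (cluster %s): mean plDDT %.1f, ipTM %s\n",
              x$cluster, x$mean_plddt,
              if (is.na(x$iptm)) "-" else sprintf("%.2f", x$iptm)))
  invisible(x)
}

#' Write / read a prediction result
#'
#' The model goes to `<name>.pdb` with plDDT in the B-factor column; the
#' scores to a `<name>_scores.json` sidecar
#' (`{"mean_plddt": , "iptm": , "cluster": }`), matching real predictor
#' output layout so downstream analysis is adapter-agnostic.
#'
#' @param result a `prediction_result`.
#' @param dir output directory (created if needed).
#' @param name file stem, e.g. `"cluster_007"`.
#' @return `dir` (write) or a `prediction_result` (read).
#' @export
write_prediction <- function(result, dir, name) {
  stopifnot(inherits(result, "prediction_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_structure(result$model, file.path(dir, paste0(name, ".pdb")))
  jsonlite::write_json(
    list(mean_plddt = result$mean_plddt,
         iptm = if (is.na(result$iptm)) NULL else result$iptm,
         cluster = result$cluster),
    file.path(dir, paste0(name, "_scores.json")),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_prediction
#' @export
read_prediction <- function(dir, name) {
  model <- read_structure(file.path(dir, paste0(name, ".pdb")))
  sc <- jsonlite::read_json(file.path(dir, paste0(name, "_scores.json")),
                            simplifyVector = TRUE)
  structure(list(model = model,
                 mean_plddt = sc$mean_plddt,
                 iptm = sc$iptm %||% NA_real_,
                 cluster = sc$cluster %||% NA_integer_),
            class = "prediction_result")
}
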