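# Deterministic generators of planted-cluster MSAs and two-state toy
# structures, so every pipeline stage is testable without sequence
# databases or a GPU. These emulate the family structure MSA clustering
# exploits and the active/inactive reference pair of the state analysis;
# they carry no protein energetics or phylogenetics.

#' Generate a planted-family MSA
#'
#' Each family fixes `family_signature_columns` disjoint columns to a
#' family-specific residue (other families keep the query residue there);
#' all remaining background columns are mutated and gapped i.i.d. Rows of
#' one family therefore cluster tightly while families are separated by
#' their signatures. With zero rates the one-hot geometry has an exact
#' closed form: squared Euclidean distance = 2 x Hamming distance, so
#' within-family distance is 0 and the squared between-family distance is
#' `2 * (2 * family_signature_columns)` (both families' signature blocks
#' differ).
#'
#' @param n_families number of planted families; default 2.
#' @param rows_per_family sequences per family; default 30.
#' @param match_length alignment columns; must be at least
#'   `n_families * family_signature_columns`.
#' @param family_signature_columns signature columns fixed per family.
#' @param background_mutation_rate per-column substitution probability on
#'   background columns.
#' @param gap_rate per-column gap probability on background columns.
#' @param seed integer seed; the generator is bit-reproducible.
#' @return list with `msa` (query row first), `labels` (planted family per
#'   non-query row), `spec` (the arguments) and `expected` (closed-form
#'   within/between squared distances at zero rates).
#' @export
make_two_state_msa <- function(n_families = 2L, rows_per_family = 30L,
                               match_length = 60L,
                               family_signature_columns = 3L,
                               background_mutation_rate = 0.03,
                               gap_rate = 0.05, seed = 1L) {
  s <- family_signature_columns
  if (!is_count(n_families, 1L) || !is_count(rows_per_family, 1L) ||
      !is_count(match_length, 1L) || !is_count(s, 1L)) {
    abort_argument("counts must be positive integers")
  }
  if (n_families * s > match_length) {
    abort_argument("signature columns exceed match_length: infeasible spec")
  }
  rates <- c(background_mutation_rate, gap_rate)
  if (any(rates < 0 | rates > 1)) abort_argument("rates must be in [0, 1]")
  aa <- AA_ALPHABET[1:20]
  with_seed(seed, {
    query <- sample(aa, match_length, replace = TRUE)
    sig_cols <- lapply(seq_len(n_families), function(f) ((f - 1L) * s + 1L):(f * s))
    bg <- setdiff(seq_len(match_length), unlist(sig_cols))
    # family residue at a signature column: the next alphabet letter after
    # the query's, so it always differs from query and co-resident families
    sig_res <- lapply(sig_cols, function(cols)
      aa[(match(query[cols], aa)) %% 20L + 1L])
    ids <- "query"
    seqs <- paste0(query, collapse = "")
    labels <- integer(0)
    for (f in seq_len(n_families)) {
      for (r in seq_len(rows_per_family)) {
        row <- query
        row[sig_cols[[f]]] <- sig_res[[f]]
        mut <- bg[runif(length(bg)) < background_mutation_rate]
        row[mut] <- vapply(row[mut], function(ch)
          sample(setdiff(aa, ch), 1L), "")
        gp <- bg[runif(length(bg)) < gap_rate]
        row[gp] <- "-"
        ids <- c(ids, sprintf("fam%d_row%03d", f, r))
        seqs <- c(seqs, paste0(row, collapse = ""))
        labels <- c(labels, f)
      }
    }
    list(
      msa = msa(ids, seqs),
      labels = labels,
      spec = list(n_families = n_families, rows_per_family = rows_per_family,
                  match_length = match_length,
                  family_signature_columns = s,
                  background_mutation_rate = background_mutation_rate,
                  gap_rate = gap_rate, seed = seed),
      expected = list(within_sq = 0, between_sq = 2 * (2 * s))
    )
  })
}

# Idealised CA helix trace: 2.3 A radius, 1.5 A rise, 100 degrees/residue.
helix_trace <- function(n) {
  t <- seq_len(n) - 1L
  ang <- t * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * t)
}

# Residual of v after projecting out the columns of B.
project_out <- function(v, B) qr.resid(qr(B), v)

#' Generate a two-state (active/inactive) toy structure pair
#'
#' CA-only traces emulating a conformational switch such as the TM6 swing
#' of a GPCR. The inactive reference equals the active one plus a
#' perturbation supported on a contiguous segment, constructed orthogonal
#' to all rigid motions (zero sum, zero cross-covariance with the centred
#' active coordinates). The Kabsch optimum between the two references is
#' then exactly the identity, giving the closed form
#' `reference_gap_rmsd = displacement * sqrt(fraction_displaced)` over the
#' whole chain. A third "decoy" template is built the same way (support on
#' all residues, additionally orthogonal to the first perturbation) with
#' exact RMSD `decoy_rmsd` to the active and
#' `sqrt(gap^2 + decoy_rmsd^2)` to the inactive reference.
#'
#' @param n_residues trace length; default 50.
#' @param displacement per-residue RMS displacement (Angstrom) applied to
#'   the segment; the default is chosen so the whole-chain reference gap
#'   is exactly 5 Angstrom.
#' @param segment integer vector of displaced residue indices; default the
#'   middle 40% of the chain.
#' @param noise_sigma per-coordinate Gaussian noise (Angstrom) used by the
#'   sampler; default 0.3.
#' @param decoy_rmsd exact RMSD of the decoy template to the active
#'   reference; default 8.
#' @param seed integer seed.
#' @return list with `ref_active`/`ref_inactive` (`structure_model`s,
#'   plDDT 100), `templates` (coordinate matrices `active`, `inactive`,
#'   `decoy`), `sampler(state, seed, plddt, noise_sigma)` returning a noisy
#'   `structure_model`, `selection` (whole-chain CA selection), `spec`, and
#'   closed forms `gap_rmsd`, `decoy_rmsd_active`, `decoy_rmsd_inactive`.
#' @export
make_two_state_structures <- function(n_residues = 50L, displacement = NULL,
                                      segment = NULL, noise_sigma = 0.3,
                                      decoy_rmsd = 8, seed = 1L) {
  if (!is_count(n_residues, 10L)) abort_argument("`n_residues` must be >= 10")
  if (noise_sigma < 0) abort_argument("`noise_sigma` must be >= 0")
  n <- as.integer(n_residues)
  if (is.null(segment)) segment <- (floor(0.3 * n) + 1L):floor(0.7 * n)
  f <- length(segment) / n
  if (is.null(displacement)) displacement <- 5 / sqrt(f)
  if (displacement <= 0) abort_argument("`displacement` must be > 0")
  P <- helix_trace(n)
  Pc <- sweep(P, 2, colMeans(P))
  with_seed(seed, {
    # segment-supported perturbation, orthogonal to translations and to
    # the centred coordinates (so the Kabsch rotation stays identity)
    basis_seg <- cbind(1, Pc[segment, , drop = FALSE])
    E <- matrix(0, n, 3)
    E[segment, ] <- apply(matrix(rnorm(length(segment) * 3), ncol = 3), 2,
                          project_out, B = basis_seg)
    E <- E * (displacement / sqrt(mean(rowSums(E[segment, , drop = FALSE]^2))))
    # decoy: full support, also orthogonal to E
    basis_all <- cbind(1, Pc, E)
    E2 <- apply(matrix(rnorm(n * 3), ncol = 3), 2, project_out, B = basis_all)
    E2 <- E2 * (decoy_rmsd / sqrt(mean(rowSums(E2^2))))
    templates <- list(active = P, inactive = P + E, decoy = P + E2)
    gap <- displacement * sqrt(f)
    mk_model <- function(xyz, plddt = 100) {
      new_structure_model(data.frame(
        chain = "A", resno = seq_len(n), resid = "GLY", elety = "CA",
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1,
        b = rep_len(plddt, n)))
    }
    sampler <- function(state = c("active", "inactive", "decoy"), seed,
                        plddt = 90, sigma = noise_sigma) {
      state <- match.arg(state)
      with_seed(seed, {
        xyz <- templates[[state]] +
          matrix(rnorm(n * 3, 0, sigma), ncol = 3)
        mk_model(xyz, plddt)
      })
    }
    list(
      ref_active = mk_model(templates$active),
      ref_inactive = mk_model(templates$inactive),
      templates = templates,
      sampler = sampler,
      selection = residue_selection(
        data.frame(chain = "A", start = 1L, end = n), "CA"),
      segment_selection = residue_selection(
        data.frame(chain = "A", start = min(segment), end = max(segment)), "CA"),
      spec = list(n_residues = n, displacement = displacement,
                  segment = segment, noise_sigma = noise_sigma,
                  decoy_rmsd = decoy_rmsd, seed = seed),
      gap_rmsd = gap,
      decoy_rmsd_active = decoy_rmsd,
      decoy_rmsd_inactive = sqrt(gap^2 + decoy_rmsd^2)
    )
  })
}

#' Build a mock rule table for a ligand scenario
#'
#' Encodes a conformational-selectivity scenario as planted ground truth:
#' the agonist scenario maps most clusters to the active state and places
#' the high-confidence (high ipTM) mass mostly on active clusters, the
#' antagonist scenario concentrates high confidence on inactive clusters,
#' and the apo scenario splits evenly. A `decoy` fraction models
#' predictions far from both references (excluded downstream). The planted
#' proportions default to recognisable CXCR4-style fractions; they are
#' generator inputs, not claims about predictor behaviour, and are
#' recorded in the returned object for closed-loop recovery tests.
#'
#' @param labels cluster labels the rules apply to (one prediction per
#'   cluster).
#' @param scenario `"agonist"`, `"antagonist"` or `"apo"`.
#' @param structure two-state structure fixture
#'   ([make_two_state_structures()]) whose residue count matches the
#'   receptor chain of the jobs; built with defaults when `NULL`.
#' @param proportions length-3 numeric (active, inactive, decoy) summing
#'   to 1; scenario defaults: agonist `(0.75, 0.18, 0.07)`, antagonist
#'   `(0.65, 0.29, 0.06)`, apo `(0.47, 0.47, 0.06)`.
#' @param top_fraction fraction of predictions treated as high-confidence;
#'   default 0.1.
#' @param top_active_fraction fraction of the high-confidence set planted
#'   on active clusters; scenario defaults: agonist `19/23`, antagonist
#'   `9/23`, apo `0.5`.
#' @param noise_sigma coordinate noise of the mock predictor (Angstrom).
#' @param seed integer seed for the state/confidence assignment.
#' @return a `mock_rules` object: `table` (label, state, plDDT and ipTM
#'   distribution parameters), `structure`, `noise_sigma`, `default`
#'   (NULL), and `planted` (counts, percentages and top-set composition).
#' @export
make_mock_rules <- function(labels,
                            scenario = c("agonist", "antagonist", "apo"),
                            structure = NULL, proportions = NULL,
                            top_fraction = 0.1, top_active_fraction = NULL,
                            noise_sigma = 0.3, seed = 1L) {
  scenario <- match.arg(scenario)
  labels <- sort(unique(as.integer(labels)))
  n <- length(labels)
  if (!n) abort_argument("no cluster labels given")
  if (is.null(proportions)) {
    proportions <- switch(scenario,
      agonist = c(0.75, 0.18, 0.07),
      antagonist = c(0.65, 0.29, 0.06),
      apo = c(0.47, 0.47, 0.06))
  }
  if (length(proportions) != 3L || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-8) {
    abort_argument("`proportions` must be 3 non-negative values summing to 1")
  }
  if (is.null(top_active_fraction)) {
    top_active_fraction <- switch(scenario,
      agonist = 19 / 23, antagonist = 9 / 23, apo = 0.5)
  }
  if (is.null(structure)) structure <- make_two_state_structures(seed = seed)
  n_act <- round(proportions[1L] * n)
  n_in <- round(proportions[2L] * n)
  if (n_act + n_in > n) n_in <- n - n_act
  n_dec <- n - n_act - n_in
  k_top <- ceiling(top_fraction * n)
  n_top_act <- min(max(round(top_active_fraction * k_top), k_top - n_in), n_act)
  pick <- function(v, k) v[sample.int(length(v), k)]   # safe for length-1 v
  with_seed(seed, {
    perm <- pick(labels, n)
    state <- rep(c("active", "inactive", "decoy"), c(n_act, n_in, n_dec))
    top <- c(pick(perm[seq_len(n_act)], n_top_act),
             pick(perm[n_act + seq_len(n_in)], k_top - n_top_act))
    tab <- data.frame(label = perm, state = state,
                      plddt_mean = ifelse(state == "decoy", 60, 85),
                      plddt_sd = 1,
                      iptm_mean = ifelse(perm %in% top, 0.85,
                                         ifelse(state == "decoy", 0.40, 0.55)),
                      iptm_sd = 0.01)
    tab <- tab[order(tab$label), , drop = FALSE]
    rownames(tab) <- NULL
    base::structure(list(
      table = tab, structure = structure, noise_sigma = noise_sigma,
      default = NULL, scenario = scenario,
      planted = list(
        counts = c(active = n_act, inactive = n_in, excluded = n_dec),
        pct = 100 * c(active = n_act, inactive = n_in, excluded = n_dec) / n,
        top = list(k = k_top, active = n_top_act,
                   inactive = k_top - n_top_act))),
      class = "mock_rules")
  })
}

#' @export
print.mock_rules <- function(x, ...) {
  cat(sprintf("mock_rules (%s): %d clusters — planted %d active / %d inactive / %d decoy; top %d: %d active\n",
              x$scenario, nrow(x$table), x$planted$counts[["active"]],
              x$planted$counts[["inactive"]], x$planted$counts[["excluded"]],
              x$planted$top$k, x$planted$top$active))
  invisible(x)
}
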