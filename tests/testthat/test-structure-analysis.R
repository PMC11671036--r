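pdb_line <- function(serial, name, resname, chain, resno, x, y, z, occ, b,
                     alt = " ") {
  sprintf("ATOM  %5d  %-3s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, alt, resname, chain, resno, x, y, z, occ, b)
}

test_that("read_structure parses minimal PDBs and per-residue plDDT", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "N", "GLY", "A", 1, 0, 0, 0, 1, 80),
    pdb_line(2, "CA", "GLY", "A", 1, 1.5, 0, 0, 1, 90),
    pdb_line(3, "CA", "ALA", "A", 2, 3.0, 0, 0, 1, 70),
    pdb_line(4, "CA", "SER", "A", 3, 4.5, 0, 0, 1, 50),
    "END"), f)
  m <- read_structure(f)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$plddt), 3L)
  expect_equal(m$plddt$plddt, c(85, 70, 50))  # residue 1 averages its atoms

  expect_error(read_structure(tempfile()), class = "confland_io_error")
  bad <- tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", bad)
  expect_error(read_structure(bad), class = "confland_format_error")
})

test_that("altloc records keep highest occupancy then alphabetical", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, 0.4, 10, alt = "A"),
    pdb_line(2, "CA", "GLY", "A", 1, 9, 9, 9, 0.6, 20, alt = "B"),
    pdb_line(3, "CA", "GLY", "A", 2, 1, 0, 0, 0.5, 30, alt = "B"),
    pdb_line(4, "CA", "GLY", "A", 2, 2, 0, 0, 0.5, 40, alt = "A"),
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$x, c(9, 2))   # occupancy first, then altloc A
})

test_that("write/read round-trip preserves coordinates at PDB precision", {
  st <- make_two_state_structures(n_residues = 20, seed = 4)
  f <- tempfile(fileext = ".pdb")
  write_structure(st$ref_active, f)
  back <- read_structure(f)
  expect_equal(back$atoms$x, round(st$ref_active$atoms$x, 3))
  expect_equal(back$atoms$y, round(st$ref_active$atoms$y, 3))
  expect_equal(back$plddt$plddt, st$ref_active$plddt$plddt)
})

test_that("kabsch_rmsd is exact under identity and rigid motion", {
  set.seed(10)
  P <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch_rmsd(P, P)$rmsd, 0)
  for (i in 1:10) {
    R <- random_rotation()
    t <- rnorm(3, sd = 10)
    Q <- sweep(P %*% R, 2, t, `+`)
    expect_lt(kabsch_rmsd(P, Q)$rmsd, 1e-9)
    # symmetry and invariance of the minimum under rigid motion of either side
    A <- matrix(rnorm(30), ncol = 3)
    expect_equal(kabsch_rmsd(P, A)$rmsd, kabsch_rmsd(A, P)$rmsd, tolerance = 1e-9)
    expect_equal(kabsch_rmsd(Q, A)$rmsd, kabsch_rmsd(P, A)$rmsd, tolerance = 1e-9)
  }
  expect_error(kabsch_rmsd(P, P[1:5, ]), class = "confland_argument_error")
})

test_that("kabsch rotation is proper and reproduces the fit", {
  set.seed(11)
  P <- matrix(rnorm(24), ncol = 3)
  Q <- matrix(rnorm(24), ncol = 3)
  k <- kabsch_rmsd(P, Q)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  moved <- sweep(P %*% k$rotation, 2, k$translation, `+`)
  expect_equal(sqrt(mean(rowSums((moved - Q)^2))), k$rmsd, tolerance = 1e-12)
})

test_that("kabsch agrees with bio3d's least-squares fit", {
  set.seed(12)
  for (i in 1:5) {
    P <- matrix(rnorm(36), ncol = 3)
    Q <- matrix(rnorm(36), ncol = 3)
    ours <- kabsch_rmsd(P, Q)$rmsd
    # bio3d warns when fitting on all positions; that is exactly what we want
    fitted <- matrix(suppressWarnings(
      bio3d::fit.xyz(fixed = as.numeric(t(Q)), mobile = as.numeric(t(P)))),
      ncol = 3, byrow = TRUE)
    theirs <- sqrt(mean(rowSums((fitted - Q)^2)))
    expect_equal(ours, theirs, tolerance = 1e-6)
  }
})

test_that("rmsd_to_references is symmetric around the reference pair", {
  st <- make_two_state_structures(seed = 6)
  gap <- st$gap_rmsd
  r <- rmsd_to_references(st$ref_active, st$ref_active, st$ref_inactive,
                          st$selection)
  expect_equal(unname(r), c(0, gap), tolerance = 1e-9)
  r2 <- rmsd_to_references(st$ref_inactive, st$ref_active, st$ref_inactive,
                           st$selection)
  expect_equal(unname(r2), c(gap, 0), tolerance = 1e-9)

  # midpoint structure: equidistant from both references
  mid <- st$ref_active
  mid$atoms[, c("x", "y", "z")] <-
    (st$ref_active$atoms[, c("x", "y", "z")] +
     st$ref_inactive$atoms[, c("x", "y", "z")]) / 2
  rm_ <- rmsd_to_references(mid, st$ref_active, st$ref_inactive, st$selection)
  expect_equal(rm_[["rmsd_active"]], rm_[["rmsd_inactive"]], tolerance = 1e-6)
})

test_that("whole-chain fit mode measures segment RMSD without refitting", {
  st <- make_two_state_structures(seed = 6)
  r_sel <- rmsd_to_references(st$ref_inactive, st$ref_active, st$ref_inactive,
                              st$segment_selection, fit = "selection")
  r_whole <- rmsd_to_references(st$ref_inactive, st$ref_active, st$ref_inactive,
                                st$segment_selection, fit = "whole")
  expect_equal(r_whole[["rmsd_inactive"]], 0, tolerance = 1e-9)
  # fitting on the segment itself can only lower the segment RMSD
  expect_lte(r_sel[["rmsd_active"]], r_whole[["rmsd_active"]] + 1e-9)
})

test_that("selection errors name the unresolvable residue", {
  st <- make_two_state_structures(n_residues = 20, seed = 2)
  sel <- residue_selection(data.frame(chain = "A", start = 18, end = 25))
  expect_error(select_atoms(st$ref_active, sel), regexp = "residue 21",
               class = "confland_selection_error")
  sel_b <- residue_selection(data.frame(chain = "B", start = 1, end = 2))
  expect_error(select_atoms(st$ref_active, sel_b), regexp = "chain B",
               class = "confland_selection_error")
  expect_error(residue_selection(data.frame(chain = "A", start = 5, end = 2)),
               class = "confland_argument_error")
  expect_error(
    residue_selection(data.frame(chain = "A", start = c(1, 3), end = c(4, 6))),
    class = "confland_argument_error")
})

test_that("selections load from YAML", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("atom_subset: CA", "segments:",
               "  - chain: A", "    start: 3", "    end: 9"), f)
  sel <- read_selection(f)
  expect_equal(sel$atom_subset, "CA")
  expect_equal(sel$segments$start, 3)
  tmpl <- system.file("extdata", "selection_template.yaml", package = "confland")
  expect_s3_class(read_selection(tmpl), "residue_selection")
})

test_that("classification rules follow their truth tables", {
  one <- function(ra, ri, plddt = NA_real_, rule) {
    classify_state(ra, ri, mean_plddt = plddt, rule = rule)$state
  }
  # argmin with 3 A exclusion: strictly-over-3 on the minimum excludes
  expect_equal(one(1.0, 6.0, rule = "argmin_excl3"), "active")
  expect_equal(one(6.0, 1.0, rule = "argmin_excl3"), "inactive")
  expect_equal(one(3.0, 6.0, rule = "argmin_excl3"), "active")   # boundary kept
  expect_equal(one(3.01, 3.5, rule = "argmin_excl3"), "excluded")
  expect_equal(one(2.0, 2.0, rule = "argmin_excl3"), "ambiguous")

  # strict 3.5 A threshold
  expect_equal(one(3.4, 5.0, rule = "thresh35"), "active")
  expect_equal(one(5.0, 3.4, rule = "thresh35"), "inactive")
  expect_equal(one(3.5, 5.0, rule = "thresh35"), "excluded")     # strict <
  expect_equal(one(3.6, 3.6, rule = "thresh35"), "excluded")
  expect_equal(one(2.0, 2.0, rule = "thresh35"), "ambiguous")

  # 5.4 A with plDDT > 70 gate; the argmin picks the closer reference
  expect_equal(one(4.0, 5.0, 85, "gcgr54"), "active")
  expect_equal(one(5.0, 4.0, 85, "gcgr54"), "inactive")
  expect_equal(one(4.0, 5.0, 65, "gcgr54"), "excluded")
  expect_equal(one(5.4, 6.0, 85, "gcgr54"), "active")            # boundary kept
  expect_equal(one(5.5, 6.0, 85, "gcgr54"), "excluded")
  expect_equal(one(4.0, 5.0, 70, "gcgr54"), "excluded")          # strict >
  expect_equal(one(4.0, 4.0, 85, "gcgr54"), "ambiguous")

  expect_error(classify_state(1, 2, rule = "nope"))
  expect_error(classify_state(1, 2, rule = "gcgr54"),
               class = "confland_argument_error")  # needs plDDT
})

test_that("classification is a pure vectorised function", {
  ra <- c(1, 4, 2.5, 3.2); ri <- c(5, 2, 2.5, 3.3)
  a <- classify_state(ra, ri, mean_plddt = 80, rule = "argmin_excl3")
  b <- classify_state(ra, ri, mean_plddt = 80, rule = "argmin_excl3")
  expect_identical(a, b)
  expect_equal(a$state, c("active", "inactive", "ambiguous", "excluded"))
  expect_equal(a$rule, rep("argmin_excl3", 4))
})

test_that("top-fraction ranking returns exactly ceil(f * n), order-invariant", {
  set.seed(20)
  n <- 230
  calls <- classify_state(runif(n, 0.5, 2.9), runif(n, 0.5, 2.9),
                          mean_plddt = runif(n, 60, 95),
                          iptm = runif(n), rule = "argmin_excl3",
                          model = sprintf("m%04d", sample(n)))
  top <- rank_top_fraction(calls, metric = "iptm", fraction = 0.10)
  expect_equal(nrow(top), 23L)   # ceil(0.1 * 230)
  expect_equal(top$iptm, sort(calls$iptm, decreasing = TRUE)[1:23])

  shuffled <- calls[sample(n), ]
  expect_equal(rank_top_fraction(shuffled, "iptm", 0.10), top)

  all_of_them <- rank_top_fraction(calls, "plddt", 1.0)
  expect_equal(nrow(all_of_them), n)
  expect_equal(all_of_them$mean_plddt, sort(calls$mean_plddt, decreasing = TRUE))

  mono <- calls; mono$iptm <- NA_real_
  expect_error(rank_top_fraction(mono, "iptm", 0.1),
               class = "confland_argument_error")
  expect_error(rank_top_fraction(calls, "iptm", 0),
               class = "confland_argument_error")
})

test_that("ties in the ranking metric break by model id", {
  calls <- classify_state(rep(1, 4), rep(5, 4), mean_plddt = 80,
                          iptm = c(0.9, 0.9, 0.9, 0.1),
                          rule = "argmin_excl3",
                          model = c("c", "a", "b", "d"))
  top <- rank_top_fraction(calls, "iptm", 0.5)
  expect_equal(top$model, c("a", "b"))
})

test_that("landscape summary mirrors counts and percentages", {
  states <- rep(c("active", "inactive", "excluded"), c(75, 18, 7))
  calls <- classify_state(
    rmsd_active = ifelse(states == "active", 1, ifelse(states == "inactive", 6, 9)),
    rmsd_inactive = ifelse(states == "inactive", 1, ifelse(states == "active", 6, 9)),
    mean_plddt = 80, rule = "argmin_excl3")
  s <- landscape_summary(calls)
  expect_equal(s$n, c(75L, 18L, 0L, 7L))
  expect_equal(s$pct, c(75, 18, 0, 7))
  expect_equal(sum(s$pct), 100)
  expect_equal(landscape_summary(calls[sample(nrow(calls)), ]), s)
})

test_that("reference gap RMSD matches the generator's closed form", {
  expect_equal(reference_gap_rmsd(
    make_two_state_structures(seed = 1)$ref_active,
    make_two_state_structures(seed = 1)$ref_active,
    make_two_state_structures(seed = 1)$selection), 0)
  for (seed in 1:3) {
    st <- make_two_state_structures(n_residues = 60, seed = seed)
    expect_equal(reference_gap_rmsd(st$ref_active, st$ref_inactive, st$selection),
                 st$gap_rmsd, tolerance = 1e-6)
  }
})
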