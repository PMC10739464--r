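# Rigid superposition, flank building, pseudo-energy minimization and
# ensemble generation.

core_atom_tbl <- function(tr) {
  at <- tr$complex$atoms
  at[at$chain == "P" & at$resno %in% (tr$core$start + 1:9), ]
}

test_that("core superposition recovers identity and pure translations", {
  tr <- fix_single()
  core_atoms <- core_atom_tbl(tr)
  fit <- superpose_core(core_atoms, tr)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  expect_lt(sqrt(sum(fit$translation^2)), 1e-9)

  shifted <- core_atoms
  shifted$x <- shifted$x + 5
  fit2 <- superpose_core(shifted, tr)
  expect_equal(sqrt(sum(fit2$translation^2)), 5, tolerance = 1e-9)
  expect_lt(fit2$rmsd, 1e-9)

  incomplete <- core_atoms[!(core_atoms$atom == "CA" &
                               core_atoms$resno == core_atoms$resno[1]), ]
  expect_error(superpose_core(incomplete, tr), class = "pmhc_backbone_error")
})

test_that("rigid fit of a rotated core matches the quaternion-search oracle", {
  tr <- fix_single()
  core_atoms <- core_atom_tbl(tr)
  bb <- core_atoms[core_atoms$atom %in% c("N", "CA", "C", "O"), ]
  Q <- as.matrix(bb[, c("x", "y", "z")])
  set.seed(5)
  th <- runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1])), 3, byrow = TRUE)
  Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0, -sin(th[2]), 0, cos(th[2])), 3, byrow = TRUE)
  P <- Q %*% Rx %*% Ry + matrix(rnorm(length(Q), 0, 0.3), ncol = 3)
  fit <- pmhc2model:::kabsch_fit(P, Q)
  oracle <- quat_fit_rmsd(P, Q)
  expect_lt(abs(fit$rmsd - oracle), 1e-4)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)  # no reflection
})

test_that("flank building is deterministic, ideal-geometry and core-preserving", {
  tr <- fix_single()
  cx <- tr$complex
  core <- tr$core
  rec <- cx$atoms[cx$atoms$chain %in% c("M", "N"), ]
  core_atoms <- core_atom_tbl(tr)

  # zero-length flanks: output is the placed core
  pep9 <- substr(cx$peptide_seq, core$start + 1, core$start + 9)
  core9 <- binding_core(0, 9)
  core_atoms9 <- core_atoms
  core_atoms9$resno <- core_atoms9$resno - core$start
  out9 <- build_flanks(core_atoms9, pep9, core9, rec, seed = 1)
  expect_identical(nrow(out9), nrow(core_atoms9))
  expect_equal(sort(out9$x), sort(core_atoms9$x))

  out_a <- build_flanks(core_atoms, cx$peptide_seq, core, rec, seed = 4,
                        template = tr, correspondence = NULL)
  out_b <- build_flanks(core_atoms, cx$peptide_seq, core, rec, seed = 4,
                        template = tr, correspondence = NULL)
  out_c <- build_flanks(core_atoms, cx$peptide_seq, core, rec, seed = 5,
                        template = tr, correspondence = NULL)
  expect_identical(out_a$x, out_b$x)  # same seed: bit-identical
  expect_false(identical(out_a$x, out_c$x))  # different seed: different flanks

  # core rows unchanged
  expect_equal(out_a[out_a$resno %in% (core$start + 1:9) &
                       out_a$atom %in% c("N", "CA", "C", "O"), ]$x,
               core_atoms[core_atoms$atom %in% c("N", "CA", "C", "O"), ]$x)

  # built bonds within 0.05 A of ideal values
  g <- pmhc2model:::IDEAL_GEOM
  coord <- function(r, an) {
    row <- out_a[out_a$resno == r & out_a$atom == an, ]
    c(row$x, row$y, row$z)
  }
  flank_res <- setdiff(seq_len(nchar(cx$peptide_seq)), core$start + 1:9)
  for (r in flank_res) {
    expect_lt(abs(sqrt(sum((coord(r, "N") - coord(r, "CA"))^2)) - g$b_n_ca), 0.05)
    expect_lt(abs(sqrt(sum((coord(r, "CA") - coord(r, "C"))^2)) - g$b_ca_c), 0.05)
    nxt <- coord(r + 1, "N")
    if (length(nxt)) {
      expect_lt(abs(sqrt(sum((coord(r, "C") - nxt)^2)) - g$b_c_n), 0.05)
    }
  }
})

tiny_two_atom_model <- function(pep_xyz, rec_xyz = c(0, 0, 0)) {
  atoms <- tibble::tibble(
    chain = c("M", "P"), resno = c(1L, 1L),
    resname = c("ALA", "ALA"), atom = c("CA", "CA"), element = "C",
    x = c(rec_xyz[1], pep_xyz[1]), y = c(rec_xyz[2], pep_xyz[2]),
    z = c(rec_xyz[3], pep_xyz[3]))
  pmhc2model:::new_pmhc_complex("tiny", "II", atoms, peptide_seq = "A")
}

test_that("a single free-atom restraint relaxes to its target distance", {
  m <- tiny_two_atom_model(c(5, 0, 0))
  rst <- tibble::tibble(chain_a = "P", res_a = 1L, atom_a = "CA",
                        chain_b = "M", res_b = 1L, atom_b = "CA",
                        target = 3.0, sd = 0)
  res <- minimize(m, rst, mode = "flex_core", max_steps = 500, core = NULL)
  d <- sqrt(sum((unlist(res$model$atoms[2, c("x", "y", "z")]) -
                   unlist(res$model$atoms[1, c("x", "y", "z")]))^2))
  expect_lt(abs(d - 3.0), 0.02)
  expect_true(all(diff(res$trajectory) <= 1e-9))
  expect_equal(res$energy$total,
               res$energy$bonded + res$energy$clash + res$energy$restraint)
})

test_that("a satisfied system at mild separation is a fixed point", {
  m <- tiny_two_atom_model(c(8, 0, 0))
  rst <- tibble::tibble(chain_a = "P", res_a = 1L, atom_a = "CA",
                        chain_b = "M", res_b = 1L, atom_b = "CA",
                        target = 8.0, sd = 0)
  res <- minimize(m, rst, mode = "flex_core", core = NULL)
  expect_equal(res$model$atoms$x, m$atoms$x, tolerance = 1e-9)
  expect_equal(res$energy$restraint, 0)
  expect_equal(res$energy$bonded, 0)
})

test_that("fixed-core refinement freezes the core bit-exactly", {
  tr <- fix_single()
  target <- tr$complex
  job <- modelling_job(chain_sequence(target, "M"), chain_sequence(target, "N"),
                       target$peptide_seq, tr$core, tr, n_models = 1, seed = 2)
  rst <- derive_restraints(tr, job$correspondence)
  m <- pmhc2model:::build_peptide_model(job, 3)
  before <- m$atoms[m$atoms$chain == "P" &
                      m$atoms$resno %in% (tr$core$start + 1:9), ]
  res <- minimize(m, rst, mode = "fixed_core", core = tr$core)
  after <- res$model$atoms[res$model$atoms$chain == "P" &
                             res$model$atoms$resno %in% (tr$core$start + 1:9), ]
  expect_identical(before$x, after$x)
  expect_identical(before$y, after$y)
  expect_identical(before$z, after$z)
  expect_true(all(diff(res$trajectory) <= 1e-9))
})

test_that("ensembles have the requested size, sorted ranks and reproducibility", {
  tr <- fix_single()
  target <- tr$complex
  job <- modelling_job(chain_sequence(target, "M"), chain_sequence(target, "N"),
                       target$peptide_seq, tr$core, tr, n_models = 4, seed = 9)
  rst <- derive_restraints(tr, job$correspondence)
  ens <- generate_ensemble(job, rst, max_steps = 60)
  expect_identical(nrow(ens$table), 4L)
  expect_identical(sort(ens$table$rank), 1:4)
  tb <- ens$table[order(ens$table$rank), ]
  expect_true(all(diff(tb$pseudo_energy) >= 0))
  expect_identical(ens$table$seed_used, 9L + 1:4)

  ens2 <- generate_ensemble(job, rst, max_steps = 60)
  expect_identical(ens$table$pseudo_energy, ens2$table$pseudo_energy)
  expect_identical(ens$table$rank, ens2$table$rank)
  expect_identical(ens$models[[1]]$atoms$x, ens2$models[[1]]$atoms$x)

  td <- tidy(ens)
  expect_identical(td$rank, 1:4)
  gl <- glance(ens)
  expect_identical(gl$n_models, 4L)
  expect_equal(gl$best_pseudo_energy, min(ens$table$pseudo_energy))

  dir <- withr::local_tempdir()
  write_ensemble(ens, dir)
  expect_true(file.exists(file.path(dir, "ranking.tsv")))
  expect_identical(sort(list.files(dir, pattern = "^model_\\d+\\.pdb$")),
                   sort(sprintf("model_%d.pdb", 1:4)))
})

test_that("energy breakdown terms are non-negative and sum to the total", {
  tr <- fix_single()
  target <- tr$complex
  job <- modelling_job(chain_sequence(target, "M"), chain_sequence(target, "N"),
                       target$peptide_seq, tr$core, tr, n_models = 1, seed = 2)
  rst <- derive_restraints(tr, job$correspondence)
  m <- pmhc2model:::build_peptide_model(job, 5)
  res <- minimize(m, rst, mode = "fixed_core", core = tr$core, max_steps = 40)
  e <- res$energy
  expect_true(all(c(e$bonded, e$clash, e$restraint) >= 0))
  expect_equal(e$total, e$bonded + e$clash + e$restraint)
})
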