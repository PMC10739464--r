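# Receptor-frame superposition, backbone L-RMSD and the benchmark harness.

test_that("receptor superposition recovers rigid transforms exactly", {
  tr <- fix_single()
  cx <- tr$complex
  fitted <- receptor_superpose(cx, cx)
  expect_lt(attr(fitted, "receptor_rmsd"), 1e-9)
  expect_equal(fitted$atoms$x, cx$atoms$x, tolerance = 1e-9)

  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
               byrow = TRUE)
  rot <- cx
  xyz <- as.matrix(rot$atoms[, c("x", "y", "z")]) %*% Rz
  rot$atoms$x <- xyz[, 1] + 3
  rot$atoms$y <- xyz[, 2] - 2
  rot$atoms$z <- xyz[, 3] + 1
  back <- receptor_superpose(rot, cx)
  expect_lt(attr(back, "receptor_rmsd"), 1e-6)
  rep <- lrmsd(back, cx, tr$core)
  expect_lt(rep$whole, 1e-6)  # joint rigid transforms are removed
})

test_that("receptor fit matches the quaternion oracle on a 12-atom toy", {
  set.seed(13)
  Q <- matrix(rnorm(36, sd = 4), ncol = 3)
  P <- Q + matrix(rnorm(36, 0, 0.5), ncol = 3)
  fit <- pmhc2model:::kabsch_fit(P, Q)
  expect_lt(abs(fit$rmsd - quat_fit_rmsd(P, Q)), 1e-4)
})

test_that("receptor residue mismatches raise a correspondence error", {
  tr <- fix_single()
  cx <- tr$complex
  pruned <- cx
  pruned$atoms <- cx$atoms[!(cx$atoms$chain == "M" & cx$atoms$resno == 1L), ]
  expect_error(receptor_superpose(pruned, cx),
               class = "pmhc_correspondence_error")
  expect_silent(receptor_superpose(pruned, cx, on_mismatch = "intersect"))
})

test_that("single-atom displacement has the closed-form core L-RMSD", {
  # 9-mer peptide: the core is the whole peptide, 36 backbone atoms
  sp <- fixture_spec("WRTYARQMV", core_start = 0, seed = 2, pdb_id = "nine")
  cx <- make_toy_pmhc2(sp)
  core <- attr(cx, "core")
  disp <- cx
  i <- which(disp$atoms$chain == "P" & disp$atoms$resno == 5 &
               disp$atoms$atom == "CA")
  disp$atoms$x[i] <- disp$atoms$x[i] + 6.0
  fitted <- receptor_superpose(disp, cx)
  expect_lt(attr(fitted, "receptor_rmsd"), 1e-12)  # receptor untouched
  rep <- lrmsd(fitted, cx, core)
  expect_equal(rep$core, 1.0, tolerance = 1e-9)   # 6 / sqrt(36)
  expect_equal(rep$whole, 1.0, tolerance = 1e-9)
  expect_true(is.na(rep$flanking))
  expect_identical(rep$n_core_atoms, 36L)
  expect_identical(rep$n_flank_atoms, 0L)
})

test_that("core/flanking/whole obey the atom-weighted quadratic identity", {
  tr <- fix_single()
  cx <- tr$complex
  set.seed(31)
  for (rep_i in 1:5) {
    noisy <- cx
    pep <- noisy$atoms$chain == "P"
    noisy$atoms$x[pep] <- noisy$atoms$x[pep] + rnorm(sum(pep), 0, 0.8)
    noisy$atoms$y[pep] <- noisy$atoms$y[pep] + rnorm(sum(pep), 0, 0.8)
    rep <- lrmsd(noisy, cx, tr$core)
    lhs <- rep$whole^2 * (rep$n_core_atoms + rep$n_flank_atoms)
    rhs <- rep$core^2 * rep$n_core_atoms + rep$flanking^2 * rep$n_flank_atoms
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("length mismatches raise an evaluation error", {
  tr <- fix_single()
  sp <- fixture_spec("WRTYARQMV", core_start = 0, seed = 2, pdb_id = "nine")
  other <- make_toy_pmhc2(sp)
  expect_error(lrmsd(other, tr$complex, tr$core),
               class = "pmhc_evaluation_error")
})

test_that("perturbation ground truths agree with lrmsd", {
  tr <- fix_single()
  shift <- perturb_fixture(tr, "peptide_shift", magnitude = 2.0, seed = 4)
  fitted <- receptor_superpose(shift$complex, tr$complex)
  rep <- lrmsd(fitted, tr$complex, tr$core)
  expect_equal(rep$whole, 2.0, tolerance = 1e-9)
  expect_equal(rep$core, shift$ground_truth$core, tolerance = 1e-9)

  zero <- perturb_fixture(tr, "peptide_shift", magnitude = 0, seed = 4)
  expect_identical(zero$complex$atoms$x, tr$complex$atoms$x)

  scr <- perturb_fixture(tr, "flank_scramble", magnitude = 0.6, seed = 9)
  rep2 <- lrmsd(receptor_superpose(scr$complex, tr$complex), tr$complex,
                tr$core)
  expect_equal(rep2$core, 0, tolerance = 1e-12)
  expect_gt(rep2$flanking, 0)
  expect_lt(abs(rep2$flanking - scr$ground_truth$flanking), 1e-6)
  expect_lt(abs(rep2$whole - scr$ground_truth$whole), 1e-6)

  reg <- perturb_fixture(tr, "core_register_shift", k = 1, seed = 1)
  expect_identical(reg$core$start, tr$core$start + 1L)
  expect_identical(reg$complex$atoms$x, tr$complex$atoms$x)
})

test_that("success_rate counts cases below threshold and grows with it", {
  pc <- tibble::tibble(topk_whole = c(0.5, 1.9, 2.5, NA))
  expect_equal(success_rate(pc, 2), 0.5)
  expect_equal(success_rate(pc, 0.4), 0)
  expect_equal(success_rate(pc, 3), 0.75)
  ths <- seq(0.1, 4, by = 0.3)
  expect_true(all(diff(vapply(ths, function(t) success_rate(pc, t),
                              numeric(1))) >= 0))
})

test_that("self-template modelling reproduces the fixture (no leave-one-out)", {
  tr <- fix_single()
  bm <- run_benchmark(list(tr, fix_plain_set()[[2]]), leave_one_out = FALSE,
                      n_models = 2, seed = 3, max_steps = 60)
  row <- tidy(bm)[tidy(bm)$case_id == tr$id, ]
  expect_false(row$failed)
  expect_identical(row$template_id, tr$id)
  expect_lt(row$best_whole, 0.2)
})

test_that("near-duplicate leave-one-out benchmark recovers both partners", {
  recs <- fix_pair_set()
  bm <- run_benchmark(recs, leave_one_out = TRUE, n_models = 2, seed = 5,
                      max_steps = 60)
  pc <- tidy(bm)
  expect_true(all(!pc$failed))
  expect_true(all(pc$best_whole < 0.5))
  expect_equal(success_rate(pc, 2), 1.0)

  # aggregates are recomputable from the per-case rows
  agg <- bm$aggregates
  expect_equal(agg$median[agg$metric == "best_whole"], median(pc$best_whole))
  expect_equal(agg$mean[agg$metric == "best_whole"], mean(pc$best_whole))
  expect_equal(agg$sd[agg$metric == "best_whole"], sd(pc$best_whole))

  gl <- glance(bm)
  expect_identical(gl$n_cases, nrow(pc))
  expect_equal(gl$success_rate, 1.0)

  dir <- withr::local_tempdir()
  write_benchmark(bm, dir)
  expect_true(all(file.exists(file.path(dir, c("per_case.tsv", "summary.json",
                                               "per_length.csv")))))
  summ <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(summ$success_rate, 1.0)
})

test_that("autoplot methods return ggplot objects", {
  recs <- fix_pair_set()
  bm <- run_benchmark(recs[1:2], leave_one_out = TRUE, n_models = 2, seed = 5,
                      max_steps = 40)
  expect_s3_class(autoplot(bm), "ggplot")
  tr <- fix_single()
  target <- tr$complex
  job <- modelling_job(chain_sequence(target, "M"), chain_sequence(target, "N"),
                       target$peptide_seq, tr$core, tr, n_models = 2, seed = 2)
  ens <- generate_ensemble(job, derive_restraints(tr, job$correspondence),
                           max_steps = 30)
  expect_s3_class(autoplot(ens), "ggplot")
})
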