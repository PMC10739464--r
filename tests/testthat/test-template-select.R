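# Core-anchored peptide alignment and identity-based template ranking.

pam30 <- substitution_matrix("PAM30")

pam_sum <- function(a, b) {
  sum(substitution_score(pam30, strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
}

test_that("core-anchored alignment pairs cores column-to-column", {
  pep <- "WRTYARQMVHHKLMN"
  core <- binding_core(3, 15)
  al <- align_peptide_to_template(pep, core, pep, core)
  expect_identical(al$offset_map, 1:15)
  expect_identical(al$score, as.integer(pam_sum(pep, pep)))

  # two bare 9-mer cores: score is the sum of 9 pairwise PAM30 lookups
  a <- "WRTYARQMV"
  b <- "YKTWARNLV"
  al2 <- align_peptide_to_template(a, binding_core(0, 9), b, binding_core(0, 9))
  expect_identical(al2$score, as.integer(pam_sum(a, b)))
})

test_that("length differences become terminal gaps around the core", {
  # target N-flank 5 residues, template N-flank 2: three unpaired target
  # positions at the N terminus
  target <- "AAAAAWRTYARQMV"   # 5 + 9
  tmpl <- "CCWRTYARQMVDD"      # 2 + 9 + 2
  al <- align_peptide_to_template(target, binding_core(5, 14),
                                  tmpl, binding_core(2, 13))
  expect_identical(sum(is.na(al$offset_map)), 3L)
  expect_identical(which(is.na(al$offset_map)), 1:3)
  # core maps column-to-column
  expect_identical(al$offset_map[6:14], 3:11)

  # residues aligned only to gap columns leave the score unchanged
  base <- align_peptide_to_template("WRTYARQMV", binding_core(0, 9),
                                    tmpl, binding_core(2, 13))
  longer <- align_peptide_to_template("WRTYARQMV", binding_core(0, 9),
                                      paste0(tmpl, "EEEE"), binding_core(2, 17))
  expect_identical(longer$score, base$score)

  expect_error(align_peptide_to_template("WRTYARQM", binding_core(0, 9),
                                         tmpl, binding_core(2, 13)),
               class = "pmhc_core_error")
})

test_that("ranking keys: identity first, then peptide score, then id", {
  recs <- fix_plain_set()
  target <- recs[[1]]$complex
  a_seq <- chain_sequence(target, "M")
  b_seq <- chain_sequence(target, "N")
  core <- recs[[1]]$core

  rk <- rank_templates(a_seq, b_seq, target$peptide_seq, core, recs)
  expect_s3_class(rk, "pmhc_ranking")
  expect_identical(rk$template_id[1], recs[[1]]$id)  # itself: 100% identity
  expect_true(all(diff(rk$combined_identity) <= 1e-9))

  # singleton set
  rk1 <- rank_templates(a_seq, b_seq, target$peptide_seq, core, recs[1])
  expect_identical(nrow(rk1), 1L)

  # deterministic: repeated calls identical
  rk2 <- rank_templates(a_seq, b_seq, target$peptide_seq, core, recs)
  expect_identical(rk, rk2)

  # removing the top template promotes the previous second entry
  rk3 <- rank_templates(a_seq, b_seq, target$peptide_seq, core, recs,
                        exclude_ids = rk$template_id[1])
  expect_identical(rk3$template_id[1], rk$template_id[2])

  expect_error(rank_templates(a_seq, b_seq, target$peptide_seq, core, list()),
               class = "pmhc_selection_error")
})

test_that("higher combined identity beats any peptide score", {
  # engineer three fixtures sharing geometry but with controlled chain
  # identities and peptide scores
  L <- 13L
  n_chain <- 60L + L + 4L
  base_a <- paste(rep(c("A", "R", "N", "D"), length.out = n_chain), collapse = "")
  base_b <- paste(rep(c("E", "Q", "H", "K"), length.out = n_chain), collapse = "")
  mut <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    ch[seq_len(n)] <- "W"
    paste(ch, collapse = "")
  }
  pep_hi <- "LKWYARQMVHKLM"
  pep_lo <- "AAAAAAAAAAAAA"
  mk <- function(id, aseq, bseq, pep) {
    template_record(make_toy_pmhc2(fixture_spec(
      pep, core_start = 2, seed = 3, alpha_seq = aseq, beta_seq = bseq,
      pdb_id = id)), core_start = 2)
  }
  t_close <- mk("tclose", mut(base_a, 4), mut(base_b, 4), pep_lo)
  t_far <- mk("tfar", mut(base_a, 20), mut(base_b, 20), pep_hi)
  rk <- rank_templates(base_a, base_b, pep_hi, binding_core(2, L),
                       list(t_far, t_close))
  expect_identical(rk$template_id, c("tclose", "tfar"))
  expect_gt(rk$peptide_score[2], rk$peptide_score[1])

  # equal identity: peptide score decides (31-ish vs low), via the
  # direct-summation oracle
  t_same_hi <- mk("same_hi", mut(base_a, 4), mut(base_b, 4), pep_hi)
  rk2 <- rank_templates(base_a, base_b, pep_hi, binding_core(2, L),
                        list(t_close, t_same_hi))
  expect_identical(rk2$template_id[1], "same_hi")
  expect_identical(rk2$peptide_score[1], as.integer(pam_sum(pep_hi, pep_hi)))
  expect_identical(rk2$peptide_score[2], as.integer(pam_sum(pep_hi, pep_lo)))
})

test_that("select_template returns the ranking head and supports exclusion", {
  recs <- fix_plain_set()
  target <- recs[[2]]$complex
  sel <- select_template(chain_sequence(target, "M"),
                         chain_sequence(target, "N"),
                         target$peptide_seq, recs[[2]]$core, recs)
  expect_identical(sel$id, recs[[2]]$id)
  rk <- attr(sel, "ranking")
  expect_s3_class(rk, "pmhc_ranking")

  sel2 <- select_template(chain_sequence(target, "M"),
                          chain_sequence(target, "N"),
                          target$peptide_seq, recs[[2]]$core, recs,
                          exclude_ids = recs[[2]]$id)
  expect_identical(sel2$id, rk$template_id[2])

  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranking_tsv(rk, path)
  tab <- read.table(path, sep = "\t", header = TRUE)
  expect_identical(nrow(tab), nrow(rk))
  expect_true(tab$selected[1])
})
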