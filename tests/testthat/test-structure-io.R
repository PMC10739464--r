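# Reading, standardization, filtering and writing of pMHC structures.

test_that("write/read round-trip preserves coordinates and chain content", {
  tr <- fix_single()
  cx <- tr$complex
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(cx, path)
  raw <- read_structure(path, fmt = "pdb")
  back <- standardize_chains(raw, mhc_class = "II", pdb_id = cx$pdb_id)

  expect_identical(sort(unique(back$atoms$chain)), c("M", "N", "P"))
  expect_equal(nrow(back$atoms), nrow(cx$atoms))
  expect_identical(back$peptide_seq, cx$peptide_seq)
  a <- cx$atoms[order(cx$atoms$chain, cx$atoms$resno, cx$atoms$atom), ]
  b <- back$atoms[order(back$atoms$chain, back$atoms$resno, back$atoms$atom), ]
  expect_equal(as.matrix(b[, c("x", "y", "z")]),
               as.matrix(a[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("standardize_chains renames by chain length and is idempotent", {
  tr <- fix_single()
  atoms <- tr$complex$atoms
  relabeled <- atoms
  relabeled$chain <- c(M = "A", N = "B", P = "C")[relabeled$chain]
  std <- standardize_chains(relabeled, mhc_class = "II", pdb_id = "x")
  expect_identical(sort(unique(std$atoms$chain)), c("M", "N", "P"))
  # alpha chain (first long chain in file order) becomes M
  expect_identical(chain_sequence(std, "M"), chain_sequence(tr$complex, "M"))

  # already-standard input is unchanged
  again <- standardize_chains(std$atoms, mhc_class = "II", pdb_id = "x")
  expect_identical(again$atoms$chain, std$atoms$chain)
  expect_identical(again$peptide_seq, std$peptide_seq)
  expect_equal(again$atoms$x, std$atoms$x)
})

test_that("peptide renumbering is contiguous and order/sequence preserving", {
  tr <- fix_single()
  atoms <- tr$complex$atoms
  shifted <- atoms
  pep <- shifted$chain == "P"
  shifted$resno[pep] <- shifted$resno[pep] + 500L  # arbitrary author numbering
  std <- standardize_chains(shifted, mhc_class = "II", pdb_id = "x")
  L <- nchar(tr$complex$peptide_seq)
  expect_identical(sort(unique(std$atoms$resno[std$atoms$chain == "P"])),
                   seq_len(L))
  expect_identical(std$peptide_seq, tr$complex$peptide_seq)
})

test_that("class I standardization names beta2m as B and write can drop it", {
  raw <- fix_class1_raw()
  std <- standardize_chains(raw, mhc_class = "I", pdb_id = "c1")
  expect_identical(sort(unique(std$atoms$chain)), c("B", "M", "P"))
  expect_identical(nchar(std$peptide_seq), 9L)

  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(std, path, keep_b2m = FALSE)
  back <- read_structure(path)
  expect_false("B" %in% unique(back$atoms$chain))

  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(std, path2, keep_b2m = TRUE)
  expect_true("B" %in% unique(read_structure(path2)$atoms$chain))
})

test_that("ambiguous chain sets raise a standardization error", {
  raw <- fix_class1_raw()
  two_short <- dplyr::bind_rows(
    raw[raw$chain == "H", ],
    dplyr::mutate(raw[raw$chain == "C", ], chain = "D"),
    raw[raw$chain == "C", ])
  expect_error(standardize_chains(two_short, mhc_class = "II"),
               class = "pmhc_standardize_error")
})

test_that("altloc records collapse to the highest-occupancy variant", {
  pdb_line <- function(serial, name, alt, x, occ, elem) {
    sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, name, alt, "ALA", "A", 1L, x, 0, 0, occ, 10, elem)
  }
  lines <- c(pdb_line(1L, " N", "A", 0.0, 0.40, "N"),
             pdb_line(2L, " N", "B", 1.0, 0.60, "N"),
             pdb_line(3L, " CA", " ", 1.458, 1.00, "C"),
             "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  raw <- read_structure(path)
  n_atoms <- raw$atoms[raw$atoms$atom == "N", ]
  expect_identical(nrow(n_atoms), 1L)
  expect_equal(n_atoms$x, 1.0)  # occupancy 0.60 variant wins
})

test_that("modified residues map to their parent; unknown ones are typed errors", {
  tr <- fix_single()
  atoms <- tr$complex$atoms
  pep1 <- atoms$chain == "P" & atoms$resno == 1L
  atoms$resname[pep1] <- "MSE"
  std <- standardize_chains(atoms, mhc_class = "II", pdb_id = "x")
  expect_identical(substr(std$peptide_seq, 1, 1), "M")
  expect_identical(unique(std$atoms$resname[std$atoms$chain == "P" &
                                              std$atoms$resno == 1L]), "MET")

  atoms$resname[pep1] <- "ZZZ"
  expect_error(standardize_chains(atoms, mhc_class = "II", pdb_id = "x"),
               class = "pmhc_noncanonical_error")
})

test_that("mmCIF atom-site records parse into the same raw atom table", {
  lines <- c(
    "data_test",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 0.000 0.000 0.000 1.00 10.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 1.458 0.000 0.000 1.00 10.00 ? 1 ALA A CA 1",
    "#")
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(lines, path)
  raw <- read_structure(path)            # fmt = auto, by extension
  expect_identical(nrow(raw$atoms), 2L)
  expect_identical(raw$atoms$atom, c("N", "CA"))
  expect_equal(raw$atoms$x, c(0, 1.458))
  raw2 <- read_structure(path, fmt = "mmcif")
  expect_identical(raw$atoms, raw2$atoms)
})

test_that("missing and empty inputs raise typed I/O errors", {
  expect_error(read_structure(file.path(tempdir(), "no-such-file.pdb")),
               class = "pmhc_io_error")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1  O   HOH A   1       0.0     0.0     0.0  1.00 10.00           O",
               "END"), path)
  expect_error(read_structure(path), class = "pmhc_empty_structure_error")
})

test_that("filter partitions candidates and rejects with machine-readable reasons", {
  tr <- fix_single()
  base <- tr$complex

  trim_peptide <- function(cx, L, id) {
    at <- cx$atoms[!(cx$atoms$chain == "P" & cx$atoms$resno > L), ]
    out <- pmhc2model:::new_pmhc_complex(id, "II", at,
                                         peptide_seq = substr(cx$peptide_seq, 1, L))
    out
  }
  short6 <- trim_peptide(base, 6L, "len6")
  ok <- base

  clip <- make_toy_pmhc2(fixture_spec("PVSKMRMATPLLMQA", core_start = 3,
                                      seed = 5, pdb_id = "clip"))
  sig <- dm_signature_set()[1]
  n_chain <- 60L + 13L + 4L
  aseq <- paste0(sig, paste(rep("A", n_chain - nchar(sig)), collapse = ""))
  dm <- make_toy_pmhc2(fixture_spec("KLMNKLMNKVWHR", core_start = 2, seed = 6,
                                    alpha_seq = aseq, pdb_id = "dm"))

  flt <- filter_template_candidates(list(short6, ok, clip, dm))
  expect_identical(length(flt$kept) + nrow(flt$rejected), 4L)
  expect_identical(purrr::map_chr(flt$kept, "id"), base$pdb_id)
  expect_identical(flt$rejected$reason[flt$rejected$id == "len6"],
                   "peptide_length")
  expect_identical(flt$rejected$reason[flt$rejected$id == "clip"],
                   "clip_peptide")
  expect_identical(flt$rejected$reason[flt$rejected$id == "dm"],
                   "dm_chaperone")
})

test_that("template database round-trips through disk", {
  recs <- fix_plain_set()[1:2]
  dir <- withr::local_tempdir()
  build_template_db(recs, dir)
  expect_true(file.exists(file.path(dir, "index.json")))
  back <- read_template_db(dir)
  expect_identical(length(back), 2L)
  expect_identical(purrr::map_chr(back, "id"), purrr::map_chr(recs, "id"))
  expect_identical(back[[1]]$core$start, recs[[1]]$core$start)
  expect_identical(back[[1]]$complex$peptide_seq, recs[[1]]$complex$peptide_seq)
})
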