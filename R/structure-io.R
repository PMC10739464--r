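# Reading, standardizing, filtering and writing pMHC structures.
#
# Conventions for standardized complexes: MHC class II has the alpha chain as
# "M", the beta chain as "N" and the peptide as "P"; class I has the heavy
# chain as "M", beta2-microglobulin as "B" (optional) and the peptide as "P".
# The peptide is renumbered contiguously 1..L.

ATOM_COLS <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")

new_pmhc_complex <- function(pdb_id, mhc_class, atoms, alpha_allele = "",
                             beta_allele = "", peptide_seq = "",
                             resolution = NA_real_) {
  atoms <- as_tibble(atoms[, ATOM_COLS])
  for (col in c("x", "y", "z")) atoms[[col]] <- unname(atoms[[col]])
  structure(
    list(pdb_id = pdb_id, mhc_class = mhc_class, atoms = atoms,
         alpha_allele = alpha_allele, beta_allele = beta_allele,
         peptide_seq = peptide_seq, resolution = resolution),
    class = "pmhc_complex")
}

#' @export
print.pmhc_complex <- function(x, ...) {
  ch <- table(unique(x$atoms[, c("chain", "resno")])$chain)
  cat(sprintf("<pmhc_complex> %s (class %s)\n", x$pdb_id, x$mhc_class))
  cat(sprintf("  chains: %s\n",
              paste(sprintf("%s (%d res)", names(ch), as.integer(ch)),
                    collapse = ", ")))
  cat(sprintf("  peptide: %s\n", x$peptide_seq))
  if (nzchar(x$alpha_allele) || nzchar(x$beta_allele)) {
    cat(sprintf("  alleles: %s / %s\n", x$alpha_allele, x$beta_allele))
  }
  invisible(x)
}

validate_pmhc_complex <- function(x) {
  stopifnot(inherits(x, "pmhc_complex"))
  chains <- unique(x$atoms$chain)
  need <- if (x$mhc_class == "II") c("M", "N", "P") else c("M", "P")
  if (!all(need %in% chains)) {
    abort_pmhc(sprintf("class %s complex must have chains %s (found %s)",
                       x$mhc_class, paste(need, collapse = ","),
                       paste(chains, collapse = ",")),
               "pmhc_validation_error")
  }
  pep <- x$atoms[x$atoms$chain == "P", ]
  resno <- unique(pep$resno)
  if (!identical(as.integer(resno), seq_along(resno))) {
    abort_pmhc("peptide residues must be numbered contiguously 1..L",
               "pmhc_validation_error")
  }
  if (nchar(x$peptide_seq) != length(resno)) {
    abort_pmhc("peptide_seq length disagrees with chain P residue count",
               "pmhc_validation_error")
  }
  if (!all(is.finite(c(x$atoms$x, x$atoms$y, x$atoms$z)))) {
    abort_pmhc("non-finite atom coordinates", "pmhc_validation_error")
  }
  invisible(x)
}

#' One-letter sequence of a chain
#'
#' @param x A `pmhc_complex`.
#' @param chain Chain identifier (e.g. `"M"`, `"N"`, `"P"`).
#' @return A single string; modified residues are mapped to their parent.
#' @export
chain_sequence <- function(x, chain) {
  a <- x$atoms[x$atoms$chain == chain, ]
  if (nrow(a) == 0L) {
    abort_pmhc(sprintf("no chain '%s' in complex %s", chain, x$pdb_id),
               "pmhc_validation_error")
  }
  res <- a[!duplicated(a$resno), ]
  paste(resname_to_one(res$resname), collapse = "")
}

#' Read a pMHC structure file
#'
#' Parses a PDB or mmCIF file into a raw atom table. Alternate locations are
#' collapsed to the highest-occupancy variant (ties broken by altloc label
#' order); hydrogen/deuterium atoms and water are dropped; HETATM records are
#' kept only for modified residues with a known parent amino acid.
#'
#' @param path Path to the structure file.
#' @param fmt `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return An object of class `pmhc_raw`: a list with `path` and an atom
#'   tibble (`chain`, `resno`, `resname`, `atom`, `element`, `x`, `y`, `z`).
#' @export
read_structure <- function(path, fmt = c("auto", "pdb", "mmcif")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) {
    abort_pmhc(sprintf("file not found: %s", path), "pmhc_io_error")
  }
  if (fmt == "auto") {
    fmt <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (fmt == "pdb") bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
      else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) {
      abort_pmhc(sprintf("failed to parse %s as %s: %s",
                         path, fmt, conditionMessage(e)),
                 "pmhc_parse_error")
    })
  at <- parsed$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem))) {
    elem <- sub("^([A-Za-z]).*$", "\\1", at$elety)
  }
  elem <- toupper(ifelse(is.na(elem) | elem == "", substr(at$elety, 1, 1), elem))
  keep <- !(elem %in% c("H", "D")) & !(at$resid %in% c("HOH", "DOD", "WAT"))
  keep <- keep & (at$type == "ATOM" |
                  (at$type == "HETATM" & at$resid %in% names(NONCANONICAL_MAP)))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(at) == 0L) {
    abort_pmhc(sprintf("no protein atoms in %s", path), "pmhc_empty_structure_error")
  }
  alt <- ifelse(is.na(at$alt) | at$alt %in% c("", " "), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  atoms <- tibble(
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resno = as.integer(at$resno),
    resname = at$resid,
    atom = at$elety,
    element = elem,
    x = at$x, y = at$y, z = at$z,
    .occ = occ, .alt = alt, .row = seq_len(nrow(at)))
  # collapse altlocs: highest occupancy, ties by altloc label order
  atoms <- atoms[order(atoms$chain, atoms$resno, atoms$atom,
                       -atoms$.occ, atoms$.alt), ]
  atoms <- atoms[!duplicated(atoms[, c("chain", "resno", "atom")]), ]
  atoms <- atoms[order(atoms$.row), setdiff(names(atoms), c(".occ", ".alt", ".row"))]
  structure(list(path = path, atoms = atoms), class = "pmhc_raw")
}

chain_res_counts <- function(atoms) {
  res <- unique(atoms[, c("chain", "resno")])
  counts <- table(res$chain)
  # preserve file order of chains
  counts[match(unique(atoms$chain), names(counts))]
}

#' Standardize chain naming of a pMHC structure
#'
#' Renames chains to the M/N/P (class II) or M/B/P (class I) convention,
#' maps modified residues to their parent amino acid, renumbers the peptide
#' contiguously from 1, and extracts the peptide sequence. For class II the
#' two chains of MHC-domain length (>= 70 residues) become M (alpha, first in
#' file order) and N (beta); the single short chain (<= 30 residues) becomes
#' the peptide P. Input already using the standard names is left unchanged.
#'
#' @param raw A `pmhc_raw` from [read_structure()] or an atom tibble.
#' @param mhc_class `"II"` or `"I"`.
#' @param pdb_id,alpha_allele,beta_allele,resolution Metadata carried on the
#'   returned complex.
#' @return A `pmhc_complex`.
#' @export
standardize_chains <- function(raw, mhc_class = c("II", "I"), pdb_id = NULL,
                               alpha_allele = "", beta_allele = "",
                               resolution = NA_real_) {
  mhc_class <- match.arg(mhc_class)
  atoms <- if (inherits(raw, "pmhc_raw")) raw$atoms else as_tibble(raw)
  if (is.null(pdb_id)) {
    pdb_id <- if (inherits(raw, "pmhc_raw")) {
      sub("\\.(pdb|cif|mmcif)$", "", basename(raw$path), ignore.case = TRUE)
    } else "complex"
  }
  counts <- chain_res_counts(atoms)
  ids <- names(counts)
  n <- as.integer(counts)

  std <- if (mhc_class == "II") c("M", "N", "P") else NULL
  if (mhc_class == "II" && setequal(ids, c("M", "N", "P"))) {
    mapping <- c(M = "M", N = "N", P = "P")
  } else if (mhc_class == "I" &&
             (setequal(ids, c("M", "B", "P")) || setequal(ids, c("M", "P")))) {
    mapping <- setNames(ids, ids)
  } else if (mhc_class == "II") {
    long <- ids[n >= 70]
    short <- ids[n <= 30]
    if (length(long) != 2L || length(short) != 1L ||
        length(ids) != 3L) {
      abort_pmhc(
        sprintf(paste0("cannot standardize class II chains: need two MHC-length",
                       " chains (>=70 res) and one peptide (<=30 res); found: %s"),
                paste(sprintf("%s=%d", ids, n), collapse = ", ")),
        "pmhc_standardize_error")
    }
    mapping <- setNames(c("M", "N", "P"), c(long, short))
  } else {
    heavy <- ids[which.max(n)]
    short <- ids[n <= 30]
    mid <- setdiff(ids[n > 30], heavy)
    if (length(short) != 1L || length(mid) > 1L) {
      abort_pmhc(
        sprintf("cannot standardize class I chains; found: %s",
                paste(sprintf("%s=%d", ids, n), collapse = ", ")),
        "pmhc_standardize_error")
    }
    mapping <- setNames(c("M", if (length(mid)) "B", "P"),
                        c(heavy, if (length(mid)) mid, short))
  }

  atoms$chain <- unname(mapping[atoms$chain])
  atoms <- atoms[order(match(atoms$chain, c("M", "N", "B", "P"))), ]
  atoms$resname <- map_noncanonical_resnames(atoms$resname)

  # renumber the peptide 1..L preserving residue order
  pep <- atoms$chain == "P"
  old <- atoms$resno[pep]
  atoms$resno[pep] <- as.integer(match(old, unique(old)))
  pep_res <- atoms[pep, ]
  pep_res <- pep_res[!duplicated(pep_res$resno), ]
  peptide_seq <- paste(resname_to_one(pep_res$resname), collapse = "")

  out <- new_pmhc_complex(pdb_id, mhc_class, atoms,
                          alpha_allele = alpha_allele,
                          beta_allele = beta_allele,
                          peptide_seq = peptide_seq,
                          resolution = resolution)
  validate_pmhc_complex(out)
  out
}

#' Packaged CLIP peptide sequences
#'
#' The class-II-associated invariant-chain peptide (CLIP) occupies the groove
#' as a placeholder; complexes presenting it are excluded from template sets.
#' Detection is by exact substring match of the peptide sequence against this
#' list (the canonical human CLIP core and the longer CLIP 87-101 peptide).
#' @return Character vector of CLIP sequences.
#' @export
clip_peptide_set <- function() {
  c("MRMATPLLM", "PVSKMRMATPLLMQA")
}

#' Packaged DM-chaperone chain signatures (synthetic defaults)
#'
#' HLA-DM alters the MHC-II groove conformation; complexes containing a DM
#' chain are excluded from template sets. Detection is by exact substring
#' match of each chain sequence against this signature list. The shipped
#' defaults are synthetic marker sequences (not curated HLA-DM sequences);
#' supply your own curated signatures via the `dm_signatures` argument of
#' [filter_template_candidates()] for production template sets.
#' @return Character vector of signature substrings.
#' @export
dm_signature_set <- function() {
  c("HDWMFCQWDPLMG", "YEWKQFDHPMCGW")
}

#' Filter template candidates by the template-set curation rules
#'
#' Keeps standardized complexes with peptide length between 7 and 25
#' (inclusive), no DM-chaperone chain signature, and a non-CLIP peptide.
#' Filtering never raises: every rejected candidate carries a reason code
#' (`"peptide_length"`, `"dm_chaperone"` or `"clip_peptide"`).
#'
#' @param candidates A list of `pmhc_complex` objects.
#' @param clip_peptides,dm_signatures Sequence lists used for detection.
#' @param core_starts Optional named integer vector of known 0-based core
#'   starts (by pdb_id); cores of other kept candidates are derived from
#'   their anchor contacts.
#' @param source_paths Optional named character vector of source files.
#' @return A list with `kept` (list of `template_record`) and `rejected`
#'   (tibble with `id`, `reason`).
#' @export
filter_template_candidates <- function(candidates,
                                       clip_peptides = clip_peptide_set(),
                                       dm_signatures = dm_signature_set(),
                                       core_starts = NULL,
                                       source_paths = NULL) {
  if (inherits(candidates, "pmhc_complex")) candidates <- list(candidates)
  kept <- list()
  rejected <- list()
  for (cx in candidates) {
    id <- cx$pdb_id
    len <- nchar(cx$peptide_seq)
    reason <- NULL
    if (len < 7 || len > 25) {
      reason <- "peptide_length"
    } else {
      chains <- setdiff(unique(cx$atoms$chain), "P")
      seqs <- vapply(chains, function(ch) chain_sequence(cx, ch), character(1))
      has_dm <- any(vapply(dm_signatures, function(sig) {
        any(grepl(sig, seqs, fixed = TRUE))
      }, logical(1)))
      if (has_dm) {
        reason <- "dm_chaperone"
      } else if (any(vapply(clip_peptides, function(cp) {
        grepl(cp, cx$peptide_seq, fixed = TRUE) || grepl(cx$peptide_seq, cp, fixed = TRUE)
      }, logical(1)))) {
        reason <- "clip_peptide"
      }
    }
    if (is.null(reason)) {
      cs <- if (!is.null(core_starts) && id %in% names(core_starts)) {
        core_starts[[id]]
      } else NULL
      sp <- if (!is.null(source_paths) && id %in% names(source_paths)) {
        source_paths[[id]]
      } else NA_character_
      kept[[length(kept) + 1L]] <- template_record(cx, core_start = cs,
                                                   source_path = sp)
    } else {
      rejected[[length(rejected) + 1L]] <- tibble(id = id, reason = reason)
    }
  }
  list(kept = kept,
       rejected = if (length(rejected)) bind_rows(rejected)
                  else tibble(id = character(), reason = character()))
}

#' Create a template record
#'
#' Bundles a standardized complex with its structural binding core (derived
#' from anchor contacts in the structure when not supplied) and provenance.
#'
#' @param complex A validated `pmhc_complex`.
#' @param core_start 0-based core offset within the peptide; derived with
#'   [derive_structural_core()] when `NULL`.
#' @param source_path Optional source file path.
#' @return An object of class `template_record`.
#' @export
template_record <- function(complex, core_start = NULL, source_path = NA_character_) {
  validate_pmhc_complex(complex)
  core <- if (nchar(complex$peptide_seq) < 9L) {
    # peptides shorter than the 9-mer core carry no structural core and are
    # never used as modelling templates (but remain in the curated set)
    NULL
  } else if (is.null(core_start)) {
    derive_structural_core(complex)
  } else {
    binding_core(core_start, nchar(complex$peptide_seq))
  }
  structure(list(id = complex$pdb_id, complex = complex, core = core,
                 source_path = source_path),
            class = "template_record")
}

#' @export
print.template_record <- function(x, ...) {
  cat(sprintf("<template_record> %s  peptide %s  core start %s (0-based)\n",
              x$id, x$complex$peptide_seq,
              if (is.null(x$core)) "none" else x$core$start))
  invisible(x)
}

#' Write a standardized complex as a PDB file
#'
#' @param complex A `pmhc_complex`.
#' @param path Output file.
#' @param keep_b2m Keep the beta2-microglobulin chain "B" (class I only)?
#' @return `path`, invisibly.
#' @export
write_structure <- function(complex, path, keep_b2m = TRUE) {
  validate_pmhc_complex(complex)
  at <- complex$atoms
  if (!keep_b2m) at <- at[at$chain != "B", ]
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort_pmhc(sprintf("output directory does not exist: %s", dir),
               "pmhc_io_error")
  }
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  tryCatch(
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = at$resno, resid = at$resname,
                     chain = at$chain, elety = at$atom,
                     eleno = seq_len(nrow(at)),
                     o = rep(1, nrow(at)), b = rep(0, nrow(at)),
                     elesy = at$element),
    error = function(e) {
      abort_pmhc(sprintf("failed writing %s: %s", path, conditionMessage(e)),
                 "pmhc_io_error")
    })
  invisible(path)
}

#' Write a template database directory
#'
#' Stores standardized PDB files plus a JSON index (pdb_id, alleles, peptide
#' sequence, 0-based core start, resolution, file).
#'
#' @param records List of `template_record`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
build_template_db <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idx <- purrr::map(records, function(r) {
    file <- paste0(r$id, ".pdb")
    write_structure(r$complex, file.path(dir, file))
    list(pdb_id = r$id,
         alpha_allele = r$complex$alpha_allele,
         beta_allele = r$complex$beta_allele,
         peptide_seq = r$complex$peptide_seq,
         core_start = if (is.null(r$core)) NULL else r$core$start,
         resolution = r$complex$resolution,
         file = file)
  })
  jsonlite::write_json(idx, file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a template database directory
#'
#' @param dir Directory written by [build_template_db()].
#' @return List of `template_record`.
#' @export
read_template_db <- function(dir) {
  idx_path <- file.path(dir, "index.json")
  if (!file.exists(idx_path)) {
    abort_pmhc(sprintf("no index.json in %s", dir), "pmhc_io_error")
  }
  idx <- jsonlite::read_json(idx_path)
  purrr::map(idx, function(e) {
    raw <- read_structure(file.path(dir, e$file), fmt = "pdb")
    cx <- standardize_chains(raw, mhc_class = "II", pdb_id = e$pdb_id,
                             alpha_allele = e$alpha_allele %||% "",
                             beta_allele = e$beta_allele %||% "",
                             resolution = e$resolution %||% NA_real_)
    template_record(cx, core_start = e$core_start,
                    source_path = file.path(dir, e$file))
  })
}
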