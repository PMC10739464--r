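# The 9-mer binding core, its four anchor positions, core prediction, and
# anchor distance restraints derived from template contacts.
#
# MHC-II grooves hold a 9-residue core whose positions 1, 4, 6 and 9 (P1, P4,
# P6, P9) anchor into the main binding pockets; the spacing of the anchors
# within the core is therefore fixed at offsets (0, 3, 5, 8).

ANCHOR_OFFSETS <- c(0L, 3L, 5L, 8L)

#' Construct a binding core
#'
#' @param start 0-based offset of the 9-mer core within the peptide.
#' @param peptide_length Length of the peptide.
#' @return A `binding_core`: `start` (0-based), `anchors` (1-based peptide
#'   positions of P1, P4, P6, P9), `peptide_length`.
#' @export
binding_core <- function(start, peptide_length) {
  start <- as.integer(start)
  peptide_length <- as.integer(peptide_length)
  if (is.na(start) || start < 0L || start + 9L > peptide_length) {
    abort_pmhc(sprintf("core start %d does not fit a 9-mer inside a %d-mer peptide",
                       start, peptide_length),
               "pmhc_core_error")
  }
  structure(list(start = start,
                 anchors = start + ANCHOR_OFFSETS + 1L,
                 peptide_length = peptide_length),
            class = "binding_core")
}

#' @export
print.binding_core <- function(x, ...) {
  cat(sprintf("<binding_core> start %d (0-based), anchors %s (1-based), peptide length %d\n",
              x$start, paste(x$anchors, collapse = ","), x$peptide_length))
  invisible(x)
}

core_residues <- function(core) core$start + seq_len(9L)

#' Binding core from user-supplied anchor positions
#'
#' @param peptide Peptide sequence.
#' @param anchor_positions Four 1-based peptide positions with the canonical
#'   P1/P4/P6/P9 spacing (offsets 0, 3, 5, 8).
#' @return A `binding_core`.
#' @export
core_from_user_anchors <- function(peptide, anchor_positions) {
  check_aa_string(peptide, "peptide")
  a <- as.integer(anchor_positions)
  if (length(a) != 4L || any(is.na(a))) {
    abort_pmhc("anchor_positions must be four integer positions", "pmhc_anchor_error")
  }
  if (!identical(a - a[1], ANCHOR_OFFSETS)) {
    abort_pmhc(sprintf("anchor spacing must be (0,3,5,8); got offsets (%s)",
                       paste(a - a[1], collapse = ",")),
               "pmhc_anchor_error")
  }
  if (a[1] < 1L || a[4] > nchar(peptide)) {
    abort_pmhc("anchors fall outside the peptide", "pmhc_anchor_error")
  }
  binding_core(a[1] - 1L, nchar(peptide))
}

#' Default pocket preference profile for the fallback core predictor
#'
#' A transparent 20 x 9 position-weight table: core position 1 rewards the
#' large hydrophobics that occupy the deep P1 pocket; positions 4, 6 and 9
#' carry milder hydrophobic/small-polar preferences. This built-in profile
#' makes no claim of parity with trained binding-core predictors; it exists
#' so the pipeline runs without an external tool, and any predictor can be
#' plugged in instead (see [core_predictor_external()]).
#'
#' @return Numeric matrix, rows = residues, columns = core positions 1..9.
#' @export
default_pocket_profile <- function() {
  prof <- matrix(0, nrow = 20, ncol = 9, dimnames = list(AA1, NULL))
  big_hydro <- c(W = 5, F = 4, Y = 4, L = 3, I = 3, M = 3, V = 2)
  mid_hydro <- c(L = 2, I = 2, V = 2, M = 2, F = 1.5, Y = 1, A = 1)
  small_pol <- c(S = 1, T = 1, N = 1, Q = 1, A = 1, G = 0.5)
  prof[names(big_hydro), 1] <- big_hydro
  prof[names(mid_hydro), 4] <- mid_hydro
  prof[names(c(mid_hydro)), 6] <- mid_hydro * 0.7
  prof[names(small_pol), 6] <- prof[names(small_pol), 6] + small_pol * 0.5
  prof[names(mid_hydro), 9] <- mid_hydro
  prof
}

#' Built-in fallback binding-core predictor
#'
#' Scores every 9-mer window of the peptide against a positional preference
#' profile and returns the best-scoring window (ties resolved toward the
#' smallest start).
#'
#' @param peptide Peptide sequence (length >= 9).
#' @param pocket_profile 20 x 9 score table (rows named by residue letter).
#' @return A `binding_core`.
#' @export
predict_core_fallback <- function(peptide, pocket_profile = default_pocket_profile()) {
  check_aa_string(peptide, "peptide")
  L <- nchar(peptide)
  if (L < 9L) {
    abort_pmhc(sprintf("peptide of length %d is too short for a 9-mer core", L),
               "pmhc_length_error")
  }
  chars <- seq_to_chars(peptide)
  scores <- vapply(0:(L - 9L), function(s) {
    win <- chars[s + seq_len(9L)]
    ridx <- match(win, rownames(pocket_profile))
    keep <- !is.na(ridx)
    sum(pocket_profile[cbind(ridx[keep], seq_len(9L)[keep])])
  }, numeric(1))
  binding_core(which.max(scores) - 1L, L)
}

#' Wrap an external binding-core predictor executable
#'
#' Subprocess contract: the command is invoked with three arguments --
#' peptide sequence, alpha allele name, beta allele name -- and must print a
#' single integer, the 0-based core start, on stdout.
#'
#' @param command Path to the executable.
#' @return A predictor function `(peptide, alpha_allele, beta_allele) ->
#'   binding_core` usable wherever a core predictor is accepted.
#' @export
core_predictor_external <- function(command) {
  force(command)
  function(peptide, alpha_allele = "", beta_allele = "") {
    out <- tryCatch(
      system2(command, args = shQuote(c(peptide, alpha_allele, beta_allele)),
              stdout = TRUE, stderr = FALSE),
      error = function(e) {
        abort_pmhc(sprintf("external core predictor failed: %s",
                           conditionMessage(e)),
                   "pmhc_predictor_error")
      })
    start <- suppressWarnings(as.integer(trimws(out[length(out)])))
    if (is.na(start)) {
      abort_pmhc("external core predictor did not print an integer core start",
                 "pmhc_predictor_error")
    }
    binding_core(start, nchar(peptide))
  }
}

# Backbone-and-side-chain heavy atoms of one peptide residue.
peptide_residue_atoms <- function(complex, resno) {
  a <- complex$atoms
  a[a$chain == "P" & a$resno == resno, ]
}

receptor_atoms <- function(complex) {
  a <- complex$atoms
  a[a$chain %in% c("M", "N"), ]
}

#' Derive the structural binding core from anchor contacts
#'
#' Scans every 9-mer window of the peptide and scores it by how many of its
#' four anchor positions have at least one receptor heavy atom within
#' `cutoff` (total anchor-contact count breaks ties; remaining ties resolve
#' to the smallest start). Used when building template sets, where the core
#' is observed in the structure rather than predicted.
#'
#' @param complex A class II `pmhc_complex`.
#' @param cutoff Contact distance in Angstrom.
#' @return A `binding_core`.
#' @export
derive_structural_core <- function(complex, cutoff = 5.0) {
  validate_pmhc_complex(complex)
  L <- nchar(complex$peptide_seq)
  if (L < 9L) {
    abort_pmhc("peptide too short to hold a 9-mer core", "pmhc_length_error")
  }
  rec <- as.matrix(receptor_atoms(complex)[, c("x", "y", "z")])
  contacts <- vapply(seq_len(L), function(r) {
    pa <- as.matrix(peptide_residue_atoms(complex, r)[, c("x", "y", "z")])
    if (nrow(pa) == 0L) return(0L)
    d2 <- outer(rowSums(pa^2), rowSums(rec^2), "+") - 2 * pa %*% t(rec)
    sum(d2 <= cutoff^2)
  }, integer(1))
  starts <- 0:(L - 9L)
  key <- vapply(starts, function(s) {
    anch <- s + ANCHOR_OFFSETS + 1L
    sum(contacts[anch] > 0L) * 1e6 + sum(contacts[anch])
  }, numeric(1))
  binding_core(starts[which.max(key)], L)
}

#' Derive anchor distance restraints from a template
#'
#' For each of the four anchor residues of the template's structural core,
#' every (anchor heavy atom, receptor heavy atom) pair closer than
#' `contact_cutoff` becomes a harmonic distance restraint whose target is the
#' observed template distance. Restraints are re-indexed to the target
#' peptide numbering through the core-anchored alignment; anchors that align
#' to a gap, or have no contact under the cutoff, are dropped with a warning.
#'
#' @param template A `template_record`.
#' @param correspondence A `pmhc_core_alignment` mapping target peptide
#'   positions to template positions, or `NULL` for identity (self-modelling).
#' @param contact_cutoff Heavy-atom contact distance in Angstrom.
#' @param sd Restraint standard deviation in Angstrom (0 = rigid).
#' @return A tibble of class `pmhc_restraints`: `chain_a`, `res_a`, `atom_a`
#'   (peptide side, target numbering), `chain_b`, `res_b`, `atom_b`
#'   (receptor side), `target`, `sd`.
#' @export
derive_restraints <- function(template, correspondence = NULL,
                              contact_cutoff = 5.0, sd = 0) {
  stopifnot(inherits(template, "template_record"))
  if (contact_cutoff <= 0) {
    abort_pmhc("contact_cutoff must be positive", "pmhc_precondition_error")
  }
  cx <- template$complex
  core <- template$core
  rec <- receptor_atoms(cx)
  rec_xyz <- as.matrix(rec[, c("x", "y", "z")])
  anchors_tmpl <- core$anchors
  rows <- list()
  n_contact_free <- 0L
  for (ar in anchors_tmpl) {
    pa <- peptide_residue_atoms(cx, ar)
    pa_xyz <- as.matrix(pa[, c("x", "y", "z")])
    d2 <- outer(rowSums(pa_xyz^2), rowSums(rec_xyz^2), "+") -
      2 * pa_xyz %*% t(rec_xyz)
    d2[d2 < 0] <- 0
    hit <- which(d2 <= contact_cutoff^2, arr.ind = TRUE)
    if (nrow(hit) == 0L) {
      n_contact_free <- n_contact_free + 1L
      warn(sprintf("template anchor residue %d has no receptor contact within %.2f A",
                   ar, contact_cutoff),
           class = "pmhc_anchor_contact_warning")
      next
    }
    res_a <- if (is.null(correspondence)) {
      ar
    } else {
      m <- match(ar, correspondence$offset_map)
      if (is.na(m)) {
        warn(sprintf("template anchor residue %d aligns to a gap in the target; restraints dropped",
                     ar),
             class = "pmhc_anchor_gap_warning")
        next
      }
      m
    }
    rows[[length(rows) + 1L]] <- tibble(
      chain_a = "P", res_a = as.integer(res_a), atom_a = pa$atom[hit[, 1]],
      chain_b = rec$chain[hit[, 2]], res_b = rec$resno[hit[, 2]],
      atom_b = rec$atom[hit[, 2]],
      target = sqrt(d2[hit]), sd = sd)
  }
  if (n_contact_free == 4L) {
    abort_pmhc(sprintf("no anchor residue has receptor contacts within %.2f A",
                       contact_cutoff),
               "pmhc_restraint_error")
  }
  out <- if (length(rows)) bind_rows(rows) else {
    tibble(chain_a = character(), res_a = integer(), atom_a = character(),
           chain_b = character(), res_b = integer(), atom_b = character(),
           target = numeric(), sd = numeric())
  }
  class(out) <- c("pmhc_restraints", class(out))
  out
}

#' Write restraints as TSV
#'
#' @param restraints A `pmhc_restraints` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_restraints_tsv <- function(restraints, path) {
  write.table(as.data.frame(restraints), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read restraints from TSV
#'
#' @param path File written by [write_restraints_tsv()].
#' @return A `pmhc_restraints` tibble.
#' @export
read_restraints_tsv <- function(path) {
  out <- as_tibble(read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE))
  out$res_a <- as.integer(out$res_a)
  out$res_b <- as.integer(out$res_b)
  class(out) <- c("pmhc_restraints", class(out))
  out
}
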