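# Synthetic idealized pMHC-II fixtures with known ground-truth geometry.
#
# The generator emulates the class II groove architecture -- two alpha
# helices flanking a floor on which the peptide lies in an extended
# conformation -- as a geometric idealization, not a physical MHC fold: the
# helices are ideal poly-alpha helices, the "beta-sheet floor" is a flat
# synthetic strand under the peptide axis, and anchor side chains are CB
# atoms oriented toward the floor so every anchor residue has a receptor
# heavy atom within 5 A. Sequence content is caller-chosen, so sequence-
# identity and PAM30-score relationships between fixtures can be engineered
# exactly.

FIXTURE_GEOM <- list(
  z_helix = 0.5,      # helix axis height
  x_helix = -8,       # helix start along the groove axis
  z_floor = -5.1,     # flat floor plane
  y_floor = 0.6,      # lateral offset of the per-chain floor strands
  floor_pad = 2L      # extra floor residues beyond each peptide terminus
)

#' Specify a synthetic pMHC-II fixture
#'
#' @param peptide_seq Peptide sequence, 7-25 residues; anchor positions must
#'   not be glycine (their CB is the groove-ward contact atom).
#' @param core_start 0-based core offset (required for peptides >= 9
#'   residues; `NULL` for shorter peptides, which carry no core).
#' @param groove_width Distance between the two helix axes, Angstrom.
#' @param helix_length Residues per receptor helix.
#' @param seed Seed for the sequence draws (MHC chains, when not supplied).
#' @param alpha_seq,beta_seq Optional receptor chain sequences; random
#'   sequences of the right length are drawn when `NULL`.
#' @param alpha_allele,beta_allele Allele labels carried as metadata.
#' @param pdb_id Identifier for the fixture.
#' @param resolution Nominal resolution metadata, Angstrom.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(peptide_seq, core_start = NULL, groove_width = 18,
                         helix_length = 60, seed = 1,
                         alpha_seq = NULL, beta_seq = NULL,
                         alpha_allele = "SYNA*01:01",
                         beta_allele = "SYNB*01:01",
                         pdb_id = "fixture", resolution = 2.0) {
  check_aa_string(peptide_seq, "peptide_seq", allow_x = FALSE)
  L <- nchar(peptide_seq)
  if (L < 7L || L > 25L) {
    abort_pmhc(sprintf("fixture peptide length %d outside 7..25", L),
               "pmhc_fixture_error")
  }
  core <- NULL
  if (L >= 9L) {
    if (is.null(core_start)) {
      abort_pmhc("core_start is required for peptides of 9+ residues",
                 "pmhc_fixture_error")
    }
    core <- binding_core(core_start, L)
    anchor_res <- seq_to_chars(peptide_seq)[core$anchors]
    if (any(anchor_res == "G")) {
      abort_pmhc("anchor positions must not be glycine in synthetic fixtures",
                 "pmhc_fixture_error")
    }
  }
  structure(list(peptide_seq = peptide_seq, core = core,
                 groove_width = groove_width,
                 helix_length = as.integer(helix_length),
                 seed = as.integer(seed),
                 alpha_seq = alpha_seq, beta_seq = beta_seq,
                 alpha_allele = alpha_allele, beta_allele = beta_allele,
                 pdb_id = pdb_id, resolution = resolution),
            class = "fixture_spec")
}

random_aa_seq <- function(n, exclude = c("G", "X")) {
  paste(sample(setdiff(AA1, exclude), n, replace = TRUE), collapse = "")
}

segment_to_atoms <- function(seg, chain, resnames, resno_offset = 0L,
                             with_cb = FALSE) {
  rows <- purrr::imap(seg, function(res, i) {
    tb <- tibble(chain = chain, resno = as.integer(i + resno_offset),
                 resname = resnames[i],
                 atom = rownames(res),
                 element = substr(rownames(res), 1, 1),
                 x = res[, 1], y = res[, 2], z = res[, 3])
    if (with_cb && resnames[i] != "GLY") {
      cb <- place_cb(res["N", ], res["CA", ], res["C", ])
      tb <- bind_rows(tb, tibble(chain = chain,
                                 resno = as.integer(i + resno_offset),
                                 resname = resnames[i], atom = "CB",
                                 element = "C",
                                 x = cb[1], y = cb[2], z = cb[3]))
    }
    tb
  })
  bind_rows(rows)
}

orient_residue_list <- function(seg, origin, direction) {
  m <- do.call(rbind, seg)
  ca_idx <- which(rownames(m) == "CA")
  m2 <- orient_segment(m, ca_idx, origin, direction)
  split_idx <- rep(seq_along(seg), each = 4L)
  lapply(seq_along(seg), function(i) {
    out <- m2[split_idx == i, , drop = FALSE]
    rownames(out) <- rownames(seg[[i]])
    out
  })
}

flat_floor_strand <- function(x_positions, y0, z0, chain, resno_offset,
                              resnames) {
  rows <- purrr::imap(x_positions, function(xc, i) {
    tibble(chain = chain, resno = as.integer(i + resno_offset),
           resname = resnames[i],
           atom = c("N", "CA", "C", "O"),
           element = c("N", "C", "C", "O"),
           x = c(xc - 1.2, xc, xc + 1.2, xc + 1.2),
           y = y0 + c(0.6, 0, 0.6, 1.8) * sign(y0),
           z = z0)
  })
  bind_rows(rows)
}

#' Generate an idealized pMHC-II complex
#'
#' Deterministic given the spec: two ideal alpha-helices run along the
#' groove axis at `+/- groove_width/2`, a flat synthetic floor strand lies
#' under the peptide (one strand per receptor chain), and the peptide sits
#' in an extended beta conformation along the axis with anchor CB atoms
#' pointing at the floor. Each receptor chain is helix + floor strand
#' (>= 70 residues), so the complex standardizes and passes the template-set
#' filters.
#'
#' @param spec A `fixture_spec`.
#' @return A validated `pmhc_complex`; attribute `"core"` carries the
#'   fixture's `binding_core` (when the peptide holds one).
#' @export
make_toy_pmhc2 <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  g <- FIXTURE_GEOM
  L <- nchar(spec$peptide_seq)
  pep_chars <- seq_to_chars(spec$peptide_seq)
  pep_resnames <- unname(AA3[pep_chars])

  with_local_seed(spec$seed, {
    alpha_seq <- spec$alpha_seq
    beta_seq <- spec$beta_seq
    n_floor <- L + 2L * g$floor_pad
    n_chain <- spec$helix_length + n_floor
    if (is.null(alpha_seq)) alpha_seq <- random_aa_seq(n_chain)
    if (is.null(beta_seq)) beta_seq <- random_aa_seq(n_chain)
    if (nchar(alpha_seq) != n_chain || nchar(beta_seq) != n_chain) {
      abort_pmhc(sprintf("receptor chain sequences must have %d residues", n_chain),
                 "pmhc_fixture_error")
    }

    # peptide: extended strand along +x
    pep_seg <- build_ideal_segment(L, phi = -139, psi = 135)
    pep_seg <- orient_residue_list(pep_seg, origin = c(0, 0, 0),
                                   direction = c(1, 0, 0))
    pep_atoms <- segment_to_atoms(pep_seg, "P", pep_resnames, with_cb = TRUE)
    # anchor side chains point at the floor
    if (!is.null(spec$core)) {
      for (a in spec$core$anchors) {
        ca <- pep_seg[[a]]["CA", ]
        sel <- pep_atoms$resno == a & pep_atoms$atom == "CB"
        pep_atoms$x[sel] <- ca[1]
        pep_atoms$y[sel] <- ca[2]
        pep_atoms$z[sel] <- ca[3] - 1.53
      }
    }
    pep_ca_x <- vapply(pep_seg, function(r) r["CA", 1], numeric(1))

    # receptor chains: ideal helix + flat floor strand
    floor_x <- c(rev(pep_ca_x[1] - 3.4 * seq_len(g$floor_pad)),
                 pep_ca_x,
                 pep_ca_x[L] + 3.4 * seq_len(g$floor_pad))
    build_chain <- function(chain, side, seqstr) {
      chars <- seq_to_chars(seqstr)
      resnames <- unname(AA3[chars])
      helix <- build_ideal_segment(spec$helix_length, phi = -57, psi = -47)
      helix <- orient_residue_list(
        helix, origin = c(g$x_helix, side * spec$groove_width / 2, g$z_helix),
        direction = c(1, 0, 0))
      h_atoms <- segment_to_atoms(helix, chain,
                                  resnames[seq_len(spec$helix_length)])
      f_atoms <- flat_floor_strand(floor_x, side * g$y_floor, g$z_floor,
                                   chain, spec$helix_length,
                                   resnames[spec$helix_length + seq_len(n_floor)])
      bind_rows(h_atoms, f_atoms)
    }
    m_atoms <- build_chain("M", +1, alpha_seq)
    n_atoms <- build_chain("N", -1, beta_seq)

    atoms <- bind_rows(m_atoms, n_atoms, pep_atoms)
    cx <- new_pmhc_complex(spec$pdb_id, "II", atoms,
                           alpha_allele = spec$alpha_allele,
                           beta_allele = spec$beta_allele,
                           peptide_seq = spec$peptide_seq,
                           resolution = spec$resolution)
    validate_pmhc_complex(cx)
    attr(cx, "core") <- spec$core
    cx
  })
}

#' Perturb a fixture with known ground-truth RMSD contributions
#'
#' * `peptide_shift`: translates every peptide atom by `magnitude` along a
#'   seeded random unit vector (receptor untouched), so every backbone
#'   L-RMSD equals `magnitude` exactly.
#' * `flank_scramble`: adds seeded Gaussian noise (sd `magnitude`) to all
#'   atoms of the flank residues; core L-RMSD stays 0.
#' * `core_register_shift`: relabels the core start by `k` residues
#'   (coordinates and sequence unchanged) to emulate a wrong binding-core
#'   prediction.
#'
#' Ground-truth values are computed directly from the applied displacement
#' vectors over peptide backbone atoms, independently of any RMSD code.
#'
#' @param complex A `pmhc_complex` (or `template_record`).
#' @param kind Perturbation kind.
#' @param magnitude Shift length / noise sd in Angstrom.
#' @param k Register shift in residues (for `core_register_shift`).
#' @param seed Seed for the random direction / noise.
#' @param core `binding_core`; defaults to the complex's `"core"` attribute.
#' @return List: `complex` (perturbed), `core` (possibly re-labelled),
#'   `ground_truth` (tibble `core`, `flanking`, `whole`, or `NULL` for
#'   register shifts).
#' @export
perturb_fixture <- function(complex,
                            kind = c("none", "peptide_shift", "flank_scramble",
                                     "core_register_shift"),
                            magnitude = 0, k = 0L, seed = 1,
                            core = NULL) {
  kind <- match.arg(kind)
  if (inherits(complex, "template_record")) {
    if (is.null(core)) core <- complex$core
    complex <- complex$complex
  }
  if (is.null(core)) core <- attr(complex, "core")
  out <- complex
  at <- out$atoms
  pep <- which(at$chain == "P")
  bb <- at$chain == "P" & at$atom %in% BACKBONE_ATOMS
  gt <- NULL

  if (kind == "none" || (kind != "core_register_shift" && magnitude == 0)) {
    gt <- tibble(core = 0, flanking = 0, whole = 0)
    return(list(complex = out, core = core, ground_truth = gt))
  }
  if (kind == "peptide_shift") {
    u <- with_local_seed(seed, {
      v <- rnorm(3)
      v / vnorm(v)
    })
    at$x[pep] <- at$x[pep] + magnitude * u[1]
    at$y[pep] <- at$y[pep] + magnitude * u[2]
    at$z[pep] <- at$z[pep] + magnitude * u[3]
    has_flank <- !is.null(core) && core$peptide_length > 9L
    gt <- tibble(core = magnitude,
                 flanking = if (has_flank) magnitude else NA_real_,
                 whole = magnitude)
  } else if (kind == "flank_scramble") {
    if (is.null(core)) {
      abort_pmhc("flank_scramble needs a binding core", "pmhc_fixture_error")
    }
    flank_res <- setdiff(seq_len(core$peptide_length), core_residues(core))
    sel <- which(at$chain == "P" & at$resno %in% flank_res)
    if (length(sel) == 0L) {
      abort_pmhc("peptide has no flank residues to scramble", "pmhc_fixture_error")
    }
    disp <- with_local_seed(seed, matrix(rnorm(3 * length(sel), 0, magnitude),
                                         ncol = 3))
    at$x[sel] <- at$x[sel] + disp[, 1]
    at$y[sel] <- at$y[sel] + disp[, 2]
    at$z[sel] <- at$z[sel] + disp[, 3]
    # ground truth from the applied backbone displacements
    bb_sel <- at$atom[sel] %in% BACKBONE_ATOMS
    d2_flank <- rowSums(disp[bb_sel, , drop = FALSE]^2)
    n_core_bb <- sum(bb & at$resno %in% core_residues(core))
    gt <- tibble(core = 0,
                 flanking = sqrt(mean(d2_flank)),
                 whole = sqrt(sum(d2_flank) / (n_core_bb + length(d2_flank))))
  } else if (kind == "core_register_shift") {
    if (is.null(core)) {
      abort_pmhc("core_register_shift needs a binding core", "pmhc_fixture_error")
    }
    core <- binding_core(core$start + as.integer(k), core$peptide_length)
  }
  out$atoms <- at
  list(complex = out, core = core, ground_truth = gt)
}

#' Generate a set of fixture template records
#'
#' Draws `n` deterministic fixtures with varying peptide lengths, core
#' offsets, sequences and alleles. With `near_duplicates = TRUE` the set is
#' built as n/2 pairs: partners share geometry, peptide length and core, and
#' differ by one peptide substitution, two substitutions per MHC chain, and
#' a small seeded coordinate jitter (0.15 A) on the second partner's peptide
#' -- so leave-one-out template selection finds a near-ideal template for
#' every case.
#'
#' @param n Number of fixtures (even when `near_duplicates`).
#' @param seed Base seed.
#' @param near_duplicates Build the set as similar pairs.
#' @param dir Optional directory: when given, the set is also written as a
#'   template database ([build_template_db()]).
#' @return List of `template_record`.
#' @export
make_fixture_set <- function(n = 10, seed = 1, near_duplicates = FALSE,
                             dir = NULL) {
  lengths <- rep(c(11L, 13L, 15L, 12L, 14L, 10L, 16L, 13L, 11L, 15L),
                 length.out = if (near_duplicates) ceiling(n / 2) else n)
  records <- list()
  if (near_duplicates) {
    for (j in seq_len(ceiling(n / 2))) {
      L <- lengths[j]
      base_seed <- seed + 100L * j
      info <- with_local_seed(base_seed, {
        list(pep = random_aa_seq(L),
             core_start = sample.int(L - 8L, 1L) - 1L,
             aseq = random_aa_seq(60L + L + 4L),
             bseq = random_aa_seq(60L + L + 4L))
      })
      for (half in 1:2) {
        id <- sprintf("SYN%02d%s", j, c("A", "B")[half])
        pep <- info$pep
        aseq <- info$aseq
        bseq <- info$bseq
        if (half == 2) {
          mut <- with_local_seed(base_seed + 1L, {
            list(p = substitute_letters(pep, 1L),
                 a = substitute_letters(aseq, 2L),
                 b = substitute_letters(bseq, 2L))
          })
          pep <- mut$p
          aseq <- mut$a
          bseq <- mut$b
          # keep anchors non-glycine and the core identical
        }
        sp <- fixture_spec(pep, core_start = info$core_start,
                           seed = base_seed + half,
                           alpha_seq = aseq, beta_seq = bseq,
                           alpha_allele = sprintf("SYNA*%02d:0%d", j, half),
                           beta_allele = sprintf("SYNB*%02d:0%d", j, half),
                           pdb_id = id,
                           resolution = 1.5 + 0.1 * j)
        cx <- make_toy_pmhc2(sp)
        if (half == 2) {
          cx <- perturb_fixture(cx, "peptide_shift", magnitude = 0.15,
                                seed = base_seed + 7L,
                                core = sp$core)$complex
        }
        records[[length(records) + 1L]] <- template_record(
          cx, core_start = info$core_start)
        if (length(records) == n) break
      }
      if (length(records) == n) break
    }
  } else {
    for (i in seq_len(n)) {
      L <- lengths[i]
      base_seed <- seed + 100L * i
      info <- with_local_seed(base_seed, {
        list(pep = random_aa_seq(L),
             core_start = sample.int(L - 8L, 1L) - 1L)
      })
      sp <- fixture_spec(info$pep, core_start = info$core_start,
                         seed = base_seed,
                         alpha_allele = sprintf("SYNA*%02d:01", i),
                         beta_allele = sprintf("SYNB*%02d:01", i),
                         pdb_id = sprintf("SYN%03d", i),
                         resolution = 1.5 + 0.1 * (i %% 10))
      cx <- make_toy_pmhc2(sp)
      records[[length(records) + 1L]] <- template_record(
        cx, core_start = info$core_start)
    }
  }
  if (!is.null(dir)) build_template_db(records, dir)
  records
}

# replace `k` letters at seeded random positions (never producing G or X)
substitute_letters <- function(seqstr, k) {
  chars <- seq_to_chars(seqstr)
  pos <- sample.int(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(AA1, c("G", chars[p])), 1L)
  }
  paste(chars, collapse = "")
}
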