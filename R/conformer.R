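# Restraint-guided peptide conformer engine: place the target binding core
# on the template core, rebuild the flanking regions residue-by-residue with
# ideal covalent geometry and torsions drawn from the template (where
# aligned) or a Ramachandran-favoured set, then refine against a transparent
# three-term pseudo-energy (local-geometry harmonics + soft-sphere clash +
# flat-bottom harmonic anchor restraints) and rank the ensemble.
#
# In the default fixed-core mode the whole peptide core keeps the template
# conformation (its atoms are frozen during refinement); the
# restraint-flexible mode lets the core move within the restraints'
# standard deviation.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

RAMA_SET <- matrix(c(
  -135, 135,   # beta strand
  -120, 130,   # extended
   -75, 145,   # polyproline II
   -60, -45,   # alpha helix
   -90, 120    # bridge/extended
), ncol = 2, byrow = TRUE, dimnames = list(NULL, c("phi", "psi")))

DEFAULT_ENERGY_WEIGHTS <- c(bonded = 1, clash = 1, restraint = 10)
K_BOND <- 100       # harmonic constant on local-geometry distances
CLASH_R0 <- 3.0     # soft-sphere contact radius (heavy atoms), Angstrom
CLASH_DFLOOR <- 2.0 # repulsion capped below this distance
SD_FLOOR <- 0.01    # Angstrom; avoids division by zero when sd = 0
CA_GUIDE_WEIGHT <- 10   # template-CA guidance weight in flank candidate selection

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Define a modelling job
#'
#' @param alpha_seq,beta_seq Target MHC chain sequences.
#' @param peptide Target peptide sequence.
#' @param core `binding_core` of the target peptide.
#' @param template Selected `template_record`.
#' @param mode `"fixed_core"` (default: core keeps the template conformation,
#'   frozen during refinement) or `"flex_core"` (core moves within the
#'   restraints' standard deviation).
#' @param sd Anchor-restraint standard deviation in Angstrom.
#' @param n_models Ensemble size (default 20).
#' @param seed Base random seed; model i uses `seed + i`.
#' @param correspondence Optional `pmhc_core_alignment`; computed from the
#'   cores when `NULL`.
#' @return A `modelling_job`.
#' @export
modelling_job <- function(alpha_seq, beta_seq, peptide, core, template,
                          mode = c("fixed_core", "flex_core"), sd = 0,
                          n_models = 20, seed = 1, correspondence = NULL) {
  mode <- match.arg(mode)
  check_aa_string(peptide, "peptide")
  stopifnot(inherits(core, "binding_core"), inherits(template, "template_record"))
  if (n_models < 1L) {
    abort_pmhc("n_models must be >= 1", "pmhc_precondition_error")
  }
  if (sd < 0) abort_pmhc("sd must be >= 0", "pmhc_precondition_error")
  if (is.null(correspondence)) {
    correspondence <- align_peptide_to_template(
      peptide, core, template$complex$peptide_seq, template$core)
  }
  structure(list(alpha_seq = alpha_seq, beta_seq = beta_seq,
                 peptide = peptide, core = core, template = template,
                 mode = mode, sd = sd, n_models = as.integer(n_models),
                 seed = as.integer(seed), correspondence = correspondence),
            class = "modelling_job")
}

backbone_coords <- function(atoms, resnos, chain = "P") {
  out <- matrix(NA_real_, nrow = length(resnos) * 4L, ncol = 3L)
  k <- 0L
  for (r in resnos) {
    for (an in BACKBONE_ATOMS) {
      k <- k + 1L
      row <- atoms[atoms$chain == chain & atoms$resno == r & atoms$atom == an, ]
      if (nrow(row) != 1L) {
        abort_pmhc(sprintf("missing backbone atom %s of %s/%d", an, chain, r),
                   "pmhc_backbone_error")
      }
      out[k, ] <- c(row$x, row$y, row$z)
    }
  }
  out
}

#' Superpose a target core onto a template core
#'
#' Least-squares rigid fit (rotation + translation, no scaling or reflection)
#' of the target core backbone (N, CA, C, O of the 9 core residues) onto the
#' template core backbone. The placed core coordinates are the template core
#' backbone, per the template-anchored modelling convention.
#'
#' @param target_core_atoms Atom tibble of the 9 target core residues
#'   (chain P) with complete backbone.
#' @param template A `template_record`.
#' @return List: `rotation`, `translation`, `rmsd`, and `placed` (9x4x3
#'   template core backbone coordinates as a 36 x 3 matrix, residues in
#'   order, atoms N/CA/C/O within each residue).
#' @export
superpose_core <- function(target_core_atoms, template) {
  stopifnot(inherits(template, "template_record"))
  t_res <- sort(unique(target_core_atoms$resno))
  if (length(t_res) != 9L) {
    abort_pmhc("target core must contain exactly 9 residues", "pmhc_core_error")
  }
  P <- backbone_coords(target_core_atoms, t_res)
  tmpl_res <- core_residues(template$core)
  Q <- backbone_coords(template$complex$atoms, tmpl_res)
  fit <- kabsch_fit(P, Q)
  c(fit, list(placed = Q))
}

# phi/psi/omega of every residue of a chain (NA where undefined).
chain_torsions <- function(atoms, chain = "P") {
  res <- sort(unique(atoms$resno[atoms$chain == chain]))
  get_atom <- function(r, an) {
    row <- atoms[atoms$chain == chain & atoms$resno == r & atoms$atom == an, ]
    if (nrow(row) != 1L) return(NULL)
    c(row$x, row$y, row$z)
  }
  phi <- psi <- rep(NA_real_, length(res))
  for (i in seq_along(res)) {
    N <- get_atom(res[i], "N"); CA <- get_atom(res[i], "CA")
    C <- get_atom(res[i], "C")
    if (i > 1) {
      Cp <- get_atom(res[i - 1], "C")
      if (!is.null(Cp) && !is.null(N) && !is.null(CA) && !is.null(C)) {
        phi[i] <- dihedral_angle(Cp, N, CA, C)
      }
    }
    if (i < length(res)) {
      Nn <- get_atom(res[i + 1], "N")
      if (!is.null(Nn) && !is.null(N) && !is.null(CA) && !is.null(C)) {
        psi[i] <- dihedral_angle(N, CA, C, Nn)
      }
    }
  }
  tibble(resno = res, phi = phi, psi = psi)
}

atom_row <- function(resno, resname, atom, xyz) {
  tibble(chain = "P", resno = as.integer(resno), resname = resname,
         atom = atom, element = substr(atom, 1, 1),
         x = xyz[1], y = xyz[2], z = xyz[3])
}

# Place the target core on the template: backbone (and side chain, when the
# residue type matches) copied from the template core; mismatched residues
# truncated to CB.
place_core_from_template <- function(peptide, core, template) {
  tmpl <- template$complex
  chars <- seq_to_chars(peptide)
  tmpl_chars <- seq_to_chars(tmpl$peptide_seq)
  rows <- list()
  for (i in seq_len(9L)) {
    t_res <- core$start + i
    q_res <- template$core$start + i
    aa <- chars[t_res]
    resname <- unname(AA3[aa])
    src <- tmpl$atoms[tmpl$atoms$chain == "P" & tmpl$atoms$resno == q_res, ]
    if (tmpl_chars[q_res] == aa) {
      keep <- src
    } else {
      keep <- src[src$atom %in% c(BACKBONE_ATOMS, "CB"), ]
      if (aa == "G") keep <- keep[keep$atom != "CB", ]
      if (aa != "G" && !("CB" %in% keep$atom)) {
        bb <- function(an) unlist(keep[keep$atom == an, c("x", "y", "z")])
        cb <- place_cb(bb("N"), bb("CA"), bb("C"))
        keep <- bind_rows(keep, atom_row(q_res, resname, "CB", cb))
      }
    }
    keep$resno <- as.integer(t_res)
    keep$resname <- resname
    rows[[i]] <- keep[, ATOM_COLS]
  }
  bind_rows(rows)
}

clash_score_atoms <- function(xyz, rec_xyz) {
  if (nrow(xyz) == 0L || nrow(rec_xyz) == 0L) return(0)
  d2 <- outer(rowSums(xyz^2), rowSums(rec_xyz^2), "+") - 2 * xyz %*% t(rec_xyz)
  d <- sqrt(pmax(d2, 0))
  sum((CLASH_R0 / pmax(d, CLASH_DFLOOR))^12)
}

draw_torsion_candidates <- function(k, tmpl_phi, tmpl_psi, jitter_tmpl = 6,
                                    jitter_rama = 10) {
  rows <- sample.int(nrow(RAMA_SET), k, replace = TRUE)
  phi <- if (is.na(tmpl_phi)) {
    RAMA_SET[rows, "phi"] + rnorm(k, 0, jitter_rama)
  } else {
    tmpl_phi + rnorm(k, 0, jitter_tmpl)
  }
  psi <- if (is.na(tmpl_psi)) {
    RAMA_SET[rows, "psi"] + rnorm(k, 0, jitter_rama)
  } else {
    tmpl_psi + rnorm(k, 0, jitter_tmpl)
  }
  cbind(phi = phi, psi = psi)
}

#' Build the peptide flanking regions onto a placed core
#'
#' Extends the peptide outward from the core one residue at a time with
#' ideal bond lengths and angles. Backbone torsions of flank residues that
#' align to template residues are taken from the template (the first
#' candidate exactly, the rest with small jitter); unaligned residues sample
#' a packaged Ramachandran-favoured set. Among `k` candidates per residue the
#' placement minimizing receptor clash (plus deviation from the aligned
#' template CA, when available) is kept. Deterministic given `seed`.
#'
#' @param core_atoms Atom tibble of the placed core (target numbering).
#' @param peptide Full target peptide sequence.
#' @param core Target `binding_core`.
#' @param receptor Receptor atom tibble (chains M and N) used for clash
#'   scoring.
#' @param seed Integer seed.
#' @param template,correspondence Optional template record and core-anchored
#'   alignment supplying flank torsions and CA guidance.
#' @param k Candidate draws per residue (default 32).
#' @param clash_flag_threshold Best-candidate clash score above which the
#'   model is flagged.
#' @return Atom tibble of the complete peptide; attribute `flagged` is TRUE
#'   when no placement fell below the overlap threshold.
#' @export
build_flanks <- function(core_atoms, peptide, core, receptor, seed,
                         template = NULL, correspondence = NULL, k = 32,
                         clash_flag_threshold = 50) {
  L <- nchar(peptide)
  chars <- seq_to_chars(peptide)
  rec_xyz <- as.matrix(receptor[, c("x", "y", "z")])
  tmpl_tor <- if (!is.null(template)) {
    chain_torsions(template$complex$atoms, "P")
  } else NULL
  tmpl_ca <- if (!is.null(template)) {
    a <- template$complex$atoms
    ca <- a[a$chain == "P" & a$atom == "CA", ]
    ca[order(ca$resno), ]
  } else NULL
  omap <- if (!is.null(correspondence)) correspondence$offset_map else NULL

  tor_of <- function(target_res, which) {
    if (is.null(tmpl_tor) || is.null(omap)) return(NA_real_)
    if (target_res < 1L || target_res > L) return(NA_real_)
    q <- omap[target_res]
    if (is.na(q)) return(NA_real_)
    tmpl_tor[[which]][match(q, tmpl_tor$resno)]
  }
  ca_of <- function(target_res) {
    if (is.null(tmpl_ca) || is.null(omap)) return(NULL)
    q <- omap[target_res]
    if (is.na(q)) return(NULL)
    row <- tmpl_ca[tmpl_ca$resno == q, ]
    if (nrow(row) != 1L) return(NULL)
    c(row$x, row$y, row$z)
  }
  get_bb <- function(atoms, r) {
    lapply(setNames(BACKBONE_ATOMS, BACKBONE_ATOMS), function(an) {
      row <- atoms[atoms$resno == r & atoms$atom == an, ]
      if (nrow(row) != 1L) NULL else c(row$x, row$y, row$z)
    })
  }

  g <- IDEAL_GEOM
  flagged <- FALSE
  all_atoms <- core_atoms

  with_local_seed(seed, {
    # ---- C-terminal flank (forward) -------------------------------------
    c_end <- core$start + 9L
    if (c_end < L) {
      prev <- get_bb(all_atoms, c_end)
      deferred_o <- NULL  # (resno, N, CA, C) awaiting next N for O placement
      for (j in (c_end + 1L):L) {
        psi_prev_t <- tor_of(j - 1L, "psi")
        cand_prev <- draw_torsion_candidates(k, NA, psi_prev_t)[, "psi"]
        cand_cur <- draw_torsion_candidates(k, tor_of(j, "phi"), tor_of(j, "psi"))
        ca_t <- ca_of(j)
        best <- NULL
        for (cidx in seq_len(k)) {
          Nj <- place_atom(prev$N, prev$CA, prev$C, g$b_c_n, g$a_ca_c_n,
                           cand_prev[cidx])
          CAj <- place_atom(prev$CA, prev$C, Nj, g$b_n_ca, g$a_c_n_ca, 180)
          Cj <- place_atom(prev$C, Nj, CAj, g$b_ca_c, g$a_n_ca_c,
                           cand_cur[cidx, "phi"])
          xyz <- rbind(Nj, CAj, Cj)
          cb <- NULL
          if (chars[j] != "G") {
            cb <- place_cb(Nj, CAj, Cj)
            xyz <- rbind(xyz, cb)
          }
          sc <- clash_score_atoms(xyz, rec_xyz)
          if (!is.null(ca_t)) sc <- sc + CA_GUIDE_WEIGHT * sum((CAj - ca_t)^2)
          if (is.null(best) || sc < best$score) {
            best <- list(score = sc, N = Nj, CA = CAj, C = Cj, CB = cb,
                         psi = cand_cur[cidx, "psi"])
          }
        }
        if (best$score > clash_flag_threshold) flagged <- TRUE
        if (!is.null(deferred_o)) {
          O <- place_atom(best$N, deferred_o$CA, deferred_o$C, g$b_c_o,
                          g$a_ca_c_o, 180)
          all_atoms <- bind_rows(all_atoms,
                                 atom_row(deferred_o$resno,
                                          unname(AA3[chars[deferred_o$resno]]),
                                          "O", O))
        }
        resname <- unname(AA3[chars[j]])
        new_rows <- list(atom_row(j, resname, "N", best$N),
                         atom_row(j, resname, "CA", best$CA),
                         atom_row(j, resname, "C", best$C))
        if (!is.null(best$CB)) {
          new_rows <- c(new_rows, list(atom_row(j, resname, "CB", best$CB)))
        }
        all_atoms <- bind_rows(all_atoms, bind_rows(new_rows))
        deferred_o <- list(resno = j, CA = best$CA, C = best$C, psi = best$psi)
        prev <- list(N = best$N, CA = best$CA, C = best$C)
      }
      if (!is.null(deferred_o)) {
        # terminal O from the drawn psi of the last residue
        r <- deferred_o$resno
        bb <- get_bb(all_atoms, r)
        O <- place_atom(bb$N, bb$CA, bb$C, g$b_c_o, g$a_ca_c_o,
                        deferred_o$psi + 180)
        all_atoms <- bind_rows(all_atoms,
                               atom_row(r, unname(AA3[chars[r]]), "O", O))
      }
    }

    # ---- N-terminal flank (backward) ------------------------------------
    n_start <- core$start + 1L
    if (n_start > 1L) {
      nxt <- get_bb(all_atoms, n_start)
      for (i in (n_start - 1L):1L) {
        cand_phi <- draw_torsion_candidates(k, tor_of(i + 1L, "phi"), NA)[, "phi"]
        cand_psi <- draw_torsion_candidates(k, NA, tor_of(i, "psi"))[, "psi"]
        ca_t <- ca_of(i)
        best <- NULL
        for (cidx in seq_len(k)) {
          Ci <- place_atom(nxt$C, nxt$CA, nxt$N, g$b_c_n, g$a_c_n_ca,
                           cand_phi[cidx])
          CAi <- place_atom(nxt$CA, nxt$N, Ci, g$b_ca_c, g$a_ca_c_n, 180)
          Ni <- place_atom(nxt$N, Ci, CAi, g$b_n_ca, g$a_n_ca_c,
                           cand_psi[cidx])
          Oi <- place_atom(nxt$N, CAi, Ci, g$b_c_o, g$a_ca_c_o, 180)
          xyz <- rbind(Ni, CAi, Ci, Oi)
          cb <- NULL
          if (chars[i] != "G") {
            cb <- place_cb(Ni, CAi, Ci)
            xyz <- rbind(xyz, cb)
          }
          sc <- clash_score_atoms(xyz, rec_xyz)
          if (!is.null(ca_t)) sc <- sc + CA_GUIDE_WEIGHT * sum((CAi - ca_t)^2)
          if (is.null(best) || sc < best$score) {
            best <- list(score = sc, N = Ni, CA = CAi, C = Ci, O = Oi, CB = cb)
          }
        }
        if (best$score > clash_flag_threshold) flagged <- TRUE
        resname <- unname(AA3[chars[i]])
        new_rows <- list(atom_row(i, resname, "N", best$N),
                         atom_row(i, resname, "CA", best$CA),
                         atom_row(i, resname, "C", best$C),
                         atom_row(i, resname, "O", best$O))
        if (!is.null(best$CB)) {
          new_rows <- c(new_rows, list(atom_row(i, resname, "CB", best$CB)))
        }
        all_atoms <- bind_rows(all_atoms, bind_rows(new_rows))
        nxt <- list(N = best$N, CA = best$CA, C = best$C)
      }
    }
  })

  ord <- order(all_atoms$resno, match(all_atoms$atom, c(BACKBONE_ATOMS, "CB")))
  out <- all_atoms[ord, ]
  attr(out, "flagged") <- flagged
  out
}

# Assemble one conformer: receptor copied from the template, peptide from
# placed core + built flanks.
build_peptide_model <- function(job, model_seed) {
  core_atoms <- place_core_from_template(job$peptide, job$core, job$template)
  rec <- receptor_atoms(job$template$complex)
  pep <- build_flanks(core_atoms, job$peptide, job$core, rec, seed = model_seed,
                      template = job$template,
                      correspondence = job$correspondence)
  atoms <- bind_rows(rec[, ATOM_COLS], pep[, ATOM_COLS])
  cx <- new_pmhc_complex(
    pdb_id = sprintf("model_seed%d", model_seed), mhc_class = "II",
    atoms = atoms, alpha_allele = job$template$complex$alpha_allele,
    beta_allele = job$template$complex$beta_allele,
    peptide_seq = job$peptide)
  attr(cx, "core") <- job$core
  attr(cx, "flagged") <- isTRUE(attr(pep, "flagged"))
  cx
}

# ---- pseudo-energy ------------------------------------------------------

make_energy_model <- function(model, restraints, core, mode,
                              weights = DEFAULT_ENERGY_WEIGHTS, sd_default = 0) {
  at <- model$atoms
  pep <- at[at$chain == "P", ]
  rec <- at[at$chain %in% c("M", "N", "B"), ]
  P0 <- as.matrix(pep[, c("x", "y", "z")])
  R <- as.matrix(rec[, c("x", "y", "z")])
  np <- nrow(P0)
  # receptor atoms relevant for clash: within 10 A of the start peptide
  # (the receptor is rigid and peptide moves are local, so this set defines
  # the clash term of the objective)
  if (nrow(R)) {
    d2r <- outer(rowSums(P0^2), rowSums(R^2), "+") - 2 * P0 %*% t(R)
    R <- R[sqrt(pmax(apply(d2r, 2, min), 0)) <= 10, , drop = FALSE]
  }

  frozen <- rep(FALSE, np)
  if (!is.null(core) && mode == "fixed_core") {
    frozen <- pep$resno %in% core_residues(core)
  }

  # local-geometry pairs: same/adjacent residue, start distance <= 2.9 A
  # (covalent bonds plus 1-3 pairs); reference = start geometry.
  pr <- pep$resno
  idx <- which(outer(pr, pr, function(a, b) abs(a - b) <= 1L) &
                 upper.tri(matrix(TRUE, np, np)), arr.ind = TRUE)
  d0 <- sqrt(rowSums((P0[idx[, 1], , drop = FALSE] -
                        P0[idx[, 2], , drop = FALSE])^2))
  keep <- d0 <= 2.9
  bonded_i <- idx[keep, 1]
  bonded_j <- idx[keep, 2]
  bonded_d0 <- d0[keep]

  # intra-peptide non-bonded pairs: residues two or more apart
  nb <- which(outer(pr, pr, function(a, b) (b - a) >= 2L), arr.ind = TRUE)
  nb_i <- nb[, 1]
  nb_j <- nb[, 2]

  # restraints -> atom indices; peptide side must exist, receptor side fixed
  r_idx <- integer(0)
  r_xyz <- matrix(numeric(0), ncol = 3)
  r_target <- numeric(0)
  r_sd <- numeric(0)
  if (!is.null(restraints) && nrow(restraints) > 0L) {
    pep_key <- paste(pep$resno, pep$atom)
    for (i in seq_len(nrow(restraints))) {
      pi <- match(paste(restraints$res_a[i], restraints$atom_a[i]), pep_key)
      rrow <- rec[rec$chain == restraints$chain_b[i] &
                    rec$resno == restraints$res_b[i] &
                    rec$atom == restraints$atom_b[i], ]
      if (is.na(pi) || nrow(rrow) != 1L) next  # atom absent in this model
      r_idx <- c(r_idx, pi)
      r_xyz <- rbind(r_xyz, c(rrow$x, rrow$y, rrow$z))
      r_target <- c(r_target, restraints$target[i])
      r_sd <- c(r_sd, restraints$sd[i])
    }
  }

  w_b <- unname(weights["bonded"])
  w_c <- unname(weights["clash"])
  w_r <- unname(weights["restraint"])

  energy <- function(P, with_grad = FALSE) {
    G <- if (with_grad) matrix(0, np, 3) else NULL
    # bonded (local-geometry harmonics)
    dvec <- P[bonded_i, , drop = FALSE] - P[bonded_j, , drop = FALSE]
    d <- sqrt(rowSums(dvec^2))
    e_bond <- K_BOND * sum((d - bonded_d0)^2)
    if (with_grad && length(d)) {
      gs <- w_b * 2 * K_BOND * (d - bonded_d0) / pmax(d, 1e-9)
      gv <- dvec * gs
      for (col in 1:3) {
        G[, col] <- G[, col] +
          tabulate_add(bonded_i, gv[, col], np) -
          tabulate_add(bonded_j, gv[, col], np)
      }
    }
    # clash: intra-peptide soft sphere
    e_clash <- 0
    if (length(nb_i)) {
      dvec2 <- P[nb_i, , drop = FALSE] - P[nb_j, , drop = FALSE]
      d2 <- sqrt(rowSums(dvec2^2))
      dc <- pmax(d2, CLASH_DFLOOR)
      e_clash <- e_clash + sum((CLASH_R0 / dc)^12)
      if (with_grad) {
        gs <- w_c * ifelse(d2 > CLASH_DFLOOR,
                           -12 * CLASH_R0^12 / dc^13, 0) / pmax(d2, 1e-9)
        gv <- dvec2 * gs
        for (col in 1:3) {
          G[, col] <- G[, col] +
            tabulate_add(nb_i, gv[, col], np) -
            tabulate_add(nb_j, gv[, col], np)
        }
      }
    }
    # clash: peptide vs (rigid) receptor
    if (nrow(R)) {
      d2m <- outer(rowSums(P^2), rowSums(R^2), "+") - 2 * P %*% t(R)
      dm <- sqrt(pmax(d2m, 1e-12))
      dmc <- pmax(dm, CLASH_DFLOOR)
      e_clash <- e_clash + sum((CLASH_R0 / dmc)^12)
      if (with_grad) {
        W <- w_c * ifelse(dm > CLASH_DFLOOR,
                          -12 * CLASH_R0^12 / dmc^13, 0) / dm
        for (col in 1:3) {
          G[, col] <- G[, col] + rowSums(W * outer(P[, col], R[, col], "-"))
        }
      }
    }
    # anchor restraints (flat-bottom harmonic)
    e_res <- 0
    if (length(r_idx)) {
      dvec3 <- P[r_idx, , drop = FALSE] - r_xyz
      d3 <- sqrt(rowSums(dvec3^2))
      s <- pmax(r_sd, SD_FLOOR)
      active <- abs(d3 - r_target) > r_sd
      e_res <- sum(ifelse(active, ((d3 - r_target) / s)^2, 0))
      if (with_grad) {
        gs <- w_r * ifelse(active, 2 * (d3 - r_target) / s^2, 0) / pmax(d3, 1e-9)
        gv <- dvec3 * gs
        for (col in 1:3) {
          G[, col] <- G[, col] + tabulate_add(r_idx, gv[, col], np)
        }
      }
    }
    terms <- c(bonded = w_b * e_bond, clash = w_c * e_clash,
               restraint = w_r * e_res)
    list(terms = terms, total = sum(terms), grad = G)
  }

  list(pep = pep, P0 = P0, frozen = frozen, energy = energy,
       n_restraints = length(r_idx))
}

tabulate_add <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

energy_breakdown <- function(terms) {
  structure(tibble(bonded = terms[["bonded"]], clash = terms[["clash"]],
                   restraint = terms[["restraint"]],
                   total = sum(terms)),
            class = c("energy_breakdown", class(tibble())))
}

#' Refine a model against the pseudo-energy
#'
#' Monotone gradient descent (with backtracking step control) on
#' `total = bonded + clash + restraint`. The receptor never moves; in
#' `fixed_core` mode all atoms of the core residues are frozen as well, so
#' the core keeps the template conformation exactly. Each restraint
#' contributes `((d - target) / max(sd, 0.01))^2` when `|d - target| > sd`
#' and 0 inside the flat bottom.
#'
#' @param model A `pmhc_complex` conformer (peptide chain P mobile).
#' @param restraints A `pmhc_restraints` tibble (target peptide numbering).
#' @param mode `"fixed_core"` or `"flex_core"`.
#' @param max_steps Maximum descent trials.
#' @param core Target `binding_core`; defaults to the `"core"` attribute of
#'   the model.
#' @param weights Named term weights (bonded, clash, restraint).
#' @param gtol Gradient-norm convergence tolerance.
#' @return List: `model` (refined), `energy` (one-row `energy_breakdown`
#'   tibble), `trajectory` (accepted total energies, non-increasing).
#' @export
minimize <- function(model, restraints, mode = c("fixed_core", "flex_core"),
                     max_steps = 200, core = attr(model, "core"),
                     weights = DEFAULT_ENERGY_WEIGHTS, gtol = 1e-3) {
  mode <- match.arg(mode)
  em <- make_energy_model(model, restraints, core, mode, weights)
  P <- em$P0
  ev <- em$energy(P, with_grad = TRUE)
  check_energy_finite(ev)
  traj <- ev$total
  alpha <- 1e-3
  step <- 0L
  while (step < max_steps) {
    step <- step + 1L
    G <- ev$grad
    G[em$frozen, ] <- 0
    gn <- sqrt(sum(G^2))
    if (gn < gtol) break
    Pt <- P - alpha * G
    evt <- em$energy(Pt, with_grad = FALSE)
    if (is.finite(evt$total) && evt$total < ev$total) {
      P <- Pt
      ev <- em$energy(P, with_grad = TRUE)
      check_energy_finite(ev)
      traj <- c(traj, ev$total)
      alpha <- alpha * 1.5
    } else {
      alpha <- alpha * 0.4
      if (alpha < 1e-10) break
    }
  }
  out <- model
  at <- out$atoms
  pidx <- which(at$chain == "P")
  at$x[pidx] <- P[, 1]
  at$y[pidx] <- P[, 2]
  at$z[pidx] <- P[, 3]
  out$atoms <- at
  list(model = out, energy = energy_breakdown(ev$terms), trajectory = traj)
}

check_energy_finite <- function(ev) {
  if (!all(is.finite(ev$terms))) {
    bad <- names(ev$terms)[!is.finite(ev$terms)]
    abort_pmhc(sprintf("non-finite energy in term(s): %s",
                       paste(bad, collapse = ", ")),
               "pmhc_numeric_error")
  }
}

#' Generate and rank a conformer ensemble
#'
#' Builds `n_models` conformers (model i seeded with `seed + i`), refines
#' each against the pseudo-energy, and ranks them ascending by final total
#' pseudo-energy (rank 1 = lowest). One failing model does not abort the
#' ensemble; failures are recorded with `NA` energies and excluded from
#' ranking.
#'
#' @param job A `modelling_job`.
#' @param restraints A `pmhc_restraints` tibble.
#' @param max_steps Refinement step budget per model.
#' @return A `pmhc_ensemble`: list with `table` (tibble: `model_id`, `rank`,
#'   `seed_used`, `pseudo_energy`, `bonded`, `clash`, `restraint`, `flagged`,
#'   `failed`), `models` (list of refined `pmhc_complex`, in build order) and
#'   `job`.
#' @export
generate_ensemble <- function(job, restraints, max_steps = 200) {
  stopifnot(inherits(job, "modelling_job"))
  rows <- vector("list", job$n_models)
  models <- vector("list", job$n_models)
  for (i in seq_len(job$n_models)) {
    seed_i <- job$seed + i
    res <- tryCatch({
      m <- build_peptide_model(job, seed_i)
      mm <- minimize(m, restraints, mode = job$mode, max_steps = max_steps,
                     core = job$core)
      list(model = mm$model, energy = mm$energy,
           flagged = isTRUE(attr(m, "flagged")), failed = FALSE, err = NULL)
    }, error = function(e) {
      list(model = NULL, energy = NULL, flagged = NA, failed = TRUE,
           err = conditionMessage(e))
    })
    models[[i]] <- res$model
    rows[[i]] <- tibble(
      model_id = sprintf("model_%d", i), seed_used = seed_i,
      pseudo_energy = if (res$failed) NA_real_ else res$energy$total,
      bonded = if (res$failed) NA_real_ else res$energy$bonded,
      clash = if (res$failed) NA_real_ else res$energy$clash,
      restraint = if (res$failed) NA_real_ else res$energy$restraint,
      flagged = res$flagged, failed = res$failed,
      error = res$err %||% NA_character_)
  }
  tb <- bind_rows(rows)
  ok <- !tb$failed
  tb$rank <- NA_integer_
  tb$rank[ok] <- rank(tb$pseudo_energy[ok], ties.method = "first")
  structure(list(table = tb, models = models, job = job),
            class = "pmhc_ensemble")
}

#' @export
print.pmhc_ensemble <- function(x, ...) {
  cat(sprintf("<pmhc_ensemble> %d models (%d failed), peptide %s, template %s\n",
              nrow(x$table), sum(x$table$failed), x$job$peptide,
              x$job$template$id))
  best <- x$table[which(x$table$rank == 1L), ]
  if (nrow(best)) {
    cat(sprintf("  best pseudo-energy: %.3f (%s)\n",
                best$pseudo_energy, best$model_id))
  }
  invisible(x)
}

#' Write an ensemble to disk
#'
#' Writes `model_<rank>.pdb` files plus a `ranking.tsv` (rank, file,
#' pseudo-energy and its term breakdown).
#'
#' @param ensemble A `pmhc_ensemble`.
#' @param dir Output directory (created if needed).
#' @param keep_b2m Keep chain B when present.
#' @return `dir`, invisibly.
#' @export
write_ensemble <- function(ensemble, dir, keep_b2m = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tb <- ensemble$table
  tb$file <- NA_character_
  for (i in seq_len(nrow(tb))) {
    if (tb$failed[i]) next
    file <- sprintf("model_%d.pdb", tb$rank[i])
    write_structure(ensemble$models[[i]], file.path(dir, file),
                    keep_b2m = keep_b2m)
    tb$file[i] <- file
  }
  out <- tb[order(tb$rank), c("rank", "file", "model_id", "seed_used",
                              "pseudo_energy", "bonded", "clash", "restraint",
                              "flagged", "failed")]
  write.table(as.data.frame(out), file.path(dir, "ranking.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
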