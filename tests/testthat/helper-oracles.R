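# Independent oracles and shared (memoized) fixtures for the test suite.
# Every oracle here is written without reusing the package's implementation
# path: alignment by exhaustive enumeration, RMSD by naive double loops,
# superposition by quaternion search.

# ---- brute-force global affine-gap alignment ---------------------------

# Optimal global alignment score by exhaustive enumeration of all gapped
# alignments; a gap run of length L costs open + L * ext, end gaps included.
brute_align_score <- function(a, b, mat, open = 11, ext = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, score + mat[ca[i], cb[j]], "m")
    }
    if (i <= length(ca)) {
      rec(i + 1, j, score - ext - if (state != "gb") open else 0, "gb")
    }
    if (j <= length(cb)) {
      rec(i, j + 1, score - ext - if (state != "ga") open else 0, "ga")
    }
  }
  rec(1, 1, 0, "m")
  best
}

# ---- naive backbone L-RMSD (double loop, no matrix algebra) ------------

naive_lrmsd <- function(model, reference, core) {
  bb <- c("N", "CA", "C", "O")
  core_res <- core$start + 1:9
  sums <- c(core = 0, flank = 0)
  ns <- c(core = 0L, flank = 0L)
  L <- nchar(reference$peptide_seq)
  for (r in seq_len(L)) {
    for (an in bb) {
      m <- model$atoms[model$atoms$chain == "P" & model$atoms$resno == r &
                         model$atoms$atom == an, ]
      f <- reference$atoms[reference$atoms$chain == "P" &
                             reference$atoms$resno == r &
                             reference$atoms$atom == an, ]
      if (nrow(m) != 1 || nrow(f) != 1) next
      d2 <- (m$x - f$x)^2 + (m$y - f$y)^2 + (m$z - f$z)^2
      key <- if (r %in% core_res) "core" else "flank"
      sums[key] <- sums[key] + d2
      ns[key] <- ns[key] + 1L
    }
  }
  list(core = sqrt(sums[["core"]] / ns[["core"]]),
       flanking = if (ns[["flank"]] > 0) sqrt(sums[["flank"]] / ns[["flank"]])
                  else NA_real_,
       whole = sqrt(sum(sums) / sum(ns)))
}

# ---- quaternion-search rigid-fit oracle --------------------------------

quat_rotate <- function(q, X) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  X %*% t(R)
}

# Best-fit RMSD of P onto Q found by seeded random quaternion search plus
# Nelder-Mead polish on the quaternion parameters (never uses svd/Kabsch).
quat_fit_rmsd <- function(P, Q, n_grid = 4000, seed = 7) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(q) {
    if (sum(q^2) < 1e-12) return(Inf)
    sqrt(mean(rowSums((quat_rotate(q, Pc) - Qc)^2)))
  }
  set.seed(seed)
  qs <- matrix(rnorm(4 * n_grid), ncol = 4)
  vals <- apply(qs, 1, obj)
  q0 <- qs[which.min(vals), ]
  fit <- optim(q0, obj, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-14))
  fit2 <- optim(fit$par, obj, method = "Nelder-Mead",
                control = list(maxit = 4000, reltol = 1e-14))
  fit2$value
}

# ---- shared fixtures (memoized across test files) ----------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, maker(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fix_single <- function() {
  cached("single", function() {
    make_fixture_set(1, seed = 11)[[1]]
  })
}

fix_pair_set <- function() {
  cached("pair4", function() {
    make_fixture_set(4, seed = 21, near_duplicates = TRUE)
  })
}

fix_plain_set <- function() {
  cached("plain4", function() {
    make_fixture_set(4, seed = 31)
  })
}

# a toy class I complex: heavy chain (M), beta2-microglobulin-sized chain
# (B) and a 9-mer peptide, assembled from ideal segments
fix_class1_raw <- function() {
  cached("class1", function() {
    seg_atoms <- function(n, chain, origin, seed) {
      seg <- pmhc2model:::build_ideal_segment(n, phi = -57, psi = -47)
      m <- do.call(rbind, seg)
      ca <- which(rownames(m) == "CA")
      m <- pmhc2model:::orient_segment(m, ca, origin, c(1, 0, 0))
      resnames <- rep("ALA", n)
      tibble::tibble(
        chain = chain,
        resno = rep(seq_len(n), each = 4L),
        resname = rep(resnames, each = 4L),
        atom = rownames(do.call(rbind, seg)),
        element = substr(rownames(do.call(rbind, seg)), 1, 1),
        x = m[, 1], y = m[, 2], z = m[, 3])
    }
    dplyr::bind_rows(
      seg_atoms(110, "H", c(0, 8, 0)),
      seg_atoms(60, "L", c(0, -12, 0)),
      seg_atoms(9, "C", c(0, 0, 0)))
  })
}
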