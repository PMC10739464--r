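# Shared constants and small helpers.

# 20 canonical residues; X = unknown/any.
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_ALPHABET <- c(AA1, "X")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
AA3_TO_1 <- setNames(names(AA3), unname(AA3))

# Common modified residues mapped to their parent amino acid. Structures with
# residues outside this table raise a typed error instead of being modelled
# silently with a wrong identity.
NONCANONICAL_MAP <- c(
  MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR", CSO = "CYS",
  HYP = "PRO", MLY = "LYS", M3L = "LYS", KCX = "LYS", PCA = "GLU",
  CME = "CYS", OCS = "CYS", CSD = "CYS", FME = "MET", MLE = "LEU",
  ALY = "LYS", AIB = "ALA", SAR = "GLY", DAL = "ALA", NLE = "LEU"
)

abort_pmhc <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "pmhc2model_error"), ...)
}

seq_to_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

check_aa_string <- function(x, what = "sequence", allow_x = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    abort_pmhc(sprintf("%s must be a non-empty character scalar", what),
               "pmhc_precondition_error")
  }
  alpha <- if (allow_x) AA_ALPHABET else AA1
  bad <- setdiff(unique(seq_to_chars(x)), alpha)
  if (length(bad) > 0L) {
    abort_pmhc(sprintf("%s contains letters outside the amino-acid alphabet: %s",
                       what, paste(bad, collapse = ", ")),
               "pmhc_alphabet_error")
  }
  invisible(x)
}

resname_to_one <- function(resnames) {
  mapped <- ifelse(resnames %in% names(NONCANONICAL_MAP),
                   unname(NONCANONICAL_MAP[resnames]), resnames)
  unknown <- setdiff(unique(mapped), names(AA3_TO_1))
  if (length(unknown) > 0L) {
    abort_pmhc(
      sprintf("non-canonical residue(s) with no parent mapping: %s",
              paste(unknown, collapse = ", ")),
      "pmhc_noncanonical_error")
  }
  unname(AA3_TO_1[mapped])
}

map_noncanonical_resnames <- function(resnames) {
  ifelse(resnames %in% names(NONCANONICAL_MAP),
         unname(NONCANONICAL_MAP[resnames]), resnames)
}
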