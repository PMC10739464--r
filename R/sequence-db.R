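# Reference allele sequences, substitution matrices, global alignment and
# allele-name assignment.
#
# MHC chains are globally homologous, so template selection and allele naming
# use global (Needleman-Wunsch, affine-gap) alignment identity with BLOSUM62
# and BLAST-protein-style gap costs (open 11, extend 1; a gap of length L
# costs open + L * extend). Peptide core scoring uses PAM30.

#' Built-in substitution matrices
#'
#' Returns the canonical PAM30 or BLOSUM62 integer substitution matrix
#' (symmetric, NCBI scores).
#'
#' @param name `"PAM30"` or `"BLOSUM62"`.
#' @return An integer matrix with residue letters as dimnames.
#' @export
substitution_matrix <- function(name = c("PAM30", "BLOSUM62")) {
  name <- match.arg(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  storage.mode(m) <- "integer"
  m
}

#' Read a substitution matrix in NCBI format
#'
#' Parses the whitespace-separated NCBI matrix layout (optional `#` comment
#' lines, a header row of letters, one labelled row per letter).
#'
#' @param path Path to the matrix file.
#' @return An integer matrix.
#' @export
read_substitution_matrix <- function(path) {
  if (!file.exists(path)) {
    abort_pmhc(sprintf("matrix file not found: %s", path), "pmhc_io_error")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  labs <- vapply(rows, `[[`, character(1), 1)
  vals <- t(vapply(rows, function(r) as.integer(r[-1]), integer(length(header))))
  dimnames(vals) <- list(labs, header)
  if (!isTRUE(all.equal(unname(vals[header, header]),
                        unname(t(vals[header, header]))))) {
    abort_pmhc("substitution matrix is not symmetric", "pmhc_matrix_error")
  }
  vals
}

#' Write a substitution matrix in NCBI format
#'
#' @param mat Integer matrix with letter dimnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_substitution_matrix <- function(mat, path) {
  letters <- colnames(mat)
  lines <- c(paste(" ", paste(letters, collapse = " ")),
             vapply(letters, function(l) {
               paste(l, paste(sprintf("%3d", mat[l, letters]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Look up a substitution score
#'
#' @param matrix A substitution matrix (see [substitution_matrix()]).
#' @param a,b Single residue letters (vectorized).
#' @return Integer score(s); symmetric in `a` and `b`.
#' @export
substitution_score <- function(matrix, a, b) {
  bad <- setdiff(unique(c(a, b)), rownames(matrix))
  if (length(bad) > 0L) {
    abort_pmhc(sprintf("letter(s) not in matrix alphabet: %s",
                       paste(bad, collapse = ", ")),
               "pmhc_alphabet_error")
  }
  as.integer(matrix[cbind(a, b)])
}

new_alignment_result <- function(score, aligned_a, aligned_b) {
  ca <- seq_to_chars(aligned_a)
  cb <- seq_to_chars(aligned_b)
  cols <- ca != "-" | cb != "-"
  identity_pct <- 100 * sum(ca == cb & cols) / sum(cols)
  structure(list(score = score, aligned_a = aligned_a, aligned_b = aligned_b,
                 identity_pct = identity_pct),
            class = "pmhc_alignment")
}

#' @export
print.pmhc_alignment <- function(x, ...) {
  cat(sprintf("<alignment> score %s, identity %.1f%%\n  %s\n  %s\n",
              format(x$score), x$identity_pct, x$aligned_a, x$aligned_b))
  invisible(x)
}

#' Global pairwise alignment with affine gaps
#'
#' Optimal Needleman-Wunsch alignment (end gaps penalized) where a gap of
#' length L costs `gap_open + L * gap_extend`. Identity is computed over
#' aligned columns, excluding double-gap columns.
#'
#' @param a,b Amino-acid sequences (strings).
#' @param matrix Substitution matrix; default BLOSUM62.
#' @param gap_open,gap_extend Affine gap costs (positive).
#' @return A `pmhc_alignment`: `score`, `aligned_a`, `aligned_b`,
#'   `identity_pct`.
#' @export
global_align <- function(a, b, matrix = substitution_matrix("BLOSUM62"),
                         gap_open = 11, gap_extend = 1) {
  check_aa_string(a, "sequence a")
  check_aa_string(b, "sequence b")
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  new_alignment_result(
    score = Biostrings::score(pa),
    aligned_a = as.character(Biostrings::alignedPattern(pa)),
    aligned_b = as.character(Biostrings::alignedSubject(pa)))
}

#' Percentage identity between two sequences
#'
#' @inheritParams global_align
#' @return Identity over aligned columns, in percent.
#' @export
sequence_identity <- function(a, b, matrix = substitution_matrix("BLOSUM62"),
                              gap_open = 11, gap_extend = 1) {
  global_align(a, b, matrix, gap_open, gap_extend)$identity_pct
}

as_sequence_records <- function(reference) {
  if (is.data.frame(reference)) {
    tibble(id = as.character(reference$id), seq = as.character(reference$seq))
  } else if (is.character(reference) && !is.null(names(reference))) {
    tibble(id = names(reference), seq = unname(reference))
  } else {
    abort_pmhc("reference must be a tibble with id/seq or a named character vector",
               "pmhc_config_error")
  }
}

#' Assign an allele name to an MHC sequence
#'
#' Aligns the query against every reference allele sequence and returns the
#' best-identity allele (ties broken lexicographically by allele id).
#'
#' @param mhc_seq Query chain sequence.
#' @param reference Reference set: tibble with `id`, `seq` columns or a named
#'   character vector (names = allele ids).
#' @inheritParams global_align
#' @return One-row tibble: `allele`, `identity_pct`.
#' @export
assign_allele_name <- function(mhc_seq, reference,
                               matrix = substitution_matrix("BLOSUM62"),
                               gap_open = 11, gap_extend = 1) {
  ref <- as_sequence_records(reference)
  if (nrow(ref) == 0L) {
    abort_pmhc("reference allele set is empty", "pmhc_config_error")
  }
  check_aa_string(mhc_seq, "query sequence")
  ids <- map_dbl(ref$seq, function(s) {
    sequence_identity(mhc_seq, s, matrix, gap_open, gap_extend)
  })
  ord <- order(-ids, ref$id)
  tibble(allele = ref$id[ord[1]], identity_pct = ids[ord[1]])
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Tibble with `id` and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort_pmhc(sprintf("FASTA file not found: %s", path), "pmhc_io_error")
  }
  ss <- Biostrings::readAAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(ss)), seq = unname(as.character(ss)))
}

#' Write protein sequences to FASTA
#'
#' @param records Tibble with `id` and `seq` (or named character vector).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  rec <- as_sequence_records(records)
  ss <- Biostrings::AAStringSet(setNames(rec$seq, rec$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
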