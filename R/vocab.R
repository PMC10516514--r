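#' Amino-acid vocabulary
#'
#' The model's token alphabet: the 20 standard amino acids in alphabetical
#' one-letter order, preceded by the padding character `"0"` at index 0.
#' Residue indices are therefore 1..20 and are stable across sessions.
#'
#' @return Character vector of length 21; names are the tokens, values their
#'   integer indices (pad = 0).
#' @export
#' @examples
#' v <- aa_vocabulary()
#' v[["A"]]  # 1
#' v[["0"]]  # 0 (padding)
aa_vocabulary <- function() {
  tokens <- c("0", strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  stats::setNames(seq_along(tokens) - 1L, tokens)
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# fast residue -> index lookup table over raw byte values
.aa_lookup <- local({
  tab <- rep(NA_integer_, 256L)
  tab[utf8ToInt("0") + 1L] <- 0L
  codes <- vapply(.AA20, utf8ToInt, integer(1))
  tab[codes + 1L] <- seq_along(codes)
  tab
})

#' Convert residue strings to integer index vectors
#'
#' @param x character vector of residue strings.
#' @return list of integer vectors (0 = pad, 1..20 = residues).
#' @keywords internal
aa_indices <- function(x) {
  lapply(x, function(s) {
    idx <- .aa_lookup[utf8ToInt(s) + 1L]
    if (anyNA(idx)) {
      bad <- unique(strsplit(s, "")[[1]][is.na(idx)])
      stop("sequence contains non-standard residue(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    idx
  })
}

#' Encode a peptide as a fixed-length index vector
#'
#' Peptides of length 8 to `model_length` are right-padded with the pad index 0
#' so that the N-terminal anchor positions stay aligned across lengths.
#'
#' @param peptide single residue string (length 8..`model_length`).
#' @param model_length model input length (default 15).
#' @return integer vector of length `model_length`.
#' @export
#' @examples
#' encode_peptide("ACDEFGHIK")  # 9 residue indices then six zeros
encode_peptide <- function(peptide, model_length = 15L) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  n <- nchar(peptide)
  if (n < 8L || n > model_length) {
    stop("peptide length ", n, " outside supported range [8, ",
         model_length, "]: ", peptide, call. = FALSE)
  }
  idx <- aa_indices(peptide)[[1]]
  if (any(idx == 0L)) {
    stop("peptide may not contain the padding character: ", peptide,
         call. = FALSE)
  }
  c(idx, integer(model_length - n))
}

#' Encode a batch of peptides as an index matrix
#'
#' @param peptides character vector.
#' @inheritParams encode_peptide
#' @return integer matrix, one row per peptide, `model_length` columns.
#' @export
encode_peptides <- function(peptides, model_length = 15L) {
  out <- matrix(0L, nrow = length(peptides), ncol = model_length)
  idx <- aa_indices(peptides)
  for (i in seq_along(idx)) {
    v <- idx[[i]]
    n <- length(v)
    if (n < 8L || n > model_length) {
      stop("peptide length ", n, " outside supported range [8, ",
           model_length, "]: ", peptides[i], call. = FALSE)
    }
    if (any(v == 0L)) {
      stop("peptide may not contain the padding character: ", peptides[i],
           call. = FALSE)
    }
    out[i, seq_len(n)] <- v
  }
  out
}

#' Encode an MHC pseudo-sequence
#'
#' @param pseudo 34-residue string.
#' @return integer vector of length 34 (indices 1..20).
#' @export
encode_pseudo <- function(pseudo) {
  stopifnot(is.character(pseudo), length(pseudo) == 1L)
  if (nchar(pseudo) != 34L) {
    stop("pseudo-sequence must have exactly 34 residues, got ",
         nchar(pseudo), call. = FALSE)
  }
  idx <- aa_indices(pseudo)[[1]]
  if (any(idx == 0L)) {
    stop("pseudo-sequence may not contain the padding character",
         call. = FALSE)
  }
  idx
}

#' Length bin of a peptide
#'
#' Benchmark reporting groups peptides into the bins 8, 9, 10, 11 and >=12.
#'
#' @param length integer vector of peptide lengths.
#' @return character vector in `c("8","9","10","11","ge12")`.
#' @export
length_bin <- function(length) {
  ifelse(length >= 12L, "ge12", as.character(length))
}
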