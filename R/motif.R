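# Binding-motif extraction: score a large random peptide set, keep the top
# fraction of predicted binders, and tally a position-frequency matrix with
# per-position information content (the data behind a sequence logo).

#' Sample background peptides
#'
#' Draws random peptides either i.i.d. uniformly over the 20 standard residues
#' (`source = NULL`) or as contiguous windows from a protein source (a FASTA
#' file path or a character vector of protein sequences). In windowed mode,
#' records are weighted by their number of valid start positions, so every
#' window across the source is equally likely. Windows containing non-standard
#' residues are rejected and resampled.
#'
#' @param n number of peptides.
#' @param length peptide length.
#' @param source `NULL`, FASTA path, or character vector of protein sequences.
#' @param seed RNG seed.
#' @return character vector of `n` peptides.
#' @export
sample_background_peptides <- function(n, length, source = NULL, seed = NULL) {
  stopifnot(n >= 1L, length >= 1L)
  with_seed(seed, {
    if (is.null(source)) {
      return(vapply(seq_len(n), function(i)
        paste(sample(.AA20, length, replace = TRUE), collapse = ""),
        character(1)))
    }
    seqs <- if (length(source) == 1L && file.exists(source)) {
      fa <- seqinr::read.fasta(source, seqtype = "AA", as.string = TRUE)
      toupper(vapply(fa, `[[`, "", 1L))
    } else toupper(source)
    nlen <- nchar(seqs)
    weights <- pmax(nlen - length + 1L, 0L)
    if (all(weights == 0L))
      stop("no source protein long enough for windows of length ", length,
           call. = FALSE)
    out <- character(0)
    tries <- 0L
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 1000L)
        stop("no valid windows without non-standard residues in source",
             call. = FALSE)
      m <- n - length(out)
      rec <- sample.int(length(seqs), m, replace = TRUE, prob = weights)
      start <- vapply(rec, function(r)
        sample.int(weights[r], 1L), integer(1))
      cand <- substr(seqs[rec], start, start + length - 1L)
      ok <- !grepl(paste0("[^", paste(.AA20, collapse = ""), "]"), cand)
      out <- c(out, cand[ok])
    }
    out
  })
}

#' Extract a binding motif from a trained model
#'
#' Scores `n` random peptides of the given length for one allele, keeps the
#' `ceiling(n * top_fraction)` highest-scoring ones (ties broken by
#' lexicographic peptide order, for determinism) and tallies per-position
#' residue frequencies together with per-position information content.
#'
#' @param model a fitted model or ensemble (anything with a `predict` method
#'   accepting `allele` and `peptide` arguments).
#' @param allele allele name known to the model.
#' @param length peptide length of the motif.
#' @param n number of background peptides to score (default 100000).
#' @param top_fraction fraction of top-scoring peptides kept (default 0.01).
#' @param source background source passed to [sample_background_peptides()].
#' @param seed RNG seed for the background sample.
#' @return object of class `motif_matrix`: list with `length`, `frequencies`
#'   (length x 20 matrix, rows summing to 1), `ic` (bits, in
#'   \[0, log2(20)\]), and `n_sequences`.
#' @export
extract_motif <- function(model, allele, length, n = 100000L,
                          top_fraction = 0.01, source = NULL, seed = NULL) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  peptides <- sample_background_peptides(n, length, source = source,
                                         seed = seed)
  scores <- stats::predict(model, allele = rep(allele, length(peptides)),
                           peptide = peptides)
  k <- ceiling(n * top_fraction)
  ord <- order(-scores, peptides)
  motif_from_peptides(peptides[ord[seq_len(k)]])
}

#' Position-frequency matrix with information content from peptides
#'
#' @param peptides character vector of equal-length peptides.
#' @return `motif_matrix` object.
#' @export
motif_from_peptides <- function(peptides) {
  L <- unique(nchar(peptides))
  if (length(L) != 1L)
    stop("all peptides must share one length", call. = FALSE)
  mat <- do.call(rbind, lapply(aa_indices(peptides), identity))
  freq <- matrix(0, nrow = L, ncol = 20L,
                 dimnames = list(NULL, .AA20))
  for (p in seq_len(L)) {
    tab <- tabulate(mat[, p], nbins = 20L)
    freq[p, ] <- tab / length(peptides)
  }
  ic <- apply(freq, 1L, function(f) {
    f <- f[f > 0]
    log2(20) + sum(f * log2(f))
  })
  structure(list(length = L, frequencies = freq, ic = as.numeric(ic),
                 n_sequences = length(peptides)),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat("Binding motif, length", x$length, "from", x$n_sequences,
      "peptides\n")
  cat("Information content (bits):",
      paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  top <- apply(x$frequencies, 1L, function(f) .AA20[which.max(f)])
  cat("Consensus:", paste(top, collapse = ""), "\n")
  invisible(x)
}

#' Anchor positions of a motif
#'
#' Convenience accessor: positions ranked by decreasing information content.
#'
#' @param motif `motif_matrix` object.
#' @param k number of positions to return (default 2).
#' @return integer vector of the `k` highest-IC positions.
#' @export
motif_anchors <- function(motif, k = 2L) {
  order(-motif$ic)[seq_len(k)]
}

#' Write a motif matrix as TSV
#'
#' Header: the 20 residue letters plus `IC`; one row per position with
#' frequencies and the position's information content.
#'
#' @param motif `motif_matrix` object.
#' @param path output path.
#' @export
write_motif <- function(motif, path) {
  df <- as.data.frame(motif$frequencies)
  df$IC <- motif$ic
  header <- paste(c(.AA20, "IC"), collapse = "\t")
  body <- apply(df, 1L, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a motif matrix written by [write_motif()]
#'
#' @param path file path.
#' @return `motif_matrix` object (with `n_sequences = NA`).
#' @export
read_motif <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  freq <- as.matrix(df[, .AA20, drop = FALSE])
  dimnames(freq) <- list(NULL, .AA20)
  structure(list(length = nrow(df), frequencies = freq,
                 ic = df$IC, n_sequences = NA_integer_),
            class = "motif_matrix")
}
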