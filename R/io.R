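# Readers/writers for the on-disk formats and the binding-table container.
#
# A binding table is a data.frame with columns
#   allele, peptide, affinity, origin ("measured"/"artificial_negative"),
#   fold (integer or NA), length, length_bin
# carrying the allele -> 34-residue pseudo-sequence map as attribute "pseudo".

#' Evaluate an expression under a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a binding table
#'
#' @param records data.frame with at least columns `allele`, `peptide`,
#'   `affinity`; optional `origin`, `fold`.
#' @param pseudo named character vector mapping allele names to 34-residue
#'   pseudo-sequences; must cover every allele in `records`.
#' @return validated binding table (class `binding_table`).
#' @export
binding_table <- function(records, pseudo) {
  stopifnot(is.data.frame(records),
            all(c("allele", "peptide", "affinity") %in% names(records)))
  if (length(pseudo) &&
      (is.null(names(pseudo)) || any(!nzchar(names(pseudo)))))
    stop("pseudo map must be a named character vector", call. = FALSE)
  if (!is.null(records$affinity) &&
      any(records$affinity < 0 | records$affinity > 1))
    stop("affinity values must lie in [0, 1]", call. = FALSE)
  missing_alleles <- setdiff(unique(records$allele), names(pseudo))
  if (length(missing_alleles))
    stop("allele(s) missing from pseudo map: ",
         paste(missing_alleles, collapse = ", "), call. = FALSE)
  for (a in names(pseudo)) encode_pseudo(pseudo[[a]])  # validates
  if (is.null(records$origin))
    records$origin <- rep("measured", nrow(records))
  if (is.null(records$fold))
    records$fold <- rep(NA_integer_, nrow(records))
  records$length <- nchar(records$peptide)
  records$length_bin <- length_bin(records$length)
  out <- records[, c("allele", "peptide", "affinity", "origin", "fold",
                     "length", "length_bin")]
  rownames(out) <- NULL
  attr(out, "pseudo") <- pseudo[sort(unique(c(names(pseudo))))]
  class(out) <- c("binding_table", "data.frame")
  out
}

#' Pseudo-sequence map of a binding table
#' @param table binding table.
#' @return named character vector.
#' @export
pseudo_map <- function(table) attr(table, "pseudo")

#' Read an allele -> pseudo-sequence map
#'
#' Two-column whitespace/tab separated file: allele name, 34-residue
#' pseudo-sequence. Duplicate identical rows are deduplicated; duplicates with
#' conflicting sequences are an error.
#'
#' @param path file path.
#' @return named character vector (allele -> pseudo-sequence).
#' @export
read_pseudo_map <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed pseudo-map row at line ", bad[1], call. = FALSE)
  allele <- vapply(parts, `[[`, "", 1L)
  seqs <- vapply(parts, `[[`, "", 2L)
  for (i in seq_along(allele)) {
    if (nchar(seqs[i]) != 34L)
      stop("pseudo-sequence for ", allele[i], " has length ", nchar(seqs[i]),
           ", expected 34", call. = FALSE)
    encode_pseudo(seqs[i])
  }
  dup <- duplicated(allele)
  if (any(dup)) {
    for (a in unique(allele[dup])) {
      if (length(unique(seqs[allele == a])) > 1L)
        stop("conflicting pseudo-sequences for allele ", a, call. = FALSE)
    }
  }
  stats::setNames(seqs[!dup], allele[!dup])
}

#' Read a binding-affinity table
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`netmhcpan_train`}{whitespace-separated columns
#'     `peptide target allele [fold]`, `#` comments allowed; `target` is the
#'     already-normalized affinity in \[0,1\].}
#'   \item{`tsv_ic50`}{TSV with header `allele  peptide  ic50_nm`; raw IC50
#'     values are passed through [transform_ic50()].}
#' }
#' Peptides shorter than 8 or longer than `max_length` residues are skipped
#' with a warning (model input cap), not an error.
#'
#' @param path file path.
#' @param dialect `"netmhcpan_train"` or `"tsv_ic50"`.
#' @param pseudo named character vector (see [read_pseudo_map()]).
#' @param strict if `TRUE` (default) an allele absent from `pseudo` is an
#'   error; otherwise its rows are dropped with a warning.
#' @param fold_file optional sidecar file with one integer fold id per
#'   retained data row.
#' @param max_length model input length cap (default 15).
#' @return a [binding_table()].
#' @export
read_binding_table <- function(path,
                               dialect = c("netmhcpan_train", "tsv_ic50"),
                               pseudo,
                               strict = TRUE,
                               fold_file = NULL,
                               max_length = 15L) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- trimws(lines[keep])

  if (dialect == "netmhcpan_train") {
    parts <- strsplit(lines, "[ \t]+")
    nf <- lengths(parts)
    bad <- which(nf < 3L | nf > 4L)
    if (length(bad))
      stop("malformed row at line ", lineno[bad[1]], " of ", path,
           call. = FALSE)
    peptide <- vapply(parts, `[[`, "", 1L)
    target <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    allele <- vapply(parts, `[[`, "", 3L)
    fold <- rep(NA_integer_, length(parts))
    has4 <- nf == 4L
    if (any(has4))
      fold[has4] <- as.integer(vapply(parts[has4], `[[`, "", 4L))
    if (anyNA(target))
      stop("non-numeric target at line ", lineno[which(is.na(target))[1]],
           " of ", path, call. = FALSE)
    if (any(target < 0 | target > 1))
      stop("target outside [0,1] at line ",
           lineno[which(target < 0 | target > 1)[1]], " of ", path,
           call. = FALSE)
    affinity <- target
  } else {
    header <- strsplit(lines[1], "\t")[[1]]
    if (!identical(tolower(header), c("allele", "peptide", "ic50_nm")))
      stop("tsv_ic50 dialect requires header 'allele\\tpeptide\\tic50_nm'",
           call. = FALSE)
    parts <- strsplit(lines[-1], "\t")
    lineno <- lineno[-1]
    bad <- which(lengths(parts) != 3L)
    if (length(bad))
      stop("malformed row at line ", lineno[bad[1]], " of ", path,
           call. = FALSE)
    allele <- vapply(parts, `[[`, "", 1L)
    peptide <- vapply(parts, `[[`, "", 2L)
    ic50 <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    if (anyNA(ic50) || any(ic50 <= 0))
      stop("invalid ic50 at line ",
           lineno[which(is.na(ic50) | ic50 <= 0)[1]], " of ", path,
           call. = FALSE)
    affinity <- transform_ic50(ic50)
    fold <- rep(NA_integer_, length(parts))
  }

  len <- nchar(peptide)
  oversize <- len > max_length | len < 8L
  if (any(oversize)) {
    warning(sum(oversize), " peptide(s) outside length range [8, ",
            max_length, "] skipped", call. = FALSE)
    peptide <- peptide[!oversize]; affinity <- affinity[!oversize]
    allele <- allele[!oversize]; fold <- fold[!oversize]
  }

  unknown <- setdiff(unique(allele), names(pseudo))
  if (length(unknown)) {
    if (strict)
      stop("allele(s) not in pseudo map: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    warning("dropping rows for allele(s) not in pseudo map: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    ok <- !(allele %in% unknown)
    peptide <- peptide[ok]; affinity <- affinity[ok]
    allele <- allele[ok]; fold <- fold[ok]
  }

  if (!is.null(fold_file)) {
    f <- as.integer(readLines(fold_file))
    if (length(f) != length(peptide))
      stop("fold sidecar has ", length(f), " entries for ", length(peptide),
           " data rows", call. = FALSE)
    fold <- f
  }

  binding_table(data.frame(allele = allele, peptide = peptide,
                           affinity = affinity, fold = fold,
                           stringsAsFactors = FALSE),
                pseudo[intersect(names(pseudo), unique(allele))])
}

#' Write a binding table in the training dialect
#'
#' Columns `peptide target allele [fold]`, whitespace-separated; the fold
#' column is written only when any fold id is present.
#'
#' @param table binding table.
#' @param path output path.
#' @export
write_binding_table <- function(table, path) {
  has_fold <- any(!is.na(table$fold))
  lines <- if (has_fold) {
    paste(table$peptide, format(table$affinity, digits = 17, trim = TRUE),
          table$allele, ifelse(is.na(table$fold), -1L, table$fold))
  } else {
    paste(table$peptide, format(table$affinity, digits = 17, trim = TRUE),
          table$allele)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a pseudo-sequence map
#' @param pseudo named character vector.
#' @param path output path.
#' @export
write_pseudo_map <- function(pseudo, path) {
  writeLines(paste(names(pseudo), pseudo, sep = "\t"), path)
  invisible(path)
}

#' Write predictions as TSV
#'
#' Columns: allele, peptide, length, pred_affinity, pred_ic50_nm, binder.
#'
#' @param predictions data.frame with columns `allele`, `peptide`,
#'   `pred_affinity`.
#' @param path output path.
#' @export
write_predictions <- function(predictions, path) {
  out <- data.frame(
    allele = predictions$allele,
    peptide = predictions$peptide,
    length = nchar(predictions$peptide),
    pred_affinity = predictions$pred_affinity,
    pred_ic50_nm = inverse_transform(predictions$pred_affinity),
    binder = classify_binder(predictions$pred_affinity))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Add random-peptide artificial negatives
#'
#' For each allele in the table, adds `per_length` random natural peptides at
#' each requested length with target affinity 0 and origin
#' `"artificial_negative"`. These records are used during training only and
#' are excluded from all evaluation sets.
#'
#' @param table binding table.
#' @param per_length peptides per allele per length (default 25).
#' @param lengths peptide lengths to draw (default 8:11).
#' @param background `NULL` for i.i.d. uniform residues, or a character vector
#'   of protein sequences / FASTA path sampled as contiguous windows.
#' @param seed RNG seed for reproducibility.
#' @return the augmented binding table.
#' @export
add_artificial_negatives <- function(table, per_length = 25L,
                                     lengths = c(8L, 9L, 10L, 11L),
                                     background = NULL, seed = NULL) {
  if (per_length <= 0L) return(table)
  alleles <- unique(table$allele)
  with_seed(seed, {
    rows <- lapply(alleles, function(a) {
      peps <- unlist(lapply(lengths, function(L)
        sample_background_peptides(per_length, L, source = background)))
      data.frame(allele = a, peptide = peps, affinity = 0,
                 origin = "artificial_negative", fold = NA_integer_,
                 stringsAsFactors = FALSE)
    })
    neg <- do.call(rbind, rows)
    out <- rbind(table[, c("allele", "peptide", "affinity", "origin", "fold")],
                 neg)
    binding_table(out, pseudo_map(table))
  })
}
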