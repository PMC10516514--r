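# Benchmark statistics: grouped AUC/PCC/SRCC with the standard reporting
# filters, the overall percent-rank aggregate, the Frank epitope statistic,
# and the exact one-tailed binomial sign test.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability: the mean over all
#' (positive, negative) pairs of the indicator that the positive scores
#' higher, ties counting one half (implemented via average ranks).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\], or `NA` when only one class is present.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pearson correlation coefficient
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return correlation in \[-1, 1\], `NA` when either input has zero
#'   variance.
#' @export
pcc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of average-rank-transformed data (ties get average
#' ranks).
#'
#' @inheritParams pcc
#' @return correlation in \[-1, 1\], `NA` on zero rank variance.
#' @export
srcc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Per-allele, per-length-bin metric report
#'
#' Groups measured records by (allele, length bin in 8/9/10/11/>=12),
#' applies the standard reporting filters -- a group is reported only when it
#' has more than 20 data points and at least three binders -- and computes
#' AUC (binder labels from the measured affinity at the 500 nM threshold),
#' PCC and SRCC of predictions against measured affinities. Aggregates are
#' unweighted means over reported groups per length bin.
#'
#' @param table binding table of measured records (artificial negatives are
#'   ignored).
#' @param predictions numeric vector of predicted affinities, parallel to
#'   `table` rows (entries for artificial negatives may be `NA`).
#' @param min_points,min_binders reporting filters (defaults 21 points i.e.
#'   "more than 20", and 3 binders).
#' @return object of class `metric_report`: list with `rows` (one line per
#'   reported group) and `aggregates` (per length bin).
#' @export
build_report <- function(table, predictions, min_points = 21L,
                         min_binders = 3L) {
  stopifnot(length(predictions) == nrow(table))
  measured <- table$origin == "measured"
  if (anyNA(predictions[measured])) {
    bad <- which(measured & is.na(predictions))
    stop("missing predictions for measured record(s), e.g. ",
         paste(utils::head(paste(table$allele[bad], table$peptide[bad]), 3L),
               collapse = "; "), call. = FALSE)
  }
  tab <- table[measured, ]
  pred <- predictions[measured]
  labels <- classify_binder(tab$affinity)
  key <- interaction(tab$allele, tab$length_bin, drop = TRUE)
  rows <- lapply(levels(key), function(kk) {
    sel <- key == kk
    n <- sum(sel)
    nb <- sum(labels[sel])
    if (n < min_points || nb < min_binders) return(NULL)
    data.frame(allele = tab$allele[sel][1],
               length_bin = tab$length_bin[sel][1],
               n = n, n_binders = nb,
               auc = auc(pred[sel], labels[sel]),
               pcc = pcc(pred[sel], tab$affinity[sel]),
               srcc = srcc(pred[sel], tab$affinity[sel]),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  aggregates <- NULL
  if (!is.null(rows) && nrow(rows)) {
    aggregates <- do.call(rbind, lapply(split(rows, rows$length_bin),
      function(g) data.frame(length_bin = g$length_bin[1],
                             n_groups = nrow(g),
                             auc = mean(g$auc, na.rm = TRUE),
                             pcc = mean(g$pcc, na.rm = TRUE),
                             srcc = mean(g$srcc, na.rm = TRUE),
                             stringsAsFactors = FALSE)))
    rownames(aggregates) <- NULL
  }
  structure(list(rows = rows, aggregates = aggregates),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Metric report:", if (is.null(x$rows)) 0 else nrow(x$rows),
      "reported (allele, length-bin) groups\n")
  if (!is.null(x$aggregates)) {
    cat("Aggregates per length bin:\n")
    print(x$aggregates, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write / read a metric report as TSV
#'
#' Per-group lines first, then an aggregate block introduced by a line
#' starting with `#aggregate`.
#'
#' @param report `metric_report`.
#' @param path file path.
#' @export
write_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(report$rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(report$aggregates)) {
    writeLines("#aggregate", con)
    utils::write.table(report$aggregates, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  cut <- match("#aggregate", lines)
  rows <- utils::read.table(text = lines[seq_len(if (is.na(cut))
    length(lines) else cut - 1L)], header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, colClasses = c(length_bin = "character"))
  aggregates <- NULL
  if (!is.na(cut))
    aggregates <- utils::read.table(text = lines[(cut + 1L):length(lines)],
                                    header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE,
                                    colClasses = c(length_bin = "character"))
  structure(list(rows = rows, aggregates = aggregates),
            class = "metric_report")
}

#' Percent rank of one method among N
#'
#' `PR = (n_l - 1) / (N - 1) * 100` where `n_l` counts the methods (including
#' the method itself) with an equal or lower value, so the best of N distinct
#' values scores 100 and the worst 0; tied methods share the higher rank.
#'
#' @param values metric values, one per method (N >= 2).
#' @param method_index index of the method of interest.
#' @return percent rank in \[0, 100\].
#' @export
percent_rank <- function(values, method_index) {
  N <- length(values)
  if (N < 2L) stop("percent rank needs at least two methods", call. = FALSE)
  n_l <- sum(values <= values[method_index])
  (n_l - 1) / (N - 1) * 100
}

#' Overall percent-rank aggregate over metrics and datasets
#'
#' Mean of [percent_rank()] over all M metrics and D datasets for one method:
#' `Ov = 1/(M D) * sum_i sum_j PR(m_i(d_j))`.
#'
#' @param values 3-d array of metric values with dimensions
#'   (metric, method, dataset).
#' @param method_index method column of interest.
#' @return Ov in \[0, 100\].
#' @export
overall_metric <- function(values, method_index) {
  stopifnot(length(dim(values)) == 3L)
  if (anyNA(values))
    stop("metric x method x dataset matrix has missing cells", call. = FALSE)
  M <- dim(values)[1]; D <- dim(values)[3]
  total <- 0
  for (i in seq_len(M)) for (j in seq_len(D))
    total <- total + percent_rank(values[i, , j], method_index)
  total / (M * D)
}

#' Frank statistic for one epitope
#'
#' Fraction of same-length peptides from the epitope's source protein with a
#' prediction score strictly greater than the epitope's: `Frank = n_p /
#' N_all`. 0 means the epitope is top-ranked; peptides tied with the epitope
#' do not count against it.
#'
#' @param scores scores of all `N_all` peptides tiled over the source
#'   protein (the epitope included).
#' @param epitope_index position of the epitope in `scores`.
#' @return Frank value in \[0, (N_all - 1)/N_all\].
#' @export
frank <- function(scores, epitope_index) {
  stopifnot(length(scores) >= 1L, epitope_index >= 1L,
            epitope_index <= length(scores))
  sum(scores > scores[epitope_index]) / length(scores)
}

#' One-tailed exact binomial sign test
#'
#' Compares two methods over D datasets from per-dataset performance
#' differences: ties are excluded, and the p-value is the exact upper tail
#' `P(X >= wins)` for `X ~ Binomial(wins + losses, 1/2)`.
#'
#' @param deltas per-dataset differences (method A minus method B).
#' @return object of class `sign_test`: list with `wins`, `losses`, `ties`,
#'   `p_value` (`NA` when every dataset is tied).
#' @export
sign_test <- function(deltas) {
  stopifnot(length(deltas) >= 1L)
  wins <- sum(deltas > 0)
  losses <- sum(deltas < 0)
  ties <- sum(deltas == 0)
  n <- wins + losses
  p <- if (n == 0L) NA_real_ else
    stats::pbinom(wins - 1L, n, 0.5, lower.tail = FALSE)
  structure(list(wins = wins, losses = losses, ties = ties, p_value = p),
            class = "sign_test")
}

#' @export
print.sign_test <- function(x, ...) {
  cat(sprintf(
    "Sign test: %d wins / %d losses (%d ties excluded), one-tailed p = %.3g\n",
    x$wins, x$losses, x$ties, x$p_value))
  invisible(x)
}
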