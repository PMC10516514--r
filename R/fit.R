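# Model fitting: MSE loss, Adadelta with weight decay, reduce-on-plateau
# learning-rate schedule, 5-fold cross-validation repeated with fresh
# initializations, and prediction averaging over the resulting ensemble.

#' Assign cross-validation folds
#'
#' If any measured record already carries a fold id (e.g. read from a file),
#' the table is returned unchanged: provided splits are authoritative.
#' Otherwise records are grouped by peptide sequence (identical peptides
#' always share a fold, a guard against trivial train/test leakage), the
#' groups are shuffled and dealt round-robin into `folds` balanced folds.
#' Artificial negatives never receive a fold: they join every training
#' partition and no validation partition.
#'
#' @param table binding table.
#' @param folds number of folds F (default 5).
#' @param seed RNG seed.
#' @return the table with its `fold` column populated (0 .. F-1).
#' @export
assign_folds <- function(table, folds = 5L, seed = NULL) {
  measured <- table$origin == "measured"
  if (any(!is.na(table$fold[measured]))) return(table)
  groups <- unique(table$peptide[measured])
  if (folds > length(groups))
    stop("more folds (", folds, ") than distinct peptides (",
         length(groups), ")", call. = FALSE)
  with_seed(seed, {
    shuffled <- sample(groups)
    fold_of <- stats::setNames(rep_len(0:(folds - 1L), length(shuffled)),
                               shuffled)
    table$fold[measured] <- unname(fold_of[table$peptide[measured]])
  })
  table
}

# parameter names actually updated by the optimizer for a given config
.trainable_names <- function(params, config) {
  nm <- names(params)
  if (config$embedding_mode == "one_hot") nm <- setdiff(nm, "E")
  if (!config$use_gate)
    nm <- setdiff(nm, c("gate_W", "gate_V", "gate_b", "gate_c"))
  if (!config$use_residual)
    nm <- nm[!grepl("_b1_", nm) & !grepl("^bn_b1_", nm)]
  nm
}

#' Fit a single binding-affinity model
#'
#' Minimizes the mean squared error between predicted and measured affinity
#' by mini-batch Adadelta (decay rho 0.9, eps 1e-6) with weight decay, for a
#' fixed number of epochs; the learning rate starts at `lr` and is reduced by
#' `factor` when the monitored MSE has not improved for more than `patience`
#' epochs. When `held_out_fold` is given, records of that fold are held out
#' for monitoring and artificial negatives (fold `NA`) stay in the training
#' partition; the final-epoch parameters are returned (no early stopping).
#'
#' @param table binding table (see [binding_table()], [assign_folds()]).
#' @param held_out_fold fold id excluded from training, or `NULL` to train on
#'   everything (the scheduler then monitors training MSE).
#' @param config `mhci_config`.
#' @param epochs training epochs (default 50).
#' @param batch_size mini-batch size (default 128).
#' @param lr initial Adadelta learning rate (default 0.9).
#' @param weight_decay L2 weight decay added to the gradient (default 1e-4).
#' @param patience scheduler patience in epochs (default 5).
#' @param factor learning-rate reduction factor (default 0.1).
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @param pseudo allele -> pseudo-sequence map (default: taken from `table`).
#' @param verbose print per-epoch losses.
#' @return object of class `mhci_model`.
#' @export
mhci_fit <- function(table, held_out_fold = NULL, config = mhci_config(),
                     epochs = 50L, batch_size = 128L, lr = 0.9,
                     weight_decay = 1e-4, patience = 5L, factor = 0.1,
                     seed = NULL, pseudo = pseudo_map(table),
                     verbose = FALSE) {
  if (is.null(held_out_fold)) {
    train_idx <- seq_len(nrow(table))
    val_idx <- integer(0)
  } else {
    train_idx <- which(is.na(table$fold) | table$fold != held_out_fold)
    val_idx <- which(!is.na(table$fold) & table$fold == held_out_fold &
                       table$origin == "measured")
    if (!length(train_idx))
      stop("held-out fold leaves no training records", call. = FALSE)
  }
  prep <- nn_prepare(table$allele, table$peptide, pseudo, config)
  y <- table$affinity

  with_seed(seed, {
    params <- mhci_init_params(config)
    buffers <- attr(params, "buffers")
    attr(params, "buffers") <- NULL
    trainable <- .trainable_names(params, config)
    sq <- nn_zero_grads(params)
    dacc <- nn_zero_grads(params)
    rho <- 0.9; eps <- 1e-6
    cur_lr <- lr
    best <- Inf; wait <- 0L
    history <- data.frame(epoch = integer(0), train_mse = numeric(0),
                          val_mse = numeric(0), lr = numeric(0))

    eval_mse <- function(idx) {
      if (!length(idx)) return(NA_real_)
      preds <- .predict_prepared(params, buffers, config, prep, idx)
      mean((preds - y[idx])^2)
    }

    for (ep in seq_len(epochs)) {
      perm <- sample(train_idx)
      tot <- 0
      for (start in seq(1L, length(perm), by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1L, length(perm))]
        batch <- list(P = prep$P[idx, , drop = FALSE], gid = prep$gid[idx],
                      pseudo_idx = prep$pseudo_idx)
        fw <- nn_forward_batch(params, buffers, config, batch, train = TRUE)
        buffers <- fw$buffers
        resid <- fw$yhat - y[idx]
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", ep,
               call. = FALSE)
        tot <- tot + loss * length(idx)
        gr <- nn_backward_batch(params, config, fw$cache,
                                2 * resid / length(idx))
        for (nm in trainable) {
          g <- gr[[nm]] + weight_decay * params[[nm]]
          sq[[nm]] <- rho * sq[[nm]] + (1 - rho) * g * g
          dlt <- sqrt((dacc[[nm]] + eps) / (sq[[nm]] + eps)) * g
          dacc[[nm]] <- rho * dacc[[nm]] + (1 - rho) * dlt * dlt
          params[[nm]] <- params[[nm]] - cur_lr * dlt
        }
        if (config$embedding_mode == "learned") params$E[1L, ] <- 0
      }
      train_mse <- tot / length(perm)
      val_mse <- eval_mse(val_idx)
      monitored <- if (is.na(val_mse)) train_mse else val_mse
      if (monitored < best) { best <- monitored; wait <- 0L }
      else {
        wait <- wait + 1L
        if (wait > patience) { cur_lr <- cur_lr * factor; wait <- 0L }
      }
      history <- rbind(history, data.frame(epoch = ep, train_mse = train_mse,
                                           val_mse = val_mse, lr = cur_lr))
      if (verbose)
        message(sprintf("epoch %3d  train MSE %.5f  val MSE %s  lr %.4g",
                        ep, train_mse,
                        ifelse(is.na(val_mse), "-", sprintf("%.5f", val_mse)),
                        cur_lr))
    }
    attr(params, "buffers") <- buffers
    structure(list(params = params, config = config, pseudo = pseudo,
                   history = history, held_out_fold = held_out_fold,
                   seed = seed, n_train = length(train_idx),
                   vocab = paste(names(aa_vocabulary()), collapse = "")),
              class = "mhci_model")
  })
}

# eval-mode predictions for a subset of a prepared pair set
.predict_prepared <- function(params, buffers, config, prep, idx,
                              batch_size = 2048L) {
  out <- numeric(length(idx))
  for (start in seq(1L, length(idx), by = batch_size)) {
    sel <- idx[start:min(start + batch_size - 1L, length(idx))]
    batch <- list(P = prep$P[sel, , drop = FALSE], gid = prep$gid[sel],
                  pseudo_idx = prep$pseudo_idx)
    fw <- nn_forward_batch(params, buffers, config, batch, train = FALSE,
                           keep_cache = FALSE)
    out[(start):(start + length(sel) - 1L)] <- fw$yhat
  }
  out
}

#' Predict binding affinities from a fitted model
#'
#' Deterministic inference-mode predictions (no dropout, frozen normalization
#' statistics): the same pair always yields the same value regardless of
#' batch composition.
#'
#' @param object `mhci_model`.
#' @param allele character vector of allele names (recycled if length 1).
#' @param peptide character vector of peptides.
#' @param pseudo optional extra allele -> pseudo-sequence entries for alleles
#'   unseen at training time.
#' @param ... unused.
#' @return numeric vector of predicted affinities in (0, 1).
#' @export
predict.mhci_model <- function(object, allele, peptide, pseudo = NULL, ...) {
  if (length(allele) == 1L) allele <- rep(allele, length(peptide))
  stopifnot(length(allele) == length(peptide))
  map <- c(object$pseudo, pseudo)
  map <- map[!duplicated(names(map))]
  prep <- nn_prepare(allele, peptide, map, object$config)
  params <- object$params
  .predict_prepared(params, attr(params, "buffers"), object$config, prep,
                    seq_along(peptide))
}

#' Train a cross-validated model ensemble
#'
#' Runs `repeats` rounds of F-fold cross-validation, each round with a fresh
#' random initialization (and a fresh fold assignment when folds were not
#' provided with the data), yielding `repeats * folds` models whose averaged
#' predictions form the final estimate. With the published protocol
#' (10 repeats of 5-fold CV) this is the 50-model bagging ensemble.
#' Artificial negatives, when requested, are regenerated each repeat with a
#' repeat-specific seed.
#'
#' @param table binding table of measured records.
#' @param config `mhci_config`.
#' @param repeats number of CV repetitions R (default 10).
#' @param folds folds per repetition F (default 5).
#' @param seed master seed; all per-model seeds derive from it.
#' @param negatives `NULL`, or a list of arguments for
#'   [add_artificial_negatives()] (e.g. `list(per_length = 25)`).
#' @param verbose print progress.
#' @param ... further arguments to [mhci_fit()] (epochs, batch_size, ...).
#' @return object of class `mhci_ensemble`.
#' @export
mhci_ensemble <- function(table, config = mhci_config(), repeats = 10L,
                          folds = 5L, seed = NULL, negatives = NULL,
                          verbose = FALSE, ...) {
  stopifnot(repeats >= 1L, folds >= 2L)
  file_folds <- any(!is.na(table$fold[table$origin == "measured"]))
  seeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                             repeats * (folds + 2L)),
                                  nrow = repeats))
  models <- list()
  logs <- list()
  for (r in seq_len(repeats)) {
    tab_r <- table
    if (!is.null(negatives))
      tab_r <- do.call(add_artificial_negatives,
                       c(list(table = tab_r, seed = seeds[r, folds + 1L]),
                         negatives))
    if (!file_folds)
      tab_r <- assign_folds(tab_r, folds = folds,
                            seed = seeds[r, folds + 2L])
    for (f in seq_len(folds) - 1L) {
      if (verbose) message("repeat ", r, " fold ", f)
      m <- mhci_fit(tab_r, held_out_fold = f, config = config,
                    seed = seeds[r, f + 1L], ...)
      models[[sprintf("repeat%d_fold%d", r, f)]] <- m
      logs[[sprintf("repeat%d_fold%d", r, f)]] <- m$history
    }
  }
  structure(list(models = models, repeats = repeats, folds = folds,
                 config = config, pseudo = pseudo_map(table),
                 seeds = seeds[, seq_len(folds), drop = FALSE],
                 training_log = logs),
            class = "mhci_ensemble")
}

#' Ensemble prediction: mean over member models
#'
#' @param object `mhci_ensemble`.
#' @inheritParams predict.mhci_model
#' @return numeric vector of averaged predicted affinities.
#' @export
predict.mhci_ensemble <- function(object, allele, peptide, pseudo = NULL,
                                  ...) {
  if (!length(object$models)) stop("empty ensemble", call. = FALSE)
  preds <- vapply(object$models, function(m)
    predict(m, allele = allele, peptide = peptide, pseudo = pseudo),
    numeric(if (length(allele) == 1L) length(peptide)
            else length(allele)))
  if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
}

#' @export
print.mhci_model <- function(x, ...) {
  cat("Pan-specific MHC-I binding affinity model\n")
  print(x$config)
  cat("  trained", nrow(x$history), "epochs on", x$n_train, "records")
  if (!is.null(x$held_out_fold))
    cat(" (fold", x$held_out_fold, "held out)")
  cat("\n")
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final train MSE %.5f%s\n", last$train_mse,
              if (!is.na(last$val_mse))
                sprintf(", held-out MSE %.5f", last$val_mse) else ""))
  cat("  parameters:", count_params(x$params, x$config), "\n")
  invisible(x)
}

#' @export
summary.mhci_model <- function(object, ...) {
  h <- object$history
  cat("Training history (", nrow(h), " epochs):\n", sep = "")
  print(h[unique(pmin(nrow(h), c(1, seq(5, nrow(h), by = 5), nrow(h)))), ],
        row.names = FALSE)
  invisible(h)
}

#' @export
coef.mhci_model <- function(object, ...) object$params

#' @export
plot.mhci_model <- function(x, ...) {
  h <- x$history
  ylim <- range(c(h$train_mse, h$val_mse), na.rm = TRUE)
  plot(h$epoch, h$train_mse, type = "l", xlab = "epoch", ylab = "MSE",
       ylim = ylim, ...)
  if (any(!is.na(h$val_mse)))
    graphics::lines(h$epoch, h$val_mse, lty = 2)
  graphics::legend("topright", c("train", "held-out"), lty = 1:2, bty = "n")
  invisible(x)
}

#' @export
residuals.mhci_model <- function(object, table, ...) {
  table$affinity - predict(object, allele = table$allele,
                           peptide = table$peptide)
}

#' @export
print.mhci_ensemble <- function(x, ...) {
  cat("Binding-model ensemble:", length(x$models), "models (",
      x$repeats, "repeats x", x$folds, "folds )\n")
  print(x$config)
  invisible(x)
}
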