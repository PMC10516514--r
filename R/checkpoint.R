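# Model checkpointing: a single file per model holding the configuration,
# all weights and normalization buffers, and the vocabulary string; loading
# re-validates shapes against the configuration.

# expected shape of every parameter array for a config
.expected_shapes <- function(config) {
  d <- config$embed_dim
  L <- config$model_length
  ng <- if (config$tie_gate) 1L else L
  sh <- list(E = c(21L, d),
             gate_W = c(d, d, ng), gate_V = c(d, d, ng),
             gate_b = c(d, ng), gate_c = c(d, ng))
  for (br in c("b1", "b2")) {
    for (i in seq_along(config$kernel_sizes)) {
      k <- config$kernel_sizes[i]; H <- config$kernel_counts[i]
      sh[[paste0("U_", br, "_", k)]] <- c(H * k, 34L)
      sh[[paste0("cb_", br, "_", k)]] <- H
    }
    sh[[paste0("bn_", br, "_g")]] <- config$d0
    sh[[paste0("bn_", br, "_b")]] <- config$d0
  }
  dims <- c(config$d0, config$fc_dims)
  for (n in seq_along(config$fc_dims)) {
    sh[[paste0("fc_W", n)]] <- c(dims[n + 1L], dims[n])
    sh[[paste0("fc_b", n)]] <- dims[n + 1L]
    sh[[paste0("bn_fc", n, "_g")]] <- dims[n + 1L]
    sh[[paste0("bn_fc", n, "_b")]] <- dims[n + 1L]
  }
  sh$out_w <- config$fc_dims[length(config$fc_dims)]
  sh$out_b <- 1L
  sh
}

#' Validate parameter shapes against a configuration
#'
#' @param params parameter set.
#' @param config `mhci_config`.
#' @return `TRUE` invisibly; errors on any mismatch.
#' @export
check_params <- function(params, config) {
  sh <- .expected_shapes(config)
  for (nm in names(sh)) {
    x <- params[[nm]]
    if (is.null(x)) stop("missing parameter ", nm, call. = FALSE)
    got <- if (is.array(x)) dim(x) else length(x)
    if (!identical(as.integer(got), as.integer(sh[[nm]])))
      stop("parameter ", nm, " has shape (",
           paste(got, collapse = ","), "), expected (",
           paste(sh[[nm]], collapse = ","), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Save / load a fitted model checkpoint
#'
#' One file per model, containing the configuration, every weight array, the
#' normalization running statistics, the pseudo-sequence map and the
#' vocabulary string. Loading verifies the vocabulary and all shapes.
#'
#' @param model `mhci_model`.
#' @param path checkpoint path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model`: the restored `mhci_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mhci_model"))
    stop("not a model checkpoint: ", path, call. = FALSE)
  if (!identical(model$vocab, paste(names(aa_vocabulary()), collapse = "")))
    stop("checkpoint vocabulary does not match this package", call. = FALSE)
  check_params(model$params, model$config)
  model
}

#' Save / load an ensemble as a checkpoint directory
#'
#' Writes `repeat<r>_fold<f>.ckpt` files plus a `manifest.json` describing
#' the configuration and per-model seeds.
#'
#' @param ensemble `mhci_ensemble`.
#' @param dir checkpoint directory (created if needed).
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(ensemble$models))
    save_model(ensemble$models[[nm]], file.path(dir, paste0(nm, ".ckpt")))
  manifest <- list(repeats = ensemble$repeats, folds = ensemble$folds,
                   models = names(ensemble$models),
                   seeds = ensemble$seeds,
                   config = unclass(ensemble$config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_ensemble
#' @return `load_ensemble`: the restored `mhci_ensemble`.
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  models <- lapply(manifest$models, function(nm)
    load_model(file.path(dir, paste0(nm, ".ckpt"))))
  names(models) <- manifest$models
  cfg <- models[[1]]$config
  structure(list(models = models, repeats = manifest$repeats,
                 folds = manifest$folds, config = cfg,
                 pseudo = models[[1]]$pseudo,
                 seeds = manifest$seeds, training_log = NULL),
            class = "mhci_ensemble")
}
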