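#' Model configuration
#'
#' Architecture hyperparameters of the anchor-aware binding model. Defaults
#' are the published configuration: input length 15, embedding dimension 16,
#' kernel counts 128/64/32 at sizes 9/11/13, two fully connected layers of
#' 256 and 128 units, ReLU activation, dropout 0.25, with both the
#' position-wise gated layer and the residual (two-branch) interaction
#' convolution enabled.
#'
#' @param model_length padded peptide input length L (default 15).
#' @param embed_dim embedding dimension d (default 16; forced to 21 when
#'   `embedding_mode = "one_hot"`).
#' @param kernel_spec named integer vector: kernel size -> kernel count; all
#'   sizes must be odd and >= 9.
#' @param fc_dims widths of the fully connected layers (default c(256, 128)).
#' @param dropout_rate dropout after each FC activation (default 0.25).
#' @param use_gate enable the position-wise gated layer (default TRUE).
#' @param use_residual enable the second (ungated-input) convolution branch
#'   with residual combination (default TRUE).
#' @param tie_gate share one set of gate parameters across positions
#'   (default FALSE: untied, position-specific gates).
#' @param embedding_mode `"learned"` (default) or `"one_hot"` (fixed
#'   indicator embeddings, d = 21).
#' @return object of class `mhci_config`.
#' @export
mhci_config <- function(model_length = 15L,
                        embed_dim = 16L,
                        kernel_spec = c("9" = 128L, "11" = 64L, "13" = 32L),
                        fc_dims = c(256L, 128L),
                        dropout_rate = 0.25,
                        use_gate = TRUE,
                        use_residual = TRUE,
                        tie_gate = FALSE,
                        embedding_mode = c("learned", "one_hot")) {
  embedding_mode <- match.arg(embedding_mode)
  ks <- as.integer(names(kernel_spec))
  if (any(is.na(ks)) || any(ks %% 2L == 0L) || any(ks < 9L))
    stop("kernel sizes must be odd integers >= 9", call. = FALSE)
  if (model_length < 9L)
    stop("model_length must be at least 9", call. = FALSE)
  if (!length(fc_dims))
    stop("fc_dims must be nonempty", call. = FALSE)
  if (embedding_mode == "one_hot") embed_dim <- 21L
  structure(list(model_length = as.integer(model_length),
                 embed_dim = as.integer(embed_dim),
                 kernel_sizes = ks,
                 kernel_counts = as.integer(unname(kernel_spec)),
                 fc_dims = as.integer(fc_dims),
                 dropout_rate = dropout_rate,
                 use_gate = isTRUE(use_gate),
                 use_residual = isTRUE(use_residual),
                 tie_gate = isTRUE(tie_gate),
                 embedding_mode = embedding_mode,
                 conv_width = as.integer(model_length - 9L + 1L),
                 d0 = as.integer(sum(kernel_spec))),
            class = "mhci_config")
}

#' @export
print.mhci_config <- function(x, ...) {
  cat("Binding model configuration\n")
  cat("  input length L =", x$model_length, ", embed dim d =", x$embed_dim,
      "(", x$embedding_mode, ")\n")
  cat("  kernels:", paste(sprintf("%d x size %d", x$kernel_counts,
                                  x$kernel_sizes), collapse = ", "),
      " (d0 =", x$d0, ")\n")
  cat("  FC widths:", paste(x$fc_dims, collapse = ", "),
      " dropout:", x$dropout_rate, "\n")
  cat("  gated layer:", x$use_gate,
      if (x$tie_gate) "(tied)" else "(untied)",
      " residual branch:", x$use_residual, "\n")
  invisible(x)
}

# uniform init with fan-in bound, PyTorch Linear style
.init_unif <- function(nr, nc, fan_in) {
  b <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

#' Initialize model parameters
#'
#' Learned embeddings are drawn from N(0, 1/d) with the pad row frozen at
#' zero; in one-hot mode the embedding table is a fixed 21 x 21 indicator
#' matrix (pad row zero). Linear maps use uniform fan-in initialization;
#' batch-norm scales start at 1 and shifts at 0.
#'
#' @param config `mhci_config`.
#' @param seed RNG seed.
#' @return parameter set (list of numeric arrays) with attribute `buffers`
#'   holding batch-norm running statistics.
#' @export
mhci_init_params <- function(config, seed = NULL) {
  with_seed(seed, {
    d <- config$embed_dim
    L <- config$model_length
    nk <- length(config$kernel_sizes)
    p <- list()
    if (config$embedding_mode == "one_hot") {
      # rows 2..21 are unit basis vectors; row 1 (pad) zero
      E <- matrix(0, 21L, 21L)
      E[cbind(2:21, 2:21)] <- 1
      p$E <- E
    } else {
      p$E <- matrix(stats::rnorm(21L * d) / sqrt(d), 21L, d)
      p$E[1L, ] <- 0
    }
    ng <- if (config$tie_gate) 1L else L
    p$gate_W <- array(stats::runif(d * d * ng, -1, 1) / sqrt(d), c(d, d, ng))
    p$gate_V <- array(stats::runif(d * d * ng, -1, 1) / sqrt(d), c(d, d, ng))
    p$gate_b <- matrix(0, d, ng)
    p$gate_c <- matrix(0, d, ng)
    for (br in c("b1", "b2")) {
      for (i in seq_len(nk)) {
        k <- config$kernel_sizes[i]
        H <- config$kernel_counts[i]
        p[[paste0("U_", br, "_", k)]] <- .init_unif(H * k, 34L, 34L)
        p[[paste0("cb_", br, "_", k)]] <-
          stats::runif(H, -1, 1) / sqrt(k * d)
      }
      p[[paste0("bn_", br, "_g")]] <- rep(1, config$d0)
      p[[paste0("bn_", br, "_b")]] <- rep(0, config$d0)
    }
    dims <- c(config$d0, config$fc_dims)
    for (n in seq_along(config$fc_dims)) {
      p[[paste0("fc_W", n)]] <- .init_unif(dims[n + 1L], dims[n], dims[n])
      p[[paste0("fc_b", n)]] <- rep(0, dims[n + 1L])
      p[[paste0("bn_fc", n, "_g")]] <- rep(1, dims[n + 1L])
      p[[paste0("bn_fc", n, "_b")]] <- rep(0, dims[n + 1L])
    }
    hN <- config$fc_dims[length(config$fc_dims)]
    p$out_w <- stats::runif(hN, -1, 1) / sqrt(hN)
    p$out_b <- 0
    buffers <- list()
    for (br in c("b1", "b2")) {
      buffers[[paste0("bn_", br, "_mean")]] <- rep(0, config$d0)
      buffers[[paste0("bn_", br, "_var")]] <- rep(1, config$d0)
    }
    for (n in seq_along(config$fc_dims)) {
      buffers[[paste0("bn_fc", n, "_mean")]] <- rep(0, config$fc_dims[n])
      buffers[[paste0("bn_fc", n, "_var")]] <- rep(1, config$fc_dims[n])
    }
    attr(p, "buffers") <- buffers
    p
  })
}

#' Number of trainable parameters
#'
#' Counts every entry of every trainable array (batch-norm running statistics
#' excluded; the frozen pad embedding row and, in one-hot mode, the fixed
#' embedding table are excluded too).
#'
#' @param params parameter set from [mhci_init_params()].
#' @param config matching `mhci_config`.
#' @return integer count.
#' @export
count_params <- function(params, config) {
  n <- sum(vapply(params, length, integer(1)))
  if (config$embedding_mode == "one_hot") {
    n <- n - length(params$E)
  } else {
    n <- n - ncol(params$E)  # frozen pad row
  }
  # unused branches still carry arrays; count reflects the stored set
  as.integer(n)
}
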