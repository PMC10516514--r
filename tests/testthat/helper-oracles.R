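# Independent naive-loop oracles used to pin down layer and metric semantics.
# These deliberately avoid the package's vectorized code paths.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_pseudo <- function() paste(sample(AA20, 34, replace = TRUE),
                                  collapse = "")
random_peptide <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

# elementwise gated-linear-unit oracle: loops over positions and output dims
oracle_gate <- function(X, params, config) {
  L <- nrow(X); d <- ncol(X)
  out <- matrix(0, L, d)
  for (i in seq_len(L)) {
    gi <- if (config$tie_gate) 1L else i
    for (r in seq_len(d)) {
      s1 <- params$gate_b[r, gi]
      s2 <- params$gate_c[r, gi]
      for (c in seq_len(d)) {
        s1 <- s1 + params$gate_W[r, c, gi] * X[i, c]
        s2 <- s2 + params$gate_V[r, c, gi] * X[i, c]
      }
      out[i, r] <- (1 / (1 + exp(-s1))) * s2
    }
  }
  out
}

# kernel-generation oracle: explicit triple loop over entries of U_i %*% Y
oracle_kernels <- function(Y, params, config, branch = 2L) {
  br <- paste0("b", branch)
  out <- list()
  for (i in seq_along(config$kernel_sizes)) {
    k <- config$kernel_sizes[i]; H <- config$kernel_counts[i]
    U <- params[[paste0("U_", br, "_", k)]]
    ks <- vector("list", H)
    for (h in seq_len(H)) {
      Ki <- matrix(0, k, ncol(Y))
      for (p in seq_len(k)) for (dd in seq_len(ncol(Y))) {
        s <- 0
        for (q in 1:34) s <- s + U[(h - 1L) * k + p, q] * Y[q, dd]
        Ki[p, dd] <- max(s, 0)
      }
      ks[[h]] <- Ki
    }
    out[[as.character(k)]] <- ks
  }
  out
}

# sliding-window convolution oracle over the padded input
oracle_bicl <- function(X_in, Y, params, config, branch = 2L) {
  L <- nrow(X_in); d <- ncol(X_in); w <- L - 9L + 1L
  kern <- oracle_kernels(Y, params, config, branch)
  br <- paste0("b", branch)
  blocks <- list()
  for (i in seq_along(config$kernel_sizes)) {
    k <- config$kernel_sizes[i]
    off <- (k - 9L) %/% 2L
    b <- params[[paste0("cb_", br, "_", k)]]
    Xp <- rbind(matrix(0, off, d), X_in, matrix(0, off, d))
    Ks <- kern[[as.character(k)]]
    Ck <- matrix(0, length(Ks), w)
    for (h in seq_along(Ks)) for (j in seq_len(w)) {
      s <- b[h]
      for (p in seq_len(k)) for (dd in seq_len(d))
        s <- s + Ks[[h]][p, dd] * Xp[j + p - 1L, dd]
      Ck[h, j] <- max(s, 0)
    }
    blocks[[i]] <- Ck
  }
  do.call(rbind, blocks)
}

# FC + max-pool + sigmoid head oracle with inference-mode normalization
oracle_head <- function(C0, params, config, buffers) {
  C <- C0
  for (n in seq_along(config$fc_dims)) {
    W <- params[[paste0("fc_W", n)]]
    b <- params[[paste0("fc_b", n)]]
    out <- matrix(0, nrow(W), ncol(C))
    for (r in seq_len(nrow(W))) for (j in seq_len(ncol(C))) {
      s <- b[r]
      for (c in seq_len(ncol(W))) s <- s + W[r, c] * C[c, j]
      m <- buffers[[paste0("bn_fc", n, "_mean")]][r]
      v <- buffers[[paste0("bn_fc", n, "_var")]][r]
      g <- params[[paste0("bn_fc", n, "_g")]][r]
      be <- params[[paste0("bn_fc", n, "_b")]][r]
      out[r, j] <- max((s - m) / sqrt(v + 1e-5) * g + be, 0)
    }
    C <- out
  }
  g <- numeric(nrow(C))
  for (r in seq_len(nrow(C))) g[r] <- max(C[r, ])
  s <- params$out_b
  for (r in seq_along(g)) s <- s + params$out_w[r] * g[r]
  1 / (1 + exp(-s))
}

# O(n^2) pairwise-concordance AUC oracle (ties count one half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# exact binomial upper-tail oracle by direct pmf summation
oracle_binom_tail <- function(wins, n) {
  s <- 0
  for (k in wins:n) s <- s + choose(n, k) / 2^n
  s
}

# double-loop percent-rank / overall-metric oracle
oracle_overall <- function(values, method_index) {
  M <- dim(values)[1]; N <- dim(values)[2]; D <- dim(values)[3]
  tot <- 0
  for (i in seq_len(M)) for (j in seq_len(D)) {
    nl <- 0
    for (m in seq_len(N))
      if (values[i, m, j] <= values[i, method_index, j]) nl <- nl + 1
    tot <- tot + (nl - 1) / (N - 1) * 100
  }
  tot / (M * D)
}

# small randomly-parameterized config for layer tests
small_config <- function(...) {
  mhci_config(kernel_spec = c("9" = 5L, "11" = 3L, "13" = 2L),
              fc_dims = c(8L, 6L), ...)
}
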