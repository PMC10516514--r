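# The anchor-aware interaction network.
#
# Two implementations live here on purpose:
#  * reference single-instance layer ops (embed, position_gate,
#    generate_kernels, bicl_forward, resbicl_forward, head_forward,
#    mhci_forward) written in the mathematical orientation -- these define the
#    semantics and are what the layer tests exercise;
#  * a batched engine (nn_forward_batch / nn_backward_batch) with hand-derived
#    gradients over BLAS matrix ops -- this is the production path used by
#    fitting and prediction, and is tested against the reference ops.
#
# Parameter orientation: gate_W[, , i] and gate_V[, , i] are the d x d maps
# W_i, V_i applied as W_i %*% x; fc_W<n> is (out x in) applied as W %*% c;
# U_<branch>_<k> stacks the per-kernel generator matrices U_i (k x 34)
# row-wise, kernel i occupying rows (i-1)*k + 1 .. i*k.

.sigmoid <- function(x) 1 / (1 + exp(-x))
.addrow <- function(M, v) M + rep(v, each = nrow(M))

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

# Channel-wise batch normalization, channels-first: Z is (channels x
# samples), so per-channel vectors broadcast down columns by native
# recycling. Normalization uses the biased batch variance; running variance
# is updated with the unbiased estimate.
.bn_forward <- function(Z, gamma, beta, rmean, rvar, train) {
  if (train) {
    mu <- rowMeans(Z)
    xc <- Z - mu
    v <- rowMeans(xc * xc)
    inv <- 1 / sqrt(v + .BN_EPS)
    xhat <- xc * inv
    n <- ncol(Z)
    rmean <- (1 - .BN_MOMENTUM) * rmean + .BN_MOMENTUM * mu
    rvar <- (1 - .BN_MOMENTUM) * rvar + .BN_MOMENTUM * v * n / max(n - 1, 1)
    list(out = xhat * gamma + beta,
         xhat = xhat, inv = inv, rmean = rmean, rvar = rvar)
  } else {
    # inference: single fused affine; xhat is never needed (no backward)
    inv <- 1 / sqrt(rvar + .BN_EPS)
    a <- gamma * inv
    list(out = Z * a + (beta - rmean * a),
         xhat = NULL, inv = inv, rmean = rmean, rvar = rvar)
  }
}

.bn_backward <- function(dY, bn, gamma) {
  # gamma is constant per channel, so the per-channel sums of dxhat and
  # dxhat*xhat factor as gamma * rowSums(dY) and gamma * dgamma
  n <- ncol(dY)
  dgamma <- rowSums(dY * bn$xhat)
  dbeta <- rowSums(dY)
  c1 <- gamma * bn$inv
  dx <- dY * c1 - (c1 * dbeta / n) - bn$xhat * (c1 * dgamma / n)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Embedding lookup
#'
#' @param indices integer vector of token indices (0 = pad).
#' @param table embedding matrix (21 x d; row 1 is the pad token).
#' @return length(indices) x d matrix.
#' @export
embed <- function(indices, table) {
  if (any(indices < 0L | indices > nrow(table) - 1L))
    stop("token index out of range", call. = FALSE)
  table[indices + 1L, , drop = FALSE]
}

#' Position-wise gated layer
#'
#' Applies a gated linear unit independently at every peptide position i:
#' `xbar_i = sigmoid(W_i x_i + b_i) * (V_i x_i + c_i)`. With untied gates
#' (the default) each position has its own parameters, which is what lets the
#' model treat anchor positions differently; `tie_gate` shares one set.
#'
#' @param X L x d peptide embedding matrix.
#' @param params parameter set.
#' @param config `mhci_config`.
#' @return L x d gated matrix.
#' @export
position_gate <- function(X, params, config) {
  L <- nrow(X)
  out <- X
  for (i in seq_len(L)) {
    gi <- if (config$tie_gate) 1L else i
    x <- X[i, ]
    a <- .sigmoid(params$gate_W[, , gi] %*% x + params$gate_b[, gi])
    v <- params$gate_V[, , gi] %*% x + params$gate_c[, gi]
    out[i, ] <- a * v
  }
  out
}

#' Generate allele-conditioned convolution kernels
#'
#' Kernel i of size k is `K_i = f(U_i Y)` where Y is the 34 x d pseudo-sequence
#' embedding, so the filter bank is a deterministic function of the MHC
#' molecule.
#'
#' @param Y 34 x d pseudo-sequence embedding.
#' @param params parameter set.
#' @param config `mhci_config`.
#' @param branch 1 (raw-embedding branch) or 2 (gated branch).
#' @return named list, one element per kernel size, each a list of k x d
#'   kernel matrices.
#' @export
generate_kernels <- function(Y, params, config, branch = 2L) {
  br <- paste0("b", branch)
  out <- list()
  for (i in seq_along(config$kernel_sizes)) {
    k <- config$kernel_sizes[i]
    H <- config$kernel_counts[i]
    U <- params[[paste0("U_", br, "_", k)]]
    Kall <- pmax(U %*% Y, 0)
    out[[as.character(k)]] <- lapply(seq_len(H), function(h)
      Kall[((h - 1L) * k + 1L):(h * k), , drop = FALSE])
  }
  out
}

#' Binding-interaction convolution (one branch)
#'
#' Slides the allele-generated kernels over the peptide representation:
#' `C[i, j] = f(<K_i, X[j : j+k-1]> + b_i)`. For kernel sizes above 9 the
#' input is zero-padded by (k-9)/2 rows on each side so every size yields the
#' same output width `L - 9 + 1`; the per-size maps are stacked channel-wise.
#'
#' @param X_in L x d input (gated or raw peptide embedding).
#' @param Y 34 x d pseudo-sequence embedding.
#' @param params parameter set.
#' @param config `mhci_config`.
#' @param branch 1 or 2.
#' @return d0 x (L - 9 + 1) matrix, d0 = total kernel count.
#' @export
bicl_forward <- function(X_in, Y, params, config, branch = 2L) {
  L <- nrow(X_in)
  d <- ncol(X_in)
  w <- L - 9L + 1L
  kern <- generate_kernels(Y, params, config, branch)
  br <- paste0("b", branch)
  blocks <- list()
  for (i in seq_along(config$kernel_sizes)) {
    k <- config$kernel_sizes[i]
    off <- (k - 9L) %/% 2L
    b <- params[[paste0("cb_", br, "_", k)]]
    Xp <- rbind(matrix(0, off, d), X_in, matrix(0, off, d))
    Ck <- matrix(0, config$kernel_counts[i], w)
    Ks <- kern[[as.character(k)]]
    for (h in seq_along(Ks)) {
      for (j in seq_len(w)) {
        win <- Xp[j:(j + k - 1L), , drop = FALSE]
        Ck[h, j] <- sum(Ks[[h]] * win) + b[h]
      }
    }
    blocks[[i]] <- pmax(Ck, 0)
  }
  do.call(rbind, blocks)
}

#' Residual binding-interaction convolution
#'
#' `C0 = f(norm(BICL1(X, Y)) + norm(BICL2(Xbar, Y)))`: one branch sees the raw
#' peptide embedding, the other the gated one; each branch output is
#' batch-normalized per channel before the residual sum. With the residual
#' branch disabled only the gated branch is used; with the gate disabled
#' `Xbar = X`.
#'
#' @param X raw L x d peptide embedding.
#' @param Xbar gated L x d peptide matrix (ignored when `use_gate` is off).
#' @param Y 34 x d pseudo-sequence embedding.
#' @param params parameter set.
#' @param config `mhci_config`.
#' @param buffers batch-norm running statistics (default: taken from
#'   `params`); inference-mode normalization is used.
#' @return d0 x (L - 9 + 1) matrix.
#' @export
resbicl_forward <- function(X, Xbar, Y, params, config,
                            buffers = attr(params, "buffers")) {
  if (!config$use_gate) Xbar <- X
  bn_eval <- function(C, br) {
    g <- params[[paste0("bn_", br, "_g")]]
    b <- params[[paste0("bn_", br, "_b")]]
    m <- buffers[[paste0("bn_", br, "_mean")]]
    v <- buffers[[paste0("bn_", br, "_var")]]
    (C - m) / sqrt(v + .BN_EPS) * g + b   # per-row (channel) broadcast
  }
  C2 <- bn_eval(bicl_forward(Xbar, Y, params, config, branch = 2L), "b2")
  S <- if (config$use_residual) {
    C1 <- bn_eval(bicl_forward(X, Y, params, config, branch = 1L), "b1")
    C1 + C2
  } else C2
  pmax(S, 0)
}

#' Fully connected head: position-wise FC stack, max-pool, sigmoid output
#'
#' Each FC layer acts identically at every one of the `L - 9 + 1` positions
#' (`C_n = f(W_n C_{n-1} + b_n)`, with inference-mode batch normalization
#' between the linear map and the activation); the final representation is the
#' per-channel maximum over positions, projected to a scalar through a
#' sigmoid.
#'
#' @param C0 d0 x (L - 9 + 1) matrix from [resbicl_forward()].
#' @param params parameter set.
#' @param config `mhci_config`.
#' @param buffers batch-norm running statistics.
#' @return predicted affinity in (0, 1).
#' @export
head_forward <- function(C0, params, config,
                         buffers = attr(params, "buffers")) {
  C <- C0
  for (n in seq_along(config$fc_dims)) {
    W <- params[[paste0("fc_W", n)]]
    b <- params[[paste0("fc_b", n)]]
    pre <- W %*% C + b
    g <- params[[paste0("bn_fc", n, "_g")]]
    be <- params[[paste0("bn_fc", n, "_b")]]
    m <- buffers[[paste0("bn_fc", n, "_mean")]]
    v <- buffers[[paste0("bn_fc", n, "_var")]]
    C <- pmax((pre - m) / sqrt(v + .BN_EPS) * g + be, 0)
  }
  gvec <- apply(C, 1L, max)
  .sigmoid(sum(params$out_w * gvec) + params$out_b)
}

#' Full forward pass for one peptide-allele pair
#'
#' Deterministic inference-mode composition of the layer ops: encode, embed,
#' gate, residual interaction convolution, FC head.
#'
#' @param peptide residue string (length 8..L).
#' @param pseudo 34-residue pseudo-sequence of the allele.
#' @param params parameter set.
#' @param config `mhci_config`.
#' @return predicted affinity in (0, 1).
#' @export
mhci_forward <- function(peptide, pseudo, params, config) {
  X <- embed(encode_peptide(peptide, config$model_length), params$E)
  Y <- embed(encode_pseudo(pseudo), params$E)
  Xbar <- if (config$use_gate) position_gate(X, params, config) else X
  C0 <- resbicl_forward(X, Xbar, Y, params, config)
  head_forward(C0, params, config)
}

# ---------------------------------------------------------------------------
# Batched engine
# ---------------------------------------------------------------------------

# Encode (allele, peptide) pairs for the batched engine.
# Returns P (B x L index matrix), gid (group id per row), pseudo_idx (list of
# 34-index vectors per group).
nn_prepare <- function(allele, peptide, pseudo, config) {
  P <- encode_peptides(peptide, config$model_length)
  ga <- unique(allele)
  missing <- setdiff(ga, names(pseudo))
  if (length(missing))
    stop("no pseudo-sequence for allele(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  list(P = P,
       gid = match(allele, ga),
       pseudo_idx = lapply(pseudo[ga], encode_pseudo))
}

# Batched forward pass, channels-first: every activation matrix is
# (features x samples) so per-channel bias/normalization broadcasts use R's
# native column-major recycling. When train = TRUE uses batch statistics,
# applies dropout (consumes RNG), and returns updated running buffers plus a
# cache for nn_backward_batch.
nn_forward_batch <- function(params, buffers, config, batch,
                             train = FALSE, keep_cache = train) {
  P <- batch$P; gid <- batch$gid; pseudo_idx <- batch$pseudo_idx
  B <- nrow(P)
  d <- config$embed_dim
  L <- config$model_length
  w <- config$conv_width
  ks <- config$kernel_sizes
  Hs <- config$kernel_counts
  offmax <- (max(ks) - 9L) %/% 2L
  Et <- t(params$E)                       # d x 21, columns = tokens

  Xlist <- lapply(seq_len(L), function(i) Et[, P[, i] + 1L, drop = FALSE])

  gate_cache <- NULL
  if (config$use_gate) {
    gate_cache <- vector("list", L)
    Xbar <- vector("list", L)
    for (i in seq_len(L)) {
      gi <- if (config$tie_gate) 1L else i
      pre1 <- params$gate_W[, , gi] %*% Xlist[[i]] + params$gate_b[, gi]
      A <- .sigmoid(pre1)
      V <- params$gate_V[, , gi] %*% Xlist[[i]] + params$gate_c[, gi]
      Xbar[[i]] <- A * V
      if (keep_cache) gate_cache[[i]] <- list(A = A, V = V)
    }
  } else Xbar <- Xlist

  padblock <- matrix(0, offmax * d, B)
  Xpad2 <- do.call(rbind, c(list(padblock), Xbar, list(padblock)))
  Xpad1 <- if (config$use_residual)
    do.call(rbind, c(list(padblock), Xlist, list(padblock))) else NULL

  G <- length(pseudo_idx)
  gcols <- split(seq_len(B), gid)
  Ylist <- lapply(pseudo_idx, function(pi)
    params$E[pi + 1L, , drop = FALSE])    # 34 x d, for kernel generation

  branches <- if (config$use_residual) c("b1", "b2") else "b2"
  conv_cache <- list()
  Zbar <- list()
  for (br in branches) {
    Xp <- if (br == "b1") Xpad1 else Xpad2
    Z <- matrix(0, config$d0, B * w)
    for (g in seq_len(G)) {
      cg <- gcols[[as.character(g)]]
      if (is.null(cg)) next
      Bg <- length(cg)
      tr <- rep(cg, times = w) + rep((seq_len(w) - 1L) * B, each = Bg)
      crow <- 0L
      for (i in seq_along(ks)) {
        k <- ks[i]; H <- Hs[i]
        off <- (k - 9L) %/% 2L
        U <- params[[paste0("U_", br, "_", k)]]
        cb <- params[[paste0("cb_", br, "_", k)]]
        Kpre <- U %*% Ylist[[g]]
        K <- Kpre * (Kpre > 0)
        Kflat <- matrix(aperm(array(K, c(k, H, d)), c(2L, 3L, 1L)), nrow = H)
        rows0 <- (offmax - off) * d
        Wmat <- do.call(cbind, lapply(seq_len(w), function(j)
          Xp[(rows0 + (j - 1L) * d + 1L):(rows0 + (j - 1L + k) * d), cg,
             drop = FALSE]))
        pre <- Kflat %*% Wmat + cb
        pre_pos <- pre > 0
        Z[(crow + 1L):(crow + H), tr] <- pre * pre_pos
        if (keep_cache)
          conv_cache[[paste(br, g, k, sep = "_")]] <-
            list(Wmat = Wmat, Kflat = Kflat, Kpre_pos = Kpre > 0,
                 pre_pos = pre_pos, tr = tr, cg = cg, rows0 = rows0)
        crow <- crow + H
      }
    }
    Zbar[[br]] <- Z
  }

  bn <- list()
  for (br in branches) {
    bn[[br]] <- .bn_forward(Zbar[[br]],
                            params[[paste0("bn_", br, "_g")]],
                            params[[paste0("bn_", br, "_b")]],
                            buffers[[paste0("bn_", br, "_mean")]],
                            buffers[[paste0("bn_", br, "_var")]],
                            train)
    buffers[[paste0("bn_", br, "_mean")]] <- bn[[br]]$rmean
    buffers[[paste0("bn_", br, "_var")]] <- bn[[br]]$rvar
  }
  S <- if (config$use_residual) bn$b1$out + bn$b2$out else bn$b2$out
  S_pos <- S > 0
  C0 <- S * S_pos

  fc_cache <- list()
  C <- C0
  for (n in seq_along(config$fc_dims)) {
    W <- params[[paste0("fc_W", n)]]
    pre <- W %*% C + params[[paste0("fc_b", n)]]
    bnn <- .bn_forward(pre,
                       params[[paste0("bn_fc", n, "_g")]],
                       params[[paste0("bn_fc", n, "_b")]],
                       buffers[[paste0("bn_fc", n, "_mean")]],
                       buffers[[paste0("bn_fc", n, "_var")]],
                       train)
    buffers[[paste0("bn_fc", n, "_mean")]] <- bnn$rmean
    buffers[[paste0("bn_fc", n, "_var")]] <- bnn$rvar
    act_pos <- bnn$out > 0
    act <- bnn$out * act_pos
    drop_mask <- NULL
    if (train && config$dropout_rate > 0) {
      drop_mask <- matrix(
        (stats::runif(length(act)) >= config$dropout_rate) /
          (1 - config$dropout_rate),
        nrow(act), ncol(act))
      out <- act * drop_mask
    } else out <- act
    if (keep_cache)
      fc_cache[[n]] <- list(input = C, bn = bnn, act_pos = act_pos,
                            drop_mask = drop_mask)
    C <- out
  }

  hN <- config$fc_dims[length(config$fc_dims)]
  gmat <- C[, seq_len(B), drop = FALSE]
  amax <- matrix(1L, hN, B)
  if (w > 1L) for (j in 2:w) {
    Cj <- C[, ((j - 1L) * B + 1L):(j * B), drop = FALSE]
    upd <- Cj > gmat
    amax[upd] <- j
    gmat[upd] <- Cj[upd]
  }
  s <- colSums(gmat * params$out_w) + params$out_b
  yhat <- .sigmoid(s)

  cache <- NULL
  if (keep_cache) {
    cache <- list(batch = batch, Xlist = Xlist, Xbar = Xbar,
                  gate_cache = gate_cache, Ylist = Ylist, gcols = gcols,
                  conv_cache = conv_cache, bn = bn, S_pos = S_pos,
                  fc_cache = fc_cache, gmat = gmat, amax = amax,
                  yhat = yhat, B = B, branches = branches)
  }
  list(yhat = yhat, cache = cache, buffers = buffers)
}

# empty gradient structure matching params
nn_zero_grads <- function(params) {
  lapply(params, function(x) {
    if (is.array(x)) array(0, dim(x)) else numeric(length(x))
  })
}

# Batched backward pass. dyhat is dL/dyhat per sample. Returns gradients with
# the same names/shapes as params (pad embedding row forced to zero; the
# embedding gradient is zero in one-hot mode; unused branches get zeros).
nn_backward_batch <- function(params, config, cache, dyhat) {
  gr <- nn_zero_grads(params)
  B <- cache$B
  d <- config$embed_dim
  L <- config$model_length
  w <- config$conv_width
  ks <- config$kernel_sizes
  Hs <- config$kernel_counts
  offmax <- (max(ks) - 9L) %/% 2L
  hN <- config$fc_dims[length(config$fc_dims)]

  yhat <- cache$yhat
  ds <- dyhat * yhat * (1 - yhat)
  gr$out_w <- drop(cache$gmat %*% ds)
  gr$out_b <- sum(ds)
  dgmat <- outer(params$out_w, ds)

  # max-pool scatter: entry (c, b) goes to column b + (amax - 1) * B
  dC <- matrix(0, hN, B * w)
  colv <- rep(seq_len(B), each = hN) + (as.vector(cache$amax) - 1L) * B
  dC[cbind(rep(seq_len(hN), times = B), colv)] <- as.vector(dgmat)

  for (n in rev(seq_along(config$fc_dims))) {
    fc <- cache$fc_cache[[n]]
    if (!is.null(fc$drop_mask)) dC <- dC * fc$drop_mask
    dbn_out <- dC * fc$act_pos
    bb <- .bn_backward(dbn_out, fc$bn, params[[paste0("bn_fc", n, "_g")]])
    gr[[paste0("bn_fc", n, "_g")]] <- bb$dgamma
    gr[[paste0("bn_fc", n, "_b")]] <- bb$dbeta
    gr[[paste0("fc_W", n)]] <- tcrossprod(bb$dx, fc$input)
    gr[[paste0("fc_b", n)]] <- rowSums(bb$dx)
    dC <- crossprod(params[[paste0("fc_W", n)]], bb$dx)
  }

  dS <- dC * cache$S_pos
  dXpad <- list()
  G <- length(cache$Ylist)
  for (br in cache$branches) {
    bb <- .bn_backward(dS, cache$bn[[br]],
                       params[[paste0("bn_", br, "_g")]])
    gr[[paste0("bn_", br, "_g")]] <- bb$dgamma
    gr[[paste0("bn_", br, "_b")]] <- bb$dbeta
    dZ <- bb$dx
    dXp <- matrix(0, (L + 2L * offmax) * d, B)
    dYlist <- vector("list", G)
    for (g in seq_len(G)) {
      cg <- cache$gcols[[as.character(g)]]
      if (is.null(cg)) next
      Bg <- length(cg)
      dY <- matrix(0, 34L, d)
      crow <- 0L
      for (i in seq_along(ks)) {
        k <- ks[i]; H <- Hs[i]
        cc <- cache$conv_cache[[paste(br, g, k, sep = "_")]]
        dpre <- dZ[(crow + 1L):(crow + H), cc$tr, drop = FALSE] * cc$pre_pos
        gr[[paste0("cb_", br, "_", k)]] <-
          gr[[paste0("cb_", br, "_", k)]] + rowSums(dpre)
        dKflat <- tcrossprod(dpre, cc$Wmat)
        dWmat <- crossprod(cc$Kflat, dpre)
        for (j in seq_len(w)) {
          rows <- (cc$rows0 + (j - 1L) * d + 1L):(cc$rows0 + (j - 1L + k) * d)
          dXp[rows, cg] <- dXp[rows, cg] +
            dWmat[, ((j - 1L) * Bg + 1L):(j * Bg), drop = FALSE]
        }
        dK <- matrix(aperm(array(dKflat, c(H, d, k)), c(3L, 1L, 2L)),
                     nrow = H * k)
        dK <- dK * cc$Kpre_pos
        U <- params[[paste0("U_", br, "_", k)]]
        gr[[paste0("U_", br, "_", k)]] <-
          gr[[paste0("U_", br, "_", k)]] + tcrossprod(dK, cache$Ylist[[g]])
        dY <- dY + crossprod(U, dK)
        crow <- crow + H
      }
      dYlist[[g]] <- dY
    }
    dXpad[[br]] <- dXp
    # pseudo-sequence embedding gradient
    if (config$embedding_mode == "learned") {
      for (g in seq_len(G)) {
        if (is.null(dYlist[[g]])) next
        pidx <- cache$batch$pseudo_idx[[g]] + 1L
        agg <- rowsum(dYlist[[g]], pidx)
        gr$E[as.integer(rownames(agg)), ] <-
          gr$E[as.integer(rownames(agg)), ] + agg
      }
    }
  }

  # per-position gradients into gate and embedding
  P <- cache$batch$P
  for (i in seq_len(L)) {
    rows <- ((offmax + i - 1L) * d + 1L):((offmax + i) * d)
    dXbar_i <- dXpad$b2[rows, , drop = FALSE]
    dX_i <- if (config$use_residual)
      dXpad$b1[rows, , drop = FALSE] else matrix(0, d, B)
    if (config$use_gate) {
      gi <- if (config$tie_gate) 1L else i
      gc <- cache$gate_cache[[i]]
      dA <- dXbar_i * gc$V
      dV <- dXbar_i * gc$A
      dpre1 <- dA * gc$A * (1 - gc$A)
      gr$gate_W[, , gi] <- gr$gate_W[, , gi] +
        tcrossprod(dpre1, cache$Xlist[[i]])
      gr$gate_b[, gi] <- gr$gate_b[, gi] + rowSums(dpre1)
      gr$gate_V[, , gi] <- gr$gate_V[, , gi] +
        tcrossprod(dV, cache$Xlist[[i]])
      gr$gate_c[, gi] <- gr$gate_c[, gi] + rowSums(dV)
      dX_i <- dX_i + crossprod(params$gate_W[, , gi], dpre1) +
        crossprod(params$gate_V[, , gi], dV)
    } else {
      dX_i <- dX_i + dXbar_i
    }
    if (config$embedding_mode == "learned") {
      agg <- rowsum(t(dX_i), P[, i] + 1L)
      gr$E[as.integer(rownames(agg)), ] <-
        gr$E[as.integer(rownames(agg)), ] + agg
    }
  }
  gr$E[1L, ] <- 0  # pad row frozen
  if (config$embedding_mode == "one_hot") gr$E[] <- 0
  gr
}
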