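test_that("embedding lookup returns the requested rows", {
  cfg <- small_config()
  p <- mhci_init_params(cfg, seed = 1)
  idx <- encode_peptide("ACDEFGHIK")
  X <- embed(idx, p$E)
  expect_identical(dim(X), c(15L, cfg$embed_dim))
  expect_identical(X[1, ], p$E[idx[1] + 1L, ])
  expect_true(all(X[10:15, ] == 0))  # pad rows are the zero pad embedding
  I <- diag(21)
  expect_identical(embed(c(0L, 5L), I), I[c(1L, 6L), ])
  expect_error(embed(25L, p$E), "range")
  # one-hot mode: rows are unit basis vectors
  cfg1 <- small_config(embedding_mode = "one_hot")
  p1 <- mhci_init_params(cfg1, seed = 1)
  expect_identical(cfg1$embed_dim, 21L)
  X1 <- embed(encode_peptide("ACDEFGHIK"), p1$E)
  expect_true(all(rowSums(X1[1:9, ]) == 1))
  expect_true(all(X1[cbind(1:9, encode_peptide("ACDEFGHIK")[1:9] + 1L)] == 1))
})

test_that("gated layer matches an elementwise loop oracle", {
  set.seed(42)
  for (rep in 1:100) {
    cfg <- small_config(embed_dim = sample(3:8, 1),
                        tie_gate = rep %% 4 == 0)
    p <- mhci_init_params(cfg)
    X <- matrix(rnorm(15 * cfg$embed_dim), 15)
    expect_lt(max(abs(position_gate(X, p, cfg) - oracle_gate(X, p, cfg))),
              1e-6)
  }
})

test_that("gate closed forms: zero gate halves, saturated gate passes", {
  cfg <- small_config()
  d <- cfg$embed_dim
  p <- mhci_init_params(cfg, seed = 2)
  p$gate_W[] <- 0; p$gate_b[] <- 0
  p$gate_c[] <- 0
  for (i in seq_len(15)) p$gate_V[, , i] <- diag(d)
  X <- matrix(rnorm(15 * d), 15)
  expect_equal(position_gate(X, p, cfg), 0.5 * X)
  p$gate_b[] <- 30  # saturate the sigmoid
  expect_equal(position_gate(X, p, cfg), X, tolerance = 1e-9)
})

test_that("kernel generation matches the matrix-product oracle", {
  set.seed(43)
  for (rep in 1:20) {
    cfg <- small_config(embed_dim = sample(3:6, 1))
    p <- mhci_init_params(cfg)
    Y <- matrix(rnorm(34 * cfg$embed_dim), 34)
    br <- sample(1:2, 1)
    got <- generate_kernels(Y, p, cfg, branch = br)
    want <- oracle_kernels(Y, p, cfg, branch = br)
    for (k in names(got))
      for (h in seq_along(got[[k]]))
        expect_lt(max(abs(got[[k]][[h]] - want[[k]][[h]])), 1e-6)
  }
  cfg <- small_config(embed_dim = 4L)
  p <- mhci_init_params(cfg, seed = 9)
  Y <- matrix(rnorm(34 * 4), 34)
  # zero generator -> zero kernels; different pseudo-embeddings differ
  p0 <- p; p0$U_b2_9[] <- 0
  expect_true(all(generate_kernels(Y, p0, cfg)[["9"]][[1]] == 0))
  Y2 <- matrix(rnorm(34 * 4), 34)
  expect_false(isTRUE(all.equal(generate_kernels(Y, p, cfg)[["9"]][[1]],
                                generate_kernels(Y2, p, cfg)[["9"]][[1]])))
})

test_that("interaction convolution matches the sliding-window oracle", {
  set.seed(44)
  for (rep in 1:30) {
    cfg <- small_config(embed_dim = sample(3:5, 1))
    p <- mhci_init_params(cfg)
    X <- matrix(rnorm(15 * cfg$embed_dim), 15)
    Y <- matrix(rnorm(34 * cfg$embed_dim), 34)
    br <- sample(1:2, 1)
    expect_lt(max(abs(bicl_forward(X, Y, p, cfg, br) -
                        oracle_bicl(X, Y, p, cfg, br))), 1e-5)
  }
  # zero kernels with negative bias -> all-zero activations
  cfg <- small_config()
  p <- mhci_init_params(cfg, seed = 4)
  for (k in cfg$kernel_sizes) {
    p[[paste0("U_b2_", k)]][] <- 0
    p[[paste0("cb_b2_", k)]][] <- -1
  }
  X <- matrix(rnorm(15 * cfg$embed_dim), 15)
  Y <- matrix(rnorm(34 * cfg$embed_dim), 34)
  expect_true(all(bicl_forward(X, Y, p, cfg, 2L) == 0))
})

test_that("residual combination composes the two branch oracles", {
  set.seed(45)
  for (rep in 1:10) {
    cfg <- small_config(embed_dim = 4L)
    p <- mhci_init_params(cfg)
    buf <- attr(p, "buffers")
    # non-trivial normalization statistics
    for (nm in grep("^bn_b[12]_", names(buf), value = TRUE))
      buf[[nm]] <- abs(rnorm(cfg$d0)) + 0.5
    attr(p, "buffers") <- buf
    X <- matrix(rnorm(15 * 4), 15)
    Xb <- position_gate(X, p, cfg)
    Y <- matrix(rnorm(34 * 4), 34)
    norm_or <- function(C, br)
      (C - buf[[paste0("bn_", br, "_mean")]]) /
        sqrt(buf[[paste0("bn_", br, "_var")]] + 1e-5) *
        p[[paste0("bn_", br, "_g")]] + p[[paste0("bn_", br, "_b")]]
    want <- pmax(norm_or(oracle_bicl(X, Y, p, cfg, 1L), "b1") +
                   norm_or(oracle_bicl(Xb, Y, p, cfg, 2L), "b2"), 0)
    expect_lt(max(abs(resbicl_forward(X, Xb, Y, p, cfg) - want)), 1e-5)
    # single-branch ablation drops branch 1 entirely
    cfg0 <- small_config(embed_dim = 4L, use_residual = FALSE)
    want0 <- pmax(norm_or(oracle_bicl(Xb, Y, p, cfg0, 2L), "b2"), 0)
    expect_lt(max(abs(resbicl_forward(X, Xb, Y, p, cfg0,
                                      buffers = buf) - want0)), 1e-5)
  }
})

test_that("FC head matches the loop oracle and saturates correctly", {
  set.seed(46)
  for (rep in 1:30) {
    cfg <- small_config(embed_dim = 4L)
    p <- mhci_init_params(cfg)
    buf <- attr(p, "buffers")
    C0 <- matrix(rnorm(cfg$d0 * cfg$conv_width), cfg$d0)
    expect_lt(abs(head_forward(C0, p, cfg) -
                    oracle_head(C0, p, cfg, buf)), 1e-6)
  }
  cfg <- small_config()
  p <- mhci_init_params(cfg, seed = 3)
  for (n in seq_along(cfg$fc_dims)) {
    p[[paste0("fc_W", n)]][] <- 0; p[[paste0("fc_b", n)]][] <- 0
    p[[paste0("bn_fc", n, "_b")]][] <- 0
  }
  p$out_w[] <- 0; p$out_b <- 0
  C0 <- matrix(0, cfg$d0, cfg$conv_width)
  expect_equal(head_forward(C0, p, cfg), 0.5)   # sigmoid(0)
  p$out_b <- 30
  expect_gt(head_forward(C0, p, cfg), 0.999)
  expect_lt(head_forward(C0, p, cfg), 1)
})

test_that("default architecture has the published shape chain", {
  cfg <- mhci_config()
  expect_identical(cfg$d0, 224L)            # 128 + 64 + 32 kernels
  expect_identical(cfg$conv_width, 7L)      # L - 9 + 1
  p <- mhci_init_params(cfg, seed = 5)
  X <- embed(encode_peptide("ACDEFGHIK"), p$E)
  Y <- embed(encode_pseudo(random_pseudo()), p$E)
  expect_identical(dim(X), c(15L, 16L))
  Xb <- position_gate(X, p, cfg)
  expect_identical(dim(Xb), c(15L, 16L))
  Cb <- bicl_forward(Xb, Y, p, cfg, 2L)
  expect_identical(dim(Cb), c(224L, 7L))
  C0 <- resbicl_forward(X, Xb, Y, p, cfg)
  expect_identical(dim(C0), c(224L, 7L))
  expect_length(p$out_w, 128L)              # g lives in R^128
  expect_error(mhci_config(kernel_spec = c("8" = 4L)), "odd")
  expect_error(mhci_config(kernel_spec = c("7" = 4L)), "odd")
})

test_that("default parameter count lies in the expected band", {
  cfg <- mhci_config()
  p <- mhci_init_params(cfg, seed = 6)
  n <- count_params(p, cfg)
  expect_gte(n, 2e5)
  expect_lte(n, 4e5)
})

test_that("forward output is in (0,1), deterministic, batch-independent", {
  cfg <- small_config()
  p <- mhci_init_params(cfg, seed = 7)
  pseudo <- random_pseudo()
  set.seed(8)
  peps <- vapply(sample(8:15, 12, TRUE), random_peptide, "")
  y1 <- vapply(peps, function(pp) mhci_forward(pp, pseudo, p, cfg), 0)
  y2 <- vapply(peps, function(pp) mhci_forward(pp, pseudo, p, cfg), 0)
  expect_identical(y1, y2)                 # bit-identical eval mode
  expect_true(all(y1 > 0 & y1 < 1))
  # batched engine agrees with the single-pair composition
  buf <- attr(p, "buffers")
  prep <- mhcbind:::nn_prepare(rep("A", 12), peps,
                               c(A = pseudo), cfg)
  fw <- mhcbind:::nn_forward_batch(p, buf, cfg, prep)
  expect_lt(max(abs(fw$yhat - unname(y1))), 1e-6)
  # shuffling the batch leaves per-item predictions unchanged
  ord <- sample(12)
  prep2 <- mhcbind:::nn_prepare(rep("A", 12), peps[ord], c(A = pseudo), cfg)
  fw2 <- mhcbind:::nn_forward_batch(p, buf, cfg, prep2)
  expect_lt(max(abs(fw2$yhat - fw$yhat[ord])), 1e-6)
})

test_that("one optimization step sees nonzero gradients everywhere", {
  cfg <- small_config()
  p <- mhci_init_params(cfg, seed = 9)
  buf <- attr(p, "buffers"); attr(p, "buffers") <- NULL
  set.seed(10)
  peps <- c(random_peptide(15), random_peptide(15), random_peptide(15),
            random_peptide(15))
  prep <- mhcbind:::nn_prepare(rep(c("A", "B"), 2), peps,
                               c(A = random_pseudo(), B = random_pseudo()),
                               cfg)
  fw <- mhcbind:::nn_forward_batch(p, buf, cfg, prep, train = TRUE)
  y <- runif(4)
  gr <- mhcbind:::nn_backward_batch(p, cfg, fw$cache,
                                    2 * (fw$yhat - y) / 4)
  for (nm in names(gr)) {
    expect_true(any(gr[[nm]] != 0), info = nm)
  }
  # every gate position receives gradient (15-mer input covers all L)
  for (i in 1:15) expect_true(any(gr$gate_W[, , i] != 0),
                              info = paste("gate position", i))
  # single-branch ablation: branch-1 parameters receive no gradient
  cfg0 <- small_config(use_gate = FALSE, use_residual = FALSE)
  p0 <- mhci_init_params(cfg0, seed = 9)
  buf0 <- attr(p0, "buffers"); attr(p0, "buffers") <- NULL
  fw0 <- mhcbind:::nn_forward_batch(p0, buf0, cfg0, prep, train = TRUE)
  gr0 <- mhcbind:::nn_backward_batch(p0, cfg0, fw0$cache,
                                     2 * (fw0$yhat - y) / 4)
  for (nm in grep("_b1_|^gate", names(gr0), value = TRUE))
    expect_true(all(gr0[[nm]] == 0), info = nm)
})

test_that("permuting kernels within a size class leaves output invariant", {
  cfg <- small_config()
  p <- mhci_init_params(cfg, seed = 11)
  buf <- attr(p, "buffers")
  pseudo <- random_pseudo()
  set.seed(12)
  peps <- vapply(c(9L, 11L, 13L), random_peptide, "")
  base <- vapply(peps, function(pp) mhci_forward(pp, pseudo, p, cfg), 0)

  H9 <- cfg$kernel_counts[1]
  perm <- sample(H9)
  k <- 9L
  p2 <- p
  # permute the stacked generator blocks, biases, BN channels and the
  # matching input columns of the first FC layer (channels 1..H9)
  rowblocks <- function(h) ((h - 1L) * k + 1L):(h * k)
  for (br in c("b1", "b2")) {
    Unm <- paste0("U_", br, "_9"); cnm <- paste0("cb_", br, "_9")
    p2[[Unm]] <- p[[Unm]][unlist(lapply(perm, rowblocks)), , drop = FALSE]
    p2[[cnm]] <- p[[cnm]][perm]
    for (suf in c("_g", "_b")) {
      nm <- paste0("bn_", br, suf)
      p2[[nm]][1:H9] <- p[[nm]][perm]
    }
    for (suf in c("_mean", "_var")) {
      nm <- paste0("bn_", br, suf)
      attr(p2, "buffers")[[nm]][1:H9] <- buf[[nm]][perm]
    }
  }
  p2$fc_W1[, 1:H9] <- p$fc_W1[, perm]
  permuted <- vapply(peps, function(pp) mhci_forward(pp, pseudo, p2, cfg), 0)
  expect_equal(permuted, base, tolerance = 1e-10)
})

test_that("checkpoints round-trip and loading validates shape and vocab", {
  cfg <- small_config()
  tab <- generate_dataset(n_alleles = 2, peptides_per_allele_per_length = 10,
                          lengths = 9, seed = 31)$table
  m <- mhci_fit(tab, config = cfg, epochs = 1, batch_size = 32, seed = 1)
  f <- withr::local_tempfile()
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$params, m$params)
  p <- predict(m, allele = tab$allele[1], peptide = tab$peptide[1])
  expect_identical(predict(m2, allele = tab$allele[1],
                           peptide = tab$peptide[1]), p)
  # corrupt a shape -> load refuses
  m3 <- m; m3$params$fc_W1 <- m3$params$fc_W1[, -1]
  saveRDS(m3, f)
  expect_error(load_model(f), "shape")
  m4 <- m; m4$vocab <- "bogus"
  saveRDS(m4, f)
  expect_error(load_model(f), "vocabulary")
})
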