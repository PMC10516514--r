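tiny_table <- function(n_per = 25, seed = 17) {
  generate_dataset(n_alleles = 2, peptides_per_allele_per_length = n_per,
                   lengths = 9:10, seed = seed)$table
}

test_that("fold assignment is balanced, reproducible and peptide-grouped", {
  set.seed(33)
  pm <- c(A1 = random_pseudo(), A2 = random_pseudo())
  peps <- vapply(1:100, function(i) random_peptide(9), "")
  df <- data.frame(allele = "A1", peptide = peps, affinity = runif(100))
  # one duplicated peptide measured on the other allele
  df <- rbind(df, data.frame(allele = "A2", peptide = peps[1],
                             affinity = 0.3))
  tab <- binding_table(df, pm)
  t1 <- assign_folds(tab, folds = 5, seed = 1)
  t2 <- assign_folds(tab, folds = 5, seed = 1)
  expect_identical(t1$fold, t2$fold)
  counts <- table(t1$fold[!duplicated(t1$peptide)])
  expect_length(counts, 5L)
  expect_true(all(counts >= 15 & counts <= 25))
  # identical peptides share a fold across alleles
  expect_identical(t1$fold[101], t1$fold[1])
  # provided folds pass through unchanged
  tab$fold <- rep(c(0L, 1L), length.out = nrow(tab))
  expect_identical(assign_folds(tab, folds = 5, seed = 9)$fold, tab$fold)
  # more folds than peptide groups is an error
  small <- binding_table(df[1:3, ], pm)
  expect_error(assign_folds(small, folds = 10), "folds")
})

test_that("no peptide appears on both sides of a fold split", {
  tab <- assign_folds(tiny_table(), folds = 5, seed = 3)
  for (f in 0:4) {
    held <- unique(tab$peptide[!is.na(tab$fold) & tab$fold == f])
    train <- unique(tab$peptide[is.na(tab$fold) | tab$fold != f])
    expect_length(intersect(held, train), 0L)
  }
})

test_that("training reduces MSE and is seed-reproducible", {
  tab <- tiny_table()
  cfg <- small_config()
  m <- mhci_fit(tab, config = cfg, epochs = 3, batch_size = 32, seed = 5)
  expect_lt(m$history$train_mse[3], m$history$train_mse[1])
  m2 <- mhci_fit(tab, config = cfg, epochs = 3, batch_size = 32, seed = 5)
  expect_identical(m$history, m2$history)
  expect_identical(m$params, m2$params)
  m3 <- mhci_fit(tab, config = cfg, epochs = 3, batch_size = 32, seed = 6)
  expect_false(identical(m$params, m3$params))
})

test_that("zero learning rate freezes weights but not BN statistics", {
  tab <- tiny_table()
  cfg <- small_config()
  init <- mhci_init_params(cfg, seed = 7)
  m <- mhci_fit(tab, config = cfg, epochs = 1, batch_size = 32, lr = 0,
                seed = 7)
  got <- m$params
  buf <- attr(got, "buffers")
  attr(got, "buffers") <- NULL
  ref <- init; attr(ref, "buffers") <- NULL
  expect_equal(got, ref, tolerance = 0)
  expect_false(isTRUE(all.equal(buf$bn_b2_mean,
                                attr(init, "buffers")$bn_b2_mean)))
})

test_that("artificial negatives stay out of held-out partitions", {
  tab <- add_artificial_negatives(tiny_table(), per_length = 5, seed = 8)
  tab <- assign_folds(tab, folds = 5, seed = 8)
  expect_true(all(is.na(tab$fold[tab$origin == "artificial_negative"])))
  # the training partition includes them for every held-out fold
  for (f in 0:4) {
    train <- is.na(tab$fold) | tab$fold != f
    expect_identical(sum(tab$origin[train] == "artificial_negative"),
                     sum(tab$origin == "artificial_negative"))
  }
})

test_that("ensembles have repeats x folds members with derived seeds", {
  tab <- tiny_table(n_per = 15)
  cfg <- small_config()
  ens <- mhci_ensemble(tab, config = cfg, repeats = 2, folds = 2,
                       seed = 9, epochs = 1, batch_size = 32)
  expect_s3_class(ens, "mhci_ensemble")
  expect_length(ens$models, 4L)
  expect_identical(names(ens$models),
                   c("repeat1_fold0", "repeat1_fold1",
                     "repeat2_fold0", "repeat2_fold1"))
  ens2 <- mhci_ensemble(tab, config = cfg, repeats = 2, folds = 2,
                        seed = 9, epochs = 1, batch_size = 32)
  expect_identical(ens$seeds, ens2$seeds)
  expect_identical(predict(ens, allele = tab$allele[1:4],
                           peptide = tab$peptide[1:4]),
                   predict(ens2, allele = tab$allele[1:4],
                           peptide = tab$peptide[1:4]))
})

test_that("ensemble prediction is the member mean, order-invariant", {
  tab <- tiny_table(n_per = 10)
  cfg <- small_config()
  m1 <- mhci_fit(tab, config = cfg, epochs = 1, batch_size = 32, seed = 1)
  m2 <- mhci_fit(tab, config = cfg, epochs = 1, batch_size = 32, seed = 2)
  mk <- function(mods) structure(
    list(models = mods, repeats = 1, folds = length(mods),
         config = cfg, pseudo = pseudo_map(tab)), class = "mhci_ensemble")
  al <- tab$allele[1:6]; pe <- tab$peptide[1:6]
  p1 <- predict(m1, allele = al, peptide = pe)
  p2 <- predict(m2, allele = al, peptide = pe)
  expect_equal(predict(mk(list(m1, m2)), allele = al, peptide = pe),
               (p1 + p2) / 2, tolerance = 1e-12)
  expect_equal(predict(mk(list(m2, m1)), allele = al, peptide = pe),
               predict(mk(list(m1, m2)), allele = al, peptide = pe),
               tolerance = 1e-12)
  # identical members collapse to the single model
  expect_equal(predict(mk(list(m1, m1)), allele = al, peptide = pe), p1,
               tolerance = 1e-12)
  expect_error(predict(mk(list()), allele = al, peptide = pe), "empty")
})

test_that("averaging members shrinks prediction spread and error", {
  syn <- generate_dataset(n_alleles = 2, peptides_per_allele_per_length = 40,
                          lengths = 9:10, seed = 23)
  tab <- assign_folds(syn$table, folds = 5, seed = 23)
  ho <- !is.na(tab$fold) & tab$fold == 0
  cfg <- small_config()
  mods <- lapply(1:5, function(s)
    mhci_fit(tab, held_out_fold = 0, config = cfg, epochs = 4,
             batch_size = 32, seed = s))
  preds <- vapply(mods, function(m)
    predict(m, allele = tab$allele[ho], peptide = tab$peptide[ho]),
    numeric(sum(ho)))
  member_sd <- apply(preds, 1, sd)
  expect_true(all(member_sd > 0))          # members genuinely differ
  ens_pred <- rowMeans(preds)
  truth <- tab$affinity[ho]
  member_mse <- mean(colMeans((preds - truth)^2))
  ens_mse <- mean((ens_pred - truth)^2)
  expect_lt(ens_mse, member_mse)           # variance reduction
})
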