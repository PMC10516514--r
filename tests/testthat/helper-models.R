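# Shared trained-model fixtures, built lazily and cached for the whole test
# run so that several test files can reuse the same (expensive) fits.
# The benchmark protocol: the default synthetic dataset (4 alleles, 6000
# records, planted anchors at position 2 and the C-terminus, seed 42), a
# 5-fold split with fold 0 held out, and 30 training epochs.

.model_cache <- new.env(parent = emptyenv())

bench_seed <- 42L

bench_data <- function() {
  if (is.null(.model_cache$data)) {
    syn <- generate_dataset(seed = bench_seed)
    syn$table <- assign_folds(syn$table, folds = 5, seed = bench_seed)
    .model_cache$data <- syn
  }
  .model_cache$data
}

bench_heldout <- function() {
  tab <- bench_data()$table
  which(!is.na(tab$fold) & tab$fold == 0)
}

bench_model <- function(seed = bench_seed) {
  key <- paste0("model_", seed)
  if (is.null(.model_cache[[key]])) {
    .model_cache[[key]] <- mhci_fit(bench_data()$table, held_out_fold = 0,
                                    epochs = 30, seed = seed)
  }
  .model_cache[[key]]
}

bench_model_ablated <- function(seed = bench_seed) {
  key <- paste0("ablated_", seed)
  if (is.null(.model_cache[[key]])) {
    cfg <- mhci_config(use_gate = FALSE, use_residual = FALSE)
    .model_cache[[key]] <- mhci_fit(bench_data()$table, held_out_fold = 0,
                                    config = cfg, epochs = 30, seed = seed)
  }
  .model_cache[[key]]
}

# four independently initialized members (shorter schedule) sharing the
# benchmark train/held-out split, plus their prediction average
bench_members <- function() {
  if (is.null(.model_cache$members)) {
    .model_cache$members <- lapply(101:104, function(s)
      mhci_fit(bench_data()$table, held_out_fold = 0, epochs = 12, seed = s))
  }
  .model_cache$members
}

bench_member_ensemble <- function() {
  mods <- bench_members()
  names(mods) <- paste0("member", seq_along(mods))
  structure(list(models = mods, repeats = 1L, folds = length(mods),
                 config = mods[[1]]$config,
                 pseudo = pseudo_map(bench_data()$table)),
            class = "mhci_ensemble")
}

heldout_auc <- function(model) {
  tab <- bench_data()$table
  ho <- bench_heldout()
  pred <- predict(model, allele = tab$allele[ho], peptide = tab$peptide[ho])
  auc(pred, classify_binder(tab$affinity[ho]))
}
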