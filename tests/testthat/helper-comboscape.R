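# Shared fixtures, built once per test run.

.cs_test_cache <- new.env(parent = emptyenv())

# The packaged taxonomy (validated load is itself exercised in
# test-taxonomy.R; cached here for every other file).
test_taxonomy <- function() {
  if (is.null(.cs_test_cache$tax)) {
    .cs_test_cache$tax <- load_taxonomy()
  }
  .cs_test_cache$tax
}

# A small classifier trained on a light simulation (all 123 profiles, one
# regime), sufficient for structural pipeline tests.
test_small_model <- function() {
  if (is.null(.cs_test_cache$model)) {
    tax <- test_taxonomy()
    tr <- build_training_set(tax, regimes = 4, instances_per_profile = 8,
                             seed = 7001)
    f <- features_from_instances(tr)
    .cs_test_cache$model <- train_classifier(
      f, f$profile_id, tax, "random_forest",
      hyperparams = list(num_trees = 150), seed = 7002
    )
  }
  .cs_test_cache$model
}

# Write a taxonomy definition file for a hand-built profile table.
write_test_taxonomy <- function(profiles) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  write_taxonomy(profiles, path)
  path
}

# One-profile tibble in the shape write_taxonomy() expects.
make_profile <- function(id, name, category, sign, relations,
                         signature = NA_character_, modifies = "none",
                         mirror_id = id) {
  tibble::tibble(
    id = id, name = name, category = category, sign = sign,
    signature = signature, modifies = modifies, mirror_id = mirror_id,
    relations = list(relations)
  )
}

rel_tbl <- function(...) {
  rows <- list(...)
  num <- function(i) vapply(rows, function(r) as.numeric(r[[i]]), 0)
  tibble::tibble(
    c_e0 = num(1), c_eX = num(2), c_eY = num(3), c_eXY = num(4),
    rel = vapply(rows, function(r) as.character(r[[5]]), "")
  )
}
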