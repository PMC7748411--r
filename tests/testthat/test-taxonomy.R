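test_that("the packaged taxonomy has 123 valid, distinct profiles", {
  tax <- test_taxonomy()
  prof <- tidy(tax)
  expect_equal(nrow(prof), 123L)
  expect_false(anyDuplicated(prof$id) > 0)
  expect_false(anyDuplicated(prof$signature) > 0)
  expect_true(all(prof$category %in% c(
    "emergent", "potentiation", "restoration", "suppression", "inhibition",
    "synergistic_reversal", "antagonistic_reversal", "floor", "ceiling",
    "additive", "constant"
  )))
  # sign consistency with category semantics
  expect_true(all(prof$sign[prof$category %in% c("additive", "constant")] == "0"))
  expect_true(all(prof$sign[prof$category == "emergent"] != "0"))
  expect_true(all(prof$sign[prof$category == "restoration"] == "+"))
  expect_true(all(prof$sign[prof$category == "suppression"] == "-"))
  # X/Y role swap is an involution on profile ids
  expect_equal(prof$mirror_id[prof$mirror_id], prof$id)
})

test_that("the enumeration generator reproduces the packaged definition", {
  tax <- test_taxonomy()
  gen <- enumerate_interaction_profiles()
  expect_equal(nrow(gen), 123L)
  expect_equal(gen$signature, tax$profiles$signature)
  expect_equal(gen$category, tax$profiles$category)
  expect_equal(gen$sign, tax$profiles$sign)
  expect_equal(gen$mirror_id, tax$profiles$mirror_id)
})

test_that("satisfies honours the worked emergent-synergy instances", {
  tax <- test_taxonomy()
  es <- profile_id(tax, "emergent synergy")
  expect_true(satisfies(tax, es, c(2.2, 2.2, 2.2, 5.5)))
  expect_true(satisfies(tax, es, c(4.1, 4.1, 4.1, 7.8)))
  expect_false(satisfies(tax, es, c(0, 0, 0, 0)))
  expect_true(satisfies(tax, profile_id(tax, "constant"), c(0, 0, 0, 0)))
  expect_identical(category_of(tax, es), "emergent")
  expect_identical(interaction_sign_of(tax, es), "+")
})

test_that("strict relations require a margin beyond the tolerance", {
  tax <- test_taxonomy()
  es <- profile_id(tax, "emergent synergy")
  # within tolerance: the tiny eX offset is snapped to equality
  expect_equal(match_deterministic(c(0, 0.001, 0, 5), tax, tolerance = 0.01),
               es)
  # a gap exactly at the tolerance must not count as strictly greater
  expect_false(satisfies(tax, es, c(0, 0, 0, 0.01), tolerance = 0.01))
  expect_true(satisfies(tax, es, c(0, 0, 0, 0.5), tolerance = 0.01))
})

test_that("every random mean vector matches exactly one profile", {
  tax <- test_taxonomy()
  set.seed(421)
  V <- matrix(stats::runif(4e4, -14, 14), ncol = 4)
  expect_no_warning(ids <- match_deterministic(V, tax))
  expect_length(ids, 1e4)
  expect_true(all(ids %in% tax$profiles$id))
  # generic-position vectors land in full-dimensional cells only
  expect_true(all(interaction_sign_of(tax, ids) != "0"))
  expect_equal(match_deterministic(c(0, 0, 0, 0), tax),
               profile_id(tax, "constant"))
})

test_that("category and sign lookups reject unknown profile ids", {
  tax <- test_taxonomy()
  expect_error(category_of(tax, 999), "unknown profile id")
  expect_error(interaction_sign_of(tax, 999), "unknown profile id")
  expect_error(profile_id(tax, "no such profile"), "unknown profile name")
  add <- tidy(tax)$id[tidy(tax)$category == "additive"][1]
  expect_identical(interaction_sign_of(tax, add), "0")
})

test_that("loading rejects contradictory, duplicate and unsatisfiable files", {
  # contradictory: e0 < eX and eX < e0
  contradictory <- make_profile(
    1L, "impossible", "additive", "0",
    rel_tbl(c(-1, 1, 0, 0, "gt"), c(1, -1, 0, 0, "gt"))
  )
  expect_error(load_taxonomy(write_test_taxonomy(contradictory)),
               "unsatisfiable.*1")

  # identical solution sets under two ids
  r <- rel_tbl(c(-1, 1, 0, 0, "gt"))  # eX > e0
  dup_sets <- dplyr::bind_rows(
    make_profile(1L, "a", "potentiation", "+", r),
    make_profile(2L, "b", "potentiation", "+", r)
  )
  expect_error(load_taxonomy(write_test_taxonomy(dup_sets)),
               "identical solution sets")

  # duplicated id
  dup_id <- dplyr::bind_rows(
    make_profile(1L, "a", "potentiation", "+", r),
    make_profile(1L, "b", "inhibition", "-",
                 rel_tbl(c(1, -1, 0, 0, "gt")))
  )
  expect_error(load_taxonomy(write_test_taxonomy(dup_id)),
               "duplicate profile id")

  # checksum pinning: tampering with the body is detected
  tax_file <- cs_taxonomy_file()
  tampered <- withr::local_tempfile(fileext = ".tsv")
  lines <- readLines(tax_file)
  lines[length(lines)] <- sub("\t1\t", "\t2\t", lines[length(lines)])
  writeLines(lines, tampered)
  expect_error(load_taxonomy(tampered), "checksum mismatch")
})

test_that("a valid single-profile file round-trips through write/load", {
  one <- make_profile(
    5L, "X up, additive", "additive", "0",
    rel_tbl(c(-1, 1, 0, 0, "gt"),        # eX > e0
            c(0, 0, -1, 1, "gt"),        # eXY > eY
            c(1, -1, -1, 1, "eq"),       # eXY = eX + eY - e0
            c(1, 0, -1, 0, "eq"))        # eY = e0
  )
  tax <- load_taxonomy(write_test_taxonomy(one))
  expect_equal(tax$profiles$id, 5L)
  expect_true(satisfies(tax, 5L, c(0, 2, 0, 2)))
  expect_false(satisfies(tax, 5L, c(0, 2, 0, 3)))
})
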