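fake_calls <- function(tax, genes, profile_ids, p = 0.9) {
  sign <- interaction_sign_of(tax, profile_ids)
  b <- ifelse(sign == "-", -2, ifelse(sign == "+", 2, 0.1))
  tibble::tibble(
    gene = genes, profile_id = profile_ids,
    category = category_of(tax, profile_ids),
    p = p, b = b, score = b * p,
    sign = ifelse(sign == "0", "0", ifelse(b >= 0, "+", "-"))
  )
}

fake_meta <- function(ids) {
  tibble::tibble(dataset = ids, accession = ids, species = "Human",
                 cell_type = "moDC", signal_X = "TNF", signal_Y = "IFNb",
                 time_point = "1h")
}

test_that("landscapes assemble calls with metadata and reject bad input", {
  tax <- test_taxonomy()
  set.seed(91)
  prof <- tidy(tax)
  calls <- list(
    d1 = fake_calls(tax, sprintf("G%02d", 1:10),
                    sample(prof$id[prof$sign != "0"], 10)),
    d2 = fake_calls(tax, sprintf("G%02d", 1:10),
                    sample(prof$id[prof$sign != "0"], 10))
  )
  ls <- build_landscape(calls, fake_meta(c("d1", "d2")), taxonomy = tax)
  expect_equal(nrow(ls$calls), 20L)
  expect_equal(nrow(tidy(ls)), 20L)
  expect_true("species" %in% colnames(tidy(ls)))

  expect_error(build_landscape(calls, fake_meta(c("d1", "d1"))),
               "duplicate dataset")
  expect_error(build_landscape(calls, fake_meta("d1")), "without metadata")
  # empty gene families are fine at build time, slicing then errors
  ls2 <- build_landscape(calls, fake_meta(c("d1", "d2")),
                         gene_families = tibble::tibble(family = character(0),
                                                        gene = character(0)),
                         taxonomy = tax)
  expect_error(slice_landscape(ls2, "checkpoints"), "unknown gene family")
})

test_that("category frequencies are proportions over interacting calls", {
  tax <- test_taxonomy()
  prof <- tidy(tax)
  pick <- function(cat, n) rep(prof$id[prof$category == cat][1], n)
  ids <- c(pick("suppression", 4), pick("potentiation", 3),
           pick("emergent", 2), pick("inhibition", 1),
           pick("additive", 5))  # additive excluded from the denominator
  calls <- list(d1 = fake_calls(tax, sprintf("G%02d", seq_along(ids)), ids))
  ls <- build_landscape(calls, fake_meta("d1"), taxonomy = tax)
  freq <- profile_frequencies(ls)
  expect_equal(sum(freq$proportion), 1)
  expect_equal(freq$proportion[freq$category == "suppression"], 0.4)
  expect_equal(freq$proportion[freq$category == "restoration"], 0)
  expect_true(all(freq$proportion >= 0 & freq$proportion <= 1))
  expect_s3_class(plot_profile_frequencies(ls), "ggplot")
})

test_that("planted category mixes are recovered within multinomial error", {
  tax <- test_taxonomy()
  prof <- tidy(tax)
  set.seed(92)
  n <- 2000
  cats <- sample(c("suppression", "inhibition", "emergent"), n, replace = TRUE,
                 prob = c(0.5, 0.3, 0.2))
  ids <- vapply(cats, function(cc) sample(prof$id[prof$category == cc], 1), 0L)
  ls <- build_landscape(list(d1 = fake_calls(tax, sprintf("G%05d", 1:n), ids)),
                        fake_meta("d1"), taxonomy = tax)
  freq <- profile_frequencies(ls)
  for (cc in c("suppression", "inhibition", "emergent")) {
    target <- c(suppression = 0.5, inhibition = 0.3, emergent = 0.2)[[cc]]
    expect_lt(abs(freq$proportion[freq$category == cc] - target),
              4 * sqrt(target * (1 - target) / n))
  }
})

test_that("slices project the landscape losslessly", {
  tax <- test_taxonomy()
  prof <- tidy(tax)
  set.seed(93)
  mk <- function(genes) fake_calls(tax, genes,
                                   sample(prof$id[prof$sign != "0"],
                                          length(genes)))
  calls <- list(d1 = mk(c("g1", "g2")), d2 = mk("g2"), d3 = mk(c("g1", "g3")))
  fams <- tibble::tibble(family = c("fam", "fam", "fam", "other"),
                         gene = c("g1", "g2", "g3", "g9"))
  ls <- build_landscape(calls, fake_meta(c("d1", "d2", "d3")),
                        gene_families = fams, taxonomy = tax)
  sl <- slice_landscape(ls, "fam", datasets = c("d1", "d2", "d3"))
  expect_equal(nrow(sl), 5L)  # five filled (gene, dataset) cells
  expect_equal(sl$abs_score, abs(sl$score))
  g1 <- slice_landscape(ls, "fam", datasets = "d1")
  expect_equal(nrow(g1), 2L)
  # default filter = all datasets
  expect_equal(nrow(slice_landscape(ls, "fam")), 5L)
  expect_error(slice_landscape(ls, "fam", datasets = "dX"),
               "unknown dataset")
  # union of single-dataset slices reconstructs the family's call set
  pieces <- dplyr::bind_rows(lapply(c("d1", "d2", "d3"), function(d)
    slice_landscape(ls, "fam", datasets = d)))
  expect_equal(dplyr::arrange(tibble::as_tibble(pieces), gene, dataset),
               dplyr::arrange(tibble::as_tibble(sl), gene, dataset),
               ignore_attr = TRUE)
  p <- ggplot2::autoplot(sl)
  expect_s3_class(p, "ggplot")
})

test_that("qualitative changes route by category and focal role", {
  tax <- test_taxonomy()
  prof <- tidy(tax)
  # profile whose suppression acts on X's effect, its mirror acts on Y's
  supX <- prof[prof$category == "suppression" & prof$modifies == "X", ][1, ]
  es <- prof[prof$name == "emergent synergy", ]
  add <- prof[prof$category == "additive", ][1, ]
  calls <- list(d1 = fake_calls(tax, c("gs", "ge", "ga"),
                                c(supX$id, es$id, add$id)))
  ls <- build_landscape(calls, fake_meta("d1"), taxonomy = tax)

  qx <- qualitative_change_analysis(ls, focal_role = "X")
  expect_true(all(c("gs", "ge") %in% qx$gene))
  expect_false("ga" %in% qx$gene)
  expect_equal(qx$change_type[qx$gene == "gs"], "suppression")

  qy <- qualitative_change_analysis(ls, focal_role = "Y")
  expect_false("gs" %in% qy$gene)       # X-directed suppression drops out
  expect_true("ge" %in% qy$gene)        # emergent counts for either role

  # role-swap involution: relabelling X<->Y via mirror profiles and
  # swapping the focal role reproduces the original analysis
  mirrored <- calls$d1
  mirrored$profile_id <- prof$mirror_id[match(mirrored$profile_id, prof$id)]
  mirrored$category <- category_of(tax, mirrored$profile_id)
  ls_m <- build_landscape(list(d1 = mirrored), fake_meta("d1"),
                          taxonomy = tax)
  qym <- qualitative_change_analysis(ls_m, focal_role = "Y")
  expect_equal(qym$gene, qx$gene)
  expect_equal(qym$change_type, qx$change_type)

  expect_equal(nrow(qualitative_change_analysis(
    ls, "X", change_types = "synergistic_reversal")), 0L)
  expect_error(qualitative_change_analysis(ls, "X", change_types = "floor"),
               "unsupported change type")
  meta_na <- fake_meta("d1")
  meta_na$signal_X <- NA_character_
  ls_na <- build_landscape(calls, meta_na, taxonomy = tax)
  expect_error(qualitative_change_analysis(ls_na, "X"), "absent from metadata")
})

test_that("emergent functions are combo-enriched terms absent from the mono list", {
  universe <- sprintf("G%03d", 1:200)
  combo <- universe[1:20]
  mono <- universe[101:120]
  collection <- list(
    combo_term = universe[1:25],     # enriched in combo only
    both_term = c(combo[1:10], mono[1:10]),  # enriched in both lists
    neither = universe[151:180]
  )
  out <- emergent_functions(combo, mono, collection, universe)
  expect_true("combo_term" %in% out$term)
  expect_false("both_term" %in% out$term)
  expect_false("neither" %in% out$term)
  # empty mono list: every combo-enriched term is emergent
  out2 <- emergent_functions(combo, character(0), collection, universe)
  expect_true(all(c("combo_term", "both_term") %in% out2$term))
})
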