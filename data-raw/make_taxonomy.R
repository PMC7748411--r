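# Regenerate the packaged taxonomy definition file from the enumeration rule.
# Run from the package root:  Rscript data-raw/make_taxonomy.R
devtools::load_all(".", quiet = TRUE)
prof <- enumerate_interaction_profiles()
stopifnot(nrow(prof) == 123L)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_taxonomy(prof, "inst/extdata/taxonomy.tsv")
cat("wrote inst/extdata/taxonomy.tsv with", nrow(prof), "profiles\n")
print(table(prof$category))
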