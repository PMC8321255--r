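# Shared, lazily-built fixtures. The default synthetic cohort (35 patients,
# 8:27) is generated and fully extracted once per test run and reused by the
# pipeline and acceptance tests.

.fixture_env <- new.env(parent = emptyenv())

default_cohort_fixture <- function() {
  if (is.null(.fixture_env$cohort)) {
    dir <- file.path(tempdir(), "radpseudo-fixture-cohort")
    co <- generate_cohort(cohort_spec(seed = 20260901), dir)
    tab <- extract_cohort(co)
    clin <- encode_clinical(co$records)
    full <- cbind(tab[, setdiff(names(tab), "label")], clin,
                  label = tab$label)
    .fixture_env$cohort <- list(cohort = co, table = tab, clinical = clin,
                                full_table = full,
                                clinical_features = names(clin))
  }
  .fixture_env$cohort
}

null_cohort_fixture <- function() {
  if (is.null(.fixture_env$null_cohort)) {
    dir <- file.path(tempdir(), "radpseudo-fixture-null")
    co <- generate_cohort(cohort_spec(effect_floor = 0, effect_zone = 1,
                                      seed = 7), dir)
    tab <- extract_cohort(co)
    .fixture_env$null_cohort <- list(cohort = co, table = tab)
  }
  .fixture_env$null_cohort
}
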