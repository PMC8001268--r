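test_that("change query validation requires a usable predicate", {
  expect_error(change_query(""), "non-empty")
  expect_error(change_query("ClinVar"), "at least one of")
  q <- change_query("ClinVar", previous_in = "benign")
  expect_s3_class(q, "change_query")
})

test_that("change search finds exactly the transitioned variant", {
  st <- store_with_variants(c("chr1|1|A|G", "chr1|2|A|G", "chr1|3|A|G"))
  w <- function(id, values) {
    for (j in seq_along(values)) {
      record_attribute(st, id, "ClinVar", values[j],
                       source = sprintf("f%d", j),
                       imported_at = sprintf("2021-0%d-01T00:00:00", j))
    }
  }
  w("chr1|1|A|G", c("uncertain significance", "pathogenic"))  # V1: hit
  w("chr1|2|A|G", "pathogenic")                               # no change
  w("chr1|3|A|G", c("benign", "likely benign"))               # wrong now
  q <- change_query("ClinVar",
                    previous_in = c("benign", "uncertain significance"),
                    current_equals = "pathogenic")
  res <- search_changes(st, q)
  expect_equal(res$variant, "chr1|1|A|G")
  expect_equal(res$previous_value, "uncertain significance")
  expect_equal(res$current_value, "pathogenic")

  # empty store, late since, unknown attribute
  expect_equal(nrow(search_changes(variant_store(), q)), 0L)
  q_late <- change_query("ClinVar", previous_in = "benign",
                         current_equals = "pathogenic",
                         since = "2030-01-01T00:00:00")
  expect_equal(nrow(search_changes(st, q_late)), 0L)
  q_missing <- change_query("nope", current_equals = "x")
  expect_equal(nrow(search_changes(st, q_missing)), 0L)
})

test_that("since, strict-previous and case folding refine change search", {
  st <- store_with_variants("chr1|1|A|G")
  vals <- c("benign", "uncertain significance", "pathogenic")
  for (j in seq_along(vals)) {
    record_attribute(st, "chr1|1|A|G", "ClinVar", vals[j],
                     source = "f", imported_at =
                       sprintf("2021-0%d-01T00:00:00", j))
  }
  # any-prior (default): benign qualifies even though not immediate
  q_any <- change_query("ClinVar", previous_in = "benign",
                        current_equals = "pathogenic")
  expect_equal(nrow(search_changes(st, q_any)), 1L)
  # strict: only the immediate predecessor counts
  q_strict <- change_query("ClinVar", previous_in = "benign",
                           current_equals = "pathogenic",
                           strict_previous = TRUE)
  expect_equal(nrow(search_changes(st, q_strict)), 0L)
  q_strict2 <- change_query("ClinVar",
                            previous_in = "uncertain significance",
                            current_equals = "pathogenic",
                            strict_previous = TRUE)
  expect_equal(nrow(search_changes(st, q_strict2)), 1L)
  # since boundary: current entry imported exactly at `since` matches
  q_since <- change_query("ClinVar", previous_in = "benign",
                          current_equals = "pathogenic",
                          since = "2021-03-01T00:00:00")
  expect_equal(nrow(search_changes(st, q_since)), 1L)
  # case-insensitive matching
  q_case <- change_query("ClinVar", previous_in = "Benign",
                         current_equals = "Pathogenic",
                         ignore_case = TRUE)
  expect_equal(nrow(search_changes(st, q_case)), 1L)
  expect_equal(nrow(search_changes(
    st, change_query("ClinVar", previous_in = "Benign",
                     current_equals = "Pathogenic"))), 0L)
})

test_that("change search agrees with the brute-force history oracle", {
  queries <- list(
    change_query("ClinVar",
                 previous_in = c("benign", "uncertain significance"),
                 current_equals = "pathogenic"),
    change_query("ClinVar", previous_in = "benign"),
    change_query("ClinVar", current_equals = "pathogenic"),
    change_query("ClinVar", previous_in = "uncertain significance",
                 current_equals = c("pathogenic", "likely pathogenic"),
                 strict_previous = TRUE),
    change_query("ClinVar", previous_in = "benign",
                 current_equals = "pathogenic",
                 since = "2021-03-01T00:00:00")
  )
  set.seed(99)
  for (i in 1:250) {
    st <- random_history_store(n_variants = 4L)
    q <- queries[[sample.int(length(queries), 1L)]]
    expect_equal(search_changes(st, q)$variant, brute_force_changes(st, q),
                 info = sprintf("store %d", i))
  }
})

test_that("results with previous_in set always have history length >= 2", {
  set.seed(5)
  for (i in 1:20) {
    st <- random_history_store(6L)
    q <- change_query("ClinVar", previous_in = c("benign", "pathogenic"))
    for (id in search_changes(st, q)$variant) {
      expect_gte(nrow(attribute_history(st, id, "ClinVar")), 2L)
    }
  }
})

test_that("variant search matches all current-value criteria", {
  st <- store_with_variants(sprintf("chr1|%d|A|G", 1:20))
  ids <- variant_ids(st)
  for (i in seq_along(ids)) {
    classify(st, "chr1", i, "A", "G", if (i <= 7) "C5" else "C2")
    record_attribute(st, ids[i], "gene",
                     if (i %% 2 == 0) "BRCA1" else "BRCA2")
  }
  res <- search_variants(st, c(classification = "C5"))
  expect_equal(nrow(res), 7L)
  expect_equal(unique(res$classification), "C5")
  res2 <- search_variants(st, c(classification = "C5", gene = "BRCA1"))
  expect_equal(nrow(res2), 3L)
  expect_equal(nrow(search_variants(st)), 20L)          # empty criteria
  expect_equal(nrow(search_variants(st, c(nope = "x"))), 0L)
})

test_that("classification summary reproduces printed-percentage arithmetic", {
  st <- variant_store()
  counts <- c(C5 = 330L, C4 = 38L, C3 = 333L, C2 = 206L, C1 = 109L)
  i <- 0L
  for (tier in names(counts)) {
    for (j in seq_len(counts[[tier]])) {
      i <- i + 1L
      classify(st, "chr1", i, "A", "G", tier)
    }
  }
  s <- classification_summary(st)
  expect_equal(attr(s, "total"), 1016L)
  expect_equal(s$count[match(c("C5", "C4", "C3", "C2", "C1"), s$code)],
               c(330L, 38L, 333L, 206L, 109L))
  expect_equal(s$percent[match(c("C5", "C4", "C3", "C2", "C1"), s$code)],
               c(32.5, 3.7, 32.8, 20.3, 10.7))
  # one-decimal rounding slack on the total
  expect_lt(abs(sum(s$percent) - 100), 0.2 + 1e-9)
})

test_that("summary edge cases: single variant and empty store", {
  st <- variant_store()
  classify(st, "chr1", 1, "A", "G", "C3")
  s <- classification_summary(st)
  expect_equal(attr(s, "total"), 1L)
  expect_equal(s$percent[s$code == "C3"], 100.0)

  s0 <- classification_summary(variant_store())
  expect_equal(nrow(s0), 0L)
  expect_equal(attr(s0, "total"), 0L)
})

test_that("summary percents sum to ~100 for random tier assignments", {
  set.seed(13)
  for (i in 1:25) {
    st <- variant_store()
    n <- sample(3:60, 1)
    for (j in seq_len(n)) {
      classify(st, "chr2", j, "A", "G",
               sample(classification_tiers()$code, 1))
    }
    s <- classification_summary(st)
    expect_lt(abs(sum(s$percent) - 100), 0.2 + 1e-9)
    expect_equal(sum(s$count), attr(s, "total"))
  }
})
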