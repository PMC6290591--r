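cfg <- normalization_config()

test_that("normalize_term tokenizes, strips tags and drops stop words", {
  expect_equal(
    normalize_term("Surgical biopsy of gastrointestinal tract (procedure)", cfg),
    sort(c("surgical", "biopsy", "gastrointestinal", "tract")))
  expect_equal(
    normalize_term("CT guided drainage of lesion of pelvis", cfg),
    sort(c("ct", "guided", "drainage", "lesion", "pelvis")))
  # all stop words -> empty multiset, not an error
  expect_identical(normalize_term("the of a an", cfg), character(0))
  # commas trimmed from token edges, hyphenated words stay single tokens
  expect_equal(
    normalize_term("Non-surgical gastrointestinal tract biopsy (procedure)", cfg),
    sort(c("non-surgical", "gastrointestinal", "tract", "biopsy")))
  expect_false("transverse," %in% normalize_term(
    "Tarsometatarsal arthrodesis, transverse, with osteotomy as for flatfoot correction (procedure)",
    cfg))
  # duplicates preserved: multiset, not set
  expect_equal(normalize_term("lavage lavage fluid", cfg),
               c("fluid", "lavage", "lavage"))
  expect_error(normalize_term("", cfg), "non-empty")
})

test_that("normalize_term is idempotent on re-joined tokens", {
  terms <- c(
    "Drainage of lesion of pelvis using computed tomography guidance (procedure)",
    "Non-surgical gastrointestinal tract biopsy (procedure)",
    "Referral to young disabled service (procedure)")
  for (t in terms) {
    once <- normalize_term(t, cfg)
    expect_identical(normalize_term(paste(once, collapse = " "), cfg), once)
  }
})

test_that("word_difference cancels with multiplicity and mirrors", {
  a <- c("drainage", "lesion", "pelvis", "computed", "tomography", "guidance")
  b <- c("computer", "tomography", "guided", "drainage", "pancreatic", "lesion")
  d <- word_difference(a, b)
  expect_equal(d$a_only, sort(c("pelvis", "computed", "guidance")))
  expect_equal(d$b_only, sort(c("computer", "guided", "pancreatic")))
  m <- word_difference(b, a)
  expect_identical(m$a_only, d$b_only)
  expect_identical(m$b_only, d$a_only)
  # identical bags
  expect_identical(word_difference(a, a), list(a_only = character(0),
                                               b_only = character(0)))
  # multiplicity: one shared occurrence cancels, the extra one remains
  d2 <- word_difference(c("x", "x", "y"), c("x", "z", "z"))
  expect_equal(d2$a_only, c("x", "y"))
  expect_equal(d2$b_only, c("z", "z"))
})

test_that("multiset size is conserved under word_difference", {
  set.seed(42)
  vocab <- letters[1:6]
  for (i in 1:200) {
    a <- sample(vocab, sample(0:8, 1), replace = TRUE)
    b <- sample(vocab, sample(0:8, 1), replace = TRUE)
    d <- word_difference(a, b)
    expect_equal(length(d$a_only) - length(d$b_only), length(a) - length(b))
  }
})

test_that("is_one_word_apart is a symmetric single-substitution test", {
  t1a <- normalize_term(
    "Tarsometatarsal arthrodesis, transverse, with osteotomy as for flatfoot correction (procedure)", cfg)
  t1b <- normalize_term(
    "Midtarsal arthrodesis, transverse, with osteotomy as for flatfoot correction (procedure)", cfg)
  expect_true(is_one_word_apart(t1a, t1b))
  expect_true(is_one_word_apart(t1b, t1a))
  expect_false(is_one_word_apart(t1a, t1a))
  # three-word FSN difference
  t2a <- normalize_term(
    "Drainage of lesion of pelvis using computed tomography guidance (procedure)", cfg)
  t2b <- normalize_term(
    "Computer tomography guided drainage of pancreatic lesion (procedure)", cfg)
  expect_false(is_one_word_apart(t2a, t2b))
  # strict subset (unequal sizes) never qualifies
  expect_false(is_one_word_apart(c("a1", "b1", "c1"), c("a1", "b1")))
  expect_false(is_one_word_apart(c("a1", "b1", "c1", "d1"),
                                 c("a1", "b1", "c1", "d1", "e1")))
})

test_that("is_one_word_apart is false whenever sizes differ (property)", {
  set.seed(7)
  vocab <- letters
  for (i in 1:100) {
    a <- sample(vocab, sample(1:8, 1))
    b <- sample(vocab, sample(1:8, 1))
    if (length(a) != length(b)) expect_false(is_one_word_apart(a, b))
    expect_identical(is_one_word_apart(a, b), is_one_word_apart(b, a))
  }
})

test_that("eligibility threshold counts the semantic tag when configured", {
  # four content words + tag token = 5
  expect_true(is_eligible_fsn("Referral to young disabled service (procedure)", cfg))
  expect_false(is_eligible_fsn("Short name (procedure)", cfg))
  expect_true(is_eligible_fsn(
    "Tarsometatarsal arthrodesis, transverse, with osteotomy as for flatfoot correction (procedure)", cfg))
  no_tag <- normalization_config(count_tag_for_threshold = FALSE)
  expect_false(is_eligible_fsn("Referral to young disabled service (procedure)",
                               no_tag))
})

test_that("configuration validates and round-trips through YAML and JSON", {
  expect_error(normalization_config(stop_words = c("The")), "lowercase")
  expect_error(normalization_config(min_words = 0), "positive")
  y <- tempfile(fileext = ".yaml")
  writeLines(c("stop_words: [a, the, of]", "min_words: 3",
               "strip_semantic_tag: true", "count_tag_for_threshold: false"), y)
  cy <- read_normalization_config(y)
  expect_identical(cy$stop_words, c("a", "the", "of"))
  expect_identical(cy$min_words, 3L)
  expect_false(cy$count_tag_for_threshold)
  j <- tempfile(fileext = ".json")
  jsonlite::write_json(list(min_words = 4), j, auto_unbox = TRUE)
  cj <- read_normalization_config(j)
  expect_identical(cj$min_words, 4L)
  expect_identical(cj$stop_words, default_stop_words())
})
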