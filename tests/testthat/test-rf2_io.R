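test_that("concept reader maps rows and the active flag", {
  p <- write_lines_tmp(c(concept_header,
                         concept_line("101", "1"),
                         concept_line("102", "0")))
  cc <- read_concepts(p)
  expect_equal(nrow(cc), 2L)
  expect_identical(cc$concept_id, c("101", "102"))
  expect_identical(cc$active, c(TRUE, FALSE))
  expect_equal(nrow(read_concepts(p, active_only = TRUE)), 1L)
})

test_that("malformed RF2 input fails loudly", {
  expect_error(read_concepts(tempfile()), "not found")
  # wrong header names (right column count)
  p1 <- write_lines_tmp(c("id\ttime\tactive\tmodule\tstatus",
                          concept_line("101")))
  expect_error(read_concepts(p1), "header")
  # wrong column count anywhere is fatal with the line number
  p1b <- write_lines_tmp(c("id\tactive", "1\t1"))
  expect_error(read_concepts(p1b), "malformed.*line")
  # wrong column count on a data line
  p2 <- write_lines_tmp(c(concept_header, concept_line("101"),
                          "102\t20180131\t1"))
  expect_error(read_concepts(p2), "malformed|column|expect")
  # non-numeric concept id, reported with its line number
  p3 <- write_lines_tmp(c(concept_header, concept_line("abc")))
  expect_error(read_concepts(p3), "line.*2")
  # non-integer relationship group, reported with its line number
  p4 <- write_lines_tmp(c(rel_header, rel_line("1", "2", "3", SCT_ISA,
                                               grp = "x")))
  expect_error(read_relationships(p4), "relationshipGroup.*line.*2")
  # is-a self loop
  p5 <- write_lines_tmp(c(rel_header, rel_line("1", "2", "2", SCT_ISA)))
  expect_error(read_relationships(p5), "self-loop")
})

test_that("description reader maps typeIds and filters language", {
  p <- write_lines_tmp(c(
    desc_header,
    desc_line("1", "101", "Foo bar (procedure)", SCT_FSN_TYPE),
    desc_line("2", "101", "Foo bar", SCT_SYNONYM_TYPE),
    desc_line("3", "101", "Une description", SCT_SYNONYM_TYPE, lang = "fr"),
    desc_line("4", "101", "Weird", "12345")))
  expect_warning(dd <- read_descriptions(p), "unknown description typeId")
  expect_identical(dd$type, c("FSN", "SYNONYM", "SYNONYM", "OTHER"))
  suppressWarnings({
    en <- read_descriptions(p, language_filter = "en")
  })
  expect_equal(nrow(en), 3L)
  expect_true(all(en$language_code == "en"))
})

test_that("relationship reader parses groups as integers", {
  p <- write_lines_tmp(c(rel_header,
                         rel_line("1", "2", "3", SCT_ISA, grp = "0"),
                         rel_line("2", "2", "4", "260686004", grp = "2")))
  rr <- read_relationships(p)
  expect_identical(rr$relationship_group, c(0L, 2L))
  expect_identical(rr$type_id[1], SCT_ISA)
})

test_that("generated releases round-trip through the readers", {
  g <- generate_release(fixture_spec(seed = 31, n_template_families = 8L),
                        tempfile("rel"))
  cc <- read_concepts(g$paths[["concepts"]])
  dd <- read_descriptions(g$paths[["descriptions"]])
  rr <- read_relationships(g$paths[["relationships"]])
  expect_equal(nrow(cc), g$manifest$n_concept_rows)
  expect_equal(nrow(dd), g$manifest$n_description_rows)
  expect_equal(nrow(rr), g$manifest$n_relationship_rows)
  expect_true(all(grepl("^[0-9]+$", cc$concept_id)))
})

test_that("hierarchy closure follows active is-a edges transitively", {
  cc <- data.table::data.table(
    concept_id = c("R", "B", "A", "X", "I"),
    effective_time = "t", active = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    module_id = "m", definition_status_id = "d")
  rr <- data.table::data.table(
    relationship_id = as.character(1:4),
    source_id = c("B", "A", "X", "I"),
    destination_id = c("R", "B", "X2", "R"),
    type_id = SCT_ISA, relationship_group = 0L,
    active = c(TRUE, TRUE, TRUE, TRUE),
    characteristic_type_id = "c")
  # chain A is-a B is-a R; X attached elsewhere; I inactive
  expect_identical(hierarchy_members("R", cc, rr), sort(c("R", "B", "A")))
  # root with no children
  expect_identical(hierarchy_members("X", cc, rr), "X")
  expect_error(hierarchy_members("missing", cc, rr), "absent")
  # deactivating the chain edge shrinks the closure
  rr2 <- data.table::copy(rr); rr2$active[2] <- FALSE
  expect_identical(hierarchy_members("R", cc, rr2), sort(c("R", "B")))
})

test_that("a cycle among is-a edges is fatal and names its concepts", {
  cc <- data.table::data.table(
    concept_id = c("R", "B", "A"), effective_time = "t", active = TRUE,
    module_id = "m", definition_status_id = "d")
  rr <- data.table::data.table(
    relationship_id = as.character(1:3),
    source_id = c("B", "A", "B"),
    destination_id = c("R", "B", "A"),
    type_id = SCT_ISA, relationship_group = 0L, active = TRUE,
    characteristic_type_id = "c")
  expect_error(hierarchy_members("R", cc, rr), "cycle.*A.*B")
})

test_that("closure equals the brute-force fixed point on generated releases", {
  for (seed in c(5, 17, 29)) {
    g <- generate_release(fixture_spec(seed = seed, n_template_families = 6L),
                          tempfile("rel"))
    cc <- read_concepts(g$paths[["concepts"]])
    rr <- read_relationships(g$paths[["relationships"]])
    root <- g$manifest$root_id
    got <- hierarchy_members(root, cc, rr)
    expect_identical(got, bf_hierarchy(root, cc, rr))
    expect_identical(got, sort(unlist(g$manifest$hierarchy_members),
                               method = "radix"))
    # monotonicity: dropping any single active is-a edge never grows the set
    isa_rows <- which(rr$active & rr$type_id == SCT_ISA)
    for (i in sample(isa_rows, 5)) {
      rr2 <- data.table::copy(rr); rr2$active[i] <- FALSE
      expect_true(all(hierarchy_members(root, cc, rr2) %in% got))
    }
  }
})
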