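# Independent oracles and small construction helpers shared by the tests.

# brute-force fixed point over the active is-a edge list; independent of
# hierarchy_members' BFS
bf_hierarchy <- function(root_id, concepts, relationships) {
  act <- concepts$concept_id[concepts$active]
  isa <- relationships[relationships$active &
                         relationships$type_id == SCT_ISA &
                         relationships$source_id %in% act &
                         relationships$destination_id %in% act, ]
  members <- root_id
  repeat {
    nxt <- union(members, isa$source_id[isa$destination_id %in% members])
    if (length(nxt) == length(members)) break
    members <- nxt
  }
  sort(members, method = "radix")
}

# hand-built token-bag table (bypasses RF2 reading)
make_bags <- function(...) {
  specs <- list(...)
  data.table::data.table(
    concept_id = vapply(specs, `[[`, "", "concept_id"),
    description_id = vapply(specs, `[[`, "", "description_id"),
    kind = vapply(specs, `[[`, "", "kind"),
    tokens = lapply(specs, function(s) sort(s$tokens, method = "radix"))
  )
}

bag <- function(concept_id, tokens, description_id = paste0("d", concept_id),
                kind = "FSN") {
  list(concept_id = concept_id, description_id = description_id,
       kind = kind, tokens = tokens)
}

# minimal RF2 writers for malformed-input tests
write_lines_tmp <- function(lines, name = "rf2.txt") {
  path <- tempfile(fileext = paste0("-", name))
  writeLines(lines, path)
  path
}

concept_header <- "id\teffectiveTime\tactive\tmoduleId\tdefinitionStatusId"
rel_header <- paste("id", "effectiveTime", "active", "moduleId", "sourceId",
                    "destinationId", "relationshipGroup", "typeId",
                    "characteristicTypeId", "modifierId", sep = "\t")
desc_header <- paste("id", "effectiveTime", "active", "moduleId", "conceptId",
                     "languageCode", "typeId", "term", "caseSignificanceId",
                     sep = "\t")

concept_line <- function(id, active = "1") {
  paste(id, "20180131", active, "m", "d", sep = "\t")
}
rel_line <- function(id, src, dst, type, grp = "0", active = "1") {
  paste(id, "20180131", active, "m", src, dst, grp, type, "c", "x", sep = "\t")
}
desc_line <- function(id, cid, term, type, active = "1", lang = "en") {
  paste(id, "20180131", active, "m", cid, lang, type, term, "cs", sep = "\t")
}

# all pipeline artifacts from a generated release, as the tests need them
run_on_release <- function(g, seed = 1L, out_dir = NULL) {
  run_audit(g$paths[["concepts"]], g$paths[["descriptions"]],
            g$paths[["relationships"]], root_id = g$manifest$root_id,
            seed = seed, out_dir = out_dir)
}

manifest_classification_table <- function(manifest) {
  dt <- data.table::rbindlist(lapply(manifest$classifications,
                                     data.table::as.data.table))
  dt[order(dt$set_id), ]
}
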