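# Readers for SNOMED CT RF2 "Snapshot" release files and the is-a closure.
#
# RF2 snapshot files are UTF-8 tab-separated with a fixed header row and no
# quoting. Only the Snapshot layout is supported; Full/Delta releases carry
# history rows and are rejected by the snapshot column contract.

# standard RF2 / SNOMED CT constants
#' @rdname rf2_constants
#' @export
SCT_ISA <- "116680003"
#' @rdname rf2_constants
#' @export
SCT_FSN_TYPE <- "900000000000003001"
#' @rdname rf2_constants
#' @export
SCT_SYNONYM_TYPE <- "900000000000013009"
#' Standard SNOMED CT identifiers
#'
#' \code{SCT_ISA}: the is-a relationship typeId; \code{SCT_FSN_TYPE} /
#' \code{SCT_SYNONYM_TYPE}: description typeIds; \code{SCT_PROCEDURE_ROOT}:
#' the Procedure hierarchy root concept.
#' @name rf2_constants
#' @export
SCT_PROCEDURE_ROOT <- "71388002"

RF2_CONCEPT_COLS <- c("id", "effectiveTime", "active", "moduleId",
                      "definitionStatusId")
RF2_DESCRIPTION_COLS <- c("id", "effectiveTime", "active", "moduleId",
                          "conceptId", "languageCode", "typeId", "term",
                          "caseSignificanceId")
RF2_RELATIONSHIP_COLS <- c("id", "effectiveTime", "active", "moduleId",
                           "sourceId", "destinationId", "relationshipGroup",
                           "typeId", "characteristicTypeId", "modifierId")

read_rf2_table <- function(path, expected_cols, what) {
  if (!file.exists(path)) stop("RF2 ", what, " file not found: ", path)
  # fread silently discards ragged trailing lines; enforce the column
  # contract per line so malformed input is fatal with its line number
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != length(expected_cols))
  if (length(bad))
    stop("malformed ", what, " line(s) ", paste(bad, collapse = ", "),
         " in ", path, ": expected ", length(expected_cols), " columns")
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", quote = "", header = TRUE,
                      colClasses = "character", encoding = "UTF-8",
                      fill = FALSE, data.table = TRUE),
    error = function(e) stop("malformed RF2 ", what, " file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!identical(names(dt), expected_cols))
    stop("unexpected ", what, " header in ", path, ": got [",
         paste(names(dt), collapse = ", "), "], expected [",
         paste(expected_cols, collapse = ", "), "] (snapshot layout only)")
  bad <- which(!stats::complete.cases(dt))
  if (length(bad))
    stop("malformed ", what, " line(s) ", paste(bad + 1L, collapse = ", "),
         " in ", path, " (missing fields)")
  dt
}

map_active <- function(x, path) {
  if (!all(x %in% c("0", "1")))
    stop("active column must be '0' or '1' in ", path)
  x == "1"
}

#' Read an RF2 concept snapshot file
#'
#' @param path Path to an \code{sct2_Concept_Snapshot} TSV file.
#' @param active_only Drop inactive concepts. Default \code{FALSE}.
#' @return A \code{data.table} with columns \code{concept_id},
#'   \code{effective_time}, \code{active} (logical), \code{module_id},
#'   \code{definition_status_id}.
#' @export
read_concepts <- function(path, active_only = FALSE) {
  dt <- read_rf2_table(path, RF2_CONCEPT_COLS, "concept")
  bad <- which(!grepl("^[0-9]+$", dt$id))
  if (length(bad))
    stop("non-numeric concept id on line(s) ",
         paste(bad + 1L, collapse = ", "), " in ", path)
  out <- data.table::data.table(
    concept_id = dt$id,
    effective_time = dt$effectiveTime,
    active = map_active(dt$active, path),
    module_id = dt$moduleId,
    definition_status_id = dt$definitionStatusId
  )
  if (active_only) out <- out[out$active, ]
  out[]
}

#' Read an RF2 description snapshot file
#'
#' Description typeIds are mapped to \code{"FSN"}, \code{"SYNONYM"} or
#' \code{"OTHER"}; an unknown typeId is kept as \code{"OTHER"} with a warning.
#'
#' @param path Path to an \code{sct2_Description_Snapshot} TSV file.
#' @param language_filter Optional language code (e.g. \code{"en"}); rows with
#'   another \code{languageCode} are excluded.
#' @param active_only Drop inactive descriptions. Default \code{FALSE}.
#' @return A \code{data.table} with columns \code{description_id},
#'   \code{concept_id}, \code{type}, \code{term}, \code{active},
#'   \code{language_code}.
#' @export
read_descriptions <- function(path, language_filter = NULL,
                              active_only = FALSE) {
  dt <- read_rf2_table(path, RF2_DESCRIPTION_COLS, "description")
  type <- rep("OTHER", nrow(dt))
  type[dt$typeId == SCT_FSN_TYPE] <- "FSN"
  type[dt$typeId == SCT_SYNONYM_TYPE] <- "SYNONYM"
  unknown <- setdiff(unique(dt$typeId), c(SCT_FSN_TYPE, SCT_SYNONYM_TYPE,
                                          "900000000000550004"))
  if (length(unknown))
    warning("unknown description typeId(s) kept as OTHER: ",
            paste(unknown, collapse = ", "))
  out <- data.table::data.table(
    description_id = dt$id,
    concept_id = dt$conceptId,
    type = type,
    term = dt$term,
    active = map_active(dt$active, path),
    language_code = dt$languageCode
  )
  if (!is.null(language_filter))
    out <- out[out$language_code %in% language_filter, ]
  if (any(out$active & !nzchar(out$term)))
    stop("active description with empty term in ", path)
  if (active_only) out <- out[out$active, ]
  out[]
}

#' Read an RF2 relationship snapshot file
#'
#' @param path Path to an \code{sct2_Relationship_Snapshot} (stated or
#'   inferred) TSV file. Which of the two files to feed is the caller's
#'   choice and is recorded in the pipeline run log.
#' @param active_only Drop inactive relationships. Default \code{FALSE}.
#' @return A \code{data.table} with columns \code{relationship_id},
#'   \code{source_id}, \code{destination_id}, \code{type_id},
#'   \code{relationship_group} (integer), \code{active},
#'   \code{characteristic_type_id}.
#' @export
read_relationships <- function(path, active_only = FALSE) {
  dt <- read_rf2_table(path, RF2_RELATIONSHIP_COLS, "relationship")
  grp <- suppressWarnings(as.integer(dt$relationshipGroup))
  bad <- which(is.na(grp) | grp < 0L |
                 dt$relationshipGroup != as.character(grp))
  if (length(bad))
    stop("non-integer relationshipGroup on line(s) ",
         paste(bad + 1L, collapse = ", "), " in ", path)
  out <- data.table::data.table(
    relationship_id = dt$id,
    source_id = dt$sourceId,
    destination_id = dt$destinationId,
    type_id = dt$typeId,
    relationship_group = grp,
    active = map_active(dt$active, path),
    characteristic_type_id = dt$characteristicTypeId
  )
  selfloop <- out$active & out$type_id == SCT_ISA &
    out$source_id == out$destination_id
  if (any(selfloop))
    stop("active is-a self-loop for concept(s) ",
         paste(unique(out$source_id[selfloop]), collapse = ", "), " in ", path)
  if (active_only) out <- out[out$active, ]
  out[]
}

#' Active members of a hierarchy (descendants-or-self of a root)
#'
#' Follows active is-a edges from child (\code{source_id}) to parent
#' (\code{destination_id}) transitively, starting at \code{root_id}. Only
#' active concepts are returned; edges touching inactive concepts are
#' ignored.
#'
#' @param root_id Root concept identifier (e.g. [SCT_PROCEDURE_ROOT]).
#' @param concepts Concept table from [read_concepts()].
#' @param relationships Relationship table from [read_relationships()].
#' @return Character vector of member concept identifiers (root included),
#'   sorted.
#' @export
hierarchy_members <- function(root_id, concepts, relationships) {
  act <- concepts$concept_id[concepts$active]
  if (!root_id %in% act)
    stop("root concept ", root_id, " absent from active concepts")
  isa <- relationships[relationships$active &
                         relationships$type_id == SCT_ISA &
                         relationships$source_id %in% act &
                         relationships$destination_id %in% act, ]
  children <- split(isa$source_id, isa$destination_id)
  members <- character(0)
  frontier <- root_id
  seen <- new.env(parent = emptyenv())
  assign(root_id, TRUE, envir = seen)
  while (length(frontier)) {
    members <- c(members, frontier)
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- nxt[!vapply(nxt, exists, logical(1), envir = seen)]
    for (id in nxt) assign(id, TRUE, envir = seen)
    frontier <- nxt
  }
  check_acyclic(members, isa)
  sort(members, method = "radix")
}

# Iteratively trims nodes that cannot lie on a cycle (no incoming or no
# outgoing is-a edge among the remaining nodes); anything left sits on or
# between cycles, a fatal modeling error for a subtype hierarchy.
check_acyclic <- function(members, isa) {
  src <- isa$source_id
  dst <- isa$destination_id
  keep_edge <- src %in% members & dst %in% members
  src <- src[keep_edge]; dst <- dst[keep_edge]
  nodes <- members
  repeat {
    core <- intersect(unique(src), unique(dst))
    if (length(core) == length(nodes)) break
    nodes <- core
    keep_edge <- src %in% nodes & dst %in% nodes
    src <- src[keep_edge]; dst <- dst[keep_edge]
    if (!length(src)) { nodes <- character(0); break }
  }
  if (length(nodes))
    stop("cycle among active is-a relationships involving concept(s): ",
         paste(sort(nodes, method = "radix"), collapse = ", "))
  invisible(TRUE)
}
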