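# Structural profiles and Same/Diff classification of similarity sets.
#
# The working assumption of contextual auditing: lexically similar concepts
# should be modeled alike. Each concept is summarized by three counts over
# its outgoing active relationships — parents (is-a), attributes (non-is-a),
# and role groups (distinct nonzero relationshipGroup values among its
# attributes; group 0 is the ungrouped convention and counts as no group).
# A set where any count differs across members is a Diff_Set, a candidate
# for manual audit; comparison is on counts only, never on attribute types
# or target values, which are left to the human auditor in the report.

#' Structural profiles for a set of concepts
#'
#' @param concept_ids Character vector of concept identifiers.
#' @param relationships Relationship table from [read_relationships()];
#'   inactive rows are ignored.
#' @return A \code{data.table} with one row per requested concept:
#'   \code{concept_id}, \code{parent_count}, \code{attribute_count},
#'   \code{role_group_count}. Concepts with no relationship rows get
#'   all-zero profiles.
#' @export
structural_profiles <- function(concept_ids, relationships) {
  concept_ids <- unique(as.character(concept_ids))
  rel <- relationships[relationships$active &
                         relationships$source_id %in% concept_ids, ]
  isa <- rel[rel$type_id == SCT_ISA, ]
  attr <- rel[rel$type_id != SCT_ISA, ]
  pc <- table(factor(isa$source_id, levels = concept_ids))
  ac <- table(factor(attr$source_id, levels = concept_ids))
  grp <- attr[attr$relationship_group > 0L, ]
  grp <- unique(grp[, c("source_id", "relationship_group")])
  gc <- table(factor(grp$source_id, levels = concept_ids))
  data.table::data.table(
    concept_id = concept_ids,
    parent_count = as.integer(pc[concept_ids]),
    attribute_count = as.integer(ac[concept_ids]),
    role_group_count = as.integer(gc[concept_ids])
  )
}

#' Classify one similarity set as Same_Set or Diff_Set
#'
#' A set is a \code{SAME} set iff all members agree on all three structural
#' counts; otherwise it is \code{DIFF} with non-exclusive subtype flags:
#' \code{diff_par} (parent counts differ), \code{diff_rel} (attribute counts
#' differ), \code{diff_grp} (role-group counts differ).
#'
#' @param member_ids Character vector of the set's member concept ids.
#' @param profiles Profile table from [structural_profiles()] covering every
#'   member (missing members are fatal).
#' @return Named list: \code{kind} (\code{"SAME"}/\code{"DIFF"}),
#'   \code{diff_par}, \code{diff_rel}, \code{diff_grp}.
#' @export
classify_set <- function(member_ids, profiles) {
  p <- profiles[match(member_ids, profiles$concept_id), ]
  if (anyNA(p$concept_id))
    stop("missing structural profile for concept(s): ",
         paste(member_ids[is.na(p$concept_id)], collapse = ", "))
  diff_par <- length(unique(p$parent_count)) > 1L
  diff_rel <- length(unique(p$attribute_count)) > 1L
  diff_grp <- length(unique(p$role_group_count)) > 1L
  list(kind = if (diff_par || diff_rel || diff_grp) "DIFF" else "SAME",
       diff_par = diff_par, diff_rel = diff_rel, diff_grp = diff_grp)
}

#' Classify every similarity set
#'
#' @param sets Set table from [form_sets()].
#' @param profiles Profile table from [structural_profiles()].
#' @return A \code{data.table} with columns \code{set_id}, \code{n_members},
#'   \code{kind}, \code{diff_par}, \code{diff_rel}, \code{diff_grp}.
#' @export
classify_sets <- function(sets, profiles) {
  cls <- lapply(sets$member_ids, classify_set, profiles = profiles)
  data.table::data.table(
    set_id = sets$set_id,
    n_members = sets$n_members,
    kind = vapply(cls, `[[`, character(1), "kind"),
    diff_par = vapply(cls, `[[`, logical(1), "diff_par"),
    diff_rel = vapply(cls, `[[`, logical(1), "diff_rel"),
    diff_grp = vapply(cls, `[[`, logical(1), "diff_grp")
  )
}
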