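# Synthetic RF2 snapshot generator with planted ground truth.
#
# The real SNOMED CT releases are license-restricted, so the pipeline is
# exercised on generated releases: structurally valid RF2 snapshot triples
# containing planted similarity-set families (a shared word template plus
# one unique substituted word per member), planted structural discrepancies,
# decoys, and a manifest stating exactly what the pipeline must recover.
# Synthetic identifiers are drawn from a reserved numeric range and are NOT
# valid SCTIDs (no check digit): no licensed content is reproduced beyond
# structure.

EFFECTIVE_TIME <- "20180131"
MODULE_ID <- "900000000000207008"
DEFSTATUS_ID <- "900000000000074008"
CASE_SIG_ID <- "900000000000448009"
CHAR_TYPE_ID <- "900000000000011006"
MODIFIER_ID <- "900000000000451002"

#' Default synthetic vocabulary
#'
#' Pseudo-clinical words built from anatomy-style roots crossed with
#' procedure-style suffixes ("gastrotomy", "nephropexy", ...). All lowercase,
#' unique, free of stop words.
#'
#' @return Character vector of about 900 words.
#' @export
default_vocabulary <- function() {
  roots <- c("gastro", "entero", "hepato", "nephro", "cysto", "colo",
             "duodeno", "ileo", "jejuno", "recto", "sigmoido", "procto",
             "cardio", "angio", "veno", "arterio", "phlebo", "thoraco",
             "pleuro", "broncho", "laryngo", "pharyngo", "tracheo", "rhino",
             "oto", "ophthalmo", "kerato", "retino", "cranio", "myelo",
             "neuro", "arthro", "osteo", "chondro", "myo", "teno", "dermo",
             "litho", "spleno", "pancreato", "cholecysto", "choledocho",
             "hystero", "oophoro", "salpingo")
  suffixes <- c("tomy", "stomy", "ectomy", "plasty", "scopy", "graphy",
                "pexy", "centesis", "desis", "lysis", "rrhaphy", "gram",
                "metry", "clasis", "tripsy", "stasis", "version", "fixation",
                "puncture", "section")
  as.vector(outer(roots, suffixes, paste0))
}

#' Specification of a synthetic RF2 release
#'
#' @param seed Integer seed; the whole release is a deterministic function of
#'   the spec including its seed.
#' @param n_template_families Number of planted similarity-set families.
#' @param family_sizes Named probability vector over set sizes
#'   \code{c("2"=,"3"=,"4"=)}.
#' @param fraction_synonym_only Probability that a family matches via
#'   synonyms only (divergent FSNs three words apart, synonyms one word
#'   apart).
#' @param fraction_diff_par,fraction_diff_rel,fraction_diff_grp Independent
#'   probabilities that a family is planted with a parent-count,
#'   attribute-count, or role-group-count discrepancy; a family with no flag
#'   is a Same family.
#' @param n_decoys_below_threshold Number of decoy pairs one word apart but
#'   with FSNs under the eligibility threshold.
#' @param n_decoys_two_words_apart Number of decoy pairs two words apart.
#' @param vocabulary Word list; every planted word is used at most once
#'   across the release, so no accidental cross-family matches can arise.
#' @return Object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed = 1L,
                         n_template_families = 40L,
                         family_sizes = c("2" = 0.7, "3" = 0.2, "4" = 0.1),
                         fraction_synonym_only = 0.05,
                         fraction_diff_par = 0.55,
                         fraction_diff_rel = 0.35,
                         fraction_diff_grp = 0.15,
                         n_decoys_below_threshold = 6L,
                         n_decoys_two_words_apart = 6L,
                         vocabulary = default_vocabulary()) {
  fracs <- c(fraction_synonym_only, fraction_diff_par, fraction_diff_rel,
             fraction_diff_grp)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (!setequal(names(family_sizes), c("2", "3", "4")))
    stop("family_sizes must be named over sizes 2, 3, 4")
  structure(list(
    seed = as.integer(seed),
    n_template_families = as.integer(n_template_families),
    family_sizes = family_sizes / sum(family_sizes),
    fraction_synonym_only = fraction_synonym_only,
    fraction_diff_par = fraction_diff_par,
    fraction_diff_rel = fraction_diff_rel,
    fraction_diff_grp = fraction_diff_grp,
    n_decoys_below_threshold = as.integer(n_decoys_below_threshold),
    n_decoys_two_words_apart = as.integer(n_decoys_two_words_apart),
    vocabulary = unique(tolower(vocabulary))
  ), class = "fixture_spec")
}

cap1 <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

write_rf2 <- function(dt, cols, path) {
  names(dt) <- cols
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, eol = "\n")
  path
}

#' Generate a synthetic RF2 snapshot release with ground truth
#'
#' Writes \code{sct2_Concept_Snapshot.txt}, \code{sct2_Description_Snapshot.txt},
#' \code{sct2_Relationship_Snapshot.txt} and \code{manifest.json} under
#' \code{out_dir}. Same spec + same seed produces byte-identical files.
#'
#' The release contains: a root concept; structural parent concepts (short,
#' ineligible names); the planted families, each member carrying an FSN (and
#' a redundant preferred-term synonym) of the family template plus one
#' globally unique substituted word, in per-member shuffled word order;
#' synonym-only families whose FSNs are three words apart but whose synonyms
#' are one word apart; decoy pairs below the eligibility threshold or two
#' words apart; a planted structural deviant per Diff family; plus one
#' inactive concept, one inactive description and one inactive relationship
#' to exercise active-row filtering.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with \code{paths} (named: concepts,
#'   descriptions, relationships, manifest) and \code{manifest} (the parsed
#'   ground truth).
#' @export
generate_release <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  words <- sample(spec$vocabulary)
  w_cursor <- 0L
  take_words <- function(n) {
    if (w_cursor + n > length(words))
      stop("vocabulary exhausted: spec requests more unique words than available")
    out <- words[w_cursor + seq_len(n)]
    w_cursor <<- w_cursor + n
    out
  }

  next_concept <- 2000000L
  next_desc <- 7000000L
  next_rel <- 8000000L
  conc <- list(); desc <- list(); rel <- list()

  add_concept <- function(active = "1") {
    next_concept <<- next_concept + 1L
    id <- as.character(next_concept)
    conc[[length(conc) + 1L]] <<- c(id, EFFECTIVE_TIME, active, MODULE_ID,
                                    DEFSTATUS_ID)
    id
  }
  add_desc <- function(concept_id, term, type_id, active = "1") {
    next_desc <<- next_desc + 1L
    desc[[length(desc) + 1L]] <<- c(as.character(next_desc), EFFECTIVE_TIME,
                                    active, MODULE_ID, concept_id, "en",
                                    type_id, term, CASE_SIG_ID)
    invisible(NULL)
  }
  add_rel <- function(source, dest, type_id, group = 0L, active = "1") {
    next_rel <<- next_rel + 1L
    rel[[length(rel) + 1L]] <<- c(as.character(next_rel), EFFECTIVE_TIME,
                                  active, MODULE_ID, source, dest,
                                  as.character(group), type_id, CHAR_TYPE_ID,
                                  MODIFIER_ID)
    invisible(NULL)
  }
  named_concept <- function(name, parent = NULL, active = "1") {
    id <- add_concept(active)
    add_desc(id, paste0(name, " (procedure)"), SCT_FSN_TYPE, active)
    if (!is.null(parent)) add_rel(id, parent, SCT_ISA, 0L, active)
    id
  }

  root_id <- add_concept()
  add_desc(root_id, "Synthetic procedure root (procedure)", SCT_FSN_TYPE)
  # attribute machinery: types and targets live outside the audited hierarchy
  # short names keep scaffold concepts below the eligibility threshold
  attr_types <- vapply(1:4, function(i) {
    id <- add_concept()
    add_desc(id, paste0("Attribute ", i, " (attribute)"), SCT_FSN_TYPE)
    id
  }, character(1))
  attr_targets <- vapply(1:4, function(i) {
    id <- add_concept()
    add_desc(id, paste0("Target ", i, " (value)"), SCT_FSN_TYPE)
    id
  }, character(1))

  hierarchy_ids <- root_id
  manifest_sets <- list()
  manifest_cls <- list()
  decoy_ids <- character(0)

  n_fam <- spec$n_template_families
  sizes <- as.integer(sample(names(spec$family_sizes), n_fam, replace = TRUE,
                             prob = spec$family_sizes))
  syn_only <- stats::runif(n_fam) < spec$fraction_synonym_only
  f_par <- stats::runif(n_fam) < spec$fraction_diff_par
  f_rel <- stats::runif(n_fam) < spec$fraction_diff_rel
  f_grp <- stats::runif(n_fam) < spec$fraction_diff_grp

  for (f in seq_len(n_fam)) {
    k <- sizes[f]
    m <- sample(4:6, 1L)
    template <- take_words(m)
    subs <- take_words(k)
    shared_parent <- named_concept(sprintf("Synthetic parent %d", f), root_id)
    hierarchy_ids <- c(hierarchy_ids, shared_parent)
    extra_parent <- if (f_par[f]) {
      ep <- named_concept(sprintf("Extra parent %d", f), root_id)
      hierarchy_ids <- c(hierarchy_ids, ep)
      ep
    } else NULL
    member_ids <- character(k)
    for (j in seq_len(k)) {
      id <- add_concept()
      member_ids[j] <- id
      content <- sample(c(template, subs[j]))  # member-specific word order
      if (syn_only[f]) {
        extras <- take_words(2L)
        fsn_words <- sample(c(template, subs[j], extras))
        add_desc(id, paste0(cap1(paste(fsn_words, collapse = " ")),
                            " (procedure)"), SCT_FSN_TYPE)
        add_desc(id, cap1(paste(content, collapse = " ")), SCT_SYNONYM_TYPE)
      } else {
        add_desc(id, paste0(cap1(paste(content, collapse = " ")),
                            " (procedure)"), SCT_FSN_TYPE)
        add_desc(id, cap1(paste(content, collapse = " ")), SCT_SYNONYM_TYPE)
      }
      deviant <- j == 1L && (f_par[f] || f_rel[f] || f_grp[f])
      add_rel(id, shared_parent, SCT_ISA)
      add_rel(id, root_id, SCT_ISA)
      if (deviant && f_par[f]) add_rel(id, extra_parent, SCT_ISA)
      # base attribute shape: two role groups of two attributes each
      groups <- c(1L, 1L, 2L, 2L)
      if (deviant && f_grp[f]) groups <- c(1L, 1L, 2L, 3L)
      for (a in 1:4)
        add_rel(id, attr_targets[a], attr_types[a], groups[a])
      if (deviant && f_rel[f])
        add_rel(id, attr_targets[1L], attr_types[1L], 0L)
    }
    hierarchy_ids <- c(hierarchy_ids, member_ids)
    ord <- order(member_ids, method = "radix")
    manifest_sets[[f]] <- list(
      set_id = paste(sort(member_ids, method = "radix"), collapse = "|"),
      member_ids = sort(member_ids, method = "radix"),
      template = sort(template, method = "radix"),
      diff_words = as.list(stats::setNames(subs, member_ids)[ord]),
      evidence_kind = if (syn_only[f]) "SYNONYM" else "FSN"
    )
    any_flag <- f_par[f] || f_rel[f] || f_grp[f]
    manifest_cls[[f]] <- list(
      set_id = manifest_sets[[f]]$set_id,
      kind = if (any_flag) "DIFF" else "SAME",
      diff_par = f_par[f], diff_rel = f_rel[f], diff_grp = f_grp[f]
    )
  }

  # decoy pairs below the eligibility threshold: one word apart, but only
  # four post-stop-word tokens including the semantic tag
  for (d in seq_len(spec$n_decoys_below_threshold)) {
    shared <- take_words(2L)
    uniq <- take_words(2L)
    for (j in 1:2) {
      id <- named_concept(cap1(paste(c(shared, uniq[j]), collapse = " ")),
                          root_id)
      decoy_ids <- c(decoy_ids, id)
      hierarchy_ids <- c(hierarchy_ids, id)
    }
  }
  # decoy pairs two words apart: eligible length, no one-word match
  for (d in seq_len(spec$n_decoys_two_words_apart)) {
    shared <- take_words(4L)
    for (j in 1:2) {
      uniq <- take_words(2L)
      id <- named_concept(cap1(paste(sample(c(shared, uniq)), collapse = " ")),
                          root_id)
      decoy_ids <- c(decoy_ids, id)
      hierarchy_ids <- c(hierarchy_ids, id)
    }
  }

  # inactive rows: must be invisible to the pipeline
  inactive_concept <- named_concept("Synthetic retired concept", root_id,
                                    active = "0")
  if (n_fam > 0L) {
    first_member <- manifest_sets[[1L]]$member_ids[1L]
    add_desc(first_member, cap1(paste(take_words(5L), collapse = " ")),
             SCT_SYNONYM_TYPE, active = "0")
    add_rel(first_member, root_id, SCT_ISA, active = "0")
  }

  to_dt <- function(lst) data.table::as.data.table(do.call(rbind, lst))
  paths <- c(
    concepts = write_rf2(to_dt(conc), RF2_CONCEPT_COLS,
                         file.path(out_dir, "sct2_Concept_Snapshot.txt")),
    descriptions = write_rf2(to_dt(desc), RF2_DESCRIPTION_COLS,
                             file.path(out_dir, "sct2_Description_Snapshot.txt")),
    relationships = write_rf2(to_dt(rel), RF2_RELATIONSHIP_COLS,
                              file.path(out_dir, "sct2_Relationship_Snapshot.txt")),
    manifest = file.path(out_dir, "manifest.json")
  )
  manifest <- list(
    seed = spec$seed,
    root_id = root_id,
    n_concept_rows = length(conc),
    n_description_rows = length(desc),
    n_relationship_rows = length(rel),
    hierarchy_members = sort(hierarchy_ids, method = "radix"),
    sets = manifest_sets,
    classifications = manifest_cls,
    decoy_ids = decoy_ids,
    inactive_concept = inactive_concept
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(paths = paths, manifest = manifest))
}

#' Hand-written fixture of published example concept pairs
#'
#' Writes an RF2 snapshot triple containing five concept pairs whose
#' descriptions are documented examples of the one-word-difference
#' phenomenon in the Procedure hierarchy: an FSN pair differing in one word
#' (tarsometatarsal vs. midtarsal arthrodesis), a pair whose FSNs differ by
#' three words but whose synonyms differ by one (CT-guided drainage of
#' pelvis vs. pancreatic lesion), a pair whose matching words appear in
#' permuted order (surgical vs. non-surgical gastrointestinal tract biopsy),
#' a staged-operation pair (first vs. second stage omphalocele repair) and a
#' referral/discharge pair. The relationship rows are a synthetic
#' reconstruction of the published structural descriptions (parent,
#' attribute and role-group counts), not licensed release content.
#'
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
published_examples_fixture <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  conc <- list(); desc <- list(); rel <- list()
  next_desc <- 71000000L; next_rel <- 72000000L
  add_c <- function(id) conc[[length(conc) + 1L]] <<-
    c(id, EFFECTIVE_TIME, "1", MODULE_ID, DEFSTATUS_ID)
  add_d <- function(cid, term, type_id) {
    next_desc <<- next_desc + 1L
    desc[[length(desc) + 1L]] <<- c(as.character(next_desc), EFFECTIVE_TIME,
                                    "1", MODULE_ID, cid, "en", type_id, term,
                                    CASE_SIG_ID)
  }
  add_r <- function(src, dst, type_id, grp = 0L) {
    next_rel <<- next_rel + 1L
    rel[[length(rel) + 1L]] <<- c(as.character(next_rel), EFFECTIVE_TIME, "1",
                                  MODULE_ID, src, dst, as.character(grp),
                                  type_id, CHAR_TYPE_ID, MODIFIER_ID)
  }
  root <- SCT_PROCEDURE_ROOT
  add_c(root); add_d(root, "Procedure (procedure)", SCT_FSN_TYPE)
  # structural helper concepts (parents, attribute types, targets)
  helpers <- c(par1 = "60001", par2 = "60002", par3 = "60003",
               method = "260686004", site = "405813007",
               tgt1 = "60011", tgt2 = "60012")
  for (id in helpers) {
    add_c(id)
    add_d(id, paste0("Helper concept ", id, " (procedure)"), SCT_FSN_TYPE)
    if (id %in% helpers[c("par1", "par2", "par3")]) add_r(id, root, SCT_ISA)
  }
  std_groups <- function(cid, n_groups = 2L, per_group = 2L) {
    for (g in seq_len(n_groups))
      for (a in seq_len(per_group))
        add_r(cid, helpers[[if (a == 1L) "tgt1" else "tgt2"]],
              helpers[[if (a == 1L) "method" else "site"]], g)
  }

  # pair differing by one FSN word; both modeled alike (two parents, two
  # role groups of two attributes)
  t1 <- c("40742006", "66607001")
  fsn1 <- c(paste0("Tarsometatarsal arthrodesis, transverse, with osteotomy",
                   " as for flatfoot correction (procedure)"),
            paste0("Midtarsal arthrodesis, transverse, with osteotomy as",
                   " for flatfoot correction (procedure)"))
  for (j in 1:2) {
    add_c(t1[j]); add_d(t1[j], fsn1[j], SCT_FSN_TYPE)
    add_r(t1[j], root, SCT_ISA); add_r(t1[j], helpers[["par1"]], SCT_ISA)
    std_groups(t1[j])
  }

  # pair whose FSNs differ by three words but synonyms by one; modeled
  # differently (parent and attribute counts)
  t2 <- c("16550001000119100", "314613007")
  add_c(t2[1])
  add_d(t2[1], paste0("Drainage of lesion of pelvis using computed ",
                      "tomography guidance (procedure)"), SCT_FSN_TYPE)
  add_d(t2[1], "CT guided drainage of lesion of pelvis", SCT_SYNONYM_TYPE)
  add_r(t2[1], root, SCT_ISA); add_r(t2[1], helpers[["par1"]], SCT_ISA)
  std_groups(t2[1], n_groups = 2L, per_group = 2L)
  add_c(t2[2])
  add_d(t2[2], "Computer tomography guided drainage of pancreatic lesion (procedure)",
        SCT_FSN_TYPE)
  add_d(t2[2], "CT guided drainage of pancreatic lesion", SCT_SYNONYM_TYPE)
  add_r(t2[2], root, SCT_ISA)
  add_r(t2[2], helpers[["par2"]], SCT_ISA)
  add_r(t2[2], helpers[["par3"]], SCT_ISA)
  std_groups(t2[2], n_groups = 2L, per_group = 3L)

  # pair with permuted matching words; modeled alike
  t4 <- c("60021", "60022")
  fsn4 <- c("Surgical biopsy of gastrointestinal tract (procedure)",
            "Non-surgical gastrointestinal tract biopsy (procedure)")
  for (j in 1:2) {
    add_c(t4[j]); add_d(t4[j], fsn4[j], SCT_FSN_TYPE)
    add_r(t4[j], root, SCT_ISA)
    std_groups(t4[j], n_groups = 1L)
  }

  # staged-operation pair: first-stage concept has one parent more
  t8 <- c("60031", "60032")
  fsn8 <- c("Gross operation repair of omphalocele, first stage (procedure)",
            "Gross operation repair of omphalocele, second stage (procedure)")
  for (j in 1:2) {
    add_c(t8[j]); add_d(t8[j], fsn8[j], SCT_FSN_TYPE)
    add_r(t8[j], root, SCT_ISA)
    if (j == 1L) add_r(t8[j], helpers[["par2"]], SCT_ISA)
    std_groups(t8[j], n_groups = 1L)
  }

  # referral/discharge pair: one attribute vs none
  t9 <- c("60041", "60042")
  fsn9 <- c("Referral to young disabled service (procedure)",
            "Discharge from young disabled service (procedure)")
  for (j in 1:2) {
    add_c(t9[j]); add_d(t9[j], fsn9[j], SCT_FSN_TYPE)
    add_r(t9[j], root, SCT_ISA)
    if (j == 1L) add_r(t9[j], helpers[["tgt1"]], helpers[["method"]], 1L)
  }

  to_dt <- function(lst) data.table::as.data.table(do.call(rbind, lst))
  c(concepts = write_rf2(to_dt(conc), RF2_CONCEPT_COLS,
                         file.path(out_dir, "sct2_Concept_Snapshot.txt")),
    descriptions = write_rf2(to_dt(desc), RF2_DESCRIPTION_COLS,
                             file.path(out_dir, "sct2_Description_Snapshot.txt")),
    relationships = write_rf2(to_dt(rel), RF2_RELATIONSHIP_COLS,
                              file.path(out_dir, "sct2_Relationship_Snapshot.txt")))
}
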