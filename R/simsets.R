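# Similarity-set construction.
#
# Two concepts belong together when some pair of their descriptions, one
# word bag each, differ by exactly one word. Rather than comparing all bag
# pairs, every bag of n words is indexed n times under the (n-1)-word
# template obtained by deleting one occurrence of each distinct word. Bags
# meeting at the same template key are guaranteed pairwise one word apart
# (same size, same n-1 shared words) as long as their substituted words
# differ, so the non-transitivity of "one word apart" can never produce an
# invalid set.

#' Build token bags for eligible concepts
#'
#' Normalizes every active FSN and synonym of every eligible concept into a
#' word multiset. Eligibility is decided on the concept's FSN alone (see
#' [is_eligible_fsn()]); an ineligible concept contributes none of its
#' descriptions, synonyms included. Bags that normalize to nothing are
#' dropped.
#'
#' @param descriptions Description table from [read_descriptions()]; only
#'   active FSN/SYNONYM rows are used.
#' @param config A [normalization_config()].
#' @param concept_filter Optional character vector of concept ids (e.g. a
#'   hierarchy membership) to restrict to.
#' @return A \code{data.table} with columns \code{concept_id},
#'   \code{description_id}, \code{kind} (\code{"FSN"}/\code{"SYNONYM"}) and a
#'   list column \code{tokens} (sorted word multisets).
#' @export
token_bags <- function(descriptions, config = normalization_config(),
                       concept_filter = NULL) {
  d <- descriptions[descriptions$active &
                      descriptions$type %in% c("FSN", "SYNONYM"), ]
  if (!is.null(concept_filter)) d <- d[d$concept_id %in% concept_filter, ]
  fsn <- d[d$type == "FSN", ]
  # one FSN per concept: active snapshots should have exactly one; if more,
  # the first by description_id decides eligibility
  fsn <- fsn[order(fsn$concept_id, fsn$description_id, method = "radix"), ]
  fsn <- fsn[!duplicated(fsn$concept_id), ]
  ok <- vapply(fsn$term, is_eligible_fsn, logical(1), config = config)
  eligible_ids <- fsn$concept_id[ok]
  d <- d[d$concept_id %in% eligible_ids, ]
  toks <- lapply(d$term, normalize_term, config = config)
  keep <- lengths(toks) > 0L
  out <- data.table::data.table(
    concept_id = d$concept_id[keep],
    description_id = d$description_id[keep],
    kind = d$type[keep],
    tokens = toks[keep]
  )
  out[order(out$concept_id, out$description_id, method = "radix"), ]
}

#' Build the shared-template index
#'
#' For each bag B and each distinct word w in B, emits an entry keyed by the
#' template B with one occurrence of w removed. A bag of n distinct words
#' yields n entries; repeated words yield one entry per distinct word. Two
#' templates of different length can never share a key, so bag size is
#' implicit in the key.
#'
#' @param bags Token-bag table from [token_bags()].
#' @return A \code{data.table} with columns \code{template_key} (template
#'   words joined by a space, sorted), \code{concept_id}, \code{description_id},
#'   \code{kind}, \code{word} (the removed word) and list column
#'   \code{template}.
#' @export
build_template_index <- function(bags) {
  n <- nrow(bags)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    toks <- bags$tokens[[i]]
    words <- unique(toks)
    templates <- lapply(words, function(w) {
      toks[-match(w, toks)]
    })
    rows[[i]] <- data.table::data.table(
      template_key = vapply(templates, paste, character(1), collapse = " "),
      concept_id = bags$concept_id[i],
      description_id = bags$description_id[i],
      kind = bags$kind[i],
      word = words,
      template = templates
    )
  }
  if (!n) {
    return(data.table::data.table(template_key = character(0), concept_id = character(0),
                                  description_id = character(0),
                                  kind = character(0), word = character(0),
                                  template = list()))
  }
  data.table::rbindlist(rows)
}

#' Form deduplicated similarity sets
#'
#' Groups index entries by template key. At each key whose entries span at
#' least two concepts, one evidence bag is chosen per concept (FSN preferred
#' over synonym, then smallest description_id, then alphabetical word);
#' concepts whose candidate differing words are all already claimed by
#' earlier members are dropped, so the differing words within a set are
#' pairwise distinct and every member pair is exactly one word apart.
#' Candidate sets whose member ids duplicate an earlier-emitted set (e.g. the
#' same pair matching via both FSNs and synonyms) are dropped. The result is
#' invariant under permutation of the input bag order.
#'
#' @param index Index from [build_template_index()].
#' @param bags The same bag table the index was built from (used only for
#'   sanity checks; may be omitted).
#' @return A \code{data.table}, one row per set: \code{set_id} (sorted member
#'   ids joined with \code{"|"} — a stable key), \code{n_members}, list
#'   columns \code{member_ids}, \code{template}, \code{diff_words} (named by
#'   concept id), \code{evidence} (data.table of concept_id, description_id,
#'   kind, word).
#' @export
form_sets <- function(index, bags = NULL) {
  empty <- data.table::data.table(
    set_id = character(0), n_members = integer(0), member_ids = list(),
    template = list(), diff_words = list(), evidence = list())
  if (!nrow(index)) return(empty)
  keyfreq <- table(index$template_key)
  # a set needs >= 2 entries at a key
  cand_keys <- sort(names(keyfreq)[keyfreq >= 2L], method = "radix")
  sets <- vector("list", length(cand_keys))
  n_out <- 0L
  seen_ids <- new.env(parent = emptyenv())
  idx <- index[index$template_key %in% cand_keys, ]
  groups <- split(seq_len(nrow(idx)), idx$template_key)
  for (key in cand_keys) {
    rows <- idx[groups[[key]], ]
    if (length(unique(rows$concept_id)) < 2L) next
    # canonical candidate order within each concept: FSN first, then
    # description id, then word
    rows <- rows[order(rows$concept_id, rows$kind != "FSN",
                       rows$description_id, rows$word, method = "radix"), ]
    taken <- character(0)
    ev_rows <- list()
    for (cid in unique(rows$concept_id)) {
      cr <- rows[rows$concept_id == cid, ]
      free <- which(!cr$word %in% taken)
      if (!length(free)) next
      pick <- cr[free[1L], ]
      taken <- c(taken, pick$word)
      ev_rows[[length(ev_rows) + 1L]] <- pick
    }
    if (length(ev_rows) < 2L) next
    ev <- data.table::rbindlist(ev_rows)
    member_ids <- sort(ev$concept_id, method = "radix")
    set_id <- paste(member_ids, collapse = "|")
    if (exists(set_id, envir = seen_ids)) next
    assign(set_id, TRUE, envir = seen_ids)
    ev <- ev[order(ev$concept_id, method = "radix"), ]
    n_out <- n_out + 1L
    sets[[n_out]] <- data.table::data.table(
      set_id = set_id,
      n_members = length(member_ids),
      member_ids = list(member_ids),
      template = list(ev$template[[1L]]),
      diff_words = list(stats::setNames(ev$word, ev$concept_id)),
      evidence = list(ev[, c("concept_id", "description_id", "kind", "word")])
    )
  }
  if (!n_out) return(empty)
  out <- data.table::rbindlist(sets[seq_len(n_out)])
  out[order(out$set_id, method = "radix"), ]
}

#' One-call similarity sets from token bags
#'
#' Convenience wrapper: [build_template_index()] then [form_sets()].
#'
#' @inheritParams build_template_index
#' @return See [form_sets()].
#' @export
similarity_sets <- function(bags) {
  form_sets(build_template_index(bags), bags)
}

#' Brute-force one-word-apart concept pairs (test oracle)
#'
#' Exhaustively applies [is_one_word_apart()] to every cross-concept pair of
#' bags. Quadratic; intended for small instances as an independent check on
#' [form_sets()].
#'
#' @inheritParams build_template_index
#' @return A \code{data.table} with columns \code{concept_a}, \code{concept_b}
#'   (each unordered pair once, \code{concept_a < concept_b}), sorted.
#' @export
pairwise_oracle <- function(bags) {
  n <- nrow(bags)
  pairs <- character(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (bags$concept_id[i] == bags$concept_id[j]) next
        if (is_one_word_apart(bags$tokens[[i]], bags$tokens[[j]])) {
          ab <- sort(c(bags$concept_id[i], bags$concept_id[j]),
                     method = "radix")
          pairs <- c(pairs, paste(ab, collapse = "|"))
        }
      }
    }
  }
  pairs <- sort(unique(pairs), method = "radix")
  if (!length(pairs)) {
    return(data.table::data.table(concept_a = character(0),
                                  concept_b = character(0)))
  }
  m <- do.call(rbind, strsplit(pairs, "|", fixed = TRUE))
  data.table::data.table(concept_a = m[, 1L], concept_b = m[, 2L])
}

#' All within-set concept pairs of a set table
#'
#' Utility used to compare [form_sets()] output with [pairwise_oracle()].
#'
#' @param sets Set table from [form_sets()].
#' @return A \code{data.table} with columns \code{concept_a}, \code{concept_b},
#'   unique unordered pairs, sorted.
#' @export
set_pairs <- function(sets) {
  pairs <- character(0)
  for (ids in sets$member_ids) {
    k <- length(ids)
    for (i in seq_len(k - 1L))
      for (j in seq.int(i + 1L, k))
        pairs <- c(pairs, paste(ids[i], ids[j], sep = "|"))
  }
  pairs <- sort(unique(pairs), method = "radix")
  if (!length(pairs)) {
    return(data.table::data.table(concept_a = character(0),
                                  concept_b = character(0)))
  }
  m <- do.call(rbind, strsplit(pairs, "|", fixed = TRUE))
  data.table::data.table(concept_a = m[, 1L], concept_b = m[, 2L])
}
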