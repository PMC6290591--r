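# Term normalization and one-word-difference comparison on word multisets.
#
# A description term is reduced to a bag (multiset) of lowercase words:
# the trailing semantic tag "(...)" is optionally stripped, the term is
# split on whitespace, edge punctuation is trimmed, and stop words are
# dropped. Hyphenated words stay single tokens ("non-surgical" != "surgical"
# as one token pair). No stemming or spelling normalization is applied:
# "computed" and "computer" are different words.

#' Default stop-word list
#'
#' The minimal list of function words under which every worked example in the
#' package documentation tokenizes as intended. Configurable via
#' [normalization_config()].
#'
#' @return Character vector of lowercase stop words.
#' @export
default_stop_words <- function() {
  c("a", "an", "the", "of", "with", "as", "for", "using",
    "to", "from", "by", "in", "on", "and", "or")
}

#' Normalization configuration
#'
#' Bundles the tunable parameters of term normalization and concept
#' eligibility.
#'
#' @param stop_words Character vector of lowercase words removed from every
#'   term. Default [default_stop_words()].
#' @param min_words Minimum number of post-stop-word tokens a concept's fully
#'   specified name must have for the concept to enter the analysis.
#'   Default 5.
#' @param strip_semantic_tag Drop the trailing parenthesized semantic tag
#'   (e.g. \code{"(procedure)"}) before building comparison bags, so FSNs and
#'   synonyms are comparable. Default \code{TRUE}.
#' @param count_tag_for_threshold Count the semantic-tag token toward the
#'   `min_words` eligibility threshold. Default \code{TRUE}.
#'
#' @return An object of class \code{normalization_config} (a named list).
#' @export
normalization_config <- function(stop_words = default_stop_words(),
                                 min_words = 5L,
                                 strip_semantic_tag = TRUE,
                                 count_tag_for_threshold = TRUE) {
  stop_words <- as.character(stop_words)
  if (any(stop_words != tolower(stop_words)))
    stop("stop_words must all be lowercase")
  min_words <- as.integer(min_words)
  if (is.na(min_words) || min_words < 1L)
    stop("min_words must be a positive integer")
  structure(
    list(stop_words = stop_words,
         min_words = min_words,
         strip_semantic_tag = isTRUE(strip_semantic_tag),
         count_tag_for_threshold = isTRUE(count_tag_for_threshold)),
    class = "normalization_config"
  )
}

#' Read a normalization configuration from a YAML or JSON file
#'
#' Recognized keys: \code{stop_words}, \code{min_words},
#' \code{strip_semantic_tag}, \code{count_tag_for_threshold}; missing keys
#' fall back to the defaults of [normalization_config()].
#'
#' @param path Path to a YAML (\code{.yml}/\code{.yaml}) or JSON file.
#' @return A \code{normalization_config}.
#' @export
read_normalization_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  defaults <- normalization_config()
  args <- lapply(c("stop_words", "min_words", "strip_semantic_tag",
                   "count_tag_for_threshold"),
                 function(k) if (!is.null(raw[[k]])) raw[[k]] else defaults[[k]])
  names(args) <- c("stop_words", "min_words", "strip_semantic_tag",
                   "count_tag_for_threshold")
  do.call(normalization_config, args)
}

# canonical multiset order: C-locale radix sort, so bag keys are stable
# across platforms and locales
sort_bag <- function(tokens) sort(tokens, method = "radix")

#' Normalize a description term into a word multiset
#'
#' Lowercases, optionally strips the trailing semantic tag, splits on
#' whitespace, trims punctuation (commas, periods, colons, semicolons,
#' parentheses, quotes) from token edges, and removes stop words. Duplicate
#' words are preserved: the result is a multiset, represented as a character
#' vector in canonical sorted order.
#'
#' @param term Single non-empty character string.
#' @param config A [normalization_config()].
#' @return Character vector of tokens (possibly empty), sorted.
#' @examples
#' normalize_term("Surgical biopsy of gastrointestinal tract (procedure)")
#' @export
normalize_term <- function(term, config = normalization_config()) {
  stopifnot(is.character(term), length(term) == 1L)
  if (is.na(term) || !nzchar(term)) stop("term must be non-empty")
  x <- term
  if (config$strip_semantic_tag)
    x <- sub("\\s*\\([^()]*\\)\\s*$", "", x)
  toks <- strsplit(trimws(tolower(x)), "\\s+")[[1L]]
  toks <- gsub("^[,.;:()\"']+|[,.;:()\"']+$", "", toks)
  toks <- toks[nzchar(toks)]
  toks <- toks[!toks %in% config$stop_words]
  sort_bag(toks)
}

#' Multiset difference between two word bags
#'
#' Words common to both bags cancel with multiplicity; what remains on each
#' side is the exclusive words.
#'
#' @param bag_a,bag_b Character vectors (multisets of words).
#' @return List with sorted character vectors \code{a_only} and \code{b_only}.
#' @export
word_difference <- function(bag_a, bag_b) {
  ca <- bag_counts(bag_a)
  cb <- bag_counts(bag_b)
  words <- as.character(union(names(ca), names(cb)))
  if (!length(words))
    return(list(a_only = character(0), b_only = character(0)))
  na <- ifelse(words %in% names(ca), ca[words], 0L)
  nb <- ifelse(words %in% names(cb), cb[words], 0L)
  list(a_only = sort_bag(rep(words, pmax(na - nb, 0L))),
       b_only = sort_bag(rep(words, pmax(nb - na, 0L))))
}

bag_counts <- function(bag) {
  if (!length(bag)) return(integer(0))
  tab <- table(bag)
  stats::setNames(as.integer(tab), names(tab))
}

#' Are two word bags exactly one word apart?
#'
#' True iff each bag has exactly one exclusive word after multiset
#' cancellation, i.e. the bags are equal-sized and differ by a single
#' substitution. Word order never matters (bags are multisets), and a strict
#' subset (one side empty, the other with one extra word) does not qualify.
#'
#' @inheritParams word_difference
#' @return Logical scalar.
#' @export
is_one_word_apart <- function(bag_a, bag_b) {
  d <- word_difference(bag_a, bag_b)
  length(d$a_only) == 1L && length(d$b_only) == 1L
}

#' Is a concept eligible by its fully specified name?
#'
#' A concept enters the analysis only if its FSN has at least
#' \code{config$min_words} tokens after stop-word removal. When
#' \code{count_tag_for_threshold} is set (the default) the semantic-tag token
#' counts toward the threshold even though it is stripped from comparison
#' bags.
#'
#' @param fsn_term The concept's active fully specified name.
#' @param config A [normalization_config()].
#' @return Logical scalar.
#' @export
is_eligible_fsn <- function(fsn_term, config = normalization_config()) {
  counting_cfg <- config
  counting_cfg$strip_semantic_tag <- !config$count_tag_for_threshold
  length(normalize_term(fsn_term, counting_cfg)) >= config$min_words
}
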