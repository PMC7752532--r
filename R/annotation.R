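#' Read a keyword list file
#'
#' UTF-8 plain text, one entry per line, `#` comments and blank lines
#' ignored. Entries are normalized and deduplicated.
#'
#' @param path File path.
#' @return Character vector of normalized keywords.
#' @export
read_keyword_list <- function(path) {
  if (!file.exists(path)) stop("keyword file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- normalize_text(lines)
  unique(lines[nzchar(lines)])
}

#' Read a stop-phrase file
#'
#' UTF-8 tab-separated: `phrase<TAB>note`, `#` comments allowed. Stop
#' phrases are longer expressions in which a cancer keyword takes an
#' innocuous meaning ("agseong virus" = computer virus); their occurrences
#' are masked in place so that the embedded keyword cannot fire.
#'
#' @param path File path.
#' @return Tibble with normalized `phrase` and `note`.
#' @export
read_stop_phrases <- function(path) {
  if (!file.exists(path)) stop("stop-phrase file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- stringi::stri_split_fixed(lines, "\t", n = 2)
  out <- tibble(
    phrase = normalize_text(vapply(parts, `[`, character(1), 1)),
    note = vapply(parts, function(p) if (length(p) > 1) p[2] else "", character(1)))
  out <- out[nzchar(out$phrase), ]
  out[!duplicated(out$phrase), ]
}

#' Assemble an annotation configuration
#'
#' Bundles the resources the annotator needs: the advertising keyword list
#' (a post containing any of them is removed whole), the stop-phrase list
#' (masked in place), and the id of the cancer-type superclass that defines
#' what counts as a cancer post. When an ontology is supplied, stop phrases
#' that contain no term surface form are flagged with a warning — such a
#' phrase can never mask anything.
#'
#' @param ad_keywords Character vector (normalized internally).
#' @param stop_phrases Character vector of phrases, or a tibble from
#'   [read_stop_phrases()].
#' @param cancer_type_root Concept id of the cancer-type superclass.
#' @param ont Optional `oncolex_ontology` used to sanity-check stop phrases.
#' @return An `oncolex_annotation_config` list.
#' @export
annotation_config <- function(ad_keywords = character(),
                              stop_phrases = character(),
                              cancer_type_root = "cancer_type",
                              ont = NULL) {
  if (is.data.frame(stop_phrases)) stop_phrases <- stop_phrases$phrase
  ad_keywords <- unique(normalize_text(ad_keywords))
  ad_keywords <- ad_keywords[nzchar(ad_keywords)]
  stop_phrases <- unique(normalize_text(stop_phrases))
  stop_phrases <- stop_phrases[nzchar(stop_phrases)]
  if (!is.null(ont)) {
    forms <- unique(ont$terms$norm_form)
    useless <- vapply(stop_phrases, function(p) {
      inner <- forms[stringi::stri_length(forms) < stringi::stri_length(p)]
      length(inner) == 0 ||
        !any(stringi::stri_detect_fixed(p, inner))
    }, logical(1))
    if (any(useless)) {
      warning("stop phrase(s) contain no shorter term and can never mask: ",
              paste(stop_phrases[useless], collapse = ", "))
    }
  }
  structure(list(ad_keywords = ad_keywords, stop_phrases = stop_phrases,
                 cancer_type_root = cancer_type_root),
            class = "oncolex_annotation_config")
}

#' Default annotation configuration
#'
#' Built from the packaged ad-keyword and stop-phrase files and the skeleton
#' ontology's cancer-type root.
#'
#' @param ont Ontology used to check the stop phrases (default: skeleton).
#' @return An `oncolex_annotation_config`.
#' @export
default_annotation_config <- function(ont = skeleton_ontology()) {
  annotation_config(
    ad_keywords = read_keyword_list(system.file("extdata", "ad_keywords.txt",
                                                package = "oncolex", mustWork = TRUE)),
    stop_phrases = read_stop_phrases(system.file("extdata", "stop_phrases.tsv",
                                                 package = "oncolex", mustWork = TRUE)),
    cancer_type_root = "cancer_type",
    ont = ont)
}

# Greedy non-overlapping span selection under the longest-first, then
# leftmost-first order. `cands` is a data.frame with start/end (1-based,
# inclusive) plus any payload columns; returns the accepted subset ordered
# by start. This single tie-break rule is shared by stop-phrase masking and
# term matching so the two stages cannot disagree.
select_spans <- function(cands) {
  if (nrow(cands) == 0) return(cands)
  len <- cands$end - cands$start + 1L
  ord <- order(-len, cands$start)
  cands <- cands[ord, , drop = FALSE]
  n <- nrow(cands)
  taken_start <- integer(0); taken_end <- integer(0)
  keep <- logical(n)
  for (i in seq_len(n)) {
    s <- cands$start[i]; e <- cands$end[i]
    if (!any(s <= taken_end & e >= taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, s)
      taken_end <- c(taken_end, e)
    }
  }
  out <- cands[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

# All occurrences of one literal pattern in each of several texts,
# *including self-overlapping ones* (a plain fixed search resumes after each
# hit and would miss "aba" at position 3 of "ababa"): zero-width lookahead
# on the \Q-quoted literal yields every start position.
locate_overlapping <- function(texts, pattern) {
  loc <- stringi::stri_locate_all_regex(texts,
                                        paste0("(?=\\Q", pattern, "\\E)"),
                                        omit_no_match = TRUE)
  len <- stringi::stri_length(pattern)
  lapply(loc, function(m) cbind(start = m[, 1], end = m[, 1] + len - 1L))
}

# Locate all occurrences of each fixed pattern in one text; returns
# start/end (1-based inclusive) with the pattern index as payload.
locate_all <- function(text, patterns) {
  if (length(patterns) == 0 || !nzchar(text)) {
    return(data.frame(start = integer(), end = integer(), pat = integer()))
  }
  hits <- do.call(rbind, lapply(seq_along(patterns), function(k) {
    m <- locate_overlapping(text, patterns[k])[[1]]
    if (nrow(m) == 0) NULL else data.frame(start = m[, 1], end = m[, 2], pat = k)
  }))
  if (is.null(hits)) data.frame(start = integer(), end = integer(), pat = integer())
  else hits
}

#' Mask stop-phrase occurrences in a text
#'
#' Every occurrence of every stop phrase is replaced in place by a run of
#' mask characters of the same length, so offsets of the surrounding text
#' are preserved and no later term match can cross a masked region.
#' Overlapping candidate occurrences are resolved longest-phrase-first, then
#' leftmost-first; remaining occurrences of shorter phrases are masked where
#' still intact.
#'
#' @param text A single string (already normalized).
#' @param stop_phrases Character vector of normalized phrases, or an
#'   `oncolex_annotation_config`.
#' @return List with `text` (masked string) and `spans` (tibble `start`,
#'   `end`, 1-based inclusive, and `phrase`).
#' @examples
#' mask_stop_phrases("agseong virus gamyeom", "agseong virus")
#' @export
mask_stop_phrases <- function(text, stop_phrases) {
  if (inherits(stop_phrases, "oncolex_annotation_config")) {
    stop_phrases <- stop_phrases$stop_phrases
  }
  stopifnot(length(text) == 1)
  cands <- locate_all(text, stop_phrases)
  sel <- select_spans(cands)
  masked <- text
  if (nrow(sel) > 0) {
    for (i in seq_len(nrow(sel))) {
      stringi::stri_sub(masked, sel$start[i], sel$end[i]) <-
        strrep(MASK_CHAR, sel$end[i] - sel$start[i] + 1L)
    }
  }
  list(text = masked,
       spans = tibble(start = as.integer(sel$start), end = as.integer(sel$end),
                      phrase = if (nrow(sel)) stop_phrases[sel$pat] else character()))
}

#' Is a post an advertisement?
#'
#' TRUE iff the normalized text contains at least one advertising keyword as
#' a substring. Flagged posts are excluded from all counting before any
#' concept matching takes place.
#'
#' @param post A one-row corpus tibble, or a plain string.
#' @param ad_keywords Character vector of normalized keywords, or an
#'   `oncolex_annotation_config`.
#' @return Logical scalar.
#' @export
is_advertisement <- function(post, ad_keywords) {
  if (inherits(ad_keywords, "oncolex_annotation_config")) {
    ad_keywords <- ad_keywords$ad_keywords
  }
  text <- if (is.data.frame(post)) post$text else post
  text <- normalize_text(text)
  if (length(ad_keywords) == 0) return(rep(FALSE, length(text)))
  hit <- rep(FALSE, length(text))
  for (kw in ad_keywords) {
    hit <- hit | stringi::stri_detect_fixed(text, kw)
  }
  hit
}

# Build the term index used for matching: one row per distinct normalized
# surface form. Ambiguous forms (mapping to >1 concept) are kept but marked;
# the matcher errors when it meets one.
term_index <- function(ont) {
  tm <- ont$terms[nzchar(ont$terms$norm_form), ]
  by_form <- split(tm$concept_id, tm$norm_form)
  forms <- names(by_form)
  concept <- vapply(by_form, function(x) unique(x)[1], character(1))
  ambiguous <- vapply(by_form, function(x) length(unique(x)) > 1, logical(1))
  data.frame(form = forms, concept_id = unname(concept),
             ambiguous = unname(ambiguous), stringsAsFactors = FALSE)
}

#' Match ontology terms in a text
#'
#' Dictionary concept recognition by normalized substring search: all
#' occurrences of all term surface forms are located, then overlapping
#' candidates are resolved longest-first, then leftmost-first, yielding a
#' set of non-overlapping spans each carrying the matched concept.
#' Substring (not token-boundary) search is deliberate: consumer Korean is
#' agglutinative, so "jaegeomsa" must still hit the abbreviation "jaegeom".
#' The text is expected to be normalized and stop-masked; masked runs can
#' never participate in a match.
#'
#' @param text A single string.
#' @param ont A validated `oncolex_ontology`. If the text contains a surface
#'   form that is ambiguous (maps to more than one concept), matching stops
#'   with an error naming the term — resolve the ambiguity in the
#'   terminology first.
#' @return Tibble of spans: `start`, `end` (1-based, inclusive),
#'   `surface_form`, `concept_id`, ordered by `start`.
#' @export
match_terms <- function(text, ont) {
  stopifnot(length(text) == 1)
  idx <- term_index(ont)
  cands <- locate_all(text, idx$form)
  if (nrow(cands) > 0) {
    amb <- idx$ambiguous[cands$pat]
    if (any(amb)) {
      stop("ambiguous term encountered in text: '",
           idx$form[cands$pat[amb][1]],
           "' maps to multiple concepts; resolve the terminology first")
    }
  }
  sel <- select_spans(cands)
  tibble(start = as.integer(sel$start), end = as.integer(sel$end),
         surface_form = if (nrow(sel)) idx$form[sel$pat] else character(),
         concept_id = if (nrow(sel)) idx$concept_id[sel$pat] else character())
}

#' Annotate a single post
#'
#' Fixed pipeline order: normalize, de-identify, advertising check (an ad
#' post is flagged and excluded before any matching, even if it also
#' contains genuine cancer terms), stop-phrase masking, term matching,
#' concept deduplication. `is_cancer_post` is TRUE iff at least one matched
#' concept rolls up to the configured cancer-type superclass.
#'
#' @param post One-row corpus tibble (or a list with `post_id` and `text`).
#' @param ont A validated `oncolex_ontology`.
#' @param cfg An `oncolex_annotation_config`.
#' @return A one-row tibble: `post_id`, `is_ad`, `is_cancer_post`,
#'   `concepts` (list column, sorted unique concept ids), `spans` (list
#'   column of match-span tibbles).
#' @export
annotate_post <- function(post, ont, cfg) {
  ann <- annotate_corpus(tibble(post_id = post$post_id, text = post$text),
                         ont, cfg, progress = FALSE)
  ann
}

#' Annotate a corpus
#'
#' Applies [annotate_post()]'s pipeline to every post, preserving order.
#' Pure function of (corpus, ontology, config): two runs on the same inputs
#' are identical.
#'
#' @param corpus Corpus tibble with at least `post_id` and `text`.
#' @param ont A validated `oncolex_ontology`.
#' @param cfg An `oncolex_annotation_config`.
#' @param progress Unused; reserved.
#' @return Tibble with one row per post: `post_id`, `is_ad`,
#'   `is_cancer_post`, `concepts` (list column), `spans` (list column).
#' @export
annotate_corpus <- function(corpus, ont, cfg, progress = FALSE) {
  stopifnot(inherits(ont, "oncolex_ontology"),
            inherits(cfg, "oncolex_annotation_config"))
  n <- nrow(corpus)
  empty_span <- tibble(start = integer(), end = integer(),
                       surface_form = character(), concept_id = character())
  if (n == 0) {
    return(tibble(post_id = character(), is_ad = logical(),
                  is_cancer_post = logical(), concepts = list(),
                  spans = list()))
  }

  texts <- deidentify(normalize_text(corpus$text))
  is_ad <- is_advertisement(texts, cfg$ad_keywords)

  idx <- term_index(ont)
  cancer_ids <- c(cfg$cancer_type_root, descendants(ont, cfg$cancer_type_root))

  # vectorized candidate location over the whole corpus, one fixed pattern
  # at a time (non-ad posts only)
  live <- which(!is_ad)
  h_start <- list(); h_end <- list(); h_pat <- list(); h_post <- list()
  if (length(live) > 0) {
    live_texts <- texts[live]
    # stop-phrase masking first
    if (length(cfg$stop_phrases) > 0) {
      for (j in seq_along(live)) {
        live_texts[j] <- mask_stop_phrases(live_texts[j], cfg$stop_phrases)$text
      }
    }
    for (k in seq_len(nrow(idx))) {
      loc <- locate_overlapping(live_texts, idx$form[k])
      nh <- vapply(loc, nrow, integer(1))
      if (sum(nh) == 0) next
      if (idx$ambiguous[k]) {
        stop("ambiguous term encountered in post ",
             corpus$post_id[live[which(nh > 0)[1]]],
             ": '", idx$form[k], "' maps to multiple concepts")
      }
      m <- do.call(rbind, loc[nh > 0])
      h_start[[length(h_start) + 1]] <- m[, 1]
      h_end[[length(h_end) + 1]] <- m[, 2]
      h_pat[[length(h_pat) + 1]] <- rep.int(k, sum(nh))
      h_post[[length(h_post) + 1]] <- rep.int(live, nh)
    }
  }
  all_start <- as.integer(unlist(h_start))
  all_end <- as.integer(unlist(h_end))
  all_pat <- as.integer(unlist(h_pat))
  all_post <- as.integer(unlist(h_post))
  by_post <- split(seq_along(all_post), all_post)

  concepts <- rep(list(character(0)), n)
  spans <- rep(list(empty_span), n)
  for (key in names(by_post)) {
    i <- as.integer(key)
    rows <- by_post[[key]]
    sel <- select_spans(data.frame(start = all_start[rows], end = all_end[rows],
                                   pat = all_pat[rows]))
    spans[[i]] <- tibble(start = sel$start, end = sel$end,
                         surface_form = idx$form[sel$pat],
                         concept_id = idx$concept_id[sel$pat])
    concepts[[i]] <- sort(unique(spans[[i]]$concept_id))
  }
  is_cancer <- vapply(concepts, function(cc) any(cc %in% cancer_ids), logical(1))
  tibble(post_id = corpus$post_id, is_ad = is_ad,
         is_cancer_post = is_cancer & !is_ad,
         concepts = concepts, spans = spans)
}

#' Write annotations as JSON lines
#'
#' One record per post with `post_id`, `is_ad`, `is_cancer_post` and the
#' sorted concept id list. With `spans_path`, a span detail file is also
#' written with 0-based half-open `start`/`end` offsets into the normalized
#' text.
#'
#' @param annotations Tibble from [annotate_corpus()].
#' @param path Output path.
#' @param spans_path Optional path for the span detail file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, spans_path = NULL) {
  lines <- vapply(seq_len(nrow(annotations)), function(i) {
    jsonlite::toJSON(list(post_id = annotations$post_id[i],
                          is_ad = annotations$is_ad[i],
                          is_cancer_post = annotations$is_cancer_post[i],
                          concepts = annotations$concepts[[i]]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  if (!is.null(spans_path)) {
    det <- dplyr::bind_rows(lapply(seq_len(nrow(annotations)), function(i) {
      s <- annotations$spans[[i]]
      if (nrow(s) == 0) NULL else
        tibble(post_id = annotations$post_id[i],
               start = s$start - 1L, end = s$end,  # 0-based, half-open
               surface_form = s$surface_form, concept_id = s$concept_id)
    }))
    if (is.null(det) || nrow(det) == 0) {
      det <- tibble(post_id = character(), start = integer(), end = integer(),
                    surface_form = character(), concept_id = character())
    }
    utils::write.csv(det, spans_path, row.names = FALSE)
  }
  invisible(path)
}
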