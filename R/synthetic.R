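# Per-post pseudo-random sub-stream: a deterministic 31-bit seed derived
# from (corpus seed, post index), so each post's draws are reproducible
# independently of how many posts precede it.
derive_sub_seed <- function(seed, i) {
  ((seed %% 2147483647) * 48271 + (i + 1) * 9973) %% 2147483647
}

# Default filler vocabulary: token soup that cannot collide with the
# terminology. Every word starts and ends with 'q' and uses only the
# characters {q,z,v,x,w,i,u,o}, so no term surface form (all of which
# contain at least one character outside this set) can occur inside a
# filler word or span a boundary between a planted term and filler.
default_filler_vocab <- function() {
  syl <- c("zi", "vu", "xo", "wu", "zo", "vo", "xi", "wo", "zu")
  two <- outer(syl, syl, paste0)
  paste0("q", as.vector(two), "q")
}

#' Specify a synthetic corpus
#'
#' Parameter object for [generate_corpus()]. The defaults emulate the
#' statistical structure of the crawled Korean corpus the analysis assumes:
#' the date window 2014-01-01 to 2017-06-30, a 58.7% blog share, Naver and
#' Daum carrying 97.7% of posts, per-cancer-type mention probabilities
#' headed by colon (0.064), breast (0.063) and stomach cancer (0.050), and
#' per-superclass conditional mention rates taken from the corpus-wide
#' superclass frequencies (risk factor 0.425 down to prognosis 0.094).
#'
#' @param n_posts Number of posts (>= 0).
#' @param date_range Length-2 Date (or ISO string) vector, start <= end.
#' @param platform_weights Named probabilities summing to 1.
#' @param source_weights Named probabilities (`blog`, `community`) summing to 1.
#' @param type_probs Named vector: probability a post mentions each cancer
#'   type (independent Bernoulli draws — strata may overlap).
#' @param superclass_rates Named vector (or type x superclass matrix):
#'   probability that a post mentioning a given cancer type also mentions at
#'   least one concept of each non-cancer-type superclass.
#' @param ad_fraction Probability a post is an advertisement.
#' @param confusable_fraction Probability that a post with no cancer mention
#'   contains a stop-phrase confusable (a phrase embedding a cancer keyword
#'   with an innocuous meaning).
#' @param confusable_phrases Phrases used for confusable posts; each must
#'   embed a cancer keyword.
#' @param ad_keyword_pool Advertising keywords planted into ad posts.
#' @param filler_vocab Filler words; defaults to a collision-free token
#'   soup (see package vignette).
#' @param seed Integer seed; the same (spec, seed) is guaranteed to yield a
#'   byte-identical corpus.
#' @return An `oncolex_corpus_spec` list.
#' @export
corpus_spec <- function(n_posts = 1000,
                        date_range = c("2014-01-01", "2017-06-30"),
                        platform_weights = c(naver = 0.55, daum = 0.427,
                                             tistory = 0.015, egloos = 0.008),
                        source_weights = c(blog = 0.587, community = 0.413),
                        type_probs = c(colon_cancer = 0.064,
                                       breast_cancer = 0.063,
                                       stomach_cancer = 0.050,
                                       cervical_cancer = 0.040,
                                       lung_cancer = 0.038,
                                       liver_cancer = 0.035,
                                       prostate_cancer = 0.030,
                                       pancreatic_cancer = 0.028,
                                       brain_tumor = 0.025,
                                       leukemia = 0.022),
                        superclass_rates = c(risk_factor = 0.425,
                                             emotion = 0.338,
                                             symptom = 0.322,
                                             treatment = 0.302,
                                             dealing_with_cancer = 0.294,
                                             diagnosis = 0.237,
                                             prevention = 0.144,
                                             prognosis = 0.094),
                        ad_fraction = 0.05,
                        confusable_fraction = 0.05,
                        confusable_phrases = c("agseong virus", "an-am",
                                               "game", "drama", "program"),
                        ad_keyword_pool = c("detoxification",
                                            "antioxidant therapy",
                                            "enzyme therapy"),
                        filler_vocab = default_filler_vocab(),
                        seed = 1L) {
  date_range <- as.Date(date_range)
  stopifnot(length(n_posts) == 1, n_posts >= 0,
            length(date_range) == 2, !anyNA(date_range),
            date_range[1] <= date_range[2])
  chk_prob <- function(p, nm) {
    if (any(p < 0) || any(p > 1)) stop(nm, " must be probabilities in [0, 1]")
  }
  chk_prob(type_probs, "type_probs")
  chk_prob(superclass_rates, "superclass_rates")
  chk_prob(c(ad_fraction, confusable_fraction), "fractions")
  for (w in list(platform_weights, source_weights)) {
    chk_prob(w, "weights")
    if (abs(sum(w) - 1) > 1e-8) stop("weights must sum to 1")
  }
  if (is.null(names(type_probs)) || is.null(names(platform_weights))) {
    stop("type_probs and platform_weights must be named")
  }
  structure(list(n_posts = as.integer(n_posts), date_range = date_range,
                 platform_weights = platform_weights,
                 source_weights = source_weights,
                 type_probs = type_probs,
                 superclass_rates = superclass_rates,
                 ad_fraction = ad_fraction,
                 confusable_fraction = confusable_fraction,
                 confusable_phrases = normalize_text(confusable_phrases),
                 ad_keyword_pool = normalize_text(ad_keyword_pool),
                 filler_vocab = filler_vocab,
                 seed = as.integer(seed)),
            class = "oncolex_corpus_spec")
}

#' Extend the ontology skeleton into a synthetic fixture
#'
#' Starting from the packaged skeleton structure, rebuilds the terminology
#' with exactly `n_synonyms_per_class` surface forms per class (the
#' preferred label plus synthetic synonyms) and attaches
#' `n_extra_classes` synthetic leaf classes under randomly chosen
#' superclasses or subclasses. Synthetic labels and synonyms are
#' pronounceable consonant-vowel strings of fixed length, generated with
#' rejection so that no surface form is a substring of (or equal to) any
#' other after normalization — the fixture is always validator-clean, and
#' the same seed yields a byte-identical ontology.
#'
#' @param n_extra_classes Number of synthetic leaf classes to add (>= 0).
#' @param n_synonyms_per_class Surface forms per class (>= 1); 1 keeps only
#'   the preferred term.
#' @param seed Integer seed.
#' @return An `oncolex_ontology`.
#' @export
generate_ontology_fixture <- function(n_extra_classes = 0,
                                      n_synonyms_per_class = 1,
                                      seed = 1L) {
  stopifnot(n_extra_classes >= 0, n_synonyms_per_class >= 1)
  base <- skeleton_ontology()
  nodes <- base$nodes[, c("concept_id", "parent_id", "preferred_label")]
  set.seed(derive_sub_seed(seed, 0))

  all_forms <- normalize_text(base$terms$surface_form)
  cons <- c("b", "d", "g", "h", "j", "k", "l", "n", "p", "r", "s", "t")
  vow <- c("a", "e", "i", "o", "u")
  fresh_word <- function() {
    for (try in 1:1000) {
      w <- paste0(sample(cons, 4, TRUE), sample(vow, 4, TRUE), collapse = "")
      clash <- any(stringi::stri_detect_fixed(w, all_forms)) ||
        any(stringi::stri_detect_fixed(all_forms, w))
      if (!clash) {
        all_forms <<- c(all_forms, w)
        return(w)
      }
    }
    stop("could not generate a collision-free synthetic term")
  }

  if (n_extra_classes > 0) {
    hosts <- nodes$concept_id[is.na(compute_levels(nodes$concept_id, nodes$parent_id)) == FALSE &
                                compute_levels(nodes$concept_id, nodes$parent_id) <= 2]
    new_nodes <- lapply(seq_len(n_extra_classes), function(k) {
      tibble(concept_id = sprintf("syn_class_%03d", k),
             parent_id = sample(hosts, 1),
             preferred_label = fresh_word())
    })
    nodes <- dplyr::bind_rows(nodes, dplyr::bind_rows(new_nodes))
  }

  terms <- dplyr::bind_rows(lapply(seq_len(nrow(nodes)), function(i) {
    id <- nodes$concept_id[i]
    extra <- if (n_synonyms_per_class > 1) {
      vapply(seq_len(n_synonyms_per_class - 1), function(k) fresh_word(),
             character(1))
    } else character(0)
    tibble(surface_form = c(nodes$preferred_label[i], extra),
           concept_id = id,
           term_type = c("preferred", rep("synonym", length(extra))))
  }))
  ontology(nodes, terms, strict = TRUE)
}

#' Generate a synthetic post corpus with ground truth
#'
#' Emulates the lexical structure the annotation pipeline assumes. Per post,
#' an independent pseudo-random stream derived from (seed, post index)
#' draws: platform, source type and date from the spec's weights; cancer
#' types by independent Bernoulli(`type_probs`); for each drawn type and
#' each superclass, whether to plant at least one concept of that
#' superclass (probability `superclass_rates`), the concept being drawn
#' uniformly from the superclass's subtree (including the superclass's own
#' term). Ad posts get an advertising keyword; posts with no cancer mention
#' become stop-phrase confusables with probability `confusable_fraction`.
#' The text is the planted preferred labels and filler words in random
#' order, with at least one filler word between planted phrases. Ground
#' truth records exactly what was planted.
#'
#' @param spec An `oncolex_corpus_spec`.
#' @param ont A validated `oncolex_ontology`; every concept referenced by
#'   the spec must exist in it.
#' @return List with `corpus` (tibble: `post_id`, `platform`,
#'   `source_type`, `date`, `text`) and `truth` (tibble: `post_id`,
#'   `concepts` list column, `strata` list column of drawn cancer types,
#'   `is_ad`, `is_confusable`).
#' @export
generate_corpus <- function(spec, ont) {
  stopifnot(inherits(spec, "oncolex_corpus_spec"),
            inherits(ont, "oncolex_ontology"))
  unknown <- setdiff(names(spec$type_probs), ont$nodes$concept_id)
  sc_names <- if (is.matrix(spec$superclass_rates))
    colnames(spec$superclass_rates) else names(spec$superclass_rates)
  unknown <- c(unknown, setdiff(sc_names, ont$nodes$concept_id))
  if (length(unknown) > 0) {
    stop("spec references unknown concept(s): ", paste(unknown, collapse = ", "))
  }

  pref <- stats::setNames(ont$nodes$preferred_label, ont$nodes$concept_id)
  sub_concepts <- lapply(stats::setNames(sc_names, sc_names),
                         function(s) c(s, descendants(ont, s)))
  rate_for <- function(type) {
    if (is.matrix(spec$superclass_rates)) spec$superclass_rates[type, sc_names]
    else spec$superclass_rates
  }

  # drop filler words that could collide with any matchable string
  hazards <- c(normalize_text(ont$terms$surface_form),
               spec$confusable_phrases, spec$ad_keyword_pool)
  filler <- spec$filler_vocab
  ok <- vapply(filler, function(w) {
    !any(stringi::stri_detect_fixed(w, hazards)) &&
      !any(stringi::stri_detect_fixed(hazards, w))
  }, logical(1))
  filler <- filler[ok]
  if (length(filler) == 0) stop("no usable filler words after collision filtering")

  n <- spec$n_posts
  ndays <- as.integer(spec$date_range[2] - spec$date_range[1]) + 1L
  tp <- spec$type_probs
  platform <- character(n); source_type <- character(n)
  date <- rep(spec$date_range[1], length.out = n)
  text <- character(n)
  concepts <- vector("list", n); strata <- vector("list", n)
  is_ad <- logical(n); is_conf <- logical(n)

  for (i in seq_len(n)) {
    set.seed(derive_sub_seed(spec$seed, i))
    platform[i] <- sample(names(spec$platform_weights), 1,
                          prob = spec$platform_weights)
    source_type[i] <- sample(names(spec$source_weights), 1,
                             prob = spec$source_weights)
    date[i] <- spec$date_range[1] + (sample.int(ndays, 1) - 1L)
    is_ad[i] <- stats::runif(1) < spec$ad_fraction

    types <- names(tp)[stats::runif(length(tp)) < tp]
    planted_ids <- types
    if (length(types) > 0) {
      fire <- rep(FALSE, length(sc_names))
      for (t in types) fire <- fire | (stats::runif(length(sc_names)) < rate_for(t))
      for (s in sc_names[fire]) {
        pick <- sub_concepts[[s]]
        planted_ids <- c(planted_ids, pick[sample.int(length(pick), 1)])
      }
    }
    planted_ids <- unique(planted_ids)
    phrases <- unname(pref[planted_ids])
    if (is_ad[i]) {
      phrases <- c(phrases,
                   spec$ad_keyword_pool[sample.int(length(spec$ad_keyword_pool), 1)])
    } else if (length(types) == 0 &&
               stats::runif(1) < spec$confusable_fraction) {
      is_conf[i] <- TRUE
      phrases <- c(phrases,
                   spec$confusable_phrases[sample.int(length(spec$confusable_phrases), 1)])
    }

    # interleave: >= 1 filler word between planted phrases
    if (length(phrases) > 0) phrases <- phrases[sample.int(length(phrases))]
    k_lead <- sample.int(2, 1)
    toks <- filler[sample.int(length(filler), k_lead, replace = TRUE)]
    for (ph in phrases) {
      toks <- c(toks, ph,
                filler[sample.int(length(filler), sample.int(2, 1), replace = TRUE)])
    }
    if (length(phrases) == 0) {
      toks <- c(toks, filler[sample.int(length(filler),
                                        2 + sample.int(4, 1), replace = TRUE)])
    }
    text[i] <- paste(toks, collapse = " ")
    concepts[[i]] <- sort(planted_ids)
    strata[[i]] <- types
  }

  post_id <- sprintf("post%07d", seq_len(n))
  list(
    corpus = tibble(post_id = post_id, platform = platform,
                    source_type = source_type, date = date, text = text),
    truth = tibble(post_id = post_id, concepts = concepts, strata = strata,
                   is_ad = is_ad, is_confusable = is_conf))
}

#' Write / read ground truth as JSON lines
#'
#' One record per post, parallel to the corpus file: `post_id`, `concepts`,
#' `strata`, `is_ad`, `is_confusable`.
#'
#' @param truth Ground-truth tibble from [generate_corpus()].
#' @param path File path.
#' @return `path` (write) or the ground-truth tibble (read).
#' @export
write_ground_truth <- function(truth, path) {
  lines <- vapply(seq_len(nrow(truth)), function(i) {
    jsonlite::toJSON(list(post_id = truth$post_id[i],
                          concepts = truth$concepts[[i]],
                          strata = truth$strata[[i]],
                          is_ad = truth$is_ad[i],
                          is_confusable = truth$is_confusable[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  tibble(
    post_id = vapply(recs, function(r) r$post_id, character(1)),
    concepts = lapply(recs, function(r) as.character(unlist(r$concepts))),
    strata = lapply(recs, function(r) as.character(unlist(r$strata))),
    is_ad = vapply(recs, function(r) isTRUE(r$is_ad), logical(1)),
    is_confusable = vapply(recs, function(r) isTRUE(r$is_confusable), logical(1)))
}

#' Precision/recall of annotations against planted ground truth
#'
#' Post-level presence comparison per concept: a true positive is a
#' (post, concept) pair present in both the annotation and the ground
#' truth. Advertisement posts (per ground truth) are excluded from the
#' concept metrics, because the pipeline empties their concept sets by
#' design; ad-flag agreement is reported separately.
#'
#' @param annotations Tibble from [annotate_corpus()].
#' @param truth Ground-truth tibble from [generate_corpus()].
#' @return An `oncolex_recovery` list: `per_concept` (tibble `concept_id`,
#'   `tp`, `fp`, `fn`, `precision`, `recall`), `micro_precision`,
#'   `micro_recall`, `ad_agreement` (fraction of posts whose ad flag
#'   matches).
#' @export
recovery_report <- function(annotations, truth) {
  if (!setequal(annotations$post_id, truth$post_id)) {
    stop("annotations and ground truth cover different post_ids")
  }
  if (nrow(truth) == 0) {
    return(structure(list(per_concept = tibble(
      concept_id = character(), tp = integer(), fp = integer(),
      fn = integer(), precision = numeric(), recall = numeric()),
      micro_precision = NA_real_, micro_recall = NA_real_,
      ad_agreement = NA_real_), class = "oncolex_recovery"))
  }
  truth <- truth[match(annotations$post_id, truth$post_id), ]
  ad_agreement <- mean(annotations$is_ad == truth$is_ad)

  keep <- !truth$is_ad
  pred <- annotations$concepts[keep]
  gold <- truth$concepts[keep]
  pu <- unlist(pred, use.names = FALSE); gu <- unlist(gold, use.names = FALSE)
  pp <- rep.int(seq_along(pred), lengths(pred))
  gp <- rep.int(seq_along(gold), lengths(gold))
  pkey <- paste0(pp, ":", pu); gkey <- paste0(gp, ":", gu)
  p_hit <- pkey %in% gkey; g_hit <- gkey %in% pkey
  ids <- sort(unique(c(pu, gu)))
  count_by <- function(flag, id_vec) {
    v <- tapply(flag, factor(id_vec, levels = ids), sum)
    as.integer(ifelse(is.na(v), 0L, v))
  }
  per <- tibble(concept_id = ids,
                tp = count_by(p_hit, pu),
                fp = count_by(!p_hit, pu),
                fn = count_by(!g_hit, gu))
  per$precision <- ifelse(per$tp + per$fp > 0, per$tp / (per$tp + per$fp), NA_real_)
  per$recall <- ifelse(per$tp + per$fn > 0, per$tp / (per$tp + per$fn), NA_real_)
  tp <- sum(per$tp); fp <- sum(per$fp); fn <- sum(per$fn)
  structure(list(per_concept = per,
                 micro_precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 micro_recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 ad_agreement = ad_agreement),
            class = "oncolex_recovery")
}

#' @export
print.oncolex_recovery <- function(x, ...) {
  cat("<recovery report> micro precision:", format(x$micro_precision),
      " micro recall:", format(x$micro_recall),
      " ad agreement:", format(x$ad_agreement), "\n")
  invisible(x)
}
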