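cfg_default <- default_annotation_config(skel)

test_that("stop-phrase masking blocks the embedded cancer keyword", {
  m <- mask_stop_phrases("agseong virus gamyeom", "agseong virus")
  expect_identical(m$text, "█████████████ gamyeom")
  spans <- match_terms(m$text, skel)
  expect_false("cancer_type" %in% spans$concept_id)
  expect_true("infectious_agent" %in% spans$concept_id)

  plain <- "no stop phrases here at all"
  m2 <- mask_stop_phrases(plain, cfg_default)
  expect_identical(m2$text, plain)
  expect_equal(nrow(m2$spans), 0)
})

test_that("overlapping stop phrases resolve longest-first then leftmost", {
  # phrases of length 9 and 5 competing for the same region
  text <- "xxabcdefghixxabcdexx"
  m <- mask_stop_phrases(text, c("abcde", "abcdefghi"))
  expect_identical(m$text, oracle_mask(text, c("abcde", "abcdefghi")))
  # the 9-char phrase won the first region; the shorter matched where intact
  expect_identical(m$text, "xx█████████xx█████xx")

  set.seed(33)
  phrases <- c("aba", "babab", "abababa", "cab", "bc")
  for (i in 1:200) {
    t <- paste(sample(c("a", "b", "c", " "), sample.int(60, 1), TRUE),
               collapse = "")
    expect_identical(mask_stop_phrases(t, phrases)$text,
                     oracle_mask(t, phrases), label = t)
  }
})

test_that("advertising detection is substring-based and excludes whole posts", {
  post <- tibble::tibble(post_id = "x", text = "try Detoxification today")
  expect_true(is_advertisement(post, cfg_default))
  expect_false(is_advertisement(post, character(0)))
  expect_false(is_advertisement("an honest post about colon cancer",
                                cfg_default))

  g <- generate_corpus(corpus_spec(n_posts = 300, ad_fraction = 0.1, seed = 21),
                       skel)
  flagged <- is_advertisement(g$corpus$text, cfg_default)
  expect_identical(flagged, g$truth$is_ad)
})

test_that("term matching agrees with the brute-force scanner", {
  expect_equal(nrow(match_terms("", skel)), 0)

  one <- match_terms("daejang-am", skel)
  expect_equal(nrow(one), 1)
  expect_identical(one$concept_id, "colon_cancer")
  expect_equal(c(one$start, one$end), c(1L, 10L))

  idx_forms <- unique(normalize_text(skel$terms$surface_form))
  idx_conc <- skel$terms$concept_id[match(idx_forms,
                                          normalize_text(skel$terms$surface_form))]
  set.seed(44)
  for (i in 1:300) {
    t <- normalize_text(random_matchy_text(idx_forms, 60))
    got <- match_terms(t, skel)
    want <- oracle_match(t, idx_forms, idx_conc)
    expect_equal(got$start, as.integer(want$start), label = t)
    expect_equal(got$concept_id, want$concept_id, label = t)
  }
})

test_that("ambiguous terms stop matching with the term named", {
  nodes <- tibble::tibble(concept_id = c("r", "a", "b"),
                          parent_id = c(NA, "r", "r"),
                          preferred_label = c("root", "alpha", "beta"))
  terms <- tibble::tibble(surface_form = c("root", "alpha", "beta", "twin", "twin"),
                          concept_id = c("r", "a", "b", "a", "b"),
                          term_type = c(rep("preferred", 3), "synonym", "synonym"))
  amb <- ontology(nodes, terms)
  expect_error(match_terms("a twin appears", amb), "twin")
  expect_silent(match_terms("alpha only", amb))
})

test_that("the annotation pipeline applies its stages in fixed order", {
  cfg <- cfg_default
  # ad post with genuine cancer terms is excluded before matching
  ad <- tibble::tibble(post_id = "ad1",
                       text = "colon cancer detoxification miracle")
  a <- annotate_post(ad, skel, cfg)
  expect_true(a$is_ad)
  expect_length(a$concepts[[1]], 0)
  expect_false(a$is_cancer_post)

  # colon-cancer synonym plus diet synonym
  p <- tibble::tibble(post_id = "p1", text = "daejang-am and some diet advice")
  a <- annotate_post(p, skel, cfg)
  expect_setequal(a$concepts[[1]], c("colon_cancer", "diet"))
  expect_true(a$is_cancer_post)

  # diet only: not a cancer post
  p2 <- tibble::tibble(post_id = "p2", text = "diet advice only")
  a2 <- annotate_post(p2, skel, cfg)
  expect_false(a2$is_cancer_post)
  expect_identical(a2$concepts[[1]], "diet")
})

test_that("no match span ever overlaps a masked span", {
  set.seed(55)
  forms <- unique(normalize_text(skel$terms$surface_form))
  for (i in 1:100) {
    t <- normalize_text(
      random_matchy_text(c(forms, cfg_default$stop_phrases), 60))
    m <- mask_stop_phrases(t, cfg_default)
    spans <- match_terms(m$text, skel)
    for (j in seq_len(nrow(spans))) {
      overlaps <- spans$start[j] <= m$spans$end & spans$end[j] >= m$spans$start
      expect_false(any(overlaps))
    }
  }
})

test_that("stop phrases shrink and synonyms grow concept sets monotonically", {
  set.seed(66)
  forms <- unique(normalize_text(skel$terms$surface_form))
  vocab <- c(forms, cfg_default$stop_phrases, "zebra")
  texts <- vapply(1:40, function(i) normalize_text(random_matchy_text(vocab, 60)),
                  character(1))
  corpus <- tibble::tibble(post_id = sprintf("p%02d", 1:40), text = texts)

  cfg_none <- annotation_config(cancer_type_root = "cancer_type")
  cfg_stop <- annotation_config(stop_phrases = cfg_default$stop_phrases,
                                cancer_type_root = "cancer_type")
  base <- annotate_corpus(corpus, skel, cfg_none)
  masked <- annotate_corpus(corpus, skel, cfg_stop)
  for (i in 1:40) {
    expect_true(all(masked$concepts[[i]] %in% base$concepts[[i]]))
  }

  rich <- skel
  rich$terms <- rbind(rich$terms,
                      tibble::tibble(surface_form = "zebra",
                                     concept_id = "hope", term_type = "synonym",
                                     norm_form = "zebra"))
  enriched <- annotate_corpus(corpus, rich, cfg_none)
  for (i in 1:40) {
    expect_true(all(base$concepts[[i]] %in% enriched$concepts[[i]]))
  }
})

test_that("annotation is a pure function of its inputs", {
  g <- generate_corpus(corpus_spec(n_posts = 120, seed = 77), skel)
  a1 <- annotate_corpus(g$corpus, skel, cfg_default)
  a2 <- annotate_corpus(g$corpus, skel, cfg_default)
  expect_identical(a1, a2)
})
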