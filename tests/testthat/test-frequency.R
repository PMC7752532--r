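# minimal hand-built annotation tibbles for counting tests
ann_tbl <- function(concepts, is_ad = FALSE, cancer = NULL) {
  n <- length(concepts)
  if (is.null(cancer)) {
    cancer_ids <- c("cancer_type", descendants(skel, "cancer_type"))
    cancer <- vapply(concepts, function(cc) any(cc %in% cancer_ids), logical(1))
  }
  tibble::tibble(post_id = sprintf("p%03d", seq_len(n)),
                 is_ad = rep_len(is_ad, n),
                 is_cancer_post = cancer & !rep_len(is_ad, n),
                 concepts = concepts,
                 spans = rep(list(NULL), n))
}

test_that("relative frequencies reproduce published count/percent pairs", {
  expect_equal(relative_frequency(0, 100), 0.0)
  expect_equal(relative_frequency(320568, 754744), 42.5)
  expect_equal(relative_frequency(254920, 754744), 33.8)
  expect_equal(relative_frequency(243010, 754744), 32.2)
  expect_equal(relative_frequency(227942, 754744), 30.2)
  expect_equal(relative_frequency(47940, 754744), 6.4)
  expect_equal(relative_frequency(442669, 754744), 58.7)
  expect_error(relative_frequency(1, 0), "total")
  expect_error(relative_frequency(5, 4), "<=")
  # the raw value is retained exactly
  expect_equal(relative_frequency(47940, 754744, raw = TRUE) * 754744 / 100,
               47940)
})

test_that("counting is binary per post and respects the analysis restriction", {
  ann <- ann_tbl(list(c("colon_cancer", "diet"),
                      c("colon_cancer"),
                      c("diet")))        # third post is not a cancer post
  tab <- count_posts_by_concept(ann, skel, "class")
  expect_equal(tab$total[1], 2)  # only cancer posts qualify
  expect_equal(tab$n_posts[tab$concept_id == "colon_cancer"], 2)
  expect_equal(tab$n_posts[tab$concept_id == "diet"], 1)

  empty <- count_posts_by_concept(ann_tbl(list()), skel, "class")
  expect_equal(nrow(empty), 0)

  bad <- ann_tbl(list(c("colon_cancer", "made_up")))
  expect_error(count_posts_by_concept(bad, skel), "absent from the ontology")
})

test_that("superclass rollup counts a post once per superclass subtree", {
  ann <- ann_tbl(list(c("colon_cancer", "diet", "exercise")))
  tab <- rollup_to_superclass(ann, skel)
  expect_equal(tab$n_posts[tab$concept_id == "dealing_with_cancer"], 1)

  # matches brute-force per-post ancestor sets on random annotations
  set.seed(88)
  for (rep in 1:10) {
    ont <- random_tree_ontology(sample(8:40, 1), n_roots = 3)
    ids <- ont$nodes$concept_id
    concepts <- lapply(1:30, function(i) sample(ids, sample.int(4, 1)))
    ann <- ann_tbl(concepts, cancer = rep(TRUE, 30))
    tab <- rollup_to_superclass(ann, ont)
    for (r in ont$roots) {
      want <- sum(vapply(concepts, function(cc) {
        any(vapply(cc, function(x) oracle_root_of(ont$nodes, x) == r,
                   logical(1)))
      }, logical(1)))
      got <- tab$n_posts[tab$concept_id == r]
      expect_equal(if (length(got)) got else 0L, want)
    }
  }
})

test_that("superclass counts are bounded by their children and the corpus", {
  g <- generate_corpus(corpus_spec(n_posts = 400, seed = 13), skel)
  ann <- annotate_corpus(g$corpus, skel, default_annotation_config(skel))
  sup <- rollup_to_superclass(ann, skel)
  cls <- count_posts_by_concept(ann, skel, "class")
  N <- sup$total[1]
  for (s in skel$roots) {
    kids <- c(s, descendants(skel, s))
    n_s <- cls$n_posts[match(kids, cls$concept_id)]
    n_s[is.na(n_s)] <- 0L
    n_sup <- sup$n_posts[match(s, sup$concept_id)]
    if (is.na(n_sup)) n_sup <- 0L
    expect_gte(n_sup, max(n_s))
    expect_lte(n_sup, min(N, sum(n_s)))
  }
})

test_that("stratification uses per-stratum denominators and keeps multi-type posts", {
  ann <- ann_tbl(list(c("colon_cancer", "stomach_cancer", "diet"),
                      c("colon_cancer", "surgery")))
  st <- stratify_by_cancer_type(ann, skel, c("colon_cancer", "stomach_cancer",
                                             "thyroid_cancer"))
  totals <- attr(st, "totals")
  expect_equal(totals$total[totals$stratum == "colon_cancer"], 2)
  expect_equal(totals$total[totals$stratum == "stomach_cancer"], 1)
  expect_equal(totals$total[totals$stratum == "thyroid_cancer"], 0)
  # within-stratum percentage uses the stratum's own N
  colon <- st[st$stratum == "colon_cancer", ]
  expect_equal(colon$total, rep(2L, nrow(colon)))
  expect_error(stratify_by_cancer_type(ann, skel, "diet"), "not under")
  expect_error(stratify_by_cancer_type(ann, skel, "nope"), "unknown")

  # strata totals sum to at least the number of posts with >= 1 type
  g <- generate_corpus(corpus_spec(n_posts = 300, seed = 17), skel)
  ann2 <- annotate_corpus(g$corpus, skel, default_annotation_config(skel))
  types <- names(corpus_spec()$type_probs)
  st2 <- stratify_by_cancer_type(ann2, skel, types)
  n_typed <- sum(vapply(ann2$concepts[ann2$is_cancer_post & !ann2$is_ad],
                        function(cc) any(cc %in% types), logical(1)))
  expect_gte(sum(attr(st2, "totals")$total), n_typed)
})

test_that("planted per-type stratum rates are recovered within binomial noise", {
  rates <- c(risk_factor = 0.5, emotion = 0.2)
  spec <- corpus_spec(n_posts = 4000,
                      type_probs = c(colon_cancer = 0.25),
                      superclass_rates = rates,
                      ad_fraction = 0, confusable_fraction = 0, seed = 19)
  g <- generate_corpus(spec, skel)
  ann <- annotate_corpus(g$corpus, skel, default_annotation_config(skel))
  st <- stratify_by_cancer_type(ann, skel, "colon_cancer")
  N <- attr(st, "totals")$total[1]
  for (s in names(rates)) {
    q <- rates[[s]]
    got <- st$n_posts[st$concept_id == s] / N
    expect_lt(abs(got - q), 3 * sqrt(q * (1 - q) / N))
  }
})

test_that("ranking is count-descending with lexicographic ties and a sort oracle", {
  tab <- make_tab <- tibble::tibble(
    stratum = "ALL", level = "class",
    concept_id = c("colon_cancer", "breast_cancer", "stomach_cancer"),
    label = NA_character_,
    n_posts = c(47940L, 47235L, 37378L), total = 754744L,
    pct_raw = NA_real_, pct = NA_real_)
  expect_identical(rank_top_n(tab, 3),
                   c("colon_cancer", "breast_cancer", "stomach_cancer"))
  expect_error(rank_top_n(tab, 0), "positive")

  tie <- tab; tie$n_posts <- rep(5L, 3)
  expect_identical(rank_top_n(tie, 3),
                   sort(tie$concept_id, method = "radix"))

  set.seed(99)
  for (i in 1:20) {
    t2 <- tab[sample(3), ]
    t2$n_posts <- as.integer(sample.int(100, 3, TRUE))
    ord <- t2$concept_id[order(-t2$n_posts, t2$concept_id, method = "radix")]
    expect_identical(rank_top_n(t2, 2), ord[1:2])
  }
})

test_that("rank comparison is plain set algebra with per-type ranks", {
  same <- compare_rankings(c("a", "b"), c("a", "b"))
  expect_length(same$social_only, 0)
  expect_length(same$registry_only, 0)

  cmp <- compare_rankings(c("cervical_cancer", "colon_cancer"),
                          c("colon_cancer", "thyroid_cancer"))
  expect_true("cervical_cancer" %in% cmp$social_only)
  expect_true("thyroid_cancer" %in% cmp$registry_only)
  expect_setequal(cmp$shared, "colon_cancer")
  expect_equal(cmp$ranks$registry_rank[cmp$ranks$type == "cervical_cancer"],
               NA_integer_)
  expect_error(compare_rankings(c("a", "a"), "b"), "duplicate")

  set.seed(111)
  pool <- letters[1:10]
  for (i in 1:20) {
    s <- sample(pool, sample.int(8, 1))
    r <- sample(pool, sample.int(8, 1))
    cmp <- compare_rankings(s, r)
    expect_setequal(union(cmp$shared, cmp$social_only), s)
    expect_setequal(union(cmp$shared, cmp$registry_only), r)
    expect_setequal(cmp$shared, s[s %in% r])
  }
})
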