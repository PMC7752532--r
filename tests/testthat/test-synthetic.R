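test_that("fixture generation reduces to the skeleton and is deterministic", {
  fx <- generate_ontology_fixture(0, 1, seed = 3)
  expect_identical(fx$nodes$concept_id, skel$nodes$concept_id)
  expect_identical(fx$terms$surface_form, skel$nodes$preferred_label)
  expect_true(all(fx$terms$term_type == "preferred"))

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  save_ontology(generate_ontology_fixture(100, 10, seed = 7), f1)
  save_ontology(generate_ontology_fixture(100, 10, seed = 7), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("synthetic terminologies are validator-clean at scale", {
  fx <- generate_ontology_fixture(100, 10, seed = 7)
  rep <- validate_ontology(fx)
  expect_equal(nrow(rep$errors), 0)
  expect_false("AMBIGUOUS_TERM" %in% rep$warnings$code)
  expect_equal(rep$counts$n_classes, 150)  # 50 skeleton classes + 100 synthetic
  expect_equal(rep$counts$n_terms, 159 * 10)
  expect_lte(rep$counts$max_depth, 4)
})

test_that("corpus generation honors degenerate and empty specifications", {
  g0 <- generate_corpus(corpus_spec(n_posts = 0), skel)
  expect_equal(nrow(g0$corpus), 0)
  expect_equal(nrow(g0$truth), 0)

  spec1 <- corpus_spec(n_posts = 50,
                       type_probs = c(colon_cancer = 1.0),
                       superclass_rates = c(risk_factor = 1.0, emotion = 1.0),
                       ad_fraction = 0, confusable_fraction = 0, seed = 4)
  g1 <- generate_corpus(spec1, skel)
  ann <- annotate_corpus(g1$corpus, skel, default_annotation_config(skel))
  expect_true(all(ann$is_cancer_post))
  sup <- rollup_to_superclass(ann, skel)
  expect_equal(sup$n_posts[sup$concept_id == "risk_factor"], 50L)
  expect_equal(sup$n_posts[sup$concept_id == "emotion"], 50L)
  expect_equal(sup$pct[sup$concept_id == "risk_factor"], 100.0)

  expect_error(generate_corpus(corpus_spec(type_probs = c(unicorn = 0.5)), skel),
               "unknown concept")
  expect_error(corpus_spec(type_probs = c(colon_cancer = 1.5)), "probabilities")
  expect_error(corpus_spec(platform_weights = c(a = 0.5, b = 0.4)), "sum to 1")
})

test_that("identical seeds give byte-identical corpora and ground truth", {
  spec <- corpus_spec(n_posts = 150, seed = 23)
  g1 <- generate_corpus(spec, skel)
  g2 <- generate_corpus(spec, skel)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_corpus(g1$corpus, f1); write_corpus(g2$corpus, f2)
  expect_identical(readLines(f1), readLines(f2))
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  write_ground_truth(g1$truth, t1); write_ground_truth(g2$truth, t2)
  expect_identical(readLines(t1), readLines(t2))

  g3 <- generate_corpus(corpus_spec(n_posts = 150, seed = 24), skel)
  expect_false(identical(g1$corpus$text, g3$corpus$text))
})

test_that("ground truth survives a write/read round trip", {
  g <- generate_corpus(corpus_spec(n_posts = 30, seed = 31), skel)
  f <- withr::local_tempfile()
  write_ground_truth(g$truth, f)
  back <- read_ground_truth(f)
  expect_equal(back, g$truth)
})

test_that("the annotator reproduces ground truth exactly on clean corpora", {
  cfg <- default_annotation_config(skel)
  for (seed in c(1, 2, 3)) {
    spec <- corpus_spec(n_posts = 400, ad_fraction = 0,
                        confusable_fraction = 0, seed = seed)
    g <- generate_corpus(spec, skel)
    ann <- annotate_corpus(g$corpus, skel, cfg)
    r <- recovery_report(ann, g$truth)
    expect_equal(r$micro_precision, 1.0)
    expect_equal(r$micro_recall, 1.0)
    for (i in seq_len(nrow(ann))) {
      expect_identical(ann$concepts[[i]], g$truth$concepts[[i]])
    }
  }
})

test_that("disabling stop phrases costs precision exactly on confused cancer concepts", {
  spec <- corpus_spec(n_posts = 600, ad_fraction = 0,
                      confusable_fraction = 0.3, seed = 37)
  g <- generate_corpus(spec, skel)
  cfg_on <- default_annotation_config(skel)
  cfg_off <- annotation_config(ad_keywords = cfg_on$ad_keywords,
                               stop_phrases = character(),
                               cancer_type_root = "cancer_type")
  expect_gt(sum(g$truth$is_confusable), 0)

  ann_on <- annotate_corpus(g$corpus, skel, cfg_on)
  r_on <- recovery_report(ann_on, g$truth)
  expect_equal(r_on$micro_precision, 1.0)
  expect_equal(r_on$micro_recall, 1.0)
  # with masking on, confusable-only posts are not cancer posts
  conf <- g$truth$is_confusable
  expect_false(any(ann_on$is_cancer_post[conf]))

  ann_off <- annotate_corpus(g$corpus, skel, cfg_off)
  r_off <- recovery_report(ann_off, g$truth)
  expect_lt(r_off$micro_precision, 1.0)
  expect_true(all(ann_off$is_cancer_post[conf]))
  imperfect <- r_off$per_concept$concept_id[
    !is.na(r_off$per_concept$precision) & r_off$per_concept$precision < 1]
  cancer_ids <- c("cancer_type", descendants(skel, "cancer_type"))
  expect_true(length(imperfect) > 0)
  expect_true(all(imperfect %in% cancer_ids))

  expect_error(recovery_report(ann_on[-1, ], g$truth), "different post_ids")
})

test_that("planted mention probabilities are recovered within binomial bounds", {
  q <- 0.064
  spec <- corpus_spec(n_posts = 8000, seed = 41)
  g <- generate_corpus(spec, skel)
  ann <- annotate_corpus(g$corpus, skel, default_annotation_config(skel))
  est <- mean(vapply(ann$concepts[!ann$is_ad],
                     function(cc) "colon_cancer" %in% cc, logical(1)))
  expect_lt(abs(est - q), 3 * sqrt(q * (1 - q) / sum(!ann$is_ad)))
})
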