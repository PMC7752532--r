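#' Pipeline configuration
#'
#' Bundles the file paths and analysis options for a full run. Can also be
#' read from a YAML file with the same field names via
#' `pipeline_config_from_yaml()`. All input paths are checked at
#' construction; a bad path fails here, before any stage runs.
#'
#' @param ontology Path to a tabular ontology file.
#' @param corpus Path to a JSON-lines corpus file.
#' @param out_dir Output directory (created if missing).
#' @param ad_keywords,stop_phrases Paths to keyword files; default to the
#'   packaged lists.
#' @param registry_stats Path to a registry statistics CSV, or `NULL` to
#'   skip the ranking comparison.
#' @param start_date,end_date Closed date window for the analysis.
#' @param strata Cancer-type concept ids to stratify by, or `NULL` to use
#'   the top `top_n` types found in the corpus.
#' @param top_n Size of the ranking lists.
#' @param cancer_type_root Concept id of the cancer-type superclass.
#' @return An `oncolex_pipeline_config` list.
#' @export
pipeline_config <- function(ontology, corpus, out_dir,
                            ad_keywords = system.file("extdata", "ad_keywords.txt",
                                                      package = "oncolex", mustWork = TRUE),
                            stop_phrases = system.file("extdata", "stop_phrases.tsv",
                                                       package = "oncolex", mustWork = TRUE),
                            registry_stats = system.file("extdata",
                                                         "registry_stats_synthetic.csv",
                                                         package = "oncolex", mustWork = TRUE),
                            start_date = "2014-01-01", end_date = "2017-06-30",
                            strata = NULL, top_n = 10,
                            cancer_type_root = "cancer_type") {
  for (p in c(ontology, corpus, ad_keywords, stop_phrases, registry_stats)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configuration error: input path does not exist: ", p)
    }
  }
  if (as.Date(start_date) > as.Date(end_date)) {
    stop("configuration error: start_date is after end_date")
  }
  if (top_n <= 0) stop("configuration error: top_n must be positive")
  structure(list(ontology = ontology, corpus = corpus, out_dir = out_dir,
                 ad_keywords = ad_keywords, stop_phrases = stop_phrases,
                 registry_stats = registry_stats,
                 start_date = as.Date(start_date), end_date = as.Date(end_date),
                 strata = strata, top_n = as.integer(top_n),
                 cancer_type_root = cancer_type_root),
            class = "oncolex_pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys mirror the `pipeline_config()` arguments.
#' @export
pipeline_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  args <- yaml::read_yaml(path)
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order — read, de-identify, date filter,
#' annotate (ad removal, stop masking, concept matching), count, superclass
#' rollup, cancer-type stratification, ranking, registry comparison — and
#' writes all tables under `cfg$out_dir`:
#' `corpus_summary.csv`, `annotations.jsonl`, `freq_superclass.csv`,
#' `freq_class.csv`, `freq_endnode.csv`, `freq_types.csv`,
#' `strata_superclass.csv`, `strata_totals.csv`, `rank_comparison.csv`, and
#' `run_log.txt` (stage counts and timings — the one file whose bytes vary
#' between runs; every table is a pure function of the inputs). Inputs are
#' never mutated.
#'
#' @param cfg An `oncolex_pipeline_config`.
#' @return Invisibly, the run report: a list of the counts needed to
#'   recompute every percentage the tables contain.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "oncolex_pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  log_lines <- character(0)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    t <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage=%s elapsed=%.2fs", name,
                                       as.numeric(Sys.time() - t, units = "secs")))
    res
  }

  ont <- stage("load-ontology", {
    o <- load_ontology(cfg$ontology)
    rep <- validate_ontology(o)
    if (nrow(rep$errors) > 0) {
      stop("ontology fails validation: ",
           paste(rep$errors$code, collapse = ", "))
    }
    o
  })
  cfg_ann <- annotation_config(
    ad_keywords = read_keyword_list(cfg$ad_keywords),
    stop_phrases = read_stop_phrases(cfg$stop_phrases),
    cancer_type_root = cfg$cancer_type_root, ont = ont)

  corpus <- stage("read-corpus", read_corpus(cfg$corpus))
  n_read <- nrow(corpus)
  corpus$text <- stage("deidentify", deidentify(corpus$text))
  corpus <- stage("date-filter", filter_by_date(corpus, cfg$start_date, cfg$end_date))
  summary <- summarize_corpus(corpus)
  write_corpus_summary(summary, file.path(cfg$out_dir, "corpus_summary.csv"))

  ann <- stage("annotate", annotate_corpus(corpus, ont, cfg_ann))
  n_ad <- sum(ann$is_ad)
  n_cancer <- sum(ann$is_cancer_post)
  log_lines <- c(log_lines,
                 sprintf("posts_read=%d posts_in_window=%d ads_removed=%d cancer_posts=%d",
                         n_read, nrow(corpus), n_ad, n_cancer))
  write_annotations(ann, file.path(cfg$out_dir, "annotations.jsonl"))

  tab_super <- stage("count-superclass", rollup_to_superclass(ann, ont))
  tab_class <- stage("count-class", count_posts_by_concept(ann, ont, "class"))
  tab_end <- stage("count-endnode", count_posts_by_concept(ann, ont, "end_node"))
  write_freq_table(tab_super, file.path(cfg$out_dir, "freq_superclass.csv"))
  write_freq_table(tab_class, file.path(cfg$out_dir, "freq_class.csv"))
  write_freq_table(tab_end, file.path(cfg$out_dir, "freq_endnode.csv"))

  # per-type post counts (class-level table restricted to cancer types)
  type_ids <- descendants(ont, cfg$cancer_type_root)
  tab_types <- tab_class[tab_class$concept_id %in% type_ids, , drop = FALSE]
  write_freq_table(tab_types, file.path(cfg$out_dir, "freq_types.csv"))

  strata <- cfg$strata
  if (is.null(strata) && nrow(tab_types) > 0) {
    strata <- rank_top_n(tab_types, cfg$top_n)
  }
  cmp <- NULL
  tab_strat <- NULL
  if (!is.null(strata) && length(strata) > 0) {
    tab_strat <- stage("stratify",
                       stratify_by_cancer_type(ann, ont, strata,
                                               cancer_type_root = cfg$cancer_type_root))
    write_freq_table(tab_strat, file.path(cfg$out_dir, "strata_superclass.csv"))
    utils::write.csv(as.data.frame(attr(tab_strat, "totals")),
                     file.path(cfg$out_dir, "strata_totals.csv"), row.names = FALSE)
    if (!is.null(cfg$registry_stats)) {
      reg <- read_registry_stats(cfg$registry_stats)
      cmp <- stage("rank-compare",
                   compare_rankings(strata,
                                    utils::head(reg$concept_id, cfg$top_n)))
      write_rank_comparison(cmp, file.path(cfg$out_dir, "rank_comparison.csv"))
    }
  }

  log_lines <- c(log_lines, sprintf("total_elapsed=%.2fs",
                                    as.numeric(Sys.time() - t0, units = "secs")))
  writeLines(log_lines, log_path)
  invisible(list(n_read = n_read, n_in_window = nrow(corpus), n_ads = n_ad,
                 n_cancer_posts = n_cancer, summary = summary,
                 freq_superclass = tab_super, freq_class = tab_class,
                 freq_endnode = tab_end, freq_types = tab_types,
                 strata = strata, strata_superclass = tab_strat,
                 rank_comparison = cmp))
}
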