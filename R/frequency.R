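#' Relative frequency as a percentage
#'
#' `100 * n / total`, rounded half-up to `digits` decimals — the rounding
#' convention used throughout for reported percentages. Raw (unrounded)
#' values are retained alongside rounded ones in every table this package
#' writes; use `raw = TRUE` to get the unrounded value here.
#'
#' @param n Count(s), `0 <= n <= total`.
#' @param total Denominator, `> 0`.
#' @param digits Decimals for half-up rounding.
#' @param raw If TRUE, return the unrounded percentage.
#' @return Numeric vector of percentages.
#' @examples
#' relative_frequency(320568, 754744)  # 42.5
#' @export
relative_frequency <- function(n, total, digits = 1, raw = FALSE) {
  if (any(total == 0)) stop("undefined relative frequency: total is 0")
  if (any(n < 0) || any(n > total)) stop("need 0 <= n <= total")
  pct <- 100 * n / total
  if (raw) pct else round_half_up(pct, digits)
}

# Restrict annotations to the analysis corpus: cancer posts that are not
# advertisements.
qualifying <- function(annotations) {
  annotations[annotations$is_cancer_post & !annotations$is_ad, , drop = FALSE]
}

make_freq_table <- function(counts, total, stratum, level, ont) {
  if (length(counts) == 0) {
    out <- tibble(stratum = character(), level = character(),
                  concept_id = character(), label = character(),
                  n_posts = integer(), total = integer(),
                  pct_raw = numeric(), pct = numeric())
    class(out) <- c("oncolex_freq", class(out))
    return(out)
  }
  lab <- ont$nodes$preferred_label[match(names(counts), ont$nodes$concept_id)]
  pct_raw <- if (total > 0) 100 * unname(counts) / total else
    rep(NA_real_, length(counts))
  pct <- if (total > 0) relative_frequency(unname(counts), total) else
    rep(NA_real_, length(counts))
  out <- tibble(stratum = stratum, level = level,
                concept_id = names(counts), label = lab,
                n_posts = as.integer(unname(counts)), total = as.integer(total),
                pct_raw = pct_raw, pct = pct)
  out <- out[order(-out$n_posts, out$concept_id, method = "radix"), ]
  class(out) <- c("oncolex_freq", class(out))
  out
}

#' Count posts per concept
#'
#' Post-level binary counting over the analysis corpus (cancer posts that
#' are not ads): a post contributes at most 1 to each concept's count,
#' however many times the concept's terms occur in it. `N` (the `total`
#' column) is the number of qualifying posts; percentages are `100 * n / N`.
#' Rows may sum to more than `N` — a post can mention many concepts — so
#' there is no sum-to-100 constraint.
#'
#' @param annotations Tibble from [annotate_corpus()].
#' @param ont The `oncolex_ontology` the annotations came from.
#' @param level `"class"` (every matched concept as-is), `"superclass"`
#'   (roll every concept up to its root) or `"end_node"` (leaf concepts
#'   only).
#' @return An `oncolex_freq` tibble: `stratum` (`"ALL"`), `level`,
#'   `concept_id`, `label`, `n_posts`, `total`, `pct_raw`, `pct`, ordered by
#'   descending count (ties by concept id).
#' @export
count_posts_by_concept <- function(annotations, ont,
                                   level = c("class", "superclass", "end_node")) {
  level <- match.arg(level)
  ann <- qualifying(annotations)
  all_c <- unlist(ann$concepts, use.names = FALSE)
  unknown <- setdiff(all_c, ont$nodes$concept_id)
  if (length(unknown) > 0) {
    stop("annotation references concept(s) absent from the ontology: ",
         paste(unknown, collapse = ", "))
  }
  N <- nrow(ann)
  sets <- switch(level,
    class = ann$concepts,
    superclass = {
      sc <- superclass_map(ont)
      lapply(ann$concepts, function(cc) unique(unname(sc[cc])))
    },
    end_node = {
      leaves <- setdiff(ont$nodes$concept_id, ont$nodes$parent_id)
      lapply(ann$concepts, function(cc) cc[cc %in% leaves])
    })
  counts <- table(unlist(sets, use.names = FALSE))
  counts <- stats::setNames(as.integer(counts), names(counts))
  make_freq_table(counts, N, "ALL", level, ont)
}

#' Roll post counts up to the superclass level
#'
#' A post counts once toward superclass S iff it contains at least one
#' concept in S's subtree (including a direct mention of S's own surface
#' forms). Convenience wrapper around
#' `count_posts_by_concept(level = "superclass")`.
#'
#' @inheritParams count_posts_by_concept
#' @return An `oncolex_freq` tibble at superclass level.
#' @export
rollup_to_superclass <- function(annotations, ont) {
  count_posts_by_concept(annotations, ont, level = "superclass")
}

#' Stratify frequencies by cancer type
#'
#' For each cancer type `t`, the stratum corpus is the set of qualifying
#' posts whose concepts include `t` (or a descendant of `t`); counts and
#' percentages within the stratum are computed against that stratum's own
#' post total. A post mentioning several cancer types appears in each of
#' their strata. Strata with zero posts are reported explicitly in the
#' `totals` attribute (and get no concept rows).
#'
#' @inheritParams count_posts_by_concept
#' @param types Character vector of cancer-type concept ids, each a
#'   descendant of the cancer-type superclass.
#' @param cancer_type_root Concept id of the cancer-type superclass.
#' @return An `oncolex_freq` tibble with one block of rows per stratum, with
#'   attribute `totals` (tibble `stratum`, `total`).
#' @export
stratify_by_cancer_type <- function(annotations, ont, types,
                                    level = c("superclass", "class", "end_node"),
                                    cancer_type_root = "cancer_type") {
  level <- match.arg(level)
  unknown <- setdiff(types, ont$nodes$concept_id)
  if (length(unknown) > 0) stop("unknown type id(s): ", paste(unknown, collapse = ", "))
  ok <- c(cancer_type_root, descendants(ont, cancer_type_root))
  off <- setdiff(types, ok)
  if (length(off) > 0) {
    stop("type id(s) not under the cancer-type superclass: ",
         paste(off, collapse = ", "))
  }
  ann <- qualifying(annotations)
  blocks <- list(); totals <- list()
  for (t in types) {
    tset <- c(t, descendants(ont, t))
    in_stratum <- vapply(ann$concepts, function(cc) any(cc %in% tset), logical(1))
    sub <- ann[in_stratum, , drop = FALSE]
    totals[[t]] <- tibble(stratum = t, total = nrow(sub))
    if (nrow(sub) > 0) {
      tab <- count_posts_by_concept(sub, ont, level = level)
      tab$stratum <- t
      blocks[[t]] <- tab
    }
  }
  out <- if (length(blocks)) dplyr::bind_rows(blocks) else
    tibble(stratum = character(), level = character(), concept_id = character(),
           label = character(), n_posts = integer(), total = integer(),
           pct_raw = numeric(), pct = numeric())
  class(out) <- unique(c("oncolex_freq", class(out)))
  attr(out, "totals") <- dplyr::bind_rows(totals)
  out
}

#' Top-n concepts of a frequency table
#'
#' Rows sorted by post count descending, ties broken by concept id in
#' lexicographic (C radix) order — the deterministic tie rule used
#' everywhere in the package; the first `n` concept ids are returned.
#'
#' @param table An `oncolex_freq` tibble (single stratum).
#' @param n Number of concepts to return, `> 0`.
#' @return Character vector of concept ids, highest count first.
#' @export
rank_top_n <- function(table, n) {
  if (!is.numeric(n) || length(n) != 1 || n <= 0) stop("n must be a positive number")
  if (nrow(table) == 0) stop("empty frequency table")
  ord <- order(-table$n_posts, table$concept_id, method = "radix")
  utils::head(table$concept_id[ord], n)
}

#' Compare social media and registry cancer-type rankings
#'
#' Set algebra between a top-n list derived from social media post counts
#' and a top-n list from national cancer registry incidence statistics,
#' plus a per-type rank table.
#'
#' @param social_top Ordered character vector (no duplicates).
#' @param registry_top Ordered character vector (no duplicates).
#' @return An `oncolex_rank_comparison` list: `social_top`, `registry_top`,
#'   `shared`, `social_only`, `registry_only`, and `ranks` (tibble `type`,
#'   `social_rank`, `registry_rank`, `NA` where absent).
#' @export
compare_rankings <- function(social_top, registry_top) {
  if (anyDuplicated(social_top)) stop("duplicate entries in social_top")
  if (anyDuplicated(registry_top)) stop("duplicate entries in registry_top")
  all_types <- union(social_top, registry_top)
  ranks <- tibble(
    type = all_types,
    social_rank = match(all_types, social_top),
    registry_rank = match(all_types, registry_top))
  structure(list(
    social_top = social_top, registry_top = registry_top,
    shared = intersect(social_top, registry_top),
    social_only = setdiff(social_top, registry_top),
    registry_only = setdiff(registry_top, social_top),
    ranks = ranks), class = "oncolex_rank_comparison")
}

#' @export
print.oncolex_rank_comparison <- function(x, ...) {
  cat("<rank comparison>\n  shared:       ",
      paste(x$shared, collapse = ", "), "\n  social only:  ",
      paste(x$social_only, collapse = ", "), "\n  registry only:",
      paste(x$registry_only, collapse = ", "), "\n")
  invisible(x)
}

#' Read registry incidence statistics
#'
#' CSV with columns `cancer_type_label`, `concept_id`, `incidence_rank`
#' (integer >= 1). The packaged
#' `extdata/registry_stats_synthetic.csv` is a synthetic stand-in table
#' consistent with the publicly reported constraints of the Korean national
#' cancer statistics (it is not the registry's own publication).
#'
#' @param path CSV path; defaults to the packaged synthetic table.
#' @return Tibble ordered by `incidence_rank`.
#' @export
read_registry_stats <- function(path = system.file("extdata",
                                                   "registry_stats_synthetic.csv",
                                                   package = "oncolex",
                                                   mustWork = TRUE)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cancer_type_label", "concept_id", "incidence_rank")
  if (!all(need %in% names(df))) {
    stop("registry statistics file must have columns: ",
         paste(need, collapse = ", "))
  }
  df <- df[order(df$incidence_rank), ]
  as_tibble(df)
}

#' Write a frequency table as tidy CSV
#'
#' @param table An `oncolex_freq` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Write a rank comparison as tidy CSV
#'
#' @param cmp An `oncolex_rank_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rank_comparison <- function(cmp, path) {
  utils::write.csv(as.data.frame(cmp$ranks), path, row.names = FALSE)
  invisible(path)
}
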