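#' Read a post corpus from a JSON-lines file
#'
#' The corpus format is UTF-8, one JSON object per line with keys `post_id`,
#' `platform`, `source_type` (`"blog"` or `"community"`), `date` (ISO-8601
#' day) and `text`. The post is the unit of every downstream analysis, so a
#' duplicate `post_id` aborts ingestion rather than being silently
#' deduplicated.
#'
#' @param path File path.
#' @return A tibble with one row per post: `post_id`, `platform`,
#'   `source_type`, `date` (class `Date`), `text`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(post_id = character(), platform = character(),
                  source_type = character(), date = as.Date(character()),
                  text = character()))
  }
  need <- c("post_id", "platform", "source_type", "date", "text")
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(rec) || !is.list(rec)) {
      stop("record error at line ", i, ": not a JSON object")
    }
    missing <- setdiff(need, names(rec))
    if (length(missing) > 0) {
      stop("record error at line ", i, ": missing field(s) ",
           paste(missing, collapse = ", "))
    }
    recs[[i]] <- rec[need]
  }
  out <- tibble(
    post_id = vapply(recs, function(r) as.character(r$post_id), character(1)),
    platform = vapply(recs, function(r) as.character(r$platform), character(1)),
    source_type = vapply(recs, function(r) as.character(r$source_type), character(1)),
    date = as.Date(vapply(recs, function(r) as.character(r$date), character(1))),
    text = vapply(recs, function(r) as.character(r$text), character(1))
  )
  if (anyNA(out$date)) {
    stop("record error at line ", which(is.na(out$date))[1],
         ": unparseable date")
  }
  dup <- out$post_id[duplicated(out$post_id)]
  if (length(dup) > 0) {
    stop("corpus error: duplicate post_id: ",
         paste(unique(dup), collapse = ", "))
  }
  bad <- !out$source_type %in% c("blog", "community")
  if (any(bad)) {
    stop("record error at line ", which(bad)[1],
         ": source_type must be 'blog' or 'community'")
  }
  out
}

#' Write a post corpus as JSON lines
#'
#' Inverse of [read_corpus()]; the round trip is lossless for all fields.
#'
#' @param corpus Tibble as returned by [read_corpus()] or
#'   [generate_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(post_id = corpus$post_id[i],
                          platform = corpus$platform[i],
                          source_type = corpus$source_type[i],
                          date = format(corpus$date[i], "%Y-%m-%d"),
                          text = corpus$text[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Mask identifying information in free text
#'
#' Pattern-based de-identification: URLs (which may embed account names),
#' e-mail addresses, Korean-style phone numbers (dashed `02-123-4567` /
#' `010-1234-5678` forms and bare 10-11 digit mobile numbers) and `@handles`
#' are each replaced by a fixed placeholder of the same category. Everything
#' else is untouched. The operation is idempotent, and personal names are
#' not detected (that requires named-entity recognition, a documented
#' limitation).
#'
#' @param text Character vector.
#' @return Character vector with placeholders `<url>`, `<email>`, `<phone>`,
#'   `<handle>` substituted.
#' @examples
#' deidentify("call 010-1234-5678 or mail a@b.com")
#' @export
deidentify <- function(text) {
  text <- stringi::stri_replace_all_regex(
    text, "(?:https?://|www\\.)\\S+|(?:[A-Za-z0-9-]+\\.)+(?:com|net|org|kr)/\\S+",
    "<url>")
  text <- stringi::stri_replace_all_regex(
    text, "[A-Za-z0-9._%+-]+@[A-Za-z0-9-]+(?:\\.[A-Za-z0-9-]+)*\\.[A-Za-z]{2,}",
    "<email>")
  text <- stringi::stri_replace_all_regex(
    text, "(?<![0-9])0[0-9]{1,2}-[0-9]{3,4}-[0-9]{4}(?![0-9])", "<phone>")
  text <- stringi::stri_replace_all_regex(
    text, "(?<![0-9])01[0-9]{8,9}(?![0-9])", "<phone>")
  text <- stringi::stri_replace_all_regex(
    text, "@[A-Za-z0-9_.]+", "<handle>")
  text
}

#' Restrict a corpus to a date window
#'
#' Retains posts whose date lies in the closed interval `[start, end]`
#' (both boundary days included).
#'
#' @param corpus Corpus tibble.
#' @param start,end `Date` (or ISO-8601 strings), `start <= end`.
#' @return The filtered corpus tibble.
#' @export
filter_by_date <- function(corpus, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) stop("unparseable start/end date")
  if (start > end) stop("start date is after end date")
  corpus[corpus$date >= start & corpus$date <= end, , drop = FALSE]
}

#' Summarize a corpus
#'
#' Post counts in total and by year, platform and source type. Can also be
#' constructed directly from known yearly counts via the `by_year` argument
#' (with `corpus = NULL`), in which case the total is their sum — useful for
#' bookkeeping checks against published count tables.
#'
#' @param corpus Corpus tibble, or `NULL` when `by_year` is given.
#' @param by_year Optional named numeric vector of posts per year.
#' @return A `oncolex_corpus_summary` list with `total`, `by_year`,
#'   `by_platform`, `by_source`.
#' @examples
#' summarize_corpus(by_year = c("2014" = 100, "2015" = 50))$total
#' @export
summarize_corpus <- function(corpus = NULL, by_year = NULL) {
  if (is.null(corpus)) {
    if (is.null(by_year)) stop("provide a corpus or by_year counts")
    by_year <- by_year[order(names(by_year))]
    return(structure(list(total = sum(by_year), by_year = by_year,
                          by_platform = NULL, by_source = NULL),
                     class = "oncolex_corpus_summary"))
  }
  year <- format(corpus$date, "%Y")
  cnt <- function(x) {
    t <- table(x)
    stats::setNames(as.numeric(t), names(t))
  }
  structure(list(total = nrow(corpus),
                 by_year = cnt(year),
                 by_platform = cnt(corpus$platform),
                 by_source = cnt(corpus$source_type)),
            class = "oncolex_corpus_summary")
}

#' @export
print.oncolex_corpus_summary <- function(x, ...) {
  cat("<corpus summary> total posts:", format(x$total, big.mark = ","), "\n")
  if (!is.null(x$by_year)) {
    cat("  by year: ", paste(names(x$by_year), format(x$by_year, big.mark = ","),
                             sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$by_source)) {
    cat("  by source:", paste(names(x$by_source), x$by_source,
                              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a corpus summary as tidy CSV
#'
#' Columns `stratum_kind` (total/year/platform/source), `stratum`, `n_posts`.
#'
#' @param summary A `oncolex_corpus_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_summary <- function(summary, path) {
  rows <- list(tibble(stratum_kind = "total", stratum = "ALL",
                      n_posts = summary$total))
  for (kind in c("by_year", "by_platform", "by_source")) {
    v <- summary[[kind]]
    if (!is.null(v) && length(v)) {
      rows[[length(rows) + 1]] <- tibble(stratum_kind = sub("^by_", "", kind),
                                         stratum = names(v), n_posts = unname(v))
    }
  }
  utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE)
  invisible(path)
}
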