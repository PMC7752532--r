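#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

#' Construct an ontology object
#'
#' An ontology is a single-parent concept forest (roots are the superclasses)
#' plus a terminology: the mapping from consumer surface forms (preferred
#' terms, synonyms, abbreviations, heteronyms) to concepts. Most users load
#' one with [load_ontology()] or [skeleton_ontology()] rather than calling
#' this directly.
#'
#' @param nodes Tibble with columns `concept_id`, `parent_id` (`NA` for
#'   roots), `preferred_label`.
#' @param terms Tibble with columns `surface_form`, `concept_id`,
#'   `term_type` (one of preferred/synonym/abbreviation/heteronym).
#' @param strict If `TRUE` (default), structural defects — duplicate ids,
#'   dangling parents, cycles — raise an error. With `FALSE` the object is
#'   built anyway so that [validate_ontology()] can report the defects.
#' @return An object of class `oncolex_ontology` with elements `nodes`
#'   (including a computed `level`, 0 for superclasses), `terms` (including
#'   the normalized form `norm_form`), and `roots` (ordered superclass ids).
#' @export
ontology <- function(nodes, terms, strict = TRUE) {
  nodes <- as_tibble(nodes)
  terms <- as_tibble(terms)
  stopifnot(all(c("concept_id", "parent_id", "preferred_label") %in% names(nodes)),
            all(c("surface_form", "concept_id", "term_type") %in% names(terms)))
  nodes$parent_id[!is.na(nodes$parent_id) & nodes$parent_id == ""] <- NA_character_

  if (strict) {
    dup <- nodes$concept_id[duplicated(nodes$concept_id)]
    if (length(dup) > 0) {
      stop("duplicate concept_id: ", paste(unique(dup), collapse = ", "))
    }
    bad <- setdiff(stats::na.omit(nodes$parent_id), nodes$concept_id)
    if (length(bad) > 0) {
      stop("dangling parent_id: ", paste(unique(bad), collapse = ", "))
    }
  }

  nodes$level <- compute_levels(nodes$concept_id, nodes$parent_id)
  if (strict && anyNA(nodes$level)) {
    stop("cycle in hierarchy involving: ",
         paste(nodes$concept_id[is.na(nodes$level)], collapse = ", "))
  }
  terms$norm_form <- normalize_text(terms$surface_form)
  roots <- nodes$concept_id[is.na(nodes$parent_id)]

  structure(list(nodes = nodes, terms = terms, roots = roots),
            class = "oncolex_ontology")
}

# Depth of each node (0 for roots) by iterative propagation; NA where the
# parent chain never reaches a root (cycle or dangling parent).
compute_levels <- function(ids, parents) {
  lev <- ifelse(is.na(parents), 0L, NA_integer_)
  names(lev) <- ids
  repeat {
    fill <- is.na(lev) & !is.na(parents) & !is.na(lev[parents])
    if (!any(fill)) break
    lev[fill] <- lev[parents[fill]] + 1L
  }
  unname(lev[ids])
}

#' @export
print.oncolex_ontology <- function(x, ...) {
  cat("<oncolex_ontology> ", length(x$roots), " superclasses, ",
      nrow(x$nodes) - length(x$roots), " classes, ",
      nrow(x$terms), " terms, max depth ",
      suppressWarnings(max(x$nodes$level, na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' Load an ontology from disk
#'
#' Two dialects are supported. The tabular dialect is a UTF-8 tab-separated
#' file with header `concept_id, parent_id, preferred_label, term_type,
#' surface_form`, one row per term (`parent_id` empty for superclass roots);
#' `#`-prefixed lines are comments. The OBO-like dialect uses `[Term]`
#' stanzas with `id:`, `name:`, `is_a:` and `synonym:` lines, as written by
#' [save_ontology()].
#'
#' @param path File path.
#' @param format `"tabular"` or `"obo"`.
#' @return An `oncolex_ontology`. Root order follows first appearance in the
#'   file.
#' @examples
#' ont <- skeleton_ontology()
#' ont
#' @export
load_ontology <- function(path, format = c("tabular", "obo")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("ontology file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (format == "tabular") parse_tabular_ontology(lines, path)
  else parse_obo_ontology(lines, path)
}

parse_tabular_ontology <- function(lines, path) {
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) stop("parse error in ", path, ": empty ontology file")
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  header <- fields[[1]]
  want <- c("concept_id", "parent_id", "preferred_label", "term_type", "surface_form")
  if (!identical(trimws(header), want)) {
    stop("parse error in ", path, " line ", idx[1],
         ": expected header ", paste(want, collapse = "\t"))
  }
  n_ok <- lengths(fields[-1])
  bad <- which(n_ok != 5L)
  if (length(bad) > 0) {
    stop("parse error in ", path, " line ", idx[bad[1] + 1],
         ": expected 5 tab-separated fields, got ", n_ok[bad[1]])
  }
  if (length(fields) == 1) stop("parse error in ", path, ": no term rows")
  m <- do.call(rbind, fields[-1])
  tab <- tibble(concept_id = m[, 1], parent_id = m[, 2],
                preferred_label = m[, 3], term_type = m[, 4],
                surface_form = m[, 5])

  # concept metadata must be consistent across its term rows
  first <- !duplicated(tab$concept_id)
  nodes <- tab[first, c("concept_id", "parent_id", "preferred_label")]
  key <- paste(tab$concept_id, tab$parent_id, tab$preferred_label, sep = "\r")
  ref <- key[first][match(tab$concept_id, tab$concept_id[first])]
  if (any(key != ref)) {
    off <- tab$concept_id[key != ref][1]
    stop("structural error in ", path, ": concept ", off,
         " has inconsistent parent_id/preferred_label across rows")
  }
  terms <- tab[, c("surface_form", "concept_id", "term_type")]
  terms <- terms[!duplicated(terms), ]
  ontology(nodes, terms, strict = TRUE)
}

parse_obo_ontology <- function(lines, path) {
  starts <- which(trimws(lines) == "[Term]")
  if (length(starts) == 0) stop("parse error in ", path, ": no [Term] stanzas")
  ends <- c(starts[-1] - 1L, length(lines))
  nodes <- list(); terms <- list()
  for (k in seq_along(starts)) {
    body <- lines[starts[k]:ends[k]]
    get1 <- function(tag) {
      v <- sub(paste0("^", tag, ":\\s*"), "", grep(paste0("^", tag, ":"), body, value = TRUE))
      if (length(v) == 0) NA_character_ else v[1]
    }
    id <- get1("id"); name <- get1("name")
    if (is.na(id) || is.na(name)) {
      stop("parse error in ", path, " near line ", starts[k],
           ": [Term] stanza missing id or name")
    }
    isa <- get1("is_a")
    nodes[[k]] <- tibble(concept_id = id, parent_id = isa, preferred_label = name)
    syn_lines <- grep("^synonym:", body, value = TRUE)
    sf <- stringi::stri_match_first_regex(syn_lines, '^synonym:\\s*"(.*)"\\s*(\\S*)')
    terms[[k]] <- tibble(
      surface_form = c(name, if (length(syn_lines)) sf[, 2]),
      concept_id = id,
      term_type = c("preferred", if (length(syn_lines))
        ifelse(nzchar(sf[, 3]), tolower(sf[, 3]), "synonym")))
  }
  ontology(dplyr::bind_rows(nodes), dplyr::bind_rows(terms), strict = TRUE)
}

#' Save an ontology
#'
#' Writes the tabular dialect (see [load_ontology()]) or an OBO-like export.
#' The tabular form round-trips: loading it back yields an ontology equal to
#' the original under id-wise comparison.
#'
#' @param ont An `oncolex_ontology`.
#' @param path Output file path.
#' @param format `"tabular"` or `"obo"`.
#' @return `path`, invisibly.
#' @export
save_ontology <- function(ont, path, format = c("tabular", "obo")) {
  format <- match.arg(format)
  stopifnot(inherits(ont, "oncolex_ontology"))
  ord <- order(match(ont$terms$concept_id, ont$nodes$concept_id))
  tm <- ont$terms[ord, ]
  nd <- ont$nodes[match(tm$concept_id, ont$nodes$concept_id), ]
  if (format == "tabular") {
    out <- c(paste(c("concept_id", "parent_id", "preferred_label",
                     "term_type", "surface_form"), collapse = "\t"),
             paste(nd$concept_id,
                   ifelse(is.na(nd$parent_id), "", nd$parent_id),
                   nd$preferred_label, tm$term_type, tm$surface_form,
                   sep = "\t"))
  } else {
    out <- unlist(lapply(ont$nodes$concept_id, function(id) {
      node <- ont$nodes[ont$nodes$concept_id == id, ]
      syn <- ont$terms[ont$terms$concept_id == id & ont$terms$term_type != "preferred", ]
      c("[Term]",
        paste0("id: ", id),
        paste0("name: ", node$preferred_label),
        if (!is.na(node$parent_id)) paste0("is_a: ", node$parent_id),
        if (nrow(syn)) paste0('synonym: "', syn$surface_form, '" ',
                              toupper(syn$term_type)),
        "")
    }))
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(path)
}

#' Load the packaged cancer ontology skeleton
#'
#' The skeleton encodes the nine-superclass consumer cancer ontology (cancer
#' type, prevention, diagnosis, treatment, prognosis, risk factor, symptom,
#' dealing with cancer, emotion) with the subclasses and consumer terms that
#' are publicly documented — e.g. the nine emotion classes, the risk-factor
#' and symptom subclass families, and consumer abbreviations such as
#' "jaegeom" (re-test) and heteronyms such as "jol-eob" (graduation, meaning
#' complete cure). It is a structural skeleton: the full 213-class /
#' 4061-synonym terminology of the original study was never published, and
#' [generate_ontology_fixture()] extends this skeleton with synthetic classes
#' where larger vocabularies are needed.
#'
#' @return An `oncolex_ontology` with 9 superclass roots.
#' @export
skeleton_ontology <- function() {
  load_ontology(system.file("extdata", "cancer_ontology_skeleton.tsv",
                            package = "oncolex", mustWork = TRUE))
}

#' Validate an ontology
#'
#' Checks every structural invariant and reports — rather than raises — the
#' violations: duplicate concept ids (`DUPLICATE_CONCEPT`), dangling parents
#' (`DANGLING_PARENT`), parent cycles (`CYCLE`), empty surface forms
#' (`EMPTY_TERM`), terms pointing at unknown concepts (`UNKNOWN_TERM_CONCEPT`)
#' and hierarchy depth beyond `max_depth` (`DEPTH_EXCEEDED`). A surface form
#' that maps to more than one concept after normalization is reported as the
#' warning `AMBIGUOUS_TERM` (the matcher refuses such terms until they are
#' resolved); exact duplicate rows under one concept give the warning
#' `DUPLICATE_TERM`.
#'
#' @param ont An `oncolex_ontology` (possibly built with `strict = FALSE`).
#' @param max_depth Maximum allowed node depth (root = 0).
#' @return A `oncolex_validation` list: `errors` and `warnings` (tibbles with
#'   `code`, `message`, `ids`) and `counts` (`n_superclasses`, `n_classes`,
#'   `n_terms`, `max_depth`).
#' @export
validate_ontology <- function(ont, max_depth = 4) {
  stopifnot(inherits(ont, "oncolex_ontology"))
  errs <- list(); warns <- list()
  err <- function(code, message, ids) {
    errs[[length(errs) + 1]] <<- tibble(code = code, message = message,
                                        ids = paste(ids, collapse = ","))
  }
  wrn <- function(code, message, ids) {
    warns[[length(warns) + 1]] <<- tibble(code = code, message = message,
                                          ids = paste(ids, collapse = ","))
  }

  nd <- ont$nodes
  dup <- unique(nd$concept_id[duplicated(nd$concept_id)])
  if (length(dup)) err("DUPLICATE_CONCEPT", "concept_id not unique", dup)
  dang <- unique(setdiff(stats::na.omit(nd$parent_id), nd$concept_id))
  if (length(dang)) err("DANGLING_PARENT", "parent_id not a known concept", dang)
  lev <- compute_levels(nd$concept_id, nd$parent_id)
  cyc <- nd$concept_id[is.na(lev) & !(nd$parent_id %in% dang)]
  if (length(cyc)) err("CYCLE", "parent chain never reaches a root", cyc)
  deep <- nd$concept_id[!is.na(lev) & lev > max_depth]
  if (length(deep)) {
    err("DEPTH_EXCEEDED", paste0("depth exceeds limit ", max_depth), deep)
  }

  tm <- ont$terms
  empty <- tm$concept_id[!nzchar(tm$norm_form)]
  if (length(empty)) err("EMPTY_TERM", "surface form empty after normalization", unique(empty))
  unk <- unique(setdiff(tm$concept_id, nd$concept_id))
  if (length(unk)) err("UNKNOWN_TERM_CONCEPT", "term references unknown concept", unk)

  by_form <- split(tm$concept_id, tm$norm_form)
  amb <- by_form[vapply(by_form, function(x) length(unique(x)) > 1, logical(1))]
  for (form in names(amb)) {
    wrn("AMBIGUOUS_TERM", paste0("surface form '", form,
                                 "' maps to multiple concepts"),
        sort(unique(amb[[form]])))
  }
  dup_rows <- duplicated(tm[, c("norm_form", "concept_id")])
  if (any(dup_rows)) {
    wrn("DUPLICATE_TERM", "duplicate term rows under one concept",
        unique(tm$concept_id[dup_rows]))
  }

  empty_tbl <- tibble(code = character(), message = character(), ids = character())
  structure(list(
    errors = if (length(errs)) dplyr::bind_rows(errs) else empty_tbl,
    warnings = if (length(warns)) dplyr::bind_rows(warns) else empty_tbl,
    counts = list(n_superclasses = sum(is.na(nd$parent_id)),
                  n_classes = sum(!is.na(nd$parent_id)),
                  n_terms = nrow(tm),
                  max_depth = if (all(is.na(lev))) NA_integer_ else
                    max(lev, na.rm = TRUE))
  ), class = "oncolex_validation")
}

#' @export
print.oncolex_validation <- function(x, ...) {
  c0 <- x$counts
  cat("<ontology validation> ", c0$n_superclasses, " superclasses, ",
      c0$n_classes, " classes, ", c0$n_terms, " terms, max depth ",
      c0$max_depth, "\n", sep = "")
  cat("  errors: ", nrow(x$errors), ", warnings: ", nrow(x$warnings), "\n", sep = "")
  if (nrow(x$errors)) print(x$errors)
  invisible(x)
}

#' Transitive descendants of a concept
#'
#' @param ont An `oncolex_ontology`.
#' @param concept_id A single concept id present in the ontology.
#' @return Character vector of all concepts below `concept_id` (excluding
#'   itself); empty for leaves.
#' @export
descendants <- function(ont, concept_id) {
  stopifnot(inherits(ont, "oncolex_ontology"))
  if (!concept_id %in% ont$nodes$concept_id) {
    stop("unknown concept_id: ", concept_id)
  }
  kids <- split(ont$nodes$concept_id, ont$nodes$parent_id)
  out <- character(0)
  frontier <- concept_id
  while (length(frontier) > 0) {
    nxt <- unlist(kids[frontier], use.names = FALSE)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Superclass (root ancestor) of a concept
#'
#' Walks parent links to the root; the identity for superclasses themselves.
#' This is the rollup target used by post-level superclass counting.
#'
#' @inheritParams descendants
#' @return The root concept id.
#' @export
superclass_of <- function(ont, concept_id) {
  stopifnot(inherits(ont, "oncolex_ontology"))
  nd <- ont$nodes
  cur <- concept_id
  if (!cur %in% nd$concept_id) stop("unknown concept_id: ", concept_id)
  for (i in seq_len(nrow(nd) + 1L)) {
    p <- nd$parent_id[match(cur, nd$concept_id)]
    if (is.na(p)) return(cur)
    cur <- p
    if (!cur %in% nd$concept_id) stop("dangling parent for concept: ", concept_id)
  }
  stop("cycle detected walking parents of: ", concept_id)
}

# Vectorized root lookup used by the frequency module: named vector
# concept_id -> root id, computed once per ontology.
superclass_map <- function(ont) {
  ids <- ont$nodes$concept_id
  stats::setNames(vapply(ids, function(id) superclass_of(ont, id), character(1)), ids)
}
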