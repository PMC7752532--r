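# Independent brute-force oracles used to check the package's traversal,
# masking and matching implementations. Deliberately naive: plain substring
# scans and exhaustive walks, no stringi, no shared code with R/.

# All occurrences of `phrase` in `text` by character-by-character comparison.
oracle_occurrences <- function(text, phrase) {
  n <- nchar(text); m <- nchar(phrase)
  if (m == 0 || m > n) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(n - m + 1)) {
    if (substr(text, i, i + m - 1) == phrase) starts <- c(starts, i)
  }
  starts
}

# Maximal non-overlapping span set under the (length desc, start asc) order:
# repeatedly take the longest (then leftmost) candidate that does not
# overlap anything already taken.
oracle_select <- function(text, phrases) {
  cand <- data.frame(start = integer(), end = integer(), phrase = character())
  for (p in unique(phrases)) {
    st <- oracle_occurrences(text, p)
    if (length(st)) {
      cand <- rbind(cand, data.frame(start = st, end = st + nchar(p) - 1L,
                                     phrase = p))
    }
  }
  taken <- cand[0, ]
  repeat {
    ok <- rep(TRUE, nrow(cand))
    for (j in seq_len(nrow(cand))) {
      for (k in seq_len(nrow(taken))) {
        if (cand$start[j] <= taken$end[k] && cand$end[j] >= taken$start[k]) {
          ok[j] <- FALSE
        }
      }
    }
    avail <- cand[ok, , drop = FALSE]
    if (nrow(avail) == 0) break
    len <- avail$end - avail$start + 1L
    best <- which(len == max(len))
    best <- best[which.min(avail$start[best])]
    taken <- rbind(taken, avail[best, ])
  }
  taken[order(taken$start), , drop = FALSE]
}

# Masking oracle: replace every selected span by a run of the mask char.
oracle_mask <- function(text, phrases, mask_char = "█") {
  sel <- oracle_select(text, phrases)
  out <- strsplit(text, "")[[1]]
  for (j in seq_len(nrow(sel))) {
    out[sel$start[j]:sel$end[j]] <- mask_char
  }
  paste(out, collapse = "")
}

# Matching oracle: same span selection over the term surface forms, then
# map each selected span back to its concept.
oracle_match <- function(text, forms, concepts) {
  sel <- oracle_select(text, forms)
  sel$concept_id <- concepts[match(sel$phrase, forms)]
  sel
}

# Exhaustive descendant enumeration: a node is a descendant of x iff its
# parent chain passes through x.
oracle_descendants <- function(nodes, x) {
  res <- character(0)
  for (id in nodes$concept_id) {
    cur <- id
    repeat {
      p <- nodes$parent_id[match(cur, nodes$concept_id)]
      if (is.na(p)) break
      if (p == x) { res <- c(res, id); break }
      cur <- p
    }
  }
  res
}

oracle_root_of <- function(nodes, x) {
  cur <- x
  repeat {
    p <- nodes$parent_id[match(cur, nodes$concept_id)]
    if (is.na(p)) return(cur)
    cur <- p
  }
}

# Random single-parent forest with `n` nodes and roughly `n_roots` roots.
random_tree_nodes <- function(n, n_roots = 2) {
  ids <- sprintf("n%02d", seq_len(n))
  parent <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i > n_roots) parent[i] <- ids[sample.int(i - 1, 1)]
  }
  tibble::tibble(concept_id = ids, parent_id = parent,
                 preferred_label = paste0("label ", ids))
}

random_tree_ontology <- function(n, n_roots = 2) {
  nodes <- random_tree_nodes(n, n_roots)
  terms <- tibble::tibble(surface_form = nodes$preferred_label,
                          concept_id = nodes$concept_id,
                          term_type = "preferred")
  ontology(nodes, terms)
}

# Random text assembled from term surface forms, their fragments, and
# unrelated junk — designed to provoke overlaps and partial hits.
random_matchy_text <- function(forms, max_len = 60) {
  frag <- function(f) {
    n <- nchar(f)
    if (n <= 2) return(f)
    a <- sample.int(n, 1); b <- sample.int(n, 1)
    substr(f, min(a, b), max(a, b))
  }
  pieces <- character(0)
  while (sum(nchar(pieces)) < max_len) {
    what <- sample(3, 1)
    pieces <- c(pieces, switch(what,
      sample(forms, 1),
      frag(sample(forms, 1)),
      paste(sample(letters, sample.int(5, 1), TRUE), collapse = "")))
    if (stats::runif(1) < 0.5) pieces <- c(pieces, " ")
  }
  substr(paste(pieces, collapse = ""), 1, max_len)
}

skel <- oncolex::skeleton_ontology()
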