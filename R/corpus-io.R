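#' Coerce a data frame to a doc-term corpus tibble
#'
#' A corpus is a long tibble with one row per (document, term) membership:
#' columns `doc_id` (character), `term` (character) and `major` (logical,
#' whether the term is flagged as a major topic of the document). Duplicate
#' doc-term rows are collapsed (set semantics); a term is major if any of
#' its occurrences within the document is.
#'
#' @param x A data frame with columns `doc_id`, `term` and optionally
#'   `major` (defaults to `FALSE`).
#' @return A corpus tibble, sorted by `doc_id` then `term`.
#' @export
as_corpus <- function(x) {
  if (!is.data.frame(x)) abort("A corpus must be a data frame.")
  missing_cols <- setdiff(c("doc_id", "term"), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Corpus is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)
  if (!"major" %in% names(x)) x$major <- FALSE
  x %>%
    mutate(doc_id = as.character(.data$doc_id), term = as.character(.data$term),
           major = as.logical(.data$major)) %>%
    group_by(.data$doc_id, .data$term) %>%
    summarise(major = any(.data$major), .groups = "drop") %>%
    arrange(.data$doc_id, .data$term)
}

#' Corpus summaries
#'
#' `n_docs()` counts documents; `vocabulary()` returns the sorted set of
#' distinct terms.
#'
#' @param corpus A corpus tibble (see [as_corpus()]).
#' @return An integer count, or a character vector of terms.
#' @export
n_docs <- function(corpus) {
  n_distinct(as_corpus(corpus)$doc_id)
}

#' @rdname n_docs
#' @export
vocabulary <- function(corpus) {
  sort(unique(as_corpus(corpus)$term))
}

#' Read a MEDLINE-style citation XML file
#'
#' Parses the minimal citation dialect: `MedlineCitation` records holding a
#' `PMID` and a `MeshHeadingList` of `MeshHeading` elements, each with a
#' `DescriptorName` (attribute `MajorTopicYN`) and optional `QualifierName`
#' children. The term identifier is the descriptor name verbatim. A
#' descriptor is major if its own `MajorTopicYN` is "Y" or any of its
#' qualifiers is (a major qualifier promotes its descriptor). Citations
#' without a PMID or without descriptors are skipped with a warning.
#'
#' @param path Path to an XML file (or anything [xml2::read_xml()] accepts).
#' @return A corpus tibble.
#' @export
read_medline_xml <- function(path) {
  doc <- xml2::read_xml(path)
  citations <- xml2::xml_find_all(doc, ".//MedlineCitation")
  rows <- lapply(citations, function(cit) {
    pmid <- xml2::xml_find_first(cit, "./PMID")
    if (inherits(pmid, "xml_missing")) {
      warn("Skipping citation with no PMID element.")
      return(NULL)
    }
    pmid <- xml2::xml_text(pmid)
    headings <- xml2::xml_find_all(cit, ".//MeshHeadingList/MeshHeading")
    if (length(headings) == 0) {
      warn(sprintf("Skipping citation %s: no descriptors.", pmid))
      return(NULL)
    }
    term <- vapply(headings, function(h) {
      xml2::xml_text(xml2::xml_find_first(h, "./DescriptorName"))
    }, character(1))
    major <- vapply(headings, function(h) {
      d_major <- xml2::xml_attr(xml2::xml_find_first(h, "./DescriptorName"), "MajorTopicYN")
      q_major <- xml2::xml_attr(xml2::xml_find_all(h, "./QualifierName"), "MajorTopicYN")
      isTRUE(d_major == "Y") || any(q_major == "Y", na.rm = TRUE)
    }, logical(1))
    tibble(doc_id = pmid, term = term, major = major)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(as_corpus(tibble(doc_id = character(0), term = character(0), major = logical(0))))
  }
  as_corpus(bind_rows(rows))
}

#' Read and write the doc-term TSV format
#'
#' Three tab-separated columns: `doc_id`, `term`, major flag (`0`/`1`).
#' Lines starting with `#` are comments. `write_doc_term_tsv()` emits
#' documents sorted by `doc_id` and terms sorted lexicographically, so
#' write-then-read round-trips a corpus exactly.
#'
#' @param path File path.
#' @param corpus A corpus tibble.
#' @return `read_doc_term_tsv()` returns a corpus tibble;
#'   `write_doc_term_tsv()` returns `corpus` invisibly.
#' @export
read_doc_term_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(as_corpus(tibble(doc_id = character(0), term = character(0), major = logical(0))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields != 3L)) {
    bad <- line_no[which(n_fields != 3L)[1]]
    abort(sprintf("Line %d: expected 3 tab-separated columns, found %d.",
                  bad, n_fields[which(n_fields != 3L)[1]]))
  }
  mat <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  if (!all(mat[, 3] %in% c("0", "1"))) {
    bad <- line_no[which(!mat[, 3] %in% c("0", "1"))[1]]
    abort(sprintf("Line %d: major flag must be 0 or 1.", bad))
  }
  as_corpus(tibble(doc_id = mat[, 1], term = mat[, 2], major = mat[, 3] == "1"))
}

#' @rdname read_doc_term_tsv
#' @export
write_doc_term_tsv <- function(corpus, path) {
  corpus <- as_corpus(corpus)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# doc_id\tterm\tmajor", con)
  if (nrow(corpus) > 0) {
    writeLines(sprintf("%s\t%s\t%d", corpus$doc_id, corpus$term, as.integer(corpus$major)), con)
  }
  invisible(corpus)
}

#' Default check-tag list
#'
#' The standard MEDLINE check tags (Humans, Animals, the age-group tags,
#' common model organisms, ...), shipped as an editable text file in
#' `inst/extdata/check_tags.txt`. These near-ubiquitous descriptors carry
#' little discriminative content and are removed before network
#' construction.
#'
#' @return Character vector of term names.
#' @export
default_check_tags <- function() {
  path <- system.file("extdata", "check_tags.txt", package = "conet")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines[nzchar(lines) & !grepl("^#", lines)]
}

#' Remove check-tag terms from a corpus
#'
#' Every term in `tags` is removed from every document; documents left with
#' no terms are dropped. Tags absent from the corpus are silently ignored.
#'
#' @param corpus A corpus tibble.
#' @param tags Character vector of terms to remove; defaults to the shipped
#'   MEDLINE check-tag list.
#' @return A corpus tibble.
#' @export
filter_check_tags <- function(corpus, tags = default_check_tags()) {
  corpus <- as_corpus(corpus)
  filter(corpus, !.data$term %in% tags)
}

#' Restrict a corpus to major-topic terms
#'
#' Each document keeps only the terms flagged as major; documents with no
#' major terms are dropped. Idempotent.
#'
#' @param corpus A corpus tibble.
#' @return A corpus tibble in which every remaining term is major.
#' @export
restrict_major <- function(corpus) {
  corpus <- as_corpus(corpus)
  filter(corpus, .data$major)
}
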