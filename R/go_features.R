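# GO term-frequency feature construction: compact annotation databases,
# homolog transfer with successive search, vocabularies, count vectors.

GO_ID_PATTERN <- "^GO:[0-9]{7}$"
GO_CATEGORIES <- c("CC", "MF", "BP")

is_go_id <- function(x) grepl(GO_ID_PATTERN, x)

# error condition raised when no homolog within reach has any GO annotation
null_go_terms_error <- function(query) {
  structure(class = c("sparseloc_null_go_terms", "error", "condition"),
            list(message = sprintf(
              "no GO terms could be retrieved for query '%s'", query),
              call = NULL, query = query))
}

# ---- annotation database ---------------------------------------------------

#' Read a compact GO annotation database
#'
#' The compact database is a 3- or 4-column TSV: protein accession, GO
#' identifier (`GO:` + 7 digits), GO category (`CC`, `MF` or `BP`), and an
#' optional occurrence count (default 1). Rows repeating the same
#' (accession, term) pair have their counts summed, so a term annotated
#' twice yields frequency 2. Such a database plays the role of a compact
#' GOA extract: every stored accession maps to the multiset of GO terms
#' (with occurrence counts) transferred to proteins that hit it as a
#' homolog.
#'
#' @param file path to the TSV (no header), or a character vector of lines.
#' @return an object of class `"annotation_db"`: a named list mapping
#'   accession to a named integer vector of term counts, with a
#'   `categories` attribute mapping GO id to category.
#' @seealso [gaf_to_annotation_db()] to convert standard GAF 2.x,
#'   [retrieve_go_terms()]
#' @export
read_annotation_db <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("annotation database is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield < 3L | nfield > 4L)
  if (length(bad)) {
    stop(sprintf("annotation db parse error at line %d: expected 3-4 tab-separated fields",
                 bad[1L]))
  }
  acc <- vapply(parts, `[[`, "", 1L)
  term <- vapply(parts, `[[`, "", 2L)
  cat <- vapply(parts, `[[`, "", 3L)
  count <- vapply(parts, function(p) {
    if (length(p) == 4L) suppressWarnings(as.integer(p[[4L]])) else 1L
  }, 1L)
  bad <- which(!is_go_id(term))
  if (length(bad)) {
    stop(sprintf("annotation db parse error at line %d: malformed GO id '%s'",
                 bad[1L], term[bad[1L]]))
  }
  bad <- which(!cat %in% GO_CATEGORIES)
  if (length(bad)) {
    stop(sprintf("annotation db parse error at line %d: category '%s' not in CC/MF/BP",
                 bad[1L], cat[bad[1L]]))
  }
  bad <- which(is.na(count) | count < 1L)
  if (length(bad)) {
    stop(sprintf("annotation db parse error at line %d: invalid count", bad[1L]))
  }
  agg <- tapply(count, list(paste(acc, term, sep = "\r")), sum)
  keys <- strsplit(names(agg), "\r", fixed = TRUE)
  acc2 <- vapply(keys, `[[`, "", 1L)
  term2 <- vapply(keys, `[[`, "", 2L)
  entries <- lapply(split(seq_along(acc2), acc2), function(ii) {
    v <- as.integer(agg[ii])
    names(v) <- term2[ii]
    v[order(names(v))]
  })
  categories <- cat[!duplicated(term)]
  names(categories) <- term[!duplicated(term)]
  structure(entries, categories = categories, class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat(sprintf("annotation db: %d accessions, %d distinct GO terms\n",
              length(x), length(unique(unlist(lapply(x, names))))))
  invisible(x)
}

#' Convert a GAF 2.x gene-association file to the compact database
#'
#' Extracts the DB object id (column 2), GO id (column 5) and aspect
#' (column 9; `C`/`F`/`P` mapped to `CC`/`MF`/`BP`) from a Gene Ontology
#' annotation file, ignoring `!` comment lines, and builds the same
#' structure as [read_annotation_db()]. Each annotation row counts one
#' occurrence.
#'
#' @param file path to a GAF 2.x file, or a character vector of lines.
#' @return an `"annotation_db"`.
#' @export
gaf_to_annotation_db <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0L) stop("GAF file has no annotation rows")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 9L)
  if (length(short)) stop(sprintf("GAF parse error at row %d: fewer than 9 columns",
                                  short[1L]))
  aspect <- vapply(parts, `[[`, "", 9L)
  map <- c(C = "CC", F = "MF", P = "BP")
  if (any(!aspect %in% names(map))) {
    stop("GAF parse error: aspect column must be C, F or P")
  }
  tsv <- paste(vapply(parts, `[[`, "", 2L),
               vapply(parts, `[[`, "", 5L),
               map[aspect], sep = "\t")
  read_annotation_db(tsv)
}

# ---- homolog map -----------------------------------------------------------

#' Read a BLAST tabular (outfmt 6) homolog map
#'
#' Expects the standard 12-column BLAST tabular output (`qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue
#' bitscore`). Hits are ranked per query by ascending E-value, ties broken
#' by descending bit score and then by subject accession; duplicate
#' subjects keep their best-ranked hit only.
#'
#' @param file path to the TSV, or a character vector of lines.
#' @return class `"homolog_map"`: a named list mapping query id to the
#'   ordered character vector of subject accessions, best first.
#' @export
read_homolog_map <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("homolog map is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 12L)
  if (length(short)) {
    stop(sprintf("homolog map parse error at line %d: expected 12 columns (BLAST outfmt 6)",
                 short[1L]))
  }
  q <- vapply(parts, `[[`, "", 1L)
  s <- vapply(parts, `[[`, "", 2L)
  ev <- as.numeric(vapply(parts, `[[`, "", 11L))
  bs <- as.numeric(vapply(parts, `[[`, "", 12L))
  if (any(is.na(ev)) || any(is.na(bs))) stop("homolog map: non-numeric evalue/bitscore")
  out <- lapply(split(seq_along(q), q), function(ii) {
    ord <- ii[order(ev[ii], -bs[ii], s[ii])]
    s[ord][!duplicated(s[ord])]
  })
  structure(out, class = "homolog_map")
}

#' @export
print.homolog_map <- function(x, ...) {
  cat(sprintf("homolog map: %d queries, %.1f homologs per query on average\n",
              length(x), mean(lengths(x))))
  invisible(x)
}

#' Retrieve GO terms for a query by successive homolog search
#'
#' Walks the query's ranked homolog list and returns the GO multiset of the
#' best-ranked homolog that has at least one term in the annotation
#' database, examining at most `max_homologs` entries. Homologs without
#' annotations are skipped, not merged: this successive-search strategy is
#' what prevents null GO vectors when the top homolog is unannotated. With
#' `merge_top_k > 1` the counts of the first `merge_top_k` annotated
#' homologs are summed instead (an explicitly alternative dialect).
#'
#' @param query query protein id (must be present in `homologs`).
#' @param homologs a `"homolog_map"`.
#' @param db an `"annotation_db"`.
#' @param max_homologs maximum number of ranked homologs to examine.
#' @param exclude_self drop a homolog whose accession equals the query id
#'   (on by default; avoids label leakage during cross-validation).
#' @param merge_top_k number of annotated homologs whose term counts are
#'   merged (default 1: first annotated homolog only).
#' @return named integer vector: GO term multiset with occurrence counts.
#'   Raises a condition of class `"sparseloc_null_go_terms"` when no
#'   examined homolog has any annotation.
#' @export
retrieve_go_terms <- function(query, homologs, db, max_homologs = 5L,
                              exclude_self = TRUE, merge_top_k = 1L) {
  hs <- homologs[[query]]
  if (is.null(hs) || length(hs) == 0L) stop(null_go_terms_error(query))
  if (exclude_self) hs <- hs[hs != query]
  hs <- utils::head(hs, max_homologs)
  found <- list()
  for (h in hs) {
    terms <- db[[h]]
    if (!is.null(terms) && length(terms)) {
      found[[length(found) + 1L]] <- terms
      if (length(found) >= merge_top_k) break
    }
  }
  if (length(found) == 0L) stop(null_go_terms_error(query))
  merge_multisets(found)
}

# sum named count vectors
merge_multisets <- function(multisets) {
  all_terms <- sort(unique(unlist(lapply(multisets, names))))
  out <- integer(length(all_terms))
  names(out) <- all_terms
  for (m in multisets) out[names(m)] <- out[names(m)] + as.integer(m)
  out
}

# ---- vocabulary and vectors ------------------------------------------------

#' Build the GO vocabulary of a training set
#'
#' The vocabulary is the sorted distinct union of all GO terms occurring in
#' the training multisets (lexicographic id order, so feature positions are
#' reproducible across runs). Its size `T` is the dimension of every GO
#' term-frequency vector built from it.
#'
#' @param multisets list of named integer vectors (GO multisets).
#' @return class `"go_vocabulary"`: list with `terms` (ordered character
#'   vector) and `index` (named integer lookup, term to position).
#' @export
build_vocabulary <- function(multisets) {
  if (length(multisets) == 0L) stop("cannot build a vocabulary from no multisets")
  terms <- sort(unique(unlist(lapply(multisets, names))))
  if (length(terms) == 0L) stop("training multisets contain no GO terms")
  index <- seq_along(terms)
  names(index) <- terms
  structure(list(terms = terms, index = index), class = "go_vocabulary")
}

#' @export
print.go_vocabulary <- function(x, ...) {
  cat(sprintf("GO vocabulary: T = %d terms (%s ... %s)\n",
              length(x$terms), x$terms[1L], x$terms[length(x$terms)]))
  invisible(x)
}

#' Build a GO term-frequency vector
#'
#' Entry `j` of the vector is the number of occurrences of the vocabulary's
#' `j`-th GO term in the query multiset. Terms absent from the vocabulary
#' are dropped (not an error) and reported in the `dropped` attribute.
#'
#' @param multiset named integer vector of term counts.
#' @param vocab a `"go_vocabulary"`.
#' @return integer vector of length `T` named by the vocabulary terms, with
#'   attribute `dropped` listing out-of-vocabulary terms.
#' @export
build_go_vector <- function(multiset, vocab) {
  stopifnot(inherits(vocab, "go_vocabulary"))
  counts <- integer(length(vocab$terms))
  names(counts) <- vocab$terms
  hit <- names(multiset) %in% vocab$terms
  counts[names(multiset)[hit]] <- as.integer(multiset[hit])
  attr(counts, "dropped") <- names(multiset)[!hit]
  counts
}

#' Stack GO vectors of several proteins into a design matrix
#'
#' @param multisets named list of GO multisets (one per protein).
#' @param vocab a `"go_vocabulary"`.
#' @return N x T integer matrix (rows named by protein, columns by GO id)
#'   with attribute `dropped`: per-protein out-of-vocabulary terms.
#' @export
build_go_matrix <- function(multisets, vocab) {
  vecs <- lapply(multisets, build_go_vector, vocab = vocab)
  x <- do.call(rbind, lapply(vecs, as.vector))
  colnames(x) <- vocab$terms
  rownames(x) <- names(multisets)
  attr(x, "dropped") <- lapply(vecs, attr, "dropped")
  x
}

# ---- labels ----------------------------------------------------------------

#' Read a protein label file
#'
#' One row per protein: `id<TAB>labels`, where `labels` is a comma-separated
#' list of integer location labels in `1..M` (e.g. `P12345	2,11`). Every
#' protein must carry at least one label.
#'
#' @param file path or character vector of lines.
#' @param M optional number of locations for validation.
#' @return named list of sorted integer label sets.
#' @export
read_label_sets <- function(file, M = NULL) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("label file is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop(sprintf("label file parse error at line %d", bad[1L]))
  ids <- vapply(parts, `[[`, "", 1L)
  labs <- lapply(strsplit(vapply(parts, `[[`, "", 2L), ",", fixed = TRUE),
                 function(v) sort(unique(as.integer(v))))
  if (any(vapply(labs, function(v) length(v) == 0L || anyNA(v) || any(v < 1L),
                 TRUE))) {
    stop("every protein needs at least one positive integer label")
  }
  if (!is.null(M) && any(unlist(labs) > M)) stop("label exceeds M")
  names(labs) <- ids
  labs
}

#' Sequence ids of a FASTA file
#'
#' Convenience reader returning only the record identifiers (first token of
#' each header), for checking that sequence files and label files agree.
#'
#' @param file path to a FASTA file.
#' @return character vector of ids.
#' @export
read_fasta_ids <- function(file) {
  lines <- readLines(file)
  headers <- lines[startsWith(lines, ">")]
  if (length(headers) == 0L) stop("no FASTA records found")
  vapply(strsplit(sub("^>", "", headers), "\\s+"), `[[`, "", 1L)
}
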