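# JSON serialization of fitted models and evaluation reports.

#' Write / read a fitted model as JSON
#'
#' The container records everything needed to score new proteins: mode,
#' vocabulary, essential term ids and indices, per-location refit weights
#' and intercepts, both stages' penalties, and the training dimensions.
#' `read_sparseloc` restores a `"sparseloc"` object whose predictions are
#' identical to the original's (selection-stage fits are not round-tripped;
#' only their supports are).
#'
#' @param model a `"sparseloc"` fit.
#' @param path file path for the JSON document.
#' @return `write_sparseloc` returns `path` invisibly; `read_sparseloc`
#'   returns a `"sparseloc"` object.
#' @export
write_sparseloc <- function(model, path) {
  doc <- list(
    format = "sparseloc-model",
    version = 1L,
    mode = model$mode,
    M = model$M, N = model$N, T = model$T,
    vocabulary = model$vocabulary$terms,
    essential_indices = model$essential$indices,
    essential_terms = model$essential$terms,
    per_class_support = model$essential$per_class,
    weights = model$weights,          # S x M, original count scale
    intercepts = model$intercepts,
    penalties = model$penalties,
    standardize = model$standardize,
    intercept = model$intercept)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_sparseloc
#' @export
read_sparseloc <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "sparseloc-model")) {
    stop("not a sparseloc model file")
  }
  vocab <- NULL
  if (length(doc$vocabulary)) {
    vocab <- structure(list(terms = doc$vocabulary,
                            index = stats::setNames(seq_along(doc$vocabulary),
                                                    doc$vocabulary)),
                       class = "go_vocabulary")
  }
  essential <- structure(list(indices = as.integer(doc$essential_indices),
                              terms = doc$essential_terms,
                              S = length(doc$essential_indices),
                              per_class = lapply(doc$per_class_support,
                                                 as.integer)),
                         class = "essential_terms")
  w <- matrix(as.numeric(doc$weights), nrow = essential$S, ncol = doc$M,
              byrow = FALSE)
  rownames(w) <- essential$terms
  structure(list(mode = doc$mode, M = doc$M, N = doc$N, T = doc$T,
                 vocabulary = vocab, essential = essential,
                 weights = w, intercepts = as.numeric(doc$intercepts),
                 selection = NULL, refit = NULL,
                 penalties = doc$penalties,
                 standardize = doc$standardize, intercept = doc$intercept,
                 call = NULL),
            class = "sparseloc")
}

#' Export an evaluation report as JSON
#'
#' @param report a `"sparseloc_eval"` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(report, path) {
  doc <- report[c("oaa", "ola", "accuracy", "precision", "recall", "f1",
                  "micro_f1", "macro_f1", "hamming_loss", "n_actual",
                  "n_locative", "M")]
  doc$per_location <- report$per_location
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}
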