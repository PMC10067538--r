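## Cosine-similarity ranking of decision-matrix rows against a
## scenario-derived input vector. Both vectors live in {+1,-1}^d, so
## scores always fall in [-1, 1] and a row that supports exactly the
## active factors scores 1.

#' Build a component input vector
#'
#' Encodes a set of active factors against a matrix's column order:
#' `+1` for active columns, `-1` for all others (the inactive coding
#' keeps every vector in `{+1,-1}^d`, preserving the `[-1, 1]` score
#' range).
#'
#' @param active_factors Character vector of factor labels (subset of the
#'   matrix's columns).
#' @param matrix A [decision_matrix()].
#' @return Object of class `gvr_input_vector`: integer values aligned to
#'   the matrix columns.
#' @export
#' @examples
#' kb <- load_knowledge_base()
#' build_input_vector(c("point", "contiguous", "quantitative", "task_compare"),
#'                    get_matrix(kb, "c1_encoding"))
build_input_vector <- function(active_factors, matrix) {
  active_factors <- unique(as.character(active_factors))
  unknown <- setdiff(active_factors, matrix$columns)
  if (length(unknown) > 0) {
    stop("factor(s) not among matrix columns: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  values <- ifelse(matrix$columns %in% active_factors, 1L, -1L)
  structure(list(component = matrix$component,
                 columns = matrix$columns,
                 values = values),
            class = "gvr_input_vector")
}

#' Cosine similarity of two vectors
#'
#' @param u,v Numeric vectors of equal length (neither all-zero).
#' @return `sum(u*v) / (||u|| * ||v||)`, in `[-1, 1]` for `{+1,-1}`
#'   vectors.
#' @export
#' @examples
#' cosine_similarity(c(1, 1, -1, -1), c(1, -1, -1, -1)) # 0.5
cosine_similarity <- function(u, v) {
  if (inherits(u, "gvr_input_vector")) u <- u$values
  if (inherits(v, "gvr_input_vector")) v <- v$values
  if (length(u) != length(v)) {
    stop("cosine similarity expects two vectors of equal size (",
         length(u), " vs ", length(v), ")", call. = FALSE)
  }
  s <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  max(-1, min(1, s))  # clamp floating-point spillover
}

#' Rank a matrix's output options against an input vector
#'
#' Scores every row by cosine similarity with the input vector and sorts
#' descending; ties keep matrix row order (stable), so the output is
#' deterministic.
#'
#' @param matrix A decision matrix.
#' @param input A [build_input_vector()] result (or bare `{+1,-1}` vector
#'   aligned to the matrix columns).
#' @param rows Optional subset of row labels to rank (used when hard
#'   constraints have pruned options); defaults to all rows.
#' @return A data frame with columns `option` and `score`, one row per
#'   ranked option.
#' @export
rank_options <- function(matrix, input, rows = NULL) {
  values <- if (inherits(input, "gvr_input_vector")) input$values else input
  if (length(values) != length(matrix$columns)) {
    stop("input vector length ", length(values),
         " does not match matrix column count ", length(matrix$columns),
         call. = FALSE)
  }
  keep <- if (is.null(rows)) matrix$rows else intersect(matrix$rows, rows)
  scores <- vapply(keep, function(r) cosine_similarity(matrix$cells[r, ], values),
                   numeric(1))
  ord <- order(-scores)  # stable: ties keep matrix row order
  data.frame(option = keep[ord], score = unname(scores[ord]),
             stringsAsFactors = FALSE)
}

#' Top-scoring options within a tolerance band
#'
#' Returns every option whose score is within `tolerance` of the maximum,
#' preserving ranking order. The default tolerance is a floating-point
#' equality guard: exact ties propagate as design variations, anything
#' genuinely lower is dropped.
#'
#' @param ranking Data frame from [rank_options()].
#' @param tolerance Non-negative score slack.
#' @return Character vector of option labels.
#' @export
top_set <- function(ranking, tolerance = 1e-9) {
  if (is.null(ranking) || nrow(ranking) == 0) {
    stop("top_set: empty ranking", call. = FALSE)
  }
  stopifnot(tolerance >= 0)
  ranking$option[ranking$score >= max(ranking$score) - tolerance]
}
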