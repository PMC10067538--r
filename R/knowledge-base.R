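## The recommendation knowledge: one decision matrix per component.
## Rows are output options, columns are input factors, cells are +1
## ("this option supports this factor") or -1. The matrices ship as
## editable delimiter-separated assets so the encoded domain knowledge
## can be revised without touching code.

#' Component identifiers
#'
#' The six sequential recommendation components, in execution order.
#'
#' @return Character vector of component ids.
#' @export
gvr_components <- function() {
  c("c1_encoding", "c2_alignment", "c3_layout",
    "c4_partition", "c5_arrangement", "c6_interactivity")
}

#' Construct a decision matrix
#'
#' @param component One of [gvr_components()].
#' @param columns Ordered factor labels.
#' @param rows Ordered output-option labels.
#' @param cells Integer matrix (`length(rows)` x `length(columns)`) with
#'   every cell in `{+1, -1}`.
#' @return Object of class `gvr_decision_matrix`.
#' @export
decision_matrix <- function(component, columns, rows, cells) {
  component <- match.arg(component, gvr_components())
  cells <- as.matrix(cells)
  m <- structure(list(component = component,
                      columns = as.character(columns),
                      rows = as.character(rows),
                      cells = cells),
                 class = "gvr_decision_matrix")
  viol <- .validate_matrix(m)
  if (length(viol) > 0) {
    stop("invalid decision matrix '", component, "':\n  - ",
         paste(viol, collapse = "\n  - "), call. = FALSE)
  }
  dimnames(m$cells) <- list(m$rows, m$columns)
  storage.mode(m$cells) <- "integer"
  m
}

.validate_matrix <- function(m) {
  viol <- character(0)
  if (anyDuplicated(m$rows)) viol <- c(viol, "duplicate row labels")
  if (anyDuplicated(m$columns)) viol <- c(viol, "duplicate column labels")
  if (!all(dim(m$cells) == c(length(m$rows), length(m$columns)))) {
    viol <- c(viol, sprintf("cell table is %d x %d but %d rows and %d columns are declared",
                            nrow(m$cells), ncol(m$cells),
                            length(m$rows), length(m$columns)))
  }
  bad <- which(!(m$cells %in% c(1L, -1L)), arr.ind = FALSE)
  if (length(bad) > 0) {
    idx <- arrayInd(bad, dim(m$cells))
    viol <- c(viol, sprintf("cell (%s, %s) = %s is outside {+1, -1}",
                            m$rows[idx[, 1]], m$columns[idx[, 2]],
                            m$cells[bad]))
  }
  viol
}

#' Load a knowledge base
#'
#' Without arguments, loads the packaged default knowledge base (six
#' decision matrices). With `source`, loads user-supplied matrix assets:
#' a directory containing a `manifest.json` mapping each component id to
#' a tab-separated table (first row = factor labels, first column =
#' option labels, cells `1`/`-1`).
#'
#' @param source Optional path to a matrix asset directory.
#' @return Object of class `gvr_knowledge_base` holding all six matrices.
#' @export
#' @examples
#' kb <- load_knowledge_base()
#' names(kb$matrices)
load_knowledge_base <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "kb", package = "genovizrec")
  }
  manifest_path <- file.path(source, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("knowledge-base manifest not found at ", manifest_path, call. = FALSE)
  }
  manifest <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE)
  missing <- setdiff(gvr_components(), names(manifest))
  if (length(missing) > 0) {
    stop("knowledge base is incomplete: missing matrix for ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  matrices <- lapply(gvr_components(), function(comp) {
    path <- file.path(source, manifest[[comp]])
    if (!file.exists(path)) {
      stop("matrix asset not found: ", path, call. = FALSE)
    }
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) {
      stop("malformed matrix asset ", path, ": needs an option column and at least one factor column",
           call. = FALSE)
    }
    cells <- as.matrix(tab[, -1, drop = FALSE])
    suppressWarnings(storage.mode(cells) <- "integer")
    if (anyNA(cells)) {
      stop("malformed matrix asset ", path, ": non-integer cells", call. = FALSE)
    }
    decision_matrix(comp, columns = colnames(tab)[-1],
                    rows = tab[[1]], cells = cells)
  })
  names(matrices) <- gvr_components()
  structure(list(matrices = matrices, source = source),
            class = "gvr_knowledge_base")
}

#' Write a knowledge base to matrix assets
#'
#' Inverse of [load_knowledge_base()]; `load(save(kb))` reproduces every
#' matrix.
#'
#' @param kb A knowledge base.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_knowledge_base <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- stats::setNames(
    as.list(paste0(gvr_components(), ".tsv")), gvr_components())
  for (comp in gvr_components()) {
    m <- kb$matrices[[comp]]
    tab <- data.frame(option = m$rows, m$cells, check.names = FALSE)
    utils::write.table(tab, file.path(dir, manifest[[comp]]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Fetch one component's decision matrix
#'
#' @param kb A knowledge base.
#' @param component One of [gvr_components()].
#' @return The `gvr_decision_matrix`.
#' @export
get_matrix <- function(kb, component) {
  component <- match.arg(component, gvr_components())
  kb$matrices[[component]]
}

#' Read one cell of a decision matrix
#'
#' @param m A decision matrix.
#' @param row_label Output-option label.
#' @param column_label Factor label.
#' @return `+1L` or `-1L`.
#' @export
matrix_cell <- function(m, row_label, column_label) {
  if (!row_label %in% m$rows) {
    stop("unknown option '", row_label, "' in matrix ", m$component, call. = FALSE)
  }
  if (!column_label %in% m$columns) {
    stop("unknown factor '", column_label, "' in matrix ", m$component, call. = FALSE)
  }
  m$cells[row_label, column_label]
}

#' @export
print.gvr_decision_matrix <- function(x, ...) {
  cat("<decision matrix>", x$component, ":",
      length(x$rows), "options x", length(x$columns), "factors\n")
  print(x$cells)
  invisible(x)
}

#' @export
print.gvr_knowledge_base <- function(x, ...) {
  cat("<knowledge base> components:\n")
  for (m in x$matrices) {
    cat(sprintf("  %-18s %d options x %d factors\n",
                m$component, length(m$rows), length(m$columns)))
  }
  invisible(x)
}
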