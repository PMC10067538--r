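## Scenario construction, parsing, validation, serialization.
## A scenario is the unit of input: one or more abstract file descriptors
## plus an optional analysis task. File order is significant throughout
## (it fixes the stacking order of tracks).

#' Describe one data attribute
#'
#' @param kind One of quantitative, categorical, text.
#' @param label Short identifier; defaults to the kind.
#' @return A named list of class `gvr_attribute`.
#' @export
#' @examples
#' attribute_descriptor("categorical", "gene_class")
attribute_descriptor <- function(kind, label = kind) {
  kind <- match.arg(tolower(kind), .gvr_attribute_kinds)
  structure(list(kind = kind, label = as.character(label)),
            class = "gvr_attribute")
}

#' Describe one genomics file abstractly
#'
#' Builds the abstract descriptor of a data source: its format, genome
#' assembly, attribute payload, feature extent/density and connectivity.
#' Fields left `NULL` are filled from [defaults_for_format()].
#'
#' @param format One of [gvr_formats()].
#' @param label Unique file label (e.g. `"BED1"`); defaults to the
#'   upper-cased format.
#' @param assembly Genome build the coordinates refer to.
#' @param secondary_assembly Second genome build; required when
#'   `connection = "inter"`.
#' @param attributes List of [attribute_descriptor()] objects; when `NULL`
#'   a single format-typical attribute is assumed.
#' @param extent `"point"` or `"segment"`; `NULL` = format default.
#' @param density `"sparse"` or `"contiguous"`; `NULL` = format default.
#' @param connection `"none"`, `"intra"` or `"inter"`; `NULL` = format
#'   default.
#' @param connection_density `"none"`, `"sparse"` or `"dense"`; `NULL` =
#'   format default (forced to `"none"` when `connection = "none"`).
#' @return A named list of class `gvr_file`.
#' @export
#' @examples
#' genomic_file("bigwig", "BIGWIG1")
genomic_file <- function(format, label = toupper(format), assembly = "hg38",
                         secondary_assembly = NULL, attributes = NULL,
                         extent = NULL, density = NULL, connection = NULL,
                         connection_density = NULL) {
  fmt <- tolower(as.character(format)[1])
  if (!fmt %in% gvr_formats()) {
    stop("unsupported file format: '", format, "'", call. = FALSE)
  }
  def <- defaults_for_format(fmt)
  if (is.null(extent)) extent <- def$extent
  if (is.null(density)) density <- def$density
  if (is.null(connection)) connection <- def$connection
  if (is.null(connection_density)) {
    connection_density <- if (identical(connection, def$connection)) {
      def$connection_density
    } else if (connection == "none") "none" else "sparse"
  }
  if (connection == "none") connection_density <- "none"
  if (is.null(attributes)) {
    attributes <- list(attribute_descriptor(.gvr_format_default_kind[[fmt]],
                                            paste0(label, "_value")))
  }
  if (inherits(attributes, "gvr_attribute")) attributes <- list(attributes)
  structure(list(
    format = fmt,
    label = as.character(label),
    assembly = as.character(assembly),
    secondary_assembly = if (is.null(secondary_assembly)) NULL else as.character(secondary_assembly),
    attributes = attributes,
    extent = tolower(extent),
    density = tolower(density),
    connection = tolower(connection),
    connection_density = tolower(connection_density)
  ), class = "gvr_file")
}

#' Assemble a scenario from file descriptors and a task
#'
#' @param files A `gvr_file` or list of them; order is preserved and
#'   determines track stacking order.
#' @param task One of [gvr_tasks()] or `NULL`. An unset task defaults to
#'   `"overview"`: recommendations are already meaningful before any task
#'   is chosen, and the pre-task behaviour matches the overview rules.
#' @return A named list of class `gvr_scenario`.
#' @export
#' @examples
#' scenario(list(genomic_file("bed"), genomic_file("vcf")), task = "compare")
scenario <- function(files, task = NULL) {
  if (inherits(files, "gvr_file")) files <- list(files)
  sc <- structure(list(
    files = files,
    task = if (is.null(task)) "overview" else match.arg(tolower(task), gvr_tasks()),
    task_explicit = !is.null(task)
  ), class = "gvr_scenario")
  viol <- validate_scenario(sc)
  if (length(viol) > 0) {
    stop("invalid scenario:\n  - ", paste(viol, collapse = "\n  - "),
         call. = FALSE)
  }
  sc
}

#' Validate a scenario against the type invariants
#'
#' Checks every invariant of the description space and returns violations
#' instead of raising, one entry per breach.
#'
#' @param sc An object as produced by [scenario()] (or a structurally
#'   similar list).
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate_scenario <- function(sc) {
  viol <- character(0)
  if (!is.list(sc) || is.null(sc$files) || length(sc$files) == 0) {
    return("scenario must contain at least one file descriptor")
  }
  labels <- vapply(sc$files, function(f) f$label %||% NA_character_, character(1))
  if (anyDuplicated(labels)) {
    viol <- c(viol, paste0("duplicate file labels: ",
                           paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  if (!is.null(sc$task) && !sc$task %in% gvr_tasks()) {
    viol <- c(viol, paste0("unknown task '", sc$task, "'"))
  }
  for (f in sc$files) {
    lab <- f$label %||% "<unlabelled>"
    if (!f$format %in% gvr_formats()) {
      viol <- c(viol, paste0(lab, ": unknown format '", f$format, "'"))
    }
    if (length(f$attributes) == 0) {
      viol <- c(viol, paste0(lab, ": attribute list is empty"))
    }
    for (a in f$attributes) {
      if (!a$kind %in% .gvr_attribute_kinds) {
        viol <- c(viol, paste0(lab, ": unknown attribute kind '", a$kind, "'"))
      }
    }
    if (!f$extent %in% .gvr_extents) {
      viol <- c(viol, paste0(lab, ": unknown extent '", f$extent, "'"))
    }
    if (!f$density %in% .gvr_densities) {
      viol <- c(viol, paste0(lab, ": unknown density '", f$density, "'"))
    }
    if (!f$connection %in% .gvr_connections) {
      viol <- c(viol, paste0(lab, ": unknown connection '", f$connection, "'"))
    }
    if (!f$connection_density %in% .gvr_conn_densities) {
      viol <- c(viol, paste0(lab, ": unknown connection density '",
                             f$connection_density, "'"))
    }
    if (f$connection == "inter" && is.null(f$secondary_assembly)) {
      viol <- c(viol, paste0(lab, ": inter-genome connection requires a secondary assembly"))
    }
    if (xor(f$connection == "none", f$connection_density == "none")) {
      viol <- c(viol, paste0(lab, ": connection '", f$connection,
                             "' inconsistent with connection density '",
                             f$connection_density, "'"))
    }
  }
  viol
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Parse a scenario document
#'
#' Reads the JSON scenario dialect: top-level keys `files` (array of
#' objects with `format`, `label`, `assembly`, `secondaryAssembly`,
#' `attributes`, `extent`, `density`, `connection`, `connectionDensity`)
#' and `task`; all enumeration values lower-case strings. Unset
#' extent/density/connection fields are filled from the format defaults.
#'
#' @param document Path to a JSON file, or a JSON string.
#' @return A validated [scenario()].
#' @export
parse_scenario <- function(document) {
  doc <- tryCatch(
    jsonlite::fromJSON(document, simplifyVector = FALSE),
    error = function(e) stop("scenario parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(doc$files) || length(doc$files) == 0) {
    stop("invalid scenario: scenario must contain at least one file descriptor",
         call. = FALSE)
  }
  files <- lapply(seq_along(doc$files), function(i) {
    fd <- doc$files[[i]]
    if (is.null(fd$format)) {
      stop("scenario parse error: file ", i, " is missing required field 'format'",
           call. = FALSE)
    }
    attrs <- NULL
    if (!is.null(fd$attributes)) {
      attrs <- lapply(seq_along(fd$attributes), function(j) {
        a <- fd$attributes[[j]]
        if (is.null(a$kind)) {
          stop("scenario parse error: file ", i, " attribute ", j,
               " is missing required field 'kind'", call. = FALSE)
        }
        attribute_descriptor(a$kind, a$label %||% paste0("attr", j))
      })
    }
    genomic_file(
      format = fd$format,
      label = fd$label %||% toupper(fd$format),
      assembly = fd$assembly %||% "hg38",
      secondary_assembly = fd$secondaryAssembly,
      attributes = attrs,
      extent = fd$extent,
      density = fd$density,
      connection = fd$connection,
      connection_density = fd$connectionDensity
    )
  })
  scenario(files, task = doc$task)
}

#' Serialize a scenario to the JSON dialect
#'
#' Inverse of [parse_scenario()]: `parse_scenario(serialize_scenario(sc))`
#' reproduces `sc`.
#'
#' @param sc A [scenario()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
serialize_scenario <- function(sc, path = NULL) {
  doc <- list(
    files = lapply(sc$files, function(f) {
      fd <- list(
        format = f$format, label = f$label, assembly = f$assembly,
        attributes = lapply(f$attributes, function(a) list(kind = a$kind, label = a$label)),
        extent = f$extent, density = f$density,
        connection = f$connection, connectionDensity = f$connection_density
      )
      if (!is.null(f$secondary_assembly)) fd$secondaryAssembly <- f$secondary_assembly
      fd
    })
  )
  if (isTRUE(sc$task_explicit)) doc$task <- sc$task
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.gvr_scenario <- function(x, ...) {
  cat("<scenario> task:", x$task,
      if (!isTRUE(x$task_explicit)) "(default)" else "", "\n")
  for (f in x$files) {
    cat(sprintf("  %-8s %-7s %s  [%s/%s, connection %s%s]  %s\n",
                f$label, toupper(f$format), f$assembly, f$extent, f$density,
                f$connection,
                if (f$connection != "none") paste0("/", f$connection_density) else "",
                paste(vapply(f$attributes, function(a) a$kind, character(1)),
                      collapse = "+")))
  }
  invisible(x)
}
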