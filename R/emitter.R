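## Serialization of candidates into the Gosling-grammar-subset JSON
## dialect (schema asset: extdata/gosling-subset-schema.json). Only the
## constructs the model can recommend are emitted; data blocks are
## placeholder references since descriptors, not payloads, drive the
## recommendation.

.gvr_palette <- function() {
  path <- system.file("extdata", "palette_okabe_ito.txt", package = "genovizrec")
  lines <- readLines(path)
  lines[grepl("^#[0-9A-Fa-f]{6}$", lines)]
}

## single-hue ramp for quantitative color (saturation channel)
.gvr_saturation_ramp <- c("#DEEBF7", "#08519C")

#' Colorblind-safe categorical palette for an attribute
#'
#' Returns the first `category_count` colors of the packaged 8-color
#' Okabe-Ito palette. The palette depends only on position, so the same
#' attribute always receives the same colors across tracks and
#' candidates; counts beyond the palette size cycle with a warning.
#'
#' @param attribute An [attribute_descriptor()] of kind categorical.
#' @param category_count Number of categories (>= 1).
#' @return Character vector of hex colors.
#' @export
#' @examples
#' assign_palette(attribute_descriptor("categorical", "gene_class"), 3)
assign_palette <- function(attribute, category_count) {
  if (!identical(attribute$kind, "categorical")) {
    stop("assign_palette: attribute '", attribute$label,
         "' is ", attribute$kind, ", not categorical", call. = FALSE)
  }
  stopifnot(category_count >= 1)
  pal <- .gvr_palette()
  if (category_count > length(pal)) {
    warning("category count ", category_count, " exceeds palette size ",
            length(pal), "; colors will cycle", call. = FALSE)
  }
  pal[((seq_len(category_count) - 1) %% length(pal)) + 1]
}

.track_json <- function(e, file, prefix) {
  mark <- switch(e$option,
    rect_bar = "bar",
    line_position = "line",
    point_position = "point",
    rect_interval_saturation = "rect",
    rect_interval_hue = "rect",
    point_hue = "point",
    text_position = "text",
    line_connection = if (identical(file$connection, "inter")) "betweenLink" else "withinLink"
  )
  tr <- list(
    id = paste0(prefix, e$file, ".", e$attribute),
    file = e$file,
    attribute = e$attribute,
    mark = mark,
    data = list(format = file$format,
                url = paste0("placeholder://", e$file, ".", file$format)),
    x = list(field = "position", type = "genomic")
  )
  span <- e$interval || identical(file$extent, "segment")
  if (span) tr$xe <- list(field = "position_end", type = "genomic")
  if (e$is_link) return(tr)
  if (e$channel %in% c("position", "length") && e$kind == "quantitative") {
    tr$y <- list(field = e$attribute, type = "quantitative")
  }
  if (e$channel == "hue") {
    tr$color <- list(field = e$attribute, type = "nominal",
                     range = as.list(assign_palette(
                       attribute_descriptor("categorical", e$attribute), 8)))
  }
  if (e$channel == "saturation") {
    tr$color <- list(field = e$attribute, type = "quantitative",
                     range = as.list(.gvr_saturation_ramp))
  }
  if (e$mark == "text") {
    tr$text <- list(field = e$attribute, type = "nominal")
  }
  tr
}

#' Serialize a candidate as a Gosling-subset JSON document
#'
#' Emits one view per window with the candidate's tracks stacked in file
#' order; overlay pairs are merged into a single track carrying the
#' color encoding under `overlay`; compare and focus+context designs
#' attach a genome-wide overview/brush navigation object to each view.
#' Emission is deterministic and refuses candidates violating the hard
#' design invariants.
#'
#' @param cand A `gvr_candidate`.
#' @param sc The scenario the candidate was derived from.
#' @return Object of class `gvr_gosling` with fields `text` (JSON) and
#'   `candidate_ref`.
#' @export
emit_spec <- function(cand, sc) {
  viol <- validate_candidate(cand)
  if (length(viol) > 0) {
    stop("emission refused, candidate violates design invariants:\n  - ",
         paste(viol, collapse = "\n  - "), call. = FALSE)
  }
  files <- stats::setNames(sc$files,
                           vapply(sc$files, function(f) f$label, character(1)))
  needs_nav <- "focus_context" %in% cand$interactivity || sc$task == "compare"

  build_tracks <- function(prefix) {
    enc <- cand$encodings
    merged <- rep(FALSE, length(enc))
    tracks <- list()
    for (i in seq_along(enc)) {
      if (merged[i]) next
      e <- enc[[i]]
      tr <- .track_json(e, files[[e$file]], prefix)
      if (cand$alignment == "overlayed") {
        for (p in cand$overlay_pairs) {
          if (p[["position"]] == i) {
            j <- p[["color"]]
            merged[j] <- TRUE
            ov <- .track_json(enc[[j]], files[[enc[[j]]$file]], prefix)
            tr$overlay <- list(ov)
          }
        }
      }
      tracks[[length(tracks) + 1]] <- tr
    }
    tracks
  }

  views <- lapply(seq_len(cand$view_count), function(v) {
    vid <- paste0("view", v)
    vw <- list(id = vid, layout = cand$layout, partition = cand$partition,
               tracks = build_tracks(paste0(vid, ".")))
    if (needs_nav) {
      vw$navigation <- list(type = "overview-brush", linkedView = vid,
                            genomeWide = TRUE)
    }
    vw
  })

  doc <- list(
    subsetVersion = "1.0",
    candidate = cand$id,
    assembly = sc$files[[1]]$assembly,
    arrangement = cand$arrangement,
    interactivity = as.list(cand$interactivity),
    views = views
  )
  structure(list(
    text = as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)),
    candidate_ref = cand$id
  ), class = "gvr_gosling")
}

#' Validate a document against the packaged Gosling-subset schema
#'
#' Structural validator for the subset dialect: required keys,
#' enumeration domains, view/track shapes. Returns violations rather
#' than raising.
#'
#' @param doc A `gvr_gosling`, a JSON string, or a parsed list.
#' @return Character vector of violations (empty when valid).
#' @export
validate_gosling_document <- function(doc) {
  if (inherits(doc, "gvr_gosling")) doc <- doc$text
  if (is.character(doc)) {
    doc <- tryCatch(jsonlite::fromJSON(doc, simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(doc)) return("document does not parse as JSON")
  }
  viol <- character(0)
  need <- c("subsetVersion", "candidate", "assembly", "arrangement",
            "interactivity", "views")
  miss <- setdiff(need, names(doc))
  if (length(miss) > 0) {
    return(paste0("missing top-level key(s): ", paste(miss, collapse = ", ")))
  }
  if (!identical(doc$subsetVersion, "1.0")) {
    viol <- c(viol, "unsupported subsetVersion")
  }
  if (!doc$arrangement %in% c("single", "parallel", "adjacent", "orthogonal")) {
    viol <- c(viol, paste0("unknown arrangement '", doc$arrangement, "'"))
  }
  for (ia in doc$interactivity) {
    if (!ia %in% c("focus_context", "coordinated")) {
      viol <- c(viol, paste0("unknown interactivity '", ia, "'"))
    }
  }
  if (length(doc$views) < 1) viol <- c(viol, "document has no views")
  marks <- c("bar", "line", "point", "rect", "text", "withinLink", "betweenLink")
  for (vw in doc$views) {
    vmiss <- setdiff(c("id", "layout", "partition", "tracks"), names(vw))
    if (length(vmiss) > 0) {
      viol <- c(viol, paste0("view missing key(s): ", paste(vmiss, collapse = ", ")))
      next
    }
    if (!vw$layout %in% c("linear", "circular", "space_filling")) {
      viol <- c(viol, paste0("unknown layout '", vw$layout, "'"))
    }
    if (!vw$partition %in% c("contiguous", "segregated")) {
      viol <- c(viol, paste0("unknown partition '", vw$partition, "'"))
    }
    if (length(vw$tracks) < 1) viol <- c(viol, paste0(vw$id, ": no tracks"))
    for (tr in vw$tracks) {
      tmiss <- setdiff(c("id", "file", "mark", "data", "x"), names(tr))
      if (length(tmiss) > 0) {
        viol <- c(viol, paste0("track missing key(s): ",
                               paste(tmiss, collapse = ", ")))
        next
      }
      if (!tr$mark %in% marks) {
        viol <- c(viol, paste0(tr$id, ": unknown mark '", tr$mark, "'"))
      }
      if (is.null(tr$data$format) || !tr$data$format %in% gvr_formats() ||
          is.null(tr$data$url)) {
        viol <- c(viol, paste0(tr$id, ": malformed data block"))
      }
      if (!identical(tr$x$type, "genomic")) {
        viol <- c(viol, paste0(tr$id, ": x channel must be genomic"))
      }
    }
    if (!is.null(vw$navigation) &&
        !identical(vw$navigation$type, "overview-brush")) {
      viol <- c(viol, paste0(vw$id, ": unknown navigation type"))
    }
  }
  viol
}

#' Parse an emitted document back into its structural fields
#'
#' Convenience accessor used by the round-trip checks: view count,
#' per-view track counts, layouts, marks.
#'
#' @param doc A `gvr_gosling` or JSON string.
#' @return List with `view_count`, `tracks_per_view`, `layout`,
#'   `arrangement`, `interactivity`, `marks`.
#' @export
parse_gosling_document <- function(doc) {
  if (inherits(doc, "gvr_gosling")) doc <- doc$text
  d <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  list(
    view_count = length(d$views),
    tracks_per_view = vapply(d$views, function(v) length(v$tracks), integer(1)),
    layout = unique(vapply(d$views, function(v) v$layout, character(1))),
    arrangement = d$arrangement,
    interactivity = unlist(d$interactivity),
    marks = lapply(d$views, function(v)
      vapply(v$tracks, function(t) t$mark, character(1)))
  )
}

#' @export
print.gvr_gosling <- function(x, ...) {
  info <- parse_gosling_document(x)
  cat("<gosling-subset document>", x$candidate_ref, "\n")
  cat("  views:", info$view_count, "| layout:", info$layout,
      "| arrangement:", info$arrangement, "\n")
  invisible(x)
}
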