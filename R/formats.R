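#' @keywords internal
"_PACKAGE"

## Enumerations of the abstract data/task description space.

#' Supported genomics file formats
#'
#' The six standard file formats the recommender accepts as abstract data
#' descriptors. No payloads are ever read; only the descriptor matters.
#'
#' @return Character vector of the six format identifiers.
#' @export
#' @examples
#' gvr_formats()
gvr_formats <- function() {
  c("bigwig", "bed", "bedpe", "seg", "vcf", "cooler")
}

#' Supported analysis tasks
#'
#' @return Character vector: identify, compare, overview.
#' @export
gvr_tasks <- function() {
  c("identify", "compare", "overview")
}

#' Visual marks and channels of the encoding space
#'
#' Four marks (point, line, rect, text) and four channels (position,
#' length, saturation, hue) span the encoding component's output space.
#'
#' @return A list with elements `marks` and `channels`.
#' @export
gvr_encoding_space <- function() {
  list(
    marks    = c("point", "line", "rect", "text"),
    channels = c("position", "length", "saturation", "hue")
  )
}

.gvr_attribute_kinds <- c("quantitative", "categorical", "text")
.gvr_extents         <- c("point", "segment")
.gvr_densities       <- c("sparse", "contiguous")
.gvr_connections     <- c("none", "intra", "inter")
.gvr_conn_densities  <- c("none", "sparse", "dense")

## Canonical per-format defaults for extent, density, connection and
## connection density. User-supplied values always override these.
.gvr_format_defaults <- list(
  bigwig = list(extent = "point",   density = "contiguous", connection = "none",  connection_density = "none"),
  bed    = list(extent = "segment", density = "sparse",     connection = "none",  connection_density = "none"),
  bedpe  = list(extent = "segment", density = "sparse",     connection = "intra", connection_density = "sparse"),
  seg    = list(extent = "segment", density = "sparse",     connection = "none",  connection_density = "none"),
  vcf    = list(extent = "point",   density = "sparse",     connection = "none",  connection_density = "none"),
  cooler = list(extent = "point",   density = "contiguous", connection = "intra", connection_density = "dense")
)

## Default attribute payload per format when the descriptor lists none:
## signal-like formats carry one quantitative value, feature/variant-like
## formats one categorical label.
.gvr_format_default_kind <- c(
  bigwig = "quantitative", seg = "quantitative", cooler = "quantitative",
  bed = "categorical", vcf = "categorical", bedpe = "categorical"
)

#' Canonical descriptor defaults for a file format
#'
#' Given one of the six supported formats, return the canonical
#' (extent, density, connection, connection_density) tuple that a file of
#' that format carries unless the user overrides it. BIGWIG stores
#' point-based contiguous signal; BED/SEG sparse segments; VCF sparse
#' point variants; BEDPE paired intervals (sparse intra-genome links);
#' COOLER a contact matrix (dense intra-genome network).
#'
#' @param format One of `gvr_formats()` (case-insensitive).
#' @return Named list with `extent`, `density`, `connection`,
#'   `connection_density`.
#' @export
#' @examples
#' defaults_for_format("bigwig")
defaults_for_format <- function(format) {
  fmt <- tolower(as.character(format)[1])
  if (!fmt %in% gvr_formats()) {
    stop("unsupported file format: '", format, "' (expected one of ",
         paste(gvr_formats(), collapse = ", "), ")", call. = FALSE)
  }
  .gvr_format_defaults[[fmt]]
}
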