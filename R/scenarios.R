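## Fixture scenarios, a seeded random-scenario generator for
## property-style testing, and stimulus selection for evaluation
## harnesses (top-scored design vs the design closest to the median of
## the score distribution).

#' Packaged fixture scenarios
#'
#' Three canonical scenarios: `walkthrough` (BED with one categorical
#' attribute + VCF with one categorical + BIGWIG with one quantitative,
#' compare task), `usecase_stage_a` (BED + VCF, no task chosen yet) and
#' `study_scenario_1` (VCF, one categorical attribute, point extent,
#' sparse density, no connection, identify task).
#'
#' @param name Optional single scenario name; omitted = all.
#' @return A named list of scenarios, or one scenario when `name` given.
#' @export
#' @examples
#' names(builtin_scenarios())
builtin_scenarios <- function(name = NULL) {
  dir <- system.file("extdata", "scenarios", package = "genovizrec")
  paths <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  out <- lapply(paths, parse_scenario)
  names(out) <- tools::file_path_sans_ext(basename(paths))
  if (!is.null(name)) {
    if (!name %in% names(out)) {
      stop("unknown builtin scenario '", name, "' (available: ",
           paste(names(out), collapse = ", "), ")", call. = FALSE)
    }
    return(out[[name]])
  }
  out
}

## run expr under a local RNG seeded with `seed`, restoring global state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Draw a random valid scenario
#'
#' Deterministic for a fixed seed. Draws 1-3 files with formats uniform
#' over the six supported formats, 1-2 attributes per file with kinds
#' uniform over quantitative/categorical/text, and a task uniform over
#' identify/compare/overview. Feature fields follow the format defaults,
#' except that 10% of file draws override them with an arbitrary
#' consistent combination (any extent/density, any connection with a
#' consistent connection density and, for inter-genome connection, a
#' secondary assembly).
#'
#' @param seed Integer seed.
#' @return A valid [scenario()].
#' @export
random_scenario <- function(seed) {
  .with_seed(seed, {
    n_files <- sample(1:3, 1)
    files <- lapply(seq_len(n_files), function(i) {
      fmt <- sample(gvr_formats(), 1)
      n_attr <- sample(1:2, 1)
      attrs <- lapply(seq_len(n_attr), function(j)
        attribute_descriptor(sample(.gvr_attribute_kinds, 1),
                             paste0("attr", i, "_", j)))
      override <- stats::runif(1) < 0.10
      if (override) {
        connection <- sample(.gvr_connections, 1)
        conn_density <- if (connection == "none") "none" else
          sample(c("sparse", "dense"), 1)
        genomic_file(fmt, label = paste0(toupper(fmt), i),
                     secondary_assembly = if (connection == "inter") "mm39" else NULL,
                     attributes = attrs,
                     extent = sample(.gvr_extents, 1),
                     density = sample(.gvr_densities, 1),
                     connection = connection,
                     connection_density = conn_density)
      } else {
        genomic_file(fmt, label = paste0(toupper(fmt), i), attributes = attrs)
      }
    })
    scenario(files, task = sample(gvr_tasks(), 1))
  })
}

#' Select evaluation stimuli from a scored candidate set
#'
#' Picks the top-scored design and the design whose score is closest to
#' the median of the score distribution (standard median: mean of the
#' two middle values for even counts). Score ties in either role are
#' resolved by a seeded uniform draw, so selection is deterministic for
#' a fixed seed.
#'
#' @param candidates A list of `gvr_candidate` objects or a
#'   [enumerate_all()] data frame.
#' @param seed Integer seed for tie resolution.
#' @param kb Knowledge base (used to materialize enumeration rows).
#' @return List of class `gvr_stimulus_pair`: `top`, `alternate`, `seed`,
#'   and the index of each within the input.
#' @export
select_stimuli <- function(candidates, seed = 0L, kb = load_knowledge_base()) {
  is_enum <- inherits(candidates, "gvr_enumeration")
  scores <- if (is_enum) {
    candidates$aggregate_score
  } else {
    if (length(candidates) == 0) stop("select_stimuli: empty candidate list",
                                      call. = FALSE)
    vapply(candidates, function(x) x$aggregate_score, numeric(1))
  }
  if (length(scores) == 0) stop("select_stimuli: empty candidate list",
                                call. = FALSE)
  med <- stats::median(scores)
  top_idx <- which(scores == max(scores))
  dist <- abs(scores - med)
  alt_idx <- which(dist == min(dist))
  picked <- .with_seed(seed, {
    c(top = if (length(top_idx) == 1) top_idx else sample(top_idx, 1),
      alt = if (length(alt_idx) == 1) alt_idx else sample(alt_idx, 1))
  })
  materialize <- function(i) {
    if (is_enum) enumeration_candidate(candidates, i, kb) else candidates[[i]]
  }
  structure(list(top = materialize(picked[["top"]]),
                 alternate = materialize(picked[["alt"]]),
                 top_index = unname(picked[["top"]]),
                 alternate_index = unname(picked[["alt"]]),
                 median_score = med,
                 seed = seed),
            class = "gvr_stimulus_pair")
}

#' @export
print.gvr_stimulus_pair <- function(x, ...) {
  cat(sprintf("<stimulus pair> median %.3f, seed %d\n", x$median_score, x$seed))
  cat("top (", sprintf("%.3f", x$top$aggregate_score), "): ", x$top$id, "\n", sep = "")
  cat("alternate (", sprintf("%.3f", x$alternate$aggregate_score), "): ",
      x$alternate$id, "\n", sep = "")
  invisible(x)
}
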