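## Sequential six-component recommendation pipeline.
##
## Components run in a fixed order (encoding -> alignment -> layout ->
## partition -> arrangement -> interactivity); each step ranks its
## options by cosine similarity against factors derived from the
## scenario and the choices already made, hard design constraints prune
## infeasible options, and exact ties among top options branch the
## candidate set (Cartesian product) so design variations propagate.

## mark/channel/interval semantics of each encoding-matrix row
.gvr_encoding_rows <- list(
  rect_bar                 = list(mark = "rect", channel = "length",     interval = FALSE),
  line_position            = list(mark = "line", channel = "position",   interval = FALSE),
  point_position           = list(mark = "point", channel = "position",  interval = FALSE),
  rect_interval_saturation = list(mark = "rect", channel = "saturation", interval = TRUE),
  rect_interval_hue        = list(mark = "rect", channel = "hue",        interval = TRUE),
  point_hue                = list(mark = "point", channel = "hue",       interval = FALSE),
  text_position            = list(mark = "text", channel = "position",   interval = FALSE),
  line_connection          = list(mark = "line", channel = "position",   interval = TRUE)
)

.task_col <- function(task) paste0("task_", task)

## ---- C1: encoding ---------------------------------------------------------

## Per-attribute ranking over feasible encoding rows. The hue channel is
## infeasible for quantitative attributes (hard form of the channel
## effectiveness rule); the connection-link row is never ranked for an
## attribute -- link tracks are attached separately for connected files.
.c1_rankings <- function(sc, kb) {
  m <- get_matrix(kb, "c1_encoding")
  out <- list()
  for (f in sc$files) {
    for (a in f$attributes) {
      active <- c(f$extent, f$density, a$kind, .task_col(sc$task))
      input <- build_input_vector(active, m)
      feasible <- setdiff(m$rows, "line_connection")
      if (a$kind == "quantitative") {
        hue_rows <- names(Filter(function(e) e$channel == "hue", .gvr_encoding_rows))
        feasible <- setdiff(feasible, hue_rows)
      }
      ranking <- rank_options(m, input, rows = feasible)
      out[[length(out) + 1]] <- list(file = f$label, attribute = a$label,
                                     kind = a$kind, ranking = ranking)
    }
  }
  out
}

.encoding_choice <- function(file_label, attribute_label, kind, option, score,
                             is_link = FALSE) {
  meta <- .gvr_encoding_rows[[option]]
  list(file = file_label, attribute = attribute_label, kind = kind,
       option = option, mark = meta$mark, channel = meta$channel,
       interval = meta$interval, score = score, is_link = is_link)
}

## One encoding combo = attribute tracks (one chosen row each, in file
## order) plus a link track per connected file.
.make_combo <- function(sc, per_attr_options) {
  combo <- list()
  i <- 0
  for (f in sc$files) {
    for (a in f$attributes) {
      i <- i + 1
      po <- per_attr_options[[i]]
      combo[[length(combo) + 1]] <-
        .encoding_choice(f$label, a$label, a$kind, po$option, po$score)
    }
    if (f$connection != "none") {
      combo[[length(combo) + 1]] <-
        .encoding_choice(f$label, paste0(f$label, "_links"), "connection",
                         "line_connection", NA_real_, is_link = TRUE)
    }
  }
  combo
}

#' Recommend visual encodings for every attribute of a scenario
#'
#' Ranks the encoding matrix for each data attribute (active factors:
#' feature extent, density, attribute kind, task) and returns the tied
#' top options as encoding choices. Hue is never offered for
#' quantitative attributes.
#'
#' @param sc A [scenario()].
#' @param kb A [load_knowledge_base()] result.
#' @param tolerance Tie tolerance passed to [top_set()].
#' @return A list with one element per attribute: `file`, `attribute`,
#'   `ranking` (all options with scores) and `top` (list of encoding
#'   choices).
#' @export
recommend_encodings <- function(sc, kb = load_knowledge_base(), tolerance = 1e-9) {
  lapply(.c1_rankings(sc, kb), function(r) {
    top <- top_set(r$ranking, tolerance)
    scores <- r$ranking$score[match(top, r$ranking$option)]
    r$top <- unname(Map(function(opt, s)
      .encoding_choice(r$file, r$attribute, r$kind, opt, s), top, scores))
    r
  })
}

## ---- derived design flags -------------------------------------------------

## Layout-relevant factors are derived from the data description, not
## from the encodings chosen on a particular branch: quantitative and
## text attributes occupy position/length channels, categorical
## attributes color channels, so the attribute kinds determine the
## channel profile up to the saturation design variation. Keying these
## factors on the scenario keeps layout scores identical across
## encoding variations, which makes the sequential pipeline attain the
## exhaustive maximum.
.scenario_flags <- function(sc) {
  kinds <- unlist(lapply(sc$files, function(f)
    vapply(f$attributes, function(a) a$kind, character(1))))
  conn_d <- vapply(sc$files, function(f) f$connection_density, character(1))
  list(
    pos_length = any(kinds %in% c("quantitative", "text")),
    color_only = all(kinds == "categorical"),
    quant_attribute = any(kinds == "quantitative"),
    conn_sparse = any(conn_d == "sparse"),
    conn_dense = any(conn_d == "dense"),
    any_conn = any(conn_d != "none")
  )
}

## position/length + color pairs overlayable within one file (rule: only
## same-file tracks, only position and color channels co-exist without
## occlusion)
.overlay_pairs <- function(combo) {
  pairs <- list()
  attr_idx <- which(vapply(combo, function(e) !e$is_link, logical(1)))
  for (lab in unique(vapply(combo[attr_idx], function(e) e$file, character(1)))) {
    idx <- attr_idx[vapply(combo[attr_idx], function(e) e$file == lab, logical(1))]
    pos <- idx[vapply(combo[idx], function(e)
      e$channel %in% c("position", "length"), logical(1))]
    col <- idx[vapply(combo[idx], function(e)
      e$channel %in% c("hue", "saturation"), logical(1))]
    n <- min(length(pos), length(col))
    if (n > 0) {
      for (k in seq_len(n)) {
        pairs[[length(pairs) + 1]] <- c(position = pos[k], color = col[k])
      }
    }
  }
  pairs
}

## ---- C2: alignment --------------------------------------------------------

.c2_context <- function(sc, combo, kb) {
  m <- get_matrix(kb, "c2_alignment")
  per_file <- table(vapply(combo, function(e) e$file, character(1)))
  pairs <- .overlay_pairs(combo)
  ## active factors are structural (file/track multiplicity); whether a
  ## position+color pair exists is a feasibility gate for overlay, not a
  ## scored factor, so alignment scores do not depend on the encoding
  ## branch taken
  active <- character(0)
  if (length(sc$files) > 1) active <- c(active, "multi_file")
  if (any(per_file >= 2)) active <- c(active, "same_file_multitrack")
  feasible <- if (length(pairs) > 0) m$rows else "stacked"
  list(ranking = rank_options(m, build_input_vector(active, m), rows = feasible),
       pairs = pairs)
}

#' Recommend track alignment for one encoding combination
#'
#' Stacked alignment (file order preserved) is always feasible; overlay
#' is offered only when one file contributes both a position/length
#' track and a color track, which are the only channels that co-exist
#' without occlusion.
#'
#' @param combo A list of encoding choices (one element of the Cartesian
#'   product over [recommend_encodings()] top sets).
#' @param sc The scenario.
#' @param kb The knowledge base.
#' @param tolerance Tie tolerance.
#' @return List with `ranking`, `top` (alignment labels) and
#'   `overlay_pairs`.
#' @export
recommend_alignment <- function(combo, sc, kb = load_knowledge_base(),
                                tolerance = 1e-9) {
  ctx <- .c2_context(sc, combo, kb)
  list(ranking = ctx$ranking, top = top_set(ctx$ranking, tolerance),
       overlay_pairs = ctx$pairs)
}

## rendered track count after applying an alignment decision
.track_count <- function(combo, alignment, pairs) {
  n <- length(combo)
  if (alignment == "overlayed") n <- n - length(pairs)
  n
}

## ---- C3: layout -----------------------------------------------------------

.c3_active <- function(flags, track_count, task) {
  active <- .task_col(task)
  if (flags$pos_length) active <- c(active, "pos_length")
  if (flags$color_only) active <- c(active, "color_only")
  active <- c(active, if (track_count == 1) "single_track" else "multi_track")
  if (flags$quant_attribute) active <- c(active, "quant_pos_length")
  if (task %in% c("identify", "compare")) active <- c(active, "focus_task")
  if (flags$conn_sparse) active <- c(active, "connection_sparse")
  if (flags$conn_dense) active <- c(active, "connection_dense")
  active
}

.c3_feasible <- function(flags, n_encodings, task) {
  rows <- c("linear", "circular", "space_filling")
  ## quantitative values on position/length read poorly on a circle when
  ## the task needs region-level reading/comparison -> circular pruned
  if (task %in% c("identify", "compare") && flags$quant_attribute) {
    rows <- setdiff(rows, "circular")
  }
  ## a space-filling curve renders exactly one encoded attribute (an
  ## overlaid pair is still two data series), and its strength is
  ## genome-scale pattern search, not region navigation
  if (n_encodings != 1 || task != "overview") {
    rows <- setdiff(rows, "space_filling")
  }
  rows
}

#' Recommend a layout for a partially decided candidate
#'
#' @param state List with `combo` (encoding choices), `alignment`, and
#'   `track_count`.
#' @param sc The scenario.
#' @param kb The knowledge base.
#' @param tolerance Tie tolerance.
#' @return List with `ranking` (feasible layouts scored) and `top`.
#' @export
recommend_layout <- function(state, sc, kb = load_knowledge_base(),
                             tolerance = 1e-9) {
  m <- get_matrix(kb, "c3_layout")
  flags <- .scenario_flags(sc)
  active <- .c3_active(flags, state$track_count, sc$task)
  feasible <- .c3_feasible(flags, length(state$combo), sc$task)
  ranking <- rank_options(m, build_input_vector(active, m), rows = feasible)
  list(ranking = ranking, top = top_set(ranking, tolerance))
}

## ---- C4: partition --------------------------------------------------------

.c4_ranking <- function(task, kb) {
  m <- get_matrix(kb, "c4_partition")
  active <- c(.task_col(task), "single_genomic_axis", "track_economy",
              "cross_chromosome_context")
  rank_options(m, build_input_vector(active, m))
}

#' Recommend a chromosome partition
#'
#' Partition depends primarily on the task; the contiguous (end-to-end)
#' partition carries the always-active default-preference factors and so
#' outranks segregated for every task, while segregated stays feasible
#' as an overview variation.
#'
#' @inheritParams recommend_layout
#' @export
recommend_partition <- function(state, sc, kb = load_knowledge_base(),
                                tolerance = 1e-9) {
  ranking <- .c4_ranking(sc$task, kb)
  list(ranking = ranking, top = top_set(ranking, tolerance))
}

## ---- C5: arrangement ------------------------------------------------------

.c5_context <- function(layout, flags, task, kb) {
  m <- get_matrix(kb, "c5_arrangement")
  active <- character(0)
  if (!flags$any_conn) active <- c(active, "connection_none")
  if (flags$conn_sparse) active <- c(active, "connection_sparse")
  if (flags$conn_dense) active <- c(active, "connection_dense")
  if (layout == "linear") active <- c(active, "layout_linear")
  if (layout == "circular") active <- c(active, "layout_circular")
  if (task == "compare") active <- c(active, "task_compare")
  feasible <- m$rows
  ## adjacency-matrix arrangement needs a dense network and linear tracks
  if (!(layout == "linear" && flags$conn_dense)) {
    feasible <- setdiff(feasible, "orthogonal")
  }
  ## a space-filling curve is a single self-contained panel
  if (layout == "space_filling") feasible <- "single"
  rank_options(m, build_input_vector(active, m), rows = feasible)
}

#' Recommend a view arrangement
#'
#' @param state List with `combo`, `alignment`, `track_count`, `layout`.
#' @inheritParams recommend_layout
#' @return List with `ranking`, `top`, and per-option `view_count`
#'   (2 for parallel/adjacent/orthogonal, 1 for single).
#' @export
recommend_arrangement <- function(state, sc, kb = load_knowledge_base(),
                                  tolerance = 1e-9) {
  flags <- .scenario_flags(sc)
  ranking <- .c5_context(state$layout, flags, sc$task, kb)
  top <- top_set(ranking, tolerance)
  list(ranking = ranking, top = top,
       view_count = ifelse(top == "single", 1L, 2L))
}

## ---- C6: interactivity ----------------------------------------------------

.c6_ranking <- function(view_count, track_count, task, kb) {
  m <- get_matrix(kb, "c6_interactivity")
  ## interaction patterns are chosen by task alone: view and track
  ## multiplicity are declared factors but do not discriminate during
  ## scoring (coordinated zoom/pan for multi-track views is a forced
  ## inclusion rule, and patterns apply within each view), which keeps
  ## the interactivity score independent of earlier branch choices
  rank_options(m, build_input_vector(.task_col(task), m))
}

#' Recommend interaction patterns
#'
#' Interactivity is set-valued: all tied top rows are included (so
#' focus+context and coordinated zoom/pan can co-occur), and any view
#' holding multiple tracks always gets coordinated zooming and panning.
#'
#' @param state List with `combo`, `track_count`, `view_count`.
#' @inheritParams recommend_layout
#' @return List with `ranking` and `set` (character vector).
#' @export
recommend_interactivity <- function(state, sc, kb = load_knowledge_base(),
                                    tolerance = 1e-9) {
  ranking <- .c6_ranking(state$view_count, state$track_count, sc$task, kb)
  set <- top_set(ranking, tolerance)
  if (state$track_count >= 2) set <- union(set, "coordinated")
  ## fixed order for determinism
  set <- intersect(c("focus_context", "coordinated"), set)
  list(ranking = ranking, set = set)
}

## ---- candidate assembly ---------------------------------------------------

.build_candidate <- function(sc, combo, alignment, pairs, layout, partition,
                             arrangement, interactivity, scores, id) {
  track_count <- .track_count(combo, alignment, pairs)
  structure(list(
    encodings = combo,
    alignment = alignment,
    overlay_pairs = if (alignment == "overlayed") pairs else list(),
    track_count = track_count,
    layout = layout,
    partition = partition,
    arrangement = arrangement,
    view_count = if (arrangement == "single") 1L else 2L,
    interactivity = interactivity,
    component_scores = scores,
    aggregate_score = mean(unlist(scores)),
    id = id
  ), class = "gvr_candidate")
}

#' Check a candidate against the hard design invariants
#'
#' @param cand A candidate from [run_pipeline()] or [enumerate_all()].
#' @return Character vector of violations (empty when valid).
#' @export
validate_candidate <- function(cand) {
  viol <- character(0)
  if (cand$arrangement == "orthogonal" && cand$layout != "linear") {
    viol <- c(viol, "orthogonal arrangement requires a linear layout")
  }
  if (cand$layout == "space_filling" && cand$track_count != 1) {
    viol <- c(viol, "space-filling layout can only show a single track")
  }
  if ((cand$view_count >= 2) != (cand$arrangement != "single")) {
    viol <- c(viol, "view count inconsistent with arrangement")
  }
  for (e in cand$encodings) {
    if (!e$is_link && e$channel == "hue" && e$kind == "quantitative") {
      viol <- c(viol, paste0("hue channel mapped to quantitative attribute ",
                             e$attribute))
    }
  }
  agg <- mean(unlist(cand$component_scores))
  if (!isTRUE(all.equal(agg, cand$aggregate_score))) {
    viol <- c(viol, "aggregate score is not the mean of component scores")
  }
  viol
}

#' Run the sequential recommendation pipeline
#'
#' Executes the six components in order. After each component the tied
#' top options branch the candidate set (Cartesian product); options
#' violating a hard design constraint are pruned before ranking. Each
#' surviving candidate carries per-component cosine scores and their
#' mean as aggregate score; the output is sorted by aggregate score
#' (ties keep deterministic branch order).
#'
#' @param sc A [scenario()].
#' @param kb A knowledge base.
#' @param tolerance Tie tolerance for [top_set()].
#' @param max_candidates Branch cap; expansion beyond this emits a
#'   warning and keeps the first (highest-ranked) branches.
#' @return List of `gvr_candidate` objects, best first.
#' @export
#' @examples
#' sc <- builtin_scenarios()[["walkthrough"]]
#' cands <- run_pipeline(sc)
#' length(cands)
run_pipeline <- function(sc, kb = load_knowledge_base(), tolerance = 1e-9,
                         max_candidates = 64L) {
  viol <- validate_scenario(sc)
  if (length(viol) > 0) {
    stop("invalid scenario:\n  - ", paste(viol, collapse = "\n  - "),
         call. = FALSE)
  }
  task <- sc$task

  ## C1: per-attribute top sets, Cartesian product
  c1 <- .c1_rankings(sc, kb)
  tops <- lapply(c1, function(r) {
    labs <- top_set(r$ranking, tolerance)
    lapply(labs, function(l)
      list(option = l, score = r$ranking$score[match(l, r$ranking$option)]))
  })
  grid <- expand.grid(lapply(tops, seq_along), KEEP.OUT.ATTRS = FALSE)
  ## deterministic branch order: first attribute's options vary slowest
  if (ncol(grid) > 1) grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  branches <- lapply(seq_len(nrow(grid)), function(i) {
    per_attr <- Map(function(opts, j) opts[[j]], tops, as.integer(grid[i, ]))
    combo <- .make_combo(sc, per_attr)
    attr_scores <- vapply(Filter(function(e) !e$is_link, combo),
                          function(e) e$score, numeric(1))
    list(combo = combo, c1 = mean(attr_scores))
  })

  ## C2
  branches <- .expand(branches, max_candidates, function(b) {
    ctx <- .c2_context(sc, b$combo, kb)
    lapply(top_set(ctx$ranking, tolerance), function(al) {
      b$alignment <- al
      b$pairs <- ctx$pairs
      b$track_count <- .track_count(b$combo, al, ctx$pairs)
      b$c2 <- ctx$ranking$score[match(al, ctx$ranking$option)]
      b
    })
  })

  ## C3
  m3 <- get_matrix(kb, "c3_layout")
  branches <- .expand(branches, max_candidates, function(b) {
    flags <- .scenario_flags(sc)
    active <- .c3_active(flags, b$track_count, task)
    feasible <- .c3_feasible(flags, length(b$combo), task)
    ranking <- rank_options(m3, build_input_vector(active, m3), rows = feasible)
    lapply(top_set(ranking, tolerance), function(lay) {
      b$layout <- lay
      b$c3 <- ranking$score[match(lay, ranking$option)]
      b
    })
  })

  ## C4
  rank4 <- .c4_ranking(task, kb)
  branches <- .expand(branches, max_candidates, function(b) {
    lapply(top_set(rank4, tolerance), function(p) {
      b$partition <- p
      b$c4 <- rank4$score[match(p, rank4$option)]
      b
    })
  })

  ## C5
  branches <- .expand(branches, max_candidates, function(b) {
    flags <- .scenario_flags(sc)
    ranking <- .c5_context(b$layout, flags, task, kb)
    lapply(top_set(ranking, tolerance), function(arr) {
      b$arrangement <- arr
      b$view_count <- if (arr == "single") 1L else 2L
      b$c5 <- ranking$score[match(arr, ranking$option)]
      b
    })
  })

  ## C6: set-valued, no branching
  cands <- lapply(seq_along(branches), function(i) {
    b <- branches[[i]]
    ranking <- .c6_ranking(b$view_count, b$track_count, task, kb)
    set <- top_set(ranking, tolerance)
    if (b$track_count >= 2) set <- union(set, "coordinated")
    set <- intersect(c("focus_context", "coordinated"), set)
    ## component score = score of the best supported pattern; the forced
    ## coordinated inclusion is a hard rule, not a scored preference
    c6 <- max(ranking$score[match(set, ranking$option)])
    id <- paste0(
      "e:", paste(vapply(b$combo, function(e) e$option, character(1)), collapse = "+"),
      "|a:", b$alignment, "|l:", b$layout, "|p:", b$partition, "|r:", b$arrangement)
    .build_candidate(sc, b$combo, b$alignment, b$pairs, b$layout, b$partition,
                     b$arrangement, set,
                     list(c1_encoding = b$c1, c2_alignment = b$c2,
                          c3_layout = b$c3, c4_partition = b$c4,
                          c5_arrangement = b$c5, c6_interactivity = c6),
                     id = id)
  })
  agg <- vapply(cands, function(x) x$aggregate_score, numeric(1))
  cands[order(-agg)]  # stable: ties keep branch order
}

.expand <- function(branches, max_candidates, f) {
  out <- list()
  capped <- FALSE
  for (b in branches) {
    for (nb in f(b)) {
      if (length(out) >= max_candidates) {
        capped <- TRUE
        break
      }
      out[[length(out) + 1]] <- nb
    }
    if (capped) break
  }
  if (capped) {
    warning("candidate expansion capped at ", max_candidates,
            " branches; lowest-ranked branches dropped", call. = FALSE)
  }
  out
}

#' @export
print.gvr_candidate <- function(x, ...) {
  cat(sprintf("<candidate> score %.3f | %s, %s, %s, %s (%d view%s), %s\n",
              x$aggregate_score, x$alignment, x$layout, x$partition,
              x$arrangement, x$view_count, if (x$view_count > 1) "s" else "",
              paste(x$interactivity, collapse = "+")))
  for (e in x$encodings) {
    cat(sprintf("    %-8s %-12s %s+%s%s\n", e$file, e$attribute, e$mark,
                e$channel, if (e$interval) " (interval)" else ""))
  }
  invisible(x)
}

## ---- exhaustive enumeration ----------------------------------------------

#' Enumerate and score every feasible visualization design
#'
#' Exhaustive counterpart of [run_pipeline()]: every feasible combination
#' over all components' option sets (not just tied top options) is
#' scored with the same per-component cosine scores. Used for stimulus
#' selection and as the maximality oracle for the sequential pipeline.
#'
#' @param sc A [scenario()].
#' @param kb A knowledge base.
#' @return A data frame of class `gvr_enumeration`, one row per feasible
#'   candidate, with the design choices, per-component scores and
#'   aggregate score. Materialize row `i` as a full candidate with
#'   [enumeration_candidate()].
#' @export
enumerate_all <- function(sc, kb = load_knowledge_base()) {
  viol <- validate_scenario(sc)
  if (length(viol) > 0) {
    stop("invalid scenario:\n  - ", paste(viol, collapse = "\n  - "),
         call. = FALSE)
  }
  task <- sc$task
  c1 <- .c1_rankings(sc, kb)
  feas_rows <- lapply(c1, function(r) r$ranking$option)
  score_of <- lapply(c1, function(r)
    stats::setNames(r$ranking$score, r$ranking$option))

  rank4 <- .c4_ranking(task, kb)
  c4_scores <- stats::setNames(rank4$score, rank4$option)
  m3 <- get_matrix(kb, "c3_layout")

  grid <- expand.grid(feas_rows, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  if (ncol(grid) > 1) grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]

  ## interactivity ranking depends on the task only
  rank6 <- .c6_ranking(1L, 1L, task, kb)
  c6_of_set <- function(iset) max(rank6$score[match(iset, rank6$option)])
  sets_multi <- c("coordinated", "focus_context+coordinated")
  sets_single <- c("focus_context", "coordinated", "focus_context+coordinated")
  set_score <- vapply(
    list("coordinated", c("focus_context", "coordinated"), "focus_context"),
    c6_of_set, numeric(1))
  names(set_score) <- c("coordinated", "focus_context+coordinated",
                        "focus_context")

  rows <- list()
  for (i in seq_len(nrow(grid))) {
    per_attr <- lapply(seq_along(c1), function(j)
      list(option = as.character(grid[i, j]),
           score = unname(score_of[[j]][as.character(grid[i, j])])))
    combo <- .make_combo(sc, per_attr)
    c1_score <- mean(vapply(Filter(function(e) !e$is_link, combo),
                            function(e) e$score, numeric(1)))
    flags <- .scenario_flags(sc)
    ctx2 <- .c2_context(sc, combo, kb)
    enc_label <- paste(as.character(grid[i, ]), collapse = "+")
    for (al in ctx2$ranking$option) {
      c2_score <- ctx2$ranking$score[match(al, ctx2$ranking$option)]
      tc <- .track_count(combo, al, ctx2$pairs)
      active3 <- .c3_active(flags, tc, task)
      feas3 <- .c3_feasible(flags, length(combo), task)
      rank3 <- rank_options(m3, build_input_vector(active3, m3), rows = feas3)
      isets <- if (tc >= 2) sets_multi else sets_single
      for (li in seq_len(nrow(rank3))) {
        lay <- rank3$option[li]
        rank5 <- .c5_context(lay, flags, task, kb)
        block <- expand.grid(interactivity = isets,
                             arrangement = rank5$option,
                             partition = rank4$option,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        block$encodings <- enc_label
        block$alignment <- al
        block$layout <- lay
        block$c1_encoding <- c1_score
        block$c2_alignment <- c2_score
        block$c3_layout <- rank3$score[li]
        block$c4_partition <- c4_scores[block$partition]
        block$c5_arrangement <-
          rank5$score[match(block$arrangement, rank5$option)]
        block$c6_interactivity <- set_score[block$interactivity]
        rows[[length(rows) + 1]] <- block
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[, c("encodings", "alignment", "layout", "partition",
                 "arrangement", "interactivity", "c1_encoding",
                 "c2_alignment", "c3_layout", "c4_partition",
                 "c5_arrangement", "c6_interactivity")]
  out$aggregate_score <- rowMeans(out[, paste0("c", 1:6, c("_encoding",
    "_alignment", "_layout", "_partition", "_arrangement", "_interactivity"))])
  rownames(out) <- NULL
  attr(out, "scenario") <- sc
  attr(out, "kb_source") <- kb$source
  class(out) <- c("gvr_enumeration", class(out))
  out
}

#' Materialize one enumerated design as a full candidate
#'
#' @param enum A [enumerate_all()] result.
#' @param i Row index.
#' @param kb Knowledge base (must match the one used to enumerate).
#' @return A `gvr_candidate`.
#' @export
enumeration_candidate <- function(enum, i, kb = load_knowledge_base()) {
  sc <- attr(enum, "scenario")
  row <- enum[i, ]
  opts <- strsplit(row$encodings, "+", fixed = TRUE)[[1]]
  c1 <- .c1_rankings(sc, kb)
  per_attr <- lapply(seq_along(c1), function(j)
    list(option = opts[j],
         score = c1[[j]]$ranking$score[match(opts[j], c1[[j]]$ranking$option)]))
  combo <- .make_combo(sc, per_attr)
  pairs <- .overlay_pairs(combo)
  .build_candidate(
    sc, combo, row$alignment, pairs, row$layout, row$partition,
    row$arrangement, strsplit(row$interactivity, "+", fixed = TRUE)[[1]],
    list(c1_encoding = row$c1_encoding, c2_alignment = row$c2_alignment,
         c3_layout = row$c3_layout, c4_partition = row$c4_partition,
         c5_arrangement = row$c5_arrangement,
         c6_interactivity = row$c6_interactivity),
    id = paste0("enum:", i))
}
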