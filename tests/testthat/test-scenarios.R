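test_that("builtin scenarios match their published descriptions", {
  all <- builtin_scenarios()
  expect_true(all(c("walkthrough", "usecase_stage_a", "study_scenario_1") %in%
                    names(all)))

  s1 <- builtin_scenarios("study_scenario_1")
  expect_length(s1$files, 1)
  f <- s1$files[[1]]
  expect_equal(f$format, "vcf")
  expect_length(f$attributes, 1)
  expect_equal(f$attributes[[1]]$kind, "categorical")
  expect_equal(f$extent, "point")
  expect_equal(f$density, "sparse")
  expect_equal(f$connection, "none")
  expect_equal(s1$task, "identify")

  wt <- builtin_scenarios("walkthrough")
  expect_length(wt$files, 3)
  expect_equal(vapply(wt$files, function(f) f$format, character(1)),
               c("bed", "vcf", "bigwig"))
  expect_equal(wt$task, "compare")

  sa <- builtin_scenarios("usecase_stage_a")
  expect_length(sa$files, 2)
  expect_false(isTRUE(sa$task_explicit))

  expect_error(builtin_scenarios("nope"), "unknown builtin scenario")
})

test_that("random scenarios are deterministic, valid, and cover the space", {
  expect_identical(unclass(random_scenario(99)), unclass(random_scenario(99)))

  formats_seen <- character(0)
  tasks_seen <- character(0)
  kinds_seen <- character(0)
  for (seed in 1:1000) {
    sc <- random_scenario(seed)
    expect_length(validate_scenario(sc), 0)
    formats_seen <- union(formats_seen,
                          vapply(sc$files, function(f) f$format, character(1)))
    tasks_seen <- union(tasks_seen, sc$task)
    for (f in sc$files) {
      kinds_seen <- union(kinds_seen,
                          vapply(f$attributes, function(a) a$kind, character(1)))
    }
  }
  expect_setequal(formats_seen, gvr_formats())
  expect_setequal(tasks_seen, gvr_tasks())
  expect_setequal(kinds_seen, c("quantitative", "categorical", "text"))
})

test_that("random_scenario does not disturb the global RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(random_scenario(7))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("stimulus selection picks the top and the closest-to-median design", {
  mk <- function(score, id) structure(
    list(aggregate_score = score, id = id,
         encodings = list(), alignment = "stacked", overlay_pairs = list(),
         track_count = 1L, layout = "linear", partition = "contiguous",
         arrangement = "single", view_count = 1L,
         interactivity = "coordinated",
         component_scores = list(x = score), aggregate_score = score),
    class = "gvr_candidate")
  cands <- list(mk(1.0, "a"), mk(0.5, "b"), mk(0.0, "c"))
  pair <- select_stimuli(cands, seed = 1)
  expect_equal(pair$top$aggregate_score, 1.0)
  expect_equal(pair$alternate$aggregate_score, 0.5)  # median of (1, .5, 0)
  expect_equal(pair$median_score, 0.5)

  # single candidate: top and alternate coincide
  solo <- select_stimuli(list(mk(0.3, "only")), seed = 5)
  expect_identical(solo$top_index, solo$alternate_index)

  # even count: median is the mean of the two middle scores
  cands4 <- list(mk(1, "a"), mk(0.6, "b"), mk(0.2, "c"), mk(0, "d"))
  pair4 <- select_stimuli(cands4, seed = 2)
  expect_equal(pair4$median_score, 0.4)
  expect_true(pair4$alternate$aggregate_score %in% c(0.6, 0.2))

  # ties at top: seeded draw is deterministic across runs
  tied <- list(mk(1, "a"), mk(1, "b"), mk(0, "c"))
  p1 <- select_stimuli(tied, seed = 11)
  p2 <- select_stimuli(tied, seed = 11)
  expect_identical(p1$top_index, p2$top_index)

  expect_error(select_stimuli(list()), "empty")
})

test_that("alternate stimulus minimizes |score - median| (brute force)", {
  for (seed in c(3, 9, 17)) {
    sc <- random_scenario(seed)
    n_attr <- sum(vapply(sc$files, function(f) length(f$attributes), integer(1)))
    if (n_attr > 3) next
    enum <- enumerate_all(sc, kb_default)
    pair <- select_stimuli(enum, seed = seed, kb = kb_default)
    med <- median(enum$aggregate_score)
    expect_equal(pair$median_score, med)
    best_dist <- min(abs(enum$aggregate_score - med))
    expect_equal(abs(pair$alternate$aggregate_score - med), best_dist,
                 tolerance = 1e-12)
    expect_equal(pair$top$aggregate_score, max(enum$aggregate_score))
  }
})

test_that("enumeration-based stimuli for the identify study scenario favor linear focus+context", {
  sc <- builtin_scenarios("study_scenario_1")
  enum <- enumerate_all(sc, kb_default)
  pair <- select_stimuli(enum, seed = 7, kb = kb_default)
  expect_equal(pair$top$layout, "linear")
  expect_true("focus_context" %in% pair$top$interactivity)
  # the same seed always selects the same pair
  pair2 <- select_stimuli(enum, seed = 7, kb = kb_default)
  expect_identical(pair$top_index, pair2$top_index)
  expect_identical(pair$alternate_index, pair2$alternate_index)
})
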