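test_that("walkthrough candidates serialize to two-view stacked documents", {
  sc <- walkthrough_scenario()
  cands <- run_pipeline(sc, kb_default)
  doc <- emit_spec(cands[[1]], sc)
  expect_s3_class(doc, "gvr_gosling")
  expect_length(validate_gosling_document(doc), 0)

  info <- parse_gosling_document(doc)
  expect_equal(info$view_count, cands[[1]]$view_count)
  expect_equal(info$tracks_per_view, rep(cands[[1]]$track_count, 2))
  expect_equal(info$layout, "linear")
  expect_equal(info$arrangement, "parallel")
  # tracks stacked in file order within each view
  parsed <- jsonlite::fromJSON(doc$text, simplifyVector = FALSE)
  files <- vapply(parsed$views[[1]]$tracks, function(t) t$file, character(1))
  expect_equal(files, c("BED1", "VCF1", "BIGWIG1"))
  expect_equal(info$marks[[1]], c("rect", "point", "bar"))
  # compare design: genome-wide brush/overview navigation on each view
  for (vw in parsed$views) {
    expect_equal(vw$navigation$type, "overview-brush")
    expect_true(vw$navigation$genomeWide)
  }
  # second option differs only by the line mark
  info2 <- parse_gosling_document(emit_spec(cands[[2]], sc))
  expect_equal(info2$marks[[1]], c("rect", "point", "line"))
})

test_that("single-file circular candidate emits one circular view", {
  sc <- scenario(genomic_file("vcf", attributes = list(
    attribute_descriptor("categorical"))))
  enum <- enumerate_all(sc, kb_default)
  i <- which(enum$layout == "circular" & enum$arrangement == "single")[1]
  cand <- enumeration_candidate(enum, i, kb_default)
  info <- parse_gosling_document(emit_spec(cand, sc))
  expect_equal(info$view_count, 1)
  expect_equal(info$layout, "circular")
})

test_that("emission is deterministic and refuses invalid candidates", {
  sc <- walkthrough_scenario()
  cand <- run_pipeline(sc, kb_default)[[1]]
  expect_identical(emit_spec(cand, sc)$text, emit_spec(cand, sc)$text)

  broken <- cand
  broken$arrangement <- "single"  # view_count stays 2
  expect_error(emit_spec(broken, sc), "refused")

  broken2 <- cand
  broken2$layout <- "space_filling"  # multi-track
  expect_error(emit_spec(broken2, sc), "refused")
})

test_that("overlayed candidates merge the pair into one track", {
  sc <- scenario(genomic_file("bed", "BED1", attributes = list(
    attribute_descriptor("quantitative", "score"),
    attribute_descriptor("categorical", "class"))), task = "identify")
  cands <- run_pipeline(sc, kb_default)
  ov <- Filter(function(x) x$alignment == "overlayed", cands)[[1]]
  doc <- emit_spec(ov, sc)
  expect_length(validate_gosling_document(doc), 0)
  info <- parse_gosling_document(doc)
  expect_equal(info$tracks_per_view, ov$track_count)
  parsed <- jsonlite::fromJSON(doc$text, simplifyVector = FALSE)
  tr <- parsed$views[[1]]$tracks[[1]]
  expect_length(tr$overlay, 1)
})

test_that("connection files carry link tracks with link marks", {
  sc <- single_file_scenario("cooler", task = "overview")
  cand <- run_pipeline(sc, kb_default)[[1]]
  info <- parse_gosling_document(emit_spec(cand, sc))
  expect_true("withinLink" %in% unlist(info$marks))

  sc2 <- scenario(genomic_file("bedpe", secondary_assembly = "mm39",
                               connection = "inter", connection_density = "sparse"),
                  task = "overview")
  cand2 <- run_pipeline(sc2, kb_default)[[1]]
  info2 <- parse_gosling_document(emit_spec(cand2, sc2))
  expect_true("betweenLink" %in% unlist(info2$marks))
})

test_that("every document emitted over random scenarios validates", {
  for (seed in seq(1, 200, by = 4)) {
    sc <- random_scenario(seed)
    cands <- suppressWarnings(run_pipeline(sc, kb_default))
    for (cand in cands) {
      expect_length(validate_gosling_document(emit_spec(cand, sc)), 0)
    }
  }
})

test_that("the validator rejects corrupted documents", {
  sc <- walkthrough_scenario()
  doc <- emit_spec(run_pipeline(sc, kb_default)[[1]], sc)
  parsed <- jsonlite::fromJSON(doc$text, simplifyVector = FALSE)

  bad1 <- parsed; bad1$arrangement <- "diagonal"
  expect_match(validate_gosling_document(jsonlite::toJSON(bad1, auto_unbox = TRUE)),
               "unknown arrangement", all = FALSE)
  bad2 <- parsed; bad2$views[[1]]$tracks[[1]]$mark <- "area"
  expect_match(validate_gosling_document(jsonlite::toJSON(bad2, auto_unbox = TRUE)),
               "unknown mark", all = FALSE)
  bad3 <- parsed; bad3$views <- NULL
  expect_match(validate_gosling_document(jsonlite::toJSON(bad3, auto_unbox = TRUE)),
               "missing top-level", all = FALSE)
  expect_match(validate_gosling_document("{broken"), "does not parse")
})

test_that("palette assignment is consistent, prefix-based and colorblind-safe-sized", {
  a <- attribute_descriptor("categorical", "gene_class")
  p3 <- assign_palette(a, 3)
  expect_length(p3, 3)
  expect_identical(p3, assign_palette(a, 3))
  p8 <- assign_palette(a, 8)
  expect_identical(p3, p8[1:3])
  expect_true(all(grepl("^#[0-9A-F]{6}$", p8)))
  expect_warning(p10 <- assign_palette(a, 10), "cycle")
  expect_identical(p10[9:10], p8[1:2])
  expect_error(assign_palette(attribute_descriptor("quantitative", "x"), 2),
               "not categorical")
})
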