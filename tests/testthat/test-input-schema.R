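test_that("format defaults match each format's payload semantics", {
  expect_equal(defaults_for_format("bigwig"),
               list(extent = "point", density = "contiguous",
                    connection = "none", connection_density = "none"))
  expect_equal(defaults_for_format("vcf"),
               list(extent = "point", density = "sparse",
                    connection = "none", connection_density = "none"))
  expect_equal(defaults_for_format("bed")[c("extent", "density")],
               list(extent = "segment", density = "sparse"))
  expect_equal(defaults_for_format("seg")[c("extent", "density")],
               list(extent = "segment", density = "sparse"))
  expect_equal(defaults_for_format("bedpe")[c("connection", "connection_density")],
               list(connection = "intra", connection_density = "sparse"))
  expect_equal(defaults_for_format("cooler")[c("connection", "connection_density")],
               list(connection = "intra", connection_density = "dense"))
  # total and deterministic over the six formats
  for (fmt in gvr_formats()) {
    expect_identical(defaults_for_format(fmt), defaults_for_format(fmt))
  }
  expect_error(defaults_for_format("gff"), "unsupported")
})

test_that("parse_scenario fills defaults and validates structure", {
  doc <- '{
    "files": [{"format": "vcf", "label": "VCF1",
               "attributes": [{"kind": "categorical", "label": "type"}]}],
    "task": "identify"
  }'
  sc <- parse_scenario(doc)
  expect_s3_class(sc, "gvr_scenario")
  expect_length(sc$files, 1)
  expect_equal(sc$task, "identify")
  f <- sc$files[[1]]
  expect_equal(f$extent, "point")
  expect_equal(f$density, "sparse")
  expect_equal(f$connection, "none")

  # omitted extent on a BIGWIG file falls back to point/contiguous
  sc2 <- parse_scenario('{"files": [{"format": "bigwig"}]}')
  expect_equal(sc2$files[[1]]$extent, "point")
  expect_equal(sc2$files[[1]]$density, "contiguous")
  # unset task defaults to overview
  expect_equal(sc2$task, "overview")

  expect_error(parse_scenario('{"files": []}'), "at least one file")
  expect_error(parse_scenario('{"files": [{"label": "X"}]}'), "format")
  expect_error(parse_scenario("{not json"), "parse error")
})

test_that("validate_scenario reports one entry per invariant breach", {
  good <- walkthrough_scenario()
  expect_length(validate_scenario(good), 0)

  inter <- good
  inter$files[[1]]$connection <- "inter"
  inter$files[[1]]$connection_density <- "sparse"
  v <- validate_scenario(inter)
  expect_length(v, 1)
  expect_match(v, "secondary assembly")

  dup <- good
  dup$files[[2]]$label <- "BED1"
  v2 <- validate_scenario(dup)
  expect_length(v2, 1)
  expect_match(v2, "duplicate")

  incoherent <- good
  incoherent$files[[1]]$connection_density <- "dense"  # connection stays none
  expect_match(validate_scenario(incoherent), "inconsistent")
})

test_that("serialize/parse round-trips valid scenarios", {
  for (sc in list(walkthrough_scenario(),
                  single_file_scenario("cooler", task = "overview"),
                  random_scenario(11), random_scenario(42))) {
    back <- parse_scenario(serialize_scenario(sc))
    expect_equal(back$task, sc$task)
    expect_equal(length(back$files), length(sc$files))
    for (i in seq_along(sc$files)) {
      expect_equal(back$files[[i]][names(back$files[[i]]) != "attributes"],
                   sc$files[[i]][names(sc$files[[i]]) != "attributes"])
      expect_equal(lapply(back$files[[i]]$attributes, unclass),
                   lapply(sc$files[[i]]$attributes, unclass))
    }
  }
})

test_that("file constructor enforces connection coherence", {
  f <- genomic_file("bed", connection = "intra")
  expect_equal(f$connection_density, "sparse")
  f2 <- genomic_file("bedpe", connection = "none")
  expect_equal(f2$connection_density, "none")
  expect_error(
    scenario(genomic_file("bed", connection = "inter", connection_density = "sparse")),
    "secondary assembly")
})
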