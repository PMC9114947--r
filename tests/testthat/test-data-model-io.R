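test_that("marker matrix CSVs round-trip bit-identically across dialects", {
  set.seed(11)
  for (k in 1:8) {
    n <- sample(2:12, 1); p <- sample(1:20, 1)
    dialect <- sample(c(",", ";", "\t"), 1)
    x <- randomMarkerMatrix(n, p, prob = runif(1, 0.1, 0.9))
    f <- tempfile(fileext = ".csv")
    writeMarkerMatrix(x, f, dialect = dialect)
    y <- readMarkerMatrix(f, markerSet = markerSetLabel(x), dialect = dialect)
    expect_identical(markerValues(y), markerValues(x))
    expect_identical(sampleIDs(y), sampleIDs(x))
    expect_identical(markerIDs(y), markerIDs(x))
    unlink(f)
  }
})

test_that("an all-zero file reads to an all-zero matrix with shape preserved", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,a,b", "s1,0,0", "s2,0,0", "s3,0,0"), f)
  x <- readMarkerMatrix(f)
  expect_equal(dim(x), c(3L, 2L))
  expect_true(all(markerValues(x) == 0))
  expect_identical(sampleIDs(x), c("s1", "s2", "s3"))
  unlink(f)
})

test_that("non-binary cells and duplicate sample ids are rejected by name", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,a,b", "s1,0,2", "s2,0,1"), f)
  expect_error(readMarkerMatrix(f), "'2'.*sample 's1'.*marker 'b'")
  writeLines(c("sample_id,a", "s1,0", "s1,1"), f)
  expect_error(readMarkerMatrix(f), "duplicated sample id 's1'")
  unlink(f)
})

test_that("validity catches non-binary values and duplicated ids at construction", {
  m <- matrix(c(0, 1, 2, 1), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(BinaryMarkerMatrix(m), "non-binary")
  m2 <- matrix(0, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(BinaryMarkerMatrix(m2), "duplicated sample id")
  m3 <- matrix(c(0, NA, 1, 1), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(BinaryMarkerMatrix(m3), "missing")
})

test_that("metadata reading enforces the sample-population-habitat hierarchy", {
  sf <- tempfile(fileext = ".csv"); tf <- tempfile(fileext = ".csv")
  pops <- sprintf("pop%02d", 1:10)
  samples <- data.frame(
    sample_id = paste0(rep(pops, each = 16), "_", 1:16),
    population_id = rep(pops, each = 16),
    habitat = rep(rep(c("CG", "OM"), each = 5), each = 16))
  sites <- data.frame(population_id = pops,
                      habitat = rep(c("CG", "OM"), each = 5),
                      latitude = seq(48.2, 48.7, length.out = 10),
                      longitude = seq(9.0, 10.3, length.out = 10))
  write.csv(samples, sf, row.names = FALSE)
  write.csv(sites, tf, row.names = FALSE)
  meta <- readMetadata(sf, tf)
  expect_equal(nrow(meta$samples), 160L)
  expect_equal(nrow(meta$sites), 10L)

  bad <- samples; bad$population_id[1] <- "nowhere"
  write.csv(bad, sf, row.names = FALSE)
  expect_error(readMetadata(sf, tf), "unknown population 'nowhere'")

  bad <- samples; bad$habitat[1] <- "OM"  # pop01 now spans CG and OM
  write.csv(bad, sf, row.names = FALSE)
  expect_error(readMetadata(sf, tf), "two habitats")

  # consistent non-standard label: rejected by default, allowed in free mode
  bad <- sites; bad$habitat[1] <- "forest"
  bad2 <- samples; bad2$habitat[samples$population_id == "pop01"] <- "forest"
  write.csv(bad2, sf, row.names = FALSE)
  write.csv(bad, tf, row.names = FALSE)
  expect_error(readMetadata(sf, tf), "unknown habitat label 'forest'")
  expect_silent(readMetadata(sf, tf, freeLabels = TRUE))
  unlink(c(sf, tf))
})

test_that("empty metadata yields empty tables with a warning", {
  sf <- tempfile(fileext = ".csv"); tf <- tempfile(fileext = ".csv")
  writeLines("sample_id,population_id,habitat", sf)
  writeLines("population_id,habitat,latitude,longitude", tf)
  expect_warning(meta <- readMetadata(sf, tf), "empty metadata")
  expect_equal(nrow(meta$samples), 0L)
  expect_equal(nrow(meta$sites), 0L)
  unlink(c(sf, tf))
})

test_that("coordinate and Ellenberg ranges are enforced", {
  samples <- data.frame(sample_id = c("a", "b"), population_id = "p1",
                        habitat = "CG")
  sites <- data.frame(population_id = "p1", habitat = "CG",
                      latitude = 95, longitude = 9)
  expect_error(validateMetadata(samples, sites), "coordinates out of range")
  sites$latitude <- 48; sites$eiv_M <- 12
  expect_error(validateMetadata(samples, sites), "eiv_M")
})

test_that("matrices are re-indexed to the authoritative metadata order", {
  x <- randomMarkerMatrix(4, 3)
  samples <- data.frame(sample_id = c("s03", "s01", "s04", "s02"),
                        population_id = "p1", habitat = "CG")
  y <- alignToMetadata(x, samples)
  expect_identical(sampleIDs(y), samples$sample_id)
  expect_identical(markerValues(y)["s03", ], markerValues(x)["s03", ])
  expect_error(alignToMetadata(x, data.frame(sample_id = "s99")),
               "lacks sample 's99'")
})

test_that("subepilocus CSVs preserve class and fragment annotation", {
  set.seed(3)
  scored <- mixedScoring2(randomProfilePair(6, 10))
  f <- tempfile(fileext = ".csv")
  writeSubepilocusMatrix(scored$subepiloci, f)
  y <- readSubepilocusMatrix(f)
  expect_identical(markerValues(y), markerValues(scored$subepiloci))
  expect_identical(subepilocusClasses(y), subepilocusClasses(scored$subepiloci))
  expect_identical(sourceFragments(y), sourceFragments(scored$subepiloci))
  unlink(f)
})
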