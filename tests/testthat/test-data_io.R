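test_that("canopy_dataset enforces its invariants", {
  d <- canopy_dataset(c("A", "A", "B", "B"), c(1, 2, 1, 2),
                      c(0.4, 0.6, 0.35, 0.55))
  expect_s3_class(d, "canopy_dataset")
  expect_identical(genotypes(d), c("A", "B"))
  expect_identical(n_genotypes(d), 2L)

  expect_error(canopy_dataset("A", 1, 0.5), "at least 2")
  expect_error(canopy_dataset(c("A", "A"), c(1, -1), c(0.4, 0.5)),
               "row\\(s\\): 2")
  expect_error(canopy_dataset(c("A", "A"), c(1, 2), c(0.4, 1.0)),
               "row\\(s\\): 2")
  expect_error(canopy_dataset(character(0), numeric(0), numeric(0)),
               "empty dataset")
  # Empty datasets are allowed with explicit levels (prior-only sampling).
  d0 <- canopy_dataset(character(0), numeric(0), numeric(0),
                       genotype_levels = c("A", "B"))
  expect_identical(n_genotypes(d0), 2L)
  expect_identical(nrow(d0), 0L)
})

test_that("genotype index follows first-appearance order", {
  d <- canopy_dataset(c("Z", "Z", "A", "A", "Z"), c(1, 2, 1, 2, 3),
                      rep(0.5, 5))
  expect_identical(genotypes(d), c("Z", "A"))
  expect_identical(as.integer(d$genotype), c(1L, 1L, 2L, 2L, 1L))
})

test_that("read_canopy_table round-trips, remaps columns and reports errors", {
  d <- canopy_dataset(c("A", "A", "B", "B"), c(1.25, 2.5, 0.75, 6.5),
                      c(0.41, 0.62, 0.23, 0.98), plot = c(1L, 2L, 1L, 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_canopy_table(d, path)
  d2 <- read_canopy_table(path)
  expect_identical(as.data.frame(d2), as.data.frame(d))
  # write -> read -> write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_canopy_table(d2, path2)
  expect_identical(readLines(path), readLines(path2))

  # column remapping
  raw <- read.csv(path)
  names(raw) <- c("hybrid", "LAI", "fIPAR", "plot")
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(raw, path3, row.names = FALSE)
  d3 <- read_canopy_table(path3, column_map = c(genotype = "hybrid",
                                                lai = "LAI", fpari = "fIPAR"))
  expect_equal(d3$lai, d$lai)
  expect_true("plot" %in% names(d3))

  expect_error(read_canopy_table(path3), "genotype")

  # non-numeric cell is reported with its row
  raw$LAI[2] <- "oops"
  write.csv(raw, path3, row.names = FALSE)
  expect_error(read_canopy_table(path3, column_map = c(genotype = "hybrid",
                                                       lai = "LAI",
                                                       fpari = "fIPAR")),
               "lai.*row\\(s\\): 2")

  # header-only file
  writeLines("genotype,lai,fpari", path3)
  expect_error(read_canopy_table(path3), "empty dataset")
})

test_that("validate_dataset reject and clamp policies behave as specified", {
  d <- canopy_dataset(c("A", "A"), c(1, 2), c(0.23, 0.98))
  expect_identical(validate_dataset(d, "reject"), d)       # idempotent
  expect_identical(validate_dataset(validate_dataset(d)), d)

  bad <- data.frame(genotype = c("A", "A"), lai = c(1, 2), fpari = c(0.5, 1.0))
  expect_error(validate_dataset(bad, "reject"), "row\\(s\\): 2")
  expect_warning(fixed <- validate_dataset(bad, "clamp", epsilon = 1e-6),
                 "1 row")
  expect_equal(fixed$fpari[2], 1 - 1e-6)
  # clamp is idempotent after one application
  expect_identical(validate_dataset(fixed, "clamp", epsilon = 1e-6), fixed)

  # clamping never repairs lai
  bad_lai <- data.frame(genotype = c("A", "A"), lai = c(1, -1),
                        fpari = c(0.5, 0.6))
  expect_error(validate_dataset(bad_lai, "clamp"), "lai")
})

test_that("field-derivation formulas compute and guard their domains", {
  expect_equal(leaf_area(80, 9, 0.75), 540)
  expect_equal(leaf_area(1, 1), 0.75)
  expect_error(leaf_area(0, 5), "positive")

  expect_equal(fpari_from_par(2000, 100), 0.95)
  expect_equal(fpari_from_par(2000, 2000), 0)
  expect_error(fpari_from_par(100, 200), "inconsistent")
  expect_error(fpari_from_par(0, 0), "positive")

  expect_equal(lai_from_plants(0.6, 9), 5.4)
  expect_equal(lai_from_plants(7.6 / 12, 12), 7.6)
  expect_error(lai_from_plants(0, 9), "positive")
})
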