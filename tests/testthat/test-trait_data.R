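test_that("a small CSV round-trips through read_trait_table", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession,year,replicate,trait,value",
               "A,2014,1,SL,4.5", "A,2014,2,SL,4.7",
               "A,2014,1,SW,3.1", "A,2014,2,SW,3.2"), p)
  ds <- read_trait_table(p)
  expect_s3_class(ds, "trait_dataset")
  expect_equal(nrow(ds$records), 4L)
  expect_equal(ds$traits, c("SL", "SW"))
  expect_equal(ds$accessions, "A")
})

test_that("schema remapping reads files with foreign headers", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pop,yr,rep,char,obs", "A,2014,1,SL,4.5", "A,2014,2,SL,4.6"), p)
  ds <- read_trait_table(p, schema = c(accession = "pop", year = "yr",
                                       replicate = "rep", trait = "char",
                                       value = "obs"))
  expect_equal(ds$records$value, c(4.5, 4.6))
  expect_error(read_trait_table(p), "column 'accession' not found")
})

test_that("malformed input is rejected with a precise message", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession,year,replicate,trait,value",
               "A,2014,1,SL,4.5", "A,2014,2,SL,4.6", "A,2014,3,SL,abc"), p)
  expect_error(read_trait_table(p), "non-numeric value 'abc' in row 3")

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession,year,replicate,trait,value",
               "A,2014,1,SL,4.5", "A,2014,1,SL,4.6"), p2)
  expect_error(read_trait_table(p2), "duplicate record key \\(A, 2014, 1, SL\\)")

  expect_error(trait_dataset(data.frame(accession = "A", year = 2014,
                                        replicate = 1, trait = "SL",
                                        value = Inf)),
               "non-finite")
})

test_that("write/read is the identity at full float precision", {
  set.seed(1)
  ds <- demo_seed_dataset(seed = 3)
  p <- withr::local_tempfile(fileext = ".csv")
  write_trait_table(ds, p)
  ds2 <- read_trait_table(p)
  expect_identical(ds2$records$value, ds$records$value)
  expect_identical(ds2$records$accession, ds$records$accession)
  expect_equal(ds2$traits, ds$traits)

  # writing is byte-stable
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_trait_table(ds, p2)
  expect_identical(readBin(p, "raw", file.size(p)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("unicode accession names survive the round trip", {
  df <- data.frame(accession = c("林芝", "山南,谷"), year = 2014L,
                   replicate = 1L, trait = "SL", value = c(4.5, 4.6),
                   stringsAsFactors = FALSE)
  ds <- trait_dataset(df)
  p <- withr::local_tempfile(fileext = ".csv")
  write_trait_table(ds, p)
  ds2 <- read_trait_table(p)
  expect_identical(ds2$accessions, ds$accessions)
})

test_that("an empty dataset cannot be built or written", {
  empty <- data.frame(accession = character(), year = integer(),
                      replicate = integer(), trait = character(),
                      value = numeric())
  expect_error(trait_dataset(empty), "no records")
})

test_that("validate_design reports the trial layout and balance", {
  ds <- demo_seed_dataset(seed = 5)
  d <- validate_design(ds)
  expect_equal(d$n_accessions, 15L)
  expect_equal(d$nl, 2L)
  expect_equal(d$nr, 3L)
  expect_true(d$balanced)
  expect_equal(nrow(d$missing_cells), 0L)

  # deleting one record breaks balance and flags exactly that cell
  ds2 <- trait_dataset(ds$records[-1L, , drop = FALSE])
  d2 <- validate_design(ds2)
  expect_false(d2$balanced)
  expect_equal(nrow(d2$missing_cells), 1L)
  expect_equal(d2$missing_cells$n_records, 2L)

  # single-year subset
  d3 <- validate_design(trait_dataset(ds$records[ds$records$year == 2014, ]))
  expect_equal(d3$nl, 1L)
})

test_that("validate_design is invariant to record order", {
  ds <- demo_seed_dataset(seed = 8)
  ds_miss <- trait_dataset(ds$records[-c(5L, 100L), , drop = FALSE])
  for (x in list(ds, ds_miss)) {
    d1 <- validate_design(x)
    d2 <- validate_design(shuffle_records(x, seed = 99))
    expect_equal(d1$n_accessions, d2$n_accessions)
    expect_equal(d1$nl, d2$nl)
    expect_equal(d1$nr, d2$nr)
    expect_equal(d1$balanced, d2$balanced)
    expect_equal(d1$missing_cells, d2$missing_cells)
  }
})

test_that("every simulated design validates to its configuration", {
  for (seed in 1:3) {
    a <- 3L + seed; nr <- 1L + seed
    cfg <- sim_config(list(trait_spec("x", 1, 0.1, 0.01, 0.2),
                           trait_spec("y", 2, 0.2, 0, 0.1)),
                      n_accessions = a, years = c(2000L, 2001L, 2002L),
                      nr = nr, seed = seed)
    d <- validate_design(simulate_dataset(cfg))
    expect_equal(d$n_accessions, a)
    expect_equal(d$nl, 3L)
    expect_equal(d$nr, nr)
    expect_true(d$balanced)
  }
})

test_that("site metadata reader validates structure", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession,altitude,tmax", "A,3600,18.2", "B,4100,15.9"), p)
  sm <- read_site_metadata(p)
  expect_s3_class(sm, "site_metadata")
  expect_equal(sm$altitude, c(3600, 4100))
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("accession,altitude", "A,3600", "A,4100"), p2)
  expect_error(read_site_metadata(p2), "duplicate accession")
})
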