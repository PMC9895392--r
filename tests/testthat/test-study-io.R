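test_that("read_study_table parses rows in order and validates the schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "study_id,timing,level,n_case,mean_case,sd_case,n_control,mean_control,sd_control",
    "GSE154377,middle,mRNA,7,0.714,0.951,9,1.333,2.958",
    "Tang,late,protein,130,114.787,47.627,130,81.381,32.558"), path)
  coll <- read_study_table(path)
  expect_s3_class(coll, "study_collection")
  expect_equal(nrow(coll), 2L)
  expect_equal(coll$study_id, c("GSE154377", "Tang"))
  expect_equal(coll$n_case[1], 7)
  expect_equal(coll$mean_case[1], 0.714)
  expect_equal(coll$sd_control[1], 2.958)
  # missing metadata becomes the not-available marker
  expect_equal(unique(coll$excludes_confounders), "not_available")

  # header-only file -> zero records
  writeLines(
    "study_id,timing,level,n_case,mean_case,sd_case,n_control,mean_control,sd_control",
    path)
  expect_equal(nrow(read_study_table(path)), 0L)
})

test_that("read_study_table errors name the offending column or row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "study_id,timing,level,n_case,mean_case,sd_case,n_control,mean_control",
    "S1,late,mRNA,5,1,1,5,1"), path)
  expect_error(read_study_table(path), "sd_control")

  writeLines(c(
    "study_id,timing,level,n_case,mean_case,sd_case,n_control,mean_control,sd_control",
    "S1,late,mRNA,0,1,1,5,1,1"), path)
  expect_error(read_study_table(path), "row 1.*n_case.*positive integer")

  writeLines(c(
    "study_id,timing,level,n_case,mean_case,sd_case,n_control,mean_control,sd_control",
    "S1,late,mRNA,5,1,abc,5,1,1"), path)
  expect_error(read_study_table(path), "row 1.*non-numeric")

  writeLines(c(
    "study_id,timing,level,n_case,mean_case,sd_case,n_control,mean_control,sd_control",
    "S1,late,mRNA,5,1,-0.2,5,1,1"), path)
  expect_error(read_study_table(path), "sd must be non-negative")

  expect_error(read_study_table(file.path(tempdir(), "nope.csv")),
               "file not found")
})

test_that("study_collection enforces domain invariants", {
  df <- make_study_df(2)
  expect_silent(study_collection(df))
  bad <- df; bad$timing[1] <- "early"
  expect_error(study_collection(bad), "timing")
  bad <- df; bad$study_id[2] <- bad$study_id[1]
  expect_error(study_collection(bad), "duplicate")
  # same id in different strata is allowed (GSE154377 pattern)
  ok <- df; ok$study_id[2] <- ok$study_id[1]; ok$timing[2] <- "middle"
  expect_silent(study_collection(ok))
})

test_that("fixture strata have the published record counts and tallies", {
  ml <- load_gdf15_fixture("mRNA", "late")
  expect_equal(nrow(ml), 12L)
  expect_equal(sum(ml$n_case), 142)
  expect_equal(sum(ml$n_control), 313)

  mm <- load_gdf15_fixture("mRNA", "middle")
  expect_equal(nrow(mm), 1L)
  expect_equal(mm$study_id, "GSE154377")
  expect_equal(unlist(mm[, c("n_case", "mean_case", "sd_case")],
                      use.names = FALSE), c(7, 0.714, 0.951))

  pl <- load_gdf15_fixture("protein", "late")
  expect_equal(nrow(pl), 4L)
  banerjee <- pl[pl$study_id == "Banerjee", ]
  expect_equal(unlist(banerjee[, c("n_case", "mean_case", "sd_case")],
                      use.names = FALSE), c(23, 1091.6, 115.4))
  expect_equal(unlist(banerjee[, c("n_control", "mean_control", "sd_control")],
                      use.names = FALSE), c(20, 828.5, 160.0))

  pm <- load_gdf15_fixture("protein", "middle")
  expect_equal(nrow(pm), 3L)
  expect_equal(sum(pm$n_case), 412)
  expect_equal(sum(pm$n_control), 421)

  all_rows <- load_gdf15_fixture()
  expect_equal(sum(all_rows$n_case), 789)
  expect_equal(sum(all_rows$n_control), 1202)

  expect_error(load_gdf15_fixture("metabolite"), "arg")
})

test_that("filter_studies subsets on metadata, preserving order", {
  ml <- load_gdf15_fixture("mRNA", "late")
  restricted <- filter_studies(ml, excludes_confounders = "yes")
  expect_equal(restricted$study_id,
               c("GSE70493", "GSE65737", "GSE128381", "GSE154377",
                 "GSE203346"))
  expect_equal(sum(restricted$n_case), 95)
  expect_equal(sum(restricted$n_control), 267)

  pm <- load_gdf15_fixture("protein", "middle")
  rpm <- filter_studies(pm, excludes_confounders = "yes")
  expect_equal(rpm$study_id, c("Tang", "Li"))
  expect_equal(sum(rpm$n_case), 400)

  # tautological predicate is the identity
  expect_equal(as.data.frame(filter_studies(ml)), as.data.frame(ml))
  # empty result is valid
  expect_equal(nrow(filter_studies(ml, timing = "middle")), 0L)
})

test_that("sequential filters compose like a conjunction", {
  all_rows <- load_gdf15_fixture()
  two_step <- filter_studies(filter_studies(all_rows, level = "protein"),
                             excludes_confounders = "yes")
  one_step <- filter_studies(all_rows, level = "protein",
                             excludes_confounders = "yes")
  expect_equal(as.data.frame(two_step), as.data.frame(one_step))
})

test_that("write then read round-trips every field", {
  path <- withr::local_tempfile(fileext = ".csv")
  for (coll in list(load_gdf15_fixture(),
                    simulate_collection(sim_config(k = 4, seed = 11)))) {
    write_study_table(coll, path)
    back <- read_study_table(path)
    expect_equal(as.data.frame(back), as.data.frame(coll))
  }
})
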