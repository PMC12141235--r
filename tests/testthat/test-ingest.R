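test_that("an empty file with header only yields no records and n_read = 0", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("province,vegetable,year,batch_id,pesticide,concentration,unit", f)
  recs <- read_inspection_records(f)
  expect_equal(nrow(recs), 0)
  expect_equal(cleaning_report(recs)$n_read, 0)
})

test_that("cleaning drops malformed rows and the report reconciles", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "province,vegetable,year,batch_id,pesticide,concentration,unit",
    "Hebei,leek,2021,b1,clothianidin,0.5,mg/kg",
    "Hebei,leek,2021,b1,procymidone,500,μg/kg",     # unit conversion
    "Hebei,Chilli,2021,b2,chlorpyrifos,0.05,ppm",        # synonym mapping
    "Hebei,leek,2021,b3,,,",                             # no detection: kept
    "Hebei,leek,2021,b4,clothianidin,,mg/kg",            # missing concentration
    "Hebei,leek,2021,b5,clothianidin,0.2,oz/bushel",     # unknown unit
    "Hebei,dragonfruit,2021,b6,clothianidin,0.2,mg/kg",  # unmapped vegetable
    "Hebei,leek,2019,b7,clothianidin,0.2,mg/kg",         # outside study window
    ",leek,2021,b8,clothianidin,0.2,mg/kg",              # missing province
    "Hebei,leek,2021,b9,clothianidin,-1,mg/kg"           # negative concentration
  ), f)
  expect_warning(recs <- read_inspection_records(f), "unsupported")
  rep <- cleaning_report(recs)

  expect_equal(rep$n_read, 10)
  expect_equal(rep$n_kept, 4)
  expect_equal(rep$n_dropped_missing, 3)
  expect_equal(rep$n_dropped_unmapped_name, 1)
  expect_equal(rep$n_dropped_bad_unit, 1)
  expect_equal(rep$n_dropped_out_of_window, 1)
  expect_equal(rep$n_unit_converted, 1)
  # conservation: every input row is accounted for
  drop_cols <- grep("^n_dropped", names(rep), value = TRUE)
  expect_equal(rep$n_read, rep$n_kept + sum(rep[drop_cols]))

  # ug/kg converted, ppm identity, synonym collapsed
  expect_equal(recs$concentration[recs$batch_id == "b1" &
                                    recs$pesticide == "procymidone"], 0.5)
  expect_equal(recs$vegetable[recs$batch_id == "b2"], "pepper")
  expect_true(is.na(recs$pesticide[recs$batch_id == "b3"]))
})

test_that("cleaning-report conservation holds across random messy inputs", {
  for (seed in 1:5) {
    raw <- withr::with_seed(seed, {
      n <- 300
      tibble::tibble(
        province = sample(c("Hebei", "Hunan", NA), n, replace = TRUE),
        vegetable = sample(c("leek", "tomato", "nopeberry", NA), n,
                           replace = TRUE),
        year = sample(c(2019:2024, NA), n, replace = TRUE),
        batch_id = sprintf("b%03d", sample(n)),
        pesticide = sample(c("clothianidin", "mysterycide", NA), n,
                           replace = TRUE),
        concentration = ifelse(runif(n) < 0.15, NA,
                               round(stats::rlnorm(n, -2, 1), 4)),
        unit = sample(c("mg/kg", "μg/kg", "ppm", "stone/acre", NA), n,
                      replace = TRUE)
      )
    })
    rep <- suppressWarnings(cleaning_report(clean_inspection_records(raw)))
    drop_cols <- grep("^n_dropped", names(rep), value = TRUE)
    expect_equal(rep$n_read, rep$n_kept + sum(rep[drop_cols]))
  }
})

test_that("canonicalization is deterministic, idempotent, and flags unmapped", {
  dict <- vegetable_dictionary()
  expect_equal(canonicalize_names("leek", dict), "leek")
  # two distinct aliases collapse to one category
  expect_equal(canonicalize_names(c("Chilli", "hot  pepper"), dict),
               c("pepper", "pepper"))
  expect_true(is.na(canonicalize_names("starfruit", dict)))
  x <- c("Chilli", "tomatoes", "leek", "starfruit")
  once <- canonicalize_names(x, dict)
  expect_identical(canonicalize_names(once, dict), once)
})

test_that("concentration normalization handles the supported unit dialects", {
  expect_equal(normalize_concentration(0.5, "mg/kg"), 0.5)
  expect_equal(normalize_concentration(500, "μg/kg"), 0.5)
  expect_equal(normalize_concentration(500, "ug/kg"), 0.5)
  expect_equal(normalize_concentration(2, "ppm"), 2.0)
  expect_warning(out <- normalize_concentration(1, "mol/l"), "unsupported")
  expect_true(is.na(out))
})

test_that("write/read round-trip reproduces the cleaned record set", {
  sim <- generate_inspection_data(survey_scenario(3, scale = 0.05))
  recs <- clean_inspection_records(sim$records)
  f <- withr::local_tempfile(fileext = ".csv")
  write_inspection_records(recs, f)
  back <- read_inspection_records(f)
  ord <- function(d) dplyr::arrange(tibble::as_tibble(d), batch_id, pesticide)
  expect_equal(ord(back), ord(recs), ignore_attr = TRUE)
  expect_equal(cleaning_report(back)$n_kept, nrow(recs))
})

test_that("a batch_id spanning two batches is rejected", {
  raw <- tibble::tibble(
    province = c("Hebei", "Hunan"), vegetable = "leek", year = 2021,
    batch_id = "b1", pesticide = "clothianidin", concentration = 0.1,
    unit = "mg/kg"
  )
  expect_error(clean_inspection_records(raw), "more than one batch")
})

test_that("the optional outlier cap drops extreme ratios and counts them", {
  raw <- tibble::tibble(
    province = "Hebei", vegetable = "leek", year = 2021,
    batch_id = c("b1", "b2"), pesticide = "clothianidin",
    concentration = c(0.1, 5000), unit = "mg/kg"
  )
  mrl <- make_mrl("clothianidin")
  kept <- clean_inspection_records(raw, outlier_cap = 1000, mrl = mrl)
  expect_equal(nrow(kept), 1)
  expect_equal(cleaning_report(kept)$n_dropped_outlier, 1)
  # off by default: nothing dropped
  expect_equal(nrow(clean_inspection_records(raw)), 2)
})

test_that("match_mrl binds every measurement to a limit state", {
  recs <- tibble::tibble(
    province = "hebei", vegetable = "leek", year = 2021L,
    batch_id = c("b1", "b1", "b2", "b3"),
    pesticide = c("clothianidin", "chlorpyrifos", "mystery", NA),
    concentration = c(0.1, 0.02, 0.3, NA)
  )
  mrl <- tibble::tibble(
    vegetable = "leek", pesticide = c("clothianidin", "chlorpyrifos"),
    mrl_mg_per_kg = c(0.2, NA), banned = c(FALSE, TRUE)
  )
  bound <- match_mrl(recs, mrl)
  expect_equal(bound$binding,
               c("limit", "banned", "no_limit", "none"))
  expect_equal(bound$mrl[1], 0.2)
  expect_true(bound$banned[2])
})

test_that("geo and MRL table validation rejects bad inputs", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("province,longitude_e,latitude_n", "nowhere,200,10"), f)
  expect_error(read_geo_table(f), "out of range")
  expect_error(
    validate_mrl_table(tibble::tibble(vegetable = "x", pesticide = "y",
                                      mrl_mg_per_kg = 0, banned = 0)),
    "positive")
  expect_error(
    validate_mrl_table(tibble::tibble(vegetable = "x", pesticide = "y",
                                      mrl_mg_per_kg = NA, banned = 0)),
    "banned")
})
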