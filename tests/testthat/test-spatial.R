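test_that("a single province with positive risk puts the centroid at its capital", {
  geo <- province_capitals()
  cent <- risk_centroid(tibble::tibble(province = "jiangsu", ir = 0.4), geo)
  cap <- geo[geo$province == "jiangsu", ]
  expect_equal(cent$longitude, cap$longitude_e)
  expect_equal(cent$latitude, cap$latitude_n)
  expect_equal(cent$n_provinces, 1)
})

test_that("two provinces with equal risk give the coordinate midpoint", {
  geo <- province_capitals()
  cent <- risk_centroid(
    tibble::tibble(province = c("jiangsu", "yunnan"), ir = c(0.2, 0.2)), geo)
  caps <- geo[match(c("jiangsu", "yunnan"), geo$province), ]
  expect_equal(cent$longitude, mean(caps$longitude_e))
  expect_equal(cent$latitude, mean(caps$latitude_n))
})

test_that("randomized weights match the explicit normalized weighted sum", {
  geo <- province_capitals()
  for (seed in 1:5) {
    pr <- withr::with_seed(seed, tibble::tibble(
      province = sample(geo$province, 12),
      ir = round(runif(12, 0, 2), 4)
    ))
    cent <- risk_centroid(pr, geo)
    m <- dplyr::left_join(pr, geo, by = "province")
    w <- m$ir / sum(m$ir)
    expect_equal(cent$longitude, sum(w * m$longitude_e))
    expect_equal(cent$latitude, sum(w * m$latitude_n))
    # containment in the bounding box of contributing capitals
    keep <- m$ir > 0
    expect_gte(cent$longitude, min(m$longitude_e[keep]))
    expect_lte(cent$longitude, max(m$longitude_e[keep]))
    expect_gte(cent$latitude, min(m$latitude_n[keep]))
    expect_lte(cent$latitude, max(m$latitude_n[keep]))
  }
})

test_that("degenerate centroid inputs raise named errors", {
  geo <- province_capitals()
  expect_error(
    risk_centroid(tibble::tibble(province = "jiangsu", ir = 0), geo),
    "centroid undefined")
  expect_error(
    risk_centroid(tibble::tibble(province = "atlantis", ir = 1), geo),
    "atlantis")
})

test_that("haversine distance agrees with a hand-coded oracle and is metric", {
  pts <- withr::with_seed(31, tibble::tibble(
    lon = runif(30, 80, 130), lat = runif(30, 18, 50)))
  a <- pts[1:10, ]; b <- pts[11:20, ]; c <- pts[21:30, ]
  d_ab <- haversine_km(a$lon, a$lat, b$lon, b$lat)
  expect_equal(d_ab, oracle_haversine_km(a$lon, a$lat, b$lon, b$lat),
               tolerance = 1e-9)
  # symmetry, identity, triangle inequality
  expect_equal(d_ab, haversine_km(b$lon, b$lat, a$lon, a$lat))
  expect_equal(haversine_km(a$lon, a$lat, a$lon, a$lat), rep(0, 10))
  d_ac <- haversine_km(a$lon, a$lat, c$lon, c$lat)
  d_cb <- haversine_km(c$lon, c$lat, b$lon, b$lat)
  expect_true(all(d_ab <= d_ac + d_cb + 1e-9))
})

test_that("transfer reproduces degree distance, bearing and locus labels", {
  cents <- tibble::tibble(year = c(2021L, 2023L),
                          longitude = c(114.48, 113.28),
                          latitude = c(33.70, 32.97))
  tr <- centroid_transfer(cents)
  expect_equal(tr$d_degrees, sqrt(1.20^2 + 0.73^2), tolerance = 1e-4)
  expect_equal(tr$d_degrees, 1.4046, tolerance = 1e-4)
  expect_equal(tr$label, "Northeast to Southwest")

  up <- centroid_transfer(tibble::tibble(
    year = c(2021L, 2023L), longitude = c(113.58, 114.80),
    latitude = c(34.08, 35.10)))
  expect_equal(up$bearing, (atan2(1.22, 1.02) * 180 / pi) %% 360)
  expect_equal(up$bearing, 50.1, tolerance = 0.05)
  expect_equal(up$label, "Southwest to Northeast")
})

test_that("zero displacement yields zero distance and undefined bearing", {
  tr <- centroid_transfer(tibble::tibble(
    year = c(2021L, 2022L), longitude = 110, latitude = 30))
  expect_equal(tr$d_degrees, 0)
  expect_equal(tr$d_km, 0)
  expect_true(is.na(tr$bearing))
  expect_true(is.na(tr$label))
})

test_that("pure-cardinal displacements use cardinal names", {
  north <- centroid_transfer(tibble::tibble(
    year = c(2021L, 2022L), longitude = 110, latitude = c(30, 31)))
  expect_equal(north$label, "South to North")
  expect_equal(north$bearing, 0)
  west <- centroid_transfer(tibble::tibble(
    year = c(2021L, 2022L), longitude = c(110, 109), latitude = 30))
  expect_equal(west$label, "East to West")
  expect_equal(west$bearing, 270)
})

test_that("printed yearly centroid coordinates reproduce the published trajectory", {
  cents <- centroid_table()
  tr <- cents |>
    dplyr::rename(longitude = longitude_e, latitude = latitude_n) |>
    centroid_transfer()
  published <- tibble::tribble(
    ~scope,           ~label,                   ~d_km,
    "all vegetables", "Northeast to Southwest", 137.61,
    "leek",           "Southwest to Northeast", 159.65,
    "cowpea",         "Northeast to Southwest", 100.91,
    "ginger",         "Southwest to Northeast", 375.68,
    "celery",         "Northeast to Southwest", 230.25,
    "spinach",        "Northwest to Southeast", 122.36
  )
  j <- dplyr::inner_join(tr, published, by = "scope",
                         suffix = c("", "_pub"))
  expect_equal(nrow(j), 6)
  expect_equal(j$label, j$label_pub)
  expect_true(all(abs(j$d_km - j$d_km_pub) / j$d_km_pub < 0.01))
})

test_that("centroid_track runs the spatial stage end-to-end", {
  run <- assess_samples(match_mrl(
    clean_inspection_records(
      generate_inspection_data(survey_scenario(5, scale = 0.1))$records),
    generate_inspection_data(survey_scenario(5, scale = 0.1))$mrl))
  track <- centroid_track(run)
  expect_equal(nrow(track$centroids), 3)
  expect_equal(track$transfers$from_year, c(2021L, 2022L))
  # centroid contained in the capitals' bounding box
  geo <- province_capitals()
  expect_true(all(track$centroids$longitude >= min(geo$longitude_e) &
                    track$centroids$longitude <= max(geo$longitude_e)))
})
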