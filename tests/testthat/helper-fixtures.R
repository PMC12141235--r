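# in-code fixture builders shared across test files

# measurement rows for a single-vegetable batch set
make_records <- function(batch_hazards, vegetable = "leek",
                         province = "demo", year = 2021L, mrl = 1) {
  rows <- purrr::imap(batch_hazards, function(conc, i) {
    tibble::tibble(
      province = province, vegetable = vegetable, year = year,
      batch_id = sprintf("%s-%03d", province, i),
      pesticide = if (length(conc) == 0) NA_character_ else
        paste0("pest", seq_along(conc)),
      concentration = if (length(conc) == 0) NA_real_ else conc
    )
  })
  dplyr::bind_rows(rows)
}

make_mrl <- function(pesticides = paste0("pest", 1:8), vegetable = "leek",
                     mrl = 1, banned = FALSE) {
  tibble::tibble(vegetable = vegetable, pesticide = pesticides,
                 mrl_mg_per_kg = mrl, banned = banned)
}

# random multi-pesticide samples plus an independent brute-force oracle
random_sample_set <- function(n_batches, n_pesticides = 5, seed = 1) {
  withr::with_seed(seed, {
    mrl <- tibble::tibble(
      vegetable = "veg",
      pesticide = paste0("p", seq_len(n_pesticides)),
      mrl_mg_per_kg = round(runif(n_pesticides, 0.05, 2), 3),
      banned = FALSE
    )
    rows <- purrr::map(seq_len(n_batches), function(i) {
      k <- sample(n_pesticides, sample(n_pesticides, 1))
      tibble::tibble(
        province = "prov", vegetable = "veg", year = 2022L,
        batch_id = sprintf("b%05d", i),
        pesticide = paste0("p", k),
        concentration = round(stats::rlnorm(length(k), -1, 1.2), 4)
      )
    })
    list(records = dplyr::bind_rows(rows), mrl = mrl)
  })
}

# per-batch oracle: loop over every measurement, every ratio, take the max
brute_force_assess <- function(records, mrl) {
  limits <- stats::setNames(mrl$mrl_mg_per_kg, mrl$pesticide)
  split(records, records$batch_id) |>
    purrr::map(function(b) {
      ratios <- b$concentration / limits[b$pesticide]
      viol <- ratios > 1
      tibble::tibble(batch_id = b$batch_id[1],
                     compliant = !any(viol),
                     hazard = if (any(viol)) max(ratios[viol]) else 0)
    }) |>
    dplyr::bind_rows()
}

# hand-coded haversine, independent of the geosphere-backed implementation
oracle_haversine_km <- function(lon1, lat1, lon2, lat2, r = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# assessment table with known stratum structure, for pooling identities
random_assessments <- function(n_strata, seed = 1) {
  withr::with_seed(seed, {
    strata <- tibble::tibble(
      province = sprintf("prov%02d", sample(40, n_strata, replace = TRUE)),
      vegetable = sprintf("veg%02d", sample(30, n_strata, replace = TRUE)),
      n = sample(5:40, n_strata, replace = TRUE)
    ) |> dplyr::distinct(province, vegetable, .keep_all = TRUE)
    purrr::pmap(strata, function(province, vegetable, n) {
      m <- stats::rbinom(1, n, 0.15)
      hazard <- c(1 + stats::rlnorm(m, 0.5, 0.9), rep(0, n - m))
      tibble::tibble(
        province = province, vegetable = vegetable, year = 2022L,
        batch_id = paste0(province, vegetable, seq_len(n)),
        compliant = hazard == 0, hazard = hazard
      )
    }) |> dplyr::bind_rows()
  })
}

# printed national-level reference tables packaged with vegrisk
national_risk_table <- function() {
  readr::read_csv(vegrisk_example("national_vegetable_risk_2021_2023.csv"),
                  show_col_types = FALSE)
}
centroid_table <- function() {
  readr::read_csv(vegrisk_example("risk_centroids_2021_2023.csv"),
                  show_col_types = FALSE)
}
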