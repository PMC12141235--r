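#' Default pesticide panel for the synthetic generator
#'
#' A small panel of commonly screened compounds with MRL magnitudes typical
#' of national limits for vegetables (mg/kg), one banned pesticide with no
#' limit (any detection of it is a violation), and per-pesticide detection
#' probabilities for compliant sub-limit residues.
#'
#' @return A tibble with columns `pesticide`, `mrl_mg_per_kg`, `banned`,
#'   `p_detect_when_compliant`.
#' @export
default_pesticide_panel <- function() {
  tibble::tribble(
    ~pesticide,      ~mrl_mg_per_kg, ~banned, ~p_detect_when_compliant,
    "clothianidin",  0.2,            FALSE,   0.05,
    "procymidone",   0.2,            FALSE,   0.04,
    "imidacloprid",  0.5,            FALSE,   0.06,
    "acetamiprid",   1.0,            FALSE,   0.04,
    "cypermethrin",  1.0,            FALSE,   0.03,
    "chlorpyrifos",  NA,             TRUE,    0
  )
}

#' Log-scale location for a target mean exceedance multiple
#'
#' The generator draws the exceedance multiple as `1 + LogNormal(mu,
#' sigma)`, guaranteeing strict exceedance (`C > MRL`). This helper returns
#' the `mu` whose shifted log-normal has the requested mean multiple:
#' `mu = log(mean_multiple - 1) - sigma^2 / 2`.
#'
#' @param mean_multiple Target mean of the multiple (must exceed 1).
#' @param log_sd Log-scale standard deviation `sigma`.
#' @return The log-scale mean `mu`.
#' @export
#' @examples
#' mu <- severity_meanlog(5)
#' 1 + exp(mu + 0.8^2 / 2) # back to 5
severity_meanlog <- function(mean_multiple, log_sd = 0.8) {
  stopifnot(all(mean_multiple > 1))
  log(mean_multiple - 1) - log_sd^2 / 2
}

#' Generator configuration
#'
#' Bundles the stratum design, the pesticide panel, geographic reference
#' and seed for [generate_inspection_data()]. Each stratum row describes
#' one province x vegetable x year cell: its sampled batch count, its
#' exceedance probability, and the log-normal parameters of the exceedance
#' multiple.
#'
#' @param strata A tibble with columns `province`, `vegetable`, `year`,
#'   `n_batches`, `p_exceed`, `severity_log_mean`, `severity_log_sd`.
#' @param panel Pesticide panel (see [default_pesticide_panel()]).
#' @param geo Capital coordinates table.
#' @param seed Integer seed fixing the output exactly.
#' @param p_banned_violation Probability that a violating batch's violation
#'   is a banned-pesticide detection rather than an over-limit residue.
#' @param banned_reference_mg_per_kg Reference limit used to scale banned
#'   detection concentrations.
#' @return A list of class `vegrisk_generator_config`.
#' @export
generator_config <- function(strata,
                             panel = default_pesticide_panel(),
                             geo = province_capitals(),
                             seed = 1L,
                             p_banned_violation = 0.12,
                             banned_reference_mg_per_kg = 0.01) {
  strata <- tibble::as_tibble(strata)
  need <- c("province", "vegetable", "year", "n_batches", "p_exceed",
            "severity_log_mean", "severity_log_sd")
  if (!all(need %in% names(strata))) {
    abort(paste0("strata must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(strata$p_exceed < 0 | strata$p_exceed > 1)) {
    abort("p_exceed must lie in [0, 1]")
  }
  if (any(strata$n_batches < 0)) abort("n_batches must be non-negative")
  if (p_banned_violation < 0 || p_banned_violation > 1) {
    abort("p_banned_violation must lie in [0, 1]")
  }
  structure(
    list(strata = strata, panel = tibble::as_tibble(panel), geo = geo,
         seed = as.integer(seed), p_banned_violation = p_banned_violation,
         banned_reference_mg_per_kg = banned_reference_mg_per_kg),
    class = "vegrisk_generator_config"
  )
}

#' Generate a seeded synthetic inspection dataset
#'
#' Emulates a provincial supervision database with known ground truth: per
#' stratum, `n_batches` sampled batches are drawn; each is non-compliant
#' with probability `p_exceed`. A non-compliant batch receives one
#' violating residue with concentration `multiple x limit`, the multiple
#' drawn as `1 + LogNormal(severity_log_mean, severity_log_sd)` (so
#' violations strictly exceed the limit and stratum-mean severities can
#' span the few-to-tens range with a heavy upper tail). Violations are
#' banned-pesticide detections with probability `p_banned_violation`,
#' scaled against the banned reference limit. Compliant residues are drawn
#' sub-limit per the panel's detection probabilities; batches with no
#' detection at all appear as a single empty-measurement row. A small
#' fraction of compliant detections is emitted in ug/kg to exercise unit
#' normalization downstream.
#'
#' The same `seed` reproduces the dataset exactly.
#'
#' @param config A [generator_config()].
#' @param seed Optional override of `config$seed`.
#' @return A list with `records` (raw row dialect consumed by
#'   [clean_inspection_records()]), `mrl` (panel expanded to every
#'   vegetable) and `geo`.
#' @export
generate_inspection_data <- function(config, seed = NULL) {
  stopifnot(inherits(config, "vegrisk_generator_config"))
  seed <- seed %||% config$seed
  panel <- config$panel
  normal <- panel[!panel$banned & !is.na(panel$mrl_mg_per_kg), ]
  banned <- panel[panel$banned, ]
  qref <- config$banned_reference_mg_per_kg

  records <- withr::with_seed(seed, {
    strata <- config$strata
    batches <- strata[rep(seq_len(nrow(strata)), strata$n_batches), ]
    n <- nrow(batches)
    batches$batch_id <- sprintf("B%08d", seq_len(n))
    batches$exceed <- runif(n) < batches$p_exceed

    # one violating residue per non-compliant batch
    viol <- batches[batches$exceed, ]
    viol_rows <- NULL
    if (nrow(viol) > 0) {
      use_banned <- nrow(banned) > 0 &
        runif(nrow(viol)) < config$p_banned_violation
      pest <- sample(normal$pesticide, nrow(viol), replace = TRUE)
      pest[use_banned] <- sample(banned$pesticide, sum(use_banned),
                                 replace = TRUE)
      limit <- normal$mrl_mg_per_kg[match(pest, normal$pesticide)]
      limit[use_banned] <- qref
      multiple <- 1 + rlnorm(nrow(viol), viol$severity_log_mean,
                             viol$severity_log_sd)
      viol_rows <- tibble::tibble(
        province = viol$province, vegetable = viol$vegetable,
        year = viol$year, batch_id = viol$batch_id,
        pesticide = pest, concentration = multiple * limit,
        unit = "mg/kg"
      )
    }

    # sub-limit background detections (never the banned compound)
    bg <- purrr::map(seq_len(nrow(normal)), function(k) {
      hit <- runif(n) < normal$p_detect_when_compliant[k]
      hit <- hit & !batches$exceed
      if (!any(hit)) return(NULL)
      tibble::tibble(
        province = batches$province[hit], vegetable = batches$vegetable[hit],
        year = batches$year[hit], batch_id = batches$batch_id[hit],
        pesticide = normal$pesticide[k],
        concentration = runif(sum(hit), 0.01, 0.95) *
          normal$mrl_mg_per_kg[k],
        unit = "mg/kg"
      )
    })
    rows <- dplyr::bind_rows(c(list(viol_rows), bg))

    # express some compliant detections in ug/kg
    if (nrow(rows) > 0) {
      to_ug <- runif(nrow(rows)) < 0.1 & rows$concentration < 1
      rows$concentration[to_ug] <- rows$concentration[to_ug] * 1000
      rows$unit[to_ug] <- "μg/kg"
    }

    detected <- unique(rows$batch_id)
    quiet <- batches[!batches$batch_id %in% detected, ]
    empty <- tibble::tibble(
      province = quiet$province, vegetable = quiet$vegetable,
      year = quiet$year, batch_id = quiet$batch_id,
      pesticide = NA_character_, concentration = NA_real_, unit = ""
    )
    dplyr::bind_rows(rows, empty) |>
      dplyr::arrange(.data$batch_id, .data$pesticide)
  })

  mrl <- tidyr::expand_grid(
    vegetable = sort(unique(config$strata$vegetable)),
    panel[c("pesticide", "mrl_mg_per_kg", "banned")]
  )
  list(records = records, mrl = mrl, geo = config$geo)
}

#' A packaged study-like surveillance scenario
#'
#' A generator configuration shaped like a national three-year vegetable
#' surveillance campaign: 15 provinces x 12 vegetable categories over
#' 2021-2023, heavily skewed batch counts across categories and provinces,
#' category-specific exceedance probabilities (multi-harvest leafy crops
#' such as leek and cowpea highest) and severity profiles (bean sprout rare
#' but severe), a banned pesticide in circulation, and a planted
#' geographic drift: exceedance risk concentrates in northeastern provinces
#' in 2021 and in southwestern provinces by 2023, so the risk centroid
#' moves from the northeast toward the southwest.
#'
#' @param seed Integer seed (also stored in the returned config).
#' @param scale Multiplier on all batch counts (default 1 gives roughly
#'   30,000 batches over the three years).
#' @return A [generator_config()].
#' @export
survey_scenario <- function(seed = 2021L, scale = 1) {
  provinces <- c("jiangsu", "shandong", "jilin", "heilongjiang", "beijing",
                 "henan", "hubei", "hunan", "shaanxi", "hebei",
                 "chongqing", "sichuan", "guizhou", "yunnan", "guangxi")
  ne <- c("jiangsu", "shandong", "jilin", "heilongjiang", "beijing")
  sw <- c("chongqing", "sichuan", "guizhou", "yunnan", "guangxi")

  veg <- tibble::tribble(
    ~vegetable,        ~weight, ~p_base, ~sev_mean,
    "pepper",          10,      0.029,   3.7,
    "chinese cabbage",  9,      0.013,   7.6,
    "tomato",           9,      0.002,   3.0,
    "eggplant",         8,      0.011,   3.2,
    "celery",           7,      0.036,   8.2,
    "cowpea",           5,      0.074,   8.3,
    "leek",             5,      0.093,   8.8,
    "ginger",           4,      0.081,   4.6,
    "bean sprout",      4,      0.008,  17.6,
    "cucumber",         3,      0.005,   4.8,
    "radish",           3,      0.004,   7.6,
    "spinach",          2,      0.025,   7.7
  )

  strata <- tidyr::expand_grid(
    province = provinces,
    veg,
    year = 2021:2023
  )
  # provincial sampling effort, skewed
  prov_weight <- stats::setNames(
    c(3, 3, 1.5, 1.5, 2.5, 2.5, 1.5, 1.5, 1.2, 1, 4, 1.5, 2, 2.5, 1.3),
    provinces)
  # planted spatial drift of risk: northeast-heavy in 2021, southwest-heavy
  # in 2023
  risk_mult <- function(province, year) {
    hi <- ifelse(year == 2021, province %in% ne,
                 ifelse(year == 2023, province %in% sw,
                        province %in% c("henan", "hubei", "hunan")))
    ifelse(hi, 4, 0.4)
  }
  strata <- withr::with_seed(seed, {
    noise <- rlnorm(nrow(strata), 0, 0.35)
    dplyr::mutate(
      strata,
      n_batches = pmax(5L, as.integer(round(
        6 * scale * .data$weight * prov_weight[.data$province] * noise))),
      p_exceed = pmin(0.29, .data$p_base *
                        risk_mult(.data$province, .data$year)),
      severity_log_mean = severity_meanlog(.data$sev_mean),
      severity_log_sd = 0.8
    )
  })
  generator_config(
    strata = strata[c("province", "vegetable", "year", "n_batches",
                      "p_exceed", "severity_log_mean", "severity_log_sd")],
    seed = seed
  )
}
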