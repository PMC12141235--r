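#' Pipeline run configuration
#'
#' Exactly one input source is active: either the three file paths
#' (`records`, `mrl`, `geo`) of a real surveillance export, or a synthetic
#' `scenario` (the string `"survey"` or a [generator_config()]).
#'
#' @param records,mrl,geo File paths of the inspection-record, MRL and
#'   geographic tables (`geo` defaults to the packaged capitals when
#'   omitted alongside `records`).
#' @param scenario `"survey"` or a [generator_config()].
#' @param seed Integer seed governing all randomness of the run.
#' @param threshold A [risk_threshold()].
#' @param policy A [compliance_policy()].
#' @param s_denominator `"noncompliant"` or `"all"` (see [stratum_risk()]).
#' @param earth_radius_km Mean Earth radius for transfer distances.
#' @param min_n Small-sample flag threshold for strata.
#' @param outdir Optional output directory for the table bundle.
#' @param ... Extra arguments passed to [clean_inspection_records()] /
#'   [read_inspection_records()] (e.g. `outlier_cap`, dictionaries).
#' @return A list of class `vegrisk_run_config`.
#' @export
run_config <- function(records = NULL, mrl = NULL, geo = NULL,
                       scenario = NULL, seed = 1L,
                       threshold = risk_threshold(),
                       policy = compliance_policy(),
                       s_denominator = c("noncompliant", "all"),
                       earth_radius_km = 6371, min_n = 10,
                       outdir = NULL, ...) {
  s_denominator <- match.arg(s_denominator)
  if (is.null(records) == is.null(scenario)) {
    abort("exactly one of `records` (file input) or `scenario` must be given")
  }
  if (!is.null(records) && is.null(mrl)) {
    abort("file input requires an `mrl` table path")
  }
  structure(
    list(records = records, mrl = mrl, geo = geo, scenario = scenario,
         seed = as.integer(seed), threshold = threshold, policy = policy,
         s_denominator = s_denominator, earth_radius_km = earth_radius_km,
         min_n = min_n, outdir = outdir, ingest_args = list(...)),
    class = "vegrisk_run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[stage ", name, "] ", conditionMessage(e)))
  })
}

#' Run the full residue-risk pipeline
#'
#' Orchestrates ingestion/generation, MRL matching, batch assessment,
#' stratum and aggregate risk indices, composition and descriptive tables,
#' and the spatial centroid trajectory. Any stage failure aborts with a
#' stage-named error. With `outdir` set, the table bundle and a run
#' manifest (config, seed, package version) are written as plain-text
#' files; re-running with the same configuration and seed reproduces them
#' exactly.
#'
#' @param config A [run_config()].
#' @return An object of class `vegrisk_run`: a list with the cleaning
#'   report, assessments, strata, vegetable- and province-level tables,
#'   composition and descriptive tables, centroids and transfers, and the
#'   manifest. Supports [tidy()], [glance()], [autoplot()].
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(run_config(scenario = survey_scenario(1),
#'                                seed = 1))
#' glance(run)
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "vegrisk_run_config"))

  ing <- stage("ingest", {
    if (!is.null(config$scenario)) {
      scen <- config$scenario
      if (identical(scen, "survey")) {
        scen <- survey_scenario(config$seed)
      }
      sim <- generate_inspection_data(scen, seed = config$seed)
      records <- do.call(clean_inspection_records,
                         c(list(sim$records), config$ingest_args))
      list(records = records, mrl = sim$mrl, geo = sim$geo)
    } else {
      records <- do.call(read_inspection_records,
                         c(list(config$records), config$ingest_args))
      geo <- if (is.null(config$geo)) province_capitals() else
        read_geo_table(config$geo)
      list(records = records, mrl = read_mrl_table(config$mrl), geo = geo)
    }
  })

  assessments <- stage("compliance", {
    assess_samples(match_mrl(ing$records, ing$mrl), config$policy)
  })

  risk <- stage("risk", {
    strata <- stratum_risk(assessments,
                           s_denominator = config$s_denominator,
                           min_n = config$min_n)
    list(
      strata = strata,
      vegetable = aggregate_risk(strata, "vegetable", config$threshold),
      province = aggregate_risk(strata, "province", config$threshold),
      descriptive = descriptive_stats(strata),
      composition = composition_stats(assessments)
    )
  })

  spatial <- stage("spatial", {
    if (all(assessments$compliant) ||
        length(unique(assessments$year)) < 2) {
      list(centroids = tibble::tibble(), transfers = tibble::tibble())
    } else {
      centroid_track(assessments, ing$geo,
                     s_denominator = config$s_denominator,
                     threshold = config$threshold,
                     earth_radius_km = config$earth_radius_km)
    }
  })

  manifest <- list(
    package = "vegrisk",
    version = as.character(utils::packageVersion("vegrisk")),
    seed = config$seed,
    input = if (is.null(config$scenario)) "files" else "scenario",
    s_denominator = config$s_denominator,
    ir0 = config$threshold$ir0,
    earth_radius_km = config$earth_radius_km,
    n_batches = nrow(assessments),
    n_noncompliant = sum(!assessments$compliant)
  )

  run <- structure(
    list(cleaning_report = cleaning_report(ing$records),
         records = ing$records, mrl = ing$mrl, geo = ing$geo,
         assessments = assessments, strata = risk$strata,
         vegetable_risk = risk$vegetable, province_risk = risk$province,
         descriptive = risk$descriptive, composition = risk$composition,
         centroids = spatial$centroids, transfers = spatial$transfers,
         threshold = config$threshold, manifest = manifest),
    class = "vegrisk_run"
  )

  if (!is.null(config$outdir)) {
    stage("report", write_run_bundle(run, config$outdir))
  }
  run
}

#' Write the output bundle of a pipeline run
#'
#' @param run A `vegrisk_run`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run_bundle <- function(run, outdir) {
  stopifnot(inherits(run, "vegrisk_run"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_csv(tibble::as_tibble(x),
                                       file.path(outdir, f),
                                       na = "", progress = FALSE)
  w(run$cleaning_report, "cleaning_report.csv")
  w(run$assessments, "assessments.csv")
  w(run$strata, "strata.csv")
  w(format_risk_table(run$vegetable_risk), "vegetable_risk.csv")
  w(format_risk_table(run$province_risk), "province_risk.csv")
  w(run$descriptive, "descriptive_stats.csv")
  w(run$composition$batches_by_vegetable, "composition_batches_by_vegetable.csv")
  w(run$composition$batches_by_province, "composition_batches_by_province.csv")
  w(run$composition$exceedance_by_pesticide, "composition_exceedance_by_pesticide.csv")
  w(run$composition$exceedance_by_vegetable, "composition_exceedance_by_vegetable.csv")
  w(run$centroids, "centroids.csv")
  w(run$transfers, "centroid_transfers.csv")
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.vegrisk_run <- function(x, ...) {
  m <- x$manifest
  cat("<vegrisk_run>\n")
  cat(sprintf("  batches: %d (%d non-compliant, %.2f%%)\n",
              m$n_batches, m$n_noncompliant,
              100 * m$n_noncompliant / max(m$n_batches, 1)))
  cat(sprintf("  strata: %d | vegetables: %d | provinces: %d\n",
              nrow(x$strata), nrow(x$vegetable_risk),
              nrow(x$province_risk)))
  cat(sprintf("  high-risk vegetables (IR >= %.3g): %d\n",
              x$threshold$ir0,
              sum(x$vegetable_risk$risk_class == "high")))
  if (nrow(x$transfers) > 0) {
    last <- x$transfers[nrow(x$transfers), ]
    cat(sprintf("  centroid %d -> %d: %s, %.2f km\n", last$from_year,
                last$to_year, last$label, last$d_km))
  }
  invisible(x)
}

#' Tidy a pipeline run into its stratum table
#'
#' @param x A `vegrisk_run`.
#' @param ... Unused.
#' @return The stratum-level tibble (province, vegetable, n, m, p, s, ir).
#' @method tidy vegrisk_run
#' @export
tidy.vegrisk_run <- function(x, ...) {
  x$strata
}

#' One-row summary of a pipeline run
#'
#' @param x A `vegrisk_run`.
#' @param ... Unused.
#' @return A one-row tibble: batch counts, overall exceedance probability,
#'   severity and risk index, and high-risk category counts.
#' @method glance vegrisk_run
#' @export
glance.vegrisk_run <- function(x, ...) {
  n <- nrow(x$assessments)
  m <- sum(!x$assessments$compliant)
  p <- m / n
  s_den <- attr(x$strata, "s_denominator") %||% "noncompliant"
  s <- if (m == 0) 0 else
    sum(x$assessments$hazard) / (if (s_den == "noncompliant") m else n)
  tibble::tibble(
    n_batches = n, n_noncompliant = m, p = p, s = s, ir = p * s,
    n_strata = nrow(x$strata),
    n_vegetables_high = sum(x$vegetable_risk$risk_class == "high"),
    n_provinces_high = sum(x$province_risk$risk_class == "high")
  )
}
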