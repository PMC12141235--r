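#' Risk threshold configuration
#'
#' The acceptable risk level is the product of the maximum acceptable
#' exceedance probability (2%, the regulatory benchmark that food sampling
#' pass rates should exceed 98%) and the maximum acceptable hazard severity
#' (1, a residue exactly at its limit): `ir0 = p_max * s_max = 0.02`.
#' An index at or above `ir0` is classified high-risk.
#'
#' @param p_max Acceptable exceedance probability (fraction, default 0.02).
#' @param s_max Acceptable hazard severity (default 1).
#' @return A list of class `vegrisk_threshold` with elements `p_max`,
#'   `s_max`, `ir0`.
#' @export
#' @examples
#' risk_threshold()$ir0
risk_threshold <- function(p_max = 0.02, s_max = 1) {
  stopifnot(p_max >= 0, s_max >= 0)
  structure(list(p_max = p_max, s_max = s_max, ir0 = p_max * s_max),
            class = "vegrisk_threshold")
}

#' Pesticide residue risk index
#'
#' The risk index is the product of the probability of a residue violation
#' and the severity of its harm: `IR = P x S`, with `P` a fraction and `S`
#' the dimensionless worst-case concentration-to-limit ratio.
#'
#' @param p Exceedance probability (fraction in \[0, 1\]).
#' @param s Mean hazard severity (dimensionless, >= 0).
#' @return Numeric risk index.
#' @export
#' @examples
#' risk_index(0.0738, 8.265)
risk_index <- function(p, s) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), all(s >= 0, na.rm = TRUE))
  p * s
}

#' Classify a risk index against the threshold
#'
#' @param ir Numeric risk index values (must be non-negative).
#' @param threshold A [risk_threshold()].
#' @return Character vector, `"high"` where `ir >= ir0`, else `"low"`.
#' @export
#' @examples
#' classify_risk(c(0.015, 0.02, 0.023))
classify_risk <- function(ir, threshold = risk_threshold()) {
  stopifnot(inherits(threshold, "vegrisk_threshold"))
  if (any(ir < 0, na.rm = TRUE)) abort("negative risk index: upstream invariant violated")
  ifelse(ir >= threshold$ir0, "high", "low")
}

#' Stratum-level risk: P, S and IR per province x vegetable cell
#'
#' For each stratum (by default a province x vegetable cell, the analytical
#' unit of the surveillance database) computes the number of sampled
#' batches `n`, non-compliant batches `m`, the exceedance probability
#' `p = m / n`, the mean hazard severity `s`, and the risk index
#' `ir = p * s`.
#'
#' The severity denominator is configurable. The default,
#' `"noncompliant"`, averages the worst-case hazard over the `m`
#' non-compliant batches only, so that a stratum with any violation has
#' `s >= 1` (one violating batch at its limit is the mildest possible
#' violation); `"all"` divides the hazard total by all `n` batches instead.
#' Under either choice `m = 0` gives `p = s = ir = 0` exactly.
#'
#' @param assessments Batch assessments from [assess_samples()] (or any
#'   table with the grouping columns plus `compliant` and `hazard`).
#' @param by Grouping columns defining a stratum.
#' @param s_denominator `"noncompliant"` (default) or `"all"`.
#' @param min_n Strata with fewer sampled batches than this are flagged
#'   `small_sample = TRUE` (they are retained: flagging beats silent
#'   deletion).
#' @return A tibble with one row per stratum: grouping columns, `n`, `m`,
#'   `p`, `s`, `ir`, `small_sample`.
#' @export
stratum_risk <- function(assessments,
                         by = c("province", "vegetable"),
                         s_denominator = c("noncompliant", "all"),
                         min_n = 10) {
  s_denominator <- match.arg(s_denominator)
  d <- tibble::as_tibble(assessments)
  if (!all(c(by, "compliant", "hazard") %in% names(d))) {
    abort("assessments must carry the grouping columns plus compliant and hazard")
  }
  out <- d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      m = sum(!.data$compliant),
      hazard_total = sum(.data$hazard[!.data$compliant]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p = .data$m / .data$n,
      s = dplyr::if_else(
        .data$m == 0, 0,
        .data$hazard_total /
          (if (s_denominator == "noncompliant") .data$m else .data$n)),
      ir = .data$p * .data$s,
      small_sample = .data$n < min_n
    ) |>
    dplyr::select(-"hazard_total")
  attr(out, "s_denominator") <- s_denominator
  out
}

#' Direct-weighted aggregation to vegetable or province level
#'
#' Pools stratum results to one row per vegetable (across the provinces
#' where it was sampled) or per province (across its sampled vegetables):
#' the pooled probability is total non-compliant over total sampled
#' batches, the pooled severity is the sampling-weighted mean of stratum
#' severities (weights `n`), and `ir = p * s` classified against the
#' threshold. Rows are ranked by `ir` descending, ties broken by pooled
#' `n` descending, then key.
#'
#' @param strata Output of [stratum_risk()].
#' @param level `"vegetable"` or `"province"`.
#' @param threshold A [risk_threshold()].
#' @return A tibble with columns `rank`, the key column, `group_count`
#'   (number of contributing strata), `n`, `m`, `p`, `s`, `ir`,
#'   `risk_class`.
#' @export
aggregate_risk <- function(strata,
                           level = c("vegetable", "province"),
                           threshold = risk_threshold()) {
  level <- match.arg(level)
  d <- tibble::as_tibble(strata)
  if (!all(c(level, "n", "m", "p", "s") %in% names(d))) {
    abort("strata must come from stratum_risk()")
  }
  out <- d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(level))) |>
    dplyr::summarise(
      group_count = dplyr::n(),
      s = sum(.data$s * .data$n) / sum(.data$n),
      n = sum(.data$n),
      m = sum(.data$m),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p = .data$m / .data$n,
      ir = .data$p * .data$s,
      risk_class = classify_risk(.data$ir, threshold)
    ) |>
    dplyr::arrange(dplyr::desc(.data$ir), dplyr::desc(.data$n),
                   .data[[level]]) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", dplyr::all_of(level), "group_count", "n", "m",
                  "p", "s", "ir", "risk_class")
  out
}

#' Descriptive statistics of stratum-level indicators
#'
#' Summarizes `p`, `s` and `ir` over the stratum table (mean, standard
#' deviation, minimum, maximum), mirroring the descriptive overview of the
#' analytical units.
#'
#' @param strata Output of [stratum_risk()].
#' @return A tibble with one row per indicator.
#' @export
descriptive_stats <- function(strata) {
  d <- tibble::as_tibble(strata)
  if (nrow(d) == 0) abort("no strata to summarise")
  one <- function(nm, x) tibble::tibble(
    variable = nm, obs = length(x), mean = mean(x),
    sd = if (length(x) > 1) sd(x) else 0, min = min(x), max = max(x)
  )
  dplyr::bind_rows(one("P", d$p), one("S", d$s), one("IR", d$ir))
}

#' Batch-count shares by a grouping key
#'
#' Tabulates counts (or a weight sum) by key with each group's share of the
#' total, sorted descending (ties by key), with a rank column. Used for
#' sampling-composition tables ("the top five vegetables account for X% of
#' all batches") and exceedance-composition tables.
#'
#' @param data A data frame.
#' @param key Column name (string) to tabulate.
#' @param weight Optional column name summed instead of counting rows.
#' @return A tibble `key`, `n`, `share` (fraction of total), `rank`.
#' @export
count_shares <- function(data, key, weight = NULL) {
  d <- tibble::as_tibble(data)
  if (!key %in% names(d)) abort(paste0("no such column: ", key))
  if (is.null(weight)) {
    out <- dplyr::count(d, .data[[key]], name = "n")
  } else {
    out <- d |>
      dplyr::group_by(.data[[key]]) |>
      dplyr::summarise(n = sum(.data[[weight]]), .groups = "drop")
  }
  out |>
    dplyr::arrange(dplyr::desc(.data$n), .data[[key]]) |>
    dplyr::mutate(share = .data$n / sum(.data$n),
                  rank = dplyr::row_number())
}

#' Share of the total held by the top-ranked groups
#'
#' @param shares Output of [count_shares()].
#' @param top_n How many of the largest groups to pool.
#' @return The pooled share (fraction of the total).
#' @export
#' @examples
#' shares <- count_shares(data.frame(v = c("a", "a", "b", "c")), "v")
#' top_share(shares, 2)
top_share <- function(shares, top_n) {
  stopifnot(all(c("n", "share") %in% names(shares)))
  top_n <- min(top_n, nrow(shares))
  sum(dplyr::slice_max(shares, .data$n, n = top_n, with_ties = FALSE)$share)
}

#' Sampling and exceedance composition tables
#'
#' @param assessments Batch assessments from [assess_samples()].
#' @return A named list of [count_shares()] tables: sampled batches by
#'   vegetable and by province; non-compliant batches by trigger pesticide
#'   and by vegetable.
#' @export
composition_stats <- function(assessments) {
  d <- tibble::as_tibble(assessments)
  bad <- dplyr::filter(d, !.data$compliant)
  list(
    batches_by_vegetable = count_shares(d, "vegetable"),
    batches_by_province = count_shares(d, "province"),
    exceedance_by_pesticide = count_shares(bad, "trigger_pesticide"),
    exceedance_by_vegetable = count_shares(bad, "vegetable")
  )
}

#' Render an aggregate risk table at reporting precision
#'
#' Internal arithmetic is full precision; this renders the conventional
#' report: `P` as a percentage to two decimals, `S` and `IR` to three,
#' rounding half away from zero.
#'
#' @param aggregate Output of [aggregate_risk()].
#' @return A tibble with `p_percent`, `s`, `ir` at report precision.
#' @export
format_risk_table <- function(aggregate) {
  d <- tibble::as_tibble(aggregate)
  d$p_percent <- round_half_up(d$p * 100, 2)
  d$s <- round_half_up(d$s, 3)
  d$ir <- round_half_up(d$ir, 3)
  d$p <- NULL
  dplyr::relocate(d, "p_percent", .before = "s")
}
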