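#' Compliance policy options
#'
#' Controls how measurements with no numeric limit enter the worst-case
#' hazard score. A banned pesticide with no MRL is non-compliant on any
#' detection; its hazard contribution is the ratio of the detected
#' concentration to a reference limit `banned_reference_mg_per_kg`
#' (default 0.01 mg/kg, the common determination-level surrogate), floored
#' at 1 so that any stratum containing violations has mean hazard of at
#' least 1 — consistent with 1 being the maximum acceptable hazard.
#' Pesticides absent from the MRL table are, by default, not treated as
#' violations (`no_limit_violates = FALSE`): a missing standard is a
#' configuration gap, not evidence of risk.
#'
#' @param banned_reference_mg_per_kg Reference limit (mg/kg) used in place
#'   of an MRL for banned pesticides without one.
#' @param floor_banned_at_one Floor the banned-detection hazard ratio at 1.
#' @param no_limit_violates Treat detections with no matching MRL entry as
#'   violations (hazard against the banned reference limit).
#' @return A list of class `vegrisk_policy`.
#' @export
compliance_policy <- function(banned_reference_mg_per_kg = 0.01,
                              floor_banned_at_one = TRUE,
                              no_limit_violates = FALSE) {
  stopifnot(banned_reference_mg_per_kg > 0)
  structure(
    list(banned_reference_mg_per_kg = banned_reference_mg_per_kg,
         floor_banned_at_one = floor_banned_at_one,
         no_limit_violates = no_limit_violates),
    class = "vegrisk_policy"
  )
}

#' Assess sample compliance and worst-case hazard
#'
#' Classifies every sampled batch as compliant or non-compliant and scores
#' it under the worst-case principle: a batch is non-compliant iff at least
#' one measured concentration strictly exceeds its MRL (equality is
#' compliant — the limit itself is the maximum acceptable hazard) or any
#' banned pesticide is detected. Its hazard is the maximum
#' concentration-to-limit ratio over the violating measurements; compliant
#' batches score 0. Banned detections without an MRL contribute
#' `max(C / reference, 1)` per the policy; a banned pesticide that does
#' have a table MRL uses the plain ratio `C / MRL` (still non-compliant on
#' any detection).
#'
#' @param bound Measurement rows with limit bindings from [match_mrl()].
#' @param policy A [compliance_policy()].
#' @return A tibble with one row per batch: `batch_id`, `province`,
#'   `vegetable`, `year`, `compliant`, `hazard`, `trigger_pesticide` (the
#'   arg-max violating pesticide, `NA` when compliant) and `trigger_kind`
#'   (`"over-limit"`, `"banned-detection"`, or `"none"`).
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   province = "demo", vegetable = "leek", year = 2021L,
#'   batch_id = c("b1", "b1"), pesticide = c("a", "b"),
#'   concentration = c(3, 5)
#' )
#' mrl <- tibble::tibble(vegetable = "leek", pesticide = c("a", "b"),
#'                       mrl_mg_per_kg = 1, banned = FALSE)
#' assess_samples(match_mrl(recs, mrl))
assess_samples <- function(bound, policy = compliance_policy()) {
  stopifnot(inherits(policy, "vegrisk_policy"))
  d <- tibble::as_tibble(bound)
  need <- c("batch_id", "province", "vegetable", "year", "pesticide",
            "concentration", "mrl", "banned", "binding")
  if (!all(need %in% names(d))) {
    abort("assess_samples() needs measurements bound by match_mrl()")
  }
  if (any(is.na(d$binding))) abort("unbound measurement rows present")

  detected <- !is.na(d$concentration)
  q <- policy$banned_reference_mg_per_kg
  ratio <- rep(NA_real_, nrow(d))
  over <- d$binding == "limit" & detected
  ratio[over] <- d$concentration[over] / d$mrl[over]
  noref <- (d$binding == "banned" |
              (d$binding == "no_limit" & policy$no_limit_violates)) & detected
  ratio[noref] <- d$concentration[noref] / q
  if (policy$floor_banned_at_one) ratio[noref] <- pmax(ratio[noref], 1)

  violating <- rep(FALSE, nrow(d))
  violating[over] <- (d$banned[over]) | (ratio[over] > 1)
  violating[noref] <- TRUE
  kind <- dplyr::case_when(
    violating & (d$banned | d$binding == "banned") ~ "banned-detection",
    violating ~ "over-limit",
    TRUE ~ NA_character_
  )

  d <- dplyr::mutate(d, .viol = violating, .ratio = ratio, .kind = kind)
  out <- d |>
    dplyr::group_by(.data$batch_id, .data$province, .data$vegetable,
                    .data$year) |>
    dplyr::summarise(
      compliant = !any(.data$.viol),
      hazard = ifelse(any(.data$.viol),
                      max(.data$.ratio[.data$.viol]), 0),
      trigger_pesticide = ifelse(
        any(.data$.viol),
        .data$pesticide[.data$.viol][
          which.max(.data$.ratio[.data$.viol])],
        NA_character_),
      trigger_kind = ifelse(
        any(.data$.viol),
        .data$.kind[.data$.viol][which.max(.data$.ratio[.data$.viol])],
        "none"),
      .groups = "drop"
    )
  dplyr::arrange(out, .data$province, .data$vegetable, .data$year,
                 .data$batch_id)
}
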