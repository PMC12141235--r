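#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of mean radius `radius_km` (default
#' 6371 km). Used to express the centroid transfer displacement in
#' kilometres alongside the raw degree-space distance.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (vectorized).
#' @param radius_km Sphere radius in km.
#' @return Distance(s) in km.
#' @export
#' @examples
#' haversine_km(114.48, 33.70, 113.28, 32.97)
haversine_km <- function(lon1, lat1, lon2, lat2, radius_km = 6371) {
  as.numeric(geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                      r = radius_km))
}

#' Bearing of a degree-space displacement
#'
#' Four-quadrant arctangent of (delta-longitude, delta-latitude), oriented
#' with 0 degrees due north and angles measured clockwise, in \[0, 360).
#' A single-branch arctangent of the ratio would be quadrant-ambiguous;
#' `atan2` resolves all four. Undefined (NA) for a zero displacement.
#'
#' @param dlon,dlat Displacement components in degrees.
#' @return Bearing in degrees.
#' @export
#' @examples
#' bearing_degrees(1.22, 1.02) # northeast, ~50 degrees
bearing_degrees <- function(dlon, dlat) {
  out <- (atan2(dlon, dlat) * 180 / pi) %% 360
  out[dlon == 0 & dlat == 0] <- NA_real_
  out
}

# displacement quadrant name; pure-cardinal moves keep the cardinal name
quadrant_name <- function(dlon, dlat) {
  dplyr::case_when(
    dlon == 0 & dlat == 0 ~ NA_character_,
    dlon == 0 ~ ifelse(dlat > 0, "North", "South"),
    dlat == 0 ~ ifelse(dlon > 0, "East", "West"),
    dlon > 0 & dlat > 0 ~ "Northeast",
    dlon > 0 & dlat < 0 ~ "Southeast",
    dlon < 0 & dlat < 0 ~ "Southwest",
    TRUE ~ "Northwest"
  )
}

opposite_direction <- function(x) {
  map <- c(North = "South", South = "North", East = "West", West = "East",
           Northeast = "Southwest", Southwest = "Northeast",
           Southeast = "Northwest", Northwest = "Southeast")
  unname(map[x])
}

#' Risk-weighted spatial centre of gravity
#'
#' The yearly centre of gravity of residue risk: the mean of provincial
#' capital coordinates weighted by each province's risk index,
#' `w_i = IR_i / sum(IR_i)`. Provinces with zero IR (or absent in a year)
#' carry zero weight; the centroid always lies inside the bounding box of
#' the contributing capitals.
#'
#' @param province_risk A tibble with columns `province` and `ir`, plus
#'   optional grouping columns `year` and/or `scope` (a centroid is
#'   computed per group).
#' @param geo Capital coordinates (see [province_capitals()]).
#' @return A tibble with the grouping columns plus `longitude`, `latitude`
#'   and `n_provinces` (count with positive weight).
#' @export
#' @examples
#' risk_centroid(
#'   tibble::tibble(province = c("jiangsu", "yunnan"), ir = c(1, 1)),
#'   province_capitals()
#' )
risk_centroid <- function(province_risk, geo = province_capitals()) {
  d <- tibble::as_tibble(province_risk)
  if (!all(c("province", "ir") %in% names(d))) {
    abort("province_risk needs columns province and ir")
  }
  d$province <- squish_name(d$province)
  missing_geo <- setdiff(unique(d$province), geo$province)
  if (length(missing_geo) > 0) {
    abort(paste0("no capital coordinates for province(s): ",
                 paste(missing_geo, collapse = ", ")))
  }
  d <- dplyr::left_join(d, geo, by = "province")
  grp <- intersect(c("scope", "year"), names(d))
  one <- function(g) {
    g <- g[g$ir > 0, , drop = FALSE]
    if (nrow(g) == 0) abort("centroid undefined: all risk indices are zero")
    w <- g$ir / sum(g$ir)
    tibble::tibble(longitude = sum(w * g$longitude_e),
                   latitude = sum(w * g$latitude_n),
                   n_provinces = nrow(g))
  }
  if (length(grp) == 0) return(one(d))
  d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Year-over-year transfer of the risk centroid
#'
#' For consecutive centroids, computes the displacement in degree space
#' (`d_degrees`, the Euclidean distance of the coordinate shift), the
#' great-circle distance in kilometres (`d_km`, haversine at
#' `earth_radius_km`), the transfer bearing (0 = due north, clockwise),
#' and a transfer-locus label phrased "X to Y" with Y the quadrant of
#' motion and X its opposite (a centroid drifting southwest reads
#' "Northeast to Southwest"). Bearing and label are undefined for a zero
#' displacement.
#'
#' @param centroids Output of [risk_centroid()] with a `year` column
#'   (optionally grouped by `scope`).
#' @param earth_radius_km Mean Earth radius for the km conversion.
#' @return A tibble with one row per consecutive year pair: coordinates of
#'   both endpoints, `d_degrees`, `d_km`, `bearing`, `label`.
#' @export
centroid_transfer <- function(centroids, earth_radius_km = 6371) {
  d <- tibble::as_tibble(centroids)
  if (!all(c("year", "longitude", "latitude") %in% names(d))) {
    abort("centroids need columns year, longitude, latitude")
  }
  grp <- intersect("scope", names(d))
  one <- function(g) {
    g <- dplyr::arrange(g, .data$year)
    if (nrow(g) < 2) {
      return(tibble::tibble(
        from_year = integer(), to_year = integer(),
        from_longitude = double(), from_latitude = double(),
        to_longitude = double(), to_latitude = double(),
        d_degrees = double(), d_km = double(), bearing = double(),
        label = character()
      ))
    }
    from <- g[-nrow(g), ]
    to <- g[-1, ]
    dlon <- to$longitude - from$longitude
    dlat <- to$latitude - from$latitude
    dest <- quadrant_name(dlon, dlat)
    tibble::tibble(
      from_year = from$year, to_year = to$year,
      from_longitude = from$longitude, from_latitude = from$latitude,
      to_longitude = to$longitude, to_latitude = to$latitude,
      d_degrees = sqrt(dlon^2 + dlat^2),
      d_km = haversine_km(from$longitude, from$latitude,
                          to$longitude, to$latitude, earth_radius_km),
      bearing = bearing_degrees(dlon, dlat),
      label = ifelse(is.na(dest), NA_character_,
                     paste(opposite_direction(dest), "to", dest))
    )
  }
  if (length(grp) == 0) return(one(d))
  d |>
    dplyr::group_by(.data$scope) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Full centroid trajectory from batch assessments
#'
#' Convenience wrapper running the spatial stage end-to-end: per year,
#' stratum risk is computed within provinces, aggregated to a provincial
#' risk index, and reduced to a risk-weighted centroid; consecutive
#' centroids are then paired into transfers. `scope = "all"` uses every
#' batch; a vegetable name restricts the trajectory to that category.
#'
#' @param assessments Batch assessments from [assess_samples()].
#' @param geo Capital coordinates.
#' @param scope `"all"` or a canonical vegetable name.
#' @param s_denominator,threshold Passed to the risk stage.
#' @param earth_radius_km Mean Earth radius for the km conversion.
#' @return A list with tibbles `centroids` and `transfers`.
#' @export
centroid_track <- function(assessments, geo = province_capitals(),
                           scope = "all",
                           s_denominator = "noncompliant",
                           threshold = risk_threshold(),
                           earth_radius_km = 6371) {
  d <- tibble::as_tibble(assessments)
  if (!identical(scope, "all")) {
    d <- dplyr::filter(d, .data$vegetable == scope)
    if (nrow(d) == 0) abort(paste0("no assessments for scope: ", scope))
  }
  province_year <- d |>
    stratum_risk(by = c("year", "province", "vegetable"),
                 s_denominator = s_denominator) |>
    dplyr::group_split(.data$year) |>
    purrr::map(function(g) {
      agg <- aggregate_risk(g, level = "province", threshold = threshold)
      tibble::tibble(year = g$year[1], province = agg$province,
                     ir = agg$ir)
    }) |>
    dplyr::bind_rows()
  cents <- risk_centroid(province_year, geo)
  cents$scope <- scope
  cents <- dplyr::relocate(cents, "scope")
  list(centroids = cents,
       transfers = centroid_transfer(cents, earth_radius_km))
}
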