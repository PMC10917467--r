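#' Surgical-evacuation threshold policy
#'
#' Guideline thresholds for evacuating an acute EDH: volume above 30 mL,
#' thickness above 15 mm on the initial scan, and the derived one-parameter
#' rule that a hematoma longer than 7 cm occupies more than 30 mL. Thickness
#' is interpreted as the full (double) thickness `2h`; length as the full
#' largest diameter `A`.
#'
#' @param volume_ml Volume threshold, mL.
#' @param thickness_mm Full-thickness threshold (2h), mm.
#' @param length_mm Largest-diameter threshold, mm.
#' @return A `threshold_policy` list.
#' @export
threshold_policy <- function(volume_ml = 30, thickness_mm = 15, length_mm = 70) {
  if (volume_ml <= 0 || thickness_mm <= 0 || length_mm <= 0) {
    stop("all thresholds must be positive")
  }
  structure(
    list(volume_ml = volume_ml, thickness_mm = thickness_mm, length_mm = length_mm),
    class = "threshold_policy"
  )
}

#' Lookup table of EDH volumes by largest diameter
#'
#' Regenerates the model's lookup table on a diameter grid: for each largest
#' diameter `A` the base radius, cap height, ABC/ellipsoid volume, biconvex
#' (twice-cap) volume and their ratio. At the default `r = 80` mm four
#' threshold-related rows are injected into the 10 mm grid: the exact
#' diameters at which the ABC estimate reaches 30 mL (64.7 mm), the cap height
#' reaches 7.5 mm i.e. full thickness 15 mm (67.6 mm), the biconvex estimate
#' reaches 30 mL (69.1 mm), and the 65 mm convenience row. The grid is
#' truncated where the ABC estimate would exceed the volume of the
#' half-sphere model itself (for `r = 80`: `A <= 140` mm).
#'
#' @param r Sphere radius, mm.
#' @param step Grid step in `A`, mm.
#' @param anchors Extra diameters to inject, mm. Default: the threshold rows
#'   described above when `r = 80`, none otherwise.
#' @param policy A [threshold_policy()] used to locate the anchor rows.
#' @return A tibble with columns `A_mm`, `a_mm`, `h_mm`, `v_abc_ml`,
#'   `v_sc_ml`, `ratio` (`NA` at `A = 0`), ordered by `A_mm`.
#' @examples
#' edh_table()                # the 19-row default table
#' format_edh_table(edh_table())
#' @export
edh_table <- function(r = 80, step = 10, anchors = NULL,
                      policy = threshold_policy()) {
  if (step <= 0) stop("`step` must be positive")
  if (is.null(anchors)) {
    anchors <- if (r == 80) {
      c(
        diameter_for_volume(policy$volume_ml, "abc", r = r),
        65,
        2 * base_radius_from_height(policy$thickness_mm / 2, r = r),
        diameter_for_volume(policy$volume_ml, "sc", r = r)
      )
    } else {
      numeric(0)
    }
  }
  hemisphere_ml <- (2 / 3) * pi * r^3 / 1000
  grid <- seq(0, 2 * r - step / 2, by = step)
  A <- sort(unique(c(grid, anchors)))
  tab <- edh_volumes(tibble::tibble(A_mm = A), r = r)
  dplyr::filter(tab, .data$v_abc_ml <= hemisphere_ml)
}

round_volume <- function(v) {
  # sub-0.05 mL volumes need a second decimal to be visible at all
  ifelse(v < 0.05, sprintf("%.2f", v), sprintf("%.1f", v))
}

#' Format a lookup table for display
#'
#' Applies the serialization rounding: lengths and volumes to 1 decimal
#' (volumes below 0.05 mL to 2 decimals), the ratio to 2 decimals with the
#' empty-cap row rendered `"N/A"`.
#'
#' @param tab A table from [edh_table()].
#' @return A tibble of character columns, print-ready.
#' @export
format_edh_table <- function(tab) {
  tibble::tibble(
    A_mm = sprintf("%.1f", tab$A_mm),
    a_mm = sprintf("%.1f", tab$a_mm),
    h_mm = sprintf("%.1f", tab$h_mm),
    v_abc_ml = round_volume(tab$v_abc_ml),
    v_sc_ml = round_volume(tab$v_sc_ml),
    ratio = ifelse(is.na(tab$ratio), "N/A", sprintf("%.2f", tab$ratio))
  )
}

#' Should this EDH be evacuated?
#'
#' Evaluates one or more hematomas, given only the largest diameter `A`,
#' against the guideline thresholds: the chosen volume estimate against the
#' 30 mL criterion, the model full thickness `2h` against the 15 mm criterion,
#' and `A` against the 7 cm length rule. The overall `evacuate` flag is true
#' if any criterion is exceeded. Because the apparent axial thickness `2b` can
#' exceed `2h` for high-latitude hematomas, `b_flag_possible` marks diameters
#' for which some latitude would push the apparent thickness over the
#' threshold even though the true thickness is below it (the overtreatment
#' caveat: at `|phi| = 90` the apparent full thickness reaches `2a = A`).
#'
#' @param A Largest diameter(s), mm. Vectorised.
#' @param r Sphere radius, mm.
#' @param policy A [threshold_policy()].
#' @param method Which estimate drives the volume criterion: `"sc"` or
#'   `"abc"`. Both volumes are reported.
#' @return A tibble with one row per `A`: geometry, both volumes, per-criterion
#'   logical flags and the overall `evacuate` decision.
#' @examples
#' evaluate_case(c(50, 70))
#' @export
evaluate_case <- function(A, r = 80, policy = threshold_policy(),
                          method = c("sc", "abc")) {
  method <- match.arg(method)
  if (any(A < 0)) stop("`A` must be nonnegative")
  if (any(A >= 2 * r)) {
    stop(
      "largest diameter ", max(A), " mm is out of the model: A must be < 2r = ",
      2 * r, " mm"
    )
  }
  tab <- edh_volumes(tibble::tibble(A_mm = A), r = r)
  vol <- if (method == "sc") tab$v_sc_ml else tab$v_abc_ml
  dplyr::mutate(
    tab,
    method = method,
    volume_ml = vol,
    volume_flag = vol > policy$volume_ml,
    thickness_flag = 2 * .data$h_mm > policy$thickness_mm,
    length_flag = .data$A_mm > policy$length_mm,
    evacuate = .data$volume_flag | .data$thickness_flag | .data$length_flag,
    b_flag_possible = !.data$thickness_flag & 2 * .data$a_mm > policy$thickness_mm
  )
}
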