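#' Latitude of an EDH from axial landmarks (native model)
#'
#' The latitude `phi` is the angle between the cap's symmetry axis and the
#' basal (equatorial) plane of the half-sphere model. It is recovered from the
#' z-coordinate of the hematoma centroid, `z_centroid = (z_cranial +
#' z_caudal)/2`, via `phi = asin((z_centroid - z_basal) / (r - h))` -- the
#' hypotenuse of the defining right triangle is `r - h`, the distance from the
#' sphere centre to the base-circle centre, not `r`. Negative latitudes
#' (temporal hematomas below the basal plane) are allowed.
#'
#' @param z_cranial,z_caudal z-coordinates of the most cranial / caudal axial
#'   images containing hematoma, mm. Vectorised.
#' @param z_basal z-coordinate of the basal plane (midbrain image), mm.
#' @param cap A [spherical_cap()] for the hematoma (gives `r` and `h`).
#' @return Latitude in degrees, in (-90, 90].
#' @examples
#' cap <- spherical_cap(80, h = 7.5)
#' latitude_native(66.25, 6.25, 0, cap)  # 30 degrees
#' @export
latitude_native <- function(z_cranial, z_caudal, z_basal, cap) {
  cap <- as_cap(cap)
  if (cap$h >= cap$r) stop("latitude is undefined for a full hemisphere (h = r)")
  dz <- (z_cranial + z_caudal) / 2 - z_basal
  arg <- dz / (cap$r - cap$h)
  bad <- abs(arg) > 1 + 1e-12
  if (any(bad)) {
    stop(
      "EDH centroid lies outside the model: |z_centroid - z_basal| = ",
      format(max(abs(dz[bad]))), " mm exceeds r - h = ",
      format(cap$r - cap$h), " mm"
    )
  }
  asin(pmin(1, pmax(-1, arg))) * 180 / pi
}

#' Latitude of an EDH from axial landmarks (landmark-corrected model)
#'
#' Identical to [latitude_native()] except that the model radius is replaced
#' by the per-patient vertex-to-basal distance `r_L = z_vertex - z_basal`, so
#' `phi_L = asin((z_centroid - z_basal) / (r_L - h))`. This corrects for heads
#' whose supratentorial height differs from the 80 mm model.
#'
#' @inheritParams latitude_native
#' @param z_vertex z-coordinate of the most cranial image containing brain, mm.
#' @return Latitude in degrees.
#' @export
latitude_landmark <- function(z_cranial, z_caudal, z_basal, z_vertex, cap) {
  cap <- as_cap(cap)
  r_l <- z_vertex - z_basal
  denom <- r_l - cap$h
  if (any(denom <= 0)) {
    stop(
      "degenerate landmarks: z_vertex - z_basal = ", format(min(r_l)),
      " mm does not exceed the cap height h = ", format(cap$h), " mm"
    )
  }
  dz <- (z_cranial + z_caudal) / 2 - z_basal
  arg <- dz / denom
  bad <- abs(arg) > 1 + 1e-12
  if (any(bad)) {
    stop(
      "EDH centroid lies outside the landmark-corrected model: ",
      "|z_centroid - z_basal| = ", format(max(abs(dz[bad]))),
      " mm exceeds r_L - h = ", format(min(denom)), " mm"
    )
  }
  asin(pmin(1, pmax(-1, arg))) * 180 / pi
}

#' Exact axial half-thickness of an EDH at latitude phi
#'
#' On the axial image with the largest hematoma area, the apparent
#' half-thickness `b` exceeds the true cap height `h` whenever the cap axis is
#' tilted out of the basal plane. In the working plane (spanned by the z-axis
#' and the cap axis, origin at the base-circle centre) the skull circle is
#' `(u - (h - r))^2 + v^2 = r^2` and the axial direction is the ray
#' `v = u tan(phi)`; the positive root of the resulting quadratic gives
#' `b = u sqrt(1 + tan^2(phi))`:
#' `b = ((h - r) + sqrt((h - r)^2 - (1 + tan^2 phi)(h^2 - 2rh))) / sqrt(1 + tan^2 phi)`.
#' Limits: `b = h` at `phi = 0` and `b = a` at `phi = +/-90` degrees (handled
#' as a closed-form branch). `b` is even in `phi` and satisfies
#' `h <= b <= a` always.
#'
#' @param cap A [spherical_cap()].
#' @param phi_deg Latitude in degrees, in \[-90, 90\]. Vectorised.
#' @return Half-thickness `b`, mm.
#' @examples
#' cap <- spherical_cap(80, h = 7.5)
#' thickness_exact(cap, 0)   # 7.5  (= h)
#' thickness_exact(cap, 65)  # ~15  (the vertex-on-rim worked example)
#' thickness_exact(cap, 90)  # 33.8 (= a)
#' @export
thickness_exact <- function(cap, phi_deg) {
  cap <- as_cap(cap)
  if (any(abs(phi_deg) > 90)) stop("`phi_deg` must lie in [-90, 90]")
  r <- cap$r
  h <- cap$h
  phi <- phi_deg * pi / 180
  t2 <- 1 + tan(phi)^2
  disc <- (h - r)^2 - t2 * (h^2 - 2 * r * h)
  if (any(disc < 0, na.rm = TRUE)) {
    stop("internal geometry error: negative discriminant in the working-plane quadratic")
  }
  b <- ((h - r) + sqrt(disc)) / sqrt(t2)
  # tan(phi) is singular at the poles; there the largest axial cut is the base circle
  b[abs(phi_deg) == 90] <- cap$a
  b
}

#' Small-angle approximation of the axial half-thickness
#'
#' `b_hat = h / cos(phi)`, from the tangent line through the cap apex. Accurate
#' for small latitudes (low-lying hematomas); diverges as `phi` approaches 90
#' degrees, which is why the exact working-plane solution exists.
#'
#' @inheritParams thickness_exact
#' @return Approximate half-thickness, mm. Always `>=` the exact value.
#' @export
thickness_approx <- function(cap, phi_deg) {
  cap <- as_cap(cap)
  if (any(abs(phi_deg) >= 90)) {
    stop("`h / cos(phi)` is singular at phi = +/-90 degrees; use thickness_exact()")
  }
  cap$h / cos(phi_deg * pi / 180)
}

#' Cranial-caudal half-extent of an EDH at latitude phi
#'
#' The half-extent along the z-axis is the projection of the base-circle
#' radius: `c = a cos(phi)` for `|phi| < 90` degrees, and `c = h` for a cap
#' sitting exactly at the vertex (`phi = +/-90`).
#'
#' @inheritParams thickness_exact
#' @return Half-extent `c`, mm.
#' @export
cc_extent <- function(cap, phi_deg) {
  cap <- as_cap(cap)
  if (any(abs(phi_deg) > 90)) stop("`phi_deg` must lie in [-90, 90]")
  cc <- cap$a * cos(phi_deg * pi / 180)
  cc[abs(phi_deg) == 90] <- cap$h
  cc
}

#' Latitude at which the skull vertex lies on the base-circle rim
#'
#' For a cap tilted until the skull vertex touches the circumference of its
#' base circle, `phi = 90 - acos((r - h) / r)` degrees. At that placement the
#' apparent axial thickness is maximally misleading for low caps: the worked
#' example `h = 7.5` mm, `r = 80` mm gives `phi ~ 65` degrees and `b ~ 15` mm,
#' twice the true cap height.
#'
#' @param cap A [spherical_cap()].
#' @return Latitude in degrees.
#' @export
vertex_on_rim_latitude <- function(cap) {
  cap <- as_cap(cap)
  90 - acos((cap$r - cap$h) / cap$r) * 180 / pi
}

#' Maximum apparent-to-true thickness ratio b/h
#'
#' Since `h <= b <= a`, the apparent axial thickness can overstate the true
#' cap height by at most `a / h`; small-diameter hematomas near the vertex are
#' the worst case (a 20 mm-diameter EDH can look 15.9 times thicker than it
#' is).
#'
#' @param a Base-circle radius, mm. Vectorised.
#' @param r Sphere radius, mm.
#' @return `a / h` with `h` completed from the cap relation.
#' @examples
#' thickness_ratio_bound(c(10, 20, 30, 40, 50))  # 15.9 7.9 5.1 3.7 2.8
#' @export
thickness_ratio_bound <- function(a, r = 80) {
  if (any(a <= 0)) stop("`a` must be positive")
  a / cap_height_from_base(a, r)
}

#' Predict thickness and extent for a table of measured cases
#'
#' For each case: the cap height `h` is completed from the measured half-length
#' `a_mm` on the model sphere, the latitude from the axial z-landmarks (native
#' or landmark-corrected), and the apparent half-thickness `b` and
#' cranial-caudal half-extent `c` from the working-plane solution. Cases whose
#' landmarks are unresolvable (centroid outside the model, degenerate
#' landmarks) are returned with `NA` predictions and the error message in
#' `note` rather than failing the whole table.
#'
#' @param data Measurement table: one row per case with columns `a_mm`,
#'   `z_cranial`, `z_caudal`, `z_basal` and (for the landmark model)
#'   `z_vertex`, all mm. See [read_measurements()] for the file schema.
#' @param r Model sphere radius, mm.
#' @param model `"native"` (fixed model radius) or `"landmark"`
#'   (per-patient `r_L = z_vertex - z_basal` inside the latitude formula).
#' @param landmark_radius Which radius enters the cap geometry (height and
#'   working-plane circle) under the landmark model: `"model"` keeps the fixed
#'   model sphere (default), `"landmark"` uses `r_L` throughout, for
#'   sensitivity checks.
#' @return A tibble: `data` plus `h_mm`, `phi_deg`, `b_pred_mm`, `c_pred_mm`,
#'   `model`, `note`.
#' @export
edh_predict <- function(data, r = 80, model = c("native", "landmark"),
                        landmark_radius = c("model", "landmark")) {
  model <- match.arg(model)
  landmark_radius <- match.arg(landmark_radius)
  need <- c("a_mm", "z_cranial", "z_caudal", "z_basal")
  if (model == "landmark") need <- c(need, "z_vertex")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("measurement table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  one <- function(row) {
    res <- tibble::tibble(
      h_mm = NA_real_, phi_deg = NA_real_,
      b_pred_mm = NA_real_, c_pred_mm = NA_real_,
      model = model, note = NA_character_
    )
    tryCatch(
      {
        r_geom <- if (model == "landmark" && landmark_radius == "landmark") {
          row$z_vertex - row$z_basal
        } else {
          r
        }
        cap <- spherical_cap(r = r_geom, a = row$a_mm)
        phi <- if (model == "native") {
          latitude_native(row$z_cranial, row$z_caudal, row$z_basal, cap)
        } else {
          latitude_landmark(row$z_cranial, row$z_caudal, row$z_basal, row$z_vertex, cap)
        }
        res$h_mm <- cap$h
        res$phi_deg <- phi
        res$b_pred_mm <- thickness_exact(cap, phi)
        res$c_pred_mm <- cc_extent(cap, phi)
        res
      },
      error = function(e) {
        res$note <- conditionMessage(e)
        res
      }
    )
  }
  preds <- purrr::map(seq_len(nrow(data)), function(i) one(data[i, , drop = FALSE]))
  dplyr::bind_cols(tibble::as_tibble(data), dplyr::bind_rows(preds))
}
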