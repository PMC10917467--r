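#' Spherical cap of the skull-sphere model
#'
#' A spherical cap is the portion of a sphere of radius `r` cut off by a plane;
#' its base circle has radius `a` and its height is `h`. The three parameters
#' are bound by the Pythagorean relation `r^2 = a^2 + (r - h)^2`, so any two of
#' them determine the cap. An epidural hematoma (EDH) is modelled as the union
#' of such a cap and its mirror image across the base plane (a biconvex lens),
#' with total volume twice the cap volume.
#'
#' @param r Sphere (inner skull) radius in mm. Default 80 mm, the half-sphere
#'   model of the supratentorial brain.
#' @param a Base-circle radius in mm (half the hematoma's largest diameter).
#' @param h Cap height in mm (the hematoma's true half-thickness at its apex).
#' @param A Largest hematoma diameter in mm; shorthand for `a = A/2`.
#'
#' Exactly one of `a`, `h`, `A` must be given; the missing parameter is
#' completed from the cap relation.
#'
#' @return An object of class `spherical_cap`: a list with fields `r`, `a`,
#'   `h` (mm) and `A = 2a`.
#' @examples
#' spherical_cap(r = 80, A = 100)   # h = 17.55 mm
#' spherical_cap(r = 80, h = 7.5)   # A = 67.6 mm
#' @export
spherical_cap <- function(r = 80, a = NULL, h = NULL, A = NULL) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("`r` must be a single positive number (mm), got ", format(r))
  }
  given <- c(a = !is.null(a), h = !is.null(h), A = !is.null(A))
  if (sum(given) != 1L) {
    stop("give exactly one of `a`, `h`, `A`")
  }
  if (!is.null(A)) a <- A / 2
  if (!is.null(a)) {
    h <- cap_height_from_base(a, r)
  } else {
    a <- base_radius_from_height(h, r)
  }
  structure(list(r = r, a = a, h = h, A = 2 * a), class = "spherical_cap")
}

#' @export
print.spherical_cap <- function(x, ...) {
  cat(sprintf(
    "<spherical_cap>  r = %g mm, a = %.4g mm (A = %.4g mm), h = %.4g mm\n",
    x$r, x$a, x$A, x$h
  ))
  invisible(x)
}

as_cap <- function(cap) {
  if (!inherits(cap, "spherical_cap")) {
    stop("expected a `spherical_cap` object; see spherical_cap()")
  }
  cap
}

#' Cap height from base radius
#'
#' Solves the cap relation for the height: `h = r - sqrt(r^2 - a^2)`. On the
#' fixed-radius skull model the height of an EDH cap -- its true half
#' thickness -- is determined by the hematoma's largest diameter alone.
#'
#' @param a Base-circle radius, mm. Vectorised.
#' @param r Sphere radius, mm.
#' @return Cap height `h` in `[0, r]`, mm.
#' @examples
#' cap_height_from_base(50, 80)    # 17.55 mm
#' cap_height_from_base(33.8, 80)  # ~7.5 mm
#' @export
cap_height_from_base <- function(a, r = 80) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("`r` must be positive (mm)")
  if (any(!is.finite(a)) || any(a < 0)) stop("`a` must satisfy a >= 0, got ", min(a))
  if (any(a > r)) {
    stop(
      "`a` must satisfy a <= r: base radius ", max(a),
      " mm exceeds sphere radius ", r, " mm"
    )
  }
  r - sqrt(r^2 - a^2)
}

#' Base radius from cap height
#'
#' Inverse of [cap_height_from_base()]: `a = sqrt(2*r*h - h^2)`.
#'
#' @param h Cap height, mm. Vectorised.
#' @param r Sphere radius, mm.
#' @return Base-circle radius `a`, mm.
#' @examples
#' base_radius_from_height(7.5, 80)  # 33.82 mm, i.e. A = 67.6 mm
#' @export
base_radius_from_height <- function(h, r = 80) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("`r` must be positive (mm)")
  if (any(!is.finite(h)) || any(h < 0)) stop("`h` must satisfy h >= 0, got ", min(h))
  if (any(h > r)) {
    stop(
      "`h` must satisfy h <= r: cap height ", max(h),
      " mm exceeds sphere radius ", r, " mm"
    )
  }
  sqrt(2 * r * h - h^2)
}

#' Volume of a single spherical cap
#'
#' `V_SC = (pi/3) h^2 (3r - h)`, converted from mm^3 to mL.
#'
#' @param cap A [spherical_cap()].
#' @return Volume in mL.
#' @export
cap_volume <- function(cap) {
  cap <- as_cap(cap)
  (pi / 3) * cap$h^2 * (3 * cap$r - cap$h) / 1000
}

#' Spherical-cap EDH volume estimate
#'
#' The biconvex hematoma is the cap plus its mirror image across the base
#' plane, so its volume is twice the cap volume: `2 V_SC`.
#'
#' @inheritParams cap_volume
#' @return Volume in mL.
#' @examples
#' edh_volume_sc(spherical_cap(80, A = 100))  # 143.5 mL
#' @export
edh_volume_sc <- function(cap) {
  2 * cap_volume(cap)
}

#' ABC/ellipsoid EDH volume estimate
#'
#' The classical ABC (ellipsoid) estimate `(4/3) pi (A/2)(B/2)(C/2)` applied
#' to the model at latitude 0, where the thickness radius equals the cap
#' height `h` and the cranial-caudal radius equals `a`:
#' `V_ABC = (4/3) pi a^2 h`, in mL. Exact pi is used throughout (the familiar
#' "ABC/2" shortcut corresponds to pi ~ 3).
#'
#' @inheritParams cap_volume
#' @return Volume in mL.
#' @examples
#' edh_volume_abc(spherical_cap(80, A = 100))  # 183.8 mL
#' @export
edh_volume_abc <- function(cap) {
  cap <- as_cap(cap)
  (4 / 3) * pi * cap$a^2 * cap$h / 1000
}

#' Ratio of ABC to spherical-cap volume estimates
#'
#' Substituting `a^2 = 2rh - h^2` into the ellipsoid formula gives
#' `V_ABC / (2 V_SC) = (4r - 2h) / (3r - h)`, which decreases from 4/3 (small
#' caps) to 1 (hemisphere, `h = r`). The ABC method therefore always
#' overestimates the biconvex volume, by close to a third for typical EDHs.
#'
#' @inheritParams cap_volume
#' @return Dimensionless ratio in (1, 4/3].
#' @export
volume_ratio <- function(cap) {
  cap <- as_cap(cap)
  if (cap$h == 0) {
    stop("volume ratio is undefined for an empty cap (h = 0)")
  }
  (4 * cap$r - 2 * cap$h) / (3 * cap$r - cap$h)
}

#' Largest diameter giving a target EDH volume
#'
#' Inverts either volume estimator: finds the largest hematoma diameter `A`
#' whose estimated volume equals `target_volume`, by bracketed root finding on
#' `A` in (0, 2r). Both estimators are strictly increasing in `A`, so the
#' solution is unique.
#'
#' @param target_volume Target volume, mL.
#' @param method `"abc"` (ellipsoid) or `"sc"` (twice the cap volume).
#' @param r Sphere radius, mm.
#' @param tol Absolute volume tolerance, mL.
#' @return Diameter `A` in mm.
#' @examples
#' diameter_for_volume(30, "abc")  # 64.7 mm
#' diameter_for_volume(30, "sc")   # 69.1 mm
#' @export
diameter_for_volume <- function(target_volume, method = c("sc", "abc"), r = 80,
                                tol = 1e-6) {
  method <- match.arg(method)
  vol <- function(A) {
    cap <- spherical_cap(r = r, A = A)
    if (method == "abc") edh_volume_abc(cap) else edh_volume_sc(cap)
  }
  if (!is.finite(target_volume) || target_volume <= 0) {
    stop("`target_volume` must be positive (mL)")
  }
  vmax <- vol(2 * r * (1 - 1e-12))
  if (target_volume > vmax) {
    stop(
      "target volume ", target_volume, " mL exceeds the ", method,
      " volume at the hemispheric limit (", format(vmax, digits = 6), " mL)"
    )
  }
  stats::uniroot(
    function(A) vol(A) - target_volume,
    interval = c(1e-9, 2 * r * (1 - 1e-12)),
    tol = 1e-12
  )$root
}

#' Tabulate both volume estimates for measured diameters
#'
#' Data-frame-first wrapper around the two estimators: for each largest
#' diameter `A` (mm) in `data[[col]]`, completes the cap on the model sphere
#' and appends base radius, cap height, both volume estimates and their ratio.
#'
#' @param data A data frame with a column of largest diameters, mm.
#' @param col Name of the diameter column. Default `"A_mm"`.
#' @param r Sphere radius, mm.
#' @return A tibble: `data` plus `a_mm`, `h_mm`, `v_abc_ml`, `v_sc_ml`,
#'   `ratio` (`NA` where `h = 0`).
#' @examples
#' edh_volumes(tibble::tibble(A_mm = c(50, 70, 100)))
#' @export
edh_volumes <- function(data, col = "A_mm", r = 80) {
  if (!col %in% names(data)) {
    stop("column `", col, "` not found in `data`")
  }
  A <- data[[col]]
  a <- A / 2
  h <- cap_height_from_base(a, r)
  tibble::as_tibble(data) |>
    dplyr::mutate(
      a_mm = a,
      h_mm = h,
      v_abc_ml = (4 / 3) * pi * a^2 * h / 1000,
      v_sc_ml = 2 * (pi / 3) * h^2 * (3 * r - h) / 1000,
      ratio = dplyr::if_else(h > 0, (4 * r - 2 * h) / (3 * r - h), NA_real_)
    )
}
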