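#' Apparent axial thickness as a function of diameter and latitude
#'
#' Plots the apparent full axial thickness `2b` over a grid of base radii and
#' latitudes, with the guideline thickness threshold drawn as a contour. Low
#' caps placed near the vertex can look several times thicker than they are;
#' the plot makes the overtreatment region visible at a glance.
#'
#' @param r Sphere radius, mm.
#' @param a_max Largest base radius shown, mm.
#' @param thickness_mm Guideline full-thickness threshold to contour, mm.
#' @param n Grid resolution per axis.
#' @return A ggplot.
#' @export
plot_thickness_surface <- function(r = 80, a_max = 50, thickness_mm = 15,
                                   n = 121) {
  grid <- tidyr::expand_grid(
    a = seq(1, a_max, length.out = n),
    phi = seq(0, 90, length.out = n)
  )
  grid <- dplyr::mutate(
    grid,
    b2 = purrr::map2_dbl(
      .data$a, .data$phi,
      function(a, phi) 2 * thickness_exact(spherical_cap(r = r, a = a), phi)
    )
  )
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$phi, y = .data$a, fill = .data$b2)) +
    ggplot2::geom_raster() +
    ggplot2::geom_contour(
      ggplot2::aes(z = .data$b2),
      breaks = thickness_mm, colour = "white", linewidth = 0.6
    ) +
    ggplot2::scale_fill_viridis_c(name = "2b (mm)") +
    ggplot2::labs(
      x = "latitude φ (degrees)",
      y = "base radius a (mm)",
      title = "Apparent axial thickness 2b of an EDH",
      subtitle = sprintf(
        "r = %g mm; white contour: %g mm guideline thickness", r, thickness_mm
      )
    ) +
    ggplot2::theme_minimal()
}

#' Volume estimates across the diameter range
#'
#' Plots both volume estimators against the largest diameter with the
#' guideline volume threshold and its two solution diameters marked.
#'
#' @param r Sphere radius, mm.
#' @param policy A [threshold_policy()].
#' @return A ggplot.
#' @export
plot_volume_curves <- function(r = 80, policy = threshold_policy()) {
  tab <- edh_volumes(tibble::tibble(A_mm = seq(0, 1.75 * r, length.out = 200)), r = r)
  long <- tidyr::pivot_longer(
    tab,
    c("v_abc_ml", "v_sc_ml"),
    names_to = "method", values_to = "volume_ml"
  )
  long$method <- dplyr::recode(long$method,
    v_abc_ml = "ABC / ellipsoid", v_sc_ml = "biconvex (2 V_SC)"
  )
  marks <- tibble::tibble(
    A = c(
      diameter_for_volume(policy$volume_ml, "abc", r = r),
      diameter_for_volume(policy$volume_ml, "sc", r = r)
    )
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$A_mm, .data$volume_ml, colour = .data$method)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = policy$volume_ml, linetype = 2) +
    ggplot2::geom_vline(data = marks, ggplot2::aes(xintercept = .data$A), linetype = 3) +
    ggplot2::labs(
      x = "largest diameter A (mm)", y = "estimated volume (mL)",
      colour = NULL,
      title = "EDH volume estimates vs largest diameter",
      subtitle = sprintf("dashed: %g mL evacuation threshold", policy$volume_ml)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname edh_validate
#' @param object An `edh_validation` object (for `autoplot`).
#' @exportS3Method ggplot2::autoplot
autoplot.edh_validation <- function(object, ...) {
  long <- purrr::imap(object$predictions, function(p, mod) {
    tibble::tibble(
      model = mod,
      target = rep(c("b", "c"), each = nrow(p)),
      measured = c(p$b_mm, p$c_mm),
      predicted = c(p$b_pred_mm, p$c_pred_mm)
    )
  }) |> dplyr::bind_rows()
  slopes <- object$summary
  ggplot2::ggplot(long, ggplot2::aes(.data$measured, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_abline(
      data = slopes,
      ggplot2::aes(slope = .data$slope, intercept = 0),
      linetype = 2, colour = "steelblue"
    ) +
    ggplot2::geom_point() +
    ggplot2::facet_grid(target ~ model, scales = "free") +
    ggplot2::labs(
      x = "measured (mm)", y = "predicted (mm)",
      title = "Model predictions vs measurements",
      subtitle = "dashed: through-origin fit; grey: identity"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
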