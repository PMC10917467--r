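# random valid caps on the default sphere, away from the degenerate ends
random_caps <- function(n, r = 80, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    r = r,
    a = runif(n, 0.05 * r, 0.95 * r)
  ) |>
    dplyr::mutate(h = cap_height_from_base(a, r))
}

# disc-integration oracle for the cap volume: the cap is the solid of
# revolution of the circle x^2 + z^2 = r^2 above z = r - h, so
# V = integral_{r-h}^{r} pi (r^2 - z^2) dz  (mm^3 -> mL)
cap_volume_disc <- function(r, h) {
  stats::integrate(function(z) pi * (r^2 - z^2), r - h, r,
    rel.tol = 1e-10
  )$value / 1000
}

# 2-D working-plane oracle for the axial half-thickness: walk along the ray
# at angle phi from the base-circle centre until it meets the skull circle
# (u - (h - r))^2 + v^2 = r^2, by root finding on the distance t
thickness_ray_oracle <- function(r, h, phi_deg) {
  phi <- phi_deg * pi / 180
  f <- function(t) (t * cos(phi) - (h - r))^2 + (t * sin(phi))^2 - r^2
  stats::uniroot(f, c(0, 2 * r), tol = 1e-12)$root
}

# the printed lookup table (r = 80 mm, 10 mm grid plus threshold rows),
# as the display layer should render it
printed_table <- function() {
  tibble::tribble(
    ~A_mm, ~a_mm, ~h_mm, ~v_abc_ml, ~v_sc_ml, ~ratio,
    "0.0", "0.0", "0.0", "0.00", "0.00", "N/A",
    "10.0", "5.0", "0.2", "0.02", "0.01", "1.33",
    "20.0", "10.0", "0.6", "0.3", "0.2", "1.33",
    "30.0", "15.0", "1.4", "1.3", "1.0", "1.33",
    "40.0", "20.0", "2.5", "4.3", "3.2", "1.33",
    "50.0", "25.0", "4.0", "10.5", "7.9", "1.32",
    "60.0", "30.0", "5.8", "22.0", "16.7", "1.32",
    "64.7", "32.4", "6.8", "30.0", "22.8", "1.31",
    "65.0", "32.5", "6.9", "30.5", "23.2", "1.31",
    "67.6", "33.8", "7.5", "35.9", "27.4", "1.31",
    "69.1", "34.6", "7.9", "39.3", "30.0", "1.31",
    "70.0", "35.0", "8.1", "41.4", "31.6", "1.31",
    "80.0", "40.0", "10.7", "71.8", "55.2", "1.30",
    "90.0", "45.0", "13.9", "117.5", "90.9", "1.29",
    "100.0", "50.0", "17.6", "183.8", "143.5", "1.28",
    "110.0", "55.0", "21.9", "277.6", "219.2", "1.27",
    "120.0", "60.0", "27.1", "408.4", "327.1", "1.25",
    "130.0", "65.0", "33.4", "590.4", "481.7", "1.23",
    "140.0", "70.0", "41.3", "847.1", "708.9", "1.19"
  )
}

# an exact (closed-form) synthetic measurement table: manual measurements
# replaced by the model's own b and c, used to test validation plumbing
exact_cohort <- function(a, phi_deg, r = 80, z_basal = 0) {
  caps <- lapply(a, function(ai) spherical_cap(r = r, a = ai))
  h <- vapply(caps, function(cp) cp$h, numeric(1))
  b <- mapply(function(cp, p) thickness_exact(cp, p), caps, phi_deg)
  cc <- mapply(function(cp, p) cc_extent(cp, p), caps, phi_deg)
  z_centroid <- z_basal + (r - h) * sin(phi_deg * pi / 180)
  tibble::tibble(
    case_id = sprintf("exact_%02d", seq_along(a)),
    a_mm = a, b_mm = b, c_mm = cc,
    z_cranial = z_centroid + cc, z_caudal = z_centroid - cc,
    z_basal = z_basal, z_vertex = z_basal + r
  )
}
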