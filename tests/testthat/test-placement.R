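test_that("native latitude recovers the angle from z-landmarks", {
  cap <- spherical_cap(80, h = 7.5) # r - h = 72.5
  # centroid 36.25 mm above the basal plane: asin(0.5) = 30 degrees
  expect_equal(latitude_native(36.25 + 10, 36.25 - 10, 0, cap), 30)
  expect_equal(latitude_native(10, -10, 0, cap), 0)
  expect_equal(latitude_native(72.5, 72.5, 0, cap), 90)
  # below the basal plane: negative latitude, accepted
  expect_equal(latitude_native(-26.25, -46.25, 0, cap), -30)
  expect_error(latitude_native(80, 80, 0, cap), "outside the model")
})

test_that("landmark latitude uses the per-patient vertex distance", {
  cap <- spherical_cap(80, h = 7.5)
  # z_vertex - z_basal = r: identical to the native model by substitution
  expect_equal(
    latitude_landmark(30, 10, 0, 80, cap),
    latitude_native(30, 10, 0, cap)
  )
  # r_L = 90: denominator 82.5, asin(41.25/82.5) = 30 degrees
  expect_equal(latitude_landmark(41.25 + 5, 41.25 - 5, 0, 90, cap), 30)
  expect_equal(latitude_landmark(5, -5, 0, 90, cap), 0)
  expect_error(latitude_landmark(10, 5, 0, 7, cap), "degenerate landmark")
})

test_that("exact thickness hits its closed-form limits and the 65-degree example", {
  cap <- spherical_cap(80, h = 7.5)
  expect_equal(thickness_exact(cap, 0), cap$h)
  expect_equal(thickness_exact(cap, 90), cap$a)
  expect_equal(thickness_exact(cap, -90), cap$a)
  # vertex-on-rim worked example: phi ~ 65 degrees doubles the apparent thickness
  expect_equal(round(vertex_on_rim_latitude(cap)), 65)
  expect_equal(thickness_exact(cap, 65), 15.0, tolerance = 0.1 / 15)
  # even in phi
  phis <- c(5, 20, 45, 77)
  expect_equal(thickness_exact(cap, phis), thickness_exact(cap, -phis))
  expect_error(thickness_exact(cap, 91), "90")
})

test_that("thickness is sandwiched h <= b <= a and monotone in |phi|", {
  caps <- random_caps(12, seed = 23)
  phis <- seq(0, 90, by = 7.5)
  for (i in seq_len(nrow(caps))) {
    cap <- spherical_cap(r = caps$r[i], a = caps$a[i])
    b <- thickness_exact(cap, phis)
    expect_true(all(b >= cap$h - 1e-12 & b <= cap$a + 1e-12))
    expect_true(all(diff(b) >= -1e-12))
    # extent a cos(phi) is nonincreasing on [0, 90)
    cc <- cc_extent(cap, phis)
    expect_true(all(diff(cc[phis < 90]) <= 1e-12))
  }
})

test_that("exact thickness matches the 2-D circle-ray oracle", {
  caps <- random_caps(20, seed = 5)
  set.seed(6)
  phis <- runif(20, -89, 89)
  for (i in seq_len(nrow(caps))) {
    cap <- spherical_cap(r = caps$r[i], a = caps$a[i])
    expect_equal(
      thickness_exact(cap, phis[i]),
      thickness_ray_oracle(caps$r[i], caps$h[i], phis[i]),
      tolerance = 1e-8
    )
  }
})

test_that("the small-angle approximation h/cos(phi) behaves as documented", {
  cap <- spherical_cap(80, h = 7.5)
  expect_equal(thickness_approx(cap, 0), cap$h)
  expect_equal(thickness_approx(cap, 60), 15) # 7.5 / 0.5
  expect_error(thickness_approx(cap, 90), "singular")
  # b_hat >= b everywhere, and within 1% of h of it for |phi| <= 10 degrees
  phis <- seq(0, 89, by = 1)
  b <- thickness_exact(cap, phis)
  b_hat <- thickness_approx(cap, phis)
  expect_true(all(b_hat >= b - 1e-12))
  small <- phis <= 10
  expect_true(all(abs(b[small] - b_hat[small]) / cap$h < 0.01))
})

test_that("cranial-caudal extent projects the base radius", {
  cap <- spherical_cap(80, a = 40)
  expect_equal(cc_extent(cap, 0), 40)
  expect_equal(cc_extent(cap, 60), 20)
  expect_equal(cc_extent(cap, 90), cap$h)
  expect_equal(cc_extent(cap, c(-30, 30)), rep(40 * cos(pi / 6), 2))
})

test_that("vertex-on-rim latitude covers its limiting caps", {
  expect_equal(vertex_on_rim_latitude(spherical_cap(80, h = 1e-12)), 90,
    tolerance = 1e-5
  )
  expect_equal(vertex_on_rim_latitude(spherical_cap(80, h = 80)), 0)
})

test_that("the b/h overestimation bound is a/h", {
  expect_equal(
    round(thickness_ratio_bound(c(10, 20, 30, 40, 50)), 1),
    c(15.9, 7.9, 5.1, 3.7, 2.8)
  )
  expect_equal(thickness_ratio_bound(80, 80), 1)
  expect_error(thickness_ratio_bound(0), "positive")
})

test_that("edh_predict maps a measurement table to per-case predictions", {
  tab <- exact_cohort(a = c(35, 42), phi_deg = c(0, 30))
  pred <- edh_predict(tab)
  # phi = 0 case: b = h, c = a
  expect_equal(pred$b_pred_mm[1], pred$h_mm[1])
  expect_equal(pred$c_pred_mm[1], 35)
  expect_equal(pred$phi_deg[2], 30, tolerance = 1e-9)
  expect_equal(pred$b_pred_mm, tab$b_mm, tolerance = 1e-9)
  # z_vertex - z_basal = r: native and landmark identical
  pred_l <- edh_predict(tab, model = "landmark")
  expect_equal(pred_l$b_pred_mm, pred$b_pred_mm)
  expect_equal(pred_l$c_pred_mm, pred$c_pred_mm)
  # a malformed row is skipped with a note, others still predicted
  tab_bad <- tab
  tab_bad$z_cranial[2] <- 500
  pred_bad <- edh_predict(tab_bad)
  expect_false(is.na(pred_bad$b_pred_mm[1]))
  expect_true(is.na(pred_bad$b_pred_mm[2]))
  expect_match(pred_bad$note[2], "outside the model")
  expect_error(edh_predict(tab[, -2]), "a_mm")
})
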