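test_that("cap height and base radius reproduce the model's worked values", {
  # a = 50 on the 80 mm sphere is the A = 100 lookup row
  expect_equal(round(cap_height_from_base(50, 80), 1), 17.6)
  # a 7.5 mm cap height corresponds to a 67.6 mm largest diameter
  expect_equal(round(2 * base_radius_from_height(7.5, 80), 1), 67.6)
  expect_equal(round(cap_height_from_base(33.8, 80), 1), 7.5)
  # degenerate ends: empty cap and hemisphere
  expect_equal(cap_height_from_base(0, 80), 0)
  expect_equal(cap_height_from_base(80, 80), 80)
  expect_equal(base_radius_from_height(0, 80), 0)
  expect_equal(base_radius_from_height(80, 80), 80)
})

test_that("invalid cap parameters raise domain errors naming the bound", {
  expect_error(cap_height_from_base(81, 80), "a <= r")
  expect_error(cap_height_from_base(-1, 80), "a >= 0")
  expect_error(base_radius_from_height(90, 80), "h <= r")
  expect_error(spherical_cap(r = -5, a = 1), "positive")
  expect_error(spherical_cap(80, a = 10, h = 5), "exactly one")
})

test_that("the cap relation closes and the two solvers round-trip", {
  caps <- random_caps(50, seed = 11)
  h <- cap_height_from_base(caps$a, caps$r)
  # r^2 = a^2 + (r - h)^2
  expect_equal(caps$a^2 + (caps$r - h)^2, caps$r^2, tolerance = 1e-9)
  expect_equal(base_radius_from_height(h, caps$r), caps$a, tolerance = 1e-9)
})

test_that("cap volume matches the closed hemisphere and disc integration", {
  hemi <- spherical_cap(80, h = 80)
  expect_equal(cap_volume(hemi), (2 / 3) * pi * 80^3 / 1000, tolerance = 1e-12)
  expect_equal(cap_volume(spherical_cap(80, a = 0)), 0)
  caps <- random_caps(20, seed = 3)
  for (i in seq_len(nrow(caps))) {
    cap <- spherical_cap(r = caps$r[i], a = caps$a[i])
    expect_equal(
      edh_volume_sc(cap),
      2 * cap_volume_disc(caps$r[i], caps$h[i]),
      tolerance = 1e-6
    )
  }
  # monotone increasing in h at fixed r
  v <- vapply(
    seq(1, 79, length.out = 40),
    function(h) cap_volume(spherical_cap(80, h = h)), numeric(1)
  )
  expect_true(all(diff(v) > 0))
})

test_that("both estimators reproduce the printed volumes", {
  expect_equal(round(edh_volume_abc(spherical_cap(80, A = 100)), 1), 183.8)
  expect_equal(round(edh_volume_sc(spherical_cap(80, A = 100)), 1), 143.5)
  expect_equal(round(edh_volume_abc(spherical_cap(80, A = 140)), 1), 847.1)
  expect_equal(round(edh_volume_sc(spherical_cap(80, A = 140)), 1), 708.9)
  expect_equal(edh_volume_abc(spherical_cap(80, a = 0)), 0)
  expect_equal(edh_volume_sc(spherical_cap(80, a = 0)), 0)
  # 2 V_SC is exactly twice the cap volume
  cap <- spherical_cap(80, a = 42)
  expect_identical(edh_volume_sc(cap), 2 * cap_volume(cap))
})

test_that("the ABC/SC ratio follows (4r-2h)/(3r-h) with its limits", {
  caps <- random_caps(30, seed = 7)
  for (i in seq_len(nrow(caps))) {
    cap <- spherical_cap(r = caps$r[i], a = caps$a[i])
    expect_equal(
      volume_ratio(cap),
      edh_volume_abc(cap) / edh_volume_sc(cap),
      tolerance = 1e-9
    )
  }
  # limits: 4/3 as h -> 0, exactly 1 at h = r; printed 1.19 at A = 140
  expect_equal(volume_ratio(spherical_cap(80, h = 1e-9)), 4 / 3, tolerance = 1e-9)
  expect_equal(volume_ratio(spherical_cap(80, h = 80)), 1)
  expect_equal(round(volume_ratio(spherical_cap(80, A = 140)), 2), 1.19)
  expect_error(volume_ratio(spherical_cap(80, h = 0)), "undefined")
  # ordering: ABC > SC strictly inside (0, r), ratio in (1, 4/3), decreasing in h
  hs <- seq(0.5, 79.5, length.out = 50)
  ratios <- vapply(hs, function(h) volume_ratio(spherical_cap(80, h = h)), numeric(1))
  expect_true(all(ratios > 1 & ratios < 4 / 3))
  expect_true(all(diff(ratios) < 0))
})

test_that("diameter_for_volume inverts both estimators at the 30 mL threshold", {
  expect_equal(round(diameter_for_volume(30, "abc"), 1), 64.7)
  expect_equal(round(diameter_for_volume(30, "sc"), 1), 69.1)
  expect_equal(
    round(diameter_for_volume(30, "sc") - diameter_for_volume(30, "abc"), 1),
    4.4
  )
  # composition identity at solver tolerance
  for (v in c(0.5, 10, 30, 200, 900)) {
    A_sc <- diameter_for_volume(v, "sc")
    expect_equal(edh_volume_sc(spherical_cap(80, A = A_sc)), v, tolerance = 1e-6)
    A_abc <- diameter_for_volume(v, "abc")
    expect_equal(edh_volume_abc(spherical_cap(80, A = A_abc)), v, tolerance = 1e-6)
  }
  # strictly monotone in the target
  targets <- c(1, 5, 20, 50, 100, 400)
  expect_true(all(diff(vapply(targets, diameter_for_volume, numeric(1), method = "sc")) > 0))
  # continuity at the origin: a vanishing volume needs a vanishing diameter
  A_tiny <- diameter_for_volume(1e-4, "sc")
  expect_lt(A_tiny, 5)
  expect_equal(edh_volume_sc(spherical_cap(80, A = A_tiny)), 1e-4, tolerance = 1e-6)
  # beyond the model's capacity (two caps = the whole sphere for "sc")
  expect_error(diameter_for_volume(3000, "sc"), "exceeds")
  expect_error(diameter_for_volume(3000, "abc"), "exceeds")
  expect_error(diameter_for_volume(-1, "sc"), "positive")
})

test_that("edh_volumes augments a diameter table pipe-style", {
  out <- tibble::tibble(A_mm = c(0, 50, 100)) |> edh_volumes()
  expect_s3_class(out, "tbl_df")
  expect_equal(out$h_mm, cap_height_from_base(c(0, 25, 50), 80))
  expect_true(is.na(out$ratio[1]))
  expect_equal(round(out$v_sc_ml[3], 1), 143.5)
  expect_error(edh_volumes(tibble::tibble(x = 1)), "A_mm")
})
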