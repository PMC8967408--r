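test_that("junction binning reports exact medians and IQRs", {
  j <- tibble::tibble(angle_deg = c(1, 2, 3, 4, 4.9),
                      intensity = c(1, 2, 3, 4, 5))
  b <- bin_junction_intensity(j)
  first <- b[b$angle_lo == 0, ]
  expect_equal(first$median, 3)
  expect_equal(first$iqr, 2)
  expect_equal(first$n, 5L)
  expect_equal(sum(b$n), nrow(j))
  # constant intensities: every non-empty bin has that median, zero IQR
  j2 <- gen_junctions(7, n = 200, seed = 1)
  b2 <- bin_junction_intensity(j2)
  expect_true(all(b2$median[b2$n > 0] == 7))
  expect_true(all(b2$iqr[b2$n > 0] == 0))
  expect_error(bin_junction_intensity(j2[0, ]), "empty")
})

test_that("junction binning is permutation invariant and angle-checked", {
  set.seed(2)
  j <- gen_junctions(function(th) 10 + th / 10, n = 300, sigma = 1,
                     seed = 3)
  b1 <- bin_junction_intensity(j)
  b2 <- bin_junction_intensity(j[sample(nrow(j)), ])
  expect_equal(b1, b2)
  bad <- tibble::tibble(angle_deg = 95, intensity = 1)
  expect_error(bin_junction_intensity(bad), "\\[0, 90\\]")
})

test_that("an anisotropic angular profile is recovered by binned medians", {
  prof <- function(th) 10 + 5 * cos(2 * th * pi / 180)
  j <- gen_junctions(prof, n = 4000, sigma = 0.5, seed = 4)
  b <- bin_junction_intensity(j)
  expect_equal(b$median, prof(b$angle_mid), tolerance = 0.08)
  expect_gt(b$median[1], b$median[nrow(b)]) # DV-aligned bins brighter
})

test_that("pre-pupal ECM normalization anchors at 13 hAPF and idempotes", {
  s <- tibble::tibble(t = c(12, 13, 14), intensity = c(300, 200, 100))
  n1 <- normalize_prepupal_ecm(s)
  expect_equal(n1$normalized, c(1.5, 1.0, 0.5))
  # idempotent on an already-normalized series
  n2 <- normalize_prepupal_ecm(
    tibble::tibble(t = n1$t, intensity = n1$normalized))
  expect_equal(n2$normalized, n1$normalized)
  expect_error(normalize_prepupal_ecm(tibble::tibble(t = c(1, 2),
                                                     intensity = c(1, 2))),
               "reference")
  expect_error(normalize_prepupal_ecm(tibble::tibble(t = 12:14,
                                                     intensity = c(1, 0, 1))),
               "zero")
})

test_that("pupal ECM normalization subtracts the LEC floor and rescales", {
  lec <- tibble::tibble(t = 1:8,
                        intensity = c(250, 150, 120, 50, 50, 50, 50, 50))
  hist <- tibble::tibble(t = 1:8,
                         intensity = c(250, 200, 180, 150, 120, 100, 90, 80))
  out <- normalize_pupal_ecm(lec, hist)
  l <- out[out$tissue == "lec", ]
  expect_equal(l$normalized[1], 1)
  expect_equal(l$normalized[l$intensity == 150], 0.5)
  expect_equal(min(l$normalized), 0, tolerance = 1e-12)
  # identical inputs give identical outputs
  same <- normalize_pupal_ecm(lec, lec)
  expect_equal(same$normalized[same$tissue == "lec"],
               same$normalized[same$tissue == "histoblast"])
  # gain invariance: scaling raw intensities leaves the result unchanged
  out2 <- normalize_pupal_ecm(dplyr::mutate(lec, intensity = intensity * 7),
                              dplyr::mutate(hist, intensity = intensity * 7))
  expect_equal(out2$normalized, out$normalized)
  expect_error(normalize_pupal_ecm(lec[1:3, ], hist), "at least 5")
})

test_that("FUCCI channel totals normalize to the first frame", {
  rec <- tibble::tibble(
    nucleus_id = rep(c("a", "b"), 3),
    t = rep(1:3, each = 2),
    gfp = c(10, 10, 10, 10, 10, 10),
    rfp = c(60, 40, 30, 20, 0, 0)
  )
  tot <- fucci_total_series(rec)
  rfp <- tot[tot$channel == "rfp", ]
  expect_equal(rfp$normalized, c(1, 0.5, 0))
  gfp <- tot[tot$channel == "gfp", ]
  expect_true(all(gfp$normalized == 1))
})

test_that("phase calls are ratio-based, exhaustive and gain invariant", {
  rec <- tibble::tibble(
    nucleus_id = c("g1", "mid", "s"),
    gfp = c(800, 400, 100),
    rfp = c(40, 400, 800)
  )
  called <- fucci_phase_call(rec)
  expect_equal(called$phase, c("G1", "G2M", "S"))
  # every nucleus gets exactly one label
  expect_true(all(called$phase %in% c("G1", "S", "G2M", "unclassified")))
  # rescaling one channel's gain does not change calls
  rec2 <- dplyr::mutate(rec, rfp = rfp * 50)
  expect_equal(fucci_phase_call(rec2)$phase, called$phase)
  # both channels at their means sit mid-band
  expect_equal(called$phase[2], "G2M")
  expect_error(fucci_phase_call(rec[1, ]), "at least 2")
})

test_that("RFP decay in a synthetic population shows up in totals", {
  # mimic the arrest transition: RFP fades to zero while GFP persists
  frames <- purrr::map_dfr(0:5, function(i) {
    rec <- gen_fucci(c(G1 = 1, S = 0, G2M = 0), n = 50, seed = 10 + i,
                     t = 26 + i)
    rec$rfp <- rec$rfp * (1 - i / 5)
    rec
  })
  tot <- fucci_total_series(frames)
  rfp <- tot[tot$channel == "rfp", ]
  gfp <- tot[tot$channel == "gfp", ]
  expect_equal(rfp$normalized[nrow(rfp)], 0)
  expect_true(all(gfp$normalized > 0.5))
})
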