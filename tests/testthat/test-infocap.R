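test_that("whitening divides rows by their own noise std", {
  set.seed(2)
  G <- matrix(stats::rnorm(40), 8, 5)
  expect_equal(whiten(G, rep(1, 8)), G)
  expect_equal(whiten(G, rep(2, 8)), G / 2)
  stds <- c(rep(3e-15, 4), rep(1e-14, 4))
  W <- whiten(G, stds)
  for (i in 1:8) expect_equal(W[i, ], G[i, ] / stds[i])
  expect_error(whiten(G, rep(1, 3)), "per channel")
  expect_error(whiten(G, c(rep(1, 7), 0)), "positive")
})

test_that("noise model maps sensor types to spectral densities", {
  fix <- test_fixture()
  arr <- project_to_scalp(test_helmet()[1:4, ], fix$scalp)
  L <- assemble_leadfield(arr, megarray:::subset_source_space(fix$cortex_space, 1:5))
  expect_equal(noise_model(L, opm_noise = 1e-14), rep(1e-14, 4))
  expect_equal(noise_model(L, opm_noise = 1e-14, bandwidth = 4), rep(2e-14, 4))
  sq <- project_to_scalp(test_helmet()[1:4, ], fix$scalp, standoff = 0.022,
                         sensor_type = "squid_axial_grad")
  Lsq <- assemble_leadfield(sq, megarray:::subset_source_space(fix$cortex_space, 1:5))
  expect_equal(noise_model(Lsq), rep(3e-15, 4))
})

test_that("orthogonal SNR spectrum: 1x1 case, duplication, SVD oracle", {
  w <- matrix(c(1, 2, 2), 1, 3)
  expect_equal(orthogonal_snrs(w, 0.5), 0.5 * 9)    # q2 * ||w||^2
  # two identical channels: (2 q2 ||w||^2, 0)
  w2 <- rbind(w, w)
  expect_equal(sort(orthogonal_snrs(w2, 0.5), decreasing = TRUE), c(9, 0),
               tolerance = 1e-12)
  set.seed(12)
  W <- matrix(stats::rnorm(500), 10, 50)
  got <- sort(orthogonal_snrs(W, 2), decreasing = TRUE)
  sv <- svd(W, nu = 0, nv = 0)$d
  expect_equal(got, 2 * sv^2, tolerance = 1e-9)
  expect_error(orthogonal_snrs(W, 0), "positive")
})

test_that("total information follows the Shannon sum", {
  expect_equal(total_information(1), 0.5)
  expect_equal(total_information(c(3, 0)), 1.0)
  expect_equal(total_information(rep(0, 10)), 0)
  spec <- c(7, 3, 1, 0.2)
  expect_equal(total_information(spec), 0.5 * sum(log2(spec + 1)))
})

test_that("Itot is invariant under orthogonal channel mixing", {
  set.seed(4)
  W <- matrix(stats::rnorm(240), 12, 20)
  base <- total_information(orthogonal_snrs(W, 1.3))
  for (s in 1:5) {
    set.seed(s + 50)
    Q <- qr.Q(qr(matrix(stats::rnorm(144), 12)))
    mixed <- total_information(orthogonal_snrs(Q %*% W, 1.3))
    expect_equal(mixed, base, tolerance = 1e-9)
  }
})

test_that("q2 calibration closes the loop on the mean source SNR", {
  W <- matrix(stats::rnorm(60), 6, 10)
  Wn <- sweep(W, 2, sqrt(colSums(W^2)), `/`)     # unit-norm columns
  expect_equal(calibrate_source_variance(Wn), 1)
  q2 <- calibrate_source_variance(W)
  expect_equal(calibrate_source_variance(3 * W), q2 / 9)
  expect_equal(mean(q2 * colSums(W^2)), 1, tolerance = 1e-12)
  # closed loop on a fixture array
  L <- test_leadfields("squid")
  Wf <- whiten(L$cortex, noise_model(L$cortex))
  q2f <- calibrate_source_variance(Wf)
  expect_equal(mean(q2f * colSums(Wf^2)), 1, tolerance = 1e-9)
})

test_that("info_capacity results are self-consistent and noise-monotone", {
  L <- test_leadfields("opm")
  q2 <- 1e-18
  r10 <- info_capacity(L$cerebellum, noise_model(L$cerebellum, opm_noise = 10e-15),
                       q2)
  r15 <- info_capacity(L$cerebellum, noise_model(L$cerebellum, opm_noise = 15e-15),
                       q2)
  # recomputability from the stored spectrum
  expect_equal(r10$itot, total_information(r10$snr_spectrum), tolerance = 1e-9)
  expect_equal(r10$n_channels, length(r10$snr_spectrum))
  expect_true(all(diff(r10$snr_spectrum) <= 1e-12))
  # lower noise -> strictly more information
  expect_gt(r10$itot, r15$itot)
  # whitened gain scales by 1.5, eigenvalues by 2.25
  W15 <- whiten(L$cerebellum, noise_model(L$cerebellum, opm_noise = 15e-15))
  expect_equal(sort(orthogonal_snrs(W15 * 1.5, q2), decreasing = TRUE),
               r10$snr_spectrum, tolerance = 1e-9)
})

test_that("triaxial arrays cannot carry less information than single-axis", {
  Ls <- test_leadfields("opm")
  Lt <- test_leadfields("triaxial")
  q2 <- 1e-18
  for (reg in c("cortex", "cerebellum")) {
    i1 <- info_capacity(Ls[[reg]], noise_model(Ls[[reg]], opm_noise = 1e-14), q2)
    i3 <- info_capacity(Lt[[reg]], noise_model(Lt[[reg]], opm_noise = 1e-14), q2)
    expect_gte(i3$itot, i1$itot)
  }
})

test_that("whole-brain information is subadditive and dominates regions", {
  Ls <- test_leadfields("squid")
  q2 <- 1e-18
  noise <- noise_model(Ls$cortex)
  wb <- megarray:::cbind_leadfields(Ls$cortex, Ls$cerebellum)
  i_wb <- info_capacity(wb, noise, q2)$itot
  i_ctx <- info_capacity(Ls$cortex, noise, q2)$itot
  i_crb <- info_capacity(Ls$cerebellum, noise, q2)$itot
  expect_lte(i_wb, i_ctx + i_crb)
  expect_gte(i_wb, i_ctx)
  expect_gte(i_wb, i_crb)
})

test_that("sensor-count sweep is monotone in count and ordered in noise", {
  fix <- test_fixture()
  spaces <- list(cortex = fix$cortex_space, cerebellum = fix$cerebellum_space)
  sweep_tbl <- itot_sweep(fix$scalp, spaces, test_helmet(), counts = c(8, 16, 24),
                          target_vertices = 450, n_basis = 30)
  expect_s3_class(sweep_tbl, "itot_sweep")
  expect_true(all(c("cortex", "cerebellum", "whole_brain") %in% sweep_tbl$region))
  by_cell <- split(sweep_tbl,
                   paste(sweep_tbl$family, sweep_tbl$noise_ft, sweep_tbl$region))
  for (cell in by_cell) {
    cell <- cell[order(cell$count), ]
    expect_true(all(diff(cell$itot_bits) >= -1e-9))   # nested arrays
  }
  # 10 vs 15 fT/rtHz ordering for every opm configuration
  opm <- sweep_tbl[sweep_tbl$family == "opm", ]
  wide <- tidyr::pivot_wider(opm[, c("count", "region", "noise_ft", "itot_bits")],
                             names_from = "noise_ft", values_from = "itot_bits")
  expect_true(all(wide$`10` > wide$`15`))
  # regional containment: cerebellum <= whole brain
  cmp <- tidyr::pivot_wider(
    sweep_tbl[, c("family", "noise_ft", "count", "region", "itot_bits")],
    names_from = "region", values_from = "itot_bits")
  expect_true(all(cmp$cerebellum <= cmp$whole_brain + 1e-9))
  # triaxial >= single-axis at equal count and noise
  tri <- sweep_tbl[sweep_tbl$family == "triaxial_opm", ]
  for (i in seq_len(nrow(tri))) {
    match_row <- opm[opm$count == tri$count[i] & opm$region == tri$region[i] &
                     opm$noise_ft == tri$noise_ft[i], ]
    expect_gte(tri$itot_bits[i], match_row$itot_bits - 1e-9)
  }
})

test_that("tidy and glance methods expose the capacity results", {
  L <- test_leadfields("squid")
  r <- info_capacity(L$cerebellum, noise_model(L$cerebellum), 1e-18)
  td <- tidy(r)
  expect_equal(nrow(td), r$n_channels)
  expect_equal(sum(td$bits), r$itot, tolerance = 1e-9)
  g <- glance(r)
  expect_equal(g$itot_bits, r$itot)
  gl <- glance(L$cerebellum)
  expect_equal(gl$n_channels, 102L)
  expect_s3_class(autoplot(sensitivity_map(L$cerebellum)), "ggplot")
})
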