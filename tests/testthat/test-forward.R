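test_that("radial dipoles are silent and the field is linear in the moment", {
  p0 <- c(0.02, -0.03, 0.06)
  B_rad <- dipole_field_sphere(p0, p0 / sqrt(sum(p0^2)), c(0.05, 0.02, 0.11))
  expect_lt(sqrt(sum(B_rad^2)), 1e-28)
  q <- c(1e-8, 2e-8, 0)
  B1 <- dipole_field_sphere(p0, q, c(0.05, 0.02, 0.11))
  B2 <- dipole_field_sphere(p0, 2 * q, c(0.05, 0.02, 0.11))
  expect_equal(B2, 2 * B1, tolerance = 1e-14)
  expect_error(dipole_field_sphere(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0.1)), "center")
  expect_error(dipole_field_sphere(p0, q, c(0, 0, 0.05)), "inside")
})

test_that("sphere-model field matches the single-layer quadrature oracle", {
  set.seed(101)
  n_bad <- 0
  for (i in 1:20) {
    # random tangential dipole at <= 7 cm radius, field point at 10-12 cm
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    pos <- dir * stats::runif(1, 0.04, 0.07)
    tang <- stats::rnorm(3)
    tang <- tang - sum(tang * dir) * dir
    tang <- tang / sqrt(sum(tang^2)) * 1e-8
    fdir <- stats::rnorm(3); fdir <- fdir / sqrt(sum(fdir^2))
    fp <- fdir * stats::runif(1, 0.10, 0.12)
    B_sarvas <- dipole_field_sphere(pos, tang, fp)[1, ]
    B_oracle <- oracle_field_single_layer(pos, tang, fp, R = 0.09, subdivision = 4)
    rel <- sqrt(sum((B_sarvas - B_oracle)^2)) / sqrt(sum(B_oracle^2))
    if (rel > 0.01) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})

test_that("quadrature oracle improves with boundary-mesh refinement", {
  pos <- c(0, 0.03, 0.06)
  q <- c(1e-8, 0, 0)
  q <- q - sum(q * pos) / sum(pos^2) * pos
  fp <- c(0.02, 0.01, 0.115)
  B_ref <- dipole_field_sphere(pos, q, fp)[1, ]
  err <- vapply(2:3, function(lev) {
    B <- oracle_field_single_layer(pos, q, fp, subdivision = lev)
    sqrt(sum((B - B_ref)^2)) / sqrt(sum(B_ref^2))
  }, 1)
  expect_lt(err[2], err[1])
})

test_that("potential series reduces to the infinite-medium dipole potential", {
  # validates the series (and its tangential sign convention) independently
  r0 <- c(0.01, 0.02, 0.05)
  q <- c(3e-9, -1e-9, 2e-9)
  set.seed(7)
  pts <- matrix(stats::rnorm(30), 10, 3)
  pts <- pts / sqrt(rowSums(pts^2)) * 0.085
  v_series <- sphere_potential_series(pts, r0, q, R = 0.09, surface = FALSE)
  d <- sweep(pts, 2, r0)
  v_direct <- drop(d %*% q) / (4 * pi * 0.3 * rowSums(d^2)^1.5)
  expect_equal(v_series, v_direct, tolerance = 1e-8)
})

test_that("channel gains respect projection, gradiometer differencing and quadrature", {
  p0 <- c(0, 0.02, 0.055)
  ori <- c(1, 0, 0); ori <- ori - sum(ori * p0) / sum(p0^2) * p0
  ori <- ori / sqrt(sum(ori^2))
  fp <- c(0, 0.03, 0.4)
  B <- dipole_field_sphere(p0, ori, fp)[1, ]
  # orientation orthogonal to the local field -> zero gain
  perp <- megarray:::cross3(matrix(B, 1, 3), matrix(c(0, 0, 1), 1, 3))[1, ]
  perp <- perp / sqrt(sum(perp^2))
  g <- channel_gain(list(points = fp, weights = 1, orientation = perp), p0, ori)
  expect_lt(abs(g), 1e-20)
  # gradiometer with identical points sees nothing
  g2 <- channel_gain(list(points = rbind(fp, fp), weights = c(1, -1),
                          orientation = c(0, 0, 1)), p0, ori)
  expect_equal(g2, 0)
  # 4-point square loop vs its center, far smooth source: < 1%
  t1 <- c(1, 0, 0); t2 <- c(0, 1, 0); h <- 0.0105
  loop <- list(points = rbind(fp + h * t1 + h * t2, fp + h * t1 - h * t2,
                              fp - h * t1 + h * t2, fp - h * t1 - h * t2),
               weights = rep(0.25, 4), orientation = c(0, 0, 1))
  center <- list(points = fp, weights = 1, orientation = c(0, 0, 1))
  gl <- channel_gain(loop, p0, ori)
  gc <- channel_gain(center, p0, ori)
  expect_lt(abs(gl - gc) / abs(gc), 0.01)
})

test_that("lead-field assembly: identity, column ordering, superposition", {
  fix <- test_fixture()
  arr <- project_to_scalp(test_helmet()[1:5, ], fix$scalp, name = "tiny")
  sp <- megarray:::subset_source_space(fix$cerebellum_space, 1:7)
  L <- assemble_leadfield(arr, sp)
  expect_equal(dim(L), c(5L, 7L))
  ch <- make_channels(arr)
  g11 <- channel_gain(list(points = ch$points[[1]], weights = ch$weights[[1]],
                           orientation = ch$orientation[[1]]),
                      sp$positions[1, ], sp$normals[1, ])
  expect_equal(L$gain[1, 1], g11)
  # permuting sources permutes columns identically
  perm <- c(3, 1, 7, 2, 5, 4, 6)
  Lp <- assemble_leadfield(arr, megarray:::subset_source_space(sp, perm))
  expect_equal(Lp$gain, L$gain[, perm], ignore_attr = TRUE)
  # superposition: concatenated spaces = column concatenation
  spA <- megarray:::subset_source_space(sp, 1:3)
  spB <- megarray:::subset_source_space(sp, 4:7)
  LA <- assemble_leadfield(arr, spA)
  LB <- assemble_leadfield(arr, spB)
  expect_equal(cbind(LA$gain, LB$gain), L$gain, ignore_attr = TRUE)
})

test_that("forced-radial source spaces are silent through assembly", {
  fix <- test_fixture()
  arr <- project_to_scalp(test_helmet()[1:10, ], fix$scalp, name = "tiny")
  sp <- megarray:::subset_source_space(fix$cerebellum_space, 1:50)
  sp_rad <- sp
  sp_rad$normals <- sp$positions / sqrt(rowSums(sp$positions^2))
  L_fold <- assemble_leadfield(arr, sp)
  L_rad <- assemble_leadfield(arr, sp_rad)
  expect_lt(max(abs(L_rad$gain)), 1e-3 * max(abs(L_fold$gain)))
})

test_that("channel gains are equivariant under global rotation", {
  Q <- random_rotation(11)
  fix <- test_fixture()
  arr <- project_to_scalp(test_helmet()[1:4, ], fix$scalp, name = "rot")
  sp <- megarray:::subset_source_space(fix$cortex_space, seq(1, 400, by = 40))
  L <- assemble_leadfield(arr, sp)
  arr_rot <- arr
  arr_rot[, c("x", "y", "z")] <- as.matrix(arr[, c("x", "y", "z")]) %*% t(Q)
  arr_rot[, c("rx", "ry", "rz")] <- as.matrix(arr[, c("rx", "ry", "rz")]) %*% t(Q)
  arr_rot[, c("t1x", "t1y", "t1z")] <- as.matrix(arr[, c("t1x", "t1y", "t1z")]) %*% t(Q)
  arr_rot[, c("t2x", "t2y", "t2z")] <- as.matrix(arr[, c("t2x", "t2y", "t2z")]) %*% t(Q)
  sp_rot <- source_space(sp$positions %*% t(Q), sp$normals %*% t(Q),
                         sp$region, sp$vertex_ids)
  L_rot <- assemble_leadfield(arr_rot, sp_rot)
  expect_equal(L_rot$gain, L$gain, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("near-boundary exclusion uses exact triangle distances", {
  boundary <- make_sphere_mesh(0.08, 3)
  # 93 safe sources well inside; 7 planted 2 mm under face centroids
  set.seed(3)
  dirs <- matrix(stats::rnorm(279), 93, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  safe <- dirs * 0.06
  faces <- seq(10, 70, by = 10)
  cent <- t(vapply(faces, function(f)
    colMeans(boundary$vertices[boundary$faces[f, ], ]), numeric(3)))
  near <- cent - 0.002 * cent / sqrt(rowSums(cent^2))
  sp <- source_space(rbind(safe, near), rbind(dirs, dirs[1:7, ]), "cortex")
  kept <- exclude_near_boundary(sp, boundary, 0.003)
  expect_equal(length(kept), 93L)
  expect_equal(kept$vertex_ids, 1:93)
  # no-op when everything is far
  sp_far <- source_space(safe, dirs, "cortex")
  expect_equal(length(exclude_near_boundary(sp_far, boundary, 0.003)), 93L)
  # total exclusion warns
  expect_warning(res <- exclude_near_boundary(sp_far, boundary, Inf), "excluded")
  expect_equal(length(res), 0L)
})

test_that("lead-field containers round-trip and rescale units", {
  fix <- test_fixture()
  arr <- project_to_scalp(test_helmet()[1:6, ], fix$scalp, name = "io")
  sp <- megarray:::subset_source_space(fix$cerebellum_space, 1:9)
  L <- assemble_leadfield(arr, sp)
  prefix <- file.path(withr::local_tempdir(), "lf")
  export_leadfield(L, prefix)
  L2 <- import_leadfield(prefix)
  expect_identical(L2$gain, unname(L$gain))
  expect_equal(L2$model_tag, "imported")
  # unit algebra: fT/(nA.m) = 1e-15 / 1e-9 of T/(A.m)
  expect_equal(megarray:::leadfield_unit_scale("fT/(nA.m)"), 1e-6)
  expect_equal(megarray:::leadfield_unit_scale("T/(A.m)"), 1)
  meta_path <- paste0(prefix, "_meta.json")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  meta$units <- "fT/(nA.m)"
  jsonlite::write_json(meta, meta_path, digits = NA, auto_unbox = TRUE)
  L3 <- import_leadfield(prefix)
  expect_equal(L3$gain, unname(L$gain) * 1e-6)
  # truncated gain file is a format error
  gl <- readLines(paste0(prefix, "_gain.tsv"))
  writeLines(gl[1:3], paste0(prefix, "_gain.tsv"))
  expect_error(import_leadfield(prefix), "shape|match")
  # mismatched metadata is rejected
  expect_error(import_leadfield(file.path(withr::local_tempdir(), "absent")),
               "incomplete")
})
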