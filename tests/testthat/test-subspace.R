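test_that("geodesic patches equal brute-force Dijkstra balls on a grid", {
  m <- make_grid_mesh(9, 9, 1, 1)   # unit edge length 1/8
  sp <- source_space(m$vertices, matrix(rep(c(0, 0, 1), each = 81), ncol = 3),
                     "cortex", parent_mesh = m)
  h <- 1 / 8
  patches <- geodesic_patches(sp, radius = 2.5 * h, spacing = 4 * h)
  for (i in seq_len(nrow(patches))) {
    seed_idx <- match(patches$seed_vertex[i], sp$vertex_ids)
    d <- oracle_dijkstra(m, seed_idx)
    expect_setequal(patches$members[[i]], which(d <= 2.5 * h))
    expect_true(seed_idx %in% patches$members[[i]])
  }
  # coverage: every vertex within `spacing` of some seed
  seeds <- match(patches$seed_vertex, sp$vertex_ids)
  dmin <- apply(vapply(seeds, function(s) oracle_dijkstra(m, s), numeric(81)), 1, min)
  expect_true(all(dmin <= 4 * h))
})

test_that("patch degenerate cases: tiny radius and diameter spacing", {
  m <- make_grid_mesh(6, 6, 1, 1)
  sp <- source_space(m$vertices, matrix(rep(c(0, 0, 1), each = 36), ncol = 3),
                     "cortex", parent_mesh = m)
  tiny <- geodesic_patches(sp, radius = 1e-9, spacing = 0.5)
  expect_true(all(tiny$n_members == 1L))
  expect_equal(unlist(tiny$members), match(tiny$seed_vertex, sp$vertex_ids),
               ignore_attr = TRUE)
  one <- geodesic_patches(sp, radius = 0.2, spacing = 10)
  expect_equal(nrow(one), 1L)
  expect_error(geodesic_patches(sp, radius = 0), "positive")
})

test_that("principal-angle cosines: identity, orthogonality, projector oracle", {
  set.seed(31)
  A <- matrix(stats::rnorm(18), 6, 3)
  r <- principal_angle_cosines(A, A)
  expect_equal(r$cosines, rep(1, 3))
  # coordinate subspaces on disjoint channels are orthogonal
  B1 <- rbind(diag(2), matrix(0, 4, 2))
  B2 <- rbind(matrix(0, 2, 2), diag(2), matrix(0, 2, 2))
  expect_equal(principal_angle_cosines(B1, B2)$cosines, c(0, 0))
  # 50 seeded random pairs against the projector-product oracle
  for (s in 1:50) {
    set.seed(s)
    q <- sample(1:4, 1); p <- sample(1:4, 1)
    A <- matrix(stats::rnorm(8 * q), 8, q)
    B <- matrix(stats::rnorm(8 * p), 8, p)
    got <- principal_angle_cosines(A, B)
    expect_equal(got$cosines, oracle_principal_cosines(A, B), tolerance = 1e-6)
    expect_length(got$cosines, min(got$rank_a, got$rank_b))
    expect_true(all(diff(got$cosines) <= 1e-12))
    expect_true(all(got$cosines >= 0 & got$cosines <= 1))
  }
  expect_error(principal_angle_cosines(matrix(0, 4, 2), A[1:4, ]), "zero")
})

test_that("cosines are invariant to basis recombination and channel rotation", {
  set.seed(17)
  A <- matrix(stats::rnorm(24), 8, 3)
  B <- matrix(stats::rnorm(16), 8, 2)
  base <- principal_angle_cosines(A, B)$cosines
  for (s in 1:5) {
    set.seed(s + 100)
    Ma <- matrix(stats::rnorm(9), 3) + 3 * diag(3)   # well-conditioned mixing
    Mb <- matrix(stats::rnorm(4), 2) + 3 * diag(2)
    expect_equal(principal_angle_cosines(A %*% Ma, B %*% Mb)$cosines, base,
                 tolerance = 1e-9)
    Q <- qr.Q(qr(matrix(stats::rnorm(64), 8)))
    expect_equal(principal_angle_cosines(Q %*% A, Q %*% B)$cosines, base,
                 tolerance = 1e-9)
  }
  # symmetry in the arguments
  expect_equal(principal_angle_cosines(B, A)$cosines, base, tolerance = 1e-12)
  # enlarging one subspace cannot decrease the top cosine
  B_plus <- cbind(B, stats::rnorm(8))
  expect_gte(principal_angle_cosines(A, B_plus)$cosines[1], base[1] - 1e-12)
})

test_that("mean subspace correlation and high-correlation fractions", {
  expect_equal(mean_subspace_correlation(c(1, 1, 1)), 1)
  expect_equal(mean_subspace_correlation(c(1, 0)), 0.5)
  r <- principal_angle_cosines(matrix(stats::rnorm(12), 4, 3),
                               matrix(stats::rnorm(8), 4, 2))
  mc <- mean_subspace_correlation(r)
  expect_gte(mc, min(r$cosines)); expect_lte(mc, max(r$cosines))
  fake <- function(cosines) structure(list(cosines = cosines, rank_a = 4,
                                           rank_b = 4), class = "subspace_result")
  expect_equal(high_correlation_fraction(fake(rep(0.9, 5))), 100)
  expect_equal(high_correlation_fraction(fake(rep(0.1, 5))), 0)
  expect_equal(high_correlation_fraction(fake(c(0.6, 0.4, 0.55, 0.2))), 50)
})

test_that("patch-to-patch maps: identity patch, range, standoff ordering", {
  L <- test_leadfields("opm")
  ctx_patches <- test_patches("cortex")
  crb_patches <- test_patches("cerebellum")
  # a cerebellar 'patch' with the cortical patch's own columns scores 1
  fakeL <- L$cortex
  m_self <- patch_to_patch_map(L$cortex, ctx_patches[3, ], fakeL, ctx_patches[3, ])
  expect_equal(m_self$correlation, 1.0, tolerance = 1e-9)
  m <- patch_to_patch_map(L$cortex, ctx_patches[3, ], L$cerebellum, crb_patches)
  expect_true(all(m$correlation >= 0 & m$correlation <= 1))
  expect_equal(nrow(m), nrow(crb_patches))
})

test_that("patch-to-whole maps: containment, constant coverage, distance gradient", {
  L <- test_leadfields("opm")
  ctx_patches <- test_patches("cortex")
  # cerebellar subspace covering the full channel space -> all values 1
  small <- test_fixture()
  arr6 <- project_to_scalp(test_helmet()[1:6, ], small$scalp, name = "six")
  L6_ctx <- assemble_leadfield(arr6, small$cortex_space)
  L6_crb <- assemble_leadfield(arr6, small$cerebellum_space)
  full <- patch_to_whole_map(L6_ctx, ctx_patches, L6_crb)
  expect_equal(full$patches$correlation, rep(1, nrow(ctx_patches)),
               tolerance = 1e-6)
  # a single patch containing every vertex gives a constant vertex map
  allp <- tibble::tibble(seed_vertex = ctx_patches$seed_vertex[1],
                         members = list(seq_len(ncol(L$cortex$gain))),
                         n_members = ncol(L$cortex$gain))
  class(allp) <- class(ctx_patches)
  one <- patch_to_whole_map(L$cortex, allp, L$cerebellum)
  expect_equal(length(unique(one$vertices$correlation)), 1L)
  # posterior cortical patches correlate more with the cerebellum than
  # anterior ones (distance gradient), for the triaxial array where the
  # map is non-degenerate
  Lt <- test_leadfields("triaxial")
  p2w <- patch_to_whole_map(Lt$cortex, ctx_patches, Lt$cerebellum)
  fix <- test_fixture()
  seed_pos <- fix$cortex_space$positions[
    match(ctx_patches$seed_vertex, fix$cortex_space$vertex_ids), , drop = FALSE]
  crb_c <- colMeans(fix$cerebellum_space$positions)
  d_to_crb <- sqrt(rowSums(sweep(seed_pos, 2, crb_c)^2))
  near <- p2w$patches$correlation[d_to_crb <= stats::median(d_to_crb)]
  far <- p2w$patches$correlation[d_to_crb > stats::median(d_to_crb)]
  expect_gt(mean(near), mean(far))
})
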