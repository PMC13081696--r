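#' Default pipeline run configuration
#'
#' One nested list drives all three analyses. All randomness flows from
#' `seed`; a resolved copy of the configuration (with its hash and the
#' package version) is written into every output directory.
#'
#' @param ... overrides of top-level fields.
#' @returns named list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    fixture = list(),                 # overrides for fixture_config()
    arrays = list(
      list(name = "squid_102", type = "squid_mag", n = 102,
           channel_mode = "single_axis"),
      list(name = "opm_102", type = "opm", n = 102,
           channel_mode = "single_axis"),
      list(name = "triaxial_opm_102", type = "opm", n = 102,
           channel_mode = "triaxial")),
    noise = list(opm = c(10e-15, 15e-15), squid = 3e-15),
    patch = list(radius = 0.010, spacing = 0.015),
    sweep = list(counts = c(10, 25, 50, 100), target_vertices = 2000, n_basis = 60),
    exclusion_mm = 3,
    moment = 1e-7,
    out_dir = NULL)
  mod <- list(...)
  cfg[names(mod)] <- mod
  cfg
}

resolve_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  base <- run_config()
  base[names(config)] <- config
  base
}

write_provenance <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  resolved <- cfg
  resolved$config_hash <- rlang::hash(cfg)
  resolved$package_version <- as.character(utils::packageVersion("megarray"))
  jsonlite::write_json(resolved, file.path(out_dir, "resolved_config.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(resolved)
}

# Fixture geometry with the near-boundary exclusion applied.
build_run_geometry <- function(cfg) {
  fix <- make_head_fixture(do.call(fixture_config, cfg$fixture), seed = cfg$seed)
  dmin <- cfg$exclusion_mm / 1000
  fix$cortex_space <- exclude_near_boundary(fix$cortex_space, fix$inner_boundary, dmin)
  fix$cerebellum_space <- exclude_near_boundary(fix$cerebellum_space,
                                                fix$inner_boundary, dmin)
  fix
}

# Build one configured array on the fixture scalp.
build_array <- function(spec, fix) {
  standoff <- if (!is.null(spec$standoff)) spec$standoff else default_standoff(spec$type)
  pos <- helmet_seed_positions(spec$n, radius = fix$config$scalp_radius + 0.03)
  arr <- project_to_scalp(pos, fix$scalp, standoff = standoff,
                          sensor_type = spec$type,
                          channel_mode = spec$channel_mode, name = spec$name)
  arr
}

#' Run the sensitivity-map analysis
#'
#' For every configured array: raw and per-sensor-normalized sensitivity
#' maps over both source regions, density summaries, the cortex-to-
#' cerebellum mean-sensitivity ratio, and cerebellar mean ratios of each
#' array relative to the first configured array.
#'
#' @param config a [run_config()] list or path to a JSON config.
#' @returns list with `summary` (one tibble row per array), `maps` (named
#'   list of `sensitivity_map` tibbles) and `fixture`; written to
#'   `config$out_dir` when set (`map_<array>.csv`, `sensitivity_summary.json`,
#'   `resolved_config.json`).
#' @export
run_sensitivity <- function(config = run_config()) {
  cfg <- resolve_config(config)
  fix <- build_run_geometry(cfg)
  maps <- list()
  rows <- list()
  for (spec in cfg$arrays) {
    arr <- build_array(spec, fix)
    L_ctx <- assemble_leadfield(arr, fix$cortex_space, fix$sphere_center)
    L_crb <- assemble_leadfield(arr, fix$cerebellum_space, fix$sphere_center)
    m_ctx <- sensitivity_map(L_ctx, moment = cfg$moment)
    m_crb <- sensitivity_map(L_crb, moment = cfg$moment)
    map <- dplyr::bind_rows(m_ctx, m_crb)
    class(map) <- class(m_ctx)
    attr(map, "moment") <- cfg$moment
    attr(map, "n_sensors") <- nrow(arr)
    attr(map, "per_sensor") <- FALSE
    map$sensitivity_per_sensor <- map$sensitivity / nrow(arr)
    maps[[spec$name]] <- map
    dens_crb <- summarize_density(m_crb$sensitivity)
    rows[[spec$name]] <- dplyr::bind_cols(
      tibble::tibble(array = spec$name, n_sensors = nrow(arr),
                     n_channels = n_channels(arr),
                     mean_cortex = mean(m_ctx$sensitivity),
                     mean_cerebellum = mean(m_crb$sensitivity),
                     cortex_cerebellum_ratio = region_sensitivity_ratio(m_ctx, m_crb)),
      dens_crb)
  }
  summary <- dplyr::bind_rows(rows)
  ref <- summary$mean_cerebellum[1]
  summary$cerebellum_ratio_vs_first <- summary$mean_cerebellum / ref
  if (!is.null(cfg$out_dir)) {
    write_provenance(cfg, cfg$out_dir)
    for (nm in names(maps))
      utils::write.csv(as.data.frame(maps[[nm]]),
                       file.path(cfg$out_dir, paste0("map_", nm, ".csv")),
                       row.names = FALSE)
    jsonlite::write_json(summary, file.path(cfg$out_dir, "sensitivity_summary.json"),
                         digits = NA, dataframe = "rows")
  }
  invisible(list(summary = summary, maps = maps, fixture = fix))
}

#' Run the subspace-correlation analysis
#'
#' For every configured array: the patch-to-patch cerebellar map for a
#' designated cortical seed patch (default: the cortical patch nearest the
#' cerebellum), the patch-to-whole cortical map, and the percentage of
#' highly correlated subspace angles per cortical patch.
#'
#' @param config a [run_config()] list or path to JSON.
#' @param threshold high-correlation cosine threshold.
#' @returns list with `summary` (tibble per array: mean patch-to-patch and
#'   patch-to-whole correlations, mean high-correlation percentage),
#'   `patch_maps`, `cortical_maps`, `patches`, `fixture`.
#' @export
run_correlation <- function(config = run_config(), threshold = 0.5) {
  cfg <- resolve_config(config)
  fix <- build_run_geometry(cfg)
  ctx_patches <- geodesic_patches(fix$cortex_space, cfg$patch$radius, cfg$patch$spacing)
  crb_patches <- geodesic_patches(fix$cerebellum_space, cfg$patch$radius,
                                  cfg$patch$spacing)
  # designated seed: cortical patch whose seed vertex is closest to the
  # cerebellum centroid (posterior-inferior cortex)
  crb_centroid <- colMeans(fix$cerebellum_space$positions)
  seed_pos <- fix$cortex_space$positions[
    match(ctx_patches$seed_vertex, fix$cortex_space$vertex_ids), , drop = FALSE]
  seed_idx <- which.min(rowSums(sweep(seed_pos, 2, crb_centroid)^2))
  rows <- list(); patch_maps <- list(); cortical_maps <- list()
  for (spec in cfg$arrays) {
    arr <- build_array(spec, fix)
    L_ctx <- assemble_leadfield(arr, fix$cortex_space, fix$sphere_center)
    L_crb <- assemble_leadfield(arr, fix$cerebellum_space, fix$sphere_center)
    p2p <- patch_to_patch_map(L_ctx, ctx_patches[seed_idx, ], L_crb, crb_patches)
    p2w <- patch_to_whole_map(L_ctx, ctx_patches, L_crb)
    hi <- high_correlation_fraction(p2w$patches$result, threshold)
    patch_maps[[spec$name]] <- p2p
    cortical_maps[[spec$name]] <- p2w
    rows[[spec$name]] <- tibble::tibble(
      array = spec$name, n_sensors = nrow(arr), n_channels = n_channels(arr),
      mean_patch_correlation = mean(p2p$correlation),
      sd_patch_correlation = stats::sd(p2p$correlation),
      mean_cortical_correlation = mean(p2w$patches$correlation),
      mean_high_fraction_pct = mean(hi))
  }
  summary <- dplyr::bind_rows(rows)
  if (!is.null(cfg$out_dir)) {
    write_provenance(cfg, cfg$out_dir)
    for (nm in names(patch_maps)) {
      utils::write.csv(as.data.frame(patch_maps[[nm]][, c("seed_vertex", "correlation")]),
                       file.path(cfg$out_dir, paste0("cerebellar_map_", nm, ".csv")),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(cortical_maps[[nm]]$vertices),
                       file.path(cfg$out_dir, paste0("cortical_map_", nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(cfg$out_dir, "correlation_summary.json"),
                         digits = NA, dataframe = "rows")
  }
  invisible(list(summary = summary, patch_maps = patch_maps,
                 cortical_maps = cortical_maps,
                 patches = list(cortex = ctx_patches, cerebellum = crb_patches,
                                seed_index = seed_idx),
                 fixture = fix))
}

#' Run the information-capacity analysis
#'
#' Fixed-array capacity grid (every configured array at its noise levels,
#' per region) plus the uniform-array sensor-count sweep with overlap
#' flagging. q2 is calibrated once on the largest swept array of the first
#' sweep family over the whole brain and applied everywhere.
#'
#' @param config a [run_config()] list or path to JSON.
#' @returns list with `grid` (tibble: array x noise x region), `sweep`
#'   (an `itot_sweep` tibble), `q2`, `fixture`.
#' @export
run_infocap <- function(config = run_config()) {
  cfg <- resolve_config(config)
  fix <- build_run_geometry(cfg)
  spaces <- list(cortex = fix$cortex_space, cerebellum = fix$cerebellum_space)
  spaces$whole_brain <- concat_source_spaces(spaces$cortex, spaces$cerebellum)
  helmet <- helmet_seed_positions(max(102, max(cfg$sweep$counts)),
                                  radius = fix$config$scalp_radius + 0.03)
  sweep <- itot_sweep(fix$scalp, spaces, helmet, cfg$sweep$counts,
                      sphere_center = fix$sphere_center,
                      target_vertices = cfg$sweep$target_vertices,
                      n_basis = cfg$sweep$n_basis)
  q2 <- attr(sweep, "q2")
  rows <- list()
  for (spec in cfg$arrays) {
    arr <- build_array(spec, fix)
    levels <- if (spec$type == "opm") cfg$noise$opm else cfg$noise$squid
    Ls <- lapply(spaces, function(sp) assemble_leadfield(arr, sp, fix$sphere_center))
    for (nl in levels) {
      for (reg in names(spaces)) {
        res <- info_capacity(Ls[[reg]],
                             noise_model(Ls[[reg]], opm_noise = nl, squid_noise = nl),
                             q2, region = reg)
        rows[[length(rows) + 1]] <- tibble::tibble(
          array = spec$name, region = reg, noise_ft = nl * 1e15,
          n_sensors = nrow(arr), n_channels = res$n_channels,
          itot_bits = res$itot)
      }
    }
  }
  grid <- dplyr::bind_rows(rows)
  if (!is.null(cfg$out_dir)) {
    write_provenance(cfg, cfg$out_dir)
    utils::write.csv(as.data.frame(grid), file.path(cfg$out_dir, "infocap_grid.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(dplyr::select(sweep, -"result")),
                     file.path(cfg$out_dir, "infocap_sweep.csv"), row.names = FALSE)
    jsonlite::write_json(list(q2 = q2), file.path(cfg$out_dir, "infocap_meta.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(list(grid = grid, sweep = sweep, q2 = q2, fixture = fix))
}
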