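# Shared fixtures, built once per test run (small sizes keep the suite fast).

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

test_fixture <- function() cached("fix", make_head_fixture(seed = 1))

test_helmet <- function(n = 102) cached(paste0("helmet", n),
                                        helmet_seed_positions(n, radius = 0.12))

# Lead fields of the three study arrays over both fixture regions.
test_leadfields <- function(which = c("squid", "opm", "triaxial")) {
  which <- match.arg(which)
  cached(paste0("L_", which), {
    fix <- test_fixture()
    pos <- test_helmet()
    arr <- switch(which,
      squid = project_to_scalp(pos, fix$scalp, standoff = 0.022,
                               sensor_type = "squid_mag", name = "squid_102"),
      opm = project_to_scalp(pos, fix$scalp, standoff = 0.005,
                             sensor_type = "opm", name = "opm_102"),
      triaxial = project_to_scalp(pos, fix$scalp, standoff = 0.005,
                                  sensor_type = "opm", channel_mode = "triaxial",
                                  name = "triaxial_opm_102"))
    list(array = arr,
         cortex = assemble_leadfield(arr, fix$cortex_space),
         cerebellum = assemble_leadfield(arr, fix$cerebellum_space))
  })
}

test_patches <- function(region = c("cortex", "cerebellum")) {
  region <- match.arg(region)
  cached(paste0("patches_", region),
         geodesic_patches(test_fixture()[[paste0(region, "_space")]]))
}
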