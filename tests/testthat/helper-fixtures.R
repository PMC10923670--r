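## Shared small fixtures and a run cache so expensive solves are reused
## across test files within one test session.

.run_cache <- new.env(parent = emptyenv())

cache_get <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) assign(key, expr, envir = .run_cache)
  get(key, envir = .run_cache)
}

straight_geom <- function(L = 6)
  build_channel(stenosis_spec(eps = 0, centers = numeric(0),
                              domain_length = L))

straight_mesh <- function(L = 6, h = 0.5, ny = 8)
  mesh_channel(straight_geom(L), h_far = h, h_lesion = h, ny = ny)

small_stenosis_geom <- function() build_channel(stenosis_spec())
small_aneurysm_geom <- function() build_channel(aneurysm_spec())

## reduced test meshes; the aneurysm one keeps h_lesion fine enough to
## resolve the weak flow separation on the quartic bulge flanks
small_mesh <- function(geom) {
  if (geom$model == "aneurysm")
    mesh_channel(geom, h_far = 0.45, h_lesion = 0.15, ny = 10)
  else mesh_channel(geom, h_far = 0.5, h_lesion = 0.25, ny = 8)
}

## small-mesh lesion-model run, cached (continuation handled by solve_case)
cached_run <- function(model, case, Re = 1000, Wi = 0.6, ...) {
  key <- paste("run", model, case, Re, Wi, sep = "_")
  cache_get(key, {
    geom <- if (model == "stenosis") small_stenosis_geom()
            else small_aneurysm_geom()
    solve_case(case = case, Re = Re, Wi = Wi, geom = geom,
               mesh = small_mesh(geom), ...)
  })
}

cached_metrics <- function(model, case, Re = 1000, Wi = 0.6) {
  key <- paste("metrics", model, case, Re, Wi, sep = "_")
  cache_get(key, build_metrics(cached_run(model, case, Re, Wi)))
}

all_cases <- c("newtonian", "gen_newtonian", "oldroyd_b", "gen_oldroyd_b")

## y -> -y node mapping of a mirror-symmetric mesh
mirror_map <- function(mesh) {
  key <- paste(round(mesh$coords[, 1], 9), round(-mesh$coords[, 2], 9))
  match(paste(round(mesh$coords[, 1], 9), round(mesh$coords[, 2], 9)), key)
}
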