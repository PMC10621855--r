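# Shared fixtures. Nonlinear solves are memoised so independent tests can
# reuse the same converged solutions. Models A and B (the quantitative
# comparison surface) run on the reference mesh; the scar models run on a
# moderately coarser profile adequate for their qualitative checks.

.run_cache <- new.env(parent = emptyenv())

mesh_profiles <- list(
  ref  = list(h_fine = 0.05, h_coarse = 1.5, h_lesion = 0.15),
  test = list(h_fine = 0.06, h_coarse = 1.5, h_lesion = 0.18))

profile_for <- function(model) if (model %in% c("A", "B")) "ref" else "test"

get_map <- function(model, seed = 1L) {
  key <- paste0("map_", model, "_", seed)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- build_model(
      model, geometry_spec(),
      scar = if (model %in% c("C", "D", "E", "F")) scar_spec(),
      seed = seed)
  .run_cache[[key]]
}

get_mesh <- function(model, profile = profile_for(model)) {
  key <- paste0("mesh_", model, "_", profile)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- do.call(
      generate_mesh, c(list(get_map(model)), mesh_profiles[[profile]]))
  .run_cache[[key]]
}

get_run <- function(model, current, profile = profile_for(model)) {
  key <- paste0("run_", model, "_", current, "_", profile)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- solve_at_current(
      get_mesh(model, profile), tissue_properties(), current)
  .run_cache[[key]]
}

get_lesion <- function(model, current, profile = profile_for(model)) {
  key <- paste0("les_", model, "_", current, "_", profile)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- lesion_size(get_run(model, current, profile))
  .run_cache[[key]]
}

# Model A solved on a mesh refined through the epicardial interface, for
# the interface-condition checks.
get_interface_run <- function() {
  if (is.null(.run_cache$interface_A22)) {
    mesh <- generate_mesh(get_map("A"), h_fine = 0.06, h_coarse = 1.5,
                          h_lesion = 0.075, lesion_box = c(9, 8.2))
    .run_cache$interface_A22 <- solve_at_current(mesh, tissue_properties(),
                                                 22)
  }
  .run_cache$interface_A22
}

# Assemble a results table from the cached per-model solutions
cached_results <- function(models, currents = c(19, 22, 25)) {
  do.call(rbind, lapply(models, function(m) {
    do.call(rbind, lapply(currents, function(I) {
      les <- get_lesion(m, I)
      data.frame(model = m, current_A = I, depth_mm = les$depth,
                 surface_width_mm = les$surface_width,
                 clamped_to_fat = les$clamped_to_fat)
    }))
  }))
}

# Hemispherical electrode of radius a (mm) at V volts against a concentric
# grounded hemisphere of radius Rb in a uniform linear medium; both
# spherical surfaces are staircase-approximated with the node sets centered
# on the true radii.
hemisphere_problem <- function(a = 2, Rb = 20, V = 100, sigma = 0.5,
                               h0 = 0.06) {
  key <- sprintf("hemi_%g_%g_%g_%g_%g", a, Rb, V, sigma, h0)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  hc <- 12 * h0
  R <- function(r, z) sqrt(r^2 + z^2)
  labf <- function(r, z)
    ifelse(R(r, z) < a - 0.5 * h0, "ELECTRODE",
           ifelse(R(r, z) > Rb + 0.5 * hc, "INSULATED_SHAFT", "BLOOD"))
  hfun <- function(x) pmin(hc, pmax(h0, h0 + 0.25 * (x - a)))
  rl <- pfafield:::graded_axis(c(0, a, Rb + 2.5 * hc), hfun)
  mesh <- pfafield:::tensor_mesh(
    rl, rl, labf,
    electrode_fun = function(r, z) R(r, z) <= a + 0.5 * h0 + 1e-9,
    ground_fun = function(r, z) R(r, z) >= Rb - 0.5 * hc - 1e-9)
  sol <- solve_at_voltage(mesh, tissue_properties(blood_sigma = sigma), V)
  out <- list(sol = sol, a = a, Rb = Rb, V = V, sigma = sigma,
              I_exact = 2 * pi * sigma * V / (1 / (a * 1e-3) -
                                                1 / (Rb * 1e-3)),
              phi_exact = function(Rq) V * (1 / Rq - 1 / Rb) /
                (1 / a - 1 / Rb))
  .run_cache[[key]] <- out
  out
}

# Poorly conducting sphere (radius a, conductivity sig_in) centered on the
# axis in a uniform axial far field E0 = V / (2 L) inside a conductive box.
inclusion_problem <- function(a = 1.5, L = 12, V = 240,
                              sig_out = 0.6, sig_in = 0.08, h0 = 0.05) {
  key <- sprintf("incl_%g_%g_%g_%g_%g_%g", a, L, V, sig_out, sig_in, h0)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  smap <- pfafield:::synthetic_map(list(
    pfafield:::region_rect("BLOOD", 0, L, -L, L),
    pfafield:::region_ellipse("FAT", 0, 0, a, a, inclusion = TRUE)),
    rmax = L, zmin = -L, zmax = L)
  hfun <- function(x) pmin(0.6, pmax(h0, h0 + 0.3 * (abs(x) - a)))
  rl <- pfafield:::graded_axis(c(0, a, L), hfun)
  zl <- pfafield:::graded_axis(c(-L, -a, 0, a, L), hfun)
  mesh <- pfafield:::tensor_mesh(
    rl, zl, function(r, z) label_points(smap, r, z),
    electrode_fun = function(r, z) z <= -L + 1e-9,
    ground_fun = function(r, z) z >= L - 1e-9)
  mesh$map <- smap
  sol <- solve_at_voltage(
    mesh, tissue_properties(blood_sigma = sig_out, fat_sigma = sig_in), V)
  out <- list(sol = sol, a = a, E0 = V / (2 * L * 1e-3),
              E_in_exact = 3 * sig_out / (2 * sig_out + sig_in) *
                V / (2 * L * 1e-3))
  .run_cache[[key]] <- out
  out
}

expect_rel <- function(value, target, tol) {
  expect_lt(abs(value / target - 1), tol)
}
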