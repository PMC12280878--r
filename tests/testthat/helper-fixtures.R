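# Shared fixtures. Heavy objects (meshes, transport solves) are memoised per
# test run so that several test files can reuse one solve.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# A small phantom: quick to mesh and solve, used by unit tests.
small_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(24L, 24L, 24L), brain_axes = c(9, 8, 7),
         tumor_center = c(14, 13, 12), tumor_radius = 3,
         class_label = 1L, effect_size = 3, noise_sd = 30, seed = 7L),
    list(...))
  do.call(phantom_spec, args)
}

small_volume <- function() fixture("small_volume", function() generate_phantom(small_spec()))

small_mesh <- function() fixture("small_mesh", function() build_tet_mesh(small_volume()))

# The bundled acceptance phantom: 48^3 grid.
acceptance_spec <- function() phantom_spec()

acceptance_volume <- function() {
  fixture("acceptance_volume", function() generate_phantom(acceptance_spec()))
}

acceptance_mesh <- function() {
  fixture("acceptance_mesh", function() build_tet_mesh(acceptance_volume()))
}

# Mass-preserving solves on the acceptance phantom, one per gamma, shared
# between the feasibility and monotonicity criteria. The gamma ladder is
# solved incrementally: each rung warm-starts from the previous one.
acceptance_map <- function(gamma) {
  fixture(sprintf("acceptance_map_%g", gamma), function() {
    ladder <- c(1.0, 1.5, 1.75, 2.0)
    below <- ladder[ladder < gamma - 1e-9]
    init <- if (gamma %in% ladder && length(below)) {
      acceptance_map(max(below))
    } else NULL
    vol <- acceptance_volume()
    mesh <- acceptance_mesh()
    he <- fixture("acceptance_he", function() histogram_equalize(mesh, vol))
    field <- density_from_he(mesh, he, gamma = gamma, volume = vol)
    field <- normalize_total_mass(field, mesh)
    solve_mass_preserving_map(mesh, field, init = init)
  })
}

acceptance_tensor <- function(gamma, m_hat = 64L) {
  fixture(sprintf("acceptance_tensor_%g_%d", gamma, m_hat), function() {
    comp <- compose_to_cube(acceptance_map(gamma), solve_volume_preserving_cube_map())
    resample_to_tensor(comp, acceptance_volume(), m_hat = m_hat, gamma = gamma)
  })
}

# Tumor tensors cropped straight from a cohort's phantoms (fast APC path).
cohort_tumors <- function(cohort, m = 32L) {
  lapply(seq_along(cohort$volumes), function(i) {
    tensor <- identity_tensor(cohort$volumes[[i]])
    lapply(seq_along(cohort$volumes[[i]]$intensities), function(mod) {
      crop_wt_tensor(tensor, m = m, modality = mod, subject_id = as.character(i))
    })
  })
}

# Fit APC on a train split and return held-out AUC.
apc_holdout_auc <- function(cohort, train, test, j = 8L, k = 2L, m = 32L,
                            labels = cohort$labels) {
  tumors <- cohort_tumors(cohort, m = m)
  model <- apc_fit(tumors[train], labels[train], j = j, k = k)
  preds <- apc_predict(model, tumors[test])
  auc(cohort$labels[test], preds$prob_class1)
}

# Deterministic stratified split helper for tests.
stratified_split <- function(labels, frac = 0.8, seed = 11L) {
  train <- integer(0)
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    ntr <- max(1L, min(length(idx) - 1L, round(frac * length(idx))))
    train <- c(train, with_seed(seed + cl, sample(idx, ntr)))
  }
  list(train = sort(train), test = sort(setdiff(seq_along(labels), train)))
}

with_seed <- omtapc:::with_seed
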