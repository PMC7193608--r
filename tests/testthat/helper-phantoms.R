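# Shared phantom fixtures, built in code.

beagle_radii <- c(35, 37, 41, 44)

beagle_shells <- function(conductivities = optimized_conductivities()) {
  build_shell_model(beagle_radii, conductivities)
}

beagle_shells_noscalp <- function(conductivities = optimized_conductivities()) {
  build_shell_model(beagle_radii[1:3], conductivities,
                    tissues = c("brain", "CSF", "skull"))
}

# pole/off-pole active-reference pair on a shell model
shell_pair <- function(model, attachment, area_cm2 = 1, current_mA = 1,
                       ref_angle = 2.2) {
  r_out <- max(model$shells$radius_mm)
  place_montage(model, list(
    electrode_patch(c(0, 0, r_out), area_cm2, attachment, "active",
                    current_mA),
    electrode_patch(r_out * c(sin(ref_angle), 0, cos(ref_angle)), area_cm2,
                    attachment, "reference", -current_mA)))
}

# pole pair on a voxel model
shell_pair_on_voxels <- function(model, attachment, area_cm2 = 0.3,
                                 current_mA = 1) {
  r <- max(model$boundaries)
  place_montage(model, list(
    electrode_patch(c(0, 0, r), area_cm2, attachment, "active", current_mA),
    electrode_patch(c(0, 0, -r), area_cm2, attachment, "reference",
                    -current_mA)))
}

# small voxelized sphere (radius 20 mm) for fast solver tests
small_voxel_sphere <- function(voxel_mm = 1,
                               conductivities = optimized_conductivities()) {
  build_voxel_head(rep(20, 3), layers = c(scalp = 2.5, skull = 2.5, CSF = 2.5),
                   voxel_mm = voxel_mm, conductivities = conductivities,
                   core_tissue = "brain")
}

# homogeneous voxel sphere: every layer and the core share one tissue
homogeneous_voxel_sphere <- function(radius_mm = 20, voxel_mm = 1,
                                     sigma = 0.1) {
  sig <- conductivity_set(c(scalp = sigma, skull = sigma, CSF = sigma,
                            gray_matter = sigma, white_matter = sigma,
                            brain = sigma, air = 0))
  build_voxel_head(rep(radius_mm, 3),
                   layers = c(scalp = radius_mm / 4), voxel_mm = voxel_mm,
                   conductivities = sig, core_tissue = "brain")
}

# band-change matrices (repetitions x bands) for compare_conditions()
band_change_matrix <- function(condition, seeds, ...) {
  out <- t(vapply(seeds, function(s)
    band_change(make_ieeg_session(condition, seed = s,
                                  include_artifact = FALSE, ...))$change,
    numeric(4)))
  colnames(out) <- names(eeg_bands())
  out
}
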