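#' Head phantom geometries
#'
#' Three phantom families are supported, in increasing realism:
#' a 1-D layered slab (closed-form oracle geometry), N-shell concentric
#' spheres (analytic Legendre-series oracle), and a voxelized layered
#' ellipsoid for the finite-difference solver. Coordinates are
#' right-handed, in mm, with the model center at the origin; voxel
#' indices are 0-based and voxel (i,j,k) spans a half-open cube.
#'
#' @name geometry
NULL

new_tissue_model <- function(kind, conductivities, ...) {
  stopifnot(inherits(conductivities, "conductivity_set"))
  structure(c(list(kind = kind, conductivities = conductivities), list(...)),
            class = "tissue_model")
}

#' Build a 1-D layered slab phantom
#'
#' @param thicknesses named numeric vector of layer thicknesses in mm,
#'   ordered outermost to innermost; names are tissue names present in
#'   `conductivities`.
#' @param conductivities a [conductivity_set()].
#' @return A `tissue_model` of kind `"slab"`.
#' @examples
#' build_slab(c(scalp = 2, skull = 2, brain = 40), default_conductivities())
#' @export
build_slab <- function(thicknesses, conductivities = default_conductivities()) {
  if (length(thicknesses) < 2)
    stop("a slab needs at least 2 layers", call. = FALSE)
  if (any(thicknesses <= 0))
    stop("layer thicknesses must be positive", call. = FALSE)
  check_tissues(names(thicknesses), conductivities)
  new_tissue_model("slab", conductivities,
                   layers = data.frame(tissue = names(thicknesses),
                                       thickness_mm = as.numeric(thicknesses),
                                       stringsAsFactors = FALSE))
}

#' Build an N-shell concentric sphere phantom
#'
#' Shells are listed innermost to outermost by their outer radius. The
#' 4-shell default maps to brain / CSF / skull / scalp; dropping the last
#' radius and tissue gives the scalp-removed variant.
#'
#' @param radii numeric vector of shell outer radii in mm, strictly
#'   increasing, innermost first.
#' @param conductivities a [conductivity_set()].
#' @param tissues character vector of tissue names, one per shell;
#'   defaults to brain/CSF/skull/scalp for 4 shells and to brain/skull/scalp
#'   for 3 (scalp-closed without CSF), brain/CSF/skull for a scalp-removed
#'   4-shell variant use `tissues` explicitly.
#' @return A `tissue_model` of kind `"shells"`.
#' @examples
#' # beagle-scale and human-scale 4-shell phantoms
#' build_shell_model(c(35, 37, 41, 44))
#' build_shell_model(c(80, 83, 89, 95))
#' @export
build_shell_model <- function(radii,
                              conductivities = default_conductivities(),
                              tissues = NULL) {
  if (any(diff(radii) <= 0) || any(radii <= 0))
    stop("shell radii must be positive and strictly increasing", call. = FALSE)
  if (is.null(tissues)) {
    tissues <- switch(as.character(length(radii)),
                      "1" = "brain",
                      "3" = c("brain", "skull", "scalp"),
                      "4" = c("brain", "CSF", "skull", "scalp"),
                      stop("supply `tissues` for ", length(radii), " shells",
                           call. = FALSE))
  }
  if (length(tissues) != length(radii))
    stop("one tissue per shell is required", call. = FALSE)
  check_tissues(tissues, conductivities)
  new_tissue_model("shells", conductivities,
                   shells = data.frame(tissue = tissues,
                                       radius_mm = as.numeric(radii),
                                       stringsAsFactors = FALSE))
}

#' Build a voxelized layered ellipsoid head phantom
#'
#' Concentric ellipsoidal layers are rasterized onto a regular grid.
#' The outermost layer is scalp (unless `scalp_removed`), followed by the
#' given layers inward; the remaining core is `core_tissue`. Exterior
#' voxels are labelled `air`.
#'
#' @param semi_axes numeric length-3, outer ellipsoid semi-axes (mm).
#' @param layers named numeric vector of layer thicknesses in mm, ordered
#'   outermost to innermost (e.g. `c(scalp = 2, skull = 2, CSF = 1,
#'   gray_matter = 8)`).
#' @param voxel_mm voxel edge length in mm; must not exceed half the
#'   thinnest layer.
#' @param conductivities a [conductivity_set()].
#' @param core_tissue tissue filling the innermost region.
#' @param scalp_removed if `TRUE`, the scalp layer is dropped (label never
#'   rasterized) while all interior interfaces stay in place, so the
#'   variant differs from the full model only in scalp voxels.
#' @return A `tissue_model` of kind `"voxels"` with fields `labels`
#'   (integer 3-D array, 0 = air), `tissue_names` (label index -> name),
#'   `voxel_mm`, and `origin_mm` (corner of voxel (0,0,0)).
#' @export
build_voxel_head <- function(semi_axes,
                             layers = c(scalp = 2, skull = 2, CSF = 1,
                                        gray_matter = 8),
                             voxel_mm = 1,
                             conductivities = default_conductivities(),
                             core_tissue = "white_matter",
                             scalp_removed = FALSE) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0), voxel_mm > 0)
  if (any(layers <= 0)) stop("layer thicknesses must be positive", call. = FALSE)
  if (voxel_mm > min(layers) / 2) {
    bad <- names(layers)[which.min(layers)]
    stop("voxel size ", voxel_mm, " mm too coarse to resolve layer '", bad,
         "' (", min(layers), " mm); need voxel <= thickness/2", call. = FALSE)
  }
  check_tissues(c(names(layers), core_tissue), conductivities)
  # inner semi-axes after peeling each layer
  cum <- cumsum(layers)
  if (any(min(semi_axes) - cum <= 0)) {
    bad <- names(layers)[min(which(min(semi_axes) - cum <= 0))]
    stop("layers exhaust the ellipsoid at layer '", bad, "'", call. = FALSE)
  }
  tissue_names <- c(names(layers), core_tissue)
  n_half <- ceiling(semi_axes / voxel_mm) + 1L
  dims <- 2L * n_half
  origin <- -n_half * voxel_mm          # corner of voxel (0,0,0)
  cx <- origin[1] + (seq_len(dims[1]) - 0.5) * voxel_mm
  cy <- origin[2] + (seq_len(dims[2]) - 0.5) * voxel_mm
  cz <- origin[3] + (seq_len(dims[3]) - 0.5) * voxel_mm
  labels <- array(0L, dim = dims)
  # normalized radius per layer boundary, outermost -> innermost
  bounds <- rbind(semi_axes, sweep(-outer(cum, c(1, 1, 1)), 2, semi_axes, "+"))
  X2 <- outer(cx^2, rep(1, dims[2]))
  for (k in seq_len(dims[3])) {
    # squared normalized ellipsoid radius for each boundary, innermost wins
    lab <- matrix(0L, dims[1], dims[2])
    for (b in seq_len(nrow(bounds))) {
      s <- bounds[b, ]
      r2 <- X2 / s[1]^2 + outer(rep(1, dims[1]), cy^2) / s[2]^2 + cz[k]^2 / s[3]^2
      lab[r2 <= 1] <- b
    }
    labels[, , k] <- lab
  }
  if (scalp_removed) {
    scalp_idx <- match("scalp", tissue_names)
    if (!is.na(scalp_idx)) labels[labels == scalp_idx] <- 0L
  }
  new_tissue_model("voxels", conductivities,
                   labels = labels, tissue_names = tissue_names,
                   voxel_mm = voxel_mm, origin_mm = origin,
                   scalp_removed = scalp_removed,
                   # analytic layer boundaries (semi-axes per boundary,
                   # outermost first): lets the solver homogenize face
                   # conductances below the voxel scale
                   boundaries = bounds)
}

#' @export
print.tissue_model <- function(x, ...) {
  cat("Tissue model (", x$kind, ")\n", sep = "")
  if (x$kind == "slab") print(x$layers)
  if (x$kind == "shells") print(x$shells)
  if (x$kind == "voxels") {
    cat("  grid:", paste(dim(x$labels), collapse = " x "),
        "voxels of", x$voxel_mm, "mm\n")
    tab <- table(factor(x$labels, levels = seq_along(x$tissue_names),
                        labels = x$tissue_names))
    print(tab)
  }
  cat("  conductivities:", attr(x$conductivities, "provenance"), "\n")
  invisible(x)
}

#' Electrode patches and montages
#'
#' A patch is an idealized current-source electrode: uniform current
#' density over its footprint, no metal/gel impedance. Attachment layer
#' `"scalp-surface"` injects at the outer scalp boundary (transcutaneous,
#' TES); `"skull-surface"` injects at the outer skull boundary
#' (subcutaneous, SES) — with scalp present this is the scalp-closed
#' condition, on a scalp-removed model the scalp-removed condition.
#'
#' @param center numeric length-3 position in model coordinates (mm).
#' @param area_cm2 patch area in cm^2 (> 0).
#' @param attachment `"scalp-surface"` or `"skull-surface"`.
#' @param role `"active"` or `"reference"`.
#' @param current_mA signed injected current in mA (reference carries the
#'   return current).
#' @return An `electrode_patch` object.
#' @export
electrode_patch <- function(center, area_cm2 = 1,
                            attachment = c("scalp-surface", "skull-surface"),
                            role = c("active", "reference"),
                            current_mA) {
  attachment <- match.arg(attachment)
  role <- match.arg(role)
  stopifnot(length(center) == 3, is.numeric(center))
  if (area_cm2 <= 0) stop("patch area must be > 0", call. = FALSE)
  structure(list(center = as.numeric(center), area_cm2 = area_cm2,
                 attachment = attachment, role = role,
                 current_mA = as.numeric(current_mA)),
            class = "electrode_patch")
}

#' Place an electrode montage on a tissue model
#'
#' Validates current balance, rasterizes patch footprints on voxel models
#' (uniform current density over the footprint, re-normalized so that the
#' signed currents balance to machine precision), and records attachment
#' radii for shell models.
#'
#' @param model a `tissue_model`.
#' @param patches list of [electrode_patch()] objects.
#' @return A `montage` object.
#' @export
place_montage <- function(model, patches) {
  stopifnot(inherits(model, "tissue_model"))
  if (inherits(patches, "electrode_patch")) patches <- list(patches)
  stopifnot(length(patches) >= 2,
            all(vapply(patches, inherits, TRUE, "electrode_patch")))
  currents <- vapply(patches, `[[`, numeric(1), "current_mA")
  if (abs(sum(currents)) > 1e-9)
    stop("montage currents do not balance: net ",
         format(sum(currents)), " mA", call. = FALSE)
  if (model$kind == "voxels" &&
      any(vapply(patches, `[[`, "", "attachment") == "scalp-surface") &&
      isTRUE(model$scalp_removed))
    stop("cannot attach a scalp-surface patch to a scalp-removed model",
         call. = FALSE)
  m <- structure(list(model_kind = model$kind, patches = patches),
                 class = "montage")
  if (model$kind == "voxels") {
    m$footprints <- rasterize_patches(model, patches)
  }
  m
}

# Footprint voxels: surface voxels of the attachment tissue within the disc
# radius of the patch center. Per-voxel currents are uniform per patch and
# re-normalized so the montage sums to zero exactly.
rasterize_patches <- function(model, patches) {
  labels <- model$labels
  h <- model$voxel_mm
  fp <- vector("list", length(patches))
  taken <- integer(0)
  for (p in seq_along(patches)) {
    patch <- patches[[p]]
    tissue <- if (patch$attachment == "scalp-surface") "scalp" else "skull"
    above <- if (patch$attachment == "scalp-surface") c("air") else
      c("scalp", "air")
    idx <- surface_voxels(model, tissue, above)
    if (nrow(idx) == 0)
      stop("no ", tissue, " surface available for patch ", p, call. = FALSE)
    pos <- voxel_centers(model, idx)
    r <- sqrt(patch$area_cm2 * 100 / pi)    # disc radius in mm
    # anchor the disc at the surface voxel closest to the requested center,
    # so a center specified slightly off the surface keeps the full area
    d2c <- (pos[, 1] - patch$center[1])^2 + (pos[, 2] - patch$center[2])^2 +
      (pos[, 3] - patch$center[3])^2
    anchor <- pos[which.min(d2c), ]
    d2 <- (pos[, 1] - anchor[1])^2 + (pos[, 2] - anchor[2])^2 +
      (pos[, 3] - anchor[3])^2
    sel <- which(d2 <= r^2)
    if (!length(sel))
      stop("patch ", p, " footprint does not touch the ", tissue,
           " surface; check its center position", call. = FALSE)
    lin <- linear_index(idx[sel, , drop = FALSE], dim(labels))
    if (any(lin %in% taken))
      stop("electrode patches overlap", call. = FALSE)
    taken <- c(taken, lin)
    fp[[p]] <- list(voxels = lin, n = length(lin),
                    area_cm2 = length(lin) * h^2 / 100,
                    current_mA = patch$current_mA)
  }
  # exact balance after rasterization
  tot_pos <- sum(vapply(fp, function(f) max(f$current_mA, 0), numeric(1)))
  tot_neg <- -sum(vapply(fp, function(f) min(f$current_mA, 0), numeric(1)))
  for (p in seq_along(fp)) {
    if (fp[[p]]$current_mA < 0)
      fp[[p]]$current_mA <- fp[[p]]$current_mA * tot_pos / tot_neg
  }
  fp
}

# voxels of `tissue` having a face neighbor labelled with any of `above`
surface_voxels <- function(model, tissue, above) {
  labels <- model$labels
  ti <- match(tissue, model$tissue_names)
  ai <- match(above, model$tissue_names)
  ai[above == "air"] <- 0L
  dims <- dim(labels)
  tv <- which(labels == ti, arr.ind = TRUE)
  if (!nrow(tv)) return(tv)
  keep <- logical(nrow(tv))
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    nb <- sweep(tv, 2, s, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lab <- rep(0L, nrow(tv))
    lab[ok] <- labels[nb[ok, , drop = FALSE]]
    keep <- keep | (lab %in% ai)
  }
  tv[keep, , drop = FALSE]
}

voxel_centers <- function(model, idx) {
  sweep((idx - 0.5) * model$voxel_mm, 2, model$origin_mm, "+")
}

linear_index <- function(idx, dims) {
  (idx[, 3] - 1L) * dims[1] * dims[2] + (idx[, 2] - 1L) * dims[1] + idx[, 1]
}

#' @export
print.montage <- function(x, ...) {
  cat("Montage with", length(x$patches), "patches on a", x$model_kind,
      "model\n")
  for (p in x$patches)
    cat(sprintf("  %-9s %-13s %+.3f mA, %.1f cm^2\n",
                p$role, p$attachment, p$current_mA, p$area_cm2))
  invisible(x)
}

#' Subdural strip specification
#'
#' A linear array of disc contacts (default: 8 contacts, 3 mm diameter,
#' 5 mm center spacing) placed against the inner skull surface. For shell
#' models use [strip_on_inner_surface()] to lay the strip along an arc of
#' the brain surface.
#'
#' @param contacts numeric matrix `n x 3` of contact centers (mm).
#' @param diameter_mm contact diameter.
#' @param spacing_mm nominal center-to-center spacing.
#' @param orientation unit vector along the strip.
#' @return A `strip_spec` object.
#' @export
strip_spec <- function(contacts, diameter_mm = 3, spacing_mm = 5,
                       orientation = NULL) {
  contacts <- as.matrix(contacts)
  stopifnot(ncol(contacts) == 3, nrow(contacts) >= 2)
  if (is.null(orientation)) {
    orientation <- contacts[nrow(contacts), ] - contacts[1, ]
    orientation <- orientation / sqrt(sum(orientation^2))
  }
  structure(list(contacts = contacts, n = nrow(contacts),
                 diameter_mm = diameter_mm, spacing_mm = spacing_mm,
                 orientation = orientation),
            class = "strip_spec")
}

#' @rdname strip_spec
#' @param model a shell `tissue_model`; contacts are placed on the
#'   innermost shell surface (brain surface, under the skull/CSF).
#' @param start_angle_deg polar angle of the first contact (degrees from
#'   the +z pole).
#' @param azimuth_deg azimuthal plane of the strip arc.
#' @param n_contacts number of contacts.
#' @export
strip_on_inner_surface <- function(model, start_angle_deg = 0,
                                   azimuth_deg = 0, n_contacts = 8,
                                   spacing_mm = 5, diameter_mm = 3) {
  stopifnot(model$kind == "shells")
  r <- model$shells$radius_mm[1]
  dtheta <- spacing_mm / r                   # arc spacing -> angle
  th <- (start_angle_deg * pi / 180) + (seq_len(n_contacts) - 1) * dtheta
  ph <- azimuth_deg * pi / 180
  contacts <- cbind(r * sin(th) * cos(ph), r * sin(th) * sin(ph), r * cos(th))
  strip_spec(contacts, diameter_mm = diameter_mm, spacing_mm = spacing_mm)
}

check_tissues <- function(tissues, conductivities) {
  missing <- setdiff(tissues, names(conductivities))
  if (length(missing))
    stop("tissue(s) not in conductivity set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
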