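#' Solve the quasi-static volume-conduction problem
#'
#' Solves `div(sigma grad V) = 0` with electrode current injection on a
#' tissue model. The discretization and solution strategy depend on the
#' model kind:
#'
#' * `"slab"`: closed-form series-resistor solution for a uniform current
#'   density through the layer stack.
#' * `"shells"`: analytic Legendre-series solution
#'   ([analytic_shell_potential()]) with the montage patches reduced to
#'   point monopoles at their attachment radius.
#' * `"voxels"`: 7-point finite-difference stencil with face conductances
#'   from the harmonic mean of adjacent cell conductivities (respects
#'   series composition across layer boundaries); air voxels are excluded
#'   from the system. The symmetric positive-definite sparse system is
#'   solved by Jacobi-preconditioned conjugate gradients, which is fully
#'   deterministic.
#'
#' The potential gauge is fixed to zero at the reference patch centroid;
#' all reported quantities are potential differences and therefore
#' gauge-independent. The model is purely resistive, so solutions are
#' frequency-independent and exactly linear in the injected current.
#'
#' @param model a `tissue_model`.
#' @param montage a `montage` from [place_montage()] (shell and voxel
#'   models).
#' @param current_density_A_m2 for slab models only: the uniform current
#'   density driven through the stack.
#' @param tolerance relative residual for the conjugate-gradient solve.
#' @param max_iterations iteration cap; non-convergence is an error that
#'   reports the residual reached.
#' @param n_max,series_tol passed to [analytic_shell_potential()] for
#'   shell models.
#' @return A `field_solution`.
#' @export
solve_potential <- function(model, montage = NULL,
                            current_density_A_m2 = NULL,
                            tolerance = 1e-8, max_iterations = 20000L,
                            n_max = 400, series_tol = 1e-10) {
  stopifnot(inherits(model, "tissue_model"))
  switch(model$kind,
         slab = solve_slab(model, current_density_A_m2),
         shells = solve_shells(model, montage, n_max, series_tol),
         voxels = solve_voxels(model, montage, tolerance, max_iterations),
         stop("unknown model kind ", model$kind))
}

new_field_solution <- function(kind, model, montage, ...) {
  structure(c(list(kind = kind, model = model, montage = montage),
              list(...)), class = "field_solution")
}

# ---- slab: series resistors ------------------------------------------------

solve_slab <- function(model, J) {
  if (is.null(J)) stop("slab models need `current_density_A_m2`", call. = FALSE)
  sig <- as.numeric(model$conductivities[model$layers$tissue])
  th <- model$layers$thickness_mm
  # E in each layer: J / sigma (V/m == mV/mm); V drop: E * thickness
  E <- J / sig
  drops <- E * th / 1000                  # volts across each layer
  new_field_solution("slab", model, NULL,
                     layer_field_mV_mm = stats::setNames(E, model$layers$tissue),
                     layer_drop_V = drops,
                     residual = 0, iterations = 0L)
}

# ---- shells: analytic series ----------------------------------------------

patch_radius <- function(model, patch) {
  sh <- model$shells
  if (patch$attachment == "scalp-surface") {
    if (!"scalp" %in% sh$tissue)
      stop("scalp-surface patch on a model without scalp", call. = FALSE)
    sh$radius_mm[nrow(sh)]
  } else {
    i <- match("skull", sh$tissue)
    if (is.na(i)) stop("model has no skull shell", call. = FALSE)
    sh$radius_mm[i]
  }
}

solve_shells <- function(model, montage, n_max, series_tol) {
  stopifnot(inherits(montage, "montage"))
  radii <- model$shells$radius_mm
  sigmas <- as.numeric(model$conductivities[model$shells$tissue])
  patches <- montage$patches
  dirs <- lapply(patches, function(p) unit3(p$center))
  rads <- vapply(patches, function(p) patch_radius(model, p), numeric(1))
  cur <- vapply(patches, `[[`, numeric(1), "current_mA")
  # superpose patch monopoles pairwise against a common zero-current split:
  # evaluate as sum over patches of a monopole; implemented via source/sink
  # pairs taken from the signed currents.
  evaluator <- function(points) {
    points <- matrix_3col(points)
    V <- numeric(nrow(points))
    pos <- which(cur > 0)
    neg <- which(cur < 0)
    # pair each positive patch with the negative patches proportionally
    total_pos <- sum(cur[pos])
    for (i in pos) for (j in neg) {
      share <- cur[i] * (-cur[j]) / total_pos
      V <- V + analytic_shell_potential(
        radii, sigmas, points,
        source_dir = dirs[[i]], sink_dir = dirs[[j]],
        source_radius = rads[i], sink_radius = rads[j],
        current_mA = share, n_max = n_max, series_tol = series_tol)
    }
    V
  }
  new_field_solution("shells", model, montage, evaluate = evaluator,
                     residual = 0, iterations = 0L)
}

# ---- voxels: finite differences + CG --------------------------------------

# conductivity at arbitrary positions, from the model's analytic layer
# boundaries (sub-voxel accurate); positions are mm model coordinates
sigma_at_points <- function(model, x, y, z) {
  bounds <- model$boundaries
  sig_layer <- as.numeric(model$conductivities[model$tissue_names])
  if (isTRUE(model$scalp_removed)) {
    si <- match("scalp", model$tissue_names)
    if (!is.na(si)) sig_layer[si] <- 0
  }
  lab <- array(0L, dim = dim(x))
  for (b in seq_len(nrow(bounds))) {
    s <- bounds[b, ]
    inside <- x^2 / s[1]^2 + y^2 / s[2]^2 + z^2 / s[3]^2 <= 1
    lab[inside] <- b
  }
  out <- array(0, dim = dim(x))
  out[lab > 0] <- sig_layer[lab[lab > 0]]
  out
}

# Face conductances (in siemens) between adjacent cells along each axis.
# With analytic boundaries available the face value is homogenized below
# the voxel scale: the face is split into transverse "tubes"; within each
# tube the two half-cell conductivities combine by a blend of series
# (harmonic) and parallel (arithmetic) mixing weighted by the local
# interface orientation (series when the layer interface is perpendicular
# to the flow, parallel when the flow runs along the interface). This
# respects series composition across layer boundaries and resolves thin
# high-contrast layers (e.g. the 2 mm CSF sheet) far better than a plain
# per-cell harmonic mean, which remains the fallback for label-only
# grids.
face_conductances <- function(model, subsamples = 5) {
  dims <- dim(model$labels)
  h <- model$voxel_mm
  h_m <- h / 1000
  out <- vector("list", 3)
  if (!is.null(model$boundaries)) {
    cx <- model$origin_mm[1] + (seq_len(dims[1]) - 0.5) * h
    cy <- model$origin_mm[2] + (seq_len(dims[2]) - 0.5) * h
    cz <- model$origin_mm[3] + (seq_len(dims[3]) - 0.5) * h
    toff <- ((seq_len(subsamples) - 0.5) / subsamples - 0.5) * h
    sa <- model$boundaries[1, ]      # outer semi-axes set the normal field
    for (ax in 1:3) {
      fd <- dims - (ax == 1:3)
      G <- array(0, fd)
      for (k in seq_len(fd[3])) {
        acc <- matrix(0, fd[1], fd[2])
        for (u in toff) for (v in toff) {
          if (ax == 3) {
            X <- matrix(cx + u, fd[1], fd[2])
            Y <- matrix(rep(cy + v, each = fd[1]), fd[1], fd[2])
            Z <- array(cz[k] + h / 2, dim(X))
          } else if (ax == 1) {
            X <- matrix(cx[seq_len(fd[1])] + h / 2, fd[1], fd[2])
            Y <- matrix(rep(cy + u, each = fd[1]), fd[1], fd[2])
            Z <- array(cz[k] + v, dim(X))
          } else {
            X <- matrix(cx + u, fd[1], fd[2])
            Y <- matrix(rep(cy[seq_len(fd[2])] + h / 2, each = fd[1]),
                        fd[1], fd[2])
            Z <- array(cz[k] + v, dim(X))
          }
          d <- (ax == 1:3) * h / 4
          s1 <- sigma_at_points(model, X - d[1], Y - d[2], Z - d[3])
          s2 <- sigma_at_points(model, X + d[1], Y + d[2], Z + d[3])
          # |n . e_ax| from the ellipsoid normal (x/a^2, y/b^2, z/c^2)
          nx <- X / sa[1]^2; ny <- Y / sa[2]^2; nz <- Z / sa[3]^2
          nn <- sqrt(nx^2 + ny^2 + nz^2)
          cfac <- abs(list(nx, ny, nz)[[ax]]) / pmax(nn, 1e-12)
          ok <- s1 > 0 & s2 > 0
          harm <- ifelse(ok, 2 * s1 * s2 / pmax(s1 + s2, 1e-300), 0)
          arit <- ifelse(ok, (s1 + s2) / 2, 0)
          acc <- acc + cfac * harm + (1 - cfac) * arit
        }
        G[, , k] <- acc / subsamples^2
      }
      out[[ax]] <- G * h_m
    }
  } else {
    sig_by_label <- c(0, as.numeric(model$conductivities[model$tissue_names]))
    sig <- array(sig_by_label[model$labels + 1L], dim = dims)
    slice <- function(ax, lo) {
      idx <- lapply(dims, seq_len)
      idx[[ax]] <- if (lo) seq_len(dims[ax] - 1) else 2:dims[ax]
      sig[idx[[1]], idx[[2]], idx[[3]]]
    }
    for (ax in 1:3) {
      s1 <- slice(ax, TRUE); s2 <- slice(ax, FALSE)
      out[[ax]] <- ifelse(s1 > 0 & s2 > 0,
                          2 * s1 * s2 / (s1 + s2), 0) * h_m
    }
  }
  out
}

solve_voxels <- function(model, montage, tolerance, max_iterations) {
  stopifnot(inherits(montage, "montage"))
  if (is.null(montage$footprints))
    stop("montage was not rasterized on a voxel model", call. = FALSE)
  dims <- dim(model$labels)
  faces <- face_conductances(model)
  strides <- c(1L, dims[1], dims[1] * dims[2])
  ii <- integer(0); jj <- integer(0); gg <- numeric(0)
  for (ax in 1:3) {
    idx <- which(faces[[ax]] > 0, arr.ind = TRUE)
    a <- (idx[, 3] - 1L) * strides[3] + (idx[, 2] - 1L) * strides[2] + idx[, 1]
    ii <- c(ii, a); jj <- c(jj, a + strides[ax]); gg <- c(gg, faces[[ax]][idx])
  }
  conducting <- sort(unique(c(ii, jj)))
  n <- length(conducting)
  node_of <- integer(prod(dims))
  node_of[conducting] <- seq_len(n)
  # graph Laplacian: A = D - W (symmetric positive semidefinite)
  W <- Matrix::sparseMatrix(i = c(node_of[ii], node_of[jj]),
                            j = c(node_of[jj], node_of[ii]),
                            x = c(gg, gg), dims = c(n, n))
  A <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W

  bvec <- numeric(n)
  for (f in montage$footprints) {
    nodes <- node_of[f$voxels]
    if (any(nodes == 0))
      stop("patch footprint touches a non-conducting voxel", call. = FALSE)
    bvec[nodes] <- bvec[nodes] + (f$current_mA / 1000) / f$n
  }

  # gauge: ground the node nearest the reference patch centroid
  ref <- which(vapply(montage$patches, `[[`, "", "role") == "reference")[1]
  ref_vox <- montage$footprints[[ref]]$voxels
  ref_pos <- voxel_centers(model, arrayInd(ref_vox, dims))
  cen <- colMeans(ref_pos)
  ground <- node_of[ref_vox[which.min(rowSums(sweep(ref_pos, 2, cen)^2))]]

  keep <- setdiff(seq_len(n), ground)
  Ak <- A[keep, keep]
  bk <- bvec[keep]
  sol <- cg_solve(Ak, bk, tol = tolerance, maxit = max_iterations)
  if (!sol$converged)
    stop("conjugate gradients did not converge: relative residual ",
         format(sol$residual), " after ", sol$iterations,
         " iterations (is the conductor connected?)", call. = FALSE)
  x <- numeric(n)
  x[keep] <- sol$x
  Vgrid <- array(NA_real_, dim = dims)
  Vgrid[conducting] <- x
  new_field_solution("voxels", model, montage, potential_V = Vgrid,
                     residual = sol$residual, iterations = sol$iterations,
                     faces = faces)
}

cg_solve <- function(A, b, tol, maxit) {
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(list(x = numeric(length(b)), converged = TRUE,
                           residual = 0, iterations = 0L))
  Minv <- 1 / Matrix::diag(A)
  x <- numeric(length(b))
  r <- b
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(r^2)) / nb
    if (res <= tol)
      return(list(x = x, converged = TRUE, residual = res, iterations = it))
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, converged = FALSE, residual = res, iterations = maxit)
}

# ---- derived quantities ----------------------------------------------------

#' Electric field of a solved potential
#'
#' Populates the electric field `E = -grad V` of a [solve_potential()]
#' result. Voxel solutions use central differences (one-sided at tissue
#' boundaries); shell solutions differentiate the series numerically with
#' a small symmetric step. Fields are reported in mV/mm (1 V/m = 1 mV/mm).
#'
#' @param solution a `field_solution`.
#' @param step_mm finite-difference step for shell solutions.
#' @return The `field_solution` with `field_mV_mm` populated: for voxel
#'   solutions a 4-D array (x, y, z, component) plus `field_magnitude`;
#'   for shell solutions a function `field(points)` returning an `n x 3`
#'   matrix; slab solutions already carry `layer_field_mV_mm`.
#' @export
electric_field <- function(solution, step_mm = 0.05) {
  stopifnot(inherits(solution, "field_solution"))
  if (solution$kind == "slab") return(solution)
  if (solution$kind == "shells") {
    ev <- solution$evaluate
    solution$field <- function(points) {
      points <- matrix_3col(points)
      E <- matrix(0, nrow(points), 3)
      for (k in 1:3) {
        dp <- matrix(0, nrow(points), 3); dp[, k] <- step_mm
        # -dV/dx in V/mm -> mV/mm is *1000
        E[, k] <- -(ev(points + dp) - ev(points - dp)) / (2 * step_mm) * 1000
      }
      E
    }
    solution$field_magnitude <- function(points)
      sqrt(rowSums(solution$field(points)^2))
    return(solution)
  }
  V <- solution$potential_V
  dims <- dim(V)
  h <- solution$model$voxel_mm
  E <- array(NA_real_, dim = c(dims, 3))
  for (ax in 1:3) {
    Ef <- array(NA_real_, dim = dims)
    up <- shift_array(V, ax, -1L)
    dn <- shift_array(V, ax, +1L)
    central <- !is.na(up) & !is.na(dn)
    fwd <- !is.na(up) & is.na(dn) & !is.na(V)
    bwd <- is.na(up) & !is.na(dn) & !is.na(V)
    Ef[central] <- -(up[central] - dn[central]) / (2 * h) * 1000
    Ef[fwd] <- -(up[fwd] - V[fwd]) / h * 1000
    Ef[bwd] <- -(V[bwd] - dn[bwd]) / h * 1000
    E[, , , ax] <- Ef
  }
  solution$field_mV_mm <- E
  solution$field_magnitude <- sqrt(E[, , , 1]^2 + E[, , , 2]^2 + E[, , , 3]^2)
  solution
}

# shift array along axis by s (s = -1: value at i+1 appears at i)
shift_array <- function(V, ax, s) {
  dims <- dim(V)
  out <- array(NA_real_, dim = dims)
  src <- dst <- lapply(dims, seq_len)
  if (s < 0) { dst[[ax]] <- seq_len(dims[ax] - 1); src[[ax]] <- 2:dims[ax] }
  else { dst[[ax]] <- 2:dims[ax]; src[[ax]] <- seq_len(dims[ax] - 1) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- V[src[[1]], src[[2]], src[[3]]]
  out
}

#' Sample contact potentials along a subdural strip
#'
#' Returns the potential at each contact center of a strip. Voxel
#' solutions are sampled by trilinear interpolation; shell solutions are
#' evaluated exactly.
#'
#' @param solution a `field_solution` (shells or voxels).
#' @param strip a [strip_spec()].
#' @return Numeric vector of contact potentials in volts, with the strip
#'   stored in attribute `strip`.
#' @export
field_along_strip <- function(solution, strip) {
  stopifnot(inherits(solution, "field_solution"), inherits(strip, "strip_spec"))
  pts <- strip$contacts
  v <- switch(solution$kind,
              shells = solution$evaluate(pts),
              voxels = interp_trilinear(solution, pts),
              stop("strip sampling needs a shells or voxels solution",
                   call. = FALSE))
  if (anyNA(v)) stop("strip contact lies outside the conducting grid",
                     call. = FALSE)
  attr(v, "strip") <- strip
  v
}

#' Adjacent-contact pair fields from contact potentials
#'
#' Converts contact potentials (volts) to adjacent-pair field magnitudes
#' in mV/mm using the contact spacing.
#'
#' @param potentials_V contact potentials in volts.
#' @param spacing_mm contact spacing (default 5 mm).
#' @return Numeric vector of `length(potentials) - 1` field magnitudes.
#' @export
strip_pair_fields <- function(potentials_V, spacing_mm = 5) {
  abs(diff(as.numeric(potentials_V))) * 1000 / spacing_mm
}

interp_trilinear <- function(solution, points) {
  V <- solution$potential_V
  model <- solution$model
  dims <- dim(V)
  # continuous voxel coordinates: voxel centers at origin + (i - 0.5) h
  q <- sweep(matrix_3col(points), 2, model$origin_mm) / model$voxel_mm + 0.5
  out <- numeric(nrow(q))
  for (p in seq_len(nrow(q))) {
    i0 <- floor(q[p, ]); fr <- q[p, ] - i0
    acc <- 0; wsum <- 0; bad <- FALSE
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ix <- i0 + c(dx, dy, dz)
      w <- prod(ifelse(c(dx, dy, dz) == 1, fr, 1 - fr))
      if (w == 0) next
      if (any(ix < 1) || any(ix > dims)) { bad <- TRUE; next }
      val <- V[ix[1], ix[2], ix[3]]
      if (is.na(val)) { bad <- TRUE; next }
      acc <- acc + w * val; wsum <- wsum + w
    }
    # renormalize over conducting corners; NA only if nothing usable
    out[p] <- if (wsum > 0) acc / wsum else NA_real_
    if (bad && wsum == 0) out[p] <- NA_real_
  }
  out
}

#' Field-magnitude profile along a line into the brain
#'
#' Samples the electric-field magnitude from a cortical surface point
#' inward along a direction, at fixed depth steps.
#'
#' @param solution a `field_solution` with the field populated (shell
#'   solutions are populated on the fly).
#' @param surface_point numeric length-3 starting position (mm).
#' @param direction numeric length-3 direction (into the brain).
#' @param max_depth_mm,step_mm depth range and sampling step.
#' @return A data frame of class `depth_profile` with columns `depth_mm`
#'   and `field_mV_mm`; attribute `truncated` is `TRUE` when the line
#'   left the conducting model before `max_depth_mm`.
#' @export
depth_profile <- function(solution, surface_point, direction,
                          max_depth_mm = 20, step_mm = 1) {
  stopifnot(inherits(solution, "field_solution"))
  u <- unit3(direction)
  depths <- seq(0, max_depth_mm, by = step_mm)
  pts <- sweep(outer(depths, u), 2, as.numeric(surface_point), "+")
  if (solution$kind == "shells") {
    if (is.null(solution$field)) solution <- electric_field(solution)
    rr <- sqrt(rowSums(pts^2))
    inside <- rr < solution$model$shells$radius_mm[1] - 1e-9
    mag <- rep(NA_real_, length(depths))
    mag[inside] <- solution$field_magnitude(pts[inside, , drop = FALSE])
  } else if (solution$kind == "voxels") {
    if (is.null(solution$field_mV_mm)) solution <- electric_field(solution)
    mag <- numeric(length(depths))
    for (k in 1:3) {
      sol_k <- list(potential_V = solution$field_mV_mm[, , , k],
                    model = solution$model, kind = "voxels")
      class(sol_k) <- "field_solution"
      comp <- interp_trilinear(sol_k, pts)
      mag <- mag + comp^2
    }
    mag <- sqrt(mag)
  } else stop("depth profiles need a shells or voxels solution", call. = FALSE)
  truncated <- anyNA(mag)
  keep <- !is.na(mag)
  out <- data.frame(depth_mm = depths[keep], field_mV_mm = mag[keep])
  class(out) <- c("depth_profile", "data.frame")
  attr(out, "truncated") <- truncated
  out
}

#' Net current crossing a coordinate plane
#'
#' Sums the link currents of a voxel solution across the plane
#' `axis = position`, a discrete closed-surface current when the plane
#' separates source from sink. Used to verify charge conservation.
#'
#' @param solution a voxel `field_solution`.
#' @param axis 1, 2 or 3 (x, y, z).
#' @param position_mm plane position in model coordinates.
#' @return Net current in mA (positive toward increasing coordinate).
#' @export
current_through_plane <- function(solution, axis = 3, position_mm = 0) {
  stopifnot(solution$kind == "voxels")
  model <- solution$model
  V <- solution$potential_V
  dims <- dim(V)
  # layer index just below the plane
  k <- floor((position_mm - model$origin_mm[axis]) / model$voxel_mm)
  if (k < 1 || k >= dims[axis]) stop("plane outside the grid", call. = FALSE)
  idx_lo <- lapply(dims, seq_len); idx_lo[[axis]] <- k
  idx_hi <- lapply(dims, seq_len); idx_hi[[axis]] <- k + 1L
  Vlo <- V[idx_lo[[1]], idx_lo[[2]], idx_lo[[3]]]
  Vhi <- V[idx_hi[[1]], idx_hi[[2]], idx_hi[[3]]]
  idx_f <- idx_lo; idx_f[[axis]] <- k
  g <- solution$faces[[axis]][idx_f[[1]], idx_f[[2]], idx_f[[3]]]
  flux <- g * (Vlo - Vhi)     # current flowing upward (lo -> hi), amps
  sum(flux[!is.na(flux) & g > 0]) * 1000
}

#' @export
print.field_solution <- function(x, ...) {
  cat("Field solution (", x$kind, ")\n", sep = "")
  if (x$kind == "slab") {
    cat("  per-layer field (mV/mm):\n")
    print(x$layer_field_mV_mm)
  } else {
    cat("  residual:", format(x$residual), " iterations:", x$iterations, "\n")
  }
  invisible(x)
}

#' @export
plot.depth_profile <- function(x, ...) {
  graphics::plot(x$depth_mm, x$field_mV_mm, type = "b",
                 xlab = "depth from cortical surface (mm)",
                 ylab = "field magnitude (mV/mm)", ...)
  invisible(x)
}
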