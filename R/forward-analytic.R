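#' Analytic potential in an N-shell concentric sphere
#'
#' Legendre-series solution of the quasi-static volume-conduction problem
#' for point current monopoles placed on the outer surface or on an
#' internal shell interface of a piecewise-homogeneous concentric-sphere
#' conductor. Per harmonic degree the radial solution in each shell is
#' `A r^n + B r^-(n+1)`; coefficients are matched by continuity of the
#' potential and of the radial current density `sigma dV/dr` at every
#' interface, with the monopole entering as a surface current-density
#' jump (or outer Neumann datum) expanded in Legendre polynomials.
#' Source and sink are superposed, so the net-current (n = 0) mode never
#' arises.
#'
#' @param radii shell outer radii in mm, innermost first, strictly
#'   increasing.
#' @param sigmas conductivities in S/m, one per shell (innermost first).
#' @param points numeric `n x 3` matrix of evaluation positions (mm).
#' @param source_dir,sink_dir unit direction vectors of the source and
#'   sink monopoles (positions are `dir * radius`).
#' @param source_radius,sink_radius monopole radius in mm; must equal the
#'   outer radius or one of the interface radii. Default: outer surface.
#' @param current_mA injected current (source `+`, sink `-`).
#' @param n_max maximum harmonic degree.
#' @param series_tol truncate once the last term's relative contribution
#'   drops below this at all evaluation points.
#' @return Numeric vector of potentials in volts, with attribute
#'   `converged` (FALSE if `n_max` was reached before `series_tol`).
#' @seealso [homogeneous_sphere_potential()] for the single-shell closed
#'   form used as an independent check.
#' @export
analytic_shell_potential <- function(radii, sigmas, points,
                                     source_dir, sink_dir,
                                     source_radius = max(radii),
                                     sink_radius = source_radius,
                                     current_mA = 1,
                                     n_max = 400, series_tol = 1e-10) {
  stopifnot(length(radii) == length(sigmas), all(diff(radii) > 0),
            all(sigmas > 0))
  points <- matrix_3col(points)
  source_dir <- unit3(source_dir)
  sink_dir <- unit3(sink_dir)
  r_m <- radii / 1000
  I_A <- current_mA / 1000
  rr <- sqrt(rowSums(points^2))
  if (any(rr > max(radii) * (1 + 1e-9)))
    stop("evaluation point outside the outer shell", call. = FALSE)
  # reject evaluation at a monopole position
  for (s in list(list(source_dir, source_radius), list(sink_dir, sink_radius))) {
    sp <- s[[1]] * s[[2]]
    d <- sqrt(colSums((t(points) - sp)^2))
    if (any(d < 1e-9))
      stop("cannot evaluate the potential at a source point", call. = FALSE)
  }
  cg_src <- (points %*% source_dir) / pmax(rr, 1e-300)
  cg_snk <- (points %*% sink_dir) / pmax(rr, 1e-300)
  cg_src[rr == 0] <- 0; cg_snk[rr == 0] <- 0
  shell_of <- findInterval(rr, radii[-length(radii)] * (1 + 1e-12)) + 1L

  coef_src <- shell_series_coefficients(r_m, sigmas, source_radius / 1000,
                                        I_A, n_max)
  coef_snk <- if (sink_radius == source_radius) coef_src else
    shell_series_coefficients(r_m, sigmas, sink_radius / 1000, I_A, n_max)

  V <- numeric(nrow(points))
  # Legendre recurrences per evaluation point
  P0s <- rep(1, nrow(points)); P1s <- as.numeric(cg_src)
  P0k <- rep(1, nrow(points)); P1k <- as.numeric(cg_snk)
  converged <- FALSE
  r_rel <- rr / 1000
  small_run <- 0L    # Legendre terms oscillate: require a run of small ones
  for (n in seq_len(n_max)) {
    Pn_s <- if (n == 1) P1s else ((2 * n - 1) * cg_src * P1s - (n - 1) * P0s) / n
    Pn_k <- if (n == 1) P1k else ((2 * n - 1) * cg_snk * P1k - (n - 1) * P0k) / n
    rad_s <- radial_eval(coef_src, n, shell_of, r_rel, r_m)
    rad_k <- radial_eval(coef_snk, n, shell_of, r_rel, r_m)
    term <- rad_s * Pn_s - rad_k * Pn_k
    V <- V + term
    small_run <- if (max(abs(term)) <= series_tol * max(abs(V), 1e-300))
      small_run + 1L else 0L
    if (n >= 8 && small_run >= 10L) {
      converged <- TRUE
      break
    }
    if (n > 1) { P0s <- P1s; P1s <- Pn_s; P0k <- P1k; P1k <- Pn_k }
    else { P1s <- Pn_s; P1k <- Pn_k }
  }
  if (!converged)
    warning("Legendre series not converged at n_max = ", n_max)
  attr(V, "converged") <- converged
  as.numeric(V) -> out
  attributes(out) <- list(converged = converged)
  out
}

# Solve, for every harmonic degree n, the (2N-1) coefficient system for a
# unit-expansion monopole at radius rs (meters). Returns a list of per-n
# coefficient matrices [A_j, B_j] with per-shell scaled radial bases:
# shell j spans (a_j, b_j];  V_j = A (r/b)^n + B (a/r)^(n+1)  (B_1 = 0).
shell_series_coefficients <- function(r_m, sigmas, rs, I_A, n_max) {
  N <- length(r_m)
  a <- c(0, r_m[-N]); b <- r_m
  src_iface <- which(abs(b - rs) < 1e-12)
  if (!length(src_iface))
    stop("monopole radius must lie on the outer surface or an interface",
         call. = FALSE)
  out <- vector("list", n_max)
  for (n in seq_len(n_max)) {
    nun <- 2 * N - 1
    M <- matrix(0, nun, nun)
    rhs <- numeric(nun)
    jn <- I_A * (2 * n + 1) / (4 * pi * rs^2)
    # unknown layout: A_1 at 1; (A_j, B_j) at 2j-2, 2j-1 for j >= 2
    iA <- function(j) if (j == 1) 1L else 2L * j - 2L
    iB <- function(j) 2L * j - 1L
    # scaled forms (never materialize r^n alone: avoids under/overflow)
    f  <- function(j, r) (r / b[j])^n
    fp <- function(j, r) (n / r) * (r / b[j])^n
    g  <- function(j, r) (a[j] / r)^(n + 1)
    gp <- function(j, r) -((n + 1) / r) * (a[j] / r)^(n + 1)
    row <- 0L
    for (i in seq_len(N - 1)) {          # interface at b[i]
      r0 <- b[i]
      row <- row + 1L                    # continuity of V
      M[row, iA(i)] <- f(i, r0)
      if (i > 1) M[row, iB(i)] <- g(i, r0)
      M[row, iA(i + 1)] <- -f(i + 1, r0)
      M[row, iB(i + 1)] <- -g(i + 1, r0)
      row <- row + 1L                    # jump of sigma dV/dr
      M[row, iA(i + 1)] <- sigmas[i + 1] * fp(i + 1, r0)
      M[row, iB(i + 1)] <- sigmas[i + 1] * gp(i + 1, r0)
      M[row, iA(i)] <- M[row, iA(i)] - sigmas[i] * fp(i, r0)
      if (i > 1) M[row, iB(i)] <- M[row, iB(i)] - sigmas[i] * gp(i, r0)
      if (i == src_iface) rhs[row] <- -jn
    }
    row <- row + 1L                      # outer boundary at b[N]
    M[row, iA(N)] <- sigmas[N] * fp(N, b[N])
    if (N > 1) M[row, iB(N)] <- sigmas[N] * gp(N, b[N])
    rhs[row] <- if (src_iface == N) jn else 0
    out[[n]] <- solve(M, rhs)
  }
  out
}

# evaluate the scaled radial basis for degree n at relative radii (meters)
radial_eval <- function(coefs, n, shell_of, r_rel, r_m) {
  N <- length(r_m)
  a <- c(0, r_m[-N]); b <- r_m
  cf <- coefs[[n]]
  out <- numeric(length(r_rel))
  for (j in seq_len(N)) {
    sel <- shell_of == j
    if (!any(sel)) next
    r <- pmax(r_rel[sel], 1e-300)
    A <- cf[if (j == 1) 1L else 2L * j - 2L]
    v <- A * (r / b[j])^n
    if (j > 1) v <- v + cf[2L * j - 1L] * (a[j] / r)^(n + 1)
    out[sel] <- v
  }
  out
}

#' Closed-form potential of a surface dipole pair on a homogeneous sphere
#'
#' For a point current source on the surface of a homogeneous sphere of
#' radius `R` and conductivity `sigma`, the interior potential has the
#' closed form
#' `V = I/(4 pi sigma R) * (2R/d - 2 + log(2R / (R - r cos(g) + d)))`,
#' with `d` the chordal distance to the source and `g` the angle between
#' the evaluation point and the source. Source and sink are superposed.
#' Used as an independent check of the Legendre series.
#'
#' @inheritParams analytic_shell_potential
#' @param radius_mm sphere radius (mm).
#' @param sigma conductivity (S/m).
#' @return Potentials in volts.
#' @export
homogeneous_sphere_potential <- function(radius_mm, sigma, points,
                                         source_dir, sink_dir,
                                         current_mA = 1) {
  points <- matrix_3col(points)
  R <- radius_mm / 1000
  I_A <- current_mA / 1000
  p <- points / 1000
  mono <- function(u) {
    sp <- u * R
    d <- sqrt(colSums((t(p) - sp)^2))
    r <- sqrt(rowSums(p^2))
    rc <- as.numeric(p %*% unit3(u))      # r cos(gamma)
    I_A / (4 * pi * sigma * R) * (2 * R / d - 2 + log(2 * R / (R - rc + d)))
  }
  mono(unit3(source_dir)) - mono(unit3(sink_dir))
}

matrix_3col <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  points
}

unit3 <- function(v) {
  v <- as.numeric(v)
  stopifnot(length(v) == 3)
  v / sqrt(sum(v^2))
}
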