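#' Build a combined cortical + cerebellar spherical source space
#'
#' Cortical vertices are placed quasi-uniformly (Fibonacci lattice) on the
#' upper hemispherical cap of a sphere of radius `r_cortex`; cerebellar
#' vertices on an inferior-posterior spherical patch at the smaller radius
#' `r_cerebellum`, capturing the geometry that makes cerebellar EEG hard:
#' cerebellar sources are deeper and posterior, hence low-SNR at the scalp.
#' Dipole orientations are constrained to the (radial) surface normals.
#'
#' Cortical region labels follow an electrode-seeded nearest-direction rule
#' over the 10-20 montage: frontal (F3/F4/Fz), central (C3/C4/Cz), parietal
#' (P3/P4), temporal (T3/T4) and occipital (O1/O2) seeds, with hemisphere
#' taken from the winning electrode (midline seeds split by the vertex's
#' own y sign). Cerebellar vertices are labelled cerebellum_L/R by y sign.
#'
#' @param n_cortex number of cortical vertices (>= 10).
#' @param n_cerebellum number of cerebellar vertices (>= 10).
#' @param seed RNG seed for the small symmetry-breaking jitter.
#' @param r_cortex,r_cerebellum shell radii of the two surfaces (m).
#' @param jitter angular jitter (radians, sd) applied to lattice points.
#' @return object of class `source_space`: list with `vertices` (n x 3, m),
#'   `normals` (n x 3, unit), `region` (character), `surface`
#'   (cortex/cerebellum).
#' @export
build_source_space <- function(n_cortex = 500, n_cerebellum = 100, seed = 1,
                               r_cortex = 0.070, r_cerebellum = 0.055,
                               jitter = 0.005) {
  stopifnot(n_cortex >= 10, n_cerebellum >= 10)
  with_seed(seed, {
    ctx_dir <- fibonacci_cap(n_cortex, zmin = 0.02, jitter = jitter)
    # inferior-posterior patch: axis pointing back (-x) and down (-z)
    axis <- c(-0.65, 0, -0.60); axis <- axis / sqrt(sum(axis^2))
    cb_dir <- rotate_to(fibonacci_cap(n_cerebellum, zmin = cos(35 * pi / 180),
                                      jitter = jitter), axis)
    vertices <- rbind(ctx_dir * r_cortex, cb_dir * r_cerebellum)
    normals <- rbind(ctx_dir, cb_dir)
    surface <- rep(c("cortex", "cerebellum"), c(n_cortex, n_cerebellum))
    region <- c(label_cortical(ctx_dir),
                ifelse(cb_dir[, 2] > 0, "cerebellum_L", "cerebellum_R"))
    structure(list(vertices = vertices, normals = normals,
                   region = region, surface = surface),
              class = "source_space")
  })
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %d vertices (%d cortex, %d cerebellum), %d regions\n",
              nrow(x$vertices), sum(x$surface == "cortex"),
              sum(x$surface == "cerebellum"), length(unique(x$region))))
  invisible(x)
}

n_vertices <- function(space) nrow(space$vertices)

# Fibonacci lattice on the spherical cap z in [zmin, 1]
fibonacci_cap <- function(n, zmin, jitter = 0) {
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - zmin) * i / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  p <- cbind(s * cos(phi), s * sin(phi), z)
  if (jitter > 0) {
    p <- p + matrix(stats::rnorm(3 * n, sd = jitter), n, 3)
    p <- p / sqrt(rowSums(p^2))
  }
  p
}

# Rotate points so that +z maps onto `axis` (Rodrigues)
rotate_to <- function(p, axis) {
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  s <- sqrt(sum(v^2)); c0 <- sum(z * axis)
  if (s < 1e-12) return(if (c0 > 0) p else -p)
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  R <- diag(3) + K + K %*% K * ((1 - c0) / s^2)
  p %*% t(R)
}

roi_seed_table <- function() {
  m <- montage_1020()
  seeds <- list(frontal = c("F3", "F4", "Fz"),
                central = c("C3", "C4", "Cz"),
                parietal = c("P3", "P4"),
                temporal = c("T3", "T4"),
                occipital = c("O1", "O2"))
  do.call(rbind, lapply(names(seeds), function(roi) {
    idx <- match(seeds[[roi]], m$name)
    data.frame(roi = roi, name = m$name[idx],
               x = m$x[idx], y = m$y[idx], z = m$z[idx],
               midline = abs(m$y[idx]) < 0.05, stringsAsFactors = FALSE)
  }))
}

label_cortical <- function(dirs) {
  seeds <- roi_seed_table()
  S <- as.matrix(seeds[, c("x", "y", "z")])
  dots <- dirs %*% t(S)                      # n x n_seeds
  best <- max.col(dots, ties.method = "first")
  side <- ifelse(seeds$midline[best],
                 ifelse(dirs[, 2] > 0, "L", "R"),
                 ifelse(seeds$y[best] > 0, "L", "R"))
  paste(seeds$roi[best], side, sep = "_")
}

# ---------------------------------------------------------------------------
# Analytic concentric multi-shell lead field.
#
# Potential of a current dipole inside the innermost of N concentric
# conducting shells, expanded in Legendre harmonics. Per degree n the
# radial profile in shell k is A_k r^n + B_k r^-(n+1); the dipole adds the
# infinite-medium particular term to shell 1. Boundary conditions
# (continuity of V and of sigma dV/dr at interfaces, zero normal current at
# the outer surface) give a small linear system per n whose surface factor
# F_n is computed once; for equal conductivities it reduces to the
# homogeneous-sphere series (2n+1)/(n R^(n+1)), which is the closed-form
# oracle used in tests.

shell_surface_factors <- function(radii, cond, n_terms) {
  N <- length(radii)
  stopifnot(length(cond) == N, all(diff(radii) > 0), all(cond > 0))
  Rout <- radii[N]
  radii <- radii / Rout       # solve in scaled units for conditioning;
  Fn <- numeric(n_terms)      # rescaled to F_n / Rout^(n+1) on return
  for (n in seq_len(n_terms)) {
    # unknowns: A_1, (A_k, B_k) for k = 2..N
    nun <- 1 + 2 * (N - 1)
    M <- matrix(0, nun, nun); rhs <- numeric(nun)
    colA <- function(k) if (k == 1) 1L else 2L * (k - 1L)
    colB <- function(k) { stopifnot(k >= 2); 2L * (k - 1L) + 1L }
    row <- 0L
    for (k in seq_len(N - 1)) {
      r <- radii[k]
      # continuity of V (particular source term r^-(n+1) lives in shell 1)
      row <- row + 1L
      M[row, colA(k)] <- r^n
      if (k >= 2) M[row, colB(k)] <- r^(-(n + 1))
      M[row, colA(k + 1)] <- -r^n
      M[row, colB(k + 1)] <- -r^(-(n + 1))
      rhs[row] <- if (k == 1) -r^(-(n + 1)) else 0
      # continuity of sigma dV/dr
      row <- row + 1L
      M[row, colA(k)] <- cond[k] * n * r^(n - 1)
      if (k >= 2) M[row, colB(k)] <- -cond[k] * (n + 1) * r^(-(n + 2))
      M[row, colA(k + 1)] <- -cond[k + 1] * n * r^(n - 1)
      M[row, colB(k + 1)] <- cond[k + 1] * (n + 1) * r^(-(n + 2))
      rhs[row] <- if (k == 1) cond[1] * (n + 1) * r^(-(n + 2)) else 0
    }
    # outer boundary: no current leaves the head
    row <- row + 1L
    R <- radii[N]
    M[row, colA(N)] <- n * R^(n - 1)
    if (N >= 2) M[row, colB(N)] <- -(n + 1) * R^(-(n + 2))
    rhs[row] <- if (N == 1) (n + 1) * R^(-(n + 2)) else 0
    # column equilibration: powers of the scaled radii still span many
    # orders of magnitude at high n
    cs <- apply(abs(M), 2, max)
    sol <- solve(M %*% diag(1 / cs, nun), rhs) / cs
    Ftil <- if (N == 1) sol[colA(1)] * R^n + R^(-(n + 1))
            else sol[colA(N)] * R^n + sol[colB(N)] * R^(-(n + 1))
    Fn[n] <- Ftil / Rout^(n + 1)
  }
  Fn
}

#' Default 3-shell head model
#'
#' Brain/skull/scalp shells of radii 0.087/0.092/0.100 m with
#' conductivities 0.33/0.0042/0.33 S/m.
#' @export
default_shells <- function() {
  list(radii = c(0.087, 0.092, 0.100), cond = c(0.33, 0.0042, 0.33))
}

#' Compute the analytic multi-shell lead field
#'
#' For every source vertex, evaluates the concentric-sphere potential of a
#' unit current dipole oriented along the vertex normal at every electrode
#' of the montage (electrodes projected onto the outer shell), then applies
#' the common-average projector so each lead-field column is mean-free
#' across channels -- consistent with common-average-referenced data.
#'
#' @param space a `source_space`.
#' @param montage montage data.frame (name,x,y,z unit sphere) or an
#'   `eeg_recording` carrying one.
#' @param shells list with `radii` (increasing, m) and `cond` (S/m);
#'   default [default_shells()].
#' @param n_terms Legendre series truncation (default 100).
#' @return object of class `forward_model`: list with `leadfield`
#'   (channels x vertices), `space`, `shells`, `channel_names`.
#' @export
leadfield_sphere <- function(space, montage, shells = default_shells(),
                             n_terms = 100) {
  if (inherits(montage, "eeg_recording")) montage <- montage$montage
  if (is.null(montage)) stopf("montage required")
  montage <- normalize_montage(montage, montage$name)
  E <- as.matrix(montage[, c("x", "y", "z")])     # unit directions
  b <- sqrt(rowSums(space$vertices^2))
  if (any(b >= shells$radii[1]))
    stopf("source radius %.4f m >= inner shell radius %.4f m",
          max(b), shells$radii[1])
  Fn <- shell_surface_factors(shells$radii, shells$cond, n_terms)
  nE <- nrow(E); nV <- n_vertices(space)
  L <- matrix(0, nE, nV)
  nn <- seq_len(n_terms)
  for (v in seq_len(nV)) {
    r0 <- space$vertices[v, ]
    bv <- b[v]
    rhat <- r0 / bv
    m <- space$normals[v, ]
    x <- as.vector(E %*% rhat)                    # cos gamma per electrode
    x <- pmin(pmax(x, -1), 1)
    s <- sqrt(pmax(0, 1 - x^2))
    # tangent unit vector at the source pointing toward each electrode
    Tm <- E - outer(x, rhat)                      # nE x 3
    tn <- sqrt(rowSums(Tm^2))
    mt <- ifelse(tn > 1e-12, as.vector(Tm %*% m) / tn, 0)
    mr <- sum(m * rhat)
    leg <- legendre_table(x, n_terms)
    coef <- Fn * bv^(nn - 1)
    V <- leg$P %*% (coef * nn) * mr + leg$P1 %*% coef * mt
    L[, v] <- V / (4 * pi * shells$cond[1])
  }
  L <- L - matrix(colMeans(L), nE, nV, byrow = TRUE) # common-average projection
  rownames(L) <- montage$name
  structure(list(leadfield = L, space = space, shells = shells,
                 channel_names = montage$name, montage = montage),
            class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf("<forward_model> %d channels x %d vertices, %d-shell sphere\n",
              nrow(x$leadfield), ncol(x$leadfield), length(x$shells$radii)))
  invisible(x)
}

#' Closed-form homogeneous-sphere dipole potential
#'
#' Surface potential of a current dipole in a homogeneous conducting sphere
#' (radius `R`, conductivity `sigma`) with zero current through the
#' surface, from the summed Legendre series (generating-function closed
#' form). Independent of the shell-series code path; used as its oracle.
#'
#' @param r_elec electrode positions on the surface, n x 3 (m).
#' @param r_dip dipole position inside the sphere (m).
#' @param moment dipole moment vector.
#' @param R sphere radius (m).
#' @param sigma conductivity (S/m).
#' @return potential at each electrode.
#' @export
sphere_potential_closed <- function(r_elec, r_dip, moment, R, sigma) {
  r_elec <- matrix(r_elec, ncol = 3)
  bv <- sqrt(sum(r_dip^2)); rhat <- r_dip / bv
  f <- bv / R
  ehat <- r_elec / sqrt(rowSums(r_elec^2))
  x <- pmin(pmax(as.vector(ehat %*% rhat), -1), 1)
  s <- sqrt(pmax(1e-300, 1 - x^2))
  Tm <- ehat - outer(x, rhat)
  tn <- sqrt(rowSums(Tm^2))
  mt <- ifelse(tn > 1e-12, as.vector(Tm %*% moment) / tn, 0)
  mr <- sum(moment * rhat)
  g <- 1 / sqrt(1 - 2 * f * x + f^2)
  radial <- 2 * g^3 * (x - f) + (g - 1) / f
  tangential <- 2 * s * g^3 + (g * (f - x) + x) / (f * s)
  (mr * radial + mt * tangential) / (4 * pi * sigma * R^2)
}
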