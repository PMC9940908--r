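# Triangular-lattice traveling-wave geometry: the idealized cilia carpet on
# which perfect metachronal waves live. Sites sit on a triangular lattice
# (default spacing 18 um, 16 x 16 unit cell with periodic boundaries); the
# admissible plane waves are the reciprocal-lattice fractions compatible
# with those boundaries.

#' Triangular lattice specification
#'
#' Basis vectors `a1 = a (1, 0)`, `a2 = a (1/2, sqrt(3)/2)`; the +y axis is
#' the cilia effective-stroke axis, from which wave angles are measured.
#'
#' @param n1,n2 sites along each basis direction.
#' @param spacing lattice constant in um.
#' @return An object of class `lattice_spec`.
#' @export
lattice_spec <- function(n1 = 16L, n2 = 16L, spacing = 18) {
  stopifnot(is_count(n1), is_count(n2), spacing > 0)
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), spacing = spacing,
                 a1 = spacing * c(1, 0),
                 a2 = spacing * c(1 / 2, sqrt(3) / 2)),
            class = "lattice_spec")
}

#' Site positions of a triangular lattice
#'
#' @param spec a [lattice_spec()].
#' @return A numeric matrix (`n1 * n2` x 2) of site positions in um:
#'   `x_ij = i a1 + j a2` for `i in 0..n1-1`, `j in 0..n2-1` (i fastest).
#' @export
build_lattice <- function(spec = lattice_spec()) {
  stopifnot(inherits(spec, "lattice_spec"))
  ij <- expand.grid(i = 0:(spec$n1 - 1L), j = 0:(spec$n2 - 1L))
  cbind(x = ij$i * spec$a1[1] + ij$j * spec$a2[1],
        y = ij$i * spec$a1[2] + ij$j * spec$a2[2])
}

#' Area density of a triangular lattice
#'
#' `2 / (sqrt(3) spacing^2)` sites per um^2 — one site per primitive cell.
#' At the model's 18 um spacing this is the dilute density 0.0036 um^-2.
#'
#' @param spacing lattice constant in um.
#' @return Sites per um^2.
#' @export
lattice_density <- function(spacing) {
  stopifnot(is.numeric(spacing), all(spacing > 0))
  2 / (sqrt(3) * spacing^2)
}

# Reciprocal basis: b_i . a_j = 2 pi delta_ij.
reciprocal_basis <- function(spec) {
  A <- cbind(spec$a1, spec$a2)          # columns a1, a2
  B <- 2 * pi * solve(A)                # row i satisfies b_i . a_j = 2 pi d_ij
  list(b1 = B[1, ], b2 = B[2, ])
}

# Reduce wave vectors (rows of K) to the first Brillouin zone: the
# reciprocal-lattice translate of minimal |k|, ties broken lexicographically
# (kx, then ky).
bz_reduce <- function(K, spec) {
  rb <- reciprocal_basis(spec)
  shifts <- as.matrix(expand.grid(m1 = -2:2, m2 = -2:2))
  G <- shifts %*% rbind(rb$b1, rb$b2)   # 25 x 2 translates
  out <- K
  for (r in seq_len(nrow(K))) {
    cand <- sweep(G, 2, K[r, ], "+")
    n2 <- rowSums(cand^2)
    best <- which(n2 <= min(n2) + 1e-9)
    if (length(best) > 1) {
      o <- order(round(cand[best, 1], 9), round(cand[best, 2], 9))
      best <- best[o[1]]
    }
    out[r, ] <- cand[best, ]
  }
  out
}

#' Admissible traveling waves on a periodic triangular lattice
#'
#' Periodic boundary conditions on an `n1 x n2` unit cell admit exactly
#' `n1 * n2` distinct plane waves `k = (p/n1) b1 + (q/n2) b2` (reciprocal
#' basis `b_i . a_j = 2 pi delta_ij`), each reduced to a canonical
#' first-Brillouin-zone representative. The in-phase "wave" `k = (0, 0)` is
#' included.
#'
#' @param spec a [lattice_spec()].
#' @return A data frame: `p`, `q`, `kx`, `ky` (rad/um), `k_mag`,
#'   `lambda_um` (`Inf` for `k = 0`), `theta_deg` (`NA` for `k = 0`).
#' @export
admissible_wavevectors <- function(spec = lattice_spec()) {
  stopifnot(inherits(spec, "lattice_spec"))
  rb <- reciprocal_basis(spec)
  pq <- expand.grid(p = 0:(spec$n1 - 1L), q = 0:(spec$n2 - 1L))
  K <- cbind(pq$p / spec$n1 * rb$b1[1] + pq$q / spec$n2 * rb$b2[1],
             pq$p / spec$n1 * rb$b1[2] + pq$q / spec$n2 * rb$b2[2])
  K <- bz_reduce(K, spec)
  K <- round(K, 12)
  dup <- duplicated(K)
  K <- K[!dup, , drop = FALSE]
  pq <- pq[!dup, , drop = FALSE]
  ang <- wavevector_to_angle(K[, 1], K[, 2])
  data.frame(p = pq$p, q = pq$q, kx = K[, 1], ky = K[, 2],
             k_mag = sqrt(K[, 1]^2 + K[, 2]^2),
             lambda_um = ang$wavelength, theta_deg = ang$theta)
}

#' Convert between wave angle/wavelength and wave vector
#'
#' The wave-vector parametrization `(kx, ky) = 2 pi / lambda *
#' (-sin theta, cos theta)`: `theta` is measured from the effective-stroke
#' axis (+y), so `theta = 0` is a symplectic wave traveling along the
#' stroke and `theta = 90` deg points along -x.
#'
#' @param theta wave angle in degrees.
#' @param wavelength um (> 0).
#' @return `angle_to_wavevector()`: list with `kx`, `ky` (rad/um).
#'   `wavevector_to_angle()`: list with `theta` (degrees in `[0, 360)`,
#'   `NA` for `k = 0`) and `wavelength` (um, `Inf` for `k = 0`).
#' @export
angle_to_wavevector <- function(theta, wavelength) {
  stopifnot(all(wavelength > 0))
  th <- theta * pi / 180
  list(kx = -2 * pi / wavelength * sin(th),
       ky = 2 * pi / wavelength * cos(th))
}

#' @rdname angle_to_wavevector
#' @param kx,ky wave-vector components in rad/um.
#' @export
wavevector_to_angle <- function(kx, ky) {
  k <- sqrt(kx^2 + ky^2)
  theta <- ifelse(k > 0, wrap_deg(atan2(-kx, ky) * 180 / pi), NA_real_)
  list(theta = theta, wavelength = ifelse(k > 0, 2 * pi / k, Inf))
}

#' Plane-wave phase field with Gaussian phase noise
#'
#' Phases `phi_i = wrap(k . x_i + eta_i + U)` with site noise
#' `eta_i ~ N(0, sigma^2)` i.i.d. and a global offset
#' `U ~ Uniform[0, 2 pi)`; the initial condition used to probe how phase
#' noise degrades a perfect metachronal wave.
#'
#' @param k list or vector with `kx`, `ky` (rad/um).
#' @param positions site positions (n x 2, um), e.g. [build_lattice()].
#' @param sigma phase-noise SD in rad (>= 0).
#' @param seed RNG seed (reproducible field); `NULL` uses the current RNG
#'   state.
#' @param global_offset set, e.g., to 0 to suppress the random global
#'   offset; `NULL` draws it uniformly.
#' @return An object of class `phase_field`: `phases` (rad, `(-pi, pi]`),
#'   `k`, `sigma`, `global_offset`, `positions`.
#' @export
noisy_phase_field <- function(k, positions, sigma = 0, seed = NULL,
                              global_offset = NULL) {
  stopifnot(sigma >= 0)
  if (is.list(k)) k <- c(k$kx, k$ky)
  positions <- as.matrix(positions)
  with_seed(seed, {
    if (is.null(global_offset)) global_offset <- stats::runif(1, 0, 2 * pi)
    eta <- if (sigma > 0) stats::rnorm(nrow(positions), 0, sigma) else 0
    phases <- wrap_pi(positions %*% k + eta + global_offset)
  })
  structure(list(phases = as.vector(phases), k = k, sigma = sigma,
                 global_offset = global_offset, positions = positions),
            class = "phase_field")
}
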