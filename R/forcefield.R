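## Internal unit system: length nm, charge e, energy eV, force eV/nm.
## e^2/(4 pi eps0) = 1.43996454 eV nm keeps every prefactor near unity.
.KE_EVNM <- 1.43996454
.KB_EV <- 8.617333262e-5

#' Force-field parameter set
#'
#' Collects every constant of the coarse-grained field. Internal units are
#' nm / elementary charge / eV, so forces are in eV/nm.
#'
#' Two constants the model needs are not fixed by first principles and are
#' calibrated here:
#' \itemize{
#'   \item \code{beta}, the dielectric displacement-force constant
#'     (eV nm^5 / e^2): by default the displacement force \eqn{\beta q^2/r^5}
#'     on a nonpolar site equals the Coulomb force between unit opposite
#'     charges in water at r = 0.1 nm, i.e. \eqn{\beta = K_e r^3/\epsilon_r}
#'     at that distance.
#'   \item \code{gamma} (1/nm): sets the isotropic thermal force magnitude
#'     \eqn{\gamma k T}; by default \eqn{\gamma k T} is 10\% of the Coulomb
#'     force between unit opposite charges in water at 0.5 nm, so that strong
#'     nearby electrostatic/hydrophobic pairs dominate the thermal force early
#'     in folding.
#' }
#'
#' @param temperature_K Temperature in Kelvin.
#' @param pH Ambient pH (carried along for sequence annotation).
#' @param eps_rel Relative permittivity; 78 (water) throughout.
#' @param beta Displacement constant; \code{NULL} for the calibrated default.
#' @param gamma Thermal-force constant; \code{NULL} for the calibrated
#'   default.
#' @param D Diffusivity (nm^2 per simulation time unit).
#' @param dST Magnitude of the lumped global entropy-temperature change per
#'   proposed move (eV, >= 0). Entropy-decreasing proposals see mobility
#'   \eqn{D/(kT + dST)}, entropy-increasing ones \eqn{D/(kT - dST)}.
#' @return Object of class \code{forcefield_params}.
#' @export
#' @examples
#' p <- forcefield_params()
#' p$gamma * p$k * p$T   # thermal force magnitude, eV/nm
forcefield_params <- function(temperature_K = 298, pH = 7, eps_rel = 78,
                              beta = NULL, gamma = NULL, D = 1,
                              dST = 0.005) {
  if (temperature_K < 0) stop("temperature_K must be >= 0")
  if (eps_rel <= 0 || D <= 0) stop("eps_rel and D must be positive")
  if (dST < 0) stop("dST must be >= 0")
  if (is.null(beta)) beta <- .KE_EVNM / eps_rel * 0.1^3
  if (is.null(gamma)) {
    f_ref <- 0.1 * .KE_EVNM / (eps_rel * 0.5^2)
    kT <- .KB_EV * max(temperature_K, 1)
    gamma <- f_ref / kT
  }
  if (beta < 0 || gamma < 0) stop("beta and gamma must be >= 0")
  structure(list(T = temperature_K, pH = pH, eps_rel = eps_rel,
                 beta = beta, gamma = gamma, D = D, dST = dST,
                 k = .KB_EV, ke = .KE_EVNM),
            class = "forcefield_params")
}

#' Coulomb force between two point charges
#'
#' Signed magnitude \eqn{q_1 q_2 K_e / (\epsilon_r r^2)} in eV/nm: positive
#' for like signs (repulsive along the separation axis), negative for opposite
#' signs (attractive). The pair forces are equal and opposite by construction.
#'
#' @param q1,q2 Charges (elementary-charge units).
#' @param r Separation (nm), > 0.
#' @param eps_rel Relative permittivity.
#' @return Signed force magnitude (eV/nm).
#' @export
coulomb_force <- function(q1, q2, r, eps_rel = 78) {
  if (any(r <= 0)) stop("degenerate geometry: r must be > 0")
  .KE_EVNM * q1 * q2 / (eps_rel * r^2)
}

#' Dielectric displacement force on a nonpolar site
#'
#' Magnitude \eqn{\beta q^2 / r^5} (eV/nm), always directed away from the
#' charge: polar solvent drawn toward the field sweeps nonpolar matter toward
#' lower field regions.
#'
#' @param q Source charge (e).
#' @param r Distance from the charge to the nonpolar site (nm), > 0.
#' @param beta Displacement constant (eV nm^5 / e^2).
#' @return Non-negative force magnitude (eV/nm).
#' @export
displacement_force <- function(q, r, beta = forcefield_params()$beta) {
  if (any(r <= 0)) stop("degenerate geometry: r must be > 0")
  beta * q^2 / r^5
}

#' Isotropic thermal force draw
#'
#' One random force vector of magnitude \eqn{\gamma k T} with direction
#' uniform on the sphere, drawn from R's global random number stream (seed it
#' with \code{set.seed()} for reproducibility). At T = 0 the zero vector is
#' returned without consuming random numbers.
#'
#' @param params A [forcefield_params()] object.
#' @return Length-3 numeric force vector (eV/nm).
#' @export
thermal_force <- function(params) {
  mag <- params$gamma * params$k * params$T
  if (mag == 0) return(c(0, 0, 0))
  v <- stats::rnorm(3)
  nv <- sqrt(sum(v^2))
  while (nv < 1e-12) {        # essentially impossible; guards division
    v <- stats::rnorm(3)
    nv <- sqrt(sum(v^2))
  }
  mag * v / nv
}

#' Entropy-modified drift mobility
#'
#' With no entropy coupling (\code{dST = 0}) this is the Einstein relation
#' \eqn{\mu = D/kT}. A proposed move that decreases global entropy
#' (\code{entropy_change_sign = -1}, e.g. chain compaction) sees
#' \eqn{D/(kT + dST)}; an entropy-increasing move sees \eqn{D/(kT - dST)},
#' i.e. proceeds with higher mobility.
#'
#' @param params A [forcefield_params()] object.
#' @param entropy_change_sign +1, 0 or -1: the sign of the global entropy
#'   change of the proposed move.
#' @return Mobility (nm^2 / (eV * time unit)).
#' @export
mobility <- function(params, entropy_change_sign = 0) {
  if (!entropy_change_sign %in% c(-1, 0, 1))
    stop("entropy_change_sign must be -1, 0 or +1")
  denom <- params$k * params$T - entropy_change_sign * params$dST
  if (denom <= 0)
    stop("parameter error: kT - sign*dST must be positive (dST too large?)")
  params$D / denom
}

#' Drift speed
#'
#' @param mu Mobility (>= 0).
#' @param F Force magnitude.
#' @return \code{mu * F}.
#' @export
drift_speed <- function(mu, F) {
  if (any(mu < 0)) stop("mobility must be >= 0")
  mu * F
}

## Deterministic (Coulomb + displacement) force on every site: n x 3 matrix.
## Self and nearest bonded neighbour pairs excluded. Vectorised over pairs.
.force_field_matrix <- function(chain, params) {
  X <- chain$xyz
  n <- nrow(X)
  q <- chain$q
  nonpolar <- chain$h > 0
  F <- matrix(0, n, 3)
  if (n < 2L) return(F)
  dx <- outer(X[, 1], X[, 1], "-")
  dy <- outer(X[, 2], X[, 2], "-")
  dz <- outer(X[, 3], X[, 3], "-")
  r2 <- dx * dx + dy * dy + dz * dz
  excl <- abs(row(r2) - col(r2)) <= 1L
  if (any(r2[!excl] <= 0))
    stop("degenerate geometry: coincident non-bonded sites")
  r2[excl] <- Inf
  r <- sqrt(r2)
  ## signed Coulomb magnitude on i from j (positive = repulsive, along i - j)
  mag <- params$ke * outer(q, q) / (params$eps_rel * r2)
  ## displacement on nonpolar i from charged j, away from j
  disp <- params$beta * outer(rep(1, n), q^2) / (r2 * r2 * r)
  disp[!nonpolar, ] <- 0
  mag <- mag + disp
  w <- mag / r          # per-pair coefficient of (x_i - x_j)
  w[excl] <- 0
  F[, 1] <- rowSums(w * dx)
  F[, 2] <- rowSums(w * dy)
  F[, 3] <- rowSums(w * dz)
  F
}

#' Net force on one chain site
#'
#' Sums, over every other site excluding the nearest bonded neighbours, the
#' Coulomb force (charged pairs) and the dielectric displacement force (from
#' each charged site onto this site when it is nonpolar, i.e. carries positive
#' net hydropathy), plus optionally one isotropic thermal draw.
#'
#' @param chain A [build_extended_chain()] / [coarse_grain_regions()] chain.
#' @param site Site index.
#' @param params A [forcefield_params()] object.
#' @param thermal Add one thermal force draw (default \code{TRUE}).
#' @return Length-3 force vector (eV/nm).
#' @export
net_force_on_site <- function(chain, site, params = forcefield_params(),
                              thermal = TRUE) {
  stopifnot(inherits(chain, "coarse_chain"))
  n <- nrow(chain$xyz)
  if (n < 2L) stop("chain must have at least 2 sites")
  if (site < 1L || site > n) stop("site index out of range")
  F <- .force_field_matrix(chain, params)[site, ]
  if (thermal) F <- F + thermal_force(params)
  F
}
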