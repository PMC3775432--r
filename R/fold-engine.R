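#' Folding run configuration
#'
#' @param dt Time step (simulation time units). Together with the default
#'   diffusivity it is sized so that a typical early-fold rotation
#'   \eqn{\mu F \Delta t / r_0} is a few hundredths of a radian (about 0.05
#'   rad on the bundled amphipathic fixture).
#' @param max_steps Maximum number of Markov steps.
#' @param freeze_threshold A pivot that produces the maximum torque for this
#'   many consecutive steps is permanently frozen (default 5).
#' @param theta_max Per-step rotation cap (radians).
#' @param seed Random seed driving every thermal draw of the run.
#' @param clash_rejection Reject moves that bring any non-bonded site pair
#'   closer than \code{clash_dist} (off by default; thermal and repulsive
#'   electrostatic forces normally suffice to avoid unphysical collapse).
#' @param clash_dist Hard-core distance (nm) used when
#'   \code{clash_rejection} is on.
#' @param win_reset Reset the win count of non-winning pivots each step
#'   (the "sequential wins" reading, default). \code{FALSE} accumulates wins
#'   across the run.
#' @param frame_every Store expanded per-residue coordinates every this many
#'   steps (0 = never).
#' @return Object of class \code{fold_config}.
#' @export
fold_config <- function(dt = 1, max_steps = 5000, freeze_threshold = 5,
                        theta_max = 0.1, seed = 1, clash_rejection = FALSE,
                        clash_dist = 0.36, win_reset = TRUE,
                        frame_every = 0) {
  stopifnot(dt > 0, max_steps >= 0, freeze_threshold >= 1, theta_max > 0)
  structure(list(dt = dt, max_steps = as.integer(max_steps),
                 freeze_threshold = as.integer(freeze_threshold),
                 theta_max = theta_max, seed = as.integer(seed),
                 clash_rejection = clash_rejection, clash_dist = clash_dist,
                 win_reset = win_reset, frame_every = as.integer(frame_every)),
            class = "fold_config")
}

#' Per-pivot torque census
#'
#' For every unfrozen pivot: the net force on each site of the pivot's mobile
#' block (deterministic Coulomb + displacement field, plus one fresh isotropic
#' thermal draw per site) is resolved into a torque about the pivot-bond axis.
#' The lever arm is the mean distance from the pivot to the mobile-block
#' sites, and the recorded driving force is torque / lever. Frozen pivots are
#' excluded from the census.
#'
#' @param chain A \code{coarse_chain} with at least one unfrozen pivot.
#' @param params A [forcefield_params()] object.
#' @return data.frame with one row per unfrozen pivot: \code{pivot},
#'   \code{torque} (eV, magnitude), \code{force} (eV/nm), \code{lever} (nm)
#'   and \code{sign} (rotation direction of the torque about the axis).
#' @export
torque_census <- function(chain, params = forcefield_params()) {
  stopifnot(inherits(chain, "coarse_chain"))
  live <- which(!chain$pivots$frozen)
  if (length(live) == 0L) stop("terminated fold: all pivots frozen")
  n <- nrow(chain$xyz)
  Fdet <- .force_field_matrix(chain, params)
  rows <- lapply(live, function(k) {
    mob <- .mobile_block(n, k)
    if (length(mob) == 0L)
      return(c(pivot = k, torque = 0, force = 0, lever = 0, sign = 0))
    u <- chain$xyz[k + 1L, ] - chain$xyz[k, ]
    u <- u / sqrt(sum(u^2))
    Fm <- Fdet[mob, , drop = FALSE]
    if (params$T > 0 && params$gamma > 0)
      for (ii in seq_along(mob))
        Fm[ii, ] <- Fm[ii, ] + thermal_force(params)
    rel <- sweep(chain$xyz[mob, , drop = FALSE], 2, chain$xyz[k, ])
    tq <- c(sum(rel[, 2] * Fm[, 3] - rel[, 3] * Fm[, 2]),
            sum(rel[, 3] * Fm[, 1] - rel[, 1] * Fm[, 3]),
            sum(rel[, 1] * Fm[, 2] - rel[, 2] * Fm[, 1]))
    t_axis <- sum(u * tq)
    lever <- mean(sqrt(rowSums(rel^2)))
    c(pivot = k, torque = abs(t_axis),
      force = if (lever > 0) abs(t_axis) / lever else 0,
      lever = lever, sign = sign(t_axis))
  })
  as.data.frame(do.call(rbind, rows))
}

## Re-lay the chain as a gentle random walk: consecutive inter-site distances
## are preserved exactly, the direction takes a small random bend per step.
## Breaks the collinear degeneracy of the extended start (zero axial torque).
.perturb_chain <- function(chain, bend_sd = 0.2) {
  n <- nrow(chain$xyz)
  if (n < 3L) return(chain)
  seg <- diff(chain$xyz)
  lens <- sqrt(rowSums(seg^2))
  dir <- seg[1, ] / lens[1]
  pos <- matrix(0, n, 3, dimnames = dimnames(chain$xyz))
  for (k in seq_len(n - 1L)) {
    if (k > 1L) {
      dir <- dir + bend_sd * stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
    }
    pos[k + 1L, ] <- pos[k, ] + lens[k] * dir
  }
  chain$xyz <- pos
  chain
}

## Smallest distance between non-bonded site pairs.
.min_nonbonded_dist <- function(chain) {
  X <- chain$xyz
  n <- nrow(X)
  if (n < 3L) return(Inf)
  d <- as.matrix(stats::dist(X))
  d[abs(row(d) - col(d)) <= 1L] <- Inf
  min(d)
}

#' Advance the folding simulation by one step
#'
#' Runs a torque census, selects the maximum-torque pivot (ties: lowest
#' index), evaluates the entropy sign of the proposed rotation through its
#' effect on the site radius of gyration (compaction = entropy decrease),
#' converts the driving force to a rotation angle
#' \eqn{\theta = \min(\mu F \Delta t / r_0, \theta_{max})} with the
#' entropy-modified mobility, applies the rotation, updates win counts
#' (winner +1, others reset) and freezes the winner once its win count
#' reaches the freeze threshold. The energy decrement is the work
#' \eqn{\Delta E = F \theta r_0}.
#'
#' @param chain A \code{coarse_chain} with unfrozen pivots.
#' @param config A [fold_config()].
#' @param params A [forcefield_params()].
#' @return List with elements \code{chain} (advanced) and \code{row} (named
#'   numeric: pivot, torque, force, theta, lever, dE, n_frozen).
#' @export
step_once <- function(chain, config = fold_config(),
                      params = forcefield_params()) {
  census <- torque_census(chain, params)
  w <- which.max(census$torque)          # first max = lowest pivot index
  k <- census$pivot[w]
  Fmag <- census$force[w]
  r0 <- census$lever[w]
  s <- census$sign[w]
  theta <- 0
  if (Fmag > 0 && r0 > 0 && s != 0) {
    mu0 <- mobility(params, 0)
    th_trial <- min(mu0 * Fmag * config$dt / r0, config$theta_max)
    esign <- 0
    if (th_trial > 0) {
      trial <- rotate_about_pivot(chain, k, s * th_trial)
      drg <- radius_of_gyration(trial$xyz) - radius_of_gyration(chain$xyz)
      esign <- if (drg < -1e-12) -1 else if (drg > 1e-12) 1 else 0
    }
    mu <- mobility(params, esign)
    theta <- min(mu * Fmag * config$dt / r0, config$theta_max)
    if (theta > 0) {
      cand <- rotate_about_pivot(chain, k, s * theta)
      if (config$clash_rejection &&
          .min_nonbonded_dist(cand) < config$clash_dist) {
        theta <- 0
      } else {
        chain <- cand
      }
    }
  }
  if (config$win_reset) {
    chain$pivots$win_count[chain$pivots$from != k & !chain$pivots$frozen] <- 0L
  }
  chain$pivots$win_count[k] <- chain$pivots$win_count[k] + 1L
  if (chain$pivots$win_count[k] >= config$freeze_threshold)
    chain$pivots$frozen[k] <- TRUE
  list(chain = chain,
       row = c(pivot = k, torque = census$torque[w], force = Fmag,
               theta = s * theta, lever = r0, dE = Fmag * theta * r0,
               n_frozen = sum(chain$pivots$frozen)))
}

#' Run the Markov pivot-torque folding simulation
#'
#' Full pipeline: annotate the sequence, predict (or accept) the secondary
#' structure, build the extended chain, insert rigid templates, coarse-grain
#' the rigid regions, then iterate [step_once()] until \code{max_steps} is
#' reached or every pivot is frozen. The per-step energy trace records the
#' work \eqn{F \theta r_0} subtracted from an arbitrary initial energy of 0;
#' the run does not claim full cessation of motion (at finite temperature the
#' thermal force never vanishes).
#'
#' The straight extended chain is a degenerate starting point for pivot
#' kinematics: every site lies on every pivot-bond axis, so all torques vanish
#' identically and no move can occur. Runs therefore start from a physically
#' permissible random perturbation of the extended conformation
#' (\code{init = "perturbed"}, the default): consecutive inter-site distances
#' are kept exactly while the local chain direction takes a small seeded
#' random bend at each site.
#'
#' @param seq A sequence string, character vector or [annotate_sequence()]
#'   result.
#' @param ss Optional \code{ss_annotation}; predicted from \code{seq} when
#'   \code{NULL}.
#' @param config A [fold_config()]; \code{config$seed} seeds every random
#'   draw of the run.
#' @param params A [forcefield_params()].
#' @param init \code{"perturbed"} (default) or \code{"extended"} (strictly
#'   collinear; only useful for bookkeeping tests).
#' @return Object of class \code{fold_result}: final \code{chain}, expanded
#'   per-residue \code{coords} (nm), the \code{trace} data.frame (columns
#'   step, pivot, torque_eV, F_eV_per_nm, theta_rad, r0_nm, dE_eV, E_eV,
#'   n_frozen), the \code{ss} annotation used, initial extended-chain
#'   \code{extended_rg} and final \code{rg} (nm), optional \code{frames},
#'   and the \code{config}/\code{params} used.
#' @export
run_fold <- function(seq, ss = NULL, config = fold_config(),
                     params = forcefield_params(),
                     init = c("perturbed", "extended")) {
  init <- match.arg(init)
  set.seed(config$seed)
  if (!inherits(seq, "annotated_seq"))
    seq <- annotate_sequence(seq, pH = params$pH)
  if (is.null(ss)) ss <- predict_secondary(seq)
  chain <- build_extended_chain(seq)
  extended_rg <- radius_of_gyration(chain$xyz)
  chain <- coarse_grain_regions(insert_templates(chain, ss))
  if (init == "perturbed") chain <- .perturb_chain(chain)

  cols <- c("step", "pivot", "torque_eV", "F_eV_per_nm", "theta_rad",
            "r0_nm", "dE_eV", "E_eV", "n_frozen")
  trace <- matrix(NA_real_, config$max_steps, length(cols),
                  dimnames = list(NULL, cols))
  frames <- list()
  E <- 0
  t_done <- 0L
  if (nrow(chain$pivots) > 0L) {
    for (t in seq_len(config$max_steps)) {
      if (all(chain$pivots$frozen)) break
      st <- step_once(chain, config, params)
      chain <- st$chain
      E <- E - st$row[["dE"]]
      trace[t, ] <- c(t, st$row[["pivot"]], st$row[["torque"]],
                      st$row[["force"]], st$row[["theta"]],
                      st$row[["lever"]], st$row[["dE"]], E,
                      st$row[["n_frozen"]])
      t_done <- t
      if (config$frame_every > 0L && t %% config$frame_every == 0L)
        frames[[length(frames) + 1L]] <- expand_to_residues(chain)
    }
  }
  coords <- expand_to_residues(chain)
  structure(list(chain = chain, coords = coords,
                 trace = as.data.frame(trace[seq_len(t_done), , drop = FALSE]),
                 ss = ss, extended_rg = extended_rg,
                 rg = radius_of_gyration(coords),
                 frames = frames, config = config, params = params),
            class = "fold_result")
}

#' Rolling fluctuation profile of an energy trace
#'
#' Rolling (sliding-window) standard deviation of the per-step energy
#' decrements; the simulated analogue of watching the energy swings of a
#' folding trajectory die down.
#'
#' @param trace A \code{fold_result}, its \code{trace} data.frame, or a plain
#'   numeric vector of per-step energy decrements.
#' @param window Window width (steps); the trace must be at least twice as
#'   long.
#' @return Numeric vector of window standard deviations, one per window start.
#' @export
fluctuation_profile <- function(trace, window) {
  dE <- if (inherits(trace, "fold_result")) trace$trace$dE_eV
        else if (is.data.frame(trace)) trace$dE_eV
        else as.numeric(trace)
  n <- length(dE)
  if (window < 2L || n < 2L * window)
    stop("trace must contain at least 2*window steps")
  vapply(seq_len(n - window + 1L),
         function(i) stats::sd(dE[i:(i + window - 1L)]), numeric(1))
}

#' @export
print.fold_result <- function(x, ...) {
  cat("fold_result:", x$chain$n_res, "residues,", nrow(x$trace), "steps\n")
  cat("  Rg:", round(x$extended_rg, 3), "->", round(x$rg, 3), "nm;",
      "final E:", signif(utils::tail(x$trace$E_eV, 1), 4), "eV;",
      utils::tail(x$trace$n_frozen, 1), "pivot(s) frozen\n")
  invisible(x)
}
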