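# Quasi-static XPBD solver layer: material parameters, constraint assembly,
# single-constraint projection wrappers (unit-test surface over the compiled
# kernels), and the outer simulation driver.

#' Brain-tissue material parameters
#'
#' Defaults follow experimentally reported ranges for brain tissue: Young's
#' moduli of 1.895 kPa (white) and 1.389 kPa (gray), Poisson ratio 0.48,
#' density 1040 kg/m^3. `visco_beta` is the viscoelastic rest-pose relaxation
#' rate (1/s): each step the tetrahedral rest matrix is blended toward the
#' current pose with weight `1 - exp(-beta * dt)`, relaxing deviatoric stress
#' while preserving volume memory.
#'
#' @param E_white,E_gray tissue stiffness (Pa).
#' @param nu Poisson ratio, in (0, 0.5).
#' @param density tissue density (kg/m^3).
#' @param visco_beta rest-pose relaxation rate (1/s), >= 0.
#' @return object of class `material_params` including the derived Lame
#'   parameters for both tissues.
#' @export
material_params <- function(E_white = 1895, E_gray = 1389, nu = 0.48,
                            density = 1040, visco_beta = 0.001) {
  stopifnot(E_white > 0, E_gray > 0, nu > 0, nu < 0.5, density > 0,
            visco_beta >= 0)
  lame <- function(E) c(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
                        mu = E / (2 * (1 + nu)))
  structure(list(E_white = E_white, E_gray = E_gray, nu = nu,
                 density = density, visco_beta = visco_beta,
                 lame_white = lame(E_white), lame_gray = lame(E_gray)),
            class = "material_params")
}

#' Simulation configuration
#'
#' Schedule, solver, and compliance settings for [run_simulation()]. The
#' surface rest areas decay geometrically, `R <- R * (1 - rate_area * dt)`
#' per step (and rest distances with `rate_smooth`) when unfolding;
#' refolding replays the recorded per-step targets in reverse. `dt` is a
#' schedule clock only: viscous damping is infinite, so each step is an
#' equilibrium solve (`substeps` XPBD substeps of `iterations` Gauss-Seidel
#' sweeps each).
#'
#' @param n_steps number of outer steps.
#' @param dt step duration (s).
#' @param substeps XPBD substeps per step.
#' @param iterations Gauss-Seidel sweeps per substep (Lagrange multipliers
#'   persist across sweeps within a substep).
#' @param rate_area,rate_smooth schedule rates (fraction per unit time).
#' @param scale_hydro,scale_dev multipliers on the physical compliances
#'   `1/(lambda V0)` and `1/(mu V0)` of the tetrahedral constraints.
#' @param alpha_area,alpha_smooth compliances of the surface-area and
#'   smoothing constraints.
#' @param direction `"unfold"` or `"refold"`.
#' @param snapshot_every record a trajectory snapshot every this many steps.
#' @param gi_target optional gyrification-index stop criterion (unfolding
#'   stops once GI <= target, checked at snapshots).
#' @param inverted_limit abort when more than this fraction of tets inverts.
#' @param seed integer seed stored with the run (the solver itself is
#'   deterministic; the seed governs downstream stochastic stages).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_steps = 400L, dt = 1, substeps = 30L,
                       iterations = 1L, rate_area = 0.004,
                       rate_smooth = 0.004, scale_hydro = 100,
                       scale_dev = 100, alpha_area = 0.005,
                       alpha_smooth = 0.005,
                       direction = c("unfold", "refold"),
                       snapshot_every = 10L, gi_target = NULL,
                       inverted_limit = 0.02, settle_steps = 0L,
                       rest_stable = TRUE, seed = 1L) {
  direction <- match.arg(direction)
  stopifnot(dt > 0, substeps >= 1, iterations >= 1, n_steps >= 0)
  structure(list(n_steps = as.integer(n_steps), dt = dt,
                 substeps = as.integer(substeps),
                 iterations = as.integer(iterations),
                 rate_area = rate_area, rate_smooth = rate_smooth,
                 scale_hydro = scale_hydro, scale_dev = scale_dev,
                 alpha_area = alpha_area, alpha_smooth = alpha_smooth,
                 direction = direction,
                 snapshot_every = as.integer(snapshot_every),
                 gi_target = gi_target, inverted_limit = inverted_limit,
                 settle_steps = as.integer(settle_steps),
                 rest_stable = isTRUE(rest_stable),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Deformation gradient of a tetrahedron
#'
#' `F = Ds %*% solve(Dm)` where `Ds` is the current edge matrix and `Dm` the
#' rest edge matrix; `F` is the identity when the current pose equals rest.
#'
#' @param tet_positions 4 x 3 matrix of current vertex positions.
#' @param Dm 3 x 3 rest edge matrix (columns `x_i - x_0` at rest).
#' @return 3 x 3 deformation gradient.
#' @export
deformation_gradient <- function(tet_positions, Dm) {
  if (abs(det(Dm)) < .Machine$double.eps) stop("singular rest matrix")
  Ds <- t(tet_positions[2:4, , drop = FALSE] -
            matrix(tet_positions[1, ], 3, 3, byrow = TRUE))
  Ds %*% solve(Dm)
}

#' Neo-Hookean energy split
#'
#' `Psi_H = (lambda/2) (det F - 1)^2` (hydrostatic) and
#' `Psi_D = (mu/2) (tr(F^T F) - 3)` (deviatoric, signed as written: it is
#' negative when the pose is contracted below `tr = 3`).
#'
#' @param F 3 x 3 deformation gradient.
#' @param lambda,mu Lame parameters (Pa).
#' @return named numeric vector `c(psi_h, psi_d)`.
#' @export
neo_hookean_energy <- function(F, lambda, mu) {
  c(psi_h = lambda / 2 * (det(F) - 1)^2,
    psi_d = mu / 2 * (sum(F * F) - 3))
}

#' Minimal solver state for single-constraint projections
#'
#' @param positions N x 3 matrix (mm).
#' @param inv_mass inverse node masses (1/kg); 0 pins a node.
#' @param freemask optional N x 3 matrix of 1 (free) / 0 (held axis).
#' @return object of class `sim_state`.
#' @export
sim_state <- function(positions, inv_mass, freemask = NULL) {
  positions <- as.matrix(positions)
  if (is.null(freemask)) freemask <- matrix(1, nrow(positions), 3)
  structure(list(positions = positions, inv_mass = as.numeric(inv_mass),
                 freemask = freemask), class = "sim_state")
}

# node-major flattening used by the compiled kernels
flatten_nodes <- function(m) as.numeric(t(m))
unflatten_nodes <- function(v) matrix(v, ncol = 3, byrow = TRUE)

#' Stable neo-Hookean tetrahedral constraint
#'
#' Captures a tet's rest edge matrix `Dm`, rest volume, and the XPBD
#' compliances `alpha_H = 1/(lambda V0)` (hydrostatic, `C_H = det(F) - 1`)
#' and `alpha_D = 1/(mu V0)` (deviatoric, `C_D = sqrt(tr(F^T F))`). The
#' hydrostatic constraint keeps its original rest volume even when the rest
#' matrix is later relaxed viscoelastically.
#'
#' @param verts 4 node indices (1-based).
#' @param rest_positions 4 x 3 rest vertex positions.
#' @param lambda,mu Lame parameters (Pa).
#' @return object of class `tet_constraint`.
#' @export
tet_constraint <- function(verts, rest_positions, lambda, mu, gamma = 1) {
  Dm <- t(rest_positions[2:4, , drop = FALSE] -
            matrix(rest_positions[1, ], 3, 3, byrow = TRUE))
  V0 <- det(Dm) / 6
  if (V0 <= 0) stop("rest tetrahedron must be positively oriented")
  structure(list(verts = as.integer(verts), Dm = Dm, rest_volume = V0,
                 lambda = lambda, mu = mu, gamma = gamma,
                 alpha_H = 1 / (lambda * V0), alpha_D = 1 / (mu * V0)),
            class = "tet_constraint")
}

#' Project one tetrahedral constraint pair (XPBD)
#'
#' Applies one XPBD projection of the hydrostatic constraint
#' `C_H = det(F) - 1` followed by one of the deviatoric constraint
#' `C_D = sqrt(tr(F^T F))`, with Lagrange-multiplier update
#' `dlambda = (-C - alpha_t * lambda) / (sum_i w_i |grad_i C|^2 + alpha_t)`,
#' `alpha_t = alpha / dt_sub^2`. Displacements are mass-weighted; nodes with
#' zero inverse mass (or masked axes) do not move.
#'
#' @param state a [sim_state()].
#' @param constraint a [tet_constraint()].
#' @param dt_sub substep duration (s).
#' @param lambda_h,lambda_d accumulated Lagrange multipliers.
#' @return the state with updated positions; attributes `lambda_h`,
#'   `lambda_d`, `C_H` (value before projection) and `C_D`.
#' @export
project_tet_constraint <- function(state, constraint, dt_sub = 1,
                                   lambda_h = 0, lambda_d = 0, cap = Inf) {
  r <- cpp_project_tet(flatten_nodes(state$positions), state$inv_mass,
                       flatten_nodes(state$freemask),
                       constraint$verts - 1L, constraint$rest_volume,
                       constraint$gamma %||% 1,
                       as.numeric(constraint$Dm), constraint$alpha_H,
                       constraint$alpha_D, dt_sub, lambda_h, lambda_d, cap)
  state$positions <- unflatten_nodes(r$x)
  attr(state, "lambda_h") <- r$lamH
  attr(state, "lambda_d") <- r$lamD
  attr(state, "C_H") <- r$absC_H
  attr(state, "C_D") <- r$C_D
  state
}

#' Project one surface-area constraint (XPBD)
#'
#' Constraint `C = 0.5 * ||(x2 - x1) x (x3 - x1)|| - R`: no motion when the
#' face area equals the rest area `R`; otherwise the projection reduces
#' `|C|`, shrinking or growing the face toward its (scheduled) rest area.
#'
#' @param state a [sim_state()].
#' @param verts 3 node indices.
#' @param rest_area rest area R (mm^2).
#' @param alpha compliance.
#' @param dt_sub substep duration (s).
#' @param lambda accumulated multiplier.
#' @return updated state with attributes `lambda` and `absC`.
#' @export
project_area_constraint <- function(state, verts, rest_area, alpha = 0,
                                    dt_sub = 1, lambda = 0, cap = Inf) {
  r <- cpp_project_area(flatten_nodes(state$positions), state$inv_mass,
                        flatten_nodes(state$freemask), as.integer(verts) - 1L,
                        rest_area, alpha, dt_sub, lambda, cap)
  state$positions <- unflatten_nodes(r$x)
  attr(state, "lambda") <- r$lambda
  attr(state, "absC") <- r$absC
  state
}

#' Project one smoothing constraint (XPBD)
#'
#' For two surface triangles sharing edge `(s0, s1)` with opposite vertices
#' `a, b`, the constraint `C = 0.5 * ||(a + b) - (s0 + s1)|| - L` moves the
#' shared-edge midpoint toward the midpoint of `a, b` as `L` decreases,
#' flattening the dihedral.
#'
#' @param state a [sim_state()].
#' @param verts 4 node indices, ordered `(a, s0, s1, b)`.
#' @param rest_distance rest value L (mm).
#' @param alpha compliance.
#' @param dt_sub substep duration (s).
#' @param lambda accumulated multiplier.
#' @return updated state with attributes `lambda` and `absC`.
#' @export
project_smoothing_constraint <- function(state, verts, rest_distance,
                                         alpha = 0, dt_sub = 1, lambda = 0,
                                         cap = Inf) {
  r <- cpp_project_smooth(flatten_nodes(state$positions), state$inv_mass,
                          flatten_nodes(state$freemask),
                          as.integer(verts) - 1L, rest_distance, alpha,
                          dt_sub, lambda, cap)
  state$positions <- unflatten_nodes(r$x)
  attr(state, "lambda") <- r$lambda
  attr(state, "absC") <- r$absC
  state
}

#' Viscoelastic rest-pose relaxation
#'
#' Blends a rest edge matrix toward the current pose,
#' `Dm <- (1 - kappa) Dm + kappa Ds` with `kappa = 1 - exp(-beta * dt)`:
#' `beta = 0` leaves the rest pose unchanged; `kappa = 1` makes the current
#' pose the deviatoric rest (F = I next step). Exponential blending composes
#' consistently: two half-steps equal one full step. Rest volumes are not
#' touched, so hydrostatic volume memory is preserved.
#'
#' @param Dm 3 x 3 rest edge matrix.
#' @param Ds 3 x 3 current edge matrix.
#' @param beta relaxation rate (1/s).
#' @param dt elapsed time (s).
#' @return updated 3 x 3 rest matrix.
#' @export
update_viscoelastic_rest <- function(Dm, Ds, beta, dt) {
  stopifnot(beta >= 0, dt >= 0)
  kappa <- 1 - exp(-beta * dt)
  (1 - kappa) * Dm + kappa * Ds
}

# ---------------------------------------------------------------------------
# constraint assembly

# Smoothing quads (a, s0, s1, b) over pairs of cortical faces sharing an edge.
smoothing_quads <- function(faces) {
  ek <- rbind(cbind(faces[, 1], faces[, 2], faces[, 3]),
              cbind(faces[, 2], faces[, 3], faces[, 1]),
              cbind(faces[, 3], faces[, 1], faces[, 2]))
  key <- paste(pmin(ek[, 1], ek[, 2]), pmax(ek[, 1], ek[, 2]))
  sp <- split(seq_len(nrow(ek)), key)
  quads <- lapply(sp, function(idx) {
    if (length(idx) != 2L) return(NULL)
    c(ek[idx[1], 3], ek[idx[1], 1], ek[idx[1], 2], ek[idx[2], 3])
  })
  quads <- do.call(rbind, quads[!vapply(quads, is.null, logical(1))])
  if (is.null(quads)) quads <- matrix(integer(0), 0, 4)
  rownames(quads) <- NULL
  storage.mode(quads) <- "integer"
  quads
}

# Assemble all solver arrays for a mesh + material + config.
build_sim <- function(mesh, mat, config) {
  if (is.null(mesh$node_mass)) mesh <- compute_node_masses(mesh, mat$density)
  x <- mesh$nodes
  tets <- mesh$tets
  V0 <- tet_volumes(mesh)
  if (any(V0 <= 0)) stop("input mesh has inverted tetrahedra")

  Enode <- ifelse(mesh$tissue == "white", mat$E_white, mat$E_gray)
  Etet <- rowMeans(matrix(Enode[tets], nrow(tets), 4))
  lam <- Etet * mat$nu / ((1 + mat$nu) * (1 - 2 * mat$nu))
  mu <- Etet / (2 * (1 + mat$nu))

  Dm <- matrix(0, nrow(tets), 9)
  for (c in 1:3) {
    e <- x[tets[, c + 1], , drop = FALSE] - x[tets[, 1], , drop = FALSE]
    Dm[, (c - 1) * 3 + 1:3] <- e
  }

  cf <- mesh$metadata$cortical_faces
  if (is.null(cf)) cf <- seq_len(nrow(mesh$faces))
  faces <- mesh$faces[cf, , drop = FALSE]
  restA <- face_areas(x, faces)
  quads <- smoothing_quads(faces)
  restL <- if (nrow(quads) > 0) {
    d <- (x[quads[, 1], , drop = FALSE] + x[quads[, 4], , drop = FALSE]) -
         (x[quads[, 2], , drop = FALSE] + x[quads[, 3], , drop = FALSE])
    0.5 * sqrt(rowSums(d^2))
  } else numeric(0)

  freemask <- mesh$metadata$freemask
  if (is.null(freemask)) freemask <- matrix(1, nrow(x), 3)

  # With infinite damping the solve is purely quasi-static, so masses act
  # only as the projection metric; rescaling them to mean 1 leaves every
  # equilibrium (and all mass *ratios*) unchanged while keeping the
  # compliance terms alpha/dt^2 on a numerically sensible scale.
  mass_scale <- mean(mesh$node_mass)
  # inverse masses clamped at 4x the mean: boundary lattice nodes carry ~10x
  # the mean inverse mass, which destabilizes Gauss-Seidel sweeps; under
  # infinite damping the masses are a projection metric, so the clamp alters
  # the path, never the equilibria
  list(mesh = mesh,
       x = flatten_nodes(x),
       invmass = pmin(mass_scale / mesh$node_mass, 4),
       freemask = flatten_nodes(freemask),
       tets0 = tets - 1L,
       Dm = as.numeric(t(Dm)),      # per-tet 9 values, tet-major
       restvol = V0,
       # rest-stabilized hydrostatic target det F = 1 + mu_eff/lambda_eff
       # (stable constraint split, in terms of the effective solver moduli
       # mu/scale_dev and lambda/scale_hydro); gamma = 1 recovers the plain
       # printed energy
       gammaH = if (config$rest_stable %||% TRUE)
                  1 + (mu * config$scale_hydro) / (lam * config$scale_dev)
                else rep(1, length(V0)),
       alphaH = config$scale_hydro / (lam * V0),
       alphaD = config$scale_dev / (mu * V0),
       faces0 = faces - 1L,
       restA = restA,
       alphaA = rep(config$alpha_area, nrow(faces)),
       quads0 = quads - 1L,
       restL = restL,
       alphaS = rep(config$alpha_smooth, nrow(quads)),
       # per-projection displacement cap: a fraction of the mean element
       # size, guarding light boundary nodes against overshoot
       cap = 0.2 * (6 * mean(V0))^(1 / 3))
}

#' One quasi-static step
#'
#' Advances the schedules by one step (rest areas and rest distances scaled
#' by the supplied factors) and runs the configured substeps of Gauss-Seidel
#' sweeps over all constraints with zeroed velocities, returning the
#' equilibriated state and residual diagnostics (max |C| per family).
#' Primarily a building block of [run_simulation()], exposed for inspection.
#'
#' @param sim solver arrays from a previous call or as produced internally
#'   (list with `x`, `Dm`, `restA`, `restL`, and the static arrays).
#' @param config a [sim_config()].
#' @param fac_area,fac_smooth schedule factors for this step.
#' @return the updated `sim` with a `residuals` entry.
#' @export
quasi_static_step <- function(sim, config, fac_area = 1, fac_smooth = 1) {
  r <- cpp_xpbd_advance(sim$x, sim$invmass, sim$freemask, sim$tets0, sim$Dm,
                        sim$restvol, sim$gammaH, sim$alphaH, sim$alphaD,
                        sim$faces0,
                        sim$restA, sim$alphaA, sim$quads0, sim$restL,
                        sim$alphaS, fac_area, fac_smooth, config$substeps,
                        config$iterations, config$dt, sim$beta %||% 0,
                        sim$cap %||% Inf)
  if (r$nan_abort) stop("simulation aborted: non-finite node positions")
  sim$x <- r$x
  sim$Dm <- r$Dm
  sim$restA <- r$restA
  sim$restL <- r$restL
  sim$residuals <- cbind(hydro = r$res_hydro, dev = r$res_dev,
                         area = r$res_area, smooth = r$res_smooth,
                         inverted = r$inverted)
  sim
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a quasi-static folding simulation
#'
#' Executes `n_steps` quasi-static steps on a validated mesh, recording
#' node-position snapshots every `snapshot_every` steps (always including the
#' first and last states). Unfolding decays the surface rest areas and
#' smoothing rest distances geometrically; refolding replays the recorded
#' schedule of an unfold run in reverse, resuming from its final solver state
#' (positions, relaxed rest matrices, schedule targets).
#'
#' @param mesh a [tet_mesh()]; boundary conditions and the cortical face
#'   subset are taken from its metadata.
#' @param mat a [material_params()].
#' @param config a [sim_config()].
#' @param resume for `direction = "refold"`: the `fold_trajectory` returned
#'   by the unfold run to reverse.
#' @param init_positions optional N x 3 matrix of starting positions when the
#'   simulation should not start at the rest configuration (rest matrices,
#'   rest volumes, and rest areas are always taken from `mesh$nodes`).
#' @return object of class `fold_trajectory`: snapshot list, raw step times,
#'   per-snapshot gyrification index, residual history, the schedule factors,
#'   and the final solver state.
#' @export
run_simulation <- function(mesh, mat, config, resume = NULL,
                           init_positions = NULL) {
  rep <- validate_mesh(mesh)
  if (!rep$ok) stop("invalid mesh: ", format(rep))
  sim <- build_sim(mesh, mat, config)
  sim$beta <- mat$visco_beta
  mesh <- sim$mesh   # with masses
  if (!is.null(init_positions)) {
    stopifnot(nrow(init_positions) == nrow(mesh$nodes))
    sim$x <- flatten_nodes(as.matrix(init_positions))
  }

  if (config$direction == "refold") {
    if (is.null(resume) || !inherits(resume, "fold_trajectory"))
      stop("refolding requires the unfold trajectory to resume from")
    fs <- attr(resume, "final_state")
    sim$x <- fs$x
    sim$Dm <- fs$Dm
    sim$restA <- fs$restA
    sim$restL <- fs$restL
    sched <- attr(resume, "schedule")
    facA <- rev(1 / sched$fac_area)
    facL <- rev(1 / sched$fac_smooth)
    settle <- config$settle_steps %||% 0L
    if (settle > 0L) {
      facA <- c(facA, rep(1, settle))
      facL <- c(facL, rep(1, settle))
    }
    n_steps <- length(facA)
  } else {
    n_steps <- config$n_steps
    facA <- rep(1 - config$rate_area * config$dt, n_steps)
    facL <- rep(1 - config$rate_smooth * config$dt, n_steps)
  }

  snaps <- list(unflatten_nodes(sim$x))
  times <- 0
  gi <- gyrification_index(mesh, snaps[[1]])
  res <- NULL
  stop_gi <- !is.null(config$gi_target) && config$direction == "unfold"
  step <- 0L
  stopped_early <- FALSE

  if (stop_gi && gi <= config$gi_target) {
    n_steps <- 0L
    stopped_early <- TRUE
  }

  while (step < n_steps) {
    k <- min(config$snapshot_every, n_steps - step)
    chunk <- (step + 1L):(step + k)
    r <- cpp_xpbd_advance(sim$x, sim$invmass, sim$freemask, sim$tets0,
                          sim$Dm, sim$restvol, sim$gammaH, sim$alphaH,
                          sim$alphaD,
                          sim$faces0, sim$restA, sim$alphaA, sim$quads0,
                          sim$restL, sim$alphaS, facA[chunk], facL[chunk],
                          config$substeps, config$iterations, config$dt,
                          sim$beta, sim$cap)
    if (r$nan_abort)
      stop("simulation aborted: non-finite node positions at step ", step + k)
    sim$x <- r$x; sim$Dm <- r$Dm; sim$restA <- r$restA; sim$restL <- r$restL
    res <- rbind(res, cbind(hydro = r$res_hydro, dev = r$res_dev,
                            area = r$res_area, smooth = r$res_smooth,
                            inverted = r$inverted))
    inv_frac <- max(r$inverted) / nrow(mesh$tets)
    if (inv_frac > config$inverted_limit)
      stop(sprintf("simulation aborted: %.1f%% of tetrahedra inverted",
                   100 * inv_frac))
    step <- step + k
    snaps[[length(snaps) + 1L]] <- unflatten_nodes(sim$x)
    times <- c(times, step)
    gi <- c(gi, gyrification_index(mesh, snaps[[length(snaps)]]))
    if (stop_gi && gi[length(gi)] <= config$gi_target) {
      facA <- facA[seq_len(step)]
      facL <- facL[seq_len(step)]
      stopped_early <- TRUE
      break
    }
  }

  structure(list(mesh = mesh, snapshots = snaps, times = times,
                 gi = as.numeric(gi), direction = config$direction,
                 residuals = res),
            schedule = list(fac_area = facA[seq_len(step)],
                            fac_smooth = facL[seq_len(step)]),
            final_state = list(x = sim$x, Dm = sim$Dm, restA = sim$restA,
                               restL = sim$restL),
            config = config, material = mat, stopped_early = stopped_early,
            class = "fold_trajectory")
}

#' @export
print.fold_trajectory <- function(x, ...) {
  cat(sprintf("<fold_trajectory> %s, %d snapshots (steps 0..%d), GI %.3f -> %.3f\n",
              x$direction, length(x$snapshots), max(x$times),
              x$gi[1], x$gi[length(x$gi)]))
  invisible(x)
}
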