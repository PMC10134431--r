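#' Run configuration for polariton surface-hopping dynamics
#'
#' Collects every knob of a trajectory ensemble. Defaults follow the standard
#' protocol: 0.2 fs nuclear steps, 100 quantum substeps per nuclear step,
#' decoherence parameter 0.1 Hartree, the third polariton as the initial
#' active state, Wigner-sampled initial conditions at the cis minimum.
#'
#' @param cavity A [cavity_parameters()].
#' @param model A [model_molecule()] backend.
#' @param dt_fs Nuclear time step in femtoseconds (default 0.2).
#' @param n_steps Number of nuclear steps, >= 1.
#' @param n_sub Quantum substeps per nuclear step (default 100).
#' @param n_trajectories Ensemble size (default 1).
#' @param init_state Initial active polariton: a 1-based index (default 3) or
#'   \code{"e0"} for the state of dominant \code{|e,0>} character (the natural
#'   choice in the decoupled \code{g_c = 0} limit).
#' @param alpha Decoherence parameter (Hartree, default 0.1).
#' @param seed_ic Seed for initial-condition sampling.
#' @param seed_hop Base seed for the per-trajectory hopping streams
#'   (trajectory \code{l} uses \code{seed_hop + l}).
#' @param include_dse Keep the dipole self-energy in the Hamiltonian.
#' @param engine \code{"compiled"} (Rcpp, default) or \code{"reference"}
#'   (pure R; identical algorithm and random stream, used for cross-checks
#'   and for KRR-supplied dipoles).
#' @param dipole_model Optional [krr_dipole_model()] replacing the backend's
#'   analytic dipoles and gradients (reference engine only).
#' @param store_geometry Record full coordinates each step (default FALSE;
#'   the CNNC dihedral is always recorded).
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(cavity, model = model_molecule(), dt_fs = 0.2,
                       n_steps = 100L, n_sub = 100L, n_trajectories = 1L,
                       init_state = 3L, alpha = 0.1, seed_ic = 1L,
                       seed_hop = 1000L, include_dse = TRUE,
                       engine = c("compiled", "reference"),
                       dipole_model = NULL, store_geometry = FALSE) {
  engine <- match.arg(engine)
  stopifnot(dt_fs > 0, n_steps >= 1, n_sub >= 1, n_trajectories >= 1)
  if (!is.null(dipole_model) && engine != "reference") {
    stop("KRR dipoles require engine = 'reference'")
  }
  structure(
    list(cavity = cavity, model = model, dt = dt_fs * polhop_units$au_per_fs,
         n_steps = as.integer(n_steps), n_sub = as.integer(n_sub),
         n_trajectories = as.integer(n_trajectories), init_state = init_state,
         alpha = alpha, seed_ic = as.integer(seed_ic),
         seed_hop = as.integer(seed_hop), include_dse = include_dse,
         engine = engine, dipole_model = dipole_model,
         store_geometry = store_geometry),
    class = "run_config"
  )
}

#' One velocity-Verlet step
#'
#' Standard kick-drift-kick update with the force evaluated by a caller-
#' supplied provider at the new positions.
#'
#' @param R Positions (\code{N_a x 3}, Bohr).
#' @param P Momenta (length \code{3N_a}, atom-major).
#' @param masses Per-atom masses (electron masses).
#' @param force Force at \code{R} (length \code{3N_a}, Hartree/Bohr).
#' @param force_provider Function \code{R -> force} evaluated at the drifted
#'   positions.
#' @param dt Time step (atomic units).
#' @return List with \code{R}, \code{P}, \code{force} (at the new positions).
#' @export
velocity_verlet_step <- function(R, P, masses, force, force_provider, dt) {
  m3 <- expand_masses(masses, length(P))
  P_half <- P + 0.5 * dt * force
  R_new <- R + matrix(dt * P_half / m3, ncol = 3, byrow = TRUE)
  F_new <- force_provider(R_new)
  if (!all(is.finite(F_new))) stop("non-finite force encountered")
  list(R = R_new, P = P_half + 0.5 * dt * F_new, force = F_new)
}

# evaluate the backend (optionally with KRR dipoles) at coords
eval_frame <- function(config, coords) {
  fr <- model_electronic_frame(config$model, coords = coords)
  if (!is.null(config$dipole_model)) {
    kd <- krr_frame_dipoles(config$dipole_model, coords)
    fr$dipoles <- kd$dipoles
    fr$dipole_grads <- kd$dipole_grads
  }
  fr
}

resolve_init_state <- function(init_state, sol, basis) {
  if (identical(init_state, "e0")) {
    target <- af_index(basis, 2L, 0L)
    return(which.max(sol$U[target, ]^2))
  }
  as.integer(init_state)
}

#' Run a single surface-hopping trajectory
#'
#' Full per-step loop: evaluate the backend at the drifted geometry, rebuild
#' the polariton Hamiltonian and eigenbasis with phase continuity, propagate
#' the reduced density (Hamiltonian/NAC phase, then Lindblad phase), perform
#' the two global-flux hop checks (velocity-rescaled after the Hamiltonian
#' phase, momentum-preserving after the loss phase), apply the decoherence
#' correction and advance the nuclei by velocity Verlet. The initial quantum
#' state is the pure chosen polariton state transformed to the adiabatic-Fock
#' basis.
#'
#' @param config A [run_config()].
#' @param seed Integer seed for this trajectory's hopping stream.
#' @param init Optional list with \code{coords} (Bohr) and \code{momenta};
#'   defaults to the model template at rest.
#' @return A trajectory record: list with \code{time} (au), \code{active},
#'   \code{energies}, \code{pop_af} (mixed estimator), \code{pop_pl}
#'   (density diagonal), \code{photon}, \code{dihedral}, \code{ekin},
#'   \code{etot}, \code{hops} (data frame), \code{n_frustrated},
#'   \code{dissipated}, final phase-space point, and optionally
#'   \code{geometry}.
#' @export
run_trajectory <- function(config, seed, init = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(init)) {
    init <- list(coords = config$model$template,
                 momenta = rep(0, 3 * nrow(config$model$template)))
  }
  if (config$engine == "compiled") {
    return(run_trajectory_compiled(config, seed, init))
  }
  run_trajectory_reference(config, seed, init)
}

run_trajectory_reference <- function(config, seed, init) {
  set.seed(seed)
  model <- config$model; cavity <- config$cavity
  basis <- af_basis(2L, cavity$n_fock)
  K <- basis$size
  m3 <- rep(model$masses, each = 3)
  dt <- config$dt; n_steps <- config$n_steps; n_sub <- config$n_sub
  L <- jump_matrix(basis)
  Rc <- init$coords
  P <- as.numeric(init$momenta)

  fr <- eval_frame(config, Rc)
  V <- build_potential_matrix(fr, cavity, basis, config$include_dse)
  sol <- diagonalize_potential(V)
  active <- resolve_init_state(config$init_state, sol, basis)
  rho_af <- outer(sol$U[, active], sol$U[, active]) + 0i
  d_af <- nac_adiabatic_fock(fr, basis)
  dV <- grad_potential_matrix(fr, cavity, basis, config$include_dse)
  gradV <- full_gradient_matrix(dV, d_af, V)
  Fc <- active_force(sol, gradV, active)
  D_now <- contract_nac(d_af, P / m3)

  nt <- n_steps + 1L
  rec <- list(
    time = (0:n_steps) * dt, active = integer(nt),
    energies = matrix(0, nt, K), pop_af = matrix(0, nt, K),
    pop_pl = matrix(0, nt, K), photon = numeric(nt), dihedral = numeric(nt),
    ekin = numeric(nt), etot = numeric(nt),
    hops = data.frame(step = integer(0), type = character(0),
                      from = integer(0), to = integer(0), dE = numeric(0)),
    n_frustrated = 0L, dissipated = 0
  )
  if (config$store_geometry) rec$geometry <- array(0, c(nt, nrow(Rc), 3))

  record <- function(i) {
    rho_pl <- to_polariton_density(rho_af, sol$U)
    mixed <- mixed_estimator_density(rho_pl, active)
    rec$active[i] <<- active
    rec$energies[i, ] <<- sol$energies
    rec$pop_af[i, ] <<- Re(diag(sol$U %*% mixed %*% t(sol$U)))
    rec$pop_pl[i, ] <<- Re(diag(rho_pl))
    rec$photon[i] <<- photon_number(rho_af, fr, cavity, basis)
    rec$dihedral[i] <<- dihedral_angle(Rc, model$dihedral_idx)
    ke <- sum(P^2 / (2 * m3))
    rec$ekin[i] <<- ke
    rec$etot[i] <<- ke + sol$energies[active]
    if (config$store_geometry) rec$geometry[i, , ] <<- Rc
  }
  record(1L)

  for (step in seq_len(n_steps)) {
    P_half <- P + 0.5 * dt * Fc
    Rc <- Rc + matrix(dt * P_half / m3, ncol = 3, byrow = TRUE)
    fr_new <- eval_frame(config, Rc)
    V_new <- build_potential_matrix(fr_new, cavity, basis, config$include_dse)
    sol_new <- diagonalize_potential(V_new, prev_U = sol$U)
    active <- which(sol_new$match == active)
    d_af_new <- nac_adiabatic_fock(fr_new, basis)
    dV_new <- grad_potential_matrix(fr_new, cavity, basis, config$include_dse)
    gradV_new <- full_gradient_matrix(dV_new, d_af_new, V_new)
    F_new <- active_force(sol_new, gradV_new, active)
    if (!all(is.finite(F_new))) stop("non-finite force: trajectory aborted")
    P <- P_half + 0.5 * dt * F_new

    # quantum phase A: Hamiltonian/NAC evolution with linear interpolation
    D_new <- contract_nac(d_af_new, P / m3)
    st <- quantum_state(rho_af, check = FALSE)
    dt_sub <- dt / n_sub
    for (k in seq_len(n_sub)) {
      w <- (k - 0.5) / n_sub
      Vk <- (1 - w) * V + w * V_new
      Dk <- (1 - w) * D_now + w * D_new
      st <- hamiltonian_substep(st, Vk, Dk, NULL, dt_sub)
    }
    rho_A <- st$rho

    # hop check 1 (velocity-rescaled)
    rho_pl_prev <- to_polariton_density(rho_af, sol_new$U)
    rho_pl_A <- to_polariton_density(rho_A, sol_new$U)
    probs <- gfsh_probabilities(rho_pl_prev, rho_pl_A, active)
    dest <- attempt_hop(probs)
    if (!is.na(dest)) {
      dE <- sol_new$energies[dest] - sol_new$energies[active]
      dvec <- tryCatch(nac_polariton(sol_new, gradV_new, active, dest),
                       error = function(e) P)
      rs <- suppressWarnings(rescale_velocity(P, m3, dvec, dE))
      if (rs$frustrated) {
        rec$n_frustrated <- rec$n_frustrated + 1L
      } else {
        P <- rs$P
        rec$hops <- rbind(rec$hops, data.frame(
          step = step, type = "rescaled", from = active, to = dest, dE = dE))
        active <- dest
        F_new <- active_force(sol_new, gradV_new, active)
      }
    }

    # quantum phase B: Lindblad loss
    if (cavity$gamma > 0) {
      st <- quantum_state(rho_A, check = FALSE)
      for (k in seq_len(n_sub)) st <- lindblad_substep(st, L, cavity$gamma, dt_sub)
      rho_B <- st$rho
    } else rho_B <- rho_A

    # hop check 2 (loss channel, never rescaled)
    rho_pl_A2 <- to_polariton_density(rho_A, sol_new$U)
    rho_pl_B <- to_polariton_density(rho_B, sol_new$U)
    lh <- loss_hop_channel(rho_pl_A2, rho_pl_B, active, sol_new$energies)
    if (lh$hopped) {
      rec$hops <- rbind(rec$hops, data.frame(
        step = step, type = "loss", from = active, to = lh$active,
        dE = sol_new$energies[lh$active] - sol_new$energies[active]))
      rec$dissipated <- rec$dissipated + lh$dissipated
      active <- lh$active
      F_new <- active_force(sol_new, gradV_new, active)
    }

    # decoherence correction, once per nuclear step after hop resolution
    ekin <- sum(P^2 / (2 * m3))
    if (ekin > 1e-12) {
      rho_pl_B <- decoherence_correction(rho_pl_B, active, sol_new$energies,
                                         ekin, dt, config$alpha)
    }
    rho_af <- sol_new$U %*% rho_pl_B %*% t(sol_new$U)
    rho_af <- (rho_af + Conj(t(rho_af))) / 2

    fr <- fr_new; V <- V_new; sol <- sol_new; Fc <- F_new; D_now <- D_new
    record(step + 1L)
  }
  rec$final <- list(coords = Rc, momenta = P)
  rec
}

#' Run a trajectory ensemble
#'
#' Samples Wigner initial conditions at the cis minimum (seed
#' \code{config$seed_ic}), runs \code{config$n_trajectories} independent
#' trajectories (trajectory \code{l} seeded with \code{config$seed_hop + l})
#' and aggregates the ensemble observables.
#'
#' @param config A [run_config()].
#' @param wigner Optional precomputed [model_wigner_spec()] (recomputed when
#'   missing).
#' @param at_rest If TRUE, start every trajectory from the template at rest
#'   instead of Wigner sampling.
#' @return List with \code{ensemble} (an [ensemble_record()]) and
#'   \code{observables}, a tidy data frame over the time grid with polariton
#'   and adiabatic-Fock populations, photon number, trans fraction and their
#'   standard errors.
#' @export
run_ensemble <- function(config, wigner = NULL, at_rest = FALSE) {
  stopifnot(inherits(config, "run_config"))
  n <- config$n_trajectories
  if (at_rest) {
    inits <- replicate(n, list(coords = config$model$template,
                               momenta = rep(0, 3 * nrow(config$model$template))),
                       simplify = FALSE)
  } else {
    if (is.null(wigner)) wigner <- model_wigner_spec(config$model)
    inits <- wigner_sample(wigner, n, seed = config$seed_ic)
  }
  trajs <- vector("list", n)
  failed <- 0L
  for (l in seq_len(n)) {
    trajs[[l]] <- tryCatch(
      run_trajectory(config, seed = config$seed_hop + l, init = inits[[l]]),
      error = function(e) {
        warning(sprintf("trajectory %d failed: %s", l, conditionMessage(e)))
        NULL
      })
    if (is.null(trajs[[l]])) failed <- failed + 1L
  }
  trajs <- Filter(Negate(is.null), trajs)
  if (length(trajs) == 0) stop("all trajectories failed")
  ens <- ensemble_record(trajs)
  obs <- ensemble_observables(ens)
  list(ensemble = ens, observables = obs, n_failed = failed)
}

#' Tidy observable table for an ensemble
#'
#' @param ensemble An [ensemble_record()].
#' @return Data frame with one row per time point and columns
#'   \code{time_fs}, \code{pop_pl_J}/\code{pop_af_i} per state,
#'   \code{photon}, \code{photon_se}, \code{trans_fraction},
#'   \code{trans_fraction_se}.
#' @export
ensemble_observables <- function(ensemble) {
  nt <- length(ensemble$time)
  n <- ensemble$n
  pl <- polariton_population(ensemble)
  af <- adiabatic_fock_population(ensemble)
  ph <- sapply(ensemble$trajectories, function(tr) tr$photon)
  tf_each <- sapply(ensemble$trajectories, function(tr) {
    phi <- atan2(sin(tr$dihedral), cos(tr$dihedral))
    as.numeric(abs(phi) >= pi / 2)
  })
  ph <- matrix(ph, nrow = nt); tf_each <- matrix(tf_each, nrow = nt)
  se <- function(x) apply(x, 1, stats::sd) / sqrt(max(1, n))
  out <- data.frame(time_fs = ensemble$time / polhop_units$au_per_fs)
  for (j in seq_len(ncol(pl))) out[[paste0("pop_pl_", j)]] <- pl[, j]
  for (i in seq_len(ncol(af))) out[[paste0("pop_af_", i)]] <- af[, i]
  out$photon <- rowMeans(ph)
  out$photon_se <- se(ph)
  out$trans_fraction <- rowMeans(tf_each)
  out$trans_fraction_se <- se(tf_each)
  out
}
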