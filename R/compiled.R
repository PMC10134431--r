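# Marshal a run_config into the compiled engine and reshape its record to the
# reference-engine layout. The compiled engine draws from R's RNG stream, so
# set.seed here makes the two engines reproduce each other draw for draw.
run_trajectory_compiled <- function(config, seed, init) {
  model <- config$model
  cavity <- config$cavity
  basis <- af_basis(2L, cavity$n_fock)
  init_code <- if (identical(config$init_state, "e0")) -1L
               else as.integer(config$init_state)
  mp <- list(
    W1 = model$W1, W2 = model$W2, E2 = model$E2, c1 = model$c1,
    delta = model$delta,
    mu_trans_y = model$mu$trans_y,
    mu_perm_z1 = model$mu$perm_z[1], mu_perm_z2 = model$mu$perm_z[2],
    mu_perm_x1 = model$mu$perm_x[1], mu_perm_x2 = model$mu$perm_x[2],
    bonds = matrix(as.integer(model$scaffold$bonds), ncol = 2),
    kb = model$scaffold$kb, r0 = model$scaffold$r0,
    angles = matrix(as.integer(model$scaffold$angles), ncol = 3),
    ka = model$scaffold$ka, th0 = model$scaffold$th0,
    dih = as.integer(model$dihedral_idx), masses = model$masses
  )
  cv <- list(omega = cavity$omega_c, g_c = cavity$g_c, lambda = cavity$lambda,
             gamma = cavity$gamma, eps = cavity$epsilon,
             n_fock = as.integer(cavity$n_fock),
             include_dse = isTRUE(config$include_dse))
  rn <- list(dt = config$dt, n_steps = config$n_steps, n_sub = config$n_sub,
             alpha = config$alpha, init_state = init_code,
             store_geometry = isTRUE(config$store_geometry))
  set.seed(seed)
  raw <- run_trajectory_cpp(mp, cv, rn, init$coords, as.numeric(init$momenta))
  rec <- list(
    time = (0:config$n_steps) * config$dt,
    active = as.integer(raw$active),
    energies = raw$energies, pop_af = raw$pop_af, pop_pl = raw$pop_pl,
    photon = as.numeric(raw$photon), dihedral = as.numeric(raw$dihedral),
    ekin = as.numeric(raw$ekin), etot = as.numeric(raw$etot),
    hops = data.frame(step = as.integer(raw$hop_step),
                      type = as.character(raw$hop_type),
                      from = as.integer(raw$hop_from),
                      to = as.integer(raw$hop_to),
                      dE = as.numeric(raw$hop_dE)),
    n_frustrated = as.integer(raw$n_frustrated),
    dissipated = as.numeric(raw$dissipated),
    final = list(coords = raw$final_coords,
                 momenta = as.numeric(raw$final_momenta))
  )
  if (isTRUE(config$store_geometry)) {
    g <- raw$geometry                       # N_a x 3 x nt
    rec$geometry <- aperm(g, c(3, 1, 2))
  }
  rec
}
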