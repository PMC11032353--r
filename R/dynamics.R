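## Langevin NVT dynamics. The integrator is the iterated BAOAB map with
## one force evaluation per step:
##   v += dt F/m ; x += dt/2 v ; v <- c1 v + c2 xi ; x += dt/2 v
## with c1 = exp(-gamma dt) and c2 = sqrt(kB T (1 - c1^2) / m) (exact
## Ornstein-Uhlenbeck damping). Systems whose force field reduces to
## harmonic bonds + HPS + electrostatics run through the compiled chunked
## integrator; everything else takes the per-step R path.

#' Construct a simulation state
#'
#' @param coords N x 3 coordinate matrix (A).
#' @param box orthorhombic box edge lengths (A), length 3.
#' @param velocities optional N x 3 velocities (A/fs); defaults to zero
#'   (draw thermal ones with [maxwell_velocities()]).
#' @param step step counter.
#' @param seed RNG seed recorded with the state; all randomness of a run
#'   flows from it.
#' @return object of class `cg_state`.
#' @export
cg_state <- function(coords, box, velocities = NULL, step = 0L, seed = 1L) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)), length(box) == 3,
            all(box > 0))
  if (is.null(velocities)) velocities <- matrix(0, nrow(coords), 3)
  stopifnot(all(dim(velocities) == dim(coords)), all(is.finite(velocities)))
  structure(list(coords = coords, velocities = velocities,
                 box = as.numeric(box), step = as.integer(step),
                 seed = as.integer(seed)),
            class = "cg_state")
}

#' @export
print.cg_state <- function(x, ...) {
  cat(sprintf("<cg_state> %d particles, box %.1f x %.1f x %.1f A, step %d, seed %d\n",
              nrow(x$coords), x$box[1], x$box[2], x$box[3], x$step, x$seed))
  invisible(x)
}

#' Maxwell-Boltzmann velocities
#'
#' Draws thermal velocities at the target temperature; per-axis standard
#' deviation `sqrt(kB T / m)` in the internal unit system.
#'
#' @param masses particle masses (Da).
#' @param temperature_K target temperature (K).
#' @param seed RNG seed.
#' @return N x 3 velocity matrix (A/fs).
#' @export
maxwell_velocities <- function(masses, temperature_K, seed = 1L) {
  cst <- physical_constants()
  set.seed(seed)
  sv <- sqrt(cst$kB * temperature_K / (masses * cst$ke_conv))
  matrix(stats::rnorm(length(masses) * 3), ncol = 3) * sv
}

#' Kinetic temperature of a state
#'
#' @param state a `cg_state`.
#' @param masses particle masses (Da).
#' @return instantaneous kinetic temperature (K), `2 KE / (3 N kB)`.
#' @export
kinetic_temperature <- function(state, masses) {
  cst <- physical_constants()
  ke <- 0.5 * sum(masses * rowSums(state$velocities^2)) * cst$ke_conv
  2 * ke / (3 * nrow(state$coords) * cst$kB)
}

#' One Langevin step
#'
#' Advances the state by one BAOAB-map step using the supplied forces
#' (evaluated at the current coordinates). With `friction_ps = 0` and no
#' forces this reduces to free streaming; with `friction_ps = 0` it is
#' velocity-Verlet dynamics. Uses the R RNG stream (seed it once per
#' trajectory for reproducibility).
#'
#' @param state a `cg_state`.
#' @param forces N x 3 force matrix (kcal/mol/A).
#' @param dt time step (fs).
#' @param friction_ps Langevin friction (1/ps).
#' @param temperature_K thermostat temperature (K).
#' @param masses particle masses (Da).
#' @return the advanced `cg_state`.
#' @export
langevin_step <- function(state, forces, dt, friction_ps, temperature_K,
                          masses) {
  stopifnot(dt > 0, friction_ps >= 0)
  if (!all(is.finite(forces)))
    stop("non-finite force on particle ",
         which(!apply(is.finite(forces), 1, all))[1])
  cst <- physical_constants()
  x <- state$coords; v <- state$velocities
  v <- v + dt * forces / (masses * cst$ke_conv)
  x <- x + 0.5 * dt * v
  c1 <- exp(-friction_ps * 1e-3 * dt)
  if (friction_ps > 0) {
    sv <- sqrt(cst$kB * temperature_K * (1 - c1^2) / (masses * cst$ke_conv))
    v <- c1 * v + matrix(stats::rnorm(length(v)), ncol = 3) * sv
  }
  x <- x + 0.5 * dt * v
  state$coords <- x
  state$velocities <- v
  state$step <- state$step + 1L
  state
}

# TRUE when the topology is served by the compiled bonds+HPS+ele kernel
.fast_path_ok <- function(topology) {
  nz <- function(df) !is.null(df) && nrow(df) > 0
  !nz(topology$angles) && !nz(topology$dihedrals) &&
    !nz(topology$native_contacts) && !nz(topology$dna_stack) &&
    !nz(topology$dna_pair) && !nz(topology$dna_cross) &&
    !nz(topology$pwmcos_sites) &&
    (!nz(topology$bonds) || all(topology$bonds$style == "harmonic")) &&
    all(topology$particles$kind %in%
          c("ordered_protein", "disordered_protein"))
}

# pair tables for the compiled kernel, derived from the current lists
.fast_tables <- function(topology, params, nblists) {
  rt <- params$residues
  ridx <- match(topology$particles$code, rt$code)
  kind <- topology$particles$kind
  ph <- nblists$pairs$hps
  app <- kind[ph$i] == "disordered_protein" | kind[ph$j] == "disordered_protein"
  ph <- ph[app, , drop = FALSE]
  hps <- list(i = ph$i, j = ph$j,
              sigma = (rt$sigma[ridx[ph$i]] + rt$sigma[ridx[ph$j]]) / 2,
              lambda = (rt$lambda[ridx[ph$i]] + rt$lambda[ridx[ph$j]]) / 2)
  Tk <- params$environment$temperature_K
  epsr <- relative_permittivity(Tk, params$environment$salt_molarity)
  q <- topology$particles$charge
  pe <- nblists$pairs$ele
  ele <- list(i = pe$i, j = pe$j,
              qq = physical_constants()$coulomb * q[pe$i] * q[pe$j] / epsr)
  lam_d <- if (nrow(pe) > 0)
    debye_length(Tk, params$environment$ionic_strength, epsr) else 1
  b <- topology$bonds
  bonds <- if (!is.null(b) && nrow(b) > 0)
    list(i = b$i, j = b$j, k = b$k, b0 = b$b0)
  else list(i = integer(0), j = integer(0), k = numeric(0), b0 = numeric(0))
  list(bonds = bonds, hps = hps, ele = ele, lambda_d = lam_d)
}

#' Run a Langevin MD simulation
#'
#' The driver loop: rebuild neighbor lists when the buffer criterion
#' fires, refresh the domain partition at the load-balance period,
#' integrate, and record energy/frames at the output stride. Identical
#' seeds give identical trajectories; the partition never influences the
#' physics (forces are summed in global pair order), so the rebalance
#' schedule is bit-neutral.
#'
#' @param topology a `cg_topology`.
#' @param state initial `cg_state` (its `seed` drives all randomness).
#' @param params a [cg_parameters()] set.
#' @param steps number of integration steps.
#' @param dt time step (fs), default 10.
#' @param friction_ps Langevin friction (1/ps), default 0.01.
#' @param out_stride energy/frame recording stride (steps).
#' @param balance_period load-balance update period (steps; `Inf` never).
#' @param n_subdomains subdomain count for the emulated decomposition.
#' @param keep_frames record coordinate frames at the output stride.
#' @return list with final `state`, `log` (step, per-class energies,
#'   kinetic temperature), `frames` (list of coordinate matrices, when
#'   kept), `frame_steps`, `partition` (last `cg_partition` or NULL) and
#'   `events` (rebuild/rebalance step log).
#' @export
run_simulation <- function(topology, state, params, steps,
                           dt = 10, friction_ps = 0.01,
                           out_stride = max(1L, steps %/% 100L),
                           balance_period = Inf, n_subdomains = 1L,
                           keep_frames = TRUE) {
  masses <- topology$particles$mass
  rp_ele <- params$cutoffs$ele + params$buffer
  excl <- .exclusion_keys(topology, params$exclusion$bonded_orders)
  rebuild <- function(st) {
    grid <- build_cell_grid(st, rp_ele)
    list(grid = grid,
         lists = build_neighbor_lists(st, grid, params, topology, excl))
  }
  fast <- .fast_path_ok(topology)
  partition <- NULL
  last_grid <- NULL
  if (n_subdomains > 1) {
    last_grid <- build_cell_grid(state, rp_ele)
    counts <- vapply(last_grid$members, length, integer(1))
    partition <- kdtree_partition(last_grid, counts, n_subdomains)
  }
  ev_steps <- integer(0); ev_what <- character(0)
  note_event <- function(step, what) {
    ev_steps[[length(ev_steps) + 1]] <<- step
    ev_what[[length(ev_what) + 1]] <<- what
  }
  log_rows <- list(); frames <- list(); frame_steps <- integer(0)
  record <- function(st, lists) {
    res <- total_energy_forces(topology, st, params, lists,
                               check_stale = FALSE)
    if (!all(is.finite(res$energies)))
      stop("non-finite energy at step ", st$step, " in class ",
           names(res$energies)[!is.finite(res$energies)][1])
    c(step = st$step, res$energies,
      kinetic_T = kinetic_temperature(st, masses))
  }
  take_frame <- function(st) {
    frames[[length(frames) + 1]] <<- st$coords
    frame_steps <<- c(frame_steps, st$step)
  }
  start_step <- state$step
  do_rebalance <- function(st) {
    grid <- build_cell_grid(st, rp_ele)
    counts <- vapply(grid$members, length, integer(1))
    partition <<- rebalance(partition, grid, counts, st$step,
                            balance_period)
    note_event(st$step, "rebalance")
  }
  if (fast) {
    # lean rebuilds: per-particle tables combined on the fly, full class
    # lists only at log points
    kind <- topology$particles$kind
    is_dis <- kind == "disordered_protein"
    rt <- params$residues
    ridx <- match(topology$particles$code, rt$code)
    psig <- rt$sigma[ridx]; plam <- rt$lambda[ridx]
    q <- topology$particles$charge
    ch_idx <- which(q != 0)
    Tk <- params$environment$temperature_K
    epsr <- relative_permittivity(Tk, params$environment$salt_molarity)
    lam_d <- if (length(ch_idx) >= 2)
      debye_length(Tk, params$environment$ionic_strength, epsr) else 1
    kC <- physical_constants()$coulomb
    b <- topology$bonds
    bonds_tb <- if (!is.null(b) && nrow(b) > 0)
      list(i = b$i, j = b$j, k = b$k, b0 = b$b0)
    else list(i = integer(0), j = integer(0), k = numeric(0),
              b0 = numeric(0))
    drop_keys <- c(excl$bonded, excl$go)
    rp_hps <- params$cutoffs$hps + params$buffer
    lean_rebuild <- function(st) {
      cand <- cpp_pairs_within(st$coords, st$box, rp_hps)
      keep <- is_dis[cand$i] | is_dis[cand$j]
      if (length(drop_keys))
        keep <- keep & !(.pair_num_key(cand$i, cand$j) %in% drop_keys)
      i <- cand$i[keep]; j <- cand$j[keep]
      hps_tb <- list(i = i, j = j, sigma = (psig[i] + psig[j]) / 2,
                     lambda = (plam[i] + plam[j]) / 2)
      if (length(ch_idx) >= 2) {
        ec <- cpp_pairs_within(st$coords[ch_idx, , drop = FALSE], st$box,
                               rp_ele)
        gi <- ch_idx[ec$i]; gj <- ch_idx[ec$j]
        ekeep <- rep(TRUE, length(gi))
        if (length(excl$bonded))
          ekeep <- !(.pair_num_key(gi, gj) %in% excl$bonded)
        ele_tb <- list(i = gi[ekeep], j = gj[ekeep],
                       qq = kC * q[gi[ekeep]] * q[gj[ekeep]] / epsr)
      } else {
        ele_tb <- list(i = integer(0), j = integer(0), qq = numeric(0))
      }
      list(hps = hps_tb, ele = ele_tb, ref = st$coords)
    }
    lt <- lean_rebuild(state)
    full_lists <- function(st)
      build_neighbor_lists(st, NULL, params, topology, excl)
    log_rows[[1]] <- record(state, full_lists(state))
    if (keep_frames) take_frame(state)
    while (state$step - start_step < steps) {
      boundary <- min(steps - (state$step - start_step),
                      out_stride - ((state$step - start_step) %% out_stride))
      if (is.finite(balance_period)) {
        to_bal <- balance_period - (state$step %% balance_period)
        boundary <- min(boundary, to_bal)
      }
      if (boundary <= 0) break
      res <- cpp_langevin_chunk(
        state$coords, state$velocities, masses, state$box,
        bonds_tb, lt$hps, lt$ele,
        params$hps$epsilon, params$cutoffs$hps,
        lam_d, params$cutoffs$ele,
        dt, friction_ps, params$environment$temperature_K,
        as.integer(boundary), params$buffer / 2, lt$ref,
        as.double(state$seed), as.double(state$step))
      state$coords <- res$x; state$velocities <- res$v
      state$step <- state$step + res$steps
      if (res$need_rebuild || res$steps == 0) {
        lt <- lean_rebuild(state)
        note_event(state$step, "nblist_rebuild")
        if (res$steps == 0) next
      }
      done <- state$step - start_step
      if (done %% out_stride == 0 || done == steps) {
        log_rows[[length(log_rows) + 1]] <- record(state, full_lists(state))
        if (keep_frames) take_frame(state)
      }
      if (is.finite(balance_period) && state$step %% balance_period == 0 &&
          !is.null(partition))
        do_rebalance(state)
    }
  } else {
    sp <- rebuild(state)
    log_rows[[1]] <- record(state, sp$lists)
    if (keep_frames) take_frame(state)
    set.seed(state$seed)
    for (s in seq_len(steps)) {
      if (needs_rebuild(state, sp$lists)) {
        sp <- rebuild(state)
        note_event(state$step, "nblist_rebuild")
      }
      res <- total_energy_forces(topology, state, params, sp$lists,
                                 check_stale = FALSE)
      state <- langevin_step(state, res$forces, dt, friction_ps,
                             params$environment$temperature_K, masses)
      if (s %% out_stride == 0 || s == steps) {
        log_rows[[length(log_rows) + 1]] <- record(state, sp$lists)
        if (keep_frames) take_frame(state)
      }
      if (is.finite(balance_period) && state$step %% balance_period == 0 &&
          !is.null(partition))
        do_rebalance(state)
    }
  }
  log <- as.data.frame(do.call(rbind, log_rows))
  list(state = state, log = log, frames = frames, frame_steps = frame_steps,
       partition = partition,
       events = data.frame(step = ev_steps, event = ev_what,
                           stringsAsFactors = FALSE))
}
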