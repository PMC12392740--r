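# R-level interface to the rigid-body Langevin dynamics engine.

#' Random non-overlapping initial state
#'
#' Places `N` subunits uniformly in the periodic box, rejection-sampled so
#' that no two subunit circumspheres overlap; orientations are uniform on
#' the rotation group and velocities / body-frame angular momenta are
#' Maxwell-Boltzmann at temperature `T`.
#'
#' @param N number of subunits (>= 1).
#' @param L box edge length.
#' @param template subunit template.
#' @param seed integer seed (same seed, same state).
#' @param T temperature (reduced units; default 1).
#' @param max_retry placement retries per subunit before failing.
#' @return an object of class `system_state`.
#' @export
initialize_random <- function(N, L, template, seed, T = 1, max_retry = 1e4) {
  if (N < 1) stop("'N' must be >= 1", call. = FALSE)
  set.seed(seed)
  rmin <- 2 * template$circumradius
  if (N * (4 / 3) * pi * (rmin / 2)^3 > 0.45 * L^3) {
    stop("packing infeasible: requested density too high for random ",
         "placement", call. = FALSE)
  }
  centers <- matrix(0, N, 3)
  n_placed <- 0L
  while (n_placed < N) {
    ok <- FALSE
    for (try in seq_len(max_retry)) {
      cand <- stats::runif(3, -L / 2, L / 2)
      if (n_placed == 0L) { ok <- TRUE; break }
      d <- sweep(centers[seq_len(n_placed), , drop = FALSE], 2, cand)
      d <- d - L * round(d / L)
      if (min(rowSums(d^2)) > rmin^2) { ok <- TRUE; break }
    }
    if (!ok) stop("packing infeasible: placement failed after ", max_retry,
                  " retries", call. = FALSE)
    n_placed <- n_placed + 1L
    centers[n_placed, ] <- cand
  }
  orientations <- random_quaternions(N)
  velocities <- matrix(stats::rnorm(3 * N, sd = sqrt(T / template$mass)), N, 3)
  angmom <- cbind(stats::rnorm(N, sd = sqrt(T * template$principal[1])),
                  stats::rnorm(N, sd = sqrt(T * template$principal[2])),
                  stats::rnorm(N, sd = sqrt(T * template$principal[3])))
  structure(list(centers = centers, orientations = orientations,
                 velocities = velocities, angmom = angmom,
                 images = matrix(0L, N, 3), box_L = L, time = 0,
                 seed = seed, template = template), class = "system_state")
}

#' Construct a system state from explicit poses
#'
#' Used by the fixture generator and tests; velocities default to zero.
#' @param centers N x 3 centers.
#' @param orientations N x 4 unit quaternions.
#' @param L box edge length.
#' @param template subunit template.
#' @param velocities,angmom optional N x 3 matrices.
#' @return a `system_state`.
#' @export
system_state <- function(centers, orientations, L, template,
                         velocities = NULL, angmom = NULL) {
  centers <- matrix(centers, ncol = 3)
  N <- nrow(centers)
  if (is.null(velocities)) velocities <- matrix(0, N, 3)
  if (is.null(angmom)) angmom <- matrix(0, N, 3)
  structure(list(centers = centers,
                 orientations = matrix(orientations, ncol = 4),
                 velocities = velocities, angmom = angmom,
                 images = matrix(0L, N, 3), box_L = L, time = 0,
                 seed = NA_integer_, template = template),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state: %d %s subunits, box L = %.4g, t = %.4g>\n",
              nrow(x$centers), x$template$model, x$box_L, x$time))
  invisible(x)
}

# map pseudoatom roles to integer types and encode the interaction table as
# matrices for the engine
#' @keywords internal
encode_rules <- function(table, template) {
  roles <- unique(template$atoms$role)
  nt <- length(roles)
  kind <- matrix(0L, nt, nt); eps <- matrix(0, nt, nt)
  par <- matrix(0, nt, nt); rcut <- matrix(0, nt, nt)
  shift <- matrix(0, nt, nt)
  kind_code <- c(WCA = 1L, MORSE = 2L, LJ = 3L)
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    rl <- lookup_rule(table, roles[i], roles[j])
    if (is.null(rl)) next
    if (rl$eps == 0 && rl$kind != "WCA") next   # zero-strength attraction
    kind[i, j] <- kind_code[[rl$kind]]
    eps[i, j] <- rl$eps
    par[i, j] <- if (rl$kind == "MORSE") rl$alpha else rl$sigma
    rcut[i, j] <- rl$r_cut
    shift[i, j] <- rl$shift
  }
  list(roles = roles,
       atom_type = match(template$atoms$role, roles) - 1L,
       rules = list(kind = kind, eps = eps, par = par, rcut = rcut,
                    shift = shift))
}

#' Run configuration for the dynamics engine
#'
#' @param dt integration time step (default 5e-3).
#' @param gamma translational friction (mass/time); default 1, so the
#'   Einstein diffusion constant is D = T/gamma = 1.
#' @param T temperature (default 1).
#' @param t_F final time.
#' @param snapshot_every snapshot interval in time units (default 500).
#' @param seed integer seed for the thermostat noise stream.
#' @param gamma_rot rotational friction; default `gamma * circumradius^2`
#'   (isotropic), resolved at run time.
#' @param neighbor_skin Verlet-list skin (default 0.8; rotational motion of
#'   the rigid bodies makes small skins rebuild-bound).
#' @return list of validated run parameters.
#' @export
run_config <- function(dt = 5e-3, gamma = 1, T = 1, t_F, snapshot_every = 500,
                       seed = 1, gamma_rot = NULL, neighbor_skin = 0.8) {
  stopifnot(dt > 0, gamma >= 0, t_F >= 0, T > 0, snapshot_every > 0)
  list(dt = dt, gamma = gamma, T = T, t_F = t_F,
       snapshot_every = snapshot_every, seed = as.integer(seed),
       gamma_rot = gamma_rot, neighbor_skin = neighbor_skin)
}

#' Pairwise forces, torques and potential energy
#'
#' Evaluates all pseudoatom pair interactions (minimum image) accumulated to
#' body forces/torques, plus the condensate force at each body center.
#'
#' @param state a `system_state`.
#' @param table interaction table matching the state's template.
#' @param spec optional [condensate_spec()]; omit (or `eps_c = 0`) for bulk.
#' @return list with `forces` (N x 3), `torques` (world frame, N x 3),
#'   `torques_body` (N x 3) and `energy`.
#' @export
compute_forces <- function(state, table, spec = NULL) {
  tpl <- state$template
  enc <- encode_rules(table, tpl)
  if (is.null(spec)) spec <- condensate_spec(R_c = 1, eps_c = 0)
  engine_forces_cpp(state$centers, state$orientations, state$box_L,
                    tpl$atoms$pos, enc$atom_type, enc$rules,
                    tpl$principal, tpl$mass, spec$eps_c, spec$R_c,
                    spec$alpha_C, 0.4)
}

#' Run rigid-body Langevin dynamics
#'
#' Integrates the translational and rotational Langevin equations (BAOAB
#' splitting; symplectic free-rotor axis-permutation update with per-step
#' quaternion renormalization) and records snapshots every
#' `snapshot_every` time units.  Identical seeds and configuration give
#' identical trajectories on one platform.
#'
#' @param state initial `system_state`.
#' @param config a [run_config()].
#' @param table interaction table.
#' @param spec optional [condensate_spec()].
#' @return an object of class `trajectory`: fields `times`, `x`
#'   (3 x N x n_frames), `q` (4 x N x n_frames), `image`, `epot`, `ekin`,
#'   `final` (final `system_state`), plus run metadata.
#' @export
run_dynamics <- function(state, config, table, spec = NULL) {
  tpl <- state$template
  enc <- encode_rules(table, tpl)
  bulk <- is.null(spec) || spec$eps_c == 0
  if (is.null(spec)) spec <- condensate_spec(R_c = 1, eps_c = 0)
  if (!bulk) {
    max_rcut <- max(vapply(table$rules, `[[`, numeric(1), "r_cut"))
    if (spec$R_c + max_rcut + 1 / spec$alpha_C >= state$box_L / 2) {
      stop("condensate too large for the box: require R_c + interaction ",
           "range < L/2", call. = FALSE)
    }
  }
  n_steps <- as.integer(round(config$t_F / config$dt))
  snap_stride <- max(1L, as.integer(round(config$snapshot_every / config$dt)))
  gamma_rot <- config$gamma_rot
  if (is.null(gamma_rot)) gamma_rot <- config$gamma * tpl$circumradius^2
  gamma_rot <- rep(gamma_rot, length.out = 3)

  res <- engine_run_cpp(state$centers, state$orientations, state$velocities,
                        state$angmom, state$images, state$box_L,
                        tpl$atoms$pos, enc$atom_type, enc$rules,
                        tpl$principal, tpl$mass, spec$eps_c, spec$R_c,
                        spec$alpha_C, config$dt, config$gamma, gamma_rot,
                        config$T, n_steps, snap_stride,
                        as.double(config$seed), state$time,
                        config$neighbor_skin)
  N <- nrow(state$centers)
  nf <- res$n_frames
  final <- state
  final$centers <- res$x; final$orientations <- res$q
  final$velocities <- res$v; final$angmom <- res$Lb
  final$images <- res$image
  final$time <- res$times[nf]
  structure(list(
    times = res$times[seq_len(nf)],
    x = array(res$snap_x, dim = c(3, N, nf)),
    q = array(res$snap_q, dim = c(4, N, nf)),
    image = array(res$snap_image, dim = c(3, N, nf)),
    epot = res$epot[seq_len(nf)], ekin = res$ekin[seq_len(nf)],
    final = final, box_L = state$box_L, template = tpl,
    condensate = spec, config = config, model = tpl$model,
    package_version = as.character(utils::packageVersion("condcap"))
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames, %d subunits, t in [%.4g, %.4g]>\n",
              length(x$times), dim(x$x)[2], x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' Extract one frame of a trajectory as a `system_state`
#' @param traj a `trajectory`.
#' @param frame frame index (1-based).
#' @export
frame_state <- function(traj, frame) {
  N <- dim(traj$x)[2]
  st <- system_state(t(traj$x[, , frame]), t(traj$q[, , frame]),
                     traj$box_L, traj$template)
  st$images <- t(traj$image[, , frame])
  st$time <- traj$times[frame]
  st
}

#' Translational diffusion constant from a trajectory
#'
#' Least-squares slope of the mean-square displacement of unwrapped body
#' centers, `D = slope / 6`, fitted beyond the ballistic window
#' (`t - t_0 > fit_from`, default `20 m / gamma`).
#'
#' @param traj a `trajectory` of non-interacting subunits.
#' @param fit_from start of the diffusive fitting window (time units).
#' @return diffusion constant.
#' @export
measure_translational_diffusion <- function(traj, fit_from = NULL) {
  if (is.null(fit_from)) fit_from <- 20 / max(traj$config$gamma, 1e-6)
  nf <- length(traj$times)
  if (nf < 6) stop("insufficient data: need at least 6 frames", call. = FALSE)
  L <- traj$box_L
  u0 <- traj$x[, , 1] + L * traj$image[, , 1]
  lag <- traj$times - traj$times[1]
  msd <- vapply(seq_len(nf), function(f) {
    u <- traj$x[, , f] + L * traj$image[, , f]
    mean(colSums((u - u0)^2))
  }, numeric(1))
  sel <- lag > fit_from
  if (sum(sel) < 4) stop("insufficient data: trajectory too short for the ",
                         "diffusive window", call. = FALSE)
  fit <- stats::lm(msd[sel] ~ lag[sel])
  unname(stats::coef(fit)[2] / 6)
}

# ---------------------------------------------------------------------------
# extended-XYZ trajectory files (text; quaternion and image columns)

#' Write a trajectory as extended XYZ
#'
#' One block per frame: an atom count line (bodies, not pseudoatoms), a
#' comment line with `Time`, `Lattice` and a `Properties` descriptor, then
#' one row per subunit: species, center, quaternion, image flags.
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  N <- dim(traj$x)[2]
  L <- traj$box_L
  for (f in seq_along(traj$times)) {
    writeLines(as.character(N), con)
    writeLines(sprintf(
      paste0("Time=%.10g Lattice=\"%.10g 0 0 0 %.10g 0 0 0 %.10g\" ",
             "Model=%s Properties=species:S:1:pos:R:3:quat:R:4:image:I:3"),
      traj$times[f], L, L, L, traj$model), con)
    rows <- sprintf("SUB %.12g %.12g %.12g %.12g %.12g %.12g %.12g %d %d %d",
                    traj$x[1, , f], traj$x[2, , f], traj$x[3, , f],
                    traj$q[1, , f], traj$q[2, , f], traj$q[3, , f],
                    traj$q[4, , f],
                    traj$image[1, , f], traj$image[2, , f],
                    traj$image[3, , f])
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read an extended-XYZ trajectory written by [write_trajectory_xyz()]
#'
#' @param path file path.
#' @param template subunit template to attach (the file stores only poses).
#' @return a `trajectory` (positions, quaternions, images, times; no
#'   energies).
#' @export
read_trajectory_xyz <- function(path, template) {
  lines <- readLines(path)
  frames_x <- list(); frames_q <- list(); frames_im <- list()
  times <- numeric(0); L <- NA_real_; model <- NA_character_
  i <- 1
  while (i <= length(lines)) {
    N <- as.integer(lines[i])
    hdr <- lines[i + 1]
    times <- c(times, as.numeric(sub(".*Time=([-0-9.eE+]+).*", "\\1", hdr)))
    L <- as.numeric(sub(".*Lattice=\"([-0-9.eE+]+) .*", "\\1", hdr))
    model <- sub(".*Model=([a-z]+).*", "\\1", hdr)
    block <- lines[(i + 2):(i + 1 + N)]
    m <- do.call(rbind, lapply(strsplit(block, " +"), function(s)
      as.numeric(s[-1])))
    frames_x[[length(frames_x) + 1]] <- t(m[, 1:3, drop = FALSE])
    frames_q[[length(frames_q) + 1]] <- t(m[, 4:7, drop = FALSE])
    frames_im[[length(frames_im) + 1]] <- t(m[, 8:10, drop = FALSE])
    i <- i + 2 + N
  }
  nf <- length(times)
  N <- ncol(frames_x[[1]])
  structure(list(
    times = times,
    x = array(unlist(frames_x), dim = c(3, N, nf)),
    q = array(unlist(frames_q), dim = c(4, N, nf)),
    image = array(as.integer(unlist(frames_im)), dim = c(3, N, nf)),
    epot = rep(NA_real_, nf), ekin = rep(NA_real_, nf),
    final = NULL, box_L = L, template = template, condensate = NULL,
    config = NULL, model = model
  ), class = "trajectory")
}
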