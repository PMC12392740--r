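# Ideal-solution and hard-sphere two-state equilibrium theories of
# condensate-coupled capsid assembly.
#
# The two-state approximation allows only free monomers and complete capsids
# (N_cap subunits).  Within each phase (condensate, background) the law of
# mass action holds, mu_cap = N_cap * mu_1, and across phases each species'
# chemical potential is equal.  Excluded volume is treated by mapping
# monomers and capsids to effective hard spheres (diameters sigma_sub,
# sigma_cap) with the Carnahan-Starling equation of state and its BMCSL
# binary-mixture extension.  Densities are in reduced units; thermal
# wavelength factors are absorbed into dG_cap, so dG_cap is defined relative
# to unit number density.

.condcap_cache <- new.env(parent = emptyenv())

#' Ideal-solution partition coefficient
#'
#' In the ideal-solution limit the monomer partition coefficient is
#' `K_c = exp(eps_c)` (beta = 1 in reduced units).
#'
#' @param eps_c condensate well depth (kT).
#' @return partition coefficient.
#' @export
kc_ideal <- function(eps_c) exp(eps_c)

#' Carnahan-Starling excess chemical potential
#'
#' `mu_ex(eta) = (8 eta - 9 eta^2 + 3 eta^3) / (1 - eta)^3` for a
#' one-component hard-sphere fluid at packing fraction `eta`.
#'
#' @param eta packing fraction(s), `0 <= eta < 1`.
#' @param warn if `TRUE`, warn when `eta > 0.5`, where the
#'   Carnahan-Starling form deviates appreciably from real hard-sphere
#'   behavior.
#' @return excess chemical potential (kT), vectorized.
#' @export
cs_mu_excess <- function(eta, warn = FALSE) {
  if (any(!is.finite(eta)) || any(eta < 0) || any(eta >= 1)) {
    stop("'eta' must satisfy 0 <= eta < 1", call. = FALSE)
  }
  if (warn && any(eta > 0.5)) {
    warning("eta > 0.5: Carnahan-Starling is inaccurate at this packing",
            call. = FALSE)
  }
  (8 * eta - 9 * eta^2 + 3 * eta^3) / (1 - eta)^3
}

#' BMCSL excess chemical potential for a hard-sphere mixture
#'
#' Excess chemical potential of one species in a (binary) hard-sphere
#' mixture from the Boublik-Mansoori-Carnahan-Starling-Leland equation of
#' state, evaluated as the analytic density derivative of the BMCSL excess
#' free energy.  Reduces exactly to [cs_mu_excess()] of the total packing
#' fraction when all diameters are equal.
#'
#' @param etas per-species packing fractions (numeric vector).
#' @param sigmas per-species hard-sphere diameters.
#' @param species index (1-based) of the species whose chemical potential is
#'   returned.
#' @return excess chemical potential (kT).
#' @export
bmcsl_mu_excess <- function(etas, sigmas, species = 1) {
  if (length(etas) != length(sigmas)) {
    stop("'etas' and 'sigmas' must have equal length", call. = FALSE)
  }
  if (any(etas < 0)) stop("packing fractions must be >= 0", call. = FALSE)
  eta_tot <- sum(etas)
  if (eta_tot >= 1) stop("total packing fraction must be < 1", call. = FALSE)
  if (eta_tot < 1e-14) return(0)
  rho <- 6 * etas / (pi * sigmas^3)
  xi <- vapply(0:3, function(n) pi / 6 * sum(rho * sigmas^n), numeric(1))
  x3 <- xi[4]; x2 <- xi[3]; x1 <- xi[2]; x0 <- xi[1]
  om <- 1 - x3
  l1m <- log(om)
  df0 <- -l1m
  df1 <- 3 * x2 / om
  df2 <- 3 * x2^2 / x3^2 * l1m + 3 * x1 / om + 3 * x2^2 / (x3 * om^2)
  df3 <- -2 * x2^3 / x3^3 * l1m - (x2^3 / x3^2 - x0) / om +
    3 * x1 * x2 / om^2 +
    x2^3 * (-1 / (x3^2 * om^2) + 2 / (x3 * om^3))
  s <- sigmas[species]
  df0 + df1 * s + df2 * s^2 + df3 * s^3
}

# ---------------------------------------------------------------------------
# effective hard-sphere diameters

#' Effective hard-sphere diameter of a subunit from its repulsions
#'
#' Maps the subunit's (soft, anisotropic) repulsive interactions to an
#' effective hard-sphere diameter by matching the orientation-averaged
#' second virial coefficient: `B2 = (2 pi / 3) sigma_eff^3`, with
#' `B2 = 2 pi int r^2 (1 - <exp(-u_rep)>_Omega) dr` estimated by Monte Carlo
#' over relative orientations (fixed internal seed, so the estimate is
#' deterministic).
#'
#' @param template subunit template.
#' @param table interaction table (only its purely repulsive rules are used).
#' @param n_orient number of orientation samples.
#' @param n_r radial grid points.
#' @return effective diameter (length units).
#' @export
effective_subunit_diameter <- function(template, table, n_orient = 400,
                                       n_r = 80) {
  rep_roles <- c("T", "B", "EXCLUDER")
  keep <- template$atoms$role %in% rep_roles
  pos <- template$atoms$pos[keep, , drop = FALSE]
  role <- template$atoms$role[keep]
  n_at <- nrow(pos)
  r_max <- 2 * template$circumradius + 2 * template$length_scale
  r_grid <- seq(0, r_max, length.out = n_r + 1)[-1]
  dr <- r_grid[2] - r_grid[1]
  # pair rule parameters (WCA only)
  eps <- matrix(0, n_at, n_at); sig <- matrix(0, n_at, n_at)
  for (i in seq_len(n_at)) for (j in seq_len(n_at)) {
    rl <- lookup_rule(table, role[i], role[j])
    if (!is.null(rl) && rl$kind == "WCA") {
      eps[i, j] <- rl$eps; sig[i, j] <- rl$sigma
    }
  }
  has_rule <- eps > 0
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(815423L)
  mean_mayer <- numeric(length(r_grid))
  for (k in seq_len(n_orient)) {
    q1 <- random_quaternions(1); q2 <- random_quaternions(1)
    p1 <- quat_rotate(q1[1, ], pos); p2 <- quat_rotate(q2[1, ], pos)
    u_of_r <- numeric(length(r_grid))
    for (i in seq_len(n_at)) for (j in seq_len(n_at)) {
      if (!has_rule[i, j]) next
      dxy2 <- (p2[j, 1] - p1[i, 1])^2 + (p2[j, 2] - p1[i, 2])^2
      dz <- r_grid + (p2[j, 3] - p1[i, 3])
      d <- sqrt(dxy2 + dz^2)
      s6 <- (sig[i, j] / d)^6
      u <- ifelse(d < 2^(1 / 6) * sig[i, j],
                  4 * eps[i, j] * (s6^2 - s6) + eps[i, j], 0)
      u_of_r <- u_of_r + u
    }
    mean_mayer <- mean_mayer + exp(-pmin(u_of_r, 700))
  }
  mean_mayer <- mean_mayer / n_orient
  B2 <- 2 * pi * sum(r_grid^2 * (1 - mean_mayer)) * dr
  (3 * B2 / (2 * pi))^(1 / 3)
}

#' @keywords internal
default_sigma_sub <- function(model) {
  key <- paste0("sigma_sub_", model)
  if (!is.null(.condcap_cache[[key]])) return(.condcap_cache[[key]])
  tpl <- switch(model, dodecahedron = build_dodecahedron_subunit(),
                icosahedron = build_icosahedron_subunit())
  tab <- build_interaction_table(model, eps_ss = 0, template = tpl)
  n_or <- if (model == "dodecahedron") 400 else 60
  val <- effective_subunit_diameter(tpl, tab, n_orient = n_or)
  .condcap_cache[[key]] <- val
  val
}

#' @keywords internal
default_sigma_cap <- function(model) {
  if (model == "dodecahedron") return(5.1)
  key <- "sigma_cap_icosahedron"
  if (!is.null(.condcap_cache[[key]])) return(.condcap_cache[[key]])
  val <- capsid_diameter(assemble_reference_capsid("icosahedron"))
  .condcap_cache[[key]] <- val
  val
}

# ---------------------------------------------------------------------------
# capsid formation free energy

#' Capsid formation standard free energy from the binding affinity
#'
#' `dG_cap = -n_bonds * (eps_bond - delta_s_bond)` where `eps_bond` is the
#' per-bond well depth measured from the (cut-and-shifted) attractive pair
#' potential minimum -- each bond comprises two attractor contacts -- and
#' `delta_s_bond` is a single per-bond entropic penalty.  The default
#' `delta_s_bond` is calibrated once so that the bulk two-state critical
#' subunit concentration at `eps_ss = 6` (dodecahedron) is 5e-4.
#'
#' @param eps_ss subunit-subunit well depth (kT).
#' @param model `"dodecahedron"` or `"icosahedron"`.
#' @param delta_s_bond per-bond entropy penalty (kT).
#' @param table optional interaction table (rebuilt if omitted).
#' @return capsid formation free energy (kT, negative for stable capsids).
#' @export
dg_capsid <- function(eps_ss, model = "dodecahedron", delta_s_bond = 7.153,
                      table = NULL) {
  if (is.null(table)) table <- build_interaction_table(model, eps_ss = eps_ss)
  eps_bond <- 2 * bond_contact_depth(table)
  -30 * (eps_bond - delta_s_bond)
}

# well depth of one attractor contact (positive number), from the shifted
# pair potential minimum
#' @keywords internal
bond_contact_depth <- function(table) {
  if (table$eps_ss == 0) return(0)
  if (table$model == "dodecahedron") {
    rl <- table$rules[["A|A"]]
    # Morse with r_eq = 0: minimum at r -> 0
    -(raw_pair_potential(rl, 1e-12) - rl$shift)
  } else {
    rl <- table$rules[["Aa|Ab"]]
    -(raw_pair_potential(rl, 2^(1 / 6) * rl$sigma) - rl$shift)
  }
}

# ---------------------------------------------------------------------------
# parameter container

#' Parameters for the two-state equilibrium theories
#'
#' @param model `"dodecahedron"` or `"icosahedron"` (sets `N_cap` and the
#'   diameter defaults).
#' @param rho_T total subunit number density.
#' @param V_r condensate-to-background volume ratio.
#' @param eps_c condensate well depth (kT).
#' @param eps_ss subunit-subunit well depth (sets `dG_cap` via
#'   [dg_capsid()] unless `dG_cap` is given).
#' @param mode `"hard_sphere"` or `"ideal"`.
#' @param sigma_sub,sigma_cap effective hard-sphere diameters; defaults are
#'   the B2-matched subunit diameter and 5.1 (dodecahedron) or the measured
#'   reference-capsid diameter (icosahedron).
#' @param dG_cap capsid formation free energy; overrides `eps_ss`.
#' @param delta_s_bond per-bond entropy penalty passed to [dg_capsid()].
#' @return an object of class `theory_params`.
#' @export
theory_params <- function(model = "dodecahedron", rho_T, V_r, eps_c,
                          eps_ss = NULL, mode = c("hard_sphere", "ideal"),
                          sigma_sub = NULL, sigma_cap = NULL, dG_cap = NULL,
                          delta_s_bond = 7.153) {
  mode <- match.arg(mode)
  if (rho_T <= 0) stop("'rho_T' must be positive", call. = FALSE)
  if (V_r <= 0) stop("'V_r' must be positive", call. = FALSE)
  N_cap <- switch(model, dodecahedron = 12L, icosahedron = 20L,
                  stop("unknown model: ", model))
  if (is.null(sigma_sub)) sigma_sub <- default_sigma_sub(model)
  if (is.null(sigma_cap)) sigma_cap <- default_sigma_cap(model)
  if (sigma_cap <= sigma_sub || sigma_sub <= 0) {
    stop("need sigma_cap > sigma_sub > 0", call. = FALSE)
  }
  if (is.null(dG_cap)) {
    dG_cap <- if (is.null(eps_ss)) Inf else
      dg_capsid(eps_ss, model, delta_s_bond)
  }
  structure(list(model = model, N_cap = N_cap, rho_T = rho_T, V_r = V_r,
                 eps_c = eps_c, mode = mode, sigma_sub = sigma_sub,
                 sigma_cap = sigma_cap, dG_cap = dG_cap),
            class = "theory_params")
}

# ---------------------------------------------------------------------------
# solvers

# excess chemical potentials of (monomer, capsid) at given densities
#' @keywords internal
mu_ex_pair <- function(rho1, rhocap, params) {
  if (params$mode == "ideal") return(c(0, 0))
  etas <- c(pi / 6 * rho1 * params$sigma_sub^3,
            pi / 6 * rhocap * params$sigma_cap^3)
  sig <- c(params$sigma_sub, params$sigma_cap)
  c(bmcsl_mu_excess(etas, sig, 1), bmcsl_mu_excess(etas, sig, 2))
}

# solve ln(rho1) + mu_ex_1(rho1, rhocap) - field = mu1_target for rho1
#' @keywords internal
solve_rho1_in_phase <- function(mu1_target, field, rhocap, params) {
  if (params$mode == "ideal") return(exp(mu1_target + field))
  eta_max <- 0.95
  rho_hi <- eta_max * 6 / (pi * params$sigma_sub^3)
  etacap <- pi / 6 * rhocap * params$sigma_cap^3
  if (etacap < 0.95) {
    rho_hi <- min(rho_hi, (0.95 - etacap) * 6 / (pi * params$sigma_sub^3))
  }
  g <- function(lr) {
    r1 <- exp(lr)
    lr + mu_ex_pair(r1, rhocap, params)[1] - field - mu1_target
  }
  # infinite-dilution excess chemical potential of the monomer in the
  # capsid background can be large at high packing; widen the bracket
  mex0 <- mu_ex_pair(0, rhocap, params)[1]
  lo <- min(mu1_target + field - mex0, log(rho_hi)) - 30
  hi <- log(rho_hi * 0.999999)
  if (g(hi) < 0) stop("condensate saturated: no monomer density below the ",
                      "packing limit matches the chemical potential",
                      call. = FALSE)
  exp(stats::uniroot(g, c(lo, hi), tol = 1e-14)$root)
}

# densities (rho1, rhocap) in one phase at common monomer chemical
# potential mu1; field = eps_c inside the condensate, 0 outside
#' @keywords internal
phase_densities <- function(mu1, field, params) {
  if (!is.finite(params$dG_cap) && params$dG_cap > 0) {
    rho1 <- solve_rho1_in_phase(mu1, field, 0, params)
    return(c(rho1 = rho1, rhocap = 0))
  }
  if (params$mode == "ideal") {
    rho1 <- exp(mu1 + field)
    rhocap <- exp(params$N_cap * mu1 + params$N_cap * field - params$dG_cap)
    return(c(rho1 = rho1, rhocap = rhocap))
  }
  eta_max <- 0.95
  rcap_hi <- eta_max * 6 / (pi * params$sigma_cap^3)
  g <- function(lrc) {
    rc <- exp(lrc)
    r1 <- solve_rho1_in_phase(mu1, field, rc, params)
    lrc + mu_ex_pair(r1, rc, params)[2] + params$dG_cap -
      params$N_cap * field - params$N_cap * mu1
  }
  ideal_guess <- params$N_cap * (mu1 + field) - params$dG_cap
  lo <- min(ideal_guess, log(rcap_hi)) - 60
  hi <- log(rcap_hi * 0.999999)
  if (g(hi) < 0) stop("condensate saturated: capsid density would exceed ",
                      "the packing limit", call. = FALSE)
  if (g(lo) > 0) {        # essentially no capsids at this mu1
    rho1 <- solve_rho1_in_phase(mu1, field, 0, params)
    return(c(rho1 = rho1, rhocap = 0))
  }
  rc <- exp(stats::uniroot(g, c(lo, hi), tol = 1e-13)$root)
  r1 <- solve_rho1_in_phase(mu1, field, rc, params)
  c(rho1 = r1, rhocap = rc)
}

#' @keywords internal
build_phase_solution <- function(mu1, params) {
  dc <- phase_densities(mu1, params$eps_c, params)
  db <- phase_densities(mu1, 0, params)
  V_r <- params$V_r
  rho_mean <- (dc["rho1"] + params$N_cap * dc["rhocap"]) * V_r / (1 + V_r) +
    (db["rho1"] + params$N_cap * db["rhocap"]) / (1 + V_r)
  eta_c <- pi / 6 * (dc["rho1"] * params$sigma_sub^3 +
                     dc["rhocap"] * params$sigma_cap^3)
  eta_bg <- pi / 6 * (db["rho1"] * params$sigma_sub^3 +
                      db["rhocap"] * params$sigma_cap^3)
  rho_cap_tot <- dc["rhocap"] * V_r / (1 + V_r) + db["rhocap"] / (1 + V_r)
  f_c_c <- params$N_cap * dc["rhocap"] / params$rho_T * V_r / (1 + V_r)
  f_c_bg <- params$N_cap * db["rhocap"] / params$rho_T / (1 + V_r)
  structure(list(
    rho1_c = unname(dc["rho1"]), rho1_bg = unname(db["rho1"]),
    rhocap_c = unname(dc["rhocap"]), rhocap_bg = unname(db["rhocap"]),
    K_c = unname(dc["rho1"] / db["rho1"]),
    eta_c = unname(eta_c), eta_bg = unname(eta_bg),
    f_c = unname(f_c_c + f_c_bg), f_c_c = unname(f_c_c),
    f_c_bg = unname(f_c_bg),
    rho_cap = unname(rho_cap_tot), rho_mean = unname(rho_mean),
    mu1 = mu1, high_eta = unname(eta_c > 0.5 || eta_bg > 0.5),
    params = params), class = "phase_solution")
}

#' @keywords internal
solve_equilibrium <- function(params) {
  # a saturated phase at a trial mu1 means that chemical potential already
  # carries more mass than the system holds: treat as a large positive
  # residual so the bracketed root find backs off
  resid <- function(mu1) {
    tryCatch(build_phase_solution(mu1, params)$rho_mean - params$rho_T,
             error = function(e) params$rho_T * 1e6)
  }
  lo <- log(params$rho_T) - 40
  hi <- log(params$rho_T * (1 + params$V_r)) +
    cs_mu_excess(min(pi / 6 * params$rho_T * (1 + params$V_r) *
                     params$sigma_sub^3, 0.9)) + 5
  root <- stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
  sol <- build_phase_solution(root, params)
  if (params$mode == "hard_sphere" &&
      (sol$eta_c >= 0.74 || sol$eta_bg >= 0.74)) {
    stop("solution rejected: packing fraction at or above the close-packing",
         " bound (0.74)", call. = FALSE)
  }
  sol
}

#' Monomer partitioning without assembly
#'
#' Solves the cross-phase equality of the monomer chemical potential,
#' `ln rho_1 + mu_ex(eta) - eps_c * [in condensate]`, together with mass
#' conservation.  In ideal mode this returns the closed form
#' `K_c = exp(eps_c)`; in hard-sphere mode excluded volume reduces `K_c`.
#'
#' @param params a [theory_params()]; `dG_cap` is ignored (set to +Inf).
#' @return a `phase_solution` with monomer densities, `K_c` and packing
#'   fractions (capsid densities are zero).
#' @export
solve_partition_no_assembly <- function(params) {
  params$dG_cap <- Inf
  solve_equilibrium(params)
}

#' Two-state assembly equilibrium in condensate and background
#'
#' Simultaneously solves (i) mass action in each phase
#' (`mu_cap = N_cap * mu_1`), (ii) cross-phase equality of each species'
#' chemical potential, and (iii) total mass conservation, reduced to nested
#' bracketed root finds.  Returns densities, the partition coefficient and
#' the yields `f_c = f_c_c + f_c_bg`.
#'
#' @param params a [theory_params()] with finite `dG_cap`.
#' @return a `phase_solution`.
#' @export
solve_two_state_equilibrium <- function(params) {
  solve_equilibrium(params)
}

#' @export
print.phase_solution <- function(x, ...) {
  cat(sprintf(paste0("<phase_solution: K_c = %.4g, f_c = %.4g ",
                     "(condensate %.4g, background %.4g)>\n"),
              x$K_c, x$f_c, x$f_c_c, x$f_c_bg))
  invisible(x)
}

# ---------------------------------------------------------------------------
# close-packing limits

#' Capsid close-packing concentration
#'
#' FCC close packing of spheres of diameter `sigma_cap`:
#' `rho_CP = (pi / (3 sqrt 2)) / ((4 pi / 3)(sigma_cap / 2)^3)
#'        = sqrt(2) / sigma_cap^3`.
#'
#' @param sigma_cap capsid effective diameter.
#' @return number density.
#' @export
close_packing_concentration <- function(sigma_cap) {
  if (sigma_cap <= 0) stop("'sigma_cap' must be positive", call. = FALSE)
  sqrt(2) / sigma_cap^3
}

#' Threshold condensate volume ratio
#'
#' Below `V_r* = 1 / (N_cap * rho_CP / rho_T - 1)` the condensate cannot hold
#' all subunits as close-packed capsids and the close-packing argument
#' predicts declining yield.
#'
#' @param rho_T total subunit density.
#' @param N_cap subunits per capsid.
#' @param rho_CP capsid close-packing concentration (derived from
#'   `sigma_cap` via [close_packing_concentration()] or given directly, e.g.
#'   the printed value 1.28e-2).
#' @return threshold volume ratio.
#' @export
threshold_volume_ratio <- function(rho_T, N_cap, rho_CP) {
  if (N_cap * rho_CP <= rho_T) {
    stop("N_cap * rho_CP must exceed rho_T: the condensate can never hold ",
         "all subunits", call. = FALSE)
  }
  1 / (N_cap * rho_CP / rho_T - 1)
}

#' Close-packed yield bound
#'
#' For `V_r <= V_r*` the maximum yield under the sphere-packing argument is
#' `f_CP = (1/V_r* + 1) / (1/V_r + 1)`; above the threshold the bound is 1.
#'
#' @param V_r condensate volume ratio.
#' @param V_r_star threshold from [threshold_volume_ratio()].
#' @return yield bound in (0, 1].
#' @export
close_packed_yield <- function(V_r, V_r_star) {
  if (any(V_r <= 0) || any(V_r_star <= 0)) {
    stop("'V_r' and 'V_r_star' must be positive", call. = FALSE)
  }
  pmin((1 / V_r_star + 1) / (1 / V_r + 1), 1)
}

#' Yield-vs-density theory curve
#'
#' Convenience scan of [solve_two_state_equilibrium()] over `rho_T`.
#'
#' @param rho_T_grid densities to scan.
#' @param ... passed to [theory_params()].
#' @return data.frame with columns rho_T, f_c, f_c_c, f_c_bg, K_c, eta_c.
#' @export
yield_curve <- function(rho_T_grid, ...) {
  rows <- lapply(rho_T_grid, function(rt) {
    sol <- try(solve_two_state_equilibrium(theory_params(rho_T = rt, ...)),
               silent = TRUE)
    if (inherits(sol, "try-error")) {
      data.frame(rho_T = rt, f_c = NA, f_c_c = NA, f_c_bg = NA, K_c = NA,
                 eta_c = NA)
    } else {
      data.frame(rho_T = rt, f_c = sol$f_c, f_c_c = sol$f_c_c,
                 f_c_bg = sol$f_c_bg, K_c = sol$K_c, eta_c = sol$eta_c)
    }
  })
  do.call(rbind, rows)
}
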