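# Synthetic-configuration generator: deterministic fixtures for the
# analytics and theory (monomer gases, planted complete capsids, danglers,
# condensate-packed capsid arrays).  These are constructed states, not
# dynamics output.

#' Generate a synthetic configuration
#'
#' Kinds:
#' \describe{
#'   \item{monomer_gas}{`N` subunits with all pairwise center distances
#'     greater than 3 circumradii (no bonds by construction).}
#'   \item{planted_capsid}{one exact reference capsid at the box center
#'     plus `n_free` well-separated monomers.}
#'   \item{dangler}{a reference capsid whose last subunit is hinged outward
#'     about one of its bonded edges by `tilt` (default 40 degrees -- wide
#'     enough that all four non-hinge edge midpoints move beyond the bond
#'     criterion), so that exactly one of its five bonds survives:
#'     12 subunits, 26 bonds.}
#'   \item{packed_condensate}{complete capsids on an FCC lattice clipped to
#'     the sphere of radius `R_c`, realizing capsid packing fraction `eta`
#'     within 2% by construction (capsids treated as spheres of diameter
#'     `sigma_cap`).}
#' }
#'
#' @param kind fixture kind (see above).
#' @param seed integer seed (orientations of free monomers / packed
#'   capsids).
#' @param model `"dodecahedron"` or `"icosahedron"`.
#' @param N monomer count (monomer_gas).
#' @param L box edge length.
#' @param n_free free monomers to add (planted_capsid).
#' @param tilt hinge angle in radians (dangler).
#' @param eta requested capsid packing fraction (packed_condensate).
#' @param R_c condensate radius (packed_condensate).
#' @param sigma_cap capsid effective diameter (packed_condensate); default
#'   5.1 (dodecahedron) or measured (icosahedron).
#' @return a `system_state`; packed_condensate attaches attributes
#'   `n_capsids` and `achieved_eta`.
#' @export
generate_fixture <- function(kind = c("monomer_gas", "planted_capsid",
                                      "dangler", "packed_condensate"),
                             seed = 1, model = "dodecahedron", N = 100,
                             L = NULL, n_free = 0, tilt = 40 * pi / 180,
                             eta = NULL, R_c = NULL, sigma_cap = NULL) {
  kind <- match.arg(kind)
  tpl <- switch(model, dodecahedron = build_dodecahedron_subunit(),
                icosahedron = build_icosahedron_subunit(),
                stop("unknown model: ", model))
  set.seed(seed)
  switch(kind,
    monomer_gas = {
      if (is.null(L)) L <- max(20, 2 * (3.5 * tpl$circumradius) * N^(1 / 3))
      st <- place_separated(N, L, tpl, min_sep = 3 * tpl$circumradius + 0.5)
      st
    },
    planted_capsid = {
      ref <- assemble_reference_capsid(model, tpl)
      if (is.null(L)) L <- max(12 * tpl$circumradius,
                               4 * (3.5 * tpl$circumradius) *
                                 max(1, n_free)^(1 / 3))
      centers <- ref$centers
      quats <- ref$orientations
      if (n_free > 0) {
        free <- place_separated(n_free, L, tpl,
                                min_sep = 3 * tpl$circumradius + 0.5,
                                exclude_radius = capsid_diameter(ref) / 2 +
                                  3 * tpl$circumradius)
        centers <- rbind(centers, free$centers)
        quats <- rbind(quats, free$orientations)
      }
      system_state(centers, quats, L, tpl)
    },
    dangler = {
      ref <- assemble_reference_capsid(model, tpl)
      if (model != "dodecahedron") {
        stop("dangler fixture is defined for the dodecahedron model",
             call. = FALSE)
      }
      if (is.null(L)) L <- 12 * tpl$circumradius
      k <- ref$N_cap
      ctr <- ref$centers[k, ]; qk <- ref$orientations[k, ]
      # hinge about the subunit's first pentagon edge (world frame)
      sites <- sweep(quat_rotate(qk, tpl$edge_sites), 2, ctr, "+")
      A_world <- sweep(quat_rotate(qk, tpl$atoms$pos[1:5, , drop = FALSE]),
                       2, ctr, "+")
      p <- sites[1, ]
      u <- A_world[2, ] - A_world[1, ]          # edge 1 connects A1-A2
      u <- u / sqrt(sum(u^2))
      best <- NULL
      for (sgn in c(1, -1)) {
        qrot <- c(cos(sgn * tilt / 2), sin(sgn * tilt / 2) * u)
        newc <- p + drop(quat_rotate(qrot, matrix(ctr - p, 1)))
        if (is.null(best) || sum(newc^2) > sum(best$c^2)) {
          best <- list(c = newc, q = quat_multiply(qrot, qk))
        }
      }
      centers <- ref$centers; quats <- ref$orientations
      centers[k, ] <- best$c
      quats[k, ] <- best$q / sqrt(sum(best$q^2))
      system_state(centers, quats, L, tpl)
    },
    packed_condensate = {
      if (is.null(eta) || is.null(R_c)) {
        stop("packed_condensate requires 'eta' and 'R_c'", call. = FALSE)
      }
      eta_max <- pi / (3 * sqrt(2))
      if (eta > eta_max + 1e-12) {
        stop("infeasible packing: eta exceeds the FCC limit", call. = FALSE)
      }
      if (is.null(sigma_cap)) sigma_cap <- default_sigma_cap(model)
      v_cap <- pi / 6 * sigma_cap^3
      V_c <- 4 / 3 * pi * R_c^3
      n_target <- round(eta * V_c / v_cap)
      if (n_target < 1) stop("infeasible packing: condensate too small",
                             call. = FALSE)
      # FCC lattice with the cubic cell set by the requested packing
      # fraction (4 capsids per cell): eta = 4 v_cap / a^3
      a_fcc <- (4 * v_cap / eta)^(1 / 3)
      pts <- fcc_points(a_fcc, R_c + a_fcc)
      ord <- order(rowSums(pts^2), pts[, 1], pts[, 2], pts[, 3])
      pts <- pts[ord[seq_len(min(n_target, nrow(pts)))], , drop = FALSE]
      if (nrow(pts) < n_target) {
        stop("infeasible packing: lattice cannot supply the requested ",
             "capsid count", call. = FALSE)
      }
      achieved <- nrow(pts) * v_cap / V_c
      if (abs(achieved - eta) > 0.02 * max(eta, achieved)) {
        stop("packing discreteness exceeds 2%: use a larger R_c",
             call. = FALSE)
      }
      ref <- assemble_reference_capsid(model, tpl)
      if (is.null(L)) L <- 2 * (R_c + 2 * sigma_cap)
      centers <- NULL; quats <- NULL
      for (i in seq_len(nrow(pts))) {
        qr <- random_quaternions(1)[1, ]
        centers <- rbind(centers,
                         sweep(quat_rotate(qr, ref$centers), 2, pts[i, ], "+"))
        quats <- rbind(quats, t(apply(ref$orientations, 1, function(qq)
          quat_multiply(qr, qq))))
      }
      st <- system_state(centers, quats, L, tpl)
      attr(st, "n_capsids") <- nrow(pts)
      attr(st, "achieved_eta") <- achieved
      st
    })
}

#' @keywords internal
place_separated <- function(N, L, tpl, min_sep, exclude_radius = 0,
                            max_retry = 1e4) {
  centers <- matrix(0, N, 3)
  n_placed <- 0L
  while (n_placed < N) {
    ok <- FALSE
    for (try in seq_len(max_retry)) {
      cand <- stats::runif(3, -L / 2, L / 2)
      if (exclude_radius > 0 && sum(cand^2) < exclude_radius^2) next
      if (n_placed == 0L) { ok <- TRUE; break }
      d <- sweep(centers[seq_len(n_placed), , drop = FALSE], 2, cand)
      d <- d - L * round(d / L)
      if (min(rowSums(d^2)) > min_sep^2) { ok <- TRUE; break }
    }
    if (!ok) stop("fixture placement failed: box too small", call. = FALSE)
    n_placed <- n_placed + 1L
    centers[n_placed, ] <- cand
  }
  system_state(centers, random_quaternions(N), L, tpl)
}

# FCC lattice points within radius rmax of the origin (cubic cell a, basis
# of 4)
#' @keywords internal
fcc_points <- function(a, rmax) {
  nmax <- ceiling(rmax / a) + 1
  g <- expand.grid(i = -nmax:nmax, j = -nmax:nmax, k = -nmax:nmax)
  base <- cbind(g$i, g$j, g$k) * a
  basis <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5),
                 c(0, 0.5, 0.5)) * a
  pts <- do.call(rbind, lapply(seq_len(4), function(b)
    sweep(base, 2, basis[b, ], "+")))
  pts[rowSums(pts^2) <= rmax^2, , drop = FALSE]
}
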