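# Subunit models, pair interaction rules and reference capsid geometries.
#
# Two coarse-grained capsid models are provided:
#  * dodecahedron: pentagonal subunits (circumradius l0) carrying five vertex
#    attractor ('A') pseudoatoms, one top ('T') and one bottom ('B')
#    pseudoatom; 12 subunits tile a dodecahedral shell.
#  * icosahedron: triangular subunits (diameter ~ 3 sigma) made of 45 excluder
#    pseudoatoms and 6 edge attractors with lock-and-key complementarity;
#    20 subunits tile a T=1 icosahedral shell.
#
# All quantities are in reduced units: kB*T = 1, subunit mass m = 1, and the
# subunit length scale (l0 or sigma) = 1 unless rescaled.

PHI <- (1 + sqrt(5)) / 2

# ---------------------------------------------------------------------------
# platonic solid scaffolds

# signed permutation helper: all sign combinations of (a, b, c) in the three
# cyclic coordinate orders requested
#' @keywords internal
sign_combos <- function(a, b, c) {
  out <- NULL
  sa <- if (a == 0) 0 else c(-a, a)
  sb <- if (b == 0) 0 else c(-b, b)
  sc <- if (c == 0) 0 else c(-c, c)
  for (x in sa) for (y in sb) for (z in sc) out <- rbind(out, c(x, y, z))
  out
}

#' @keywords internal
dodecahedron_vertices <- function() {
  p <- PHI
  rbind(sign_combos(1, 1, 1),
        sign_combos(0, 1 / p, p),
        sign_combos(1 / p, p, 0),
        sign_combos(p, 0, 1 / p))
  # canonical coordinates: edge length 2/phi
}

#' @keywords internal
dodecahedron_face_normals <- function() {
  n <- rbind(sign_combos(0, PHI, 1),
             sign_combos(PHI, 1, 0),
             sign_combos(1, 0, PHI))
  n / sqrt(rowSums(n^2))
}

#' @keywords internal
icosahedron_vertices <- function() {
  rbind(sign_combos(0, 1, PHI),
        sign_combos(1, PHI, 0),
        sign_combos(PHI, 0, 1))
  # canonical coordinates: edge length 2
}

#' @keywords internal
icosahedron_face_normals <- function() {
  p <- PHI
  n <- rbind(sign_combos(1, 1, 1),
             sign_combos(0, p, 1 / p),
             sign_combos(p, 1 / p, 0),
             sign_combos(1 / p, 0, p))
  n / sqrt(rowSums(n^2))
}

# faces of a platonic solid: for each outward normal pick the k vertices with
# the largest projection, ordered counter-clockwise seen from outside
#' @keywords internal
solid_faces <- function(vertices, normals, k) {
  lapply(seq_len(nrow(normals)), function(i) {
    n <- normals[i, ]
    proj <- drop(vertices %*% n)
    idx <- order(proj, decreasing = TRUE)[seq_len(k)]
    ctr <- colMeans(vertices[idx, , drop = FALSE])
    # in-face basis for angular ordering
    e1 <- vertices[idx[1], ] - ctr
    e1 <- e1 - sum(e1 * n) * n
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(n[2] * e1[3] - n[3] * e1[2],
            n[3] * e1[1] - n[1] * e1[3],
            n[1] * e1[2] - n[2] * e1[1])
    rel <- sweep(vertices[idx, , drop = FALSE], 2, ctr)
    ang <- atan2(rel %*% e2, rel %*% e1)
    list(vertices = idx[order(ang)], normal = n, center = ctr)
  })
}

# ---------------------------------------------------------------------------
# subunit builders

#' Build the pentagonal (dodecahedron-model) subunit
#'
#' The subunit is a rigid pentagon of circumradius `l0` with five attractor
#' ('A') pseudoatoms at its vertices, a top ('T') pseudoatom at height `h_T`
#' above the pentagon plane and a bottom ('B') pseudoatom at depth `h_B`
#' below it, both on the symmetry axis.  The T and B repulsive diameters are
#' calibrated so that, for two subunits bonded edge-to-edge at the regular
#' dodecahedron dihedral angle (116.57 degrees), both the T-T and the B-T
#' WCA contacts are exactly tangent (zero energy and force).  The repulsions
#' therefore enforce the target dihedral at bonded contact: flattening the
#' hinge engages T-T, over-closing engages B-T.
#'
#' The body frame has the center of mass at the origin and the pentagon
#' normal along +z; total mass is 1, distributed equally over the
#' pseudoatoms, and the inertia tensor is computed from the point masses.
#'
#' @param l0 pentagon circumradius (the unit of length); must be positive.
#' @param h_T,h_B heights of the T and B pseudoatoms above/below the pentagon
#'   plane, in units of `l0`.
#' @return an object of class `subunit_template`.
#' @examples
#' tpl <- build_dodecahedron_subunit(1)
#' tpl$circumradius
#' @export
build_dodecahedron_subunit <- function(l0 = 1, h_T = 0.5 * l0, h_B = 0.25 * l0) {
  if (!is.numeric(l0) || length(l0) != 1 || !is.finite(l0) || l0 <= 0) {
    stop("'l0' must be a positive finite number", call. = FALSE)
  }
  a <- 2 * sin(pi / 5) * l0                   # pentagon edge length
  apo <- cos(pi / 5) * l0                     # pentagon apothem
  dihedral <- acos(-1 / sqrt(5))              # 116.565 deg
  gam <- pi - dihedral                        # angle between adjacent normals
  r_in <- (a / 2) * sqrt(5 / 2 + 11 / (2 * sqrt(5)))  # dodecahedron inradius

  # tangency calibration of the WCA diameters at the reference dihedral
  d_TT <- 2 * (r_in + h_T) * sin(gam / 2)
  d_BT <- sqrt((r_in + h_T)^2 + (r_in - h_B)^2 -
               2 * (r_in + h_T) * (r_in - h_B) * cos(gam))
  sigma_TT <- d_TT / 2^(1 / 6)
  sigma_BT <- d_BT / 2^(1 / 6)

  ang <- 2 * pi * (0:4) / 5
  A <- cbind(l0 * cos(ang), l0 * sin(ang), 0)
  pos <- rbind(A, c(0, 0, h_T), c(0, 0, -h_B))
  label <- c(paste0("A", 1:5), "T", "B")
  role <- c(rep("A", 5), "T", "B")
  diameter <- c(rep(0, 5), sigma_TT, sigma_BT)

  # shift the center of mass to the body origin (equal point masses)
  com <- colMeans(pos)
  pos <- sweep(pos, 2, com)

  masses <- rep(1 / nrow(pos), nrow(pos))
  inertia <- point_mass_inertia(pos, masses)

  # edge midpoints (bond sites): midpoints of adjacent A pairs
  edges <- cbind(1:5, c(2:5, 1))
  edge_sites <- (pos[edges[, 1], ] + pos[edges[, 2], ]) / 2

  structure(list(
    model = "dodecahedron",
    length_scale = l0,
    atoms = list(label = label, role = role, pos = pos, diameter = diameter),
    mass = 1,
    masses = masses,
    inertia = inertia,
    principal = diag(inertia),
    circumradius = max(sqrt(rowSums(pos^2))),
    n_bond_sites = 5L,
    edge_sites = edge_sites,
    geometry = list(h_T = h_T, h_B = h_B, sigma_TT = sigma_TT,
                    sigma_BT = sigma_BT, edge = a, apothem = apo,
                    inradius = r_in, dihedral = dihedral,
                    pentagon_center = -com)
  ), class = "subunit_template")
}

#' Build the triangular (icosahedron-model) subunit
#'
#' A rigid equilateral triangle of 45 excluder pseudoatoms (diameter `sigma`,
#' 9 rows of a triangular grid, corner excluders at distance `sigma` from the
#' centroid, overall circumscribed diameter 3 `sigma`) plus 6 attractor
#' pseudoatoms, two per edge at 1/3 and 2/3 along the (counter-clockwise)
#' edge.  Attractors carry complementarity tags: the 1/3-position atoms
#' ('Aa') bind only the 2/3-position atoms ('Ab') of a partner subunit via a
#' Lennard-Jones well, so two triangles bind edge-to-edge in antiparallel
#' registry with both attractor pairs at the LJ minimum (~1.12 sigma), and
#' non-complementary pairs carry no attraction.
#'
#' @param sigma excluder pseudoatom diameter (the unit of length).
#' @return an object of class `subunit_template`.
#' @export
build_icosahedron_subunit <- function(sigma = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0) {
    stop("'sigma' must be a positive finite number", call. = FALSE)
  }
  R_t <- 1.0 * sigma                          # corner excluder center radius
  ang <- pi / 2 + 2 * pi * (0:2) / 3
  corners <- cbind(R_t * cos(ang), R_t * sin(ang), 0)

  # 45 excluders: triangular grid, barycentric indices a+b+c = 8
  gridpts <- NULL
  for (a in 0:8) for (b in 0:(8 - a)) {
    cc <- 8 - a - b
    gridpts <- rbind(gridpts,
                     (a * corners[1, ] + b * corners[2, ] + cc * corners[3, ]) / 8)
  }
  stopifnot(nrow(gridpts) == 45)

  # 6 attractors on the edges (counter-clockwise seen from +z)
  ed <- cbind(1:3, c(2, 3, 1))
  attr_pos <- NULL
  attr_role <- character(0)
  edge_attr <- vector("list", 3)
  for (e in 1:3) {
    va <- corners[ed[e, 1], ]; vb <- corners[ed[e, 2], ]
    pa <- va + (vb - va) / 3
    pb <- va + 2 * (vb - va) / 3
    attr_pos <- rbind(attr_pos, pa, pb)
    attr_role <- c(attr_role, "Aa", "Ab")
    edge_attr[[e]] <- c(45 + 2 * e - 1, 45 + 2 * e)  # indices into atom list
  }

  pos <- rbind(gridpts, attr_pos)
  label <- c(paste0("E", 1:45),
             paste0("ATTRACTOR-", 1:6))
  role <- c(rep("EXCLUDER", 45), attr_role)
  diameter <- c(rep(sigma, 45), rep(0, 6))

  com <- colMeans(pos)   # symmetric: essentially zero, keep exact
  pos <- sweep(pos, 2, com)

  masses <- rep(1 / nrow(pos), nrow(pos))
  inertia <- point_mass_inertia(pos, masses)

  structure(list(
    model = "icosahedron",
    length_scale = sigma,
    atoms = list(label = label, role = role, pos = pos, diameter = diameter),
    mass = 1,
    masses = masses,
    inertia = inertia,
    principal = diag(inertia),
    circumradius = max(sqrt(rowSums(pos^2)) + diameter / 2),
    n_bond_sites = 3L,
    edge_attr = edge_attr,
    geometry = list(R_t = R_t, sigma = sigma, edge = sqrt(3) * R_t,
                    dihedral = acos(-sqrt(5) / 3),
                    corners = sweep(corners, 2, com))
  ), class = "subunit_template")
}

#' @keywords internal
point_mass_inertia <- function(pos, masses) {
  I <- matrix(0, 3, 3)
  for (i in seq_len(nrow(pos))) {
    p <- pos[i, ]
    I <- I + masses[i] * (sum(p^2) * diag(3) - outer(p, p))
  }
  I
}

#' @export
print.subunit_template <- function(x, ...) {
  cat(sprintf("<subunit_template: %s model, %d pseudoatoms, circumradius %.3f>\n",
              x$model, nrow(x$atoms$pos), x$circumradius))
  invisible(x)
}

# ---------------------------------------------------------------------------
# interaction tables

#' Build the pair-interaction table for a subunit model
#'
#' Encodes the pairwise pseudoatom interaction rules.  For the dodecahedron
#' model: A-A attract via a Morse well of depth `eps_ss` (range parameter
#' `alpha_M`, equilibrium separation 0 so that bonded subunits' vertex
#' attractors coincide), T-T and B-T are purely repulsive WCA with the
#' diameters calibrated by [build_dodecahedron_subunit()].  For the
#' icosahedron model: EXCLUDER-EXCLUDER is WCA at diameter sigma and
#' complementary attractor pairs (Aa-Ab) interact via a Lennard-Jones well of
#' depth `eps_ss`; non-complementary attractor pairs carry no rule.  All
#' potentials are cut and shifted to zero at their cutoff.
#'
#' @param model `"dodecahedron"` or `"icosahedron"`.
#' @param eps_ss subunit-subunit well depth (kT); must be >= 0.
#' @param template matching subunit template; built with defaults if omitted.
#' @param eps_rep repulsive (WCA) energy scale.
#' @param alpha_M Morse range parameter (dodecahedron), in 1/l0.
#' @return an object of class `interaction_table`.
#' @export
build_interaction_table <- function(model = c("dodecahedron", "icosahedron"),
                                    eps_ss, template = NULL, eps_rep = 1,
                                    alpha_M = NULL) {
  model <- match.arg(model)
  if (!is.numeric(eps_ss) || length(eps_ss) != 1 || !is.finite(eps_ss) ||
      eps_ss < 0) {
    stop("'eps_ss' must be a finite non-negative number", call. = FALSE)
  }
  if (is.null(template)) {
    template <- switch(model,
      dodecahedron = build_dodecahedron_subunit(),
      icosahedron  = build_icosahedron_subunit())
  }
  if (!identical(template$model, model)) {
    stop("template model does not match 'model'", call. = FALSE)
  }
  ls <- template$length_scale
  rules <- list()
  if (model == "dodecahedron") {
    if (is.null(alpha_M)) alpha_M <- 5 / ls
    r_cut <- 2.5 / alpha_M
    rules[["A|A"]] <- list(kind = "MORSE", eps = eps_ss, alpha = alpha_M,
                           r_eq = 0, r_cut = r_cut)
    rules[["T|T"]] <- list(kind = "WCA", eps = eps_rep,
                           sigma = template$geometry$sigma_TT,
                           r_cut = 2^(1 / 6) * template$geometry$sigma_TT)
    rules[["B|T"]] <- list(kind = "WCA", eps = eps_rep,
                           sigma = template$geometry$sigma_BT,
                           r_cut = 2^(1 / 6) * template$geometry$sigma_BT)
  } else {
    sg <- template$geometry$sigma
    rules[["EXCLUDER|EXCLUDER"]] <- list(kind = "WCA", eps = eps_rep,
                                         sigma = sg, r_cut = 2^(1 / 6) * sg)
    # cutoff between the bonded-pair separation (2^(1/6) sigma ~ 1.12) and
    # the nearest non-bonded complementary pair in the assembled shell
    # (~1.82 sigma), so only the intended edge contacts attract
    rules[["Aa|Ab"]] <- list(kind = "LJ", eps = eps_ss, sigma = sg,
                             r_cut = 1.75 * sg)
  }
  # precompute cut-and-shift constants (raw potential value at r_cut)
  for (nm in names(rules)) {
    rl <- rules[[nm]]
    rules[[nm]]$shift <- raw_pair_potential(rl, rl$r_cut)
  }
  structure(list(model = model, eps_ss = eps_ss, eps_rep = eps_rep,
                 rules = rules), class = "interaction_table")
}

# raw (unshifted) potential of a rule descriptor at separation r
#' @keywords internal
raw_pair_potential <- function(rule, r) {
  switch(rule$kind,
    WCA = {
      sr6 <- (rule$sigma / r)^6
      ifelse(r < 2^(1 / 6) * rule$sigma,
             4 * rule$eps * (sr6^2 - sr6) + rule$eps, 0)
    },
    MORSE = {
      ex <- exp(-rule$alpha * (r - rule$r_eq))
      rule$eps * (ex^2 - 2 * ex)
    },
    LJ = {
      sr6 <- (rule$sigma / r)^6
      4 * rule$eps * (sr6^2 - sr6)
    },
    stop("unknown rule kind: ", rule$kind))
}

#' @keywords internal
lookup_rule <- function(table, role_i, role_j) {
  key1 <- paste(role_i, role_j, sep = "|")
  key2 <- paste(role_j, role_i, sep = "|")
  if (!is.null(table$rules[[key1]])) table$rules[[key1]] else table$rules[[key2]]
}

#' Pairwise pseudoatom energy
#'
#' Evaluates the cut-and-shifted pair potential between two pseudoatom roles
#' at separation `r`.  Role pairs without a rule return 0.  The potential is
#' exactly 0 at and beyond the rule's cutoff and continuous there.
#'
#' @param table an [build_interaction_table()] object.
#' @param role_i,role_j pseudoatom role tags (e.g. `"A"`, `"T"`, `"B"`,
#'   `"EXCLUDER"`, `"Aa"`, `"Ab"`).
#' @param r separation(s); must be positive.
#' @return energy (vectorized over `r`).
#' @export
pair_energy <- function(table, role_i, role_j, r) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("separation 'r' must be positive and finite", call. = FALSE)
  }
  rule <- lookup_rule(table, role_i, role_j)
  if (is.null(rule)) return(rep(0, length(r)))
  e <- raw_pair_potential(rule, r) - rule$shift
  e[r >= rule$r_cut] <- 0
  e
}

# ---------------------------------------------------------------------------
# reference capsids

#' Assemble the complete reference capsid
#'
#' Places `N_cap` subunits (12 pentagons or 20 triangles) on the faces of the
#' regular dodecahedron or icosahedron so that every inter-subunit bond site
#' pair satisfies the trajectory-analysis bond criterion.  For the
#' dodecahedron the subunit vertex attractors coincide exactly at the shell's
#' vertices.  For the icosahedron the tiled shell is inflated radially so
#' that facing edge attractors sit at the Lennard-Jones minimum and the
#' excluder plates are tangent across each hinge.
#'
#' @param model `"dodecahedron"` or `"icosahedron"`.
#' @param template matching subunit template (defaults built if omitted).
#' @return an object of class `reference_capsid` with fields `centers`
#'   (N_cap x 3), `orientations` (N_cap x 4 unit quaternions), `N_cap`,
#'   `n_bonds_complete`, and `template`.
#' @export
assemble_reference_capsid <- function(model = c("dodecahedron", "icosahedron"),
                                      template = NULL) {
  model <- match.arg(model)
  if (is.null(template)) {
    template <- switch(model,
      dodecahedron = build_dodecahedron_subunit(),
      icosahedron  = build_icosahedron_subunit())
  }
  if (!identical(template$model, model)) {
    stop("template model does not match 'model'", call. = FALSE)
  }
  if (model == "dodecahedron") {
    l0 <- template$length_scale
    verts <- dodecahedron_vertices()
    scale <- template$geometry$edge / (2 / PHI)
    verts <- verts * scale
    faces <- solid_faces(verts, dodecahedron_face_normals(), 5)
    poses <- lapply(faces, function(f) {
      n <- f$normal
      ctr <- r_in_of(verts, f)                    # exact face center
      v1 <- verts[f$vertices[1], ]
      ex <- (v1 - ctr); ex <- ex / sqrt(sum(ex^2))
      ey <- cross3(n, ex)
      R <- cbind(ex, ey, n)
      # body A1 sits at (l0, 0, z_plane); body pentagon center at p0
      center <- ctr - drop(R %*% template$geometry$pentagon_center)
      list(center = center, q = matrix_to_quat(R))
    })
    N_cap <- 12L
  } else {
    sg <- template$length_scale
    verts <- icosahedron_vertices()
    # scale so face circumradius equals the template corner radius R_t
    scale <- template$geometry$R_t / (2 / sqrt(3))
    verts <- verts * scale
    faces <- solid_faces(verts, icosahedron_face_normals(), 3)
    # radial inflation so facing edge attractors sit at the LJ minimum
    beta <- (pi - template$geometry$dihedral) / 2
    delta <- 2^(1 / 6) * sg / (2 * sin(beta))
    poses <- lapply(faces, function(f) {
      n <- f$normal
      ctr <- r_in_of(verts, f) + delta * n
      v1 <- verts[f$vertices[1], ]
      ex <- v1 - r_in_of(verts, f); ex <- ex / sqrt(sum(ex^2))
      ey <- cross3(n, ex)
      R <- cbind(ex, ey, n)
      # template corner 1 is along body +y; rotate so corners map to face
      # vertices: body corner1 direction is (cos 90, sin 90) = +y
      # align body corner1 with (v1 - center) instead of +x
      ang <- pi / 2
      Rz <- matrix(c(cos(-ang), -sin(-ang), 0, sin(-ang), cos(-ang), 0,
                     0, 0, 1), 3, 3, byrow = TRUE)
      R <- R %*% Rz      # now body +y maps to ex direction
      list(center = ctr, q = matrix_to_quat(R))
    })
    N_cap <- 20L
  }
  centers <- do.call(rbind, lapply(poses, `[[`, "center"))
  quats <- do.call(rbind, lapply(poses, `[[`, "q"))
  structure(list(model = model, centers = centers, orientations = quats,
                 N_cap = N_cap, n_bonds_complete = 30L, template = template),
            class = "reference_capsid")
}

#' @keywords internal
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @keywords internal
r_in_of <- function(verts, face) {
  colMeans(verts[face$vertices, , drop = FALSE])
}

#' Estimate the capsid excluded-volume diameter
#'
#' Diameter of the sphere circumscribing all pseudoatoms of the reference
#' capsid, each extended by its repulsive radius.  Used as the default
#' capsid effective hard-sphere diameter for the icosahedron model (the
#' dodecahedron default follows the two-state theory convention, 5.1 l0).
#'
#' @param capsid a [assemble_reference_capsid()] object.
#' @return diameter (length units).
#' @export
capsid_diameter <- function(capsid) {
  tpl <- capsid$template
  rmax <- 0
  for (i in seq_len(capsid$N_cap)) {
    X <- quat_rotate(capsid$orientations[i, ], tpl$atoms$pos)
    X <- sweep(X, 2, capsid$centers[i, ], "+")
    rmax <- max(rmax, sqrt(rowSums(X^2)) + tpl$atoms$diameter / 2)
  }
  2 * rmax
}

# ---------------------------------------------------------------------------
# JSON serialization so engine and analyzers can share one definition file

#' Serialize a subunit template to JSON
#' @param template a `subunit_template`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @export
template_to_json <- function(template, path = NULL) {
  x <- list(model = template$model, length_scale = template$length_scale,
            label = template$atoms$label, role = template$atoms$role,
            pos = template$atoms$pos, diameter = template$atoms$diameter)
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Rebuild a subunit template from JSON
#'
#' The template is reconstructed by calling the matching builder at the
#' serialized length scale, then checked against the serialized pseudoatom
#' positions.
#' @param path file path or JSON string produced by [template_to_json()].
#' @export
template_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  tpl <- switch(x$model,
    dodecahedron = build_dodecahedron_subunit(x$length_scale),
    icosahedron  = build_icosahedron_subunit(x$length_scale),
    stop("unknown model in JSON: ", x$model))
  if (max(abs(tpl$atoms$pos - x$pos)) > 1e-8) {
    stop("serialized template does not match builder geometry", call. = FALSE)
  }
  tpl
}
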