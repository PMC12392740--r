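# Shared model objects (built once per test run) and an independent
# brute-force force/energy oracle written in R.

tpl_dodeca <- build_dodecahedron_subunit()
tpl_icosa <- build_icosahedron_subunit()
tab_dodeca6 <- build_interaction_table("dodecahedron", eps_ss = 6,
                                       template = tpl_dodeca)
tab_dodeca0 <- build_interaction_table("dodecahedron", eps_ss = 0,
                                       template = tpl_dodeca)
tab_icosa6 <- build_interaction_table("icosahedron", eps_ss = 6,
                                      template = tpl_icosa)
ref_dodeca <- assemble_reference_capsid("dodecahedron", tpl_dodeca)
ref_icosa <- assemble_reference_capsid("icosahedron", tpl_icosa)

# all-pairs force/torque/energy oracle, independent of the engine: loops
# over every pseudoatom pair of every body pair and evaluates the pair
# potentials directly
brute_forces <- function(state, table, spec = NULL) {
  tpl <- state$template
  N <- nrow(state$centers)
  L <- state$box_L
  roles <- tpl$atoms$role
  n_at <- nrow(tpl$atoms$pos)
  world <- lapply(seq_len(N), function(i) {
    sweep(condcap:::quat_rotate(state$orientations[i, ], tpl$atoms$pos), 2,
          state$centers[i, ], "+")
  })
  F <- matrix(0, N, 3); Tau <- matrix(0, N, 3); E <- 0
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    for (a in seq_len(n_at)) for (b in seq_len(n_at)) {
      rl <- condcap:::lookup_rule(table, roles[a], roles[b])
      if (is.null(rl) || rl$eps == 0) next
      d <- world[[i]][a, ] - world[[j]][b, ]
      d <- d - L * round(d / L)
      r <- sqrt(sum(d^2))
      if (r >= rl$r_cut) next
      if (rl$kind == "WCA") {
        sr6 <- (rl$sigma / r)^6
        E <- E + 4 * rl$eps * (sr6^2 - sr6) + rl$eps
        dEdr <- -24 * rl$eps * (2 * sr6^2 - sr6) / r
      } else if (rl$kind == "MORSE") {
        ex <- exp(-rl$alpha * r)
        E <- E + rl$eps * (ex^2 - 2 * ex) - rl$shift
        dEdr <- 2 * rl$alpha * rl$eps * (ex - ex^2)
      } else {
        sr6 <- (rl$sigma / r)^6
        E <- E + 4 * rl$eps * (sr6^2 - sr6) - rl$shift
        dEdr <- -24 * rl$eps * (2 * sr6^2 - sr6) / r
      }
      fa <- -dEdr * d / r
      F[i, ] <- F[i, ] + fa
      F[j, ] <- F[j, ] - fa
      Tau[i, ] <- Tau[i, ] + cross3_vec(world[[i]][a, ] - state$centers[i, ], fa)
      Tau[j, ] <- Tau[j, ] + cross3_vec(world[[j]][b, ] - state$centers[j, ], -fa)
    }
  }
  if (!is.null(spec) && spec$eps_c > 0) {
    E <- E + sum(condensate_potential(spec, sqrt(rowSums(state$centers^2))))
    F <- F + condensate_force(spec, state$centers)
  }
  list(forces = F, torques = Tau, energy = E)
}

cross3_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
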