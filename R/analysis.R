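# Trajectory analytics: bond graphs, cluster taxonomy, yields, partition
# coefficients, median assembly times and maximum assembly rates.
#
# Bond criteria follow the cluster analysis used for these models:
# dodecahedron subunits are bonded when two pentagon edge midpoints are
# within 0.3 l0 (minimum image); icosahedron subunits when both
# complementary attractor pairs of a shared edge are within 1.3 sigma.

DODECA_BOND_CUT <- 0.3
ICOSA_BOND_CUT <- 1.3

#' Detect subunit-subunit bonds in a configuration
#'
#' @param state a `system_state`.
#' @param model model tag; defaults to the state's template model.
#' @return an object of class `bond_graph`: fields `n`, `edges` (m x 2),
#'   `N_cap`, `max_degree`, `model`.  Each subunit edge participates in at
#'   most one bond (nearest partner wins).
#' @export
detect_bonds <- function(state, model = NULL) {
  tpl <- state$template
  if (is.null(model)) model <- tpl$model
  if (!identical(model, tpl$model)) {
    stop("state template does not match 'model'", call. = FALSE)
  }
  N <- nrow(state$centers)
  L <- state$box_L
  if (model == "dodecahedron") {
    n_sites <- 5L
    cut <- DODECA_BOND_CUT
    sites_body <- tpl$edge_sites
  } else {
    n_sites <- 3L
    cut <- ICOSA_BOND_CUT
  }
  # candidate body pairs from a center-distance prefilter
  reach <- 2 * tpl$circumradius + cut
  cand <- body_pairs_within(state$centers, L, reach)
  matches <- NULL
  if (model == "dodecahedron" && nrow(cand) > 0) {
    site_w <- lapply(seq_len(N), function(i) {
      sweep(quat_rotate(state$orientations[i, ], sites_body), 2,
            state$centers[i, ], "+")
    })
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      d <- site_pair_dists(site_w[[i]], site_w[[j]], L)
      hits <- which(d < cut, arr.ind = TRUE)
      if (nrow(hits) > 0) {
        matches <- rbind(matches, cbind(i, hits[, 1], j, hits[, 2],
                                        d[hits]))
      }
    }
  } else if (nrow(cand) > 0) {
    atoms <- tpl$atoms
    a_idx <- unlist(lapply(tpl$edge_attr, `[`, 1))  # 'Aa' per edge
    b_idx <- unlist(lapply(tpl$edge_attr, `[`, 2))  # 'Ab' per edge
    pa_w <- lapply(seq_len(N), function(i) {
      sweep(quat_rotate(state$orientations[i, ],
                        atoms$pos[a_idx, , drop = FALSE]), 2,
            state$centers[i, ], "+")
    })
    pb_w <- lapply(seq_len(N), function(i) {
      sweep(quat_rotate(state$orientations[i, ],
                        atoms$pos[b_idx, , drop = FALSE]), 2,
            state$centers[i, ], "+")
    })
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      dab <- site_pair_dists(pa_w[[i]], pb_w[[j]], L)  # Aa_i vs Ab_j
      dba <- site_pair_dists(pb_w[[i]], pa_w[[j]], L)  # Ab_i vs Aa_j
      for (ei in 1:3) for (ej in 1:3) {
        if (dab[ei, ej] < cut && dba[ei, ej] < cut) {
          matches <- rbind(matches,
                           cbind(i, ei, j, ej, dab[ei, ej] + dba[ei, ej]))
        }
      }
    }
  }
  edges <- matrix(integer(0), 0, 2)
  if (!is.null(matches) && nrow(matches) > 0) {
    matches <- matches[order(matches[, 5]), , drop = FALSE]
    used <- character(0)
    for (r in seq_len(nrow(matches))) {
      ki <- paste(matches[r, 1], matches[r, 2])
      kj <- paste(matches[r, 3], matches[r, 4])
      if (ki %in% used || kj %in% used) next
      used <- c(used, ki, kj)
      edges <- rbind(edges, matches[r, c(1, 3)])
    }
    # collapse duplicate body pairs (distinct edge pairs of one body pair)
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  structure(list(n = N, edges = edges, model = model,
                 N_cap = if (model == "dodecahedron") 12L else 20L,
                 max_degree = tpl$n_bond_sites),
            class = "bond_graph")
}

#' @keywords internal
body_pairs_within <- function(centers, L, reach) {
  N <- nrow(centers)
  if (N < 2) return(matrix(integer(0), 0, 2))
  idx <- t(utils::combn(N, 2))
  d <- centers[idx[, 1], , drop = FALSE] - centers[idx[, 2], , drop = FALSE]
  d <- d - L * round(d / L)
  idx[rowSums(d^2) < reach^2, , drop = FALSE]
}

# all pairwise min-image distances between two site sets (rows)
#' @keywords internal
site_pair_dists <- function(A, B, L) {
  nA <- nrow(A); nB <- nrow(B)
  d2 <- matrix(0, nA, nB)
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    dk <- dk - L * round(dk / L)
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

#' Connected clusters and their taxonomy
#'
#' Partitions subunits into connected components of the bond graph and
#' classifies them: a cluster is *complete* when it has exactly `N_cap`
#' subunits and every subunit carries the maximal bond count (5 or 3);
#' a *dangler* has `N_cap` subunits but fewer bonds; *malformed* clusters
#' are danglers, clusters larger than `N_cap`, or clusters containing an
#' over-bonded subunit.
#'
#' @param graph a [detect_bonds()] result.
#' @param state optional `system_state` for centroids and condensate
#'   membership.
#' @param R_c optional condensate radius (with `state`): clusters are
#'   assigned to the condensate when their minimum-image centroid lies
#'   within `R_c` of the box center.
#' @return an object of class `cluster_report`.
#' @export
find_clusters <- function(graph, state = NULL, R_c = NULL) {
  N <- graph$n
  if (nrow(graph$edges) > 0) {
    g <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, N - igraph::vcount(g)))
    membership <- igraph::components(g)$membership
    degree <- igraph::degree(g)
  } else {
    membership <- seq_len(N)
    degree <- rep(0L, N)
  }
  sizes <- tabulate(membership)
  n_clust <- length(sizes)
  bonds_per_cluster <- rep(0L, n_clust)
  if (nrow(graph$edges) > 0) {
    ec <- membership[graph$edges[, 1]]
    bonds_per_cluster <- tabulate(ec, nbins = n_clust)
  }
  max_deg_cluster <- vapply(seq_len(n_clust), function(cl) {
    max(degree[membership == cl])
  }, numeric(1))
  min_deg_cluster <- vapply(seq_len(n_clust), function(cl) {
    min(degree[membership == cl])
  }, numeric(1))
  N_cap <- graph$N_cap; max_deg <- graph$max_degree
  complete <- sizes == N_cap & min_deg_cluster == max_deg &
    max_deg_cluster == max_deg
  dangler <- sizes == N_cap & !complete
  malformed <- dangler | sizes > N_cap | max_deg_cluster > max_deg

  centroid <- matrix(NA_real_, n_clust, 3)
  in_condensate <- rep(NA, n_clust)
  if (!is.null(state)) {
    L <- state$box_L
    for (cl in seq_len(n_clust)) {
      mem <- which(membership == cl)
      anchor <- state$centers[mem[1], ]
      d <- sweep(state$centers[mem, , drop = FALSE], 2, anchor)
      d <- d - L * round(d / L)
      ctr <- anchor + colMeans(d)
      ctr <- ctr - L * round(ctr / L)
      centroid[cl, ] <- ctr
    }
    if (!is.null(R_c)) {
      in_condensate <- sqrt(rowSums(centroid^2)) < R_c
    }
  }
  structure(list(
    membership = membership, degree = degree,
    cluster_sizes = sizes, bonds = bonds_per_cluster,
    complete = complete, dangler = dangler, malformed = malformed,
    n_complete = sum(complete), n_danglers = sum(dangler),
    n_malformed = sum(malformed),
    centroid = centroid, in_condensate = in_condensate,
    N = N, N_cap = N_cap, max_degree = max_deg
  ), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf(paste0("<cluster_report: %d subunits, %d clusters, ",
                     "%d complete, %d danglers, %d malformed>\n"),
              x$N, length(x$cluster_sizes), x$n_complete, x$n_danglers,
              x$n_malformed))
  invisible(x)
}

#' Capsid yields from a cluster report
#'
#' `f_c = N_cap * rho_cap / rho_T` with `rho_cap = n_complete / V` and
#' `rho_T = N / V`; the condensate and background components use the
#' complete-capsid centroid positions, so `f_c = f_c_c + f_c_bg` holds
#' exactly.
#'
#' @param report a [find_clusters()] result (with condensate membership for
#'   the split; otherwise the split is all-background).
#' @param N total subunits.
#' @param V total volume.
#' @param V_c condensate volume.
#' @return list with `f_c`, `f_c_c`, `f_c_bg`, `rho_cap`.
#' @export
compute_yields <- function(report, N, V, V_c = 0) {
  n_complete <- report$n_complete
  inside <- report$in_condensate & report$complete
  n_in <- if (all(is.na(report$in_condensate))) 0L else sum(inside, na.rm = TRUE)
  n_out <- n_complete - n_in
  f_c_c <- report$N_cap * n_in / N
  f_c_bg <- report$N_cap * n_out / N
  list(f_c = f_c_c + f_c_bg, f_c_c = f_c_c, f_c_bg = f_c_bg,
       rho_cap = n_complete / V)
}

#' Measured monomer partition coefficient
#'
#' `K_c = rho_1^c / rho_1^bg` where monomers are clusters of size 1 and the
#' condensate is the sphere of radius `R_c` at the box center.  When the
#' background holds no monomers a flagged sentinel (`K_c = Inf`,
#' `flagged = TRUE`) is returned rather than an error.
#'
#' @param state a `system_state`.
#' @param R_c condensate radius.
#' @param report optional precomputed [find_clusters()] report.
#' @return list with `K_c`, `rho1_c`, `rho1_bg`, `n_monomer`, `flagged`.
#' @export
measure_partition_coefficient <- function(state, R_c, report = NULL) {
  if (is.null(report)) {
    report <- find_clusters(detect_bonds(state), state = state, R_c = R_c)
  }
  L <- state$box_L
  V_c <- 4 / 3 * pi * R_c^3
  V_bg <- L^3 - V_c
  mono_clusters <- which(report$cluster_sizes == 1)
  mono_members <- which(report$membership %in% mono_clusters)
  r <- sqrt(rowSums(state$centers[mono_members, , drop = FALSE]^2))
  n_in <- sum(r < R_c)
  n_out <- length(mono_members) - n_in
  rho1_c <- n_in / V_c
  rho1_bg <- n_out / V_bg
  flagged <- rho1_bg == 0
  list(K_c = if (flagged) Inf else rho1_c / rho1_bg,
       rho1_c = rho1_c, rho1_bg = rho1_bg,
       n_monomer = length(mono_members), flagged = flagged)
}

#' Fraction of subunits in malformed (off-target) clusters
#'
#' @param report a [find_clusters()] result.
#' @param N total subunits.
#' @return fraction in [0, 1].
#' @export
off_target_fraction <- function(report, N) {
  mal_clusters <- which(report$malformed)
  sum(report$cluster_sizes[mal_clusters]) / N
}

#' Per-frame assembly time series of a trajectory
#'
#' Applies bond detection, clustering, yields and the measured partition
#' coefficient to every `every`-th frame.
#'
#' @param traj a `trajectory`.
#' @param R_c condensate radius (defaults to the trajectory's condensate).
#' @param every analyze every n-th frame (default 1).
#' @return data.frame with columns `time`, `f_c`, `f_c_c`, `f_c_bg`,
#'   `K_c_meas`, `rho1_c`, `rho1_bg`, `mean_cluster_size`,
#'   `off_target_fraction`, `n_complete`, `n_danglers`.
#' @export
analyze_trajectory <- function(traj, R_c = NULL, every = 1L) {
  if (is.null(R_c)) {
    R_c <- if (!is.null(traj$condensate)) traj$condensate$R_c else
      stop("'R_c' required: trajectory has no condensate", call. = FALSE)
  }
  N <- dim(traj$x)[2]
  V <- traj$box_L^3
  V_c <- 4 / 3 * pi * R_c^3
  frames <- seq(1, length(traj$times), by = every)
  if (frames[length(frames)] != length(traj$times)) {
    frames <- c(frames, length(traj$times))
  }
  rows <- lapply(frames, function(f) {
    st <- frame_state(traj, f)
    gr <- detect_bonds(st)
    rep_ <- find_clusters(gr, state = st, R_c = R_c)
    yl <- compute_yields(rep_, N, V, V_c)
    kc <- measure_partition_coefficient(st, R_c, report = rep_)
    data.frame(time = traj$times[f], f_c = yl$f_c, f_c_c = yl$f_c_c,
               f_c_bg = yl$f_c_bg, K_c_meas = kc$K_c,
               rho1_c = kc$rho1_c, rho1_bg = kc$rho1_bg,
               mean_cluster_size = mean(rep_$cluster_sizes),
               off_target_fraction = off_target_fraction(rep_, N),
               n_complete = rep_$n_complete, n_danglers = rep_$n_danglers)
  })
  do.call(rbind, rows)
}

#' Median assembly time of a yield series
#'
#' Earliest time at which the yield reaches half its final value, linearly
#' interpolated between snapshots.
#'
#' @param series data.frame with columns `time` and `f_c` (e.g. from
#'   [analyze_trajectory()]).
#' @return median assembly time.
#' @export
median_assembly_time <- function(series) {
  t <- series$time; f <- series$f_c
  f_final <- f[length(f)]
  if (f_final <= 0) {
    stop("median assembly time undefined: final yield is zero", call. = FALSE)
  }
  target <- f_final / 2
  i <- which(f >= target)[1]
  if (i == 1) return(t[1])
  t[i - 1] + (target - f[i - 1]) / (f[i] - f[i - 1]) * (t[i] - t[i - 1])
}

#' Maximum assembly rate of a yield series
#'
#' Convolves `f_c(t)` with the first derivative of a Gaussian
#' (reflect-padded) and returns the maximum of the smoothed derivative; an
#' estimate of the peak (initial) nucleation-driven assembly rate.
#'
#' @param series data.frame with `time` and `f_c` on a uniform grid.
#' @param width Gaussian width (time units); default 10 snapshot intervals.
#' @return maximum smoothed rate.
#' @export
max_assembly_rate <- function(series, width = NULL) {
  t <- series$time; f <- series$f_c
  n <- length(t)
  if (n < 5) stop("insufficient data: need at least 5 snapshots",
                  call. = FALSE)
  h <- t[2] - t[1]
  if (max(abs(diff(t) - h)) > 1e-6 * h) {
    stop("series must be on a uniform time grid", call. = FALSE)
  }
  if (is.null(width)) width <- 10 * h
  m <- max(3L, ceiling(4 * width / h))
  s <- (-m):m
  w <- (-(s * h) / width^2) * exp(-(s * h)^2 / (2 * width^2)) /
    (sqrt(2 * pi) * width) * h
  # reflect padding
  fp <- c(f[(m + 1):2], f, f[(n - 1):(n - m)])
  deriv <- vapply(seq_len(n), function(i) {
    sum(w * fp[(i):(i + 2 * m)][(2 * m + 1):1])
  }, numeric(1))
  max(deriv)
}

#' Mean and twice the standard error over replicate observables
#'
#' @param values numeric vector (one value per replicate).
#' @return list with `mean`, `sem2` (twice the standard error of the mean),
#'   `n`.
#' @export
replicate_stats <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  m <- mean(values)
  sem <- if (n > 1) stats::sd(values) / sqrt(n) else NA_real_
  list(mean = m, sem2 = 2 * sem, n = n)
}
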