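# Closed-form kinetic estimates for condensate-coupled assembly: the
# characteristic time for subunit diffusion into the condensate, the
# nucleation speedup from partitioning, and the resulting median assembly
# time.  These are scaling estimates, not rate-equation integrations.

#' Characteristic subunit diffusion time into the condensate
#'
#' `tau_D = [V_c / (V_r + 1/K_c) + f_c * V_tot] / (4 pi R_c D)`.
#' The first numerator term accounts for diffusion of free subunits, the
#' second for subunits that eventually assemble into capsids; the
#' denominator is the Smoluchowski diffusive flux factor onto a sphere of
#' radius `R_c`.
#'
#' @param params list (or [kinetics_params()]) with `V_c`, `V_r`, `K_c`,
#'   `f_c`, `V_tot`, `R_c`, `D`.
#' @return diffusion time scale.
#' @export
diffusion_time <- function(params) {
  p <- params
  stopifnot(p$V_c > 0, p$V_r > 0, p$K_c > 0, p$R_c > 0, p$D > 0,
            p$f_c >= 0, p$V_tot > 0)
  (p$V_c / (p$V_r + 1 / p$K_c) + p$f_c * p$V_tot) / (4 * pi * p$R_c * p$D)
}

#' Nucleation speedup from condensate partitioning
#'
#' `s_nuc = V_r * (V_r + 1/K_c)^(-n_nuc)` for `V_r << 1`: the factor by
#' which partitioning into a small condensate accelerates nucleation, with
#' `n_nuc` the critical nucleus size.  For strong partitioning
#' (`K_c -> Inf`) this tends to `V_r^(1 - n_nuc) >> 1`.
#'
#' @param V_r condensate volume ratio (warn if > 0.2; the scaling assumes
#'   `V_r << 1`).
#' @param K_c partition coefficient (equilibrium or measured).
#' @param n_nuc critical nucleus size (>= 2); default 5 (dodecahedron).
#' @return speedup factor.
#' @export
nucleation_speedup <- function(V_r, K_c, n_nuc = 5) {
  if (n_nuc < 2) stop("'n_nuc' must be >= 2", call. = FALSE)
  if (any(V_r <= 0) || any(K_c <= 0)) {
    stop("'V_r' and 'K_c' must be positive", call. = FALSE)
  }
  if (any(V_r > 0.2)) {
    warning("V_r > 0.2: the nucleation-speedup scaling assumes V_r << 1",
            call. = FALSE)
  }
  V_r * (V_r + 1 / K_c)^(-n_nuc)
}

#' Median assembly time with condensate coupling
#'
#' `tau_1/2 = tau_1/2^0 / s_nuc + tau_D / 2`, where `tau_1/2^0` is the
#' median assembly time without phase separation.  The diffusion term is a
#' floor: for strong partitioning the median time saturates at `tau_D / 2`.
#'
#' @param tau_half_0 median assembly time without phase separation.
#' @param s_nuc nucleation speedup ([nucleation_speedup()]).
#' @param tau_D diffusion time ([diffusion_time()]).
#' @return median assembly time estimate.
#' @export
median_time <- function(tau_half_0, s_nuc, tau_D) {
  if (any(tau_half_0 <= 0) || any(s_nuc <= 0) || any(tau_D < 0)) {
    stop("'tau_half_0' and 's_nuc' must be positive, 'tau_D' non-negative",
         call. = FALSE)
  }
  tau_half_0 / s_nuc + tau_D / 2
}

#' Bundle kinetics inputs
#'
#' @param D subunit diffusion constant (defaults to the Einstein value 1/gamma
#'   should be replaced by the engine-measured value where available).
#' @param R_c condensate radius.
#' @param V_c condensate volume (computed from `R_c` if omitted).
#' @param V_r condensate volume ratio.
#' @param V_tot total volume (computed from `V_c`, `V_r` if omitted).
#' @param K_c partition coefficient.
#' @param f_c final yield fraction.
#' @param n_nuc critical nucleus size.
#' @param tau_half_0 median assembly time without phase separation.
#' @return list of validated kinetics parameters.
#' @export
kinetics_params <- function(D = 1, R_c, V_c = NULL, V_r, V_tot = NULL, K_c,
                            f_c = 0, n_nuc = 5, tau_half_0 = NULL) {
  if (is.null(V_c)) V_c <- 4 / 3 * pi * R_c^3
  if (is.null(V_tot)) V_tot <- V_c * (1 + V_r) / V_r
  p <- list(D = D, R_c = R_c, V_c = V_c, V_r = V_r, V_tot = V_tot,
            K_c = K_c, f_c = f_c, n_nuc = n_nuc, tau_half_0 = tau_half_0)
  stopifnot(p$D > 0, p$R_c > 0, p$V_c > 0, p$V_r > 0, p$K_c > 0,
            p$n_nuc >= 2)
  p
}

#' Full kinetic report
#'
#' Evaluates the diffusion time, nucleation speedup and median-time
#' estimates for one parameter set.
#'
#' @param params a [kinetics_params()] with non-NULL `tau_half_0`.
#' @return list with `tau_D`, `s_nuc`, `tau_half`.
#' @export
kinetics_report <- function(params) {
  tau_D <- diffusion_time(params)
  s_nuc <- nucleation_speedup(params$V_r, params$K_c, params$n_nuc)
  tau_half <- if (is.null(params$tau_half_0)) NA_real_ else
    median_time(params$tau_half_0, s_nuc, tau_D)
  list(tau_D = tau_D, s_nuc = s_nuc, tau_half = tau_half)
}
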