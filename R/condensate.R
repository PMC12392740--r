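# The implicit condensate: a spherical potential well pinned at the box
# center.  Inside radius R_c the potential is flat at -eps_c; outside it
# rises to zero over a length 1/alpha_C via a Morse-like tail, so forces at
# the boundary stay bounded (|F| <= alpha_C * eps_c / 2).

#' Define an implicit condensate
#'
#' @param R_c condensate radius (length units). Exactly one of `R_c` or
#'   `V_r` must be given; with `V_r`, `R_c` is derived from the box length
#'   `L` so that the condensate/background volume ratio equals `V_r`.
#' @param eps_c well depth (kT, >= 0). `eps_c = 0` disables the field (bulk
#'   control).
#' @param alpha_C decay rate of the exterior tail (1/length). The default,
#'   10 per unit length, keeps the boundary layer much thinner than the
#'   condensate (a warning is issued if `alpha_C * R_c < 10`).
#' @param V_r condensate-to-background volume ratio (alternative to `R_c`).
#' @param L box edge length, required when `V_r` is given.
#' @return an object of class `condensate_spec` with fields `R_c`, `eps_c`,
#'   `alpha_C`, `center`.
#' @export
condensate_spec <- function(R_c = NULL, eps_c = 0, alpha_C = 10, V_r = NULL,
                            L = NULL) {
  if (is.null(R_c) == is.null(V_r)) {
    stop("exactly one of 'R_c' or 'V_r' must be given", call. = FALSE)
  }
  if (!is.null(V_r)) {
    if (is.null(L)) stop("'L' is required when specifying 'V_r'", call. = FALSE)
    if (V_r <= 0) stop("'V_r' must be positive", call. = FALSE)
    # V_c = V_r/(1+V_r) * L^3
    V_c <- V_r / (1 + V_r) * L^3
    R_c <- (3 * V_c / (4 * pi))^(1 / 3)
  }
  if (!is.numeric(R_c) || R_c <= 0) stop("'R_c' must be positive", call. = FALSE)
  if (eps_c < 0) stop("'eps_c' must be >= 0", call. = FALSE)
  if (alpha_C <= 0) stop("'alpha_C' must be positive", call. = FALSE)
  if (alpha_C * R_c < 10) {
    warning("alpha_C * R_c < 10: the boundary layer is not thin compared ",
            "with the condensate radius", call. = FALSE)
  }
  structure(list(R_c = R_c, eps_c = eps_c, alpha_C = alpha_C,
                 center = c(0, 0, 0)), class = "condensate_spec")
}

#' Condensate potential
#'
#' `u_c(r) = -eps_c` for `r < R_c` and
#' `-eps_c * (2 exp(-alpha_C (r - R_c)) - exp(-2 alpha_C (r - R_c)))` for
#' `r >= R_c`: continuous at `R_c`, monotone non-decreasing outside, and
#' bounded in `[-eps_c, 0]`.
#'
#' @param spec a [condensate_spec()].
#' @param r distance(s) from the condensate center; must be >= 0.
#' @return potential energy (vectorized over `r`).
#' @export
condensate_potential <- function(spec, r) {
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("'r' must be non-negative and finite", call. = FALSE)
  }
  ex <- exp(-spec$alpha_C * pmax(r - spec$R_c, 0))
  -spec$eps_c * (2 * ex - ex^2)
}

#' Condensate force on a subunit center
#'
#' Radial force `-du_c/dr * r_hat`; exactly zero inside the condensate and
#' decaying to zero far outside.  The field couples once per subunit at its
#' center of mass, so a cluster of n subunits gains `n * eps_c` by entering
#' the condensate.
#'
#' @param spec a [condensate_spec()].
#' @param position 3-vector or n x 3 matrix of positions.
#' @return force with the same shape as `position`.
#' @export
condensate_force <- function(spec, position) {
  X <- matrix(position, ncol = 3)
  r <- sqrt(rowSums(X^2))
  out <- matrix(0, nrow(X), 3)
  mask <- r > spec$R_c & r > 0
  if (any(mask)) {
    ex <- exp(-spec$alpha_C * (r[mask] - spec$R_c))
    # du/dr = 2 alpha eps ex (1 - ex) >= 0 ; force is -du/dr, inward
    dudr <- 2 * spec$alpha_C * spec$eps_c * ex * (1 - ex)
    out[mask, ] <- X[mask, , drop = FALSE] * (-dudr / r[mask])
  }
  if (is.null(dim(position))) drop(out) else out
}

#' Condensate, background and ratio volumes
#'
#' @param spec a [condensate_spec()].
#' @param L periodic box edge length; the condensate must fit without
#'   touching its periodic images (`2 R_c < L`).
#' @return list with `V_c = (4/3) pi R_c^3`, `V_bg = L^3 - V_c`, and
#'   `V_r = V_c / V_bg`.
#' @export
condensate_volumes <- function(spec, L) {
  if (2 * spec$R_c >= L) {
    stop("condensate does not fit in the box: 2*R_c >= L", call. = FALSE)
  }
  V_c <- 4 / 3 * pi * spec$R_c^3
  V_bg <- L^3 - V_c
  list(V_c = V_c, V_bg = V_bg, V_r = V_c / V_bg)
}
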