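# Balloon haemodynamic model and BOLD observation equation.

#' Haemodynamic parameters
#'
#' Effective values are fixed scales multiplied by `exp(theta)`:
#' signal decay eta = 0.64*exp(theta), flow-dependent elimination
#' chi = 0.32 (fixed), transit time tau_h = 2.00*exp(theta), Grubb's
#' exponent alpha = 0.32 (fixed), intra:extravascular ratio
#' epsilon = exp(theta), resting oxygen extraction E0 = 0.40 (fixed) and
#' resting blood volume fraction V0 = 0.08.
#'
#' @param theta_eta,theta_tauh,theta_epsilon log-scaling parameters, scalars
#'   or per-region vectors.
#' @param n_regions number of regions (recycled over scalars).
#' @param V0 resting blood volume fraction (default 0.08; newer estimates
#'   near 0.05 can be supplied).
#' @return object of class `haemo_parameters`: list of per-region effective
#'   values `eta`, `chi`, `tauh`, `alpha`, `epsilon`, `E0` and scalar `V0`.
#' @export
haemo_parameters <- function(theta_eta = 0, theta_tauh = 0,
                             theta_epsilon = 0, n_regions = 1L, V0 = 0.08) {
  rp <- function(x) rep_len(x, n_regions)
  structure(list(eta = 0.64 * exp(rp(theta_eta)),
                 chi = rp(0.32),
                 tauh = 2.00 * exp(rp(theta_tauh)),
                 alpha = rp(0.32),
                 epsilon = 1.00 * exp(rp(theta_epsilon)),
                 E0 = rp(0.40),
                 V0 = V0, n_regions = n_regions),
            class = "haemo_parameters")
}

#' Haemodynamic prior blocks
#'
#' The estimated haemodynamic parameters are the log-scalings of signal
#' decay, transit time and the intra:extravascular ratio, each with prior
#' N(0, 1/256) per region; the remaining parameters are fixed.
#'
#' @param n_regions number of regions.
#' @return named list of prior blocks.
#' @export
haemo_priors <- function(n_regions) {
  blk <- function() list(mean = rep(0, n_regions),
                         variance = rep(1 / 256, n_regions))
  list(theta_eta = blk(), theta_tauh = blk(), theta_epsilon = blk())
}

#' BOLD observation coefficients
#'
#' `k1 = 6.9*E0`, `k2 = epsilon*E0`, `k3 = 1 - epsilon`; always recomputed
#' from the current parameters.
#'
#' @param params a `haemo_parameters`.
#' @param region region index.
#' @return named vector (k1, k2, k3).
#' @export
bold_coefficients <- function(params, region = 1L) {
  c(k1 = 6.9 * params$E0[region],
    k2 = params$epsilon[region] * params$E0[region],
    k3 = 1 - params$epsilon[region])
}

#' Balloon-model state derivatives (single region)
#'
#' State `(hs, hin, hv, hq)`: vasodilatory signal, inflow, venous volume and
#' deoxyhaemoglobin, all relative to rest `(0, 1, 1, 1)`.  Implements
#' d(hs) = z - eta*hs - chi*(hin - 1); d(hin) = hs;
#' d(hv) = (hin - hv^(1/alpha)) / tau;
#' d(hq) = (hin*(1 - (1 - E0)^(1/hin))/E0 - hv^(1/alpha)*hq/hv) / tau.
#'
#' @param state numeric 4-vector (hs, hin, hv, hq).
#' @param z neurovascular signal value.
#' @param params a `haemo_parameters`.
#' @param region region index.
#' @return derivative 4-vector.
#' @export
haemo_derivatives <- function(state, z, params, region = 1L) {
  hs <- state[1]; hin <- state[2]; hv <- state[3]; hq <- state[4]
  if (hin <= 0 || hv <= 0 || hq <= 0)
    stop("inflow, volume and dHb must stay positive")
  eta <- params$eta[region]; chi <- params$chi[region]
  tauh <- params$tauh[region]; alpha <- params$alpha[region]
  E0 <- params$E0[region]
  fout <- hv^(1 / alpha)
  extraction <- hin * (1 - (1 - E0)^(1 / hin)) / E0
  c(z - eta * hs - chi * (hin - 1),
    hs,
    (hin - fout) / tauh,
    (extraction - fout * hq / hv) / tauh)
}

#' BOLD observation equation
#'
#' `y = V0 * (k1*(1 - hq) + k2*(1 - hq/hv) + k3*(1 - hv))`; zero at rest.
#'
#' @param hv,hq venous volume and deoxyhaemoglobin (vectorised).
#' @param params a `haemo_parameters`.
#' @param region region index.
#' @export
bold_observation <- function(hv, hq, params, region = 1L) {
  if (any(hv <= 0)) stop("venous volume must be positive")
  k <- bold_coefficients(params, region)
  params$V0 * (k[["k1"]] * (1 - hq) + k[["k2"]] * (1 - hq / hv) +
               k[["k3"]] * (1 - hv))
}

#' Predict region-wise BOLD from neurovascular signals
#'
#' Integrates the Balloon model from rest over the run (RK4 at the microtime
#' step, with inflow/volume/dHb integrated in log space so positivity is
#' structural) and applies the BOLD observation equation, then samples at
#' the repetition time (scan times `0, TR, 2 TR, ...`).
#'
#' @param z matrix (n_micro x regions) of neurovascular signals on the
#'   microtime grid.
#' @param params a `haemo_parameters` with one entry per region.
#' @param dt microtime step (s).
#' @param TR repetition time (s); set `TR = NULL` to return the full
#'   microtime BOLD series.
#' @return matrix (n_scans x regions) of BOLD values (attribute `time`
#'   holds the scan times).
#' @export
predict_bold <- function(z, params, dt, TR = NULL) {
  z <- as.matrix(z)
  res <- .balloon_integrate_cpp(z, dt, params$eta, params$chi, params$tauh,
                                params$alpha, params$E0, params$epsilon,
                                params$V0)
  if (!isTRUE(res$finite))
    stop("Balloon integration diverged; parameters: eta=",
         paste(signif(params$eta, 3), collapse = ","), " tauh=",
         paste(signif(params$tauh, 3), collapse = ","))
  y <- res$y
  if (is.null(TR)) {
    attr(y, "time") <- (seq_len(nrow(y)) - 1) * dt
    return(y)
  }
  step <- TR / dt
  if (abs(step - round(step)) > 1e-9) stop("TR must be a multiple of dt")
  idx <- seq(1, nrow(y), by = as.integer(round(step)))
  out <- y[idx, , drop = FALSE]
  attr(out, "time") <- (idx - 1) * dt
  out
}
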