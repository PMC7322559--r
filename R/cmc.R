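#' @useDynLib mmdcm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd setNames convolve quantile
#' @importFrom utils read.delim write.table read.csv write.csv modifyList
NULL

# canonical population order used throughout
.POPS <- c("ss", "sp", "ii", "dp")

# intrinsic connection names, matching the order expected by the compiled
# derivative function (self-inhibition entries are 1, 4, 7, 11)
.INTRINSIC <- c("ss_ss", "sp_ss", "ii_ss",
                "sp_sp", "ss_sp", "ii_sp",
                "ii_ii", "dp_ii", "ss_ii", "sp_ii",
                "dp_dp", "ii_dp", "sp_dp")
.INTRINSIC_SELF <- c(1L, 4L, 7L, 11L)

# prior scales of the neuronal model: postsynaptic rate constants per
# population and intrinsic gain scales.  The published scale vector
# a = [2 1 1 1] * 512 is mapped so that the spiny-stellate self-inhibition
# takes the doubled scale and every other intrinsic connection the base
# scale; both vectors can be overridden through `cmc_scales()`.
.KAPPA_SCALE <- c(ss = 256, sp = 128, ii = 16, dp = 32)
.A_SCALE_SELF_SS <- 2 * 512
.A_SCALE_OTHER <- 512

#' Default scale constants of the neuronal model
#'
#' Returns the fixed scale constants multiplied by `exp(theta)` to give the
#' effective rate constants and intrinsic gains.  `kappa` is ordered as the
#' canonical populations (ss, sp, ii, dp); `a` is one value per intrinsic
#' connection named as `source_target`.
#'
#' @param kappa optional replacement 4-vector of rate constants (1/s).
#' @param a_self_ss,a_other optional replacement intrinsic gain scales.
#' @return list with elements `kappa` (named 4-vector) and `a`
#'   (named 13-vector).
#' @export
cmc_scales <- function(kappa = NULL, a_self_ss = NULL, a_other = NULL) {
  k <- if (is.null(kappa)) .KAPPA_SCALE else setNames(kappa, .POPS)
  s1 <- if (is.null(a_self_ss)) .A_SCALE_SELF_SS else a_self_ss
  s2 <- if (is.null(a_other)) .A_SCALE_OTHER else a_other
  a <- setNames(rep(s2, 13L), .INTRINSIC)
  a["ss_ss"] <- s1
  list(kappa = k, a = a)
}

#' Define a canonical-microcircuit network architecture
#'
#' The architecture declares the regions, the allowed extrinsic forward and
#' backward connections (laminar-specific: forward connections arise from
#' superficial pyramidal cells and target spiny stellate and deep pyramidal
#' cells; backward connections arise from deep pyramidal cells and target
#' superficial pyramidal cells and inhibitory interneurons), and which
#' regions receive the exogenous (thalamic) input.
#'
#' @param n_regions number of regions.
#' @param forward,backward square 0/1 adjacency matrices with zero diagonal;
#'   entry `[i, j] = 1` allows a connection from region `j` to region `i`.
#' @param input_regions 0/1 vector flagging regions that receive input.
#' @param region_names optional character names.
#' @return an object of class `cmc_architecture`.
#' @export
cmc_architecture <- function(n_regions, forward, backward, input_regions,
                             region_names = NULL) {
  forward <- as.matrix(forward); backward <- as.matrix(backward)
  stopifnot(nrow(forward) == n_regions, ncol(forward) == n_regions,
            nrow(backward) == n_regions, ncol(backward) == n_regions,
            length(input_regions) == n_regions)
  if (any(diag(forward) != 0) || any(diag(backward) != 0))
    stop("extrinsic adjacency matrices must have zero diagonal")
  if (!any(input_regions > 0))
    stop("at least one region must receive the exogenous input")
  if (is.null(region_names)) region_names <- paste0("R", seq_len(n_regions))
  structure(list(n_regions = n_regions,
                 forward = (forward != 0) * 1,
                 backward = (backward != 0) * 1,
                 input_regions = as.numeric(input_regions != 0),
                 region_names = region_names,
                 population_labels = .POPS),
            class = "cmc_architecture")
}

# edge index helper: matrix with one row per allowed edge (target, source)
.edges <- function(adj) {
  idx <- which(adj != 0, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Define the between-condition design
#'
#' Encodes the between-trial-effects matrix: each non-baseline condition
#' switches on one or more effect columns, and each active effect adds its
#' condition-specific parameters to the extrinsic forward/backward and
#' self-inhibition log-gains.  The baseline row is all zero.
#'
#' @param condition_names ordered condition labels.
#' @param btf conditions x effects 0/1 matrix (baseline row all zero).
#' @param baseline_index row index of the baseline condition.
#' @return an object of class `condition_design`.
#' @export
condition_design <- function(condition_names, btf, baseline_index = 1L) {
  btf <- as.matrix(btf)
  stopifnot(nrow(btf) == length(condition_names))
  if (any(btf[baseline_index, ] != 0))
    stop("baseline condition must have an all-zero design row")
  structure(list(condition_names = condition_names, btf = btf,
                 baseline_index = baseline_index,
                 n_effects = ncol(btf)),
            class = "condition_design")
}

#' Default four-condition roving-oddball design
#'
#' Conditions SR (standard/respond; baseline), DR (deviant/respond),
#' SC (standard/control) and DC (deviant/control); each non-baseline
#' condition carries its own between-trial effect.
#'
#' @return a `condition_design`.
#' @export
oddball_design <- function() {
  btf <- rbind(SR = c(0, 0, 0), DR = c(1, 0, 0),
               SC = c(0, 1, 0), DC = c(0, 0, 1))
  condition_design(c("SR", "DR", "SC", "DC"), btf, baseline_index = 1L)
}

#' Prior specification for the neuronal parameter blocks
#'
#' Builds Gaussian priors (mean and diagonal variance) over the log-scaling
#' parameters of the CMC model: rate constants and intrinsic gains are fixed
#' (zero prior variance); extrinsic log-gains and condition effects have
#' variance 1/8; the input log-gain has variance 1/32; the input onset is a
#' Gaussian in seconds (mean 0.070 s, SD 0.016 s) and the input dispersion is
#' fixed at 0.016 s.  A parameter with zero prior variance is pinned to its
#' prior mean and excluded from estimation.
#'
#' @param arch a `cmc_architecture`.
#' @param design a `condition_design`.
#' @return named list of blocks, each a list with `mean` and `variance`.
#' @export
cmc_priors <- function(arch, design) {
  nf <- nrow(.edges(arch$forward))
  nb <- nrow(.edges(arch$backward))
  nself <- 4L * arch$n_regions
  nB <- nf + nb + nself
  blk <- function(n, mean = 0, var = 0)
    list(mean = rep(mean, n), variance = rep(var, n))
  priors <- list(
    kappa = blk(4L, 0, 0),
    a = blk(13L, 0, 0),
    A_f = blk(nf, 0, 1 / 8),
    A_b = blk(nb, 0, 1 / 8),
    B = blk(nB * design$n_effects, 0, 1 / 8),
    C = blk(sum(arch$input_regions > 0), 0, 1 / 32),
    onset = list(mean = 0.070, variance = 0.016^2),
    dispersion = list(mean = 0.016, variance = 0))
  priors
}

#' Synaptic impulse response kernel
#'
#' `h(t) = t * kappa * exp(-t * kappa)` for `t >= 0`, zero for negative
#' times.  Peaks at `t = 1/kappa` with value `exp(-1)`; integrates to
#' `1/kappa`.
#'
#' @param t time in seconds (vectorised).
#' @param kappa synaptic rate constant (1/s), positive.
#' @export
synaptic_kernel <- function(t, kappa) {
  if (!is.numeric(kappa) || any(kappa <= 0)) stop("kappa must be positive")
  ifelse(t >= 0, t * kappa * exp(-t * kappa), 0)
}

#' Firing-rate sigmoid
#'
#' Centred logistic mapping depolarisation to firing-rate deviation from
#' baseline; zero at `V = threshold` and odd-symmetric when the threshold is
#' zero, so negative deviations (below-baseline firing) are allowed.
#'
#' @param V depolarisation (vectorised).
#' @param slope sigmoid slope (default 1).
#' @param threshold firing threshold (default 0).
#' @export
firing_sigmoid <- function(V, slope = 1, threshold = 0) {
  1 / (1 + exp(-slope * (V - threshold))) - 1 / (1 + exp(slope * threshold))
}

#' Gaussian exogenous input
#'
#' Unit-amplitude bell-shaped input bump encoding the delay and dispersion of
#' the subcortical volley driving the lowest region(s) of the hierarchy.
#'
#' @param t time (s), vectorised.
#' @param onset centre of the bump (s).
#' @param dispersion standard deviation of the bump (s), positive.
#' @export
gaussian_input <- function(t, onset, dispersion) {
  if (dispersion <= 0) stop("dispersion must be positive")
  exp(-0.5 * ((t - onset) / dispersion)^2)
}

#' Assemble neuronal parameters at their prior means
#'
#' @param arch a `cmc_architecture`.
#' @param design a `condition_design`.
#' @return named list of parameter vectors (theta, i.e. log-scalings except
#'   `onset`/`dispersion` which are in seconds).
#' @export
cmc_parameters <- function(arch, design) {
  pr <- cmc_priors(arch, design)
  lapply(pr, function(b) b$mean)
}

# layout of the condition-effect vector for one effect column:
# forward edges, then backward edges, then self-inhibition (region-major,
# population order ss, sp, ii, dp)
.b_layout <- function(arch) {
  nf <- nrow(.edges(arch$forward))
  nb <- nrow(.edges(arch$backward))
  nself <- 4L * arch$n_regions
  list(nf = nf, nb = nb, nself = nself, n = nf + nb + nself)
}

#' Apply condition-specific effects to the neuronal parameters
#'
#' Adds the condition effects (in log space) of the active effect columns to
#' the extrinsic forward/backward log-gains and the per-population
#' self-inhibition log-gains.  The baseline condition returns the parameters
#' unchanged.
#'
#' @param params parameter list from [cmc_parameters()] (or posterior means).
#' @param condition condition index into `design$condition_names`.
#' @param design a `condition_design`.
#' @param arch a `cmc_architecture`.
#' @return parameter list with an extra element `a_self_delta`
#'   (4 x n_regions matrix of additive self-inhibition log-gain changes).
#' @export
apply_condition_effects <- function(params, condition, design, arch) {
  stopifnot(condition >= 1, condition <= nrow(design$btf))
  lay <- .b_layout(arch)
  out <- params
  out$a_self_delta <- matrix(0, 4, arch$n_regions)
  active <- which(design$btf[condition, ] != 0)
  for (e in active) {
    be <- params$B[(e - 1) * lay$n + seq_len(lay$n)]
    if (lay$nf > 0) out$A_f <- out$A_f + be[seq_len(lay$nf)]
    if (lay$nb > 0) out$A_b <- out$A_b + be[lay$nf + seq_len(lay$nb)]
    out$a_self_delta <- out$a_self_delta +
      matrix(be[lay$nf + lay$nb + seq_len(lay$nself)], 4, arch$n_regions)
  }
  out
}

# build effective (positive) quantities for the integrator from theta
.cmc_effective <- function(params, arch, scales = cmc_scales()) {
  R <- arch$n_regions
  kap <- exp(params$kappa) * scales$kappa
  g <- matrix(exp(params$a) * scales$a, 13L, R)
  delta <- params$a_self_delta
  if (!is.null(delta))
    g[.INTRINSIC_SELF, ] <- g[.INTRINSIC_SELF, ] * exp(delta)
  Af <- matrix(0, R, R); Ab <- matrix(0, R, R)
  ef <- .edges(arch$forward); eb <- .edges(arch$backward)
  if (nrow(ef) > 0) Af[ef] <- exp(params$A_f)
  if (nrow(eb) > 0) Ab[eb] <- exp(params$A_b)
  Cv <- numeric(R)
  Cv[arch$input_regions > 0] <- exp(params$C)
  list(kappa = kap, g = g, Af = Af, Ab = Ab, C = Cv,
       onset = params$onset, dispersion = params$dispersion)
}

#' CMC state derivatives
#'
#' Reference (R-level) implementation of the coupled second-order population
#' dynamics: for population i, `d2V/dt2 = kappa_i^2 (f_i - V) - 2 kappa_i
#' dV/dt`, where the forcing `f_i` mixes the population-specific intrinsic
#' afferents, the A-weighted extrinsic afferents (forward from distal
#' superficial pyramidal cells to ss/dp; backward from distal deep pyramidal
#' cells to sp/ii) and, for spiny stellates, the exogenous input.  The
#' compiled integrator used by [integrate_erp()] implements the same
#' equations.
#'
#' @param state numeric matrix (8 x n_regions): rows 1-4 the potentials V
#'   (ss, sp, ii, dp), rows 5-8 the velocities dV/dt.
#' @param params parameter list, optionally carrying `a_self_delta` from
#'   [apply_condition_effects()].
#' @param arch a `cmc_architecture`.
#' @param u exogenous input value.
#' @param scales scale constants.
#' @return matrix like `state` holding the time derivative; attribute
#'   `forcing` carries the per-population f values (4 x n_regions).
#' @export
cmc_derivatives <- function(state, params, arch, u = 0,
                            scales = cmc_scales()) {
  if (length(state) != 8 * arch$n_regions)
    stop("state must have 8 entries (V, dV/dt per population) per region")
  state <- matrix(state, 8, arch$n_regions)
  eff <- .cmc_effective(params, arch, scales)
  R <- arch$n_regions
  V <- state[1:4, , drop = FALSE]
  W <- state[5:8, , drop = FALSE]
  s <- firing_sigmoid(V)
  # extrinsic afferents per region
  ef <- as.numeric(eff$Af %*% s[2, ])   # distal sp -> ss, dp targets
  eb <- as.numeric(eff$Ab %*% s[4, ])   # distal dp -> sp, ii targets
  f <- matrix(0, 4, R)
  for (k in seq_len(R)) {
    g <- setNames(eff$g[, k], .INTRINSIC)
    f[1, k] <- ef[k] - g["ss_ss"] * s[1, k] - g["sp_ss"] * s[2, k] -
      g["ii_ss"] * s[3, k] + eff$C[k] * u
    f[2, k] <- eb[k] - g["sp_sp"] * s[2, k] + g["ss_sp"] * s[1, k] -
      g["ii_sp"] * s[3, k]
    f[3, k] <- eb[k] - g["ii_ii"] * s[3, k] - g["dp_ii"] * s[4, k] +
      g["ss_ii"] * s[1, k] + g["sp_ii"] * s[2, k]
    f[4, k] <- ef[k] - g["dp_dp"] * s[4, k] - g["ii_dp"] * s[3, k] +
      g["sp_dp"] * s[2, k]
  }
  kap <- matrix(eff$kappa, 4, R)
  out <- rbind(W, kap^2 * (f - V) - 2 * kap * W)
  attr(out, "forcing") <- f
  out
}

#' Integrate the CMC model for one condition (event-related response)
#'
#' Integrates the coupled second-order population dynamics from rest over a
#' post-stimulus window, returning the per-population depolarisations and the
#' signed afferent components of the forcing term, bookkept separately as
#' intrinsic-excitatory, intrinsic-inhibitory, extrinsic and exogenous-input
#' contributions so that presynaptic drive functions can be assembled without
#' re-integration.
#'
#' Trajectories are reported on a uniform grid of step `dt`; internally each
#' reported step is subdivided into `substeps` RK4 steps, which keeps the
#' integrator inside its stability region for the strong intrinsic gains of
#' this model.
#'
#' @param params parameter list (see [cmc_parameters()]).
#' @param arch a `cmc_architecture`.
#' @param design a `condition_design`.
#' @param condition condition index.
#' @param t_end window length in seconds (default 0.4).
#' @param dt output sampling step in seconds (default 1e-3; must be <= 1 ms).
#' @param substeps internal RK4 substeps per output step (default 4).
#' @param scales scale constants from [cmc_scales()].
#' @return object of class `cmc_erp`: list with `time`, `V` and component
#'   matrices `exc`, `inh`, `ext`, `inp`, each (steps+1) x (4 * n_regions)
#'   with columns region-major in population order (ss, sp, ii, dp).
#' @export
integrate_erp <- function(params, arch, design, condition, t_end = 0.4,
                          dt = 1e-3, substeps = 4L, scales = cmc_scales()) {
  if (dt > 1e-3 + 1e-12) stop("output step must be at most 1 ms")
  eff_par <- apply_condition_effects(params, condition, design, arch)
  eff <- .cmc_effective(eff_par, arch, scales)
  n_out <- round(t_end / dt)
  res <- .cmc_integrate_cpp(eff$kappa, eff$g, eff$Af, eff$Ab, eff$C,
                            eff$onset, eff$dispersion, as.integer(n_out),
                            dt, as.integer(substeps))
  if (!isTRUE(res$finite))
    stop("CMC integration diverged (non-finite trajectory); ",
         "check connectivity and condition-effect parameters")
  cols <- as.vector(outer(.POPS, arch$region_names,
                          function(p, r) paste(r, p, sep = ".")))
  for (nm in c("V", "exc", "inh", "ext", "inp")) colnames(res[[nm]]) <- cols
  structure(list(time = seq(0, t_end, by = dt), V = res$V, exc = res$exc,
                 inh = res$inh, ext = res$ext, inp = res$inp,
                 arch = arch, condition = condition),
            class = "cmc_erp")
}

#' Write an ERP trajectory to CSV (long format)
#'
#' @param erp a `cmc_erp`.
#' @param path output file.
#' @export
write_erp_csv <- function(erp, path) {
  np <- ncol(erp$V)
  reg <- rep(rep(erp$arch$region_names, each = 4), each = length(erp$time))
  pop <- rep(rep(.POPS, erp$arch$n_regions), each = length(erp$time))
  df <- data.frame(time = rep(erp$time, np), region = reg, population = pop,
                   V = as.vector(erp$V))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
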