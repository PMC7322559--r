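# Ground-truth multimodal data generator: roving-oddball style event
# schedules, event-related sensor data and region-wise BOLD series from
# known parameters, so every pipeline stage can be tested end to end.

#' Generate a roving-oddball style event schedule
#'
#' Blocks alternate between "respond" and "control" agency; each block is a
#' cue period followed by a train of tones at a fixed stimulus-onset
#' asynchrony, each tone independently a deviant with the given probability
#' (the first tone of a block is always a standard), and ends with an
#' inter-block interval.  Conditions are labelled SR/DR (respond
#' standard/deviant) and SC/DC (control standard/deviant).
#'
#' @param n_blocks number of blocks (default 16).
#' @param tones_per_block tones per block (default 12).
#' @param deviant_fraction probability that a tone is a deviant, in (0, 1)
#'   (default 0.25).
#' @param tone_interval stimulus-onset asynchrony in seconds (default 2).
#' @param block_types cycle of agency labels (default respond, control).
#' @param cue,interblock cue and inter-block durations in seconds.
#' @param TR repetition time (default 2 s).
#' @param dt_micro microtime step (default 0.1 s).
#' @param seed RNG seed (deterministic schedule).
#' @return an `event_schedule`.
#' @export
generate_schedule <- function(n_blocks = 16L, tones_per_block = 12L,
                              deviant_fraction = 0.25, tone_interval = 2,
                              block_types = c("respond", "control"),
                              cue = 2, interblock = 1, TR = 2,
                              dt_micro = 0.1, seed = 1L) {
  if (deviant_fraction < 0 || deviant_fraction >= 1)
    stop("deviant_fraction must lie in [0, 1)")
  set.seed(seed)
  onset <- c(); condition <- c()
  t0 <- 0
  for (b in seq_len(n_blocks)) {
    agency <- block_types[(b - 1) %% length(block_types) + 1]
    t0 <- t0 + cue
    dev <- runif(tones_per_block) < deviant_fraction
    dev[1] <- FALSE
    for (j in seq_len(tones_per_block)) {
      onset <- c(onset, t0)
      condition <- c(condition,
                     paste0(if (dev[j]) "D" else "S",
                            if (agency == "respond") "R" else "C"))
      t0 <- t0 + tone_interval
    }
    t0 <- t0 + interblock
  }
  duration <- ceiling(t0 / TR) * TR
  event_schedule(data.frame(onset = onset, duration = 0,
                            condition = condition),
                 duration = duration, TR = TR, dt_micro = dt_micro)
}

#' Two-region ground-truth specification
#'
#' A desk-scale network: region R1 (input region) sends a forward connection
#' to R2, which returns a backward connection.  Neuronal ground truth sets
#' the forward log-gain to log(1.5), modest condition effects on the
#' forward/backward gains and superficial-pyramidal / interneuron
#' self-inhibition, and keeps remaining parameters at their prior means.
#' The neurovascular ground truth follows the supplied model specification;
#' default coupling weights are calibrated so the noiseless BOLD response is
#' of realistic size (~1% signal change).
#'
#' @param nvc_spec generating `nvc_model_spec` (default presynaptic, local,
#'   shared weights, direct form).
#' @param beta generating coupling weights (channel vector or channels x
#'   regions matrix matching `nvc_spec`).
#' @param n_sensors number of synthetic sensors (default 16).
#' @param gain_seed seed for the synthetic gain matrix.
#' @return object of class `ground_truth`.
#' @export
synthetic_truth <- function(nvc_spec = nvc_model_spec("pre", "exclude",
                                                      FALSE, "direct"),
                            beta = NULL, n_sensors = 16L, gain_seed = 11L) {
  arch <- cmc_architecture(2L,
                           forward = rbind(c(0, 0), c(1, 0)),
                           backward = rbind(c(0, 1), c(0, 0)),
                           input_regions = c(1, 0),
                           region_names = c("R1", "R2"))
  design <- oddball_design()
  params <- cmc_parameters(arch, design)
  params$A_f <- log(1.5)
  params$A_b <- log(1.2)
  # condition effects: [forward, backward, self-inhibition (region-major,
  # ss sp ii dp per region)] per effect column (DR, SC, DC)
  # modest effects: the circuit is very sensitive to self-inhibition, and
  # reductions beyond ~10% cross into an oscillatory (unrealistic) regime
  B <- matrix(0, 10, 3)
  B[, 1] <- c(0.4, -0.2, 0, 0.1, 0, 0, 0, 0.1, 0, 0)     # DR
  B[, 2] <- c(-0.2, 0.0, 0, 0, 0.1, 0, 0, 0, 0.1, 0)     # SC
  B[, 3] <- c(0.3, 0.2, 0, -0.05, 0, 0, 0, -0.05, 0, 0)  # DC
  params$B <- as.vector(B)
  gm <- random_gain_model(n_sensors, 2L, seed = gain_seed)
  if (is.null(beta)) {
    # prior-typical weights (within ~1 prior SD of zero)
    nch <- nvc_spec$n_channels
    base <- c(0.25, 0.2, -0.15, 0.2, 0.1, -0.1, 0.1, 0.05)[seq_len(nch)]
    if (nvc_spec$parameterisation == "decomposed")
      base <- c(0.25, -0.2, 0.15)[seq_len(nch)]
    beta <- if (nvc_spec$region_specific)
      outer(base, c(1, 0.8)) else base
  }
  structure(list(arch = arch, design = design, params = params,
                 gain_model = gm,
                 psi = c(0.2, 0.8, 0.0, 0.3), theta_gain = c(0, 0),
                 nvc_spec = nvc_spec, beta = beta, tau_nc = 0.7,
                 haemo = list(theta_eta = c(0, 0), theta_tauh = c(0, 0),
                              theta_epsilon = c(0, 0)),
                 V0 = 0.08),
            class = "ground_truth")
}

#' Simulate an event-related sensor dataset from ground truth
#'
#' Integrates the neuronal model per condition, projects to sensors and adds
#' i.i.d. Gaussian noise scaled to the requested amplitude SNR (root mean
#' square of the noiseless signal over all conditions divided by the noise
#' standard deviation).
#'
#' @param truth a `ground_truth`.
#' @param snr amplitude signal-to-noise ratio; `Inf` for noiseless data.
#' @param seed RNG seed for the noise.
#' @param dt sensor sample interval (default 1 ms).
#' @return an `erp_dataset`.
#' @export
simulate_erp_dataset <- function(truth, snr = 10, seed = 1L, dt = 1e-3) {
  n_cond <- length(truth$design$condition_names)
  clean <- lapply(seq_len(n_cond), function(ci) {
    erp <- integrate_erp(truth$params, truth$arch, truth$design, ci,
                         dt = dt)
    predict_sensors(erp$V, truth$gain_model, truth$psi, truth$theta_gain)
  })
  names(clean) <- truth$design$condition_names
  rms <- sqrt(mean(unlist(clean)^2))
  sd_noise <- if (is.finite(snr)) rms / snr else 0
  set.seed(seed)
  noisy <- lapply(clean, function(Y)
    Y + matrix(rnorm(length(Y), sd = sd_noise), nrow(Y), ncol(Y)))
  ds <- erp_dataset(noisy, dt)
  ds$noise_sd <- sd_noise
  ds$clean <- clean
  ds
}

#' Simulate a region-wise BOLD dataset from ground truth
#'
#' Builds neuronal drives from the ground-truth parameters under the
#' generating neurovascular specification, combines them with the generating
#' coupling weights, integrates the Balloon model and samples at the
#' repetition time, then adds white Gaussian noise scaled to the requested
#' SNR (SD of the noiseless series divided by the noise SD).
#'
#' @param truth a `ground_truth`.
#' @param schedule an `event_schedule`.
#' @param snr amplitude SNR; `Inf` for noiseless data.
#' @param seed RNG seed for the noise.
#' @return list with `bold` (n_scans x regions), `noiseless`, `drives`,
#'   `noise_sd` and scan `time`.
#' @export
simulate_bold_dataset <- function(truth, schedule, snr = 10, seed = 1L) {
  z <- build_drives(truth$params, schedule, truth$nvc_spec,
                    arch = truth$arch, design = truth$design)
  zz <- combine_drives(z, truth$beta, truth$nvc_spec, schedule$dt_micro,
                       truth$tau_nc)
  hp <- haemo_parameters(truth$haemo$theta_eta, truth$haemo$theta_tauh,
                         truth$haemo$theta_epsilon,
                         n_regions = truth$arch$n_regions, V0 = truth$V0)
  clean <- predict_bold(zz, hp, schedule$dt_micro, schedule$TR)
  sd_sig <- sd(as.numeric(clean))
  sd_noise <- if (!is.finite(snr)) 0 else
    if (sd_sig > 0) sd_sig / snr else 1e-3
  set.seed(seed)
  bold <- clean + matrix(rnorm(length(clean), sd = sd_noise),
                         nrow(clean), ncol(clean))
  list(bold = bold, noiseless = clean, drives = z, noise_sd = sd_noise,
       time = attr(clean, "time"))
}

#' Five-region auditory-hierarchy architecture
#'
#' The network used in oddball studies of the auditory system: bilateral
#' primary auditory cortex (A1, the input regions), bilateral superior
#' temporal gyrus (STG) and right inferior frontal gyrus (IFG), with
#' forward connections ascending the hierarchy and backward connections
#' descending it.  Shipped as a ready-made configuration; the package's
#' tests use the two-region network of [synthetic_truth()].
#'
#' @return a `cmc_architecture` with regions lA1, rA1, lSTG, rSTG, rIFG.
#' @export
auditory_network_architecture <- function() {
  regions <- c("lA1", "rA1", "lSTG", "rSTG", "rIFG")
  fwd <- matrix(0, 5, 5, dimnames = list(regions, regions))
  fwd["lSTG", "lA1"] <- 1
  fwd["rSTG", "rA1"] <- 1
  fwd["rIFG", "rSTG"] <- 1
  bwd <- t(fwd)
  cmc_architecture(5L, fwd, bwd, input_regions = c(1, 1, 0, 0, 0),
                   region_names = regions)
}
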