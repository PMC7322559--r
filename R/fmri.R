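# Third estimation stage: fit neurovascular + haemodynamic models to
# region-wise BOLD time series, driven by the neuronal drive functions.

#' Build microtime drive signals for a model specification
#'
#' Convenience wrapper: computes the condition drive templates implied by an
#' `nvc_model_spec` (parameterisation, distal option, exclusion mask) from
#' an ERP inversion or a neuronal parameter list, resamples them to the
#' microtime grid and shifts-and-sums them over the event schedule.
#'
#' @param source an `erp_inversion` or a neuronal parameter list.
#' @param schedule an `event_schedule`.
#' @param spec an `nvc_model_spec`.
#' @param arch,design required when `source` is a plain parameter list.
#' @param ... further arguments to [compute_condition_drives()].
#' @return drive matrix as returned by [shift_and_sum()].
#' @export
build_drives <- function(source, schedule, spec, arch = NULL, design = NULL,
                         ...) {
  tmpl <- compute_condition_drives(source, arch = arch, design = design,
                                   signal_type = spec$parameterisation,
                                   distal = spec$distal,
                                   exclusion_mask = spec$exclusion_mask,
                                   ...)
  shift_and_sum(resample_drives(tmpl, schedule$dt_micro), schedule)
}

#' Invert a neurovascular + haemodynamic model from BOLD data
#'
#' Estimates the coupling weights (and, for delay-form models, the delay
#' time constant) together with the region-wise haemodynamic parameters from
#' the observed BOLD series, given fixed neuronal drive signals.  The
#' generator combines the drives under the model specification, integrates
#' the Balloon model per region and samples at the repetition time;
#' optimisation is variational Laplace with a single i.i.d. noise stream.
#'
#' @param bold matrix (n_scans x regions) of observed BOLD values.
#' @param z drive matrix from [shift_and_sum()]/[build_drives()], with
#'   channels matching `spec`.
#' @param spec an `nvc_model_spec`.
#' @param schedule an `event_schedule`.
#' @param priors optional prior blocks (default [nvc_priors()] +
#'   [haemo_priors()]).
#' @param hyper noise log-precision hyperprior.
#' @param control list: `max_iter`, `tol`, `fd_step`.
#' @param V0 resting blood volume fraction.
#' @return object of class `fmri_inversion`: the `inversion_result` plus
#'   spec, priors, index and a `predict` closure.
#' @export
invert_fmri <- function(bold, z, spec, schedule, priors = NULL,
                        hyper = list(mean = 0, var = 16), control = list(),
                        V0 = 0.08) {
  ctl <- modifyList(list(max_iter = 64L, tol = 0.01, fd_step = 1e-3),
                    control)
  bold <- as.matrix(bold)
  R <- ncol(bold)
  if (ncol(z) != spec$n_channels * R)
    stop("drive channels do not match the model spec and region count")
  if (is.null(priors)) priors <- c(nvc_priors(spec, R), haemo_priors(R))
  index <- .pt_index(priors)
  dt <- schedule$dt_micro
  nb <- spec$n_channels
  predict_fun <- function(pl) {
    beta <- if (spec$region_specific) matrix(pl$beta, nb, R) else pl$beta
    tau <- if (!is.null(pl$theta_tau_nc)) 0.7 * exp(pl$theta_tau_nc) else 0.7
    zz <- combine_drives(z, beta, spec, dt, tau)
    hp <- haemo_parameters(pl$theta_eta, pl$theta_tauh, pl$theta_epsilon,
                           n_regions = R, V0 = V0)
    predict_bold(zz, hp, dt, schedule$TR)[seq_len(nrow(bold)), ,
                                          drop = FALSE]
  }
  generator <- function(theta) {
    pl <- .pt_unflatten(theta, priors, index)
    as.numeric(predict_fun(pl))
  }
  vl <- variational_laplace(generator, as.numeric(bold), index$mu0,
                            index$v0, hyper = hyper,
                            max_iter = ctl$max_iter, tol = ctl$tol,
                            fd_step = ctl$fd_step, labels = index$labels)
  pl <- .pt_unflatten(vl$mean, priors, index)
  pred <- predict_fun(pl)
  ev <- 1 - colSums((bold - pred)^2) / colSums(sweep(bold, 2,
                                                     colMeans(bold))^2)
  structure(list(result = vl, posterior_params = pl, spec = spec,
                 priors = priors, index = index, predicted = pred,
                 explained_variance = ev, schedule = schedule),
            class = "fmri_inversion")
}

#' Fit the full neurovascular model space
#'
#' Inverts each candidate model against the same BOLD data, building the
#' appropriate drive signals per parameterisation/distal option, and returns
#' free energies, posterior model probabilities and family posteriors for
#' the four design factors.
#'
#' @param bold matrix (n_scans x regions).
#' @param source an `erp_inversion` or neuronal parameter list used to
#'   generate drives.
#' @param schedule an `event_schedule`.
#' @param specs list of `nvc_model_spec` (default the full 16-model space).
#' @param arch,design needed when `source` is a plain parameter list.
#' @param ... passed to [invert_fmri()] (`control`, `hyper`, ...).
#' @return object of class `model_space_fit` with `free_energies`,
#'   `probabilities`, `families` (per factor) and the per-model inversions.
#' @export
fit_model_space <- function(bold, source, schedule,
                            specs = enumerate_model_space(),
                            arch = NULL, design = NULL, ...) {
  # drives depend only on (parameterisation, distal, mask): share them
  drive_cache <- list()
  fits <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    key <- paste(sp$parameterisation, sp$distal,
                 paste(sp$exclusion_mask, collapse = ""), sep = "_")
    if (is.null(drive_cache[[key]]))
      drive_cache[[key]] <- build_drives(source, schedule, sp,
                                         arch = arch, design = design)
    fits[[i]] <- invert_fmri(bold, drive_cache[[key]], sp, schedule, ...)
  }
  Fs <- vapply(fits, function(f) f$result$free_energy, numeric(1))
  names(Fs) <- names(specs)
  cmp <- compare_models(Fs)
  fams <- lapply(c(Q1 = "Q1", Q2 = "Q2", Q3 = "Q3", Q4 = "Q4"),
                 function(q) family_posterior(Fs, family_partition(specs, q)))
  structure(list(free_energies = Fs, probabilities = cmp$probabilities,
                 families = fams, fits = fits, specs = specs),
            class = "model_space_fit")
}

#' @export
print.model_space_fit <- function(x, ...) {
  cat("Neurovascular model space fit\n")
  best <- which.max(x$free_energies)
  cat(sprintf("  winning model: %s {%s, %s} p=%.3f\n",
              names(x$free_energies)[best],
              paste(x$specs[[best]]$option_string, collapse = ","),
              x$specs[[best]]$form, x$probabilities[best]))
  for (q in names(x$families)) {
    fam <- x$families[[q]]
    cat(sprintf("  %s: %s\n", q,
                paste(sprintf("%s=%.3f", names(fam), fam), collapse = " ")))
  }
  invisible(x)
}
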