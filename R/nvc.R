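# Neurovascular coupling: weighted (optionally delayed) combination of the
# neuronal drives per region, and the factorial model space over
# parameterisation x distal inputs x region-specificity x direct/delay.

#' Neurovascular delay impulse response
#'
#' `f(t) = (t/tau) * exp(-t/tau)` for `t >= 0`, zero otherwise; models the
#' delay and dispersion introduced by astrocytic (intracellular calcium)
#' kinetics.  Peaks at `t = tau` with value `exp(-1)`; integrates to `tau`.
#' The kernel is deliberately not normalised to unit area (the coupling
#' weights absorb its scale).
#'
#' @param t time (s), vectorised.
#' @param tau_nc delay time constant (s), positive; prior expectation 0.7 s.
#' @export
delay_kernel <- function(t, tau_nc) {
  if (tau_nc <= 0) stop("tau_nc must be positive")
  ifelse(t >= 0, (t / tau_nc) * exp(-t / tau_nc), 0)
}

#' Specify one neurovascular coupling model
#'
#' @param parameterisation "pre", "post" or "decomposed".
#' @param distal "include", "exclude", or "na" (postsynaptic models have no
#'   distal option and must use "na").
#' @param region_specific logical: separate coupling weights per region?
#'   (decomposed models share weights across regions.)
#' @param form "direct" (instantaneous) or "delay" (convolved with
#'   [delay_kernel()]).
#' @param exclusion_mask 4-vector of 0/1 over populations (canonical order).
#' @return object of class `nvc_model_spec`.
#' @export
nvc_model_spec <- function(parameterisation, distal, region_specific, form,
                           exclusion_mask = c(1, 1, 1, 1)) {
  parameterisation <- match.arg(parameterisation,
                                c("pre", "post", "decomposed"))
  distal <- match.arg(distal, c("include", "exclude", "na"))
  form <- match.arg(form, c("direct", "delay"))
  if (parameterisation == "post" && distal != "na")
    stop("postsynaptic parameterisation requires distal = 'na'")
  if (parameterisation != "post" && distal == "na")
    stop("presynaptic parameterisations require distal include/exclude")
  if (parameterisation == "decomposed" && isTRUE(region_specific))
    stop("decomposed models share coupling weights across regions")
  opt1 <- c(pre = "pre", post = "post", decomposed = "de")[parameterisation]
  opt2 <- if (region_specific) "d" else "s"
  opt3 <- c(include = "exc", exclude = "int", na = "na")[distal]
  structure(list(parameterisation = parameterisation, distal = distal,
                 region_specific = isTRUE(region_specific), form = form,
                 exclusion_mask = as.numeric(exclusion_mask),
                 option_string = unname(c(opt1, opt2, opt3)),
                 n_channels = length(.drive_channels(parameterisation,
                                                     distal))),
            class = "nvc_model_spec")
}

#' @export
print.nvc_model_spec <- function(x, ...) {
  cat(sprintf("NVC model {%s} form=%s channels=%d\n",
              paste(x$option_string, collapse = ", "), x$form, x$n_channels))
  invisible(x)
}

#' Enumerate the factorial neurovascular model space
#'
#' Sixteen candidate models: presynaptic (per-population) coupling crossed
#' with distal inputs and region-specific weights, postsynaptic coupling
#' crossed with region-specific weights, and decomposed presynaptic coupling
#' crossed with distal inputs -- each under a direct and a delayed form.
#'
#' @param exclusion_mask 4-vector applied to every model.
#' @return list of 16 `nvc_model_spec` objects in canonical order.
#' @export
enumerate_model_space <- function(exclusion_mask = c(1, 1, 1, 1)) {
  rows <- list(
    list("pre", "include", TRUE), list("pre", "exclude", TRUE),
    list("pre", "include", FALSE), list("pre", "exclude", FALSE),
    list("post", "na", TRUE), list("post", "na", FALSE),
    list("decomposed", "include", FALSE), list("decomposed", "exclude",
                                               FALSE))
  out <- c(lapply(rows, function(r)
             nvc_model_spec(r[[1]], r[[2]], r[[3]], "direct",
                            exclusion_mask)),
           lapply(rows, function(r)
             nvc_model_spec(r[[1]], r[[2]], r[[3]], "delay",
                            exclusion_mask)))
  names(out) <- paste0("m", seq_along(out))
  out
}

#' Partition the model space into families
#'
#' @param specs list of `nvc_model_spec` (as from [enumerate_model_space()]).
#' @param factor one of "Q1" (parameterisation), "Q2" (distal inputs;
#'   postsynaptic models are not applicable and are excluded), "Q3"
#'   (region-specific weights) and "Q4" (direct vs delay).
#' @return named list of disjoint model-index vectors.
#' @export
family_partition <- function(specs, factor = c("Q1", "Q2", "Q3", "Q4")) {
  factor <- match.arg(factor)
  get <- function(f) vapply(specs, function(s) s[[f]], specs[[1]][[f]])
  switch(factor,
    Q1 = split(seq_along(specs), get("parameterisation")),
    Q2 = {
      d <- get("distal")
      list(include = which(d == "include"), exclude = which(d == "exclude"))
    },
    Q3 = {
      rs <- get("region_specific")
      list(region_specific = which(rs), shared = which(!rs))
    },
    Q4 = {
      fo <- get("form")
      list(direct = which(fo == "direct"), delay = which(fo == "delay"))
    })
}

#' Combine neuronal drives into per-region neurovascular signals
#'
#' Direct form: weighted sum of the drive channels per region.  Delay form:
#' the weighted sum convolved (causal discrete convolution, scaled by the
#' microtime step) with the delay kernel, whose support is truncated at
#' `8 * tau_nc` (omitted mass < 3e-3).
#'
#' @param z drive matrix (n_micro x regions*channels) from
#'   [shift_and_sum()].
#' @param beta coupling weights: channels x regions matrix for
#'   region-specific models, or a channel vector shared by all regions.
#' @param spec an `nvc_model_spec`.
#' @param dt microtime step in seconds.
#' @param tau_nc delay time constant (s), used by the delay form.
#' @return matrix (n_micro x regions) of neurovascular signals.
#' @export
combine_drives <- function(z, beta, spec, dt, tau_nc = 0.7) {
  nch <- spec$n_channels
  R <- ncol(z) / nch
  if (R != round(R)) stop("drive channels do not match the model spec")
  if (!is.matrix(beta) && length(beta) != nch)
    stop("beta dimensions do not match the model spec")
  B <- if (is.matrix(beta)) beta else matrix(beta, nch, R)
  if (nrow(B) != nch || ncol(B) != R)
    stop("beta dimensions do not match the model spec")
  out <- sapply(seq_len(R), function(k)
    z[, (k - 1) * nch + seq_len(nch), drop = FALSE] %*% B[, k])
  out <- matrix(out, nrow = nrow(z))
  if (spec$form == "delay") {
    kern <- delay_kernel(seq(0, 8 * tau_nc, by = dt), tau_nc)
    out <- apply(out, 2, function(x) {
      full <- convolve(x, rev(kern), type = "open")
      full[seq_along(x)] * dt
    })
    out <- matrix(out, nrow = nrow(z))
  }
  out
}

#' Neurovascular parameter priors
#'
#' Coupling weights have prior N(0, 1/16) (a relatively flat prior per
#' weight); the delay time constant is log-parameterised around 0.7 s with
#' prior N(0, 1/16) and is present only in delay-form models.
#'
#' @param spec an `nvc_model_spec`.
#' @param n_regions number of regions.
#' @return named list of prior blocks.
#' @export
nvc_priors <- function(spec, n_regions) {
  nb <- spec$n_channels * (if (spec$region_specific) n_regions else 1L)
  pr <- list(beta = list(mean = rep(0, nb), variance = rep(1 / 16, nb)))
  if (spec$form == "delay")
    pr$theta_tau_nc <- list(mean = 0, variance = 1 / 16)
  pr
}
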