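# Electromagnetic observation model: population depolarisations are mixed by
# a contribution vector, scaled by a per-region spatial-basis coefficient and
# projected through a gain (lead-field) matrix; data and predictions are
# reduced to the principal spatial modes of the observed ERPs.

#' Construct a gain (lead-field) model
#'
#' Head-model computation is out of scope: the gain matrix is user-supplied
#' or synthesised with near-orthonormal random columns (one per region).
#' The spatial basis defaults to a single scaling pattern per region whose
#' coefficient is estimated (log-parameterised, so positive); the
#' contribution vector weights the four populations' depolarisations.
#'
#' @param gain sensors x regions numeric matrix.
#' @param basis n_basis x regions matrix of spatial-basis values (default a
#'   single row of ones).
#' @return object of class `gain_model`.
#' @export
gain_model <- function(gain, basis = NULL) {
  gain <- as.matrix(gain)
  if (is.null(basis)) basis <- matrix(1, 1, ncol(gain))
  stopifnot(ncol(basis) == ncol(gain), all(is.finite(gain)))
  structure(list(gain = gain, basis = as.matrix(basis),
                 n_sensors = nrow(gain), n_regions = ncol(gain)),
            class = "gain_model")
}

#' Synthesise a random gain matrix
#'
#' Columns are the first `n_regions` columns of a random orthogonal matrix
#' (distinct, unit-norm sensor topographies per source).
#'
#' @param n_sensors,n_regions dimensions.
#' @param seed RNG seed.
#' @return a `gain_model`.
#' @export
random_gain_model <- function(n_sensors, n_regions, seed = 1L) {
  set.seed(seed)
  M <- matrix(rnorm(n_sensors * n_sensors), n_sensors)
  Q <- qr.Q(qr(M))[, seq_len(n_regions), drop = FALSE]
  gain_model(Q)
}

#' Observation parameter priors
#'
#' The contribution vector has prior mean (0, 1, 0, 0) -- superficial
#' pyramidal cells dominate the measured field, the field's standard
#' assumption -- with variance 1/16; the per-region basis coefficients are
#' log-scalings with prior N(0, 1/8).
#'
#' @param gm a `gain_model`.
#' @return named list of prior blocks.
#' @export
observation_priors <- function(gm) {
  nb <- nrow(gm$basis) * gm$n_regions
  list(psi = list(mean = c(0, 1, 0, 0), variance = rep(1 / 16, 4)),
       theta_gain = list(mean = rep(0, nb), variance = rep(1 / 8, nb)))
}

#' Project population trajectories to sensors
#'
#' Linear map: per region, populations are mixed by the contribution vector
#' `psi`, scaled by the basis coefficient `exp(theta_gain)` weighted by the
#' basis values, and projected through the gain matrix; regions sum.
#'
#' @param V (time x 4*regions) trajectory matrix, columns region-major in
#'   population order, e.g. from [integrate_erp()].
#' @param gm a `gain_model`.
#' @param psi length-4 contribution vector.
#' @param theta_gain basis-coefficient log-scalings (n_basis x regions, as a
#'   vector or matrix).
#' @return time x sensors prediction matrix.
#' @export
predict_sensors <- function(V, gm, psi, theta_gain) {
  R <- gm$n_regions
  if (ncol(V) != 4 * R) stop("trajectory/gain dimension mismatch")
  Th <- matrix(exp(theta_gain), nrow(gm$basis), R)
  delta0 <- colSums(gm$basis * Th)
  M <- sapply(seq_len(R), function(k)
    V[, (k - 1) * 4 + 1:4, drop = FALSE] %*% psi)
  M <- matrix(M, nrow = nrow(V))
  (M %*% (delta0 * t(gm$gain)))
}

#' Principal-mode feature projection
#'
#' Computes the top right-singular vectors (principal spatial modes) of the
#' observed sensor data and returns a projection operator that is applied
#' identically to data and model predictions, so both live in one feature
#' space.  The operator is computed once from the observed data and is not
#' refreshed during inversion.
#'
#' @param Y time x sensors matrix, or a list of such matrices (conditions)
#'   which are stacked row-wise.
#' @param n_modes number of modes to retain.
#' @return object of class `feature_projection` with the sensor-space
#'   projector `P` (sensors x n_modes) and singular values.
#' @export
project_features <- function(Y, n_modes) {
  Ym <- if (is.list(Y)) do.call(rbind, Y) else Y
  if (n_modes > min(dim(Ym))) stop("n_modes exceeds data rank bound")
  sv <- svd(Ym)
  structure(list(P = sv$v[, seq_len(n_modes), drop = FALSE],
                 singular_values = sv$d, n_modes = n_modes),
            class = "feature_projection")
}

#' @rdname project_features
#' @param proj a `feature_projection`.
#' @export
apply_projection <- function(Y, proj) Y %*% proj$P

#' Assemble an ERP dataset
#'
#' @param data named list (one time x sensors matrix per condition).
#' @param dt sample interval in seconds.
#' @return object of class `erp_dataset`.
#' @export
erp_dataset <- function(data, dt) {
  dims <- vapply(data, dim, integer(2))
  if (any(dims != dims[, 1])) stop("conditions must share grid and sensors")
  structure(list(data = data, dt = dt,
                 condition_names = names(data),
                 n_sensors = ncol(data[[1]]),
                 n_samples = nrow(data[[1]])),
            class = "erp_dataset")
}

#' Invert the ERP model (neuronal + observation parameters)
#'
#' Fits the CMC model jointly with the electromagnetic observation model to
#' the principal spatial modes of the event-related data, using variational
#' Laplace.  The generator integrates the neuronal model per condition,
#' projects to sensors and then into the feature space computed from the
#' observed data.
#'
#' @param dataset an `erp_dataset` (condition order must match `design`).
#' @param arch a `cmc_architecture`.
#' @param design a `condition_design`.
#' @param gm a `gain_model`.
#' @param priors optional named list of prior blocks; defaults to
#'   [cmc_priors()] plus [observation_priors()].
#' @param n_modes number of principal modes used as data features
#'   (default 8, capped at the number of sensors).
#' @param hyper noise log-precision hyperprior.
#' @param control list: `max_iter`, `tol`, `dt`, `substeps`, `fd_step`.
#' @return object of class `erp_inversion`: the `inversion_result` plus the
#'   priors/index needed to reconstitute full parameter lists, the feature
#'   projector and the model ingredients.
#' @export
invert_erp <- function(dataset, arch, design, gm, priors = NULL,
                       n_modes = 8L, hyper = list(mean = 0, var = 16),
                       control = list()) {
  ctl <- modifyList(list(max_iter = 64L, tol = 0.01, dt = 1e-3,
                         substeps = 4L, fd_step = 1e-3), control)
  if (is.null(priors))
    priors <- c(cmc_priors(arch, design), observation_priors(gm))
  n_modes <- min(n_modes, dataset$n_sensors, dataset$n_samples)
  proj <- project_features(dataset$data, n_modes)
  y <- as.numeric(do.call(rbind, lapply(dataset$data, apply_projection,
                                        proj = proj)))
  index <- .pt_index(priors)
  n_cond <- length(design$condition_names)
  generator <- function(theta) {
    pl <- .pt_unflatten(theta, priors, index)
    out <- lapply(seq_len(n_cond), function(ci) {
      erp <- integrate_erp(pl, arch, design, ci, dt = ctl$dt,
                           substeps = ctl$substeps)
      apply_projection(predict_sensors(erp$V, gm, pl$psi, pl$theta_gain),
                       proj)
    })
    as.numeric(do.call(rbind, out))
  }
  vl <- variational_laplace(generator, y, index$mu0, index$v0,
                            hyper = hyper, max_iter = ctl$max_iter,
                            tol = ctl$tol, fd_step = ctl$fd_step,
                            labels = index$labels)
  structure(list(result = vl,
                 posterior_params = .pt_unflatten(vl$mean, priors, index),
                 priors = priors, index = index, projector = proj,
                 arch = arch, design = design, gain_model = gm,
                 control = ctl),
            class = "erp_inversion")
}
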