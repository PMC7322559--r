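# Variational Laplace inversion, Bayesian model reduction and fixed-effects
# (family-wise) Bayesian model comparison.

# central finite-difference Jacobian of the generator
.fd_jacobian <- function(generator, theta, g0, step = 1e-3) {
  p <- length(theta)
  J <- matrix(0, length(g0), p)
  for (i in seq_len(p)) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + step
    tm[i] <- tm[i] - step
    J[, i] <- (generator(tp) - generator(tm)) / (2 * step)
  }
  J
}

.logdet <- function(M) {
  if (length(M) == 0) return(0)
  determinant(as.matrix(M), logarithm = TRUE)$modulus[[1]]
}

#' Variational Laplace model inversion
#'
#' Maximises the Laplace free energy (a lower bound on log model evidence)
#' for the nonlinear observation model `y = g(theta) + e`, with a Gaussian
#' prior over `theta` and i.i.d. Gaussian noise whose log precision `lambda`
#' is a hyperparameter with its own Gaussian hyperprior.  Optimisation is
#' Gauss-Newton ascent with Levenberg-Marquardt damping; gradients of the
#' generator are obtained by central finite differences.  Accepted steps have
#' a non-decreasing free energy; a rejected step reverts to the best iterate
#' and increases damping.
#'
#' @param generator function mapping the free parameter vector to a predicted
#'   data vector of the same length as `y`.
#' @param y observed data vector.
#' @param prior_mean,prior_var Gaussian prior over the free parameters;
#'   `prior_var` may be a variance vector (diagonal) or a covariance matrix.
#' @param hyper list with `mean` and `var` of the Gaussian hyperprior over
#'   the noise log precision; `var = 0` fixes the log precision at its mean.
#' @param max_iter maximum number of iterations (default 64).
#' @param tol convergence: free-energy improvement below `tol` for three
#'   consecutive accepted steps (default 0.01).
#' @param fd_step finite-difference step on theta (default 1e-3).
#' @param init optional starting value for the free parameters.
#' @param labels optional parameter labels.
#' @param damping_init initial log damping of the ascent (more negative =
#'   more conservative first steps).
#' @return object of class `inversion_result`: posterior `mean`, `cov`,
#'   `free_energy`, per-iteration `trace` of accepted free energies, noise
#'   log-precision posterior (`lambda`, `lambda_var`), the prior, and
#'   convergence information.
#' @export
variational_laplace <- function(generator, y, prior_mean, prior_var,
                                hyper = list(mean = 0, var = 16),
                                max_iter = 64L, tol = 0.01, fd_step = 1e-3,
                                init = NULL, labels = NULL,
                                damping_init = -4) {
  y <- as.numeric(y)
  N <- length(y)
  p <- length(prior_mean)
  C0 <- if (is.matrix(prior_var)) prior_var else diag(prior_var, p)
  P0 <- if (p) solve(C0) else matrix(0, 0, 0)
  mu0 <- as.numeric(prior_mean)
  hl <- hyper$mean; Pl <- if (hyper$var > 0) 1 / hyper$var else Inf
  hyper_free <- is.finite(Pl)

  th <- if (is.null(init)) mu0 else as.numeric(init)
  la <- hl
  v <- damping_init           # log damping (larger = closer to Gauss-Newton)
  best <- NULL
  trace <- c(); n_small <- 0L; converged <- FALSE
  polish <- 0L                # near-undamped refinement steps at the end

  free_energy <- function(r, d, la, Sg, Sl) {
    Fv <- -0.5 * exp(la) * sum(r^2) + N / 2 * (la - log(2 * pi))
    if (p) Fv <- Fv - 0.5 * sum(d * (P0 %*% d)) +
        0.5 * .logdet(Sg) + 0.5 * .logdet(P0)
    if (hyper_free)
      Fv <- Fv - 0.5 * Pl * (la - hl)^2 + 0.5 * log(Sl * Pl)
    Fv
  }

  for (it in seq_len(max_iter)) {
    g <- generator(th)
    r <- y - g
    if (any(!is.finite(r))) {
      if (is.null(best)) stop("generator returned non-finite prediction ",
                              "at the starting point")
      th <- best$th; la <- best$la; v <- v - 2
      next
    }
    J <- if (p) .fd_jacobian(generator, th, g, fd_step) else
      matrix(0, N, 0)
    G <- crossprod(J)
    # update the noise log precision (Newton, conditioned on Sigma_theta)
    ss <- sum(r^2)
    Sl <- Inf
    for (k in 1:16) {
      Sg <- if (p) solve(exp(la) * G + P0) else matrix(0, 0, 0)
      trSG <- if (p) sum(Sg * G) else 0
      d2 <- -0.5 * exp(la) * (ss + trSG) - (if (hyper_free) Pl else 0)
      if (!hyper_free) break
      d1 <- N / 2 - 0.5 * exp(la) * (ss + trSG) - Pl * (la - hl)
      step <- d1 / d2
      # the objective is far from quadratic in la: cap the Newton step
      step <- sign(step) * min(abs(step), 2)
      la <- max(-32, min(32, la - step))
    }
    Sg <- if (p) solve(exp(la) * G + P0) else matrix(0, 0, 0)
    d2 <- -0.5 * exp(la) * (ss + (if (p) sum(Sg * G) else 0)) -
      (if (hyper_free) Pl else 0)
    Sl <- -1 / d2
    Fv <- free_energy(r, th - mu0, la, Sg, Sl)

    if (is.null(best) || Fv > best$F) {
      dF <- if (is.null(best)) Inf else Fv - best$F
      best <- list(th = th, la = la, F = Fv, Sg = Sg, Sl = Sl,
                   J = J, r = r, G = G)
      v <- min(v + 0.5, 8)
      n_small <- if (dF < tol) n_small + 1L else 0L
    } else {
      th <- best$th; la <- best$la
      J <- best$J; r <- best$r; G <- best$G
      v <- v - 2
      n_small <- 0L
    }
    trace <- c(trace, best$F)
    if (p == 0 && !hyper_free) { converged <- TRUE; break }
    if (polish > 0L) {
      polish <- polish - 1L
      if (polish == 0L) { converged <- TRUE; break }
    } else if (n_small >= 3L) {
      # converged under damping: refine with (almost) undamped Gauss-Newton
      # steps so linear problems land on the exact conjugate optimum
      polish <- 3L
      v <- 12
    }
    if (p) {
      H <- exp(best$la) * G + P0
      grad <- exp(best$la) * crossprod(J, r) - P0 %*% (th - mu0)
      Hd <- H + exp(-v) * diag(diag(H), p)
      th <- th + as.numeric(solve(Hd, grad))
    }
  }

  if (is.null(labels))
    labels <- if (p) paste0("theta[", seq_len(p), "]") else character(0)
  structure(list(mean = setNames(best$th, labels),
                 cov = best$Sg,
                 free_energy = best$F,
                 trace = trace,
                 lambda = best$la, lambda_var = best$Sl,
                 prior = list(mean = setNames(mu0, labels), cov = C0),
                 labels = labels,
                 converged = converged, iterations = length(trace)),
            class = "inversion_result")
}

#' @export
print.inversion_result <- function(x, ...) {
  cat("Variational Laplace inversion\n")
  cat(sprintf("  free parameters : %d\n", length(x$mean)))
  cat(sprintf("  free energy     : %.4f\n", x$free_energy))
  cat(sprintf("  iterations      : %d (%s)\n", x$iterations,
              if (x$converged) "converged" else "max-iter"))
  cat(sprintf("  noise log-prec. : %.3f\n", x$lambda))
  invisible(x)
}

#' Bayesian model reduction
#'
#' Computes, analytically, the change in log evidence and the posterior of a
#' reduced model that differs from the full model only in its prior, given
#' the full model's Gaussian prior and posterior.  No refitting is required.
#'
#' @param full_prior,full_posterior,reduced_prior lists with `mean` and
#'   `cov` over the same parameter vector.
#' @return list with `dF` (log evidence of reduced minus full), and the
#'   reduced posterior `mean` and `cov`.
#' @export
bayesian_model_reduction <- function(full_prior, full_posterior,
                                     reduced_prior) {
  P0 <- solve(full_prior$cov)
  P <- solve(full_posterior$cov)
  Pr0 <- solve(reduced_prior$cov)
  Pr <- P + Pr0 - P0
  er <- try(Cr <- solve(Pr), silent = TRUE)
  if (inherits(er, "try-error"))
    stop("singular reduced-posterior precision; ",
         "reduced prior is incompatible with the full posterior")
  mu0 <- full_prior$mean; mu <- full_posterior$mean; nu0 <- reduced_prior$mean
  mur <- as.numeric(Cr %*% (P %*% mu + Pr0 %*% nu0 - P0 %*% mu0))
  dF <- 0.5 * (.logdet(P) + .logdet(Pr0) - .logdet(P0) - .logdet(Pr)) -
    0.5 * (sum(mu * (P %*% mu)) + sum(nu0 * (Pr0 %*% nu0)) -
           sum(mu0 * (P0 %*% mu0)) - sum(mur * (Pr %*% mur)))
  list(dF = dF, mean = setNames(mur, names(mu)), cov = Cr)
}

#' Fixed-effects Bayesian model comparison
#'
#' Posterior model probabilities from free energies (log evidences) under a
#' uniform prior over models (or a supplied prior).
#'
#' @param free_energies numeric vector of free energies.
#' @param prior optional prior model probabilities (normalised internally).
#' @return object of class `comparison_result` with `free_energies` and
#'   `probabilities`.
#' @export
compare_models <- function(free_energies, prior = NULL) {
  k <- length(free_energies)
  if (is.null(prior)) prior <- rep(1 / k, k)
  prior <- prior / sum(prior)
  w <- exp(free_energies - max(free_energies)) * prior
  structure(list(free_energies = free_energies,
                 probabilities = w / sum(w)),
            class = "comparison_result")
}

#' Family-wise posterior probabilities
#'
#' Pools posterior model probabilities over families of models under a prior
#' that is uniform over families and uniform within each family, correcting
#' for unequal family sizes.
#'
#' @param free_energies numeric vector of free energies.
#' @param partition list of disjoint index vectors (one per family); models
#'   not covered by the partition are excluded from the comparison.
#' @return named vector of family probabilities (sums to 1).
#' @export
family_posterior <- function(free_energies, partition) {
  members <- unlist(partition)
  if (anyDuplicated(members)) stop("families must be disjoint")
  K <- length(partition)
  prior <- numeric(length(free_energies))
  for (f in seq_len(K)) prior[partition[[f]]] <- 1 / (K * length(partition[[f]]))
  keep <- which(prior > 0)
  post <- compare_models(free_energies[keep], prior[keep])$probabilities
  full_post <- numeric(length(free_energies))
  full_post[keep] <- post
  fam <- vapply(partition, function(ix) sum(full_post[ix]), numeric(1))
  if (is.null(names(partition)))
    names(fam) <- paste0("family", seq_len(K))
  else names(fam) <- names(partition)
  fam
}

# reduced prior that effectively removes the listed parameters (prior
# variance shrunk to `vr`, mean 0)
.reduced_prior_remove <- function(prior, idx, vr = 1e-8) {
  rp <- prior
  rp$mean[idx] <- 0
  rp$cov[idx, ] <- 0
  rp$cov[, idx] <- 0
  diag(rp$cov)[idx] <- vr
  rp
}

#' Prune parameters by greedy Bayesian model reduction
#'
#' Greedily switches candidate parameters' priors to near-zero variance
#' (removing them from the model), accepting each reduction that does not
#' decrease the free energy.  Also reports, per candidate, the log odds of
#' the parameter being absent (evaluated against the final reduced model).
#'
#' @param result an `inversion_result`.
#' @param candidates indices (or labels) of candidate parameters; defaults
#'   to all parameters.
#' @return list with `kept`, `pruned`, `dF` (total evidence gain),
#'   `log_odds_absent` per candidate, and the reduced `posterior`.
#' @export
prune_parameters <- function(result, candidates = NULL) {
  labels <- result$labels
  if (is.null(candidates)) candidates <- seq_along(labels)
  if (is.character(candidates)) candidates <- match(candidates, labels)
  prior <- result$prior
  post <- list(mean = result$mean, cov = result$cov)
  pruned <- integer(0)
  current_prior <- prior
  total_dF <- 0
  repeat {
    remaining <- setdiff(candidates, pruned)
    if (!length(remaining)) break
    dFs <- vapply(remaining, function(i) {
      rp <- .reduced_prior_remove(current_prior, c(pruned, i))
      bayesian_model_reduction(prior, post, rp)$dF - total_dF
    }, numeric(1))
    bi <- which.max(dFs)
    if (dFs[bi] < 0) break
    pruned <- c(pruned, remaining[bi])
    total_dF <- total_dF + dFs[bi]
  }
  rp_final <- if (length(pruned))
    .reduced_prior_remove(current_prior, pruned) else current_prior
  red <- bayesian_model_reduction(prior, post, rp_final)
  # marginal present-vs-absent evidence per candidate (each removed alone
  # from the full model); positive values favour absence
  odds <- vapply(candidates, function(i) {
    bayesian_model_reduction(prior, post,
                             .reduced_prior_remove(prior, i))$dF
  }, numeric(1))
  list(kept = setdiff(candidates, pruned), pruned = pruned,
       dF = red$dF,
       log_odds_absent = setNames(odds, labels[candidates]),
       posterior = list(mean = red$mean, cov = red$cov))
}
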