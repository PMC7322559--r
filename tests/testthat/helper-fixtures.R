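# Small shared fixtures, built in code.

one_region_arch <- function() {
  cmc_architecture(1L, matrix(0, 1, 1), matrix(0, 1, 1), 1)
}

two_region_arch <- function() {
  cmc_architecture(2L,
                   forward = rbind(c(0, 0), c(1, 0)),
                   backward = rbind(c(0, 1), c(0, 0)),
                   input_regions = c(1, 0))
}

# reduced 4-model comparison space: pre/post x direct/delay, shared weights
reduced_model_space <- function() {
  list(pre_direct = nvc_model_spec("pre", "exclude", FALSE, "direct"),
       pre_delay = nvc_model_spec("pre", "exclude", FALSE, "delay"),
       post_direct = nvc_model_spec("post", "na", FALSE, "direct"),
       post_delay = nvc_model_spec("post", "na", FALSE, "delay"))
}

# fit the reduced space to one BOLD dataset; returns free energies
fit_reduced_space <- function(bold, z_pre, z_post, sched, max_iter = 32) {
  specs <- reduced_model_space()
  vapply(specs, function(sp) {
    z <- if (sp$parameterisation == "pre") z_pre else z_post
    invert_fmri(bold, z, sp, sched,
                control = list(max_iter = max_iter))$result$free_energy
  }, numeric(1))
}

# analytic linear-Gaussian evidence for y = X theta + e, e ~ N(0, s2 I),
# theta ~ N(mu0, C0)
linear_gaussian_evidence <- function(y, X, mu0, C0, s2) {
  S <- X %*% C0 %*% t(X) + diag(s2, length(y))
  m <- as.numeric(X %*% mu0)
  -0.5 * (length(y) * log(2 * pi) + determinant(S)$modulus[[1]] +
          sum((y - m) * solve(S, y - m)))
}

linear_gaussian_posterior <- function(y, X, mu0, C0, s2) {
  P <- solve(C0) + crossprod(X) / s2
  C <- solve(P)
  m <- as.numeric(C %*% (solve(C0, mu0) + crossprod(X, y) / s2))
  list(mean = m, cov = C)
}
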