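# Canonical microcircuit: kernels, sigmoid, dynamics and ERP integration.

test_that("synaptic kernel satisfies its closed-form identities", {
  for (k in c(16, 32, 128, 256)) {
    expect_equal(synaptic_kernel(0, k), 0)
    expect_equal(synaptic_kernel(-0.1, k), 0)
    # peak at t = 1/kappa with value exp(-1), found by grid search
    tg <- seq(0, 10 / k, by = 1 / (k * 1000))
    expect_equal(tg[which.max(synaptic_kernel(tg, k))], 1 / k,
                 tolerance = 1e-3)
    expect_equal(max(synaptic_kernel(tg, k)), exp(-1), tolerance = 1e-6)
    # quadrature vs closed-form area 1/kappa
    q <- integrate(synaptic_kernel, 0, 50 / k, kappa = k,
                   rel.tol = 1e-10)$value
    expect_equal(q, 1 / k, tolerance = 1e-6)
  }
  expect_error(synaptic_kernel(0.1, -1), "positive")
})

test_that("firing sigmoid is a centred, odd, saturating nonlinearity", {
  expect_equal(firing_sigmoid(0), 0)
  expect_equal(firing_sigmoid(2), 1 / (1 + exp(-2)) - 0.5, tolerance = 1e-12)
  V <- seq(-5, 5, by = 0.25)
  expect_equal(firing_sigmoid(-V), -firing_sigmoid(V))
  expect_true(all(abs(firing_sigmoid(V)) < 0.5))
  # baseline subtraction keeps zero deviation at V = 0 for any threshold
  expect_equal(firing_sigmoid(0, slope = 2, threshold = 1.3), 0)
})

test_that("gaussian input peaks at onset and has the right area", {
  expect_equal(gaussian_input(0.07, 0.07, 0.016), 1)
  expect_equal(gaussian_input(0.07 + 0.016, 0.07, 0.016), exp(-0.5))
  expect_equal(gaussian_input(0.07 - 0.016, 0.07, 0.016), exp(-0.5))
  q <- integrate(gaussian_input, -1, 1, onset = 0.07,
                 dispersion = 0.016)$value
  expect_equal(q, 0.016 * sqrt(2 * pi), tolerance = 1e-6)
  expect_error(gaussian_input(0, 0, 0), "positive")
})

test_that("rest with zero input is a fixed point of the dynamics", {
  arch <- two_region_arch()
  design <- oddball_design()
  p <- cmc_parameters(arch, design)
  dx <- cmc_derivatives(rep(0, 16), p, arch, u = 0)
  expect_equal(max(abs(dx)), 0)
  expect_equal(max(abs(attr(dx, "forcing"))), 0)
})

test_that("exogenous input enters spiny stellate acceleration only", {
  arch <- one_region_arch()
  design <- oddball_design()
  p <- cmc_parameters(arch, design)
  dx <- cmc_derivatives(rep(0, 8), p, arch, u = 1)
  # velocities stay zero; only the ss acceleration responds
  expect_equal(dx[1:4], rep(0, 4), ignore_attr = TRUE)
  expect_gt(abs(dx[5]), 0)
  expect_equal(dx[6:8], rep(0, 3), ignore_attr = TRUE)
  expect_error(cmc_derivatives(rep(0, 6), p, arch), "8 entries")
})

test_that("a forward edge routes distal sp firing to target ss and dp", {
  arch <- two_region_arch()   # forward 1 -> 2, backward 2 -> 1
  design <- oddball_design()
  p <- cmc_parameters(arch, design)
  st <- matrix(0, 8, 2)
  st[2, 1] <- 0.5             # depolarise sp in region 1
  dx <- cmc_derivatives(st, p, arch, u = 0)
  f <- attr(dx, "forcing")
  s <- firing_sigmoid(0.5)
  sc <- cmc_scales()
  # region 2 receives exp(0) * s on ss and dp via the forward edge
  expect_equal(f[1, 2], s, tolerance = 1e-12)
  expect_equal(f[4, 2], s + sc$a[["sp_dp"]] * 0, tolerance = 1e-12)
  # region 1 forcing follows the intrinsic terms only (no self edge)
  expect_equal(f[1, 1], -sc$a[["sp_ss"]] * s, tolerance = 1e-12)
  expect_equal(f[3, 1], sc$a[["sp_ii"]] * s, tolerance = 1e-12)
  expect_equal(f[2, 1], -sc$a[["sp_sp"]] * s, tolerance = 1e-12)
})

test_that("condition effects add to extrinsic and self-inhibition gains", {
  arch <- two_region_arch()
  design <- oddball_design()
  p <- cmc_parameters(arch, design)
  # baseline: untouched
  pb <- apply_condition_effects(p, design$baseline_index, design, arch)
  expect_equal(pb$A_f, p$A_f)
  expect_equal(max(abs(pb$a_self_delta)), 0)
  # all-zero effects: every condition shares parameters
  for (ci in 1:4) {
    pc <- apply_condition_effects(p, ci, design, arch)
    expect_equal(pc$A_f, p$A_f)
  }
  # log(2) on the forward edge of the DR effect doubles the effective gain
  p2 <- p
  p2$B[1] <- log(2)
  eff_base <- exp(apply_condition_effects(p2, 1, design, arch)$A_f)
  eff_dr <- exp(apply_condition_effects(p2, 2, design, arch)$A_f)
  expect_equal(eff_dr / eff_base, 2, tolerance = 1e-12)
})

test_that("ERP integration is quiescent without input and damped with it", {
  arch <- one_region_arch()
  design <- oddball_design()
  p <- cmc_parameters(arch, design)
  # theta_C -> -Inf in the limit: a very small input gain leaves rest
  p0 <- p; p0$C <- -300
  erp0 <- integrate_erp(p0, arch, design, 1)
  expect_equal(max(abs(erp0$V)), 0, tolerance = 1e-12)
  # prior-mean parameters: finite, damped response returning toward rest
  erp <- integrate_erp(p, arch, design, 1)
  expect_true(all(is.finite(erp$V)))
  peak <- max(abs(erp$V))
  late <- max(abs(erp$V[erp$time > 0.35, ]))
  expect_gt(peak, 0)
  expect_lt(late, 0.5 * peak)
  expect_error(integrate_erp(p, arch, design, 1, dt = 2e-3), "1 ms")
})

test_that("near-linear regime response scales with input amplitude", {
  arch <- one_region_arch()
  design <- oddball_design()
  p <- cmc_parameters(arch, design)
  # tiny input gains keep every sigmoid in its linear range
  p1 <- p; p1$C <- log(1e-4)
  p2 <- p; p2$C <- log(2e-4)
  e1 <- integrate_erp(p1, arch, design, 1)
  e2 <- integrate_erp(p2, arch, design, 1)
  expect_equal(2 * e1$V, e2$V, tolerance = 1e-4)
})

test_that("halving the integration step barely changes trajectories", {
  arch <- two_region_arch()
  design <- oddball_design()
  p <- cmc_parameters(arch, design)
  a <- integrate_erp(p, arch, design, 1, substeps = 4L)
  b <- integrate_erp(p, arch, design, 1, substeps = 8L)
  rel <- sqrt(sum((a$V - b$V)^2)) / sqrt(sum(b$V^2))
  expect_lt(rel, 1e-4)
})

test_that("stored afferent components reassemble the integrator's forcing", {
  arch <- two_region_arch()
  design <- oddball_design()
  p <- cmc_parameters(arch, design)
  erp <- integrate_erp(p, arch, design, 2)
  pc <- apply_condition_effects(p, 2, design, arch)
  for (i in c(1, 101, 201, 401)) {
    st <- matrix(0, 8, 2)
    st[1:4, 1] <- erp$V[i, 1:4]; st[1:4, 2] <- erp$V[i, 5:8]
    u <- gaussian_input(erp$time[i], p$onset, p$dispersion)
    f_ref <- attr(cmc_derivatives(st, pc, arch, u = u), "forcing")
    f_sum <- erp$exc[i, ] + erp$inh[i, ] + erp$ext[i, ] + erp$inp[i, ]
    expect_equal(as.numeric(f_ref), as.numeric(f_sum), tolerance = 1e-10)
  }
})

test_that("integration failure names the parameter problem", {
  arch <- one_region_arch()
  design <- oddball_design()
  p <- cmc_parameters(arch, design)
  p$kappa[1] <- 5   # rate constant far beyond the integrator's regime
  expect_error(integrate_erp(p, arch, design, 1), "diverged")
})

test_that("trajectories serialise to long-format CSV", {
  arch <- two_region_arch()
  design <- oddball_design()
  erp <- integrate_erp(cmc_parameters(arch, design), arch, design, 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_erp_csv(erp, f)
  df <- read.csv(f)
  expect_setequal(names(df), c("time", "region", "population", "V"))
  expect_equal(nrow(df), length(erp$time) * 8)
  sub <- df[df$region == "R2" & df$population == "sp", ]
  expect_equal(sub$V, unname(erp$V[, 6]), tolerance = 1e-12)
})

test_that("the shipped five-region auditory network is well formed", {
  arch <- auditory_network_architecture()
  expect_equal(arch$n_regions, 5)
  expect_equal(sum(arch$forward), 3)
  expect_equal(arch$forward, t(arch$backward), ignore_attr = TRUE)
  expect_equal(sum(arch$input_regions), 2)
  erp <- integrate_erp(cmc_parameters(arch, oddball_design()), arch,
                       oddball_design(), 1)
  expect_true(all(is.finite(erp$V)))
  expect_gt(max(abs(erp$V)), 0)
})
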