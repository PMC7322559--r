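# Neuronal drive functions: condition-specific per-population response
# templates generated from the (posterior) neuronal model, resampled to the
# fMRI microtime grid and shifted-and-summed over event onsets.

#' Define the event schedule of an fMRI run
#'
#' @param events data frame with columns `onset` (s), `duration` (s) and
#'   `condition`.
#' @param duration total run duration in seconds.
#' @param TR repetition time in seconds.
#' @param dt_micro microtime step in seconds (must divide TR).
#' @return object of class `event_schedule`.
#' @export
event_schedule <- function(events, duration, TR, dt_micro = 0.1) {
  stopifnot(all(c("onset", "condition") %in% names(events)))
  if (any(events$onset < 0 | events$onset >= duration))
    stop("onsets must lie within [0, duration)")
  if (abs(TR / dt_micro - round(TR / dt_micro)) > 1e-9)
    stop("microtime step must divide TR")
  structure(list(events = events, duration = duration, TR = TR,
                 dt_micro = dt_micro,
                 n_micro = as.integer(round(duration / dt_micro)),
                 n_scans = as.integer(floor(duration / TR))),
            class = "event_schedule")
}

# software-note exclusion-vector ordering (sp, ii, excitatory
# interneurons ~ ss, dp) -> canonical (ss, sp, ii, dp)
.mask_to_canonical <- function(O, order = c("canonical", "software")) {
  order <- match.arg(order)
  O <- as.numeric(O)
  stopifnot(length(O) == 4)
  if (order == "software") O <- O[c(3, 1, 2, 4)] else O
}

# channel labels per region for a given parameterisation
.drive_channels <- function(parameterisation, distal) {
  base <- switch(parameterisation,
                 pre = paste0("pre.", .POPS),
                 post = paste0("post.", .POPS),
                 decomposed = c("excitatory", "inhibitory"))
  if (identical(distal, "include")) {
    extra <- if (parameterisation == "decomposed") "extrinsic"
             else paste0("ext.", .POPS)
    base <- c(base, extra)
  }
  base
}

#' Compute condition-specific neuronal drive templates
#'
#' Integrates the neuronal model at the supplied (posterior-mean) parameters
#' for every condition and assembles per-region drive channels on the ERP
#' time grid: `pre` uses the signed afferent (presynaptic) components of the
#' forcing term per population (the exogenous input counts as a presynaptic
#' afferent of the spiny stellates); `post` uses the depolarisations; and
#' `decomposed` groups the presynaptic components into excitatory (terms
#' from ss/sp/dp sources plus the exogenous input), inhibitory (terms from
#' interneurons and self-inhibition) and extrinsic channels.  With
#' `distal = "include"` the A-weighted afferents from other regions become
#' separate channels; with `"exclude"` they are dropped.  The exclusion mask
#' zeroes all channels associated with an excluded population.
#'
#' @param source an `erp_inversion` (posterior means are used) or a
#'   parameter list as from [cmc_parameters()].
#' @param arch,design architecture and design (taken from `source` when it
#'   is an inversion).
#' @param signal_type one of "pre", "post", "decomposed".
#' @param distal "include", "exclude" or "na" (required "na" for "post").
#' @param exclusion_mask 4-vector of 0/1 over populations.
#' @param mask_order "canonical" (ss, sp, ii, dp) or "software"
#'   (sp, ii, ss, dp).
#' @param t_end,dt,substeps integration window and grid (see
#'   [integrate_erp()]).
#' @return object of class `drive_template`: per-condition matrices
#'   (time x regions*channels, region-major), plus channel metadata.
#' @export
compute_condition_drives <- function(source, arch = NULL, design = NULL,
                                     signal_type = c("pre", "post",
                                                     "decomposed"),
                                     distal = c("exclude", "include", "na"),
                                     exclusion_mask = c(1, 1, 1, 1),
                                     mask_order = "canonical",
                                     t_end = 0.4, dt = 1e-3, substeps = 4L) {
  signal_type <- match.arg(signal_type)
  distal <- match.arg(distal)
  if (signal_type == "post" && distal == "include")
    stop("postsynaptic drives have no distal option (use 'na')")
  if (signal_type != "post" && distal == "na") distal <- "exclude"
  if (inherits(source, "erp_inversion")) {
    params <- source$posterior_params
    arch <- source$arch
    design <- source$design
  } else params <- source
  mask <- .mask_to_canonical(exclusion_mask, mask_order)
  channels <- .drive_channels(signal_type, distal)
  nch <- length(channels)
  R <- arch$n_regions
  n_cond <- length(design$condition_names)
  out <- vector("list", n_cond)
  for (ci in seq_len(n_cond)) {
    erp <- integrate_erp(params, arch, design, ci, t_end = t_end, dt = dt,
                         substeps = substeps)
    X <- matrix(0, length(erp$time), R * nch)
    for (k in seq_len(R)) {
      cols <- (k - 1) * 4 + 1:4
      blk <- (k - 1) * nch
      if (signal_type == "post") {
        for (p in 1:4) X[, blk + p] <- mask[p] * erp$V[, cols[p]]
      } else if (signal_type == "pre") {
        loc <- erp$exc[, cols] + erp$inh[, cols] + erp$inp[, cols]
        for (p in 1:4) X[, blk + p] <- mask[p] * loc[, p]
        if (distal == "include")
          for (p in 1:4) X[, blk + 4 + p] <- mask[p] * erp$ext[, cols[p]]
      } else {
        mw <- matrix(mask, length(erp$time), 4, byrow = TRUE)
        X[, blk + 1] <- rowSums(mw * (erp$exc[, cols] + erp$inp[, cols]))
        X[, blk + 2] <- rowSums(mw * erp$inh[, cols])
        if (distal == "include")
          X[, blk + 3] <- rowSums(mw * erp$ext[, cols])
      }
    }
    out[[ci]] <- X
  }
  names(out) <- design$condition_names
  structure(list(templates = out, dt = dt, t_end = t_end,
                 signal_type = signal_type, distal = distal,
                 channels = channels, n_channels = nch,
                 exclusion_mask = mask,
                 region_names = arch$region_names, n_regions = R),
            class = "drive_template")
}

#' Resample drive templates to the microtime grid
#'
#' Integration-preserving binning: each microtime sample is the mean of the
#' fine-grid samples in its bin, so the time integral of the drive is
#' conserved.
#'
#' @param template a `drive_template` on the fine ERP grid.
#' @param dt_micro target step (s), a multiple of the template step.
#' @return a `drive_template` on the microtime grid.
#' @export
resample_drives <- function(template, dt_micro) {
  ratio <- dt_micro / template$dt
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("microtime step must be a multiple of the template step")
  ratio <- as.integer(round(ratio))
  out <- lapply(template$templates, function(X) {
    n <- (nrow(X) - 1) %/% ratio        # drop the trailing sample
    grp <- rep(seq_len(n), each = ratio)
    apply(X[seq_len(n * ratio), , drop = FALSE], 2,
          function(col) tapply(col, grp, mean))
  })
  template$templates <- lapply(out, function(X)
    matrix(X, ncol = template$n_regions * template$n_channels))
  template$dt <- dt_micro
  template
}

#' Shift-and-sum drive templates over event onsets
#'
#' Linear superposition of the time-shifted condition templates at their
#' onsets on the microtime grid; overlapping events add.
#'
#' @param template a `drive_template` on the microtime grid (see
#'   [resample_drives()]).
#' @param schedule an `event_schedule`.
#' @return matrix (n_micro x regions*channels) with the template metadata in
#'   attributes `channels`, `n_regions`, `dt`.
#' @export
shift_and_sum <- function(template, schedule) {
  if (abs(template$dt - schedule$dt_micro) > 1e-12)
    stop("template must be on the schedule's microtime grid ",
         "(see resample_drives)")
  n <- schedule$n_micro
  Z <- matrix(0, n, template$n_regions * template$n_channels)
  for (ci in seq_along(template$templates)) {
    cond <- names(template$templates)[ci]
    on <- schedule$events$onset[schedule$events$condition == cond]
    if (!length(on)) next
    if (any(on >= schedule$duration)) stop("onset beyond run duration")
    Tm <- template$templates[[ci]]
    len <- nrow(Tm)
    for (t0 in on) {
      i0 <- as.integer(round(t0 / template$dt))
      if (i0 >= n) next
      take <- seq_len(min(len, n - i0))
      Z[i0 + take, ] <- Z[i0 + take, ] + Tm[take, , drop = FALSE]
    }
  }
  attr(Z, "channels") <- template$channels
  attr(Z, "n_regions") <- template$n_regions
  attr(Z, "dt") <- template$dt
  Z
}

#' Write drive signals as long-format CSV
#'
#' @param z drive matrix from [shift_and_sum()].
#' @param path output file.
#' @export
write_drives_csv <- function(z, path) {
  ch <- attr(z, "channels"); R <- attr(z, "n_regions"); dt <- attr(z, "dt")
  nch <- length(ch)
  time <- (seq_len(nrow(z)) - 1) * dt
  df <- data.frame(
    time = rep(time, nch * R),
    region = rep(rep(seq_len(R), each = nrow(z)), each = nch)[
      seq_len(nrow(z) * nch * R)],
    channel = rep(rep(ch, each = nrow(z)), times = R),
    value = as.vector(z))
  df$region <- rep(seq_len(R), each = nrow(z) * nch)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
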