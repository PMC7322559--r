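# Block-structured parameter handling.
#
# Priors are named lists of blocks, each with `mean` and diagonal `variance`
# vectors.  Parameters with zero prior variance are pinned to their prior
# mean and excluded from the estimation vector; the remaining (free) entries
# are flattened into one vector for variational Laplace.

.pt_index <- function(priors) {
  blocks <- names(priors)
  free <- list(); mu0 <- c(); v0 <- c(); labels <- c()
  for (b in blocks) {
    v <- priors[[b]]$variance
    idx <- which(v > 0)
    free[[b]] <- idx
    if (length(idx)) {
      mu0 <- c(mu0, priors[[b]]$mean[idx])
      v0 <- c(v0, v[idx])
      labels <- c(labels, paste0(b, "[", idx, "]"))
    }
  }
  list(free = free, mu0 = mu0, v0 = v0, labels = labels,
       n_free = length(mu0))
}

.pt_unflatten <- function(theta, priors, index) {
  out <- lapply(priors, function(b) b$mean)
  pos <- 0L
  for (b in names(priors)) {
    idx <- index$free[[b]]
    if (length(idx)) {
      out[[b]][idx] <- theta[pos + seq_along(idx)]
      pos <- pos + length(idx)
    }
  }
  out
}

.pt_flatten <- function(params, priors, index) {
  theta <- numeric(index$n_free)
  pos <- 0L
  for (b in names(priors)) {
    idx <- index$free[[b]]
    if (length(idx)) {
      theta[pos + seq_along(idx)] <- params[[b]][idx]
      pos <- pos + length(idx)
    }
  }
  theta
}

# locate the flat-vector positions of one block (free entries only)
.pt_block_positions <- function(index, block) {
  pos <- 0L
  for (b in names(index$free)) {
    k <- length(index$free[[b]])
    if (b == block) return(if (k) pos + seq_len(k) else integer(0))
    pos <- pos + k
  }
  integer(0)
}
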