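# Independent oracles used across the suite. These deliberately re-derive
# quantities with naive algorithms (loops, exhaustive scans) so they share
# no code path with the package implementation.

# --- duplex Tm oracle: explicit per-step nearest-neighbor summation over
# the ten unique duplex steps, reverse-complement lookup done by hand.
oracle_tm <- function(seq, na_molar = 0.39, conc_molar = 5e-7) {
  pair_dh <- list(
    AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
    CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  pair_ds <- list(
    AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
    CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  canonical <- function(step) {
    # a doublet shares parameters with its reverse complement
    if (step %in% names(pair_dh)) return(step)
    paste0(comp[substr(step, 2, 2)], comp[substr(step, 1, 1)])
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  dh <- 0; ds <- 0
  for (i in seq_len(length(chars) - 1)) {
    key <- canonical(paste0(chars[i], chars[i + 1]))
    dh <- dh + pair_dh[[key]]
    ds <- ds + pair_ds[[key]]
  }
  for (end in c(chars[1], chars[length(chars)])) {
    if (end %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (length(chars) - 1) * log(na_molar)
  1000 * dh / (ds + 1.9872 * log(conc_molar / 4)) - 273.15
}

# --- exhaustive integer-shift search: maximize normalized circular
# cross-correlation by brute force.
oracle_shift <- function(reference, moving, max_shift) {
  a <- reference - mean(reference); b <- moving - mean(moving)
  ny <- nrow(a); nx <- ncol(a)
  best <- c(NA, NA); best_val <- -Inf
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    rolled <- b[((seq_len(ny) - 1 + dy) %% ny) + 1,
                ((seq_len(nx) - 1 + dx) %% nx) + 1]
    v <- sum(a * rolled) / sqrt(sum(a^2) * sum(b^2))
    if (v > best_val + 1e-12) { best_val <- v; best <- c(dy, dx) }
  }
  list(dy = best[1], dx = best[2], peak = best_val)
}

# --- brute-force signed distance to a mask boundary: scan every mask
# pixel, test its 4-neighborhood explicitly.
oracle_nucleus_distance <- function(y, x, mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  best <- Inf
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (mask[i, j] <= 0) next
    nb_out <- i == 1 || i == ny || j == 1 || j == nx ||
      mask[i - 1, j] <= 0 || mask[i + 1, j] <= 0 ||
      mask[i, j - 1] <= 0 || mask[i, j + 1] <= 0
    if (!nb_out) next
    d <- sqrt((i - 1 - y)^2 + (j - 1 - x)^2)
    if (d < best) best <- d
  }
  yi <- min(max(round(y) + 1, 1), ny); xi <- min(max(round(x) + 1, 1), nx)
  if (mask[yi, xi] > 0) -best else best
}

# --- tiny image with Gaussian spots, built directly from the formula.
gauss_image <- function(ny, nx, ys, xs, amps, sigma, background = 0) {
  img <- matrix(background, ny, nx)
  for (k in seq_along(ys)) {
    for (i in seq_len(ny)) for (j in seq_len(nx)) {
      img[i, j] <- img[i, j] +
        amps[k] * exp(-((i - 1 - ys[k])^2 + (j - 1 - xs[k])^2) / (2 * sigma^2))
    }
  }
  img
}

# circularly roll a matrix so content moves by (dy, dx)
roll2 <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  m[((seq_len(ny) - 1 - dy) %% ny) + 1, ((seq_len(nx) - 1 - dx) %% nx) + 1]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
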