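#' Simulation configuration
#'
#' Parameters of the synthetic multi-round acquisition model: diffraction-
#' limited spots are isotropic 2-D Gaussians of width `psf_sigma`; each
#' imaging round adds a constant `background`, optional Poisson shot noise
#' and Gaussian read noise; the stage drifts by a rigid per-round
#' translation; probe stripping between rounds leaves behind a fraction
#' `residual_fraction` of the previous round's signal at the same physical
#' position; and each spot independently fails to appear in a round with
#' probability `dropout_prob` (producing a missing digit downstream).
#' Intensities are photon-like counts on a 16-bit scale, clipped to
#' `[0, 65535]`, never wrapped.
#'
#' @param ny,nx Image size in pixels.
#' @param n_rounds Number of hybridization/imaging rounds.
#' @param channels Channel names; the last entry is the nuclear/fiducial
#'   channel, constant across rounds.
#' @param psf_sigma Gaussian PSF sigma in pixels.
#' @param amplitude_mean,amplitude_sd Per-spot peak amplitude distribution
#'   (truncated normal, counts above background).
#' @param background Constant background level in counts.
#' @param read_noise_sd Gaussian read-noise standard deviation in counts.
#' @param poisson_noise Add Poisson shot noise when `TRUE`.
#' @param drift Either `NULL` (draw uniform integer drifts in
#'   `[-drift_max, drift_max]`, round 1 fixed at zero) or an
#'   `n_rounds x 2` matrix of (dy, dx) translations, possibly fractional.
#' @param drift_max Bound for randomly drawn drifts, pixels.
#' @param residual_fraction Fraction of a round's signal carried into the
#'   next round after probe stripping; must be in `[0, 1)`.
#' @param dropout_prob Per-spot per-round probability of a missing signal.
#' @param min_separation Minimum center-to-center spot distance, pixels.
#' @param pixel_size_um Pixel size metadata, micrometres.
#' @param seed Integer seed fixing the entire scene.
#' @return A `sim_config` list.
#' @export
sim_config <- function(ny = 256L, nx = 256L, n_rounds = 2L,
                       channels = c("Cy5", "Cy3", "FAM", "DAPI"),
                       psf_sigma = 1.3, amplitude_mean = 3000,
                       amplitude_sd = 300, background = 100,
                       read_noise_sd = 5, poisson_noise = TRUE,
                       drift = NULL, drift_max = 3,
                       residual_fraction = 0.05, dropout_prob = 0,
                       min_separation = 4, pixel_size_um = 0.108,
                       seed = 1L) {
  if (residual_fraction < 0 || residual_fraction >= 1)
    stop_input("residual_fraction must be in [0, 1)")
  if (!is.null(drift)) {
    drift <- as.matrix(drift)
    if (nrow(drift) != n_rounds || ncol(drift) != 2L)
      stop_input("drift must be an n_rounds x 2 matrix")
    if (max(abs(drift)) >= min(ny, nx) / 4)
      stop_input("drift magnitude must stay below a quarter of the image")
  }
  structure(list(ny = as.integer(ny), nx = as.integer(nx),
                 n_rounds = as.integer(n_rounds), channels = channels,
                 psf_sigma = psf_sigma, amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd, background = background,
                 read_noise_sd = read_noise_sd, poisson_noise = poisson_noise,
                 drift = drift, drift_max = drift_max,
                 residual_fraction = residual_fraction,
                 dropout_prob = dropout_prob, min_separation = min_separation,
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "sim_config")
}

# Add isotropic Gaussian spots to a matrix; kernel truncated at >= 5 sigma.
# Positions are 0-based pixel coordinates (matrix row i holds y = i - 1);
# sigma may be scalar or per-spot.
render_spots <- function(img, ys, xs, amps, sigma) {
  if (!length(ys)) return(img)
  ny <- nrow(img); nx <- ncol(img)
  sig <- rep_len(sigma, length(ys))
  for (k in seq_along(ys)) {
    sigma <- sig[k]
    r <- ceiling(5 * sigma)
    y0 <- ys[k]; x0 <- xs[k]
    iy <- max(1L, floor(y0) + 1L - r):min(ny, ceiling(y0) + 1L + r)
    ix <- max(1L, floor(x0) + 1L - r):min(nx, ceiling(x0) + 1L + r)
    if (iy[1] > iy[length(iy)] || ix[1] > ix[length(ix)]) next
    gy <- exp(-((iy - 1 - y0)^2) / (2 * sigma^2))
    gx <- exp(-((ix - 1 - x0)^2) / (2 * sigma^2))
    img[iy, ix] <- img[iy, ix] + amps[k] * (gy %o% gx)
  }
  img
}

# Rejection-sample n points with pairwise distance >= min_sep inside a
# margin; returns possibly fewer points with a warning.
sample_positions <- function(n, ny, nx, min_sep, margin) {
  ys <- numeric(0); xs <- numeric(0)
  tries <- 0L; max_tries <- 200L * n
  while (length(ys) < n && tries < max_tries) {
    tries <- tries + 1L
    y <- stats::runif(1, margin, ny - margin)
    x <- stats::runif(1, margin, nx - margin)
    if (length(ys) && min((ys - y)^2 + (xs - x)^2) < min_sep^2) next
    ys <- c(ys, y); xs <- c(xs, x)
  }
  if (length(ys) < n)
    warning(sprintf("spot density too high: placed %d of %d requested spots",
                    length(ys), n))
  cbind(y = ys, x = xs)
}

draw_drift <- function(config) {
  if (!is.null(config$drift)) return(config$drift)
  d <- matrix(0, config$n_rounds, 2)
  if (config$n_rounds > 1L)
    d[-1L, ] <- sample(seq(-config$drift_max, config$drift_max),
                       2L * (config$n_rounds - 1L), replace = TRUE)
  d
}

fiducial_field <- function(config, n_blobs = 25L, blob_sigma = 5,
                           blob_amp = 1500) {
  pos <- cbind(stats::runif(n_blobs, 10, config$ny - 10),
               stats::runif(n_blobs, 10, config$nx - 10))
  list(pos = pos, sigma = blob_sigma,
       amp = stats::runif(n_blobs, 0.5, 1) * blob_amp)
}

# Shot + read noise, then quantization to integer counts on a 16-bit range
# (clipped, never wrapped); integer counts round-trip TIFF storage exactly.
add_noise <- function(img, config) {
  if (config$poisson_noise)
    img <- matrix(stats::rpois(length(img), pmax(img, 0)), nrow(img))
  if (config$read_noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, config$read_noise_sd)
  pmin(pmax(round(img), 0), 65535)
}

new_round_stack <- function(rounds, channels, pixel_size_um) {
  structure(list(rounds = rounds, channels = channels,
                 pixel_size_um = pixel_size_um), class = "round_stack")
}

#' @export
print.round_stack <- function(x, ...) {
  d <- dim(x$rounds[[1]][[1]])
  cat(sprintf("<round_stack> %d rounds x %d channels (%s), %dx%d px, %.3f um/px\n",
              length(x$rounds), length(x$channels),
              paste(x$channels, collapse = ","), d[1], d[2], x$pixel_size_um))
  invisible(x)
}

# Render the FISH channels of one scene given per-spot positions and codes.
# Residual signal: a fraction rho of the total signal a spot emitted in
# round r-1 (in whichever channel) persists into round r at the same
# physical position. Returns stack plus the per-round drift actually used.
render_scene <- function(config, codebook, spots, fid) {
  drift <- draw_drift(config)
  fish_ch <- setdiff(config$channels, config$channels[length(config$channels)])
  dapi_ch <- config$channels[length(config$channels)]
  digit_of <- stats::setNames(names(codebook$channel_digit_map),
                              codebook$channel_digit_map)
  nspot <- nrow(spots)
  dropout <- matrix(stats::runif(nspot * config$n_rounds) < config$dropout_prob,
                    nspot, config$n_rounds)
  # residual amplitude carried per spot per channel
  res <- matrix(0, nspot, length(fish_ch), dimnames = list(NULL, fish_ch))
  rounds <- vector("list", config$n_rounds)
  for (r in seq_len(config$n_rounds)) {
    dy <- drift[r, 1]; dx <- drift[r, 2]
    emitted <- matrix(0, nspot, length(fish_ch), dimnames = list(NULL, fish_ch))
    if (nspot) for (k in seq_len(nspot)) {
      dig <- substr(spots$code[k], r, r)
      if (dig == "0" || dropout[k, r]) next
      emitted[k, digit_of[[dig]]] <- spots$amplitude[k]
    }
    planes <- list()
    for (ch in fish_ch) {
      amp <- emitted[, ch] + res[, ch]
      keep <- which(amp > 0)
      img <- matrix(config$background, config$ny, config$nx)
      img <- render_spots(img, spots$y[keep] + dy, spots$x[keep] + dx,
                          amp[keep], config$psf_sigma)
      planes[[ch]] <- add_noise(img, config)
    }
    dimg <- matrix(config$background, config$ny, config$nx)
    dimg <- render_spots(dimg, fid$pos[, 1] + dy, fid$pos[, 2] + dx,
                         fid$amp, fid$sigma)
    planes[[dapi_ch]] <- add_noise(dimg, config)
    rounds[[r]] <- planes[config$channels]
    res <- config$residual_fraction * (emitted + res)
  }
  list(stack = new_round_stack(rounds, config$channels, config$pixel_size_um),
       drift = drift, dropout = dropout)
}

#' Simulate a multi-round spot field with ground truth
#'
#' Places `n_spots` diffraction-limited spots, assigns each a target drawn
#' from the codebook (uniformly, or by `gene_weights`), and renders every
#' round: a spot appears in exactly the color channel named by its code
#' digit for that round, displaced by the round's drift, on top of
#' background, shot noise, read noise and stripping residuals. The last
#' channel carries a static fiducial blob field (nuclear-stain stand-in)
#' usable for registration.
#'
#' @param config A [sim_config()].
#' @param codebook A [build_codebook()] codebook with
#'   `n_rounds == config$n_rounds`.
#' @param n_spots Number of spots to place.
#' @param gene_weights Optional sampling weights over codebook entries.
#' @return List with `stack` (a `round_stack`), and `truth`: `spots` data
#'   frame (`id`, `y`, `x`, `gene`, `code`, `amplitude`), `drift` (per-round
#'   dy/dx) and `dropout` (spot x round logical matrix).
#' @export
simulate_spot_field <- function(config, codebook, n_spots,
                                gene_weights = NULL) {
  validate_codebook(codebook)
  if (codebook$n_rounds != config$n_rounds)
    stop_input("codebook has %d rounds but config has %d", codebook$n_rounds,
               config$n_rounds)
  with_seed(config$seed, {
    pos <- sample_positions(n_spots, config$ny, config$nx,
                            config$min_separation, margin = 10)
    n <- nrow(pos)
    genes <- if (n) sample(names(codebook$entries), n, replace = TRUE,
                           prob = gene_weights) else character(0)
    amps <- if (n) pmax(stats::rnorm(n, config$amplitude_mean,
                                     config$amplitude_sd),
                        config$amplitude_mean / 4) else numeric(0)
    spots <- data.frame(id = seq_len(n), y = pos[, 1], x = pos[, 2],
                        gene = genes,
                        code = unname(codebook$entries[genes]),
                        amplitude = amps, stringsAsFactors = FALSE)
    if (n == 0L) spots$code <- character(0)
    sc <- render_scene(config, codebook, spots, fiducial_field(config))
    list(stack = sc$stack,
         truth = list(spots = spots,
                      drift = data.frame(round = seq_len(config$n_rounds),
                                         dy = sc$drift[, 1], dx = sc$drift[, 2]),
                      dropout = sc$dropout))
  })
}

#' Simulate a segmented tissue scene with cell-type barcodes
#'
#' Packs non-overlapping circular cells on a jittered grid, assigns each
#' cell a type (by frequency sampling, or by depth band in `layered` mode),
#' and fills it with spots that all carry the cell type's optical code
#' (marker genes of one type share the code). Per-cell spot counts are
#' Poisson with mean `markers_per_type * spots_per_marker_mean`. The last
#' channel holds a nuclear disk per cell, serving as DAPI fiducial; the
#' returned label mask is the ground-truth segmentation.
#'
#' @param config A [sim_config()].
#' @param codebook A per-cell-type codebook ([assign_panel()]).
#' @param n_cells Number of cells requested; fewer are placed (with a
#'   warning) if the field cannot pack them.
#' @param type_frequencies Named numeric vector over cell types, summing
#'   to 1.
#' @param markers_per_type Marker genes per cell type.
#' @param spots_per_marker_mean Mean spots per marker gene per cell.
#' @param layered If `TRUE`, assign types by horizontal depth bands (band
#'   heights proportional to `type_frequencies`, band order = order of
#'   `names(type_frequencies)`) instead of random sampling.
#' @param cell_radius Range (min, max) of cell radii in pixels.
#' @return List with `stack`, `mask` (integer label matrix), and `truth`:
#'   `cells` data frame (`label`, `y`, `x`, `radius`, `cell_type`, `code`,
#'   `band`), `spots`, `drift`, `band_edges` (layered mode).
#' @export
simulate_tissue <- function(config, codebook, n_cells, type_frequencies,
                            markers_per_type = 10, spots_per_marker_mean = 3,
                            layered = FALSE, cell_radius = c(6, 9)) {
  validate_codebook(codebook)
  if (codebook$panel_mode != "per_cell_type")
    stop_input("tissue simulation needs a per-cell-type codebook")
  if (abs(sum(type_frequencies) - 1) > 1e-6)
    stop_input("type_frequencies must sum to 1")
  types <- names(type_frequencies)
  if (!all(types %in% names(codebook$entries)))
    stop_input("type_frequencies names must match codebook cell types")
  with_seed(config$seed, {
    rmax <- cell_radius[2]
    spacing <- 2 * rmax + 3
    margin <- rmax + 4
    gy <- seq(margin, config$ny - margin, by = spacing)
    gx <- seq(margin, config$nx - margin, by = spacing)
    grid <- expand.grid(y = gy, x = gx)
    if (n_cells > nrow(grid)) {
      warning(sprintf("field packs only %d cells; %d requested", nrow(grid),
                      n_cells))
      n_cells <- nrow(grid)
    }
    pick <- sample(nrow(grid), n_cells)
    cy <- grid$y[pick] + stats::runif(n_cells, -1.5, 1.5)
    cx <- grid$x[pick] + stats::runif(n_cells, -1.5, 1.5)
    rad <- stats::runif(n_cells, cell_radius[1], cell_radius[2])
    band_edges <- NULL
    if (layered) {
      band_edges <- c(0, cumsum(type_frequencies) / sum(type_frequencies)) *
        config$ny
      band <- findInterval(cy, band_edges, rightmost.closed = TRUE)
      band <- pmin(pmax(band, 1L), length(types))
      ctype <- types[band]
    } else {
      ctype <- sample(types, n_cells, replace = TRUE, prob = type_frequencies)
      band <- rep(NA_integer_, n_cells)
    }
    cells <- data.frame(label = seq_len(n_cells), y = cy, x = cx,
                        radius = rad, cell_type = ctype,
                        code = unname(codebook$entries[ctype]), band = band,
                        stringsAsFactors = FALSE)
    # label mask: disks (grid spacing guarantees non-overlap)
    mask <- matrix(0L, config$ny, config$nx)
    yy <- row(mask) - 1; xx <- col(mask) - 1   # 0-based pixel coordinates
    for (k in seq_len(n_cells)) {
      sel <- (yy - cy[k])^2 + (xx - cx[k])^2 <= rad[k]^2
      mask[sel] <- k
    }
    # spots inside each cell
    sp <- list()
    for (k in seq_len(n_cells)) {
      m <- stats::rpois(1, markers_per_type * spots_per_marker_mean)
      if (m == 0L) next
      # keep spots >= 1 px inside the rim so pixel rounding stays in-label
      rr <- pmin(rad[k] * sqrt(stats::runif(m)), rad[k] - 1)
      th <- stats::runif(m, 0, 2 * pi)
      sp[[length(sp) + 1L]] <- data.frame(
        label = k, y = cy[k] + rr * sin(th), x = cx[k] + rr * cos(th),
        gene = ctype[k], code = cells$code[k],
        amplitude = pmax(stats::rnorm(m, config$amplitude_mean,
                                      config$amplitude_sd),
                         config$amplitude_mean / 4))
    }
    spots <- if (length(sp)) do.call(rbind, sp)
      else data.frame(label = integer(), y = numeric(), x = numeric(),
                      gene = character(), code = character(),
                      amplitude = numeric())
    spots$id <- seq_len(nrow(spots))
    fid <- list(pos = cbind(cy, cx), sigma = pmax(rad / 2.5, 1.5),
                amp = rep(1200, n_cells))
    sc <- render_scene(config, codebook, spots, fid)
    list(stack = sc$stack, mask = mask,
         truth = list(cells = cells, spots = spots,
                      drift = data.frame(round = seq_len(config$n_rounds),
                                         dy = sc$drift[, 1], dx = sc$drift[, 2]),
                      band_edges = band_edges))
  })
}

#' Simulate repeated hybridize/image/strip cycles of one labeled cell
#'
#' Renders a single labeled cell over `n_rounds` cycles. Each cycle
#' hybridizes fresh probes contributing a fixed signal `S` above background
#' inside the cell, images (post-hybridization frame), then strips probes,
#' leaving `residual_fraction` of the bound signal (post-cleavage frame).
#' Bound signal therefore follows `B_r = S + rho * B_(r-1)`, so the
#' post-hybridization contrast `(bg + B_r)/bg` stays near the configured
#' signal-to-background ratio while the post-cleavage frame decays to
#' background.
#'
#' @param config A [sim_config()]; `residual_fraction` is the stripping
#'   residue `rho`.
#' @param n_rounds Number of cycles.
#' @param signal_to_background Target post-hybridization contrast; fresh
#'   signal per round is `(signal_to_background - 1) * background`.
#' @return Data frame with `round`, `post_hyb_mean`, `post_cleave_mean`,
#'   `background` (measured outside the cell), `contrast_ratio`.
#' @export
simulate_hybridize_cleave_series <- function(config, n_rounds = 15L,
                                             signal_to_background = 10) {
  with_seed(config$seed, {
    ny <- config$ny; nx <- config$nx
    cyx <- c(ny, nx) / 2
    rad <- min(ny, nx) / 5
    yy <- row(matrix(0, ny, nx)); xx <- col(matrix(0, ny, nx))
    cellmask <- (yy - cyx[1])^2 + (xx - cyx[2])^2 <= rad^2
    S <- (signal_to_background - 1) * config$background
    B <- 0
    out <- data.frame(round = seq_len(n_rounds), post_hyb_mean = NA_real_,
                      post_cleave_mean = NA_real_, background = NA_real_,
                      contrast_ratio = NA_real_)
    for (r in seq_len(n_rounds)) {
      B <- S + config$residual_fraction * B
      hyb <- matrix(config$background, ny, nx)
      hyb[cellmask] <- hyb[cellmask] + B
      hyb <- add_noise(hyb, config)
      stripped <- matrix(config$background, ny, nx)
      stripped[cellmask] <- stripped[cellmask] + config$residual_fraction * B
      stripped <- add_noise(stripped, config)
      bg_meas <- mean(hyb[!cellmask])
      out$post_hyb_mean[r] <- mean(hyb[cellmask])
      out$post_cleave_mean[r] <- mean(stripped[cellmask])
      out$background[r] <- bg_meas
      out$contrast_ratio[r] <- out$post_hyb_mean[r] / bg_meas
    }
    out
  })
}
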