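# Signed FFT frequency indices 0,1,...,-1 (numpy fftfreq * n).
fft_freqs <- function(n) {
  idx <- 0:(n - 1)
  ifelse(idx < (n + 1) %/% 2, idx, idx - n)
}

#' Estimate the rigid shift between two images by cross-correlation
#'
#' Finds the translation of `moving` relative to `reference` as the argmax
#' of the mean-subtracted, globally normalized circular cross-correlation,
#' computed via FFT and searched within `max_shift` pixels. The returned
#' `(dy, dx)` is the displacement that `moving` has undergone: a copy of
#' the reference circularly shifted by `(3, -2)` yields the estimate
#' `(3, -2)`. Ties at the correlation peak are broken by the smallest
#' shift magnitude, then row-major order. With `subpixel = TRUE` the
#' integer peak is refined on a 10x upsampled local correlation evaluated
#' by a matrix-multiply discrete Fourier transform.
#'
#' @param reference,moving Numeric matrices of identical shape with finite
#'   values.
#' @param max_shift Search bound in pixels (applies to each axis).
#' @param subpixel Refine the peak to fractional pixels when `TRUE`.
#' @param upsample Upsampling factor for the subpixel refinement.
#' @return A `shift_estimate`: list with `dy`, `dx`, `peak` (normalized
#'   correlation at the optimum) and `max_shift`.
#' @export
estimate_shift <- function(reference, moving, max_shift = 10L,
                           subpixel = FALSE, upsample = 10L) {
  if (!is.matrix(reference) || !is.matrix(moving) ||
      !all(dim(reference) == dim(moving)))
    stop_input("reference and moving must be matrices of identical shape")
  if (!all(is.finite(reference)) || !all(is.finite(moving)))
    stop_input("images must contain only finite values")
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop(errorCondition("constant image: cross-correlation undefined",
                        class = c("spotcode_degenerate_error",
                                  "spotcode_input_error", "error")))
  ny <- nrow(a); nx <- ncol(a)
  P <- Conj(stats::fft(a)) * stats::fft(b)
  cc <- Re(stats::fft(P, inverse = TRUE)) / (ny * nx) / (na * nb)
  ms <- min(max_shift, floor(ny / 2) - 1L, floor(nx / 2) - 1L)
  cand_dy <- -ms:ms
  cand_dx <- -ms:ms
  iy <- (cand_dy %% ny) + 1L
  ix <- (cand_dx %% nx) + 1L
  sub <- cc[iy, ix, drop = FALSE]
  best <- which(sub == max(sub), arr.ind = TRUE)
  if (nrow(best) > 1L) {
    dy_c <- cand_dy[best[, 1]]; dx_c <- cand_dx[best[, 2]]
    ord <- order(dy_c^2 + dx_c^2, dy_c, dx_c)
    best <- best[ord[1L], , drop = FALSE]
  }
  dy <- as.numeric(cand_dy[best[1, 1]])
  dx <- as.numeric(cand_dx[best[1, 2]])
  peak <- sub[best[1, 1], best[1, 2]]
  if (subpixel) {
    # evaluate c(u) = sum_k P(k) exp(2 pi i k u / N) on a fine grid around
    # the integer peak
    hw <- 1.5
    uy <- dy + seq(-hw, hw, by = 1 / upsample)
    ux <- dx + seq(-hw, hw, by = 1 / upsample)
    ky <- fft_freqs(ny); kx <- fft_freqs(nx)
    Ey <- exp(2i * pi * outer(uy, ky) / ny)   # nu x ny
    Ex <- exp(2i * pi * outer(kx, ux) / nx)   # nx x nu
    cc_up <- Re(Ey %*% P %*% Ex) / (ny * nx) / (na * nb)
    w <- which(cc_up == max(cc_up), arr.ind = TRUE)[1, ]
    dy <- uy[w[1]]; dx <- ux[w[2]]
    peak <- max(cc_up)
  }
  structure(list(dy = dy, dx = dx, peak = peak, max_shift = max_shift),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("<shift_estimate> dy=%.3f dx=%.3f peak=%.4f\n", x$dy, x$dx,
              x$peak))
  invisible(x)
}

#' Translate an image by a rigid shift
#'
#' Moves image content by `(dy, dx)`: `out[y, x] = in[y - dy, x - dx]`.
#' Integer shifts relocate pixels and fill vacated regions with `fill`
#' (default `NA`, masked from downstream statistics); fractional shifts use
#' an exact Fourier phase shift (periodic boundary), which round-trips
#' losslessly.
#'
#' @param img Numeric matrix.
#' @param dy,dx Shift in pixels, possibly fractional.
#' @param fill Fill value for vacated pixels (integer shifts only).
#' @return Translated matrix.
#' @export
translate_image <- function(img, dy, dx, fill = NA_real_) {
  ny <- nrow(img); nx <- ncol(img)
  if (dy == round(dy) && dx == round(dx)) {
    dy <- as.integer(round(dy)); dx <- as.integer(round(dx))
    out <- matrix(fill, ny, nx)
    ys <- max(1, 1 + dy):min(ny, ny + dy)   # destination rows
    xs <- max(1, 1 + dx):min(nx, nx + dx)
    if (length(ys) && length(xs))
      out[ys, xs] <- img[ys - dy, xs - dx]
    return(out)
  }
  ky <- fft_freqs(ny); kx <- fft_freqs(nx)
  phase <- exp(-2i * pi * (outer(ky * dy / ny, rep(1, nx)) +
                           outer(rep(1, ny), kx * dx / nx)))
  Re(stats::fft(stats::fft(img) * phase, inverse = TRUE)) / (ny * nx)
}

#' Apply per-round registration shifts to a round stack
#'
#' Each round's estimated drift is undone by translating all of its
#' channels by the negative of the estimate, so re-estimating shifts on the
#' output yields (0, 0).
#'
#' @param stack A `round_stack`.
#' @param shifts List of [estimate_shift()] results (or a data frame with
#'   `dy`, `dx` columns), one per round.
#' @param fill Fill value for vacated pixels on integer shifts.
#' @return The registered `round_stack`.
#' @export
apply_shift <- function(stack, shifts, fill = NA_real_) {
  if (is.data.frame(shifts))
    shifts <- lapply(seq_len(nrow(shifts)), function(i)
      list(dy = shifts$dy[i], dx = shifts$dx[i]))
  if (length(shifts) != length(stack$rounds))
    stop_input("need one shift per round (%d rounds, %d shifts)",
               length(stack$rounds), length(shifts))
  for (r in seq_along(stack$rounds)) {
    s <- shifts[[r]]
    if (!is.null(s$max_shift) && max(abs(c(s$dy, s$dx))) > s$max_shift)
      stop_input("round %d shift (%.1f, %.1f) exceeds max_shift %s", r,
                 s$dy, s$dx, format(s$max_shift))
    if (s$dy == 0 && s$dx == 0) next
    stack$rounds[[r]] <- lapply(stack$rounds[[r]], translate_image,
                                dy = -s$dy, dx = -s$dx, fill = fill)
  }
  stack
}

#' Register a round stack to a reference round
#'
#' Estimates each round's drift on the registration channel (default the
#' nuclear/fiducial channel, the only signal constant across rounds) and
#' undoes it on all channels.
#'
#' @param stack A `round_stack`.
#' @param reference_round Round index serving as the fixed reference.
#' @param channel Channel used for estimation; default last channel.
#' @param max_shift Search bound in pixels.
#' @param subpixel Subpixel refinement flag, see [estimate_shift()].
#' @param fill Fill value for vacated pixels.
#' @return List with `stack` (registered) and `shifts` (data frame:
#'   `round`, `dy`, `dx`, `peak`).
#' @export
register_stack <- function(stack, reference_round = 1L, channel = NULL,
                           max_shift = 10L, subpixel = FALSE,
                           fill = NA_real_) {
  channel <- channel %||% stack$channels[length(stack$channels)]
  if (!channel %in% stack$channels)
    stop_input("registration channel '%s' not in stack", channel)
  ref <- stack$rounds[[reference_round]][[channel]]
  ests <- lapply(seq_along(stack$rounds), function(r) {
    if (r == reference_round)
      return(structure(list(dy = 0, dx = 0, peak = 1, max_shift = max_shift),
                       class = "shift_estimate"))
    estimate_shift(ref, stack$rounds[[r]][[channel]], max_shift = max_shift,
                   subpixel = subpixel)
  })
  registered <- apply_shift(stack, ests, fill = fill)
  list(stack = registered,
       shifts = data.frame(round = seq_along(ests),
                           dy = vapply(ests, `[[`, 0, "dy"),
                           dx = vapply(ests, `[[`, 0, "dx"),
                           peak = vapply(ests, `[[`, 0, "peak")))
}
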