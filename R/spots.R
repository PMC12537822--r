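# Scale-normalized Laplacian-of-Gaussian response (positive for bright
# blobs of scale ~sigma), computed by circular FFT convolution.
log_response <- function(image, sigma) {
  ny <- nrow(image); nx <- ncol(image)
  yy <- fft_freqs(ny); xx <- fft_freqs(nx)
  r2 <- outer(yy^2, rep(1, nx)) + outer(rep(1, ny), xx^2)
  g <- exp(-r2 / (2 * sigma^2)) / (2 * pi * sigma^2)
  lap <- ((r2 - 2 * sigma^2) / sigma^4) * g
  kern <- -sigma^2 * lap                    # sign-flipped, scale-normalized
  Re(stats::fft(stats::fft(image) * stats::fft(kern), inverse = TRUE)) /
    (ny * nx)
}

#' Detect diffraction-limited spots with a Laplacian-of-Gaussian filter
#'
#' Filters the image with a scale-normalized Laplacian of Gaussian at the
#' point-spread-function scale, keeps local maxima of the response above a
#' robust threshold (median plus `quality_threshold` median absolute
#' deviations of the response, so the default transfers across intensity
#' scales), and suppresses non-maxima within `min_separation` pixels
#' (greedy by descending response; exact ties fall to row-major order).
#' Detections are optionally refined to subpixel positions by an
#' intensity-weighted centroid.
#'
#' @param image Numeric matrix; non-finite pixels are replaced by the image
#'   median before filtering.
#' @param psf_sigma Expected spot sigma in pixels.
#' @param quality_threshold Threshold in MAD units of the filter response.
#' @param min_separation Minimum distance between detections; default
#'   `2 * psf_sigma`.
#' @param refine Apply [localize_subpixel()] to each detection.
#' @return Data frame with columns `id`, `y`, `x` (0-based, subpixel),
#'   `peak_intensity`, `integrated_intensity`, `quality`, `border`.
#' @export
detect_spots <- function(image, psf_sigma, quality_threshold = 8,
                         min_separation = NULL, refine = TRUE) {
  stopifnot(is.matrix(image), psf_sigma > 0)
  min_separation <- min_separation %||% (2 * psf_sigma)
  img <- image
  if (any(!is.finite(img))) img[!is.finite(img)] <- stats::median(img, na.rm = TRUE)
  resp <- log_response(img, psf_sigma)
  # robust response scale; floored at the FFT round-off level so noiseless
  # planes (MAD ~ machine epsilon) do not admit numerical ripple as spots
  scale <- max(stats::mad(resp), 1e-6 * max(abs(resp)))
  if (scale <= 0) scale <- Inf               # flat response: nothing to find
  thr <- stats::median(resp) + quality_threshold * scale
  ny <- nrow(img); nx <- ncol(img)
  is_max <- resp > thr
  if (any(is_max)) {
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                   c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
      shifted <- resp[((seq_len(ny) - 1 + d[1]) %% ny) + 1,
                      ((seq_len(nx) - 1 + d[2]) %% nx) + 1]
      is_max <- is_max & (resp >= shifted)
    }
  }
  cand <- which(is_max)                    # column-major, row-major-ish ties ok
  if (!length(cand))
    return(data.frame(id = integer(), y = numeric(), x = numeric(),
                      peak_intensity = numeric(),
                      integrated_intensity = numeric(), quality = numeric(),
                      border = logical()))
  cy <- (cand - 1) %% ny + 1
  cx <- (cand - 1) %/% ny + 1
  q <- resp[cand]
  # deterministic order: response desc, then row-major
  ord <- order(-q, cy, cx)
  cy <- cy[ord]; cx <- cx[ord]; q <- q[ord]
  keep <- logical(length(q))
  ky <- numeric(0); kx <- numeric(0)
  for (i in seq_along(q)) {
    if (length(ky) && min((ky - cy[i])^2 + (kx - cx[i])^2) < min_separation^2)
      next
    keep[i] <- TRUE
    ky <- c(ky, cy[i]); kx <- c(kx, cx[i])
  }
  cy <- cy[keep]; cx <- cx[keep]; q <- q[keep]
  out <- data.frame(id = seq_along(q), y = cy - 1, x = cx - 1,
                    peak_intensity = img[cbind(cy, cx)],
                    integrated_intensity = NA_real_, quality = q,
                    border = FALSE)
  w <- max(2L, ceiling(2 * psf_sigma))
  for (i in seq_len(nrow(out))) {
    ref <- localize_subpixel(img, out$y[i], out$x[i], window = w)
    out$y[i] <- ref$y; out$x[i] <- ref$x
    out$integrated_intensity[i] <- ref$integrated
    out$border[i] <- ref$border
    if (!refine) { out$y[i] <- cy[i] - 1; out$x[i] <- cx[i] - 1 }
  }
  out
}

#' Refine a spot position by intensity-weighted centroid
#'
#' Computes the centroid of background-subtracted intensity (local window
#' minimum as background, negative weights clipped to zero) in a square
#' window around an integer detection. Windows clipped by the image border
#' are flagged and the centroid uses the available pixels.
#'
#' @param image Numeric matrix.
#' @param y,x Integer (0-based) detection position.
#' @param window Half-width of the centroid window in pixels.
#' @return List with refined `y`, `x` (0-based), `integrated`
#'   (background-subtracted window sum) and `border` flag.
#' @export
localize_subpixel <- function(image, y, x, window = 3L) {
  ny <- nrow(image); nx <- ncol(image)
  yi <- round(y) + 1L; xi <- round(x) + 1L
  ys <- (yi - window):(yi + window)
  xs <- (xi - window):(xi + window)
  border <- any(ys < 1L | ys > ny) || any(xs < 1L | xs > nx)
  ys <- ys[ys >= 1L & ys <= ny]
  xs <- xs[xs >= 1L & xs <= nx]
  win <- image[ys, xs, drop = FALSE]
  wgt <- pmax(win - min(win), 0)
  tot <- sum(wgt)
  if (tot == 0)
    return(list(y = y, x = x, integrated = 0, border = border))
  cy <- sum(rowSums(wgt) * ys) / tot
  cx <- sum(colSums(wgt) * xs) / tot
  list(y = cy - 1, x = cx - 1, integrated = tot, border = border)
}

#' Detect spots in every FISH channel of every round
#'
#' Convenience wrapper running [detect_spots()] on each (round, channel)
#' plane of a registered stack, excluding the fiducial/nuclear channel.
#'
#' @param stack A `round_stack` (registered).
#' @param psf_sigma,quality_threshold,min_separation See [detect_spots()].
#' @param exclude Channels to skip; default the last (nuclear) channel.
#' @return Data frame of spot records with `round` and `channel` columns.
#' @export
detect_stack_spots <- function(stack, psf_sigma, quality_threshold = 8,
                               min_separation = NULL, exclude = NULL) {
  exclude <- exclude %||% stack$channels[length(stack$channels)]
  res <- list()
  for (r in seq_along(stack$rounds)) {
    for (ch in setdiff(stack$channels, exclude)) {
      df <- detect_spots(stack$rounds[[r]][[ch]], psf_sigma,
                         quality_threshold, min_separation)
      if (nrow(df)) {
        df$round <- r; df$channel <- ch
        res[[length(res) + 1L]] <- df
      }
    }
  }
  if (!length(res))
    return(data.frame(id = integer(), y = numeric(), x = numeric(),
                      peak_intensity = numeric(),
                      integrated_intensity = numeric(), quality = numeric(),
                      border = logical(), round = integer(),
                      channel = character()))
  out <- do.call(rbind, res)
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

spot_numeric_cols <- c("y", "x", "peak_intensity", "integrated_intensity",
                       "quality")

#' Write a spot table to CSV at full float precision
#'
#' Numeric fields are serialized with 17 significant digits so that
#' [read_spot_table()] round-trips them bit-exactly.
#'
#' @param records Spot data frame ([detect_spots()] /
#'   [detect_stack_spots()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(records, path) {
  df <- records
  for (cn in intersect(spot_numeric_cols, names(df)))
    df[[cn]] <- sprintf("%.17g", df[[cn]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spot table from CSV
#'
#' Validates that coordinates are finite numbers; offending rows are
#' reported by line number.
#'
#' @param path CSV path written by [write_spot_table()].
#' @return Spot data frame.
#' @export
read_spot_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in intersect(spot_numeric_cols, names(df)))
    df[[cn]] <- as.numeric(df[[cn]])
  if (nrow(df)) {
    bad <- which(!is.finite(df$y) | !is.finite(df$x))
    if (length(bad))
      stop_input("non-finite coordinates at line(s) %s of %s",
                 paste(bad + 1L, collapse = ", "), path)
  }
  df
}
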