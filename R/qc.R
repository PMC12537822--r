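#' Colocalization of two spot sets
#'
#' Greedy one-to-one matching by ascending pair distance within `radius`.
#' Matched pairs are the colocalized ("yellow") fraction; unmatched test
#' spots are false positives ("green", rate over the test set) and
#' unmatched reference spots are false negatives ("red", rate over the
#' reference set). Swapping the two sets swaps the two rates exactly.
#'
#' @param reference Data frame (or matrix) with `y`, `x` columns: the
#'   ground-truth / reference channel spots.
#' @param test Spot set under evaluation, same format and coordinate frame.
#' @param radius Maximum matching distance in pixels.
#' @return A `coloc_report`: `n_reference`, `n_test`, `n_colocalized`,
#'   `colocalized_fraction` (of the reference set),
#'   `false_positive_rate`, `false_negative_rate`, `radius`.
#' @export
colocalization <- function(reference, test, radius = 2) {
  ry <- reference[, "y"]; rx <- reference[, "x"]
  ty <- test[, "y"]; tx <- test[, "x"]
  nr <- length(ry); nt <- length(ty)
  n_match <- 0L
  if (nr && nt) {
    d2 <- outer(ry, ty, "-")^2 + outer(rx, tx, "-")^2
    cand <- which(d2 <= radius^2)
    if (length(cand)) {
      ord <- cand[order(d2[cand])]
      used_r <- logical(nr); used_t <- logical(nt)
      for (idx in ord) {
        i <- (idx - 1L) %% nr + 1L
        j <- (idx - 1L) %/% nr + 1L
        if (used_r[i] || used_t[j]) next
        used_r[i] <- TRUE; used_t[j] <- TRUE
        n_match <- n_match + 1L
      }
    }
  }
  structure(list(
    n_reference = nr, n_test = nt, n_colocalized = n_match,
    colocalized_fraction = if (nr) n_match / nr else NA_real_,
    false_positive_rate = if (nt) (nt - n_match) / nt else NA_real_,
    false_negative_rate = if (nr) (nr - n_match) / nr else NA_real_,
    radius = radius), class = "coloc_report")
}

#' @export
print.coloc_report <- function(x, ...) {
  cat(sprintf(
    "<coloc_report> %d ref / %d test, %d colocalized (%.1f%%), FP %.1f%%, FN %.1f%% @ r=%.1f px\n",
    x$n_reference, x$n_test, x$n_colocalized,
    100 * x$colocalized_fraction, 100 * x$false_positive_rate,
    100 * x$false_negative_rate, x$radius))
  invisible(x)
}

#' Signal retention across hybridize/strip cycles
#'
#' Converts per-round post-hybridization and post-stripping mean
#' intensities into background-relative contrast ratios, flagging rounds
#' whose post-hybridization contrast falls below `floor`.
#'
#' @param series Data frame with columns `round`, `post_hyb_mean`,
#'   `post_cleave_mean` (e.g. from
#'   [simulate_hybridize_cleave_series()]).
#' @param background Background intensity (scalar or per-round); must be
#'   positive.
#' @param floor Minimum acceptable post-hybridization contrast.
#' @return Data frame with `round`, `hyb_ratio`, `cleave_ratio`,
#'   `below_floor`.
#' @export
retention_series <- function(series, background, floor = 5) {
  if (any(background <= 0)) stop_input("background must be positive")
  if (!nrow(series)) stop_input("need at least one round")
  data.frame(round = series$round,
             hyb_ratio = series$post_hyb_mean / background,
             cleave_ratio = series$post_cleave_mean / background,
             below_floor = series$post_hyb_mean / background < floor)
}

# Boundary pixels of a binary mask: foreground pixels with at least one
# 4-neighbor outside the mask (image edge counts as outside).
mask_boundary <- function(mask) {
  m <- mask > 0
  ny <- nrow(m); nx <- ncol(m)
  pad <- matrix(FALSE, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- m
  core <- pad[2:(ny + 1), 2:(nx + 1)]
  inner <- pad[1:ny, 2:(nx + 1)] & pad[3:(ny + 2), 2:(nx + 1)] &
    pad[2:(ny + 1), 1:nx] & pad[2:(ny + 1), 3:(nx + 2)]
  which(core & !inner, arr.ind = TRUE)
}

#' Signed distance from spots to the nucleus boundary
#'
#' Euclidean distance from each spot to the nearest boundary pixel of a
#' binary nucleus mask, negative for spots inside the nucleus and positive
#' outside. Coordinates are 0-based pixel units; boundary pixels are mask
#' pixels with a 4-neighbor outside the mask.
#'
#' @param spots Data frame (or matrix) with `y`, `x` columns.
#' @param nucleus_mask Logical or 0/1 matrix marking nuclear pixels.
#' @param group Optional factor (e.g. timepoint or condition) for the
#'   summary.
#' @return List with `distances` (per-spot signed distances) and `summary`
#'   (mean and sd, overall or per group).
#' @export
distance_to_nucleus <- function(spots, nucleus_mask, group = NULL) {
  if (!any(nucleus_mask > 0)) stop_input("nucleus mask is empty")
  bnd <- mask_boundary(nucleus_mask)
  by <- bnd[, 1] - 1; bx <- bnd[, 2] - 1
  sy <- spots[, "y"]; sx <- spots[, "x"]
  n <- length(sy)
  d <- numeric(n)
  inside <- nucleus_mask[cbind(pmin(pmax(round(sy) + 1, 1), nrow(nucleus_mask)),
                               pmin(pmax(round(sx) + 1, 1), ncol(nucleus_mask)))] > 0
  for (i in seq_len(n))
    d[i] <- sqrt(min((by - sy[i])^2 + (bx - sx[i])^2))
  d[inside] <- -d[inside]
  if (is.null(group)) {
    summary <- data.frame(group = "all", n = n, mean = mean(d), sd = stats::sd(d))
  } else {
    summary <- do.call(rbind, lapply(split(d, group), function(v)
      data.frame(n = length(v), mean = mean(v), sd = stats::sd(v))))
    summary <- cbind(group = rownames(summary), summary)
    rownames(summary) <- NULL
  }
  list(distances = d, summary = summary)
}

# Distance from points to a polyline given as a vertex matrix (y, x).
dist_to_polyline <- function(py, px, line) {
  if (is.null(dim(line))) line <- matrix(line, ncol = 2)
  nseg <- nrow(line) - 1L
  d2min <- rep(Inf, length(py))
  if (nseg < 1L) {
    return(sqrt((py - line[1, 1])^2 + (px - line[1, 2])^2))
  }
  for (s in seq_len(nseg)) {
    a <- line[s, ]; b <- line[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, length(py))
      else pmin(pmax(((py - a[1]) * ab[1] + (px - a[2]) * ab[2]) / len2, 0), 1)
    d2 <- (py - (a[1] + t * ab[1]))^2 + (px - (a[2] + t * ab[2]))^2
    d2min <- pmin(d2min, d2)
  }
  sqrt(d2min)
}

#' Normalized cortical depth of cell positions
#'
#' Depth of each cell between two user-supplied reference polylines (the
#' cortical edge and the deep boundary):
#' `depth = d_edge / (d_edge + d_deep)`, so 0 lies on the edge and 1 on the
#' deep boundary, normalizing for local cortex thickness.
#'
#' @param cells Data frame (or matrix) with `y`, `x` columns.
#' @param edge,deep Polyline vertex matrices (columns y, x).
#' @return Numeric vector of depths in `[0, 1]`.
#' @export
normalize_depth <- function(cells, edge, deep) {
  py <- cells[, "y"]; px <- cells[, "x"]
  de <- dist_to_polyline(py, px, edge)
  dd <- dist_to_polyline(py, px, deep)
  de / (de + dd)
}

#' Kernel density profile of cell types along normalized depth
#'
#' One-dimensional Gaussian kernel density estimate per cell type over
#' depths in `[0, 1]`, with boundary reflection at both ends so each
#' profile integrates to 1 on the unit interval. Bandwidth follows Scott's
#' rule (`stats::bw.nrd`) unless overridden; types with fewer than two
#' cells are skipped with a warning.
#'
#' @param depths Numeric vector of normalized depths in `[0, 1]`.
#' @param types Character/factor vector of cell types, same length.
#' @param bandwidth Optional fixed bandwidth (depth units).
#' @param grid_n Number of evaluation points on `[0, 1]`.
#' @return A `depth_profile`: list with `grid`, `density` (matrix, grid x
#'   type), `bandwidth` (per type), `modes` (depth of each type's density
#'   maximum) and `n` (cells per type).
#' @export
kde_depth_profile <- function(depths, types, bandwidth = NULL, grid_n = 512L) {
  if (any(depths < -1e-9 | depths > 1 + 1e-9))
    stop_input("depths must be normalized to [0, 1]")
  types <- as.character(types)
  grid <- seq(0, 1, length.out = grid_n)
  keep <- character(0); dens <- list(); bws <- numeric(0); ns <- integer(0)
  for (ty in unique(types)) {
    v <- depths[types == ty]
    if (length(v) < 2L) {
      warning(sprintf("type '%s' has %d cell(s); skipped", ty, length(v)))
      next
    }
    bw <- bandwidth %||% stats::bw.nrd(v)
    # Gaussian KDE with reflection at 0 and 1
    f <- vapply(grid, function(g)
      mean(stats::dnorm(g - v, sd = bw) + stats::dnorm(g + v, sd = bw) +
             stats::dnorm(2 - g - v, sd = bw)), 0)
    keep <- c(keep, ty)
    dens[[ty]] <- f
    bws <- c(bws, bw)
    ns <- c(ns, length(v))
  }
  if (!length(keep)) stop_input("no type has enough cells for a profile")
  density <- do.call(cbind, dens[keep])
  colnames(density) <- keep
  modes <- grid[apply(density, 2L, which.max)]
  names(modes) <- keep
  structure(list(grid = grid, density = density,
                 bandwidth = stats::setNames(bws, keep),
                 modes = modes, n = stats::setNames(ns, keep)),
            class = "depth_profile")
}

#' Cell-type frequency table of an atlas
#'
#' @param atlas A `cell_atlas` (see [cell_atlas()]).
#' @return Data frame `cell_type`, `n`, `frequency` (summing to 1 over
#'   typed cells).
#' @export
type_frequencies <- function(atlas) {
  if (!inherits(atlas, "cell_atlas")) stop_input("need a cell_atlas")
  if (!nrow(atlas$summary) || sum(atlas$summary$n) == 0L)
    stop_input("atlas contains no typed cells")
  atlas$summary
}

#' Two-sample comparison of group means
#'
#' Mean, standard deviation and an unpaired two-tailed Welch t test between
#' two groups of measurements (e.g. spot distances under two conditions).
#'
#' @param a,b Numeric vectors.
#' @return List with per-group `mean`/`sd` and the `t`/`p.value` of the
#'   test.
#' @export
compare_groups <- function(a, b) {
  tt <- stats::t.test(a, b, alternative = "two.sided")
  list(mean_a = mean(a), sd_a = stats::sd(a),
       mean_b = mean(b), sd_b = stats::sd(b),
       t = unname(tt$statistic), p.value = tt$p.value)
}
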