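#' Link detected spots across rounds into chains
#'
#' Within each round, detections from different color channels closer than
#' `conflict_radius` are first collapsed into one per-round detection (the
#' brightest member is the representative; fainter cross-channel members,
#' typically stripping residuals, are kept for the ambiguity flag). The
#' per-round representatives are then linked between consecutive rounds by
#' mutual nearest neighbors within `link_radius`. Every chain holds at most
#' one detection per round; spots that never link become single-round
#' chains.
#'
#' @param spots Data frame from [detect_stack_spots()] (columns `round`,
#'   `channel`, `y`, `x`, `peak_intensity`, `id`).
#' @param n_rounds Total number of rounds in the experiment.
#' @param link_radius Maximum inter-round match distance in pixels.
#' @param conflict_radius Same-round cross-channel merge distance; default
#'   `link_radius`.
#' @return A `spot_chains` object: list with `spots` (the input plus
#'   `cluster` and `chain_id` columns) and `chains` (list of integer row
#'   vectors into `spots`, one per chain).
#' @export
link_spots <- function(spots, n_rounds, link_radius = 1.5,
                       conflict_radius = NULL) {
  conflict_radius <- conflict_radius %||% link_radius
  spots$cluster <- NA_integer_
  n_clust <- 0L
  reps <- list()   # per cluster: row of representative
  for (r in seq_len(n_rounds)) {
    rows <- which(spots$round == r)
    if (!length(rows)) next
    rows <- rows[order(-spots$peak_intensity[rows], spots$y[rows],
                       spots$x[rows])]
    seed_y <- numeric(0); seed_x <- numeric(0); seed_cl <- integer(0)
    for (i in rows) {
      if (length(seed_y)) {
        d2 <- (seed_y - spots$y[i])^2 + (seed_x - spots$x[i])^2
        j <- which.min(d2)
        if (d2[j] <= conflict_radius^2) {
          spots$cluster[i] <- seed_cl[j]
          next
        }
      }
      n_clust <- n_clust + 1L
      spots$cluster[i] <- n_clust
      seed_y <- c(seed_y, spots$y[i]); seed_x <- c(seed_x, spots$x[i])
      seed_cl <- c(seed_cl, n_clust)
      reps[[n_clust]] <- i
    }
  }
  rep_rows <- unlist(reps)
  rep_round <- spots$round[rep_rows]
  rep_y <- spots$y[rep_rows]; rep_x <- spots$x[rep_rows]
  # mutual nearest neighbor linking between consecutive rounds
  succ <- rep(NA_integer_, n_clust)   # cluster -> cluster in next round
  for (r in seq_len(max(0L, n_rounds - 1L))) {
    a <- which(rep_round == r); b <- which(rep_round == r + 1L)
    if (!length(a) || !length(b)) next
    d2 <- outer(rep_y[a], rep_y[b], "-")^2 + outer(rep_x[a], rep_x[b], "-")^2
    fwd <- apply(d2, 1L, which.min)
    bwd <- apply(d2, 2L, which.min)
    for (ii in seq_along(a)) {
      jj <- fwd[ii]
      if (bwd[jj] == ii && d2[ii, jj] <= link_radius^2)
        succ[a[ii]] <- b[jj]
    }
  }
  # chains: follow successor links from clusters with no predecessor
  has_pred <- logical(n_clust)
  has_pred[succ[!is.na(succ)]] <- TRUE
  chain_of_cluster <- rep(NA_integer_, n_clust)
  chains <- list()
  for (c0 in seq_len(n_clust)) {
    if (has_pred[c0]) next
    cid <- length(chains) + 1L
    members <- integer(0)
    cur <- c0
    while (!is.na(cur)) {
      chain_of_cluster[cur] <- cid
      members <- c(members, which(spots$cluster == cur))
      cur <- succ[cur]
    }
    chains[[cid]] <- members
  }
  spots$chain_id <- chain_of_cluster[spots$cluster]
  structure(list(spots = spots, chains = chains), class = "spot_chains")
}

#' Read the digit string of one spot chain
#'
#' Round r contributes the digit of the channel its spot was detected in
#' (e.g. Cy5 = "1", Cy3 = "2", FAM = "3" under the default map); rounds
#' with no detection contribute "0". When one round holds members in two or
#' more channels at the linked position, the brightest member wins and the
#' chain is flagged ambiguous.
#'
#' @param chain Data frame of the chain's spot rows (columns `round`,
#'   `channel`, `peak_intensity`).
#' @param n_rounds Number of rounds in the experiment.
#' @param channel_digit_map Named integer vector, channel name -> digit.
#' @return List with `code` (digit string of length `n_rounds`) and
#'   `ambiguous` flag.
#' @export
digits_from_chain <- function(chain, n_rounds, channel_digit_map) {
  unknown <- setdiff(unique(chain$channel), names(channel_digit_map))
  if (length(unknown))
    stop_input("unknown channel name(s): %s", paste(unknown, collapse = ", "))
  digits <- rep("0", n_rounds)
  ambiguous <- FALSE
  for (r in unique(chain$round)) {
    rows <- chain[chain$round == r, , drop = FALSE]
    if (length(unique(rows$channel)) > 1L) ambiguous <- TRUE
    best <- rows[order(-rows$peak_intensity), , drop = FALSE][1L, ]
    digits[r] <- as.character(channel_digit_map[[best$channel]])
  }
  list(code = paste(digits, collapse = ""), ambiguous = ambiguous)
}

#' Decode spot chains against a codebook
#'
#' Assembles each chain's digit string and looks it up. Status taxonomy:
#' `incomplete` (a missing round, digit "0"), `unknown_code` (complete but
#' unassigned code), `ambiguous` (decoded, but a round held competing
#' channels) or `decoded`. No chain is dropped: the number of outputs
#' equals the number of chains.
#'
#' @param linked A `spot_chains` object from [link_spots()].
#' @param codebook The experiment [build_codebook()] codebook.
#' @return A data frame (`decoded_spots`): `chain_id`, consensus `y`, `x`,
#'   `code`, `target`, `status`, `n_members`; the status tally is attached
#'   as `attr(, "status_counts")`.
#' @export
decode_spot_chains <- function(linked, codebook) {
  validate_codebook(codebook)
  n_rounds <- codebook$n_rounds
  n <- length(linked$chains)
  out <- data.frame(chain_id = seq_len(n), y = NA_real_, x = NA_real_,
                    code = NA_character_, target = NA_character_,
                    status = NA_character_, n_members = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    rows <- linked$spots[linked$chains[[i]], , drop = FALSE]
    dg <- digits_from_chain(rows, n_rounds, codebook$channel_digit_map)
    out$y[i] <- mean(rows$y); out$x[i] <- mean(rows$x)
    out$code[i] <- dg$code
    out$n_members[i] <- nrow(rows)
    if (grepl("0", dg$code)) {
      out$status[i] <- "incomplete"
    } else {
      hit <- names(codebook$entries)[match(dg$code, codebook$entries)]
      if (length(hit) == 0L || is.na(hit)) {
        out$status[i] <- "unknown_code"
      } else {
        out$target[i] <- hit
        out$status[i] <- if (dg$ambiguous) "ambiguous" else "decoded"
      }
    }
  }
  counts <- table(factor(out$status, levels = c("decoded", "ambiguous",
                                                "incomplete", "unknown_code")))
  attr(out, "status_counts") <- counts
  out
}

#' Normalize fluorescence channels plane by plane
#'
#' Maps every (round, channel) plane through
#' `(I - median(I)) / (q99(I) - median(I))`, clipped at zero: a robust,
#' strictly monotone per-plane transform that places background near 0 and
#' bright signal near 1, making channel intensities comparable before
#' argmax decoding.
#'
#' @param stack A registered `round_stack`.
#' @param exclude Channels left untouched; default the nuclear channel.
#' @param upper Upper percentile defining the scale (default 0.99).
#' @return The normalized `round_stack`.
#' @export
normalize_channels <- function(stack, exclude = NULL, upper = 0.99) {
  exclude <- exclude %||% stack$channels[length(stack$channels)]
  for (r in seq_along(stack$rounds)) {
    for (ch in setdiff(stack$channels, exclude)) {
      p <- stack$rounds[[r]][[ch]]
      med <- stats::median(p, na.rm = TRUE)
      sc <- stats::quantile(p, upper, na.rm = TRUE, names = FALSE) - med
      if (!is.finite(sc) || sc <= 0)
        stop(errorCondition(
          sprintf("degenerate plane (round %d, %s): scale is %s", r, ch,
                  format(sc)),
          class = c("spotcode_degenerate_error", "spotcode_input_error",
                    "error")))
      stack$rounds[[r]][[ch]] <- pmax((p - med) / sc, 0)
    }
  }
  stack
}

#' Decode segmented regions by per-round winning channel
#'
#' For every labeled mask region and every round, takes the mean normalized
#' intensity of each color channel over the region's pixels and keeps only
#' the winning channel: the region's digit for that round (Cy5 -> "1",
#' Cy3 -> "2", FAM -> "3" under the default map). Digits concatenated
#' across rounds form the region's color code, which the codebook maps to a
#' cell type. Exact ties are flagged and resolved by fixed channel priority
#' (the channel with the smallest digit wins); codes absent from the
#' codebook yield an untyped region, never a reassignment.
#'
#' @param stack A registered, [normalize_channels()]-normalized
#'   `round_stack`.
#' @param mask Integer label matrix (0 = background) matching the image
#'   shape.
#' @param codebook A per-cell-type codebook.
#' @param exclude Channels not participating in decoding; default the
#'   nuclear channel.
#' @param labels Label ids to decode; defaults to all labels present in the
#'   mask. Requested labels with no pixels are skipped with a warning.
#' @return List with `regions` (data frame: `label`, `centroid_y`,
#'   `centroid_x`, `area`, `code`, `cell_type`, `tie_flag`, plus per-round
#'   digit columns) and `atlas` (a `cell_atlas`).
#' @export
decode_masks <- function(stack, mask, codebook, exclude = NULL,
                         labels = NULL) {
  validate_codebook(codebook)
  exclude <- exclude %||% stack$channels[length(stack$channels)]
  fish_ch <- setdiff(stack$channels, exclude)
  digit_for <- codebook$channel_digit_map[fish_ch]
  present <- sort(unique(mask[mask > 0]))
  if (is.null(labels)) labels <- present
  empty <- setdiff(labels, present)
  if (length(empty)) {
    warning(sprintf("skipping empty mask label(s): %s",
                    paste(empty, collapse = ", ")))
    labels <- intersect(labels, present)
  }
  if (!length(labels)) stop_input("mask contains no labeled regions")
  n_rounds <- length(stack$rounds)
  sel <- mask > 0 & mask %in% labels
  lab_vec <- mask[sel]
  yy <- row(mask)[sel]; xx <- col(mask)[sel]
  area <- as.numeric(table(factor(lab_vec, levels = labels)))
  cy <- tapply(yy, factor(lab_vec, levels = labels), mean) - 1
  cx <- tapply(xx, factor(lab_vec, levels = labels), mean) - 1
  digits <- matrix("0", length(labels), n_rounds)
  tie <- logical(length(labels))
  for (r in seq_len(n_rounds)) {
    means <- sapply(fish_ch, function(ch) {
      v <- stack$rounds[[r]][[ch]][sel]
      as.numeric(tapply(v, factor(lab_vec, levels = labels), mean,
                        na.rm = TRUE))
    })
    means <- matrix(means, ncol = length(fish_ch),
                    dimnames = list(NULL, fish_ch))
    for (k in seq_along(labels)) {
      m <- means[k, ]
      top <- which(m == max(m))
      if (length(top) > 1L) {
        tie[k] <- TRUE
        top <- top[which.min(digit_for[top])]
      }
      digits[k, r] <- as.character(digit_for[[top]])
    }
  }
  codes <- apply(digits, 1L, paste, collapse = "")
  ctype <- names(codebook$entries)[match(codes, codebook$entries)]
  regions <- data.frame(label = labels, centroid_y = as.numeric(cy),
                        centroid_x = as.numeric(cx), area = area,
                        code = codes, cell_type = ctype, tie_flag = tie,
                        stringsAsFactors = FALSE)
  for (r in seq_len(n_rounds)) regions[[paste0("digit_r", r)]] <- digits[, r]
  list(regions = regions, atlas = cell_atlas(regions))
}

#' Build a cell atlas from decoded regions
#'
#' Summarizes typed cells into counts and frequencies; frequencies are
#' computed over successfully typed cells only, with the untyped count
#' reported separately.
#'
#' @param regions Data frame with `label`, `centroid_y`, `centroid_x`,
#'   `code` and `cell_type` columns.
#' @return A `cell_atlas`: list with `cells`, `summary` (`cell_type`, `n`,
#'   `frequency`) and `n_untyped`.
#' @export
cell_atlas <- function(regions) {
  typed <- regions[!is.na(regions$cell_type), , drop = FALSE]
  tab <- table(typed$cell_type)
  summary <- data.frame(cell_type = names(tab), n = as.integer(tab),
                        frequency = as.numeric(tab) / max(1L, sum(tab)),
                        stringsAsFactors = FALSE)
  structure(list(cells = regions, summary = summary,
                 n_untyped = sum(is.na(regions$cell_type))),
            class = "cell_atlas")
}

#' @export
print.cell_atlas <- function(x, ...) {
  cat(sprintf("<cell_atlas> %d cells (%d untyped)\n", nrow(x$cells),
              x$n_untyped))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
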