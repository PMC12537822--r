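#' Write a round stack to multi-page TIFF files
#'
#' One 16-bit multi-page TIFF per round (channel-major pages) plus a JSON
#' manifest recording the canonical channel order, the per-round page
#' order, and pixel-size metadata. Intensities are stored on the 16-bit
#' count scale (0..65535).
#'
#' @param stack A `round_stack`.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix for the round TIFFs.
#' @return Path to the manifest JSON, invisibly.
#' @export
write_round_stack <- function(stack, dir, prefix = "round") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(stack$rounds))
  for (r in seq_along(stack$rounds)) {
    pages <- lapply(stack$channels, function(ch) {
      p <- stack$rounds[[r]][[ch]]
      p[!is.finite(p)] <- 0
      pmin(pmax(p / 65535, 0), 1)
    })
    files[r] <- sprintf("%s_%02d.tif", prefix, r)
    tiff::writeTIFF(pages, file.path(dir, files[r]), bits.per.sample = 16L)
  }
  manifest <- list(
    channels = stack$channels,
    pixel_size_um = stack$pixel_size_um,
    rounds = lapply(seq_along(files), function(r)
      list(file = files[r], page_channels = stack$channels)))
  mpath <- file.path(dir, paste0(prefix, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}

#' Read a round stack from TIFF files and a manifest
#'
#' Pages are matched to channels by name through the manifest's per-round
#' `page_channels` list -- never by page index -- so shuffled page order is
#' canonicalized on read. All rounds must share one image shape and every
#' canonical channel must be present in every round.
#'
#' @param manifest_path Path to the manifest JSON written by
#'   [write_round_stack()].
#' @return A `round_stack`.
#' @export
read_round_stack <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  channels <- man$channels
  rounds <- vector("list", length(man$rounds$file %||% man$rounds))
  round_list <- if (is.data.frame(man$rounds))
    lapply(seq_len(nrow(man$rounds)), function(i)
      list(file = man$rounds$file[i],
           page_channels = man$rounds$page_channels[[i]]))
  else man$rounds
  shape <- NULL
  for (r in seq_along(round_list)) {
    info <- round_list[[r]]
    f <- file.path(dir, info$file)
    if (!file.exists(f)) stop_input("round TIFF missing: %s", f)
    pages <- tiff::readTIFF(f, all = TRUE)
    pc <- unlist(info$page_channels)
    if (length(pages) != length(pc))
      stop_input("%s has %d pages but manifest names %d channels", f,
                 length(pages), length(pc))
    miss <- setdiff(channels, pc)
    if (length(miss))
      stop_input("round %d is missing channel(s): %s", r,
                 paste(miss, collapse = ", "))
    planes <- stats::setNames(lapply(channels, function(ch)
      pages[[match(ch, pc)]] * 65535), channels)
    d <- dim(planes[[1]])
    if (is.null(shape)) shape <- d
    else if (!all(shape == d))
      stop_input("round %d shape %dx%d differs from round 1 shape %dx%d", r,
                 d[1], d[2], shape[1], shape[2])
    rounds[[r]] <- planes
  }
  new_round_stack(rounds, channels, man$pixel_size_um %||% NA_real_)
}

#' Write a label mask as TIFF
#'
#' Integer labels stored losslessly in a 16-bit single-page TIFF.
#'
#' @param mask Integer matrix (0 = background).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (max(mask) > 65535) stop_input("label ids exceed 16-bit range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#'
#' @param path TIFF path.
#' @return Integer label matrix.
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m))
}

# CSV with provenance header comments (tool version, config hash, seed).
write_csv_provenance <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s: %s", names(provenance),
                       vapply(provenance, as.character, "")), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_provenance <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(errorCondition(sprintf("stage '%s' failed: %s", stage,
                                conditionMessage(e)),
                        class = c("spotcode_stage_error", "error"))))
}

#' Run the full decoding pipeline
#'
#' Registration (on the nuclear/fiducial channel) -> spot detection ->
#' chain linking and per-spot decoding, plus mask decoding into a cell
#' atlas when a label mask is supplied. Outputs (`shifts.csv`,
#' `spots.csv`, `decoded_spots.csv`, optionally `cell_atlas.csv`, and
#' `summary.json`) are written under `out_dir` with provenance headers
#' (package version, configuration hash, seed); a rerun with an identical
#' configuration reproduces identical files. Any stage failure halts with
#' a stage-tagged error.
#'
#' @param config Either a list or a path to a JSON file with elements:
#'   `codebook` (path to codebook JSON, or a `codebook` object),
#'   `manifest` (path to a [write_round_stack()] manifest, or a
#'   `round_stack` under `stack`), optional `mask` (path or matrix),
#'   `out_dir`, `seed`, and `params` overriding `psf_sigma` (1.3),
#'   `quality_threshold` (8), `link_radius` (1.5), `max_shift` (10).
#' @return List with `shifts`, `spots`, `decoded`, `atlas` (or `NULL`) and
#'   `summary`, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  params <- utils::modifyList(
    list(psf_sigma = 1.3, quality_threshold = 8, link_radius = 1.5,
         max_shift = 10, norm_upper = 0.99),
    config$params %||% list())
  seed <- config$seed %||% 1L
  cb <- run_stage("codebook", {
    if (inherits(config$codebook, "codebook")) config$codebook
    else read_codebook(config$codebook)
  })
  stack <- run_stage("load", {
    if (!is.null(config$stack)) config$stack
    else read_round_stack(config$manifest)
  })
  if (length(stack$rounds) != cb$n_rounds)
    stop_input("stack has %d rounds but codebook expects %d",
               length(stack$rounds), cb$n_rounds)
  mask <- NULL
  if (!is.null(config$mask))
    mask <- run_stage("load", {
      if (is.matrix(config$mask)) config$mask else read_mask(config$mask)
    })
  pipeline_log("register", "estimating per-round shifts")
  reg <- run_stage("register",
                   register_stack(stack, max_shift = params$max_shift))
  pipeline_log("spots", "detecting spots in FISH channels")
  spots <- run_stage("spots",
                     detect_stack_spots(reg$stack, params$psf_sigma,
                                        params$quality_threshold))
  pipeline_log("decode", sprintf("linking %d detections", nrow(spots)))
  linked <- run_stage("decode",
                      link_spots(spots, cb$n_rounds, params$link_radius))
  decoded <- run_stage("decode", decode_spot_chains(linked, cb))
  atlas <- NULL
  if (!is.null(mask) && cb$panel_mode == "per_cell_type") {
    pipeline_log("atlas", "decoding mask regions")
    norm <- run_stage("atlas", normalize_channels(reg$stack,
                                                  upper = params$norm_upper))
    atlas <- run_stage("atlas", decode_masks(norm, mask, cb))
  }
  summary <- list(
    n_spots = nrow(spots), n_chains = length(linked$chains),
    status_counts = as.list(attr(decoded, "status_counts")),
    shifts = reg$shifts,
    frequencies = if (!is.null(atlas)) atlas$atlas$summary else NULL)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    prov <- list(tool = paste0("spotcode ",
                               utils::packageVersion("spotcode")),
                 config_hash = config_hash(config[setdiff(names(config),
                                                          c("stack", "codebook",
                                                            "mask", "out_dir"))]),
                 seed = seed)
    write_csv_provenance(reg$shifts, file.path(config$out_dir, "shifts.csv"),
                         prov)
    write_csv_provenance(spots, file.path(config$out_dir, "spots.csv"), prov)
    write_csv_provenance(decoded, file.path(config$out_dir,
                                            "decoded_spots.csv"), prov)
    if (!is.null(atlas))
      write_csv_provenance(atlas$regions[c("label", "centroid_y",
                                           "centroid_x", "code", "cell_type",
                                           "tie_flag")],
                           file.path(config$out_dir, "cell_atlas.csv"), prov)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, force = TRUE, pretty = TRUE,
                         dataframe = "columns")
  }
  invisible(list(shifts = reg$shifts, spots = spots, decoded = decoded,
                 atlas = atlas, summary = summary))
}

#' Write simulation ground truth to CSV
#'
#' @param truth Ground-truth list from [simulate_spot_field()] or
#'   [simulate_tissue()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(truth$spots))
    utils::write.csv(truth$spots, file.path(dir, "ground_truth_spots.csv"),
                     row.names = FALSE, quote = FALSE)
  if (!is.null(truth$cells))
    utils::write.csv(truth$cells, file.path(dir, "ground_truth_cells.csv"),
                     row.names = FALSE, quote = FALSE)
  if (!is.null(truth$drift))
    utils::write.csv(truth$drift, file.path(dir, "applied_drift.csv"),
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
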