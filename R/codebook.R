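#' Combinatorial capacity of an F-color, N-round barcode scheme
#'
#' With `n_colors` distinguishable fluorophores read out over `n_rounds`
#' sequential hybridization rounds, every target can carry one of
#' `n_colors ^ n_rounds` distinct color codes.
#'
#' @param n_colors Number of fluorescence channels (F), a positive integer.
#' @param n_rounds Number of hybridization/imaging rounds (N), a positive
#'   integer.
#' @return The number of distinct codes, `n_colors ^ n_rounds`.
#' @examples
#' capacity(3, 2) # 9 targets from three colors and two rounds
#' @export
capacity <- function(n_colors, n_rounds) {
  if (!is.numeric(n_colors) || length(n_colors) != 1L || n_colors < 1 ||
      n_colors != round(n_colors))
    stop_input("n_colors must be a positive integer, got %s", format(n_colors))
  if (!is.numeric(n_rounds) || length(n_rounds) != 1L || n_rounds < 1 ||
      n_rounds != round(n_rounds))
    stop_input("n_rounds must be a positive integer, got %s", format(n_rounds))
  as.numeric(n_colors)^as.numeric(n_rounds)
}

# Lexicographic enumeration of all F^N codes as strings of digits 1..F.
enumerate_codes <- function(n_colors, n_rounds) {
  total <- capacity(n_colors, n_rounds)
  if (total > 1e6)
    stop_input("refusing to enumerate %s codes; reduce F or N", format(total))
  idx <- 0:(total - 1)
  digits <- matrix(0L, nrow = total, ncol = n_rounds)
  rem <- idx
  for (k in n_rounds:1) {
    digits[, k] <- rem %% n_colors + 1L
    rem <- rem %/% n_colors
  }
  apply(digits, 1L, paste, collapse = "")
}

default_channel_map <- function(n_colors) {
  std <- c("Cy5", "Cy3", "FAM")
  nm <- if (n_colors <= 3L) std[seq_len(n_colors)]
        else c(std, paste0("ch", 4:n_colors))
  stats::setNames(seq_len(n_colors), nm)
}

#' Build a codebook assigning color codes to targets
#'
#' Enumerates all `n_colors ^ n_rounds` codes in lexicographic order over the
#' digit alphabet `1..n_colors`, shuffles them reproducibly with `seed`, and
#' assigns the first `n_targets` codes to the supplied (or auto-generated)
#' target identifiers. Digit 1 maps to Cy5, 2 to Cy3 and 3 to FAM by default;
#' the digit `0` is reserved for a missing round during decoding and never
#' appears in a code.
#'
#' @param n_colors Number of fluorescence channels (F).
#' @param n_rounds Number of hybridization rounds (N).
#' @param n_targets Number of targets to encode; must not exceed
#'   [capacity()].
#' @param seed Integer seed controlling the code shuffle (deterministic).
#' @param target_ids Optional character vector of target names, length
#'   `n_targets`. Defaults to `gene01`, `gene02`, ...
#' @param channel_digit_map Named integer vector mapping channel name to
#'   digit; default `c(Cy5 = 1, Cy3 = 2, FAM = 3)` truncated/extended to
#'   `n_colors`.
#' @return A `codebook` object: list with `n_colors`, `n_rounds`,
#'   `channel_digit_map`, `panel_mode` (`"per_gene"`) and `entries`
#'   (named character vector, target id -> code).
#' @examples
#' cb <- build_codebook(3, 2, 9, seed = 1)
#' cb$entries
#' @export
build_codebook <- function(n_colors, n_rounds, n_targets, seed = 0L,
                           target_ids = NULL, channel_digit_map = NULL) {
  total <- capacity(n_colors, n_rounds)
  if (!is.numeric(n_targets) || length(n_targets) != 1L || n_targets < 1 ||
      n_targets != round(n_targets))
    stop_input("n_targets must be a positive integer")
  if (n_targets > total)
    stop(errorCondition(
      sprintf("capacity exceeded: %d targets requested but only %s codes available (F=%d, N=%d)",
              as.integer(n_targets), format(total), n_colors, n_rounds),
      class = c("spotcode_capacity_error", "spotcode_input_error", "error")))
  codes <- enumerate_codes(n_colors, n_rounds)
  codes <- with_seed(seed, sample(codes, length(codes)))
  if (is.null(target_ids))
    target_ids <- sprintf("gene%02d", seq_len(n_targets))
  if (length(target_ids) != n_targets || anyDuplicated(target_ids))
    stop_input("target_ids must be %d unique names", as.integer(n_targets))
  cdm <- channel_digit_map %||% default_channel_map(n_colors)
  cb <- structure(list(
    n_colors = as.integer(n_colors),
    n_rounds = as.integer(n_rounds),
    channel_digit_map = cdm,
    panel_mode = "per_gene",
    entries = stats::setNames(codes[seq_len(n_targets)], target_ids)
  ), class = "codebook")
  validate_codebook(cb)
  cb
}

#' Validate codebook invariants
#'
#' Checks code length, digit alphabet, uniqueness and capacity; called by all
#' codebook constructors.
#'
#' @param cb A `codebook` object.
#' @return `cb`, invisibly, if valid; otherwise an error.
#' @export
validate_codebook <- function(cb) {
  if (!inherits(cb, "codebook")) stop_input("not a codebook object")
  ent <- cb$entries
  if (any(nchar(ent) != cb$n_rounds))
    stop_input("all codes must have exactly %d digits", cb$n_rounds)
  digs <- unique(strsplit(paste(ent, collapse = ""), "")[[1]])
  ok <- as.character(seq_len(cb$n_colors))
  if (length(digs) && !all(digs %in% ok))
    stop_input("codes may only use digits 1..%d (found '%s')",
               cb$n_colors, paste(setdiff(digs, ok), collapse = "','"))
  if (anyDuplicated(ent))
    stop_input("codes must be unique across %s",
               if (cb$panel_mode == "per_gene") "targets" else "cell types")
  if (length(ent) > capacity(cb$n_colors, cb$n_rounds))
    stop_input("more entries than the code space allows")
  if (!all(sort(unname(cb$channel_digit_map[seq_len(cb$n_colors)])) ==
           seq_len(cb$n_colors)))
    stop_input("channel_digit_map must cover digits 1..%d", cb$n_colors)
  invisible(cb)
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook> F=%d colors x N=%d rounds (capacity %s), mode %s\n",
              x$n_colors, x$n_rounds, format(capacity(x$n_colors, x$n_rounds)),
              x$panel_mode))
  cat(sprintf("  %d entr%s; channels: %s\n", length(x$entries),
              if (length(x$entries) == 1L) "y" else "ies",
              paste(sprintf("%s=%d", names(x$channel_digit_map),
                            x$channel_digit_map), collapse = ", ")))
  invisible(x)
}

#' Assign one shared code per cell type to a marker-gene panel
#'
#' In tissue mode every marker gene of a cell type carries that cell type's
#' single optical code, so a segmented cell is typed by the code its spots
#' collectively display. The returned codebook is in `per_cell_type` mode:
#' `entries` maps cell type -> code (codes unique across types) and `$panel`
#' lists every probed gene with its inherited code.
#'
#' @param codebook A `codebook` whose entry count is at least the number of
#'   cell types (extra codes are dropped), or one built with exactly that
#'   many entries.
#' @param panel Data frame with columns `cell_type` and `gene` (one row per
#'   marker gene). A gene may belong to only one cell type.
#' @return A `codebook` in `per_cell_type` mode with a `$panel` data frame
#'   (`cell_type`, `gene`, `code`).
#' @examples
#' cb <- build_codebook(3, 2, 6, seed = 1)
#' panel <- data.frame(cell_type = rep(paste0("type", 1:6), each = 10),
#'                     gene = paste0("g", 1:60))
#' tissue_cb <- assign_panel(cb, panel)
#' nrow(tissue_cb$panel) # 60 probed genes, 6 distinct codes
#' @export
assign_panel <- function(codebook, panel) {
  validate_codebook(codebook)
  if (!all(c("cell_type", "gene") %in% names(panel)))
    stop_input("panel needs columns 'cell_type' and 'gene'")
  dup <- panel$gene[duplicated(panel$gene)]
  if (length(dup))
    stop_input("gene(s) assigned to more than one cell type: %s",
               paste(unique(dup), collapse = ", "))
  types <- unique(as.character(panel$cell_type))
  if (length(types) > capacity(codebook$n_colors, codebook$n_rounds))
    stop(errorCondition(
      sprintf("capacity exceeded: %d cell types but only %s codes (F=%d, N=%d)",
              length(types), format(capacity(codebook$n_colors, codebook$n_rounds)),
              codebook$n_colors, codebook$n_rounds),
      class = c("spotcode_capacity_error", "spotcode_input_error", "error")))
  if (length(types) > length(codebook$entries))
    stop_input("codebook holds %d codes but the panel names %d cell types",
               length(codebook$entries), length(types))
  type_codes <- stats::setNames(unname(codebook$entries[seq_along(types)]), types)
  out <- codebook
  out$panel_mode <- "per_cell_type"
  out$entries <- type_codes
  out$panel <- data.frame(
    cell_type = as.character(panel$cell_type),
    gene = as.character(panel$gene),
    code = unname(type_codes[as.character(panel$cell_type)]),
    stringsAsFactors = FALSE)
  validate_codebook(out)
  out
}

#' Look up the target (or cell type) carrying a given code
#'
#' Exact reverse lookup in the codebook. Unassigned but well-formed codes
#' return `NA_character_`; malformed codes (wrong length or digits outside
#' `1..n_colors`) raise a format error.
#'
#' @param codebook A `codebook`.
#' @param code Code string of length `n_rounds` over digits `1..n_colors`.
#' @return The target id (per-gene mode) or cell type (per-cell-type mode),
#'   or `NA_character_` if the code is unassigned.
#' @export
lookup <- function(codebook, code) {
  validate_codebook(codebook)
  if (!is.character(code) || length(code) != 1L)
    stop_input("code must be a single string")
  if (nchar(code) != codebook$n_rounds)
    stop_input("code '%s' has %d digits; expected %d", code, nchar(code),
               codebook$n_rounds)
  digs <- strsplit(code, "")[[1]]
  if (!all(digs %in% as.character(seq_len(codebook$n_colors))))
    stop_input("code '%s' uses digits outside 1..%d", code, codebook$n_colors)
  hit <- names(codebook$entries)[match(code, codebook$entries)]
  if (length(hit) == 0L || is.na(hit)) NA_character_ else hit
}

#' Write a codebook to JSON
#'
#' @param codebook A `codebook`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(codebook, path) {
  validate_codebook(codebook)
  obj <- list(
    n_colors = codebook$n_colors,
    n_rounds = codebook$n_rounds,
    channel_digit_map = as.list(codebook$channel_digit_map),
    panel_mode = codebook$panel_mode,
    entries = as.list(codebook$entries))
  if (!is.null(codebook$panel)) obj$panel <- codebook$panel
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a codebook from JSON
#'
#' @param path Path to a JSON file written by [write_codebook()].
#' @return A validated `codebook`.
#' @export
read_codebook <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cb <- structure(list(
    n_colors = as.integer(obj$n_colors),
    n_rounds = as.integer(obj$n_rounds),
    channel_digit_map = stats::setNames(as.integer(unlist(obj$channel_digit_map)),
                                        names(obj$channel_digit_map)),
    panel_mode = obj$panel_mode,
    entries = stats::setNames(as.character(unlist(obj$entries)),
                              names(obj$entries))
  ), class = "codebook")
  if (!is.null(obj$panel)) cb$panel <- as.data.frame(obj$panel)
  validate_codebook(cb)
  cb
}

#' Write a marker-gene panel table to CSV
#'
#' Columns `cell_type,gene,code`; the inverse of [read_panel()].
#'
#' @param codebook A per-cell-type `codebook` with a `$panel`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(codebook, path) {
  if (is.null(codebook$panel)) stop_input("codebook carries no panel table")
  utils::write.csv(codebook$panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a marker-gene panel table from CSV
#'
#' @param path CSV with columns `cell_type,gene` (an existing `code` column
#'   is ignored; codes come from the codebook at assignment time).
#' @return Data frame with `cell_type` and `gene` columns.
#' @export
read_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_type", "gene") %in% names(df)))
    stop_input("panel CSV needs columns 'cell_type' and 'gene'")
  df[c("cell_type", "gene")]
}
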