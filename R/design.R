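# Unified nearest-neighbor thermodynamic parameters for DNA/DNA duplexes
# (SantaLucia 1998): dH in kcal/mol, dS in cal/(mol K), 1 M NaCl reference.
NN_DH <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
           CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
           GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
           TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
NN_DS <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
           CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
           GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
           TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
NN_INIT_GC <- c(dh = 0.1, ds = -2.8)   # per G/C terminal end
NN_INIT_AT <- c(dh = 2.3, ds = 4.1)    # per A/T terminal end
GAS_CONSTANT <- 1.9872                 # cal/(mol K)

check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop_input("%s must be a single string", what)
  s <- toupper(seq)
  if (nchar(s) && grepl("[^ACGT]", s))
    stop_input("%s contains non-DNA characters: %s", what,
               gsub("[ACGT]", "", s))
  s
}

#' Duplex melting temperature by nearest-neighbor thermodynamics
#'
#' Computes the melting temperature of a perfectly matched DNA/DNA duplex
#' with the unified nearest-neighbor parameter set (stacking enthalpies and
#' entropies per dinucleotide plus terminal initiation terms), an entropic
#' salt correction of `0.368 * (L-1) * ln[Na+]` cal/(mol K), and
#' `Tm = 1000 * dH / (dS + R * ln(C/4)) - 273.15` for non-self-complementary
#' duplexes at total strand concentration `C`.
#'
#' @param seq DNA sequence (one strand of the duplex), length >= 2.
#' @param na_molar Monovalent cation concentration in mol/L. Default 0.39
#'   (approximately 2x SSC hybridization buffer).
#' @param conc_molar Total strand concentration in mol/L. Default 5e-7.
#' @return Melting temperature in degrees Celsius.
#' @examples
#' melting_temperature("ACGTACGTACGTACGTACGT")
#' @export
melting_temperature <- function(seq, na_molar = 0.39, conc_molar = 5e-7) {
  s <- check_dna(seq, "seq")
  n <- nchar(s)
  if (n < 2L) stop_input("sequence must have length >= 2, got %d", n)
  if (na_molar <= 0 || conc_molar <= 0)
    stop_input("na_molar and conc_molar must be positive")
  chars <- strsplit(s, "")[[1]]
  stacks <- paste0(chars[-n], chars[-1])
  dh <- sum(NN_DH[stacks])
  ds <- sum(NN_DS[stacks])
  for (term in chars[c(1L, n)]) {
    init <- if (term %in% c("G", "C")) NN_INIT_GC else NN_INIT_AT
    dh <- dh + init[["dh"]]
    ds <- ds + init[["ds"]]
  }
  ds <- ds + 0.368 * (n - 1) * log(na_molar)
  1000 * dh / (ds + GAS_CONSTANT * log(conc_molar / 4)) - 273.15
}

longest_homopolymer <- function(seq) {
  if (nchar(seq) == 0L) return(0L)
  r <- rle(strsplit(seq, "")[[1]])
  max(r$lengths)
}

#' Probe design constraints
#'
#' Default thresholds for primary-probe screening: a 35-nt target region and
#' 30-nt readout region (65 nt total), a proper-hybridization melting
#' temperature of at least 70 degrees C, homopolymer runs of at most six
#' identical nucleotides, and optional off-target / secondary-structure
#' melting-temperature screens. The off-target and secondary-structure
#' thresholds carry explicit direction flags (`*_is_upper = TRUE` treats the
#' threshold as an upper bound, the conventional reading for cross-hyb and
#' hairpin stability screens).
#'
#' @param target_len Target-region length in nt.
#' @param readout_len Readout-region length in nt.
#' @param tm_proper_min Minimum Tm (deg C) of the properly hybridized target
#'   region.
#' @param tm_offtarget_threshold Tm threshold (deg C) for the longest
#'   contiguous complementary match against a background set.
#' @param tm_offtarget_is_upper If `TRUE`, off-target Tm at or above the
#'   threshold is a violation; if `FALSE` the comparison is inverted.
#' @param tm_secondary_threshold Tm threshold (deg C) for the strongest
#'   self-complementary stem (hairpin/self-dimer proxy).
#' @param tm_secondary_is_upper Direction flag as above.
#' @param max_homopolymer_run Longest allowed run of one nucleotide.
#' @param na_molar,conc_molar Salt and strand concentration passed to
#'   [melting_temperature()].
#' @return A `design_constraints` list.
#' @export
design_constraints <- function(target_len = 35L, readout_len = 30L,
                               tm_proper_min = 70, tm_offtarget_threshold = 72,
                               tm_offtarget_is_upper = TRUE,
                               tm_secondary_threshold = 76,
                               tm_secondary_is_upper = TRUE,
                               max_homopolymer_run = 6L,
                               na_molar = 0.39, conc_molar = 5e-7) {
  stopifnot(target_len >= 1, readout_len >= 0, is.finite(tm_proper_min),
            max_homopolymer_run >= 1)
  structure(list(target_len = as.integer(target_len),
                 readout_len = as.integer(readout_len),
                 tm_proper_min = tm_proper_min,
                 tm_offtarget_threshold = tm_offtarget_threshold,
                 tm_offtarget_is_upper = tm_offtarget_is_upper,
                 tm_secondary_threshold = tm_secondary_threshold,
                 tm_secondary_is_upper = tm_secondary_is_upper,
                 max_homopolymer_run = as.integer(max_homopolymer_run),
                 na_molar = na_molar, conc_molar = conc_molar),
            class = "design_constraints")
}

# Longest stretch of seq whose reverse complement also occurs in subject.
longest_complement_run <- function(seq, subject) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  n <- nchar(seq)
  for (k in n:4) {
    for (i in seq_len(n - k + 1L)) {
      if (grepl(substr(rc, i, i + k - 1L), subject, fixed = TRUE))
        return(k)
    }
  }
  0L
}

#' Validate a primary probe against design constraints
#'
#' Checks the target/readout length partition (default 35 + 30 = 65 nt), the
#' DNA alphabet, the homopolymer-run limit across the full probe, and the
#' target region's melting temperature against `tm_proper_min`. Optional
#' screens run when inputs are supplied: an off-target screen against a
#' background sequence set (longest contiguous complementary run, scored by
#' its Tm) and a secondary-structure screen (strongest self-complementary
#' stem within the full probe).
#'
#' @param target_seq Target-region sequence (binds the transcript).
#' @param readout_seq Readout-region sequence (recruits the amplifier).
#' @param constraints A [design_constraints()] object.
#' @param background Optional character vector of background transcript
#'   sequences for the off-target screen.
#' @return A `probe_report` list: `pass` (logical), `reasons` (character
#'   vector of violated rules, empty when passing), `tm_target` and the
#'   lengths checked.
#' @examples
#' cs <- design_constraints()
#' target <- paste(rep("ACGTGCA", 5), collapse = "")
#' readout <- paste(rep("TGCACG", 5), collapse = "")
#' validate_probe(target, readout, cs)$pass
#' @export
validate_probe <- function(target_seq, readout_seq, constraints = design_constraints(),
                           background = NULL) {
  tg <- check_dna(target_seq, "target_seq")
  ro <- check_dna(readout_seq, "readout_seq")
  full <- paste0(tg, ro)
  reasons <- character()
  if (nchar(tg) != constraints$target_len)
    reasons <- c(reasons, sprintf("target length %d != %d nt", nchar(tg),
                                  constraints$target_len))
  if (nchar(ro) != constraints$readout_len)
    reasons <- c(reasons, sprintf("readout length %d != %d nt", nchar(ro),
                                  constraints$readout_len))
  run <- longest_homopolymer(full)
  if (run > constraints$max_homopolymer_run)
    reasons <- c(reasons, sprintf("homopolymer run of %d exceeds %d", run,
                                  constraints$max_homopolymer_run))
  tm_target <- if (nchar(tg) >= 2)
    melting_temperature(tg, constraints$na_molar, constraints$conc_molar)
  else NA_real_
  if (!is.na(tm_target) && tm_target < constraints$tm_proper_min)
    reasons <- c(reasons, sprintf("target Tm %.1f below minimum %.1f",
                                  tm_target, constraints$tm_proper_min))
  tm_off <- NA_real_
  if (!is.null(background) && length(background)) {
    bg <- paste(vapply(background, check_dna, "", what = "background"),
                collapse = "|")
    k <- longest_complement_run(tg, bg)
    if (k >= 4) {
      chars <- strsplit(tg, "")[[1]]
      best <- -Inf
      for (i in seq_len(nchar(tg) - k + 1L)) {
        sub <- substr(tg, i, i + k - 1L)
        rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
        if (grepl(rc, bg, fixed = TRUE))
          best <- max(best, melting_temperature(sub, constraints$na_molar,
                                                constraints$conc_molar))
      }
      tm_off <- best
      viol <- if (constraints$tm_offtarget_is_upper)
        tm_off >= constraints$tm_offtarget_threshold
      else tm_off < constraints$tm_offtarget_threshold
      if (isTRUE(viol))
        reasons <- c(reasons, sprintf("off-target stem Tm %.1f violates threshold %.1f",
                                      tm_off, constraints$tm_offtarget_threshold))
    }
  }
  tm_sec <- secondary_structure_tm(full, constraints)
  if (!is.na(tm_sec)) {
    viol <- if (constraints$tm_secondary_is_upper)
      tm_sec >= constraints$tm_secondary_threshold
    else tm_sec < constraints$tm_secondary_threshold
    if (isTRUE(viol))
      reasons <- c(reasons, sprintf("self-complementary stem Tm %.1f violates threshold %.1f",
                                    tm_sec, constraints$tm_secondary_threshold))
  }
  structure(list(pass = length(reasons) == 0L, reasons = reasons,
                 tm_target = tm_target, tm_offtarget = tm_off,
                 tm_secondary = tm_sec,
                 target_len = nchar(tg), readout_len = nchar(ro),
                 full_len = nchar(full)),
            class = "probe_report")
}

# Tm of the strongest self-complementary stem of >= min_stem bases; NA when
# no such stem exists. A crude hairpin/self-dimer proxy, not a folding model.
secondary_structure_tm <- function(seq, constraints, min_stem = 6L) {
  n <- nchar(seq)
  if (n < 2L * min_stem) return(NA_real_)
  for (k in min(n %/% 2L, 20L):min_stem) {
    for (i in seq_len(n - k + 1L)) {
      stem <- substr(seq, i, i + k - 1L)
      # positions in seq where rc(stem) occurs, excluding overlap with stem
      rcs <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(stem)))
      j <- gregexpr(rcs, seq, fixed = TRUE)[[1]]
      j <- j[j > 0]
      if (length(j) && any(j >= i + k | j + k <= i))
        return(melting_temperature(stem, constraints$na_molar,
                                   constraints$conc_molar))
    }
  }
  NA_real_
}

#' Screen a transcript for candidate probe target windows
#'
#' Slides a window of `constraints$target_len` nucleotides across the
#' transcript and keeps windows that satisfy the sequence-level rules of
#' [validate_probe()] (alphabet, homopolymer run, minimum Tm). Coordinates
#' are 0-based and half-open.
#'
#' @param transcript Transcript sequence (sense strand).
#' @param constraints A [design_constraints()] object.
#' @return Data frame with columns `start`, `end` (0-based half-open), `seq`
#'   and `tm`; zero rows (with a warning) when the transcript is shorter
#'   than the window.
#' @export
screen_targets <- function(transcript, constraints = design_constraints()) {
  s <- check_dna(transcript, "transcript")
  L <- constraints$target_len
  empty <- data.frame(start = integer(), end = integer(),
                      seq = character(), tm = numeric())
  if (nchar(s) < L) {
    warning(sprintf("transcript (%d nt) shorter than target window (%d nt)",
                    nchar(s), L))
    return(empty)
  }
  starts <- 0:(nchar(s) - L)
  keep <- logical(length(starts))
  tms <- rep(NA_real_, length(starts))
  for (ii in seq_along(starts)) {
    w <- substr(s, starts[ii] + 1L, starts[ii] + L)
    if (longest_homopolymer(w) > constraints$max_homopolymer_run) next
    tm <- melting_temperature(w, constraints$na_molar, constraints$conc_molar)
    if (tm < constraints$tm_proper_min) next
    keep[ii] <- TRUE
    tms[ii] <- tm
  }
  data.frame(start = starts[keep], end = starts[keep] + L,
             seq = vapply(starts[keep], function(st) substr(s, st + 1L, st + L), ""),
             tm = tms[keep])
}

#' Dendritic nanostructure specification
#'
#' Describes a layered tetrahedral-DNA amplifier: a core monomer (layer 0)
#' plus `n_shells` dendritic layers, each monomer presenting `branching`
#' sticky ends to recruit the next layer, and each terminal-layer monomer
#' carrying `dyes_per_terminal` fluorophore strands. Tetrahedron edges are
#' `edge_bp` base pairs at `rise_nm_per_bp` nm per base pair of B-form
#' helical rise.
#'
#' @param edge_bp Base pairs per tetrahedron edge.
#' @param rise_nm_per_bp Helical rise in nm per base pair.
#' @param branching Sticky ends per monomer feeding the next layer.
#' @param n_shells Dendritic layers beyond the core.
#' @param dyes_per_terminal Dye strands per terminal monomer.
#' @param sticky_end_pairs List of length-2 character vectors naming the
#'   complementary overhang roles between adjacent layers, e.g.
#'   `c("T0:up", "T1:down")`.
#' @return A `dendrimer_spec` list.
#' @export
dendrimer_spec <- function(edge_bp = 17L, rise_nm_per_bp = 0.34, branching = 3L,
                      n_shells = 2L, dyes_per_terminal = 3L,
                      sticky_end_pairs = list(c("T0:up", "T1:down"),
                                              c("T1:up", "T2:down"))) {
  stopifnot(branching >= 1, n_shells >= 0, edge_bp >= 0, dyes_per_terminal >= 0)
  for (p in sticky_end_pairs) {
    ln <- vapply(p, sticky_layer_index, 0L)
    if (abs(ln[2] - ln[1]) != 1L)
      stop_input("sticky-end pair %s / %s does not link adjacent layers",
                 p[1], p[2])
  }
  structure(list(edge_bp = as.integer(edge_bp), rise_nm_per_bp = rise_nm_per_bp,
                 branching = as.integer(branching), n_shells = as.integer(n_shells),
                 dyes_per_terminal = as.integer(dyes_per_terminal),
                 sticky_end_pairs = sticky_end_pairs),
            class = "dendrimer_spec")
}

sticky_layer_index <- function(role) {
  m <- regmatches(role, regexpr("^T[0-9]+", role))
  if (!length(m)) stop_input("overhang role '%s' must start with T<layer>", role)
  as.integer(sub("T", "", m))
}

#' Per-layer mixing volumes for layer-by-layer assembly
#'
#' With every strand at equal concentration, building each dendritic layer
#' requires `per_layer_ratio` molar equivalents of the new monomer per
#' sticky end of the previous layer, so layer k takes
#' `core_volume * per_layer_ratio^k`.
#'
#' @param core_volume Volume of the core-monomer solution (any unit).
#' @param n_shells Number of dendritic layers beyond the core.
#' @param per_layer_ratio Molar ratio of layer k+1 monomer to layer k
#'   monomer. Default 3 (one monomer per sticky end).
#' @return Named numeric vector of volumes, `core` then `layer1..layerK`.
#' @examples
#' assembly_stoichiometry(5, 2) # 5, 15, 45 uL
#' @export
assembly_stoichiometry <- function(core_volume, n_shells, per_layer_ratio = 3) {
  if (core_volume <= 0) stop_input("core_volume must be positive")
  stopifnot(n_shells >= 0, per_layer_ratio > 0)
  v <- core_volume * per_layer_ratio^(0:n_shells)
  names(v) <- c("core", if (n_shells > 0) paste0("layer", seq_len(n_shells)))
  v
}

#' Monomer and fluorophore counts of a dendritic nanostructure
#'
#' Layer k of the dendrimer holds `branching^k` monomers; each terminal
#' monomer carries `dyes_per_terminal` fluorophore strands.
#'
#' @param spec A [dendrimer_spec()].
#' @return List with `monomers_per_layer` (length `n_shells + 1`),
#'   `total_monomers` and `total_fluorophores`.
#' @examples
#' count_units(dendrimer_spec()) # layers 1,3,9; 13 monomers; 27 fluorophores
#' @export
count_units <- function(spec) {
  stopifnot(inherits(spec, "dendrimer_spec"))
  per_layer <- spec$branching^(0:spec$n_shells)
  list(monomers_per_layer = per_layer,
       total_monomers = sum(per_layer),
       total_fluorophores = spec$branching^spec$n_shells * spec$dyes_per_terminal)
}

#' Characteristic edge length of a DNA tetrahedron
#'
#' Edge length in nm from base-pair count times helical rise, rounded to one
#' decimal.
#'
#' @param edge_bp Base pairs per edge.
#' @param rise_nm_per_bp Helical rise, nm per base pair (B-form default
#'   0.34).
#' @return Edge length in nm, one-decimal rounded.
#' @examples
#' edge_geometry(17) # 5.8 nm
#' @export
edge_geometry <- function(edge_bp, rise_nm_per_bp = 0.34) {
  if (edge_bp < 0) stop_input("edge_bp must be >= 0")
  round(edge_bp * rise_nm_per_bp, 1)
}

#' Check sticky-end pairing of a layered nanostructure strand set
#'
#' Verifies that every declared adjacent-layer overhang pair is exactly
#' reverse-complementary, and scans all overhang pairs exhaustively for
#' unintended full-length complements between non-adjacent layers (layer n
#' to n+2) or within one layer, which would break the strictly layered
#' assembly order.
#'
#' @param spec A [dendrimer_spec()] with `sticky_end_pairs`.
#' @param strands Named character vector (or `Biostrings::DNAStringSet`) of
#'   overhang sequences; names are roles like `"T0:up"`. See
#'   [read_strand_table()] for the FASTA form.
#' @return List with `pass` (logical) and `violations` (data frame with
#'   columns `rule`, `role_a`, `role_b`, `detail`).
#' @export
validate_sticky_ends <- function(spec, strands) {
  stopifnot(inherits(spec, "dendrimer_spec"))
  if (inherits(strands, "DNAStringSet"))
    strands <- stats::setNames(as.character(strands), names(strands))
  if (is.null(names(strands)) || any(!nzchar(names(strands))))
    stop_input("every strand needs a 'T<layer>:<end>' role name")
  strands <- vapply(strands, check_dna, "", what = "overhang")
  if (any(nchar(strands) == 0L)) stop_input("empty overhang sequence")
  layers <- vapply(names(strands), sticky_layer_index, 0L)
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  viol <- list()
  for (p in spec$sticky_end_pairs) {
    miss <- setdiff(p, names(strands))
    if (length(miss))
      stop_input("declared role(s) missing from strand table: %s",
                 paste(miss, collapse = ", "))
    a <- strands[[p[1]]]; b <- strands[[p[2]]]
    if (nchar(a) != nchar(b) || rc(a) != b)
      viol[[length(viol) + 1L]] <- data.frame(
        rule = "declared_pair_not_complementary", role_a = p[1], role_b = p[2],
        detail = sprintf("%s vs %s", a, b))
  }
  declared <- vapply(spec$sticky_end_pairs, paste, "", collapse = "|")
  nm <- names(strands)
  for (i in seq_along(strands)) for (j in seq_along(strands)) {
    if (j <= i) next
    if (nchar(strands[[i]]) != nchar(strands[[j]])) next
    if (rc(strands[[i]]) != strands[[j]]) next
    key1 <- paste(nm[i], nm[j], sep = "|"); key2 <- paste(nm[j], nm[i], sep = "|")
    if (key1 %in% declared || key2 %in% declared) next
    gap <- abs(layers[i] - layers[j])
    rule <- if (gap == 0L) "intra_layer_complement"
            else if (gap == 1L) "undeclared_adjacent_complement"
            else "cross_layer_complement"
    viol[[length(viol) + 1L]] <- data.frame(
      rule = rule, role_a = nm[i], role_b = nm[j],
      detail = sprintf("layers T%d/T%d", layers[i], layers[j]))
  }
  violations <- if (length(viol)) do.call(rbind, viol)
    else data.frame(rule = character(), role_a = character(),
                    role_b = character(), detail = character())
  list(pass = nrow(violations) == 0L, violations = violations)
}

#' Read an annotated strand table from FASTA
#'
#' Description lines carry `layer=T0 end=up` annotations; records are
#' returned as a named character vector with `"T0:up"`-style role names
#' suitable for [validate_sticky_ends()].
#'
#' @param path FASTA file path.
#' @return Named character vector of overhang sequences.
#' @export
read_strand_table <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  desc <- names(set)
  layer <- regmatches(desc, regexpr("layer=\\S+", desc))
  end <- regmatches(desc, regexpr("end=\\S+", desc))
  if (length(layer) != length(set) || length(end) != length(set))
    stop_input("every FASTA description must carry 'layer=' and 'end=' tags")
  roles <- paste0(sub("layer=", "", layer), ":", sub("end=", "", end))
  stats::setNames(as.character(set), roles)
}
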