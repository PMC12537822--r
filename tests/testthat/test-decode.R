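mk_spots <- function(...) {
  df <- data.frame(...)
  if (is.null(df$peak_intensity)) df$peak_intensity <- 1000
  df$id <- seq_len(nrow(df))
  df
}

test_that("identical coordinates across two rounds link into length-2 chains", {
  sp <- mk_spots(round = c(1, 1, 2, 2), channel = c("Cy5", "Cy3", "Cy3", "FAM"),
                 y = c(10, 40, 10, 40), x = c(10, 40, 10, 40))
  linked <- link_spots(sp, 2, link_radius = 1.5)
  expect_length(linked$chains, 2)
  expect_true(all(lengths(linked$chains) == 2))
})

test_that("spots farther apart than the link radius never cross-link", {
  sp <- mk_spots(round = c(1, 2), channel = c("Cy5", "Cy3"),
                 y = c(10, 20), x = c(10, 10))
  linked <- link_spots(sp, 2, link_radius = 2)
  expect_length(linked$chains, 2)
  expect_true(all(lengths(linked$chains) == 1))
})

test_that("chains on a jittered simulated scene recover ground-truth identity", {
  cfg <- sim_config(ny = 360, nx = 360, n_rounds = 2, seed = 61,
                    drift = matrix(0, 2, 2), residual_fraction = 0)
  cb <- build_codebook(3, 2, 9, seed = 1)
  sim <- simulate_spot_field(cfg, cb, 100)
  det <- detect_stack_spots(sim$stack, 1.3)
  linked <- link_spots(det, 2, link_radius = 1.5)
  dec <- decode_spot_chains(linked, cb)
  tr <- sim$truth$spots
  good <- 0
  usable <- dec[dec$status %in% c("decoded", "ambiguous"), ]
  for (i in seq_len(nrow(usable))) {
    j <- which.min((tr$y - usable$y[i])^2 + (tr$x - usable$x[i])^2)
    if (sqrt((tr$y[j] - usable$y[i])^2 + (tr$x[j] - usable$x[i])^2) <= 2 &&
        tr$gene[j] == usable$target[i]) good <- good + 1
  }
  expect_gte(good / nrow(tr), 0.99)
})

test_that("digit strings follow the channel map with 0 for missing rounds", {
  cdm <- c(Cy5 = 1L, Cy3 = 2L, FAM = 3L)
  two <- data.frame(round = 1:2, channel = c("Cy5", "Cy3"),
                    peak_intensity = c(500, 600))
  expect_equal(digits_from_chain(two, 2, cdm)$code, "12")
  expect_false(digits_from_chain(two, 2, cdm)$ambiguous)

  single <- data.frame(round = 1, channel = "FAM", peak_intensity = 500)
  expect_equal(digits_from_chain(single, 2, cdm)$code, "30")

  multi <- data.frame(round = c(1, 1, 2), channel = c("Cy5", "FAM", "Cy3"),
                      peak_intensity = c(900, 300, 700))
  got <- digits_from_chain(multi, 2, cdm)
  expect_equal(got$code, "12")
  expect_true(got$ambiguous)

  bad <- data.frame(round = 1, channel = "GFP", peak_intensity = 1)
  expect_error(digits_from_chain(bad, 2, cdm), class = "spotcode_input_error")
})

test_that("a full-codebook noise-free scene decodes completely", {
  cfg <- sim_config(ny = 360, nx = 360, n_rounds = 2, seed = 71,
                    read_noise_sd = 0, poisson_noise = FALSE,
                    drift = matrix(0, 2, 2), residual_fraction = 0)
  cb <- build_codebook(3, 2, 9, seed = 1)
  sim <- simulate_spot_field(cfg, cb, 90)
  det <- detect_stack_spots(sim$stack, 1.3)
  linked <- link_spots(det, 2, 1.5)
  dec <- decode_spot_chains(linked, cb)
  counts <- attr(dec, "status_counts")
  expect_equal(unname(counts["decoded"]) + unname(counts["ambiguous"]),
               nrow(sim$truth$spots))
  expect_equal(unname(counts["unknown_code"]), 0L)
  expect_equal(unname(counts["incomplete"]), 0L)
})

test_that("decoded fraction under dropout matches the closed-form rate", {
  p <- 0.1
  cfg <- sim_config(ny = 600, nx = 600, n_rounds = 2, seed = 81,
                    dropout_prob = p, residual_fraction = 0,
                    drift = matrix(0, 2, 2))
  cb <- build_codebook(3, 2, 9, seed = 1)
  sim <- simulate_spot_field(cfg, cb, 700)
  det <- detect_stack_spots(sim$stack, 1.3)
  dec <- decode_spot_chains(link_spots(det, 2, 1.5), cb)
  n_complete <- sum(dec$status %in% c("decoded", "ambiguous", "unknown_code"))
  n_truth <- nrow(sim$truth$spots)
  ci <- stats::qbinom(c(0.005, 0.995), n_truth, (1 - p)^2)
  expect_gte(n_complete, ci[1])
  expect_lte(n_complete, ci[2])
})

test_that("complete codes missing from the codebook come back unknown", {
  cdm <- c(Cy5 = 1L, Cy3 = 2L, FAM = 3L)
  cb <- build_codebook(3, 2, 6, seed = 1)
  missing_code <- setdiff(spotcode:::enumerate_codes(3, 2), cb$entries)[1]
  chans <- names(cdm)[as.integer(strsplit(missing_code, "")[[1]])]
  sp <- mk_spots(round = 1:2, channel = chans, y = c(5, 5), x = c(5, 5))
  dec <- decode_spot_chains(link_spots(sp, 2, 1.5), cb)
  expect_equal(dec$status, "unknown_code")
  expect_true(is.na(dec$target))
})

test_that("no chain is lost: statuses partition the chain set", {
  cfg <- sim_config(ny = 256, nx = 256, n_rounds = 2, seed = 91,
                    dropout_prob = 0.15)
  cb <- build_codebook(3, 2, 5, seed = 3)
  sim <- simulate_spot_field(cfg, cb, 150)
  linked <- link_spots(detect_stack_spots(sim$stack, 1.3), 2, 1.5)
  dec <- decode_spot_chains(linked, cb)
  expect_equal(nrow(dec), length(linked$chains))
  expect_equal(sum(attr(dec, "status_counts")), length(linked$chains))
})

test_that("plane normalization is scale-invariant and rejects flat planes", {
  cfg <- sim_config(ny = 64, nx = 64, n_rounds = 1, seed = 5,
                    drift = matrix(0, 1, 2))
  sim <- simulate_spot_field(cfg, build_codebook(3, 1, 3, seed = 1), 10)
  st <- sim$stack
  scaled <- st
  scaled$rounds[[1]]$Cy5 <- st$rounds[[1]]$Cy5 * 5
  a <- normalize_channels(st)
  b <- normalize_channels(scaled)
  expect_equal(a$rounds[[1]]$Cy5, b$rounds[[1]]$Cy5, tolerance = 1e-12)

  flat <- st
  flat$rounds[[1]]$Cy3 <- matrix(7, 64, 64)
  expect_error(normalize_channels(flat), class = "spotcode_degenerate_error")
})

test_that("mask decoding follows the winning-channel rule", {
  # constructed planes: two masks, known channel dominance per round
  cb <- assign_panel(build_codebook(3, 2, 2, seed = 1,
                                    target_ids = c("tA", "tB")),
                     data.frame(cell_type = c("tA", "tB"),
                                gene = c("g1", "g2")))
  code_a <- unname(cb$entries["tA"])
  mask <- matrix(0L, 40, 40)
  mask[5:15, 5:15] <- 1L
  mask[25:35, 25:35] <- 2L
  chans <- c("Cy5", "Cy3", "FAM", "DAPI")
  mkplane <- function(hot, label) {
    p <- matrix(100, 40, 40) + matrix(rnorm(1600, 0, 2), 40)
    if (!is.na(hot)) p[mask == label] <- p[mask == label] + 800
    p
  }
  digit_chan <- function(d) chans[as.integer(d)]
  rounds <- lapply(1:2, function(r) {
    pl <- lapply(chans, function(ch) matrix(100 + rnorm(1600, 0, 2), 40))
    names(pl) <- chans
    # region 1 follows code_a, region 2 follows tB's code
    for (lab in 1:2) {
      code <- unname(cb$entries[c("tA", "tB")[lab]])
      ch <- digit_chan(substr(code, r, r))
      pl[[ch]][mask == lab] <- pl[[ch]][mask == lab] + 800
    }
    pl
  })
  st <- spotcode:::new_round_stack(rounds, chans, 0.108)
  dm <- decode_masks(normalize_channels(st), mask, cb)
  expect_equal(dm$regions$cell_type, c("tA", "tB"))
  expect_false(any(dm$regions$tie_flag))
  expect_equal(dm$atlas$n_untyped, 0)
})

test_that("exact channel ties are flagged and resolved by priority", {
  cb <- assign_panel(build_codebook(3, 2, 1, seed = 1, target_ids = "tA"),
                     data.frame(cell_type = "tA", gene = "g1"))
  mask <- matrix(0L, 20, 20); mask[5:15, 5:15] <- 1L
  chans <- c("Cy5", "Cy3", "FAM", "DAPI")
  base <- matrix(c(rep(0, 200), seq_len(200)), 20, 20)  # non-degenerate plane
  rounds <- lapply(1:2, function(r)
    stats::setNames(lapply(chans, function(ch) base), chans))
  st <- spotcode:::new_round_stack(rounds, chans, 0.108)
  dm <- decode_masks(st, mask, cb)   # identical planes: all channels tie
  expect_true(dm$regions$tie_flag[1])
  expect_equal(dm$regions$code[1], "11")   # Cy5 priority on exact ties
})

test_that("mask decoding survives monotone per-plane intensity rescaling", {
  cb <- assign_panel(build_codebook(3, 2, 3, seed = 5),
                     data.frame(cell_type = rep(paste0("t", 1:3), each = 2),
                                gene = paste0("g", 1:6)))
  cfg <- sim_config(ny = 200, nx = 200, n_rounds = 2, seed = 15,
                    drift = matrix(0, 2, 2))
  sim <- simulate_tissue(cfg, cb, 30, c(t1 = 0.4, t2 = 0.3, t3 = 0.3))
  plain <- decode_masks(normalize_channels(sim$stack), sim$mask, cb)
  warped <- sim$stack
  for (r in 1:2) for (ch in c("Cy5", "Cy3", "FAM"))
    warped$rounds[[r]][[ch]] <- 3 * warped$rounds[[r]][[ch]]^1.2 + 10
  warped_dec <- decode_masks(normalize_channels(warped), sim$mask, cb)
  expect_equal(warped_dec$regions$code, plain$regions$code)
})

test_that("simulated tissue decodes to the planted cell types", {
  cb <- assign_panel(build_codebook(3, 2, 6, seed = 2),
                     data.frame(cell_type = rep(paste0("t", 1:6), each = 10),
                                gene = paste0("g", 1:60)))
  freqs <- c(t1 = 0.4, t2 = 0.2, t3 = 0.1, t4 = 0.1, t5 = 0.1, t6 = 0.1)
  cfg <- sim_config(ny = 400, nx = 400, seed = 25)
  sim <- simulate_tissue(cfg, cb, 150, freqs)
  reg <- register_stack(sim$stack)
  dm <- decode_masks(normalize_channels(reg$stack), sim$mask, cb)
  m <- merge(dm$regions, sim$truth$cells, by = "label")
  expect_gte(mean(m$cell_type.x == m$cell_type.y, na.rm = TRUE), 0.95)
})

test_that("decoded gene proportions recover planted weights", {
  cb <- build_codebook(3, 2, 9, seed = 1)
  w <- c(4, 2, 1, 1, 1, 1, 1, 1, 1); w <- w / sum(w)
  cfg <- sim_config(ny = 560, nx = 560, n_rounds = 2, seed = 35,
                    drift = matrix(0, 2, 2))
  sim <- simulate_spot_field(cfg, cb, 600, gene_weights = w)
  dec <- decode_spot_chains(link_spots(detect_stack_spots(sim$stack, 1.3),
                                       2, 1.5), cb)
  usable <- dec[dec$status %in% c("decoded", "ambiguous"), ]
  counts <- table(factor(usable$target, levels = names(cb$entries)))
  n <- sum(counts)
  for (g in names(cb$entries)) {
    ci <- stats::qbinom(c(0.005, 0.995), n, w[match(g, names(cb$entries))])
    expect_gte(counts[[g]], ci[1])
    expect_lte(counts[[g]], ci[2])
  }
})
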