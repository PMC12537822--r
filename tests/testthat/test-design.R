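test_that("nearest-neighbor Tm matches an independent per-step oracle", {
  set.seed(101)
  for (i in 1:50) {
    s <- random_dna(35)
    expect_equal(melting_temperature(s), oracle_tm(s), tolerance = 0.1 / 80)
  }
  # determinism and basic stability ordering
  s <- random_dna(30)
  expect_identical(melting_temperature(s), melting_temperature(s))
  expect_gt(melting_temperature(paste0(strrep("G", 20), strrep("C", 15))),
            melting_temperature(paste0(strrep("A", 20), strrep("T", 15))))
  expect_error(melting_temperature("A"), class = "spotcode_input_error")
  expect_error(melting_temperature("ACGTN"), class = "spotcode_input_error")
})

test_that("Tm is monotone non-decreasing in GC fraction at fixed length", {
  set.seed(77)
  tms <- sapply(0:20, function(gc) {
    s <- paste(sample(c(rep(c("G", "C"), length.out = gc),
                        rep(c("A", "T"), length.out = 20 - gc))), collapse = "")
    melting_temperature(s)
  })
  # average trend over replicates: compare GC-poor vs GC-rich halves
  expect_true(mean(tms[1:8]) < mean(tms[14:21]))
})

test_that("probe validation enforces the 35+30=65 architecture and rules", {
  cs <- design_constraints()
  set.seed(5)
  # compliant probe: moderate-GC alternating blocks, no long runs
  target <- paste(rep("ACGTGCA", 5), collapse = "")
  readout <- paste(rep("TGCACG", 5), collapse = "")
  r <- validate_probe(target, readout, cs)
  expect_true(r$pass)
  expect_equal(r$full_len, 65)
  expect_equal(r$target_len + r$readout_len, 65)

  # run of 7 fails with a homopolymer reason
  bad <- paste0("AAAAAAA", substr(target, 8, 35))
  r7 <- validate_probe(bad, readout, cs)
  expect_false(r7$pass)
  expect_true(any(grepl("homopolymer", r7$reasons)))

  # run of exactly 6 passes (boundary inclusive) when Tm is adequate
  six <- paste0("GGGGGG", "CACGTGCACGTGCACGTGCACGCACGTGC")
  expect_equal(nchar(six), 35)
  r6 <- validate_probe(six, readout, cs)
  expect_false(any(grepl("homopolymer", r6$reasons)))
  expect_true(r6$pass)

  # wrong lengths are reported
  short <- validate_probe(substr(target, 1, 20), readout, cs)
  expect_false(short$pass)
  expect_true(any(grepl("target length", short$reasons)))

  expect_error(validate_probe("ACGTX", readout, cs),
               class = "spotcode_input_error")
})

test_that("off-target and secondary screens honor their direction flags", {
  target <- paste(rep("ACGTGCA", 5), collapse = "")
  readout <- paste(rep("TGCACG", 5), collapse = "")
  # background containing the full reverse complement of the target
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(target)))
  bg <- paste0(random_dna(20), rc, random_dna(20))
  cs_up <- design_constraints(tm_offtarget_is_upper = TRUE,
                              tm_offtarget_threshold = 60)
  r <- validate_probe(target, readout, cs_up, background = bg)
  expect_false(r$pass)
  expect_true(any(grepl("off-target", r$reasons)))
  cs_down <- design_constraints(tm_offtarget_is_upper = FALSE,
                                tm_offtarget_threshold = 60)
  r2 <- validate_probe(target, readout, cs_down, background = bg)
  expect_false(any(grepl("off-target", r2$reasons)))
})

test_that("target screening equals brute-force window filtering", {
  cs <- design_constraints()
  # single compliant 35-mer -> exactly one window at [0, 35)
  one <- paste(rep("ACGTGCA", 5), collapse = "")
  w <- screen_targets(one, cs)
  expect_equal(nrow(w), 1)
  expect_equal(w$start, 0)
  expect_equal(w$end, 35)

  # poly-A: no windows, homopolymer rule
  expect_warning(w0 <- screen_targets(strrep("A", 30), cs), "shorter")
  expect_equal(nrow(w0), 0)
  expect_equal(nrow(screen_targets(strrep("A", 100), cs)), 0)

  # planted islands separated by homopolymer tracts: windows only inside
  island <- paste(rep("ACGTGCA", 10), collapse = "")   # 70 nt compliant
  seq200 <- paste0(island, strrep("T", 30), island, strrep("A", 30))
  w2 <- screen_targets(seq200, cs)
  brute <- Filter(function(st) {
    win <- substr(seq200, st + 1, st + 35)
    spotcode:::longest_homopolymer(win) <= 6 &&
      melting_temperature(win) >= cs$tm_proper_min
  }, 0:(nchar(seq200) - 35))
  expect_identical(w2$start, as.integer(unlist(brute)))

  # property: agreement with brute force on random 1-kb sequences
  set.seed(11)
  for (rep in 1:3) {
    s <- random_dna(1000)
    got <- screen_targets(s, cs)$start
    want <- Filter(function(st) {
      win <- substr(s, st + 1, st + 35)
      spotcode:::longest_homopolymer(win) <= 6 &&
        melting_temperature(win) >= cs$tm_proper_min
    }, 0:965)
    expect_identical(got, as.integer(unlist(want)))
  }
})

test_that("assembly stoichiometry follows the per-layer geometric series", {
  expect_equal(unname(assembly_stoichiometry(5, 2)), c(5, 15, 45))
  expect_equal(unname(assembly_stoichiometry(7, 0)), 7)
  expect_equal(unname(assembly_stoichiometry(2, 3, 2)), c(2, 4, 8, 16))
  expect_error(assembly_stoichiometry(0, 2), class = "spotcode_input_error")
})

test_that("monomer and fluorophore counts follow the branching tree", {
  u <- count_units(dendrimer_spec())
  expect_equal(u$monomers_per_layer, c(1, 3, 9))
  expect_equal(u$total_monomers, 13)
  expect_equal(u$total_fluorophores, 27)

  u0 <- count_units(dendrimer_spec(n_shells = 0, dyes_per_terminal = 5))
  expect_equal(u0$total_monomers, 1)
  expect_equal(u0$total_fluorophores, 5)

  # volumes ratio per layer equals monomer-count ratio per layer, k <= 5
  for (b in 2:4) {
    spec <- dendrimer_spec(branching = b, n_shells = 5,
                           sticky_end_pairs = list())
    vols <- assembly_stoichiometry(1, 5, b)
    expect_equal(unname(vols), count_units(spec)$monomers_per_layer)
  }
})

test_that("edge geometry converts base pairs to nanometres", {
  expect_equal(edge_geometry(17), 5.8)
  expect_equal(edge_geometry(0), 0)
  expect_equal(edge_geometry(10), 3.4)
})

test_that("sticky-end validation accepts layered complements and flags leaks", {
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  spec <- dendrimer_spec()
  t0 <- "ACGTTGCA"
  t1u <- "GGATCCTA"
  strands <- c("T0:up" = t0, "T1:down" = rc(t0),
               "T1:up" = t1u, "T2:down" = rc(t1u))
  ok <- validate_sticky_ends(spec, strands)
  expect_true(ok$pass)

  # a T0 overhang also complementary to a T2 overhang: cross-layer leak
  leaky <- c(strands, "T2:up" = rc(t0))
  bad <- validate_sticky_ends(spec, leaky)
  expect_false(bad$pass)
  expect_true("cross_layer_complement" %in% bad$violations$rule)

  # declared pair that is not complementary is reported
  broken <- strands
  broken[["T1:down"]] <- t0
  nb <- validate_sticky_ends(spec, broken)
  expect_true("declared_pair_not_complementary" %in% nb$violations$rule)

  expect_error(validate_sticky_ends(spec, c("T0:up" = "")),
               class = "spotcode_input_error")
  expect_error(validate_sticky_ends(spec, c(t0, rc(t0))),
               class = "spotcode_input_error")
})

test_that("annotated strand tables round-trip through FASTA", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 layer=T0 end=up", "ACGTTGCA",
               ">s2 layer=T1 end=down", "TGCAACGT"), fa)
  st <- read_strand_table(fa)
  expect_identical(names(st), c("T0:up", "T1:down"))
  expect_identical(unname(st), c("ACGTTGCA", "TGCAACGT"))
})
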