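# motif_grammar: pattern compiler, pattern scanner, composition scanner

test_that("compile_pattern parses the printed notation", {
  p <- compile_pattern("ΨKxE")
  expect_length(p$elements, 4L)
  expect_identical(vapply(p$elements, `[[`, character(1L), "kind"),
                   c("class", "fixed", "wild", "fixed"))
  expect_setequal(p$elements[[1L]]$allowed, residue_classes()$PSI)

  p2 <- compile_pattern("K(K/R)x(K/R)")
  expect_length(p2$elements, 4L)
  expect_identical(p2$elements[[2L]]$kind, "alt")
  expect_setequal(p2$elements[[2L]]$allowed, c("K", "R"))

  # canonical form round-trips and sorts alternations alphabetically
  expect_identical(render_pattern(compile_pattern("(E/D)(D/E)W")),
                   "(D/E)(D/E)W")
  expect_identical(render_pattern(compile_pattern(
    render_pattern(compile_pattern("NGYASPMS(T/S)GSYDPYSP")))),
    render_pattern(compile_pattern("NGYASPMS(T/S)GSYDPYSP")))
})

test_that("compile_pattern rejects malformed input with positions", {
  expect_error(compile_pattern("K(K/"), "alternation.*position 2",
               class = "ecr_input_error")
  expect_error(compile_pattern("ΨK9E"), "position 3",
               class = "ecr_input_error")
  expect_error(compile_pattern("K"), "fewer than 2",
               class = "ecr_input_error")
  expect_error(compile_pattern("(K/K)RRW"), class = "ecr_input_error")
})

test_that("scan_pattern finds all overlapping matches, 1-based", {
  sumo <- compile_pattern("ΨKxE")
  h <- scan_pattern("GLKSEG", sumo)
  expect_identical(h$start, 2L)
  expect_identical(h$end, 5L)
  expect_identical(h$match, "LKSE")
  expect_identical(nrow(scan_pattern("GAKSEG", sumo)), 0L)

  nls <- compile_pattern("K(K/R)x(K/R)")
  h2 <- scan_pattern("AKKRKA", nls)
  expect_identical(h2$start, 2L)
  expect_identical(h2$match, "KKRK")

  # overlapping matches are all reported
  h3 <- scan_pattern("KKKKKK", compile_pattern("KKx"))
  expect_identical(h3$start, 1:4)

  expect_error(scan_pattern("ALKZE", sumo), "non-canonical residue 'Z'",
               class = "ecr_input_error")
})

test_that("scan_pattern matches a regex oracle on random sequences", {
  withr::with_seed(7, {
    for (i in 1:60) {
      pat <- compile_pattern(random_pattern_source())
      seq <- random_seq(sample(10:200, 1L))
      got <- scan_pattern(seq, pat)$start
      expect_identical(got, oracle_scan(seq, pat),
                       info = sprintf("pattern %s", pat$source))
      # every reported hit substring re-matches the generating rule
      h <- scan_pattern(seq, pat)
      if (nrow(h)) {
        expect_true(all(h$start >= 1L & h$end <= nchar(seq)))
        expect_identical(h$match, substring(seq, h$start, h$end))
      }
    }
  })
})

test_that("scan_composition reproduces hand-count oracles", {
  dl <- class_members("ACIDIC", "BULKY")
  h <- scan_composition("DIGEVDLDFWDLDL", dl, window = 10,
                        min_fraction = 0.8)
  expect_identical(nrow(h), 1L)
  expect_identical(c(h$start, h$end), c(1L, 14L))
  expect_equal(h$score, 13 / 14)

  # S-rich on an instance of the printed consensus with x -> A: the
  # maximal qualifying run is positions 2..12 (the leading G fails the
  # first window), 8 of its 11 residues are class members
  sr <- class_members("ACIDIC", "NEUTRAL_POLAR")
  core <- compile_pattern("EV(T/S)SS")
  h2 <- scan_composition("GDEASAEVSSSS", sr, window = 8,
                         min_fraction = 0.6, core = core)
  expect_identical(nrow(h2), 1L)
  expect_identical(c(h2$start, h2$end), c(2L, 12L))
  expect_equal(h2$score, 8 / 11)
  expect_true(grepl("EVSSS", h2$match))

  expect_identical(
    nrow(scan_composition("GGGGGGGGGG", dl, window = 5,
                          min_fraction = 0.7)), 0L)
  # window longer than the sequence: empty result, not an error
  expect_identical(
    nrow(scan_composition("DED", dl, window = 10, min_fraction = 0.5)), 0L)
  expect_error(scan_composition("DED", dl, window = 3, min_fraction = 1.5),
               class = "ecr_config_error")
})

test_that("scan_composition equals the set-union oracle on random input", {
  sr <- class_members("ACIDIC", "NEUTRAL_POLAR")
  withr::with_seed(11, {
    for (i in 1:40) {
      seq <- random_seq(sample(15:120, 1L),
                        alphabet = c("D", "E", "S", "T", "G", "N", "L"))
      w <- sample(4:10, 1L)
      f <- stats::runif(1, 0.4, 0.9)
      got <- scan_composition(seq, sr, window = w, min_fraction = f)
      want <- oracle_composition(seq, sr, window = w, min_fraction = f)
      expect_identical(nrow(got), length(want))
      for (k in seq_along(want)) {
        expect_identical(got$start[k], want[[k]]$start)
        expect_identical(got$end[k], want[[k]]$end)
        expect_equal(got$score[k], want[[k]]$score)
      }
    }
  })
})

test_that("composition scores are in [0,1] and thresholds are monotone", {
  dl <- class_members("ACIDIC", "BULKY")
  withr::with_seed(3, {
    for (i in 1:30) {
      seq <- random_seq(80, alphabet = c("D", "E", "W", "L", "G", "S"))
      lo <- scan_composition(seq, dl, window = 8, min_fraction = 0.5)
      hi <- scan_composition(seq, dl, window = 8, min_fraction = 0.75)
      expect_true(all(lo$score >= 0 & lo$score <= 1))
      # every high-threshold hit lies inside some low-threshold hit
      if (nrow(hi)) {
        for (k in seq_len(nrow(hi))) {
          expect_true(any(lo$start <= hi$start[k] & lo$end >= hi$end[k]))
        }
      }
    }
  })
})

test_that("repeat scanning chains consecutive units", {
  dts <- compile_pattern("D(T/S)S")
  ex <- make_exemplar("A4", noise_rate = 0, seed = 1)
  r <- detect_microdomains(ex$sequence, "A")
  h <- r$hits[r$hits$motif_id == "DTS_REPEATS", ]
  expect_identical(nrow(h), 1L)
  expect_identical(c(h$start, h$end), c(1L, 9L))
})

test_that("catalog config round-trips and rejects unknowns", {
  cat_tab <- default_catalog()
  expect_s3_class(cat_tab, "ecr_catalog")
  expect_true(all(c("SUMO", "NLS", "DDW", "ABOX", "SRICH", "DLRICH",
                    "KRRW", "TXXPSIW", "SP") %in% names(cat_tab)))
  expect_length(cat_tab$ABOX$variants, 5L)
  expect_error(ecr_config(nonsense = 1), "unknown config key",
               class = "ecr_config_error")
  expect_identical(ecr_config(fusion_gap = 3L)$fusion_gap, 3L)
})
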