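# classifier: presence/absence decision tables for the 12 types

test_that("A decision table follows the published inventories", {
  # {DDW, ABOX} alone -> A3
  expect_identical(classify_a_region(
    fake_region("A", fake_hits(c("DDW", "ABOX"))))$label, "A3")
  # full scaffold -> A1
  expect_identical(classify_a_region(
    fake_region("A", fake_hits(c("SUMO", "NLS", "DDW", "ABOX"))))$label,
    "A1")
  # YRLN on top of the scaffold -> A5
  expect_identical(classify_a_region(
    fake_region("A", fake_hits(c("YRLN", "SUMO", "NLS", "DDW",
                                 "ABOX"))))$label, "A5")
  # D(T/S)S repeats take precedence over the N-terminal signatures
  expect_identical(classify_a_region(
    fake_region("A", fake_hits(c("DTS_REPEATS", "DLKHE", "SUMO", "NLS",
                                 "DDW", "ABOX"))))$label, "A4")
  # DLKHE/ΨAYRG -> A2 even with the full type-1 inventory
  expect_identical(classify_a_region(
    fake_region("A", fake_hits(c("DLKHE", "PSIAYRG", "SUMO", "NLS",
                                 "DDW", "ABOX"))))$label, "A2")
  # lepidopteran variant: A2 signatures without the NLS, with a note
  call <- classify_a_region(
    fake_region("A", fake_hits(c("DLKHE", "SUMO", "DDW", "ABOX"))))
  expect_identical(call$label, "A2")
  expect_match(call$notes, "Lepidoptera")
  # NLS variant satisfies the scaffold
  expect_identical(classify_a_region(
    fake_region("A", fake_hits(c("SUMO", "NLS_VARIANT", "DDW",
                                 "ABOX"))))$label, "A1")
  # nothing usable -> unclassified with missing motifs
  call2 <- classify_a_region(fake_region("A", fake_hits(c("SUMO"))))
  expect_identical(call2$label, "unclassified")
  expect_setequal(call2$missing_motifs, c("NLS", "DDW", "ABOX"))
  expect_error(classify_a_region(
    fake_region("B1", fake_hits("SRICH"))), class = "ecr_input_error")
})

test_that("Diptera taxon upgrades a scaffold-only call to A5", {
  region <- fake_region("A", fake_hits(c("SUMO", "NLS", "DDW", "ABOX")))
  call <- classify_a_region(region, taxon = "Diptera")
  expect_identical(call$label, "A5")
  expect_true(call$taxon_used)
  expect_match(call$notes, "Drosophila")
  # structure-only mode is unchanged
  expect_identical(classify_a_region(region)$label, "A1")
})

test_that("B1 decision table follows the published inventories", {
  expect_identical(classify_b1_region(
    fake_region("B1", fake_hits(c("KRRW", "SRICH", "SP", "DLRICH"))))$label,
    "B1-3")
  # TxxΨW with a wide S-rich/DL-rich gap -> B1-2
  h <- fake_hits(c("TXXPSIW", "SRICH", "SP", "DLRICH"),
                 starts = c(1L, 10L, 30L, 44L))
  expect_identical(classify_b1_region(fake_region("B1", h))$label, "B1-2")
  # fused (gap <= 5) -> B1-2'
  h2 <- fake_hits(c("TXXPSIW", "SRICH", "DLRICH"),
                  starts = c(1L, 10L, 16L))
  expect_identical(classify_b1_region(fake_region("B1", h2))$label, "B1-2'")
  # QVSSS core variant -> B1-2' regardless of gap
  h3 <- fake_hits(c("TXXPSIW", "SRICH", "SP", "DLRICH"),
                  starts = c(1L, 10L, 30L, 44L),
                  variants = c("canonical", "QVSSS", "canonical",
                               "canonical"))
  expect_identical(classify_b1_region(fake_region("B1", h3))$label, "B1-2'")
  # three core microdomains alone -> B1-1
  expect_identical(classify_b1_region(
    fake_region("B1", fake_hits(c("SRICH", "SP", "DLRICH"))))$label, "B1-1")
  call <- classify_b1_region(
    fake_region("B1", fake_hits(c("SRICH", "DLRICH"))))
  expect_identical(call$label, "B1-1")
  expect_match(call$notes, "heteropteran")
  expect_error(classify_b1_region(
    fake_region("A", fake_hits("SUMO"))), class = "ecr_input_error")
})

test_that("signature adjacency and extension separate B1-4 from B1-5", {
  mk <- function(prv_start) {
    prv_end <- prv_start + 11L
    hits <- data.frame(
      motif_id = c("PRVPVAGV", "KRRW", "SRICH", "SP", "DLRICH"),
      start = c(prv_start, prv_end + 1L, prv_end + 10L, prv_end + 25L,
                prv_end + 32L),
      end = c(prv_end, prv_end + 4L, prv_end + 20L, prv_end + 26L,
              prv_end + 45L),
      match = "X", score = 1.0, variant = "canonical",
      stringsAsFactors = FALSE)
    fake_region("B1", hits)
  }
  expect_identical(classify_b1_region(mk(1L))$label, "B1-4")
  expect_identical(classify_b1_region(mk(16L))$label, "B1-5")
})

test_that("modified-only DL-rich gives B1-6", {
  hits <- fake_hits(c("KRRW", "SRICH", "SP", "DLRICH"),
                    variants = c("canonical", "canonical", "canonical",
                                 "modified"))
  expect_identical(classify_b1_region(fake_region("B1", hits))$label,
                   "B1-6")
  # when the canonical composition rule also matched, B1-3 wins
  raw <- rbind(cbind(hits, passed_window = TRUE),
               cbind(fake_hits("DLRICH", starts = 61L), passed_window = TRUE))
  expect_identical(classify_b1_region(
    fake_region("B1", hits, raw = raw))$label, "B1-3")
})

test_that("classification is deterministic and total over random inventories", {
  labels <- c("A1", "A2", "A3", "A4", "A5", "unclassified")
  a_motifs <- c("DLKHE", "PSIAYRG", "DTS_REPEATS", "YRLN", "SUMO", "NLS",
                "NLS_VARIANT", "DDW", "ABOX")
  withr::with_seed(5, {
    for (i in 1:80) {
      inv <- sample(a_motifs, sample(0:6, 1L))
      region <- fake_region("A", fake_hits(inv))
      c1 <- classify_a_region(region)
      c2 <- classify_a_region(region)
      expect_identical(c1$label, c2$label)
      expect_true(c1$label %in% labels)
    }
    b_motifs <- c("KRRW", "TXXPSIW", "PRVPVAGV", "SRICH", "SP", "DLRICH")
    b_labels <- c("B1-1", "B1-2", "B1-2'", "B1-3", "B1-4", "B1-5", "B1-6",
                  "unclassified")
    for (i in 1:80) {
      inv <- sample(b_motifs, sample(0:5, 1L))
      region <- fake_region("B1", fake_hits(inv))
      expect_true(classify_b1_region(region)$label %in% b_labels)
    }
  })
})

test_that("type_inventory expands every label and rejects unknowns", {
  for (lab in names(ecr_templates())) {
    expect_true(length(type_inventory(lab)) >= 2L)
  }
  expect_setequal(type_inventory("B1-3"),
                  c("KRRW", "SRICH", "SP", "DLRICH"))
  expect_error(type_inventory("B1-9"), class = "ecr_input_error")
})
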