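# phylo_events: Fitch parsimony and gain/loss assignment

test_that("fitch_reconstruct reproduces small hand-checked cases", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  expect_identical(
    fitch_reconstruct(tr, c(a = 1, b = 1, c = 0, d = 0))$changes, 1L)
  expect_identical(
    fitch_reconstruct(tr, c(a = 1, b = 1, c = 1, d = 1))$changes, 0L)
  expect_identical(
    fitch_reconstruct(tr, c(a = 1, b = 0, c = 1, d = 0))$changes, 2L)
  # unknown tip states relax the reconstruction
  expect_identical(
    fitch_reconstruct(tr, c(a = 1, b = NA, c = 0, d = 0))$changes, 1L)
  expect_error(fitch_reconstruct(tr, c(a = 1, b = 1), strict = TRUE),
               "missing", class = "ecr_input_error")
  expect_error(fitch_reconstruct(tr, c(a = 1, b = NA, c = NA, d = NA)),
               class = "ecr_input_error")
  expect_error(fitch_reconstruct(ape::unroot(ape::rtree(5)),
                                 c(t1 = 1, t2 = 0, t3 = 1, t4 = 0, t5 = 1)),
               "rooted", class = "ecr_input_error")
})

test_that("Fitch equals exhaustive enumeration on 200 random cases", {
  withr::with_seed(42, {
    for (i in 1:200) {
      ntip <- sample(3:8, 1L)
      tr <- ape::rtree(ntip)
      states <- sample(c(0, 1, NA), ntip, replace = TRUE,
                       prob = c(0.45, 0.45, 0.1))
      names(states) <- tr$tip.label
      if (sum(!is.na(states)) < 2L) states[1:2] <- c(0, 1)
      fit <- fitch_reconstruct(tr, states)
      expect_identical(fit$changes, oracle_parsimony(tr, states),
                       info = sprintf("case %d", i))
    }
  })
})

test_that("gains + losses equals the Fitch count under every policy", {
  withr::with_seed(77, {
    for (i in 1:60) {
      ntip <- sample(4:8, 1L)
      tr <- ape::rtree(ntip)
      states <- stats::setNames(sample(0:1, ntip, replace = TRUE),
                                tr$tip.label)
      if (length(unique(states)) == 1L) states[1L] <- 1 - states[1L]
      fit <- fitch_reconstruct(tr, states)
      for (pol in c("absent", "present", "fitch")) {
        gl <- count_gain_loss(fit, root_state_policy = pol)
        expect_identical(gl$gains + gl$losses, as.integer(fit$changes))
      }
    }
  })
})

test_that("the holometabolan KRRW case gives one gain and no loss", {
  tr <- ape::read.tree(
    text = "(((Hymenoptera,Diptera),Hemiptera),Crustacea);")
  states <- c(Hymenoptera = 1, Diptera = 1, Hemiptera = 0, Crustacea = 0)
  gl <- count_gain_loss(fitch_reconstruct(tr, states))
  expect_identical(gl$gains, 1L)
  expect_identical(gl$losses, 0L)
  expect_identical(gl$root_state, 0L)
  expect_identical(gl$events$event, "gain")

  # all-present motif: no events, root present
  gl2 <- count_gain_loss(fitch_reconstruct(
    tr, c(Hymenoptera = 1, Diptera = 1, Hemiptera = 1, Crustacea = 1)))
  expect_identical(gl2$gains + gl2$losses, 0L)
  expect_identical(gl2$root_state, 1L)

  # 1,0,1,0 on ((a,b),(c,d)): two events under any policy
  tr2 <- ape::read.tree(text = "((a,b),(c,d));")
  st2 <- c(a = 1, b = 0, c = 1, d = 0)
  for (pol in c("absent", "present")) {
    gl3 <- count_gain_loss(fitch_reconstruct(tr2, st2),
                           root_state_policy = pol)
    expect_identical(gl3$gains + gl3$losses, 2L)
  }
})

test_that("bundled subgroup tree and state tables reproduce the models", {
  tr <- ecr_subgroup_tree()
  expect_s3_class(tr, "phylo")
  expect_true(ape::is.rooted(tr))
  b1 <- read_state_table(system.file("extdata", "b1_motif_states.tsv",
                                     package = "ecrmotifs"))
  # the (K/R)RRW motif: one gain with the holometabolans, never lost
  krrw <- stats::setNames(b1$KRRW, rownames(b1))
  gl <- count_gain_loss(fitch_reconstruct(tr, krrw))
  expect_identical(c(gl$gains, gl$losses), c(1L, 0L))
  # TxxΨW: gained in the neopteran ancestor, replaced (lost) in
  # holometabolans
  tx <- stats::setNames(b1$TXXPSIW, rownames(b1))
  glt <- count_gain_loss(fitch_reconstruct(tr, tx))
  expect_identical(c(glt$gains, glt$losses), c(1L, 1L))
  # the signature of types 4/5 is homoplastic (Hymenoptera + Mecoptera)
  prv <- stats::setNames(b1$PRVPVAGV, rownames(b1))
  expect_identical(fitch_reconstruct(tr, prv)$changes, 2L)

  # A-isoform states include unknowns and still reconstruct
  a <- read_state_table(system.file("extdata", "a_motif_states.tsv",
                                    package = "ecrmotifs"))
  yrln <- stats::setNames(a$YRLN, rownames(a))
  gla <- count_gain_loss(fitch_reconstruct(tr, yrln))
  expect_identical(c(gla$gains, gla$losses), c(1L, 0L))
})

test_that("states_from_types expands labels into presence vectors", {
  st <- states_from_types(c(Crustacea = "B1-1", Coleoptera = "B1-3",
                            Diptera = "B1-6"))
  expect_identical(st["Crustacea", "KRRW"], 0L)
  expect_identical(st["Coleoptera", "KRRW"], 1L)
  expect_identical(st["Diptera", "SRICH"], 1L)
})

test_that("Dollo mode counts losses inside a single-origin clade", {
  tr <- ape::read.tree(text = "((((a,b),c),d),e);")
  st <- c(a = 1, b = 0, c = 1, d = 0, e = 0)
  d <- dollo_count(tr, st)
  expect_identical(c(d$gains, d$losses), c(1L, 1L))
  expect_identical(dollo_count(tr, c(a = 0, b = 0, c = 0, d = 0,
                                     e = 0))$gains, 0L)
  # annotated newick export carries node states
  gl <- count_gain_loss(fitch_reconstruct(tr, st))
  nwk <- ape::write.tree(gl$tree)
  expect_match(nwk, "state[01]")
})
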