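test_that("normalization divides each position by its mean spot intensity", {
  # constant position -> all ones
  g <- toy_grid(row_scales = c(3, 1, 1, 5, 1, 1, 1, 1, 0.2))
  m <- normalize_spot_grid(g)
  expect_true(all(m$values == 1))
  # linear ramp within a position follows x / mean(x)
  prof <- matrix(1, 9, 22)
  prof[4, ] <- 1:22
  m2 <- normalize_spot_grid(toy_grid(profile = prof))
  expect_equal(unname(m2$values[4, ]), (1:22) / mean(1:22))
  # random grids match an independently coded divide-by-mean oracle
  for (seed in 1:5) {
    g <- random_grid(seed)
    m <- normalize_spot_grid(g)
    oracle <- t(apply(g$flank, 1, function(r) r / mean(r)))
    expect_equal(m$values, oracle, tolerance = 1e-12)
    expect_lt(max(abs(rowMeans(m$values) - 1)), 1e-9)
  }
})

test_that("normalization is invariant to global rescaling of the grid", {
  g <- random_grid(3)
  base <- normalize_spot_grid(g)$values
  for (c in c(0.01, 7, 1e4)) {
    g2 <- g
    g2$flank <- c * g$flank
    expect_equal(normalize_spot_grid(g2)$values, base, tolerance = 1e-12)
  }
  # normalizing already-normalized values is the identity
  g3 <- g
  g3$flank <- base
  expect_equal(normalize_spot_grid(g3)$values, base, tolerance = 1e-12)
})

test_that("an all-zero position is a degenerate-column error naming it", {
  g <- random_grid(1)
  g$flank["-2", ] <- 0
  expect_error(normalize_spot_grid(g), "-2")
})

test_that("replicate averaging is the element-wise unweighted mean", {
  m1 <- normalize_spot_grid(random_grid(1, "KA"))
  expect_equal(average_replicates(list(m1, m1))$values, m1$values)
  reps <- lapply(1:5, function(s) normalize_spot_grid(random_grid(s, "KA")))
  avg <- average_replicates(reps)
  oracle <- Reduce(`+`, lapply(reps, `[[`, "values")) / 5
  expect_equal(avg$values, oracle, tolerance = 1e-12)
  expect_equal(avg$n_replicates, 5L)
  # {0.5, 1.5} at one cell -> 1.0
  p1 <- matrix(1, 9, 22); p1[2, 5] <- 0.5; p1[2, -5] <- (22 - 0.5) / 21
  p2 <- matrix(1, 9, 22); p2[2, 5] <- 1.5; p2[2, -5] <- (22 - 1.5) / 21
  a <- average_replicates(list(normalize_spot_grid(toy_grid(profile = p1)),
                               normalize_spot_grid(toy_grid(profile = p2))))
  expect_equal(unname(a$values[2, 5]), 1.0)
  # mismatched kinases refuse to average
  mb <- normalize_spot_grid(random_grid(2, "KB"))
  expect_error(average_replicates(list(m1, mb)), "mix")
  expect_warning(average_replicates(list(m1)), "n >= 2")
})

test_that("capping truncates acceptor-like residues at 1, honoring exceptions", {
  vals <- matrix(1, 9, 22)
  dimnames(vals) <- list(sprintf("%+d", OPLS_POSITIONS), OPLS_RESIDUES)
  vals["-2", "S"] <- 1.7
  vals["+1", "T"] <- 0.6
  vals["+3", "R"] <- 2.5   # not an acceptor-like residue in the ST library
  m <- motif_matrix("K", vals, stage = "averaged", n_replicates = 2L)
  cap <- cap_acceptor_like_residues(m)
  expect_equal(unname(cap$values["-2", "S"]), 1.0)
  expect_equal(unname(cap$values["+1", "T"]), 0.6)
  expect_equal(unname(cap$values["+3", "R"]), 2.5)
  expect_equal(nrow(cap$capped_cells), 1L)
  expect_equal(cap$capped_cells$original, 1.7)

  # Y library: fixed Tyr capped, except cells listed as exceptions
  yv <- matrix(1, 9, 22)
  dimnames(yv) <- list(sprintf("%+d", OPLS_POSITIONS), OPLS_RESIDUES)
  yv["+1", "Y"] <- 2.3
  yv["-3", "Y"] <- 1.9
  ym <- motif_matrix("NEK10", yv, stage = "averaged", library = "Y",
                     n_replicates = 2L)
  ycap <- cap_acceptor_like_residues(
    ym, exceptions = data.frame(position = 1, residue = "Y"))
  expect_equal(unname(ycap$values["+1", "Y"]), 2.3)  # retained
  expect_equal(unname(ycap$values["-3", "Y"]), 1.0)
  expect_warning(
    cap_acceptor_like_residues(ym, exceptions = data.frame(position = 1,
                                                           residue = "R")),
    "non-cappable")

  # no cell above 1 -> no-op; capping a second time changes nothing
  flat <- motif_matrix("K", matrix(0.8, 9, 22,
                                   dimnames = dimnames(vals)),
                       stage = "averaged", n_replicates = 2L)
  expect_equal(cap_acceptor_like_residues(flat)$values, flat$values)
  recap <- cap$values
  m2 <- motif_matrix("K", recap, stage = "averaged", n_replicates = 2L)
  expect_equal(cap_acceptor_like_residues(m2)$values, cap$values)
})

test_that("log2 transform maps 1 to 0 and floors nonpositive values", {
  vals <- matrix(1, 9, 22)
  dimnames(vals) <- list(sprintf("%+d", OPLS_POSITIONS), OPLS_RESIDUES)
  vals["-1", "A"] <- 2
  vals["-1", "C"] <- 0.5
  vals["-1", "D"] <- 0
  m <- as_capped(vals)
  lg <- log_transform(m)
  expect_equal(unname(lg$values["-1", "A"]), 1)
  expect_equal(unname(lg$values["-1", "C"]), -1)
  expect_equal(unname(lg$values["-1", "D"]), -6)  # floored at 2^-6
  expect_equal(unname(lg$values["+2", "G"]), 0)
  expect_error(log_transform(m, floor = 0), "floor")
  expect_error(log_transform(m, floor = -1), "floor")
  # rank order above the floor is preserved within each position
  g <- random_grid(9)
  capped <- cap_acceptor_like_residues(
    average_replicates(list(normalize_spot_grid(g),
                            normalize_spot_grid(random_grid(10)))))
  lg2 <- log_transform(capped)
  for (i in 1:9) {
    above <- capped$values[i, ] > 2^-6
    expect_equal(rank(capped$values[i, above]), rank(lg2$values[i, above]))
  }
})

test_that("acceptor preference mirrors mean normalization of the pools", {
  g <- toy_grid(acceptor = c(S = 10, T = 10, Y = 10))
  ap <- acceptor_preference(g)
  expect_equal(ap$normalized, c(S = 1, T = 1, Y = 1))
  expect_equal(ap$fraction, c(S = 1, T = 1, Y = 1) / 3)
  g2 <- toy_grid(acceptor = c(S = 30, T = 10))
  ap2 <- acceptor_preference(g2)
  expect_equal(ap2$normalized, c(S = 1.5, T = 0.5))
  # zero-noise simulation recovers the true acceptor preference
  tm <- make_true_motif("K", 2, 4, acceptor_pref = c(S = 0.7, T = 0.2,
                                                     Y = 0.1), seed = 6)
  res <- recover_motif(tm, 0, seed = 4)
  expect_equal(res$acceptor_pref$fraction,
               c(S = 0.7, T = 0.2, Y = 0.1), tolerance = 1e-12)
  expect_error(acceptor_preference(toy_grid(acceptor = c(S = 5))), "at least 2")
  expect_error(acceptor_preference(toy_grid(acceptor = c(S = 0, T = 0))),
               "zero")
})

test_that("the pipeline averages before capping", {
  # cell with replicate values {1.4, 0.8}: average-then-cap gives 1.0,
  # cap-then-average would give 0.9 -- the pipeline must return 1.0
  p1 <- matrix(1, 9, 22); p1[3, 16] <- 1.4; p1[3, -16] <- (22 - 1.4) / 21
  p2 <- matrix(1, 9, 22); p2[3, 16] <- 0.8; p2[3, -16] <- (22 - 0.8) / 21
  stopifnot(OPLS_RESIDUES[16] == "S")
  res <- run_motif_pipeline(list(toy_grid(profile = p1),
                                 toy_grid(profile = p2,
                                          replicate_id = "rep2")))
  expect_equal(unname(res$capped$values["-3", "S"]), 1.0)
})

test_that("the zero-noise pipeline round-trips the true motif", {
  tm <- make_true_motif("K", 4, 8, seed = 13)
  res <- recover_motif(tm, 0, n_rep = 2, seed = 2)
  truth_capped <- tm$values
  truth_capped[, c("S", "T")] <- pmin(truth_capped[, c("S", "T")], 1)
  expect_equal(res$capped$values, truth_capped, tolerance = 1e-12)
  expect_equal(res$log2$values, log2(pmax(truth_capped, 2^-6)),
               tolerance = 1e-12)
})

test_that("the packaged fixture reproduces its golden motif matrix", {
  ext <- system.file("extdata", package = "oplsmotif")
  grids <- lapply(
    file.path(ext, sprintf("synthetic_spotgrid_SYNKIN1_rep%d.tsv", 1:2)),
    read_spot_grid)
  res <- run_motif_pipeline(grids)
  golden <- read_motif_matrix(
    file.path(ext, "synthetic_motif_SYNKIN1_capped_golden.tsv"))
  expect_equal(res$capped$values, golden$values, tolerance = 1e-5)
  expect_equal(res$capped$kinase_id, golden$kinase_id)
})
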