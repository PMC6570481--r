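toy_pssm <- function(seed = 17) {
  withr::with_seed(seed, vals <- matrix(runif(198, 0.1, 2), 9, 22))
  build_scoring_matrix(as_capped(vals))
}

test_that("scoring matrices are positive with neutral fills", {
  vals <- matrix(runif(198, 0.5, 1.5), 9, 22)
  vals[2, 4] <- 0        # below-floor entry gets clamped
  vals[5, 8] <- NA       # missing cell becomes neutral
  pssm <- build_scoring_matrix(as_capped(vals))
  expect_true(all(pssm$entries > 0))
  expect_equal(unname(pssm$entries[2, 4]), 2^-6)
  expect_equal(unname(pssm$entries[5, 8]), 1)
  expect_true(all(apply(pssm$entries, 1, max) >= 1 - 1e-9))
  expect_equal(pssm$acceptor_set, c("S", "T"))
  expect_error(build_scoring_matrix(log_transform(as_capped(vals))),
               class = "opls_stage_error")
})

test_that("the column-argmax window scores exactly zero, others above", {
  pssm <- toy_pssm()
  opt <- optimal_window(pssm)
  expect_identical(score_window(pssm, opt), 0)
  # perturbing any single position off the optimum raises the score
  for (i in c(1, 5, 9)) {
    chars <- strsplit(opt, "")[[1]]
    worst <- names(which.min(pssm$entries[i, ]))
    chars[i] <- worst
    expect_gt(score_window(pssm, paste(chars, collapse = "")), 0)
  }
})

test_that("a flat matrix scores every window zero", {
  pssm <- build_scoring_matrix(as_capped(matrix(1, 9, 22)))
  withr::with_seed(3, wins <- replicate(20, paste(
    sample(OPLS_AA20, 9, replace = TRUE), collapse = "")))
  for (w in wins) expect_identical(score_window(pssm, w), 0)
})

test_that("exhaustive dipeptide enumeration matches the brute-force oracle", {
  # restrict scoring to 2 positions by padding the other 7
  pssm <- toy_pssm(23)
  grid2 <- expand.grid(a = OPLS_AA20, b = OPLS_AA20,
                       stringsAsFactors = FALSE)
  windows <- paste0(grid2$a, grid2$b, strrep("_", 7))
  got <- vapply(windows, score_window, 0, matrix = pssm)
  oracle <- vapply(windows, brute_score, 0, matrix = pssm)
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
  expect_equal(length(got), 400)
  expect_identical(order(got), order(oracle))
  # minimum 0 attained exactly once when the argmaxes are unique
  expect_equal(sum(got == 0), 1L)
  expect_equal(min(got), 0)
})

test_that("padding positions are excluded and the mean renormalized", {
  pssm <- toy_pssm(29)
  opt <- strsplit(optimal_window(pssm), "")[[1]]
  worst1 <- names(which.min(pssm$entries[1, ]))
  dev1 <- log2(max(pssm$entries[1, ])) - log2(pssm$entries[1, worst1])
  full <- paste(c(worst1, opt[-1]), collapse = "")
  trunc <- paste(c(worst1, opt[2:5], strrep("_", 4)), collapse = "")
  expect_equal(score_window(pssm, full), dev1 / 9, tolerance = 1e-12)
  expect_equal(score_window(pssm, trunc), dev1 / 5, tolerance = 1e-12)
  expect_error(score_window(pssm, strrep("_", 9)), "padding")
  expect_error(score_window(pssm, paste0("B", strrep("A", 8))),
               class = "opls_alphabet_error")
})

test_that("scores are invariant to per-column positive rescaling", {
  pssm <- toy_pssm(31)
  scaled <- pssm
  withr::with_seed(1, scales <- runif(9, 0.2, 5))
  scaled$entries <- pssm$entries * scales
  scaled$mod_entries <- pssm$mod_entries * scales
  withr::with_seed(2, wins <- replicate(25, paste(
    sample(OPLS_AA20, 9, replace = TRUE), collapse = "")))
  for (w in wins) {
    expect_equal(score_window(scaled, w), score_window(pssm, w),
                 tolerance = 1e-12)
  }
})

test_that("modified residues are scored from the pT/pY columns", {
  vals <- matrix(1, 9, 22)
  dimnames(vals) <- list(sprintf("%+d", OPLS_POSITIONS), OPLS_RESIDUES)
  vals["-1", "pY"] <- 4    # strong preference for prior -1 phospho-Tyr
  vals["-2", "pT"] <- 0.25 # prior -2 phospho-Thr disfavored
  pssm <- build_scoring_matrix(as_capped(vals))
  win_py <- paste0(strrep("A", 4), "y", strrep("A", 4))
  win_y <- paste0(strrep("A", 4), "Y", strrep("A", 4))
  expect_identical(score_window(pssm, win_py), 0)
  # an unmodified Tyr is scored against the standard-residue columns only
  expect_identical(score_window(pssm, win_y), 0)
  win_pt <- paste0(strrep("A", 3), "t", strrep("A", 5))
  expect_equal(score_window(pssm, win_pt), 2 / 9, tolerance = 1e-12)
})

test_that("site filtering applies acceptor gating, class filter and dedupe", {
  pssm <- toy_pssm()
  sites <- data.frame(
    protein_id = c("P1", "P1", "P2", "P3", "P4", "P5", "P6", "P7", "P8",
                   "P1"),
    position = c(10, 10, 20, 30, 40, 50, 60, 70, 80, 10),
    acceptor = c("S", "S", "T", "Y", "S", "T", "S", "S", "T", "S"),
    window = strrep("A", 9), stringsAsFactors = FALSE)
  kept <- filter_sites(sites, pssm)
  # 10 sites, 2 duplicate keys removed, 1 Tyr site removed -> 7 survivors
  expect_equal(nrow(kept), 7)
  expect_true(all(kept$acceptor %in% c("S", "T")))
  sites$class <- c("I", "I", "II", "I", "I", "I", "I", "I", "I", "I")
  kept2 <- filter_sites(sites, pssm)
  expect_false(any(kept2$protein_id == "P2"))
})

test_that("percentile selection takes the ceiling count with inclusive ties", {
  scores <- data.frame(protein_id = sprintf("P%03d", 1:100),
                       position = 1:100, acceptor = "S",
                       window = strrep("A", 9),
                       score = (1:100) / 10)
  sel <- percentile_select(scores, 0.10)
  expect_equal(nrow(sel), 10)
  expect_equal(attr(sel, "nominal_n"), 10)
  expect_equal(nrow(percentile_select(scores, 1.0)), 100)
  # 3-way tie straddling the 20% cutoff of 10 scores
  tied <- data.frame(protein_id = sprintf("Q%d", 1:10), position = 1:10,
                     acceptor = "S", window = strrep("A", 9),
                     score = c(0.1, 0.5, 0.5, 0.5, 1, 2, 3, 4, 5, 6))
  sel2 <- percentile_select(tied, 0.20)
  expect_equal(attr(sel2, "nominal_n"), 2)
  expect_equal(nrow(sel2), 4)  # all three tied at the cutoff included
  expect_error(percentile_select(scores, 0), "fraction")
  expect_error(percentile_select(scores, 1.2), "fraction")
})

test_that("percentile selection is monotone in the fraction", {
  withr::with_seed(41, {
    scores <- data.frame(protein_id = sprintf("P%03d", 1:80),
                         position = 1:80, acceptor = "S",
                         window = strrep("A", 9),
                         score = round(runif(80), 2))  # includes ties
  })
  keys <- function(s) paste(s$protein_id, s$position)
  prev <- character(0)
  for (f in c(0.05, 0.1, 0.25, 0.5, 1)) {
    cur <- keys(percentile_select(scores, f))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("overlap analysis partitions the union exactly", {
  sets <- list(A = sprintf("s%d", 1:7), B = sprintf("s%d", 1:7),
               C = sprintf("s%d", 1:7), D = sprintf("s%d", 1:7))
  ov <- overlap_analysis(sets)
  expect_equal(unname(ov$counts[["A&B&C&D"]]), 7)
  expect_equal(sum(ov$counts), 7)
  disjoint <- list(A = c("a1", "a2"), B = c("b1"), C = c("c1", "c2", "c3"))
  ov2 <- overlap_analysis(disjoint)
  expect_equal(sort(names(ov2$counts)), c("A", "B", "C"))
  expect_equal(sum(ov2$counts), ov2$n_union)
  # random sets vs a per-element membership-pattern oracle
  withr::with_seed(19, {
    universe <- sprintf("e%02d", 1:40)
    sets3 <- lapply(1:3, function(i) sample(universe, 25))
  })
  names(sets3) <- c("X", "Y", "Z")
  ov3 <- overlap_analysis(sets3, reference = "X")
  oracle <- table(vapply(Reduce(union, sets3), function(e) {
    paste(names(sets3)[vapply(sets3, function(s) e %in% s, TRUE)],
          collapse = "&")
  }, ""))
  expect_equal(sum(ov3$counts), length(Reduce(union, sets3)))
  for (nm in names(oracle)) {
    expect_equal(unname(ov3$counts[[nm]]), unname(as.numeric(oracle[[nm]])))
  }
  expect_equal(ov3$reference_shared_fraction,
               mean(sets3$X %in% union(sets3$Y, sets3$Z)))
  expect_error(overlap_analysis(sets["A"]), "2 to 6")
})

test_that("score correlation requires aligned keys and matches cor()", {
  pssm_a <- toy_pssm(51)
  pssm_b <- toy_pssm(52)
  db <- simulate_site_database(site_database_spec(60, 0), list(), seed = 5)
  sa <- score_sites(pssm_a, db)
  sb <- score_sites(pssm_b, db)
  res <- score_correlation(sa, sb)
  expect_equal(res$r, pearson_oracle(sa$score, sb$score), tolerance = 1e-12)
  expect_equal(score_correlation(sa, sa)$r, 1)
  expect_error(score_correlation(sa, sb[-1, ]), "site keys")
  # same true motif, independent noise -> higher r than unrelated motifs
  tm <- make_true_motif("T1", 4, 8, seed = 61)
  p1 <- build_scoring_matrix(recover_motif(tm, 0.1, seed = 1)$capped)
  p2 <- build_scoring_matrix(recover_motif(tm, 0.1, seed = 2)$capped)
  other <- make_true_motif("T2", 4, 8, seed = 77)
  p3 <- build_scoring_matrix(recover_motif(other, 0.1, seed = 3)$capped)
  r_same <- score_correlation(score_sites(p1, db), score_sites(p2, db))$r
  r_diff <- score_correlation(score_sites(p1, db), score_sites(p3, db))$r
  expect_gt(r_same, r_diff)
})

test_that("site percentile ranks are fractions with low = good", {
  pssm <- toy_pssm()
  db <- simulate_site_database(site_database_spec(50, 0), list(), seed = 9)
  sc <- score_sites(pssm, db)
  expect_true(all(sc$percentile_rank > 0 & sc$percentile_rank <= 1))
  expect_equal(sc$percentile_rank[which.min(sc$score)],
               min(sc$percentile_rank))
  expect_equal(max(sc$percentile_rank), 1)
})
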