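test_that("stability statistics match their closed forms", {
  vals <- rbind(gA = c(2, 2, 1, 3), gB = c(0, 0, 1, 3), gC = c(1, 3, 0, 0))
  fx <- tiny_lognorm(vals, c("A", "A", "B", "B"))
  s <- stability_stats(fx$matrix, fx$annotation, min_cells = 1)
  expect_equal(s$nz["gA", "A"], 1)
  expect_equal(s$cv["gA", "A"], 0)            # constant expression
  expect_equal(s$nz["gB", "A"], 0)
  expect_equal(s$cv["gB", "A"], Inf)          # silent gene
  expect_equal(s$nz["gC", "A"], 1)
  expect_equal(s$cv["gC", "A"], 1 / 2)        # sd = 1 (population), mean = 2
  expect_equal(s$n_cells, c(A = 2L, B = 2L))
})

test_that("cell types below min_cells are dropped, K < 2 errors", {
  vals <- matrix(1, 3, 5, dimnames = list(paste0("g", 1:3), NULL))
  fx <- tiny_lognorm(vals, c("A", "A", "A", "B", "C"))
  s <- stability_stats(fx$matrix, fx$annotation, min_cells = 1)
  expect_setequal(colnames(s$nz), c("A", "B", "C"))
  expect_error(stability_stats(fx$matrix, fx$annotation, min_cells = 2),
               "fewer than 2")
})

test_that("the worked three-gene example yields (+0.5, -0.5, 0)", {
  fx <- worked_example()
  sc <- identity_scores(stability_stats(fx$matrix, fx$annotation,
                                        min_cells = 1))
  expect_equal(sc$scores["g1", ], c(A = 0.5, B = -0.5))
  expect_equal(sc$scores["g2", ], c(A = -0.5, B = 0.5))
  expect_equal(sc$scores["g3", ], c(A = 0, B = 0))
})

test_that("identity scores obey their exact invariants", {
  set.seed(10)
  for (i in 1:25) {
    s <- random_stability(sample(3:10, 1), sample(2:4, 1))
    sc <- identity_scores(s)$scores
    # per-gene sum across types is zero
    expect_lt(max(abs(rowSums(sc))), 1e-9)
    expect_lt(max(abs(sc)), 1)
    if (ncol(sc) == 2)
      expect_equal(sc[, 1], -sc[, 2])         # K = 2 antisymmetry
  }
  # identical distributions across types give all-zero scores
  nz <- matrix(rep(runif(6), 3), 6, 3)
  cv <- matrix(rep(rexp(6), 3), 6, 3)
  dimnames(nz) <- dimnames(cv) <- list(paste0("g", 1:6), c("A", "B", "C"))
  s <- structure(list(nz = nz, cv = cv), class = "stability_stats")
  expect_equal(max(abs(identity_scores(s)$scores)), 0)
})

test_that("identity scores match the brute-force pairwise-rank oracle", {
  set.seed(11)
  for (i in 1:40) {
    s <- random_stability(sample(3:10, 1), sample(2:4, 1))
    expect_equal(identity_scores(s)$scores, brute_identity_scores(s),
                 tolerance = 1e-12)
  }
})

test_that("scores are invariant to permuting cells within a type", {
  set.seed(12)
  vals <- matrix(rpois(300, 2), 15, 20,
                 dimnames = list(paste0("g", 1:15), NULL))
  types <- rep(c("A", "B"), each = 10)
  fx <- tiny_lognorm(vals, types)
  sc1 <- identity_scores(stability_stats(fx$matrix, fx$annotation,
                                         min_cells = 1))$scores
  perm <- c(sample(1:10), sample(11:20))
  fx2 <- tiny_lognorm(vals[, perm], types[perm])
  sc2 <- identity_scores(stability_stats(fx2$matrix, fx2$annotation,
                                         min_cells = 1))$scores
  expect_equal(sc1, sc2)
})

test_that("planted exclusive markers take the row maximum of their type", {
  tis <- small_tissue()
  sc <- batch_identity_scores(tis, min_cells = 10)[[1]]$scores
  tm <- tis$truth$markers
  hits <- vapply(seq_len(nrow(tm)), function(i) {
    row <- sc[tm$gene[i], ]
    names(which.max(row)) == tm$cell_type[i]
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("batch averaging follows the divisor rule and commutes", {
  g <- paste0("g", 1:4)
  a <- matrix(runif(8), 4, 2, dimnames = list(g, c("A", "B")))
  expect_equal(average_scores(list(a)), a)
  expect_equal(max(abs(average_scores(list(a, -a)))), 0)
  b <- matrix(runif(4), 4, 1, dimnames = list(g, "C"))
  avg <- average_scores(list(a, b))
  expect_equal(avg[, "C"], b[, "C"])       # type present in 1 of 2 batches
  expect_equal(avg[, "A"], a[, "A"])
  expect_equal(average_scores(list(a, b)), average_scores(list(b, a)))
  rownames(b) <- paste0("x", 1:4)
  expect_error(average_scores(list(a, b)), "empty intersection")
})

test_that("reference building pools proportions and splits fetal ages", {
  set.seed(13)
  mk <- function(nA, nB, batch, age = NA_real_,
                 source = "tissue_mature") {
    vals <- matrix(rpois(30 * (nA + nB), 2) + 1, 30, nA + nB,
                   dimnames = list(paste0("g", 1:30), NULL))
    vals[1:5, seq_len(nA)] <- vals[1:5, seq_len(nA)] + 5
    tiny_lognorm(vals, c(rep("A", nA), rep("B", nB)), batch = batch,
                 source = source, age_dpc = age)
  }
  ref <- build_reference(list(mk(60, 40, "b1"), mk(40, 60, "b2")),
                         group = "mature", min_cells = 10)
  expect_equal(unname(ref$proportions[c("A", "B")]), c(0.5, 0.5))
  expect_equal(sum(ref$proportions), 1)
  # fetal split at the default 100 dpc: {59, 82} early, {125} late
  fet <- list(mk(50, 50, "f1", 59, "tissue_fetal"),
              mk(50, 50, "f2", 82, "tissue_fetal"),
              mk(50, 50, "f3", 125, "tissue_fetal"))
  early <- build_reference(fet, group = "fetal_early", min_cells = 10)
  late <- build_reference(fet, group = "fetal_late", min_cells = 10)
  expect_equal(length(early$age_profiles), 2)
  expect_equal(length(late$age_profiles), 1)
  expect_equal(vapply(early$age_profiles, `[[`, numeric(1), "age_dpc"),
               c(59, 82))
  # organoid cells cannot enter a tissue reference
  org <- mk(50, 50, "o1")
  org$annotation$source <- "organoid"
  expect_error(build_reference(list(org), group = "mature"), "requires")
})

test_that("annotation confidence separates correct from planted-wrong labels", {
  set.seed(14)
  n <- 100
  mkcells <- function(mu) pmax(matrix(rnorm(20 * n, rep(mu, n), 0.3), 20, n), 0)
  muA <- c(rep(3, 10), rep(0.2, 10)); muB <- rev(muA)
  vals <- cbind(mkcells(muA), mkcells(muB))
  rownames(vals) <- paste0("g", 1:20)
  types <- rep(c("A", "B"), each = n)
  fx <- tiny_lognorm(vals, types)
  conf <- annotation_confidence(fx$matrix, fx$annotation, n_rounds = 25,
                                n_pcs = 5, seed = 1)
  expect_true(all(conf$probability >= 0 & conf$probability <= 1))
  expect_gte(mean(conf$probability), 0.95)
  expect_true(all(conf$band[conf$probability > 0.9] == "very_high"))
  # swap 10% of labels: swapped cells get lower confidence
  swap <- sample(2 * n, 0.1 * 2 * n)
  types2 <- types
  types2[swap] <- ifelse(types[swap] == "A", "B", "A")
  fx2 <- tiny_lognorm(vals, types2)
  conf2 <- suppressWarnings(
    annotation_confidence(fx2$matrix, fx2$annotation, n_rounds = 25,
                          n_pcs = 5, seed = 1))
  expect_lt(mean(conf2$probability[swap]), mean(conf2$probability[-swap]))
  expect_error(annotation_confidence(fx$matrix, fx$annotation, n_rounds = 0),
               "n_rounds")
})

test_that("cell types with fewer than 3 cells get NA confidence", {
  set.seed(15)
  vals <- matrix(rpois(10 * 43, 3), 10, 43,
                 dimnames = list(paste0("g", 1:10), NULL))
  fx <- tiny_lognorm(vals, c(rep("A", 20), rep("B", 21), "C", "C"))
  conf <- suppressWarnings(
    annotation_confidence(fx$matrix, fx$annotation, n_rounds = 10, seed = 1))
  expect_true(all(is.na(conf$probability[42:43])))
  expect_true(all(!is.na(conf$probability[1:41])))
})

test_that("confidence filtering uses a strict threshold", {
  ann <- cell_annotation(data.frame(
    cell_id = paste0("c", 1:3), cell_type = "rod", dataset = "d",
    batch = "b", source = "tissue_mature"))
  conf <- data.frame(cell_id = paste0("c", 1:3),
                     probability = c(0.95, 0.9, 0.2))
  suppressMessages(kept <- filter_by_confidence(ann, conf, threshold = 0.9))
  expect_equal(kept$cell_id, "c1")           # 0.9 itself is excluded
  suppressMessages(all_kept <- filter_by_confidence(ann, conf, threshold = 0))
  expect_equal(nrow(all_kept), 3)
  conf$probability <- NA_real_
  expect_warning(none <- filter_by_confidence(ann, conf), "no cells")
  expect_equal(nrow(none), 0)
})
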