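test_that("cell-identity metric is exact on self and negated references", {
  set.seed(50)
  sc <- matrix(rnorm(60), 20, 3,
               dimnames = list(paste0("g", 1:20), c("A", "B", "C")))
  self <- metric_cell_identity(sc, sc)
  expect_equal(unname(self$per_type), rep(1, 3))
  expect_equal(self$mean, 1)
  neg <- metric_cell_identity(sc, -sc)
  expect_equal(unname(neg$per_type), rep(-1, 3))
  expect_warning(nosh <- metric_cell_identity(
    sc, matrix(1, 20, 1, dimnames = list(paste0("g", 1:20), "Z"))),
    "no shared")
  expect_true(is.na(nosh$mean))
})

test_that("identity metric decreases with additive reference noise", {
  set.seed(51)
  sc <- matrix(rnorm(400), 100, 4,
               dimnames = list(paste0("g", 1:100), c("A", "B", "C", "D")))
  ms <- vapply(c(0.2, 0.6, 1.5), function(sigma) {
    metric_cell_identity(sc + matrix(rnorm(400, sd = sigma), 100, 4),
                         sc)$mean
  }, numeric(1))
  expect_true(all(diff(ms) < 0))
})

test_that("maturation metric signs organoids by their age position", {
  set.seed(52)
  g <- paste0("g", 1:60)
  base <- matrix(rnorm(120), 60, 2, dimnames = list(g, c("A", "B")))
  drift <- matrix(rnorm(120), 60, 2, dimnames = dimnames(base))
  profiles <- lapply(1:8, function(i)
    list(age_rank = i, scores = base + (i / 8) * drift +
           matrix(rnorm(120, sd = 0.05), 60, 2, dimnames = dimnames(base))))
  oldest <- base + drift
  youngest <- base + (1 / 8) * drift
  expect_gt(metric_maturation(oldest, profiles)$mean, 0)
  expect_lt(metric_maturation(youngest, profiles)$mean, 0)
  # profiles independent of age stay near zero
  null_profiles <- lapply(1:8, function(i)
    list(age_rank = i,
         scores = matrix(rnorm(120), 60, 2, dimnames = dimnames(base))))
  expect_lte(abs(metric_maturation(oldest, null_profiles)$mean), 0.3)
  # fewer than 4 profiles: type skipped
  expect_true(is.na(metric_maturation(oldest, profiles[1:3])$mean))
})

test_that("coverage counts types passing both thresholds", {
  mk_ann <- function(types) cell_annotation(data.frame(
    cell_id = paste0("c", seq_along(types)), cell_type = types,
    dataset = "d", batch = "b", source = "organoid"))
  all7 <- mk_ann(rep(cell_type_vocabulary()$canonical, each = 20))
  expect_equal(metric_coverage(all7), 1)
  six <- mk_ann(rep(setdiff(cell_type_vocabulary()$canonical, "RGC"),
                    each = 20))
  expect_equal(metric_coverage(six), 6 / 7)
  few <- mk_ann(c(rep("rod", 50), rep("cone", 3)))
  expect_equal(metric_coverage(few, min_cells = 10), 1 / 7)
})

test_that("proportion metric is one minus total variation distance", {
  mk_ann <- function(types) cell_annotation(data.frame(
    cell_id = paste0("c", seq_along(types)), cell_type = types,
    dataset = "d", batch = "b", source = "organoid"))
  ref <- c(A = 0.25, B = 0.25, C = 0.5)
  ann <- mk_ann(c(rep("A", 2), rep("B", 2)))    # p = (0.5, 0.5, 0)
  expect_equal(metric_proportion(ann, ref), 0.5)
  match_ann <- mk_ann(c("A", "B", "C", "C"))
  expect_equal(metric_proportion(match_ann, ref), 1)
  disjoint <- mk_ann(rep("Z", 4))
  expect_equal(metric_proportion(disjoint, ref), 0)
})

test_that("rejection classification applies similarity and margin rules", {
  set.seed(53)
  g <- paste0("g", 1:30)
  a <- abs(rnorm(30))
  b <- sample(a)            # same values permuted: equal sd, so the midpoint
  centroids <- matrix(c(a, b), 30, 2,   # correlates equally with both
                      dimnames = list(g, c("A", "B")))
  cells <- cbind(c1 = centroids[, "A"],
                 c2 = (centroids[, "A"] + centroids[, "B"]) / 2)
  m <- expression_matrix(Matrix::Matrix(cells, sparse = TRUE), genes = g,
                         cells = colnames(cells), layer = "lognorm")
  cls <- classify_with_rejection(m, centroids, s_min = 0.3, s_margin = 0.05)
  expect_equal(cls$label[1], "A")
  expect_equal(attr(cls, "similarity")["c1", "A"], 1)
  expect_equal(cls$label[2], "intermediate")   # equidistant, margin 0
  # pure noise is mostly unassigned
  noise <- matrix(abs(rnorm(30 * 50)), 30, 50,
                  dimnames = list(g, paste0("n", 1:50)))
  mn <- expression_matrix(Matrix::Matrix(noise, sparse = TRUE), genes = g,
                          cells = colnames(noise), layer = "lognorm")
  cln <- classify_with_rejection(mn, centroids, s_min = 0.5)
  expect_gte(mean(cln$label == "unassigned"), 0.9)
  expect_equal(metric_offtarget(cln) +
                 mean(!cln$label %in% c("intermediate", "unassigned")), 1)
})

test_that("off-target metric arithmetic is exact", {
  cls <- structure(data.frame(
    cell_id = paste0("c", 1:100),
    label = c(rep("rod", 90), rep("unassigned", 5), rep("intermediate", 5))),
    class = c("rejection_classification", "data.frame"))
  expect_equal(metric_offtarget(cls), 0.10)
  all_ok <- structure(data.frame(cell_id = "c1", label = "rod"),
                      class = c("rejection_classification", "data.frame"))
  expect_equal(metric_offtarget(all_ok), 0)
})

test_that("benchmark scales metrics, ranks deterministically and is order-invariant", {
  tis <- small_tissue()
  ref <- build_reference(split_batches(tis), group = "mature",
                         min_cells = 10)
  mk_unit <- function(noise, seed, proto) {
    o <- simulate_organoid(tis$truth, organoid_sim_config(
      identity_noise_sd = noise, n_cells = 700, protocol = proto,
      batch = proto, seed = seed))
    list(protocol = proto, matrix = o$matrix, annotation = o$annotation)
  }
  units <- list(mk_unit(0, 1, "clean"), mk_unit(0.4, 2, "noisy"),
                mk_unit(0.8, 3, "worst"))
  rep1 <- benchmark(units, refs = list(mature = ref), min_cells = 10)
  tab <- rep1$table
  expect_setequal(tab$rank, 1:3)
  # scaled columns attain 0 and 1 whenever the raw values differ
  for (cc in c("ci_mature", "coverage", "proportion")) {
    scaled <- tab[[paste0(cc, "_scaled")]]
    if (length(unique(tab[[cc]])) > 1) {
      expect_equal(min(scaled), 0)
      expect_equal(max(scaled), 1)
    } else {
      expect_true(all(scaled == 0.5))
    }
  }
  expect_equal(tab$rank[tab$protocol == "clean"], 1L)
  # unit order does not change the ranking
  rep2 <- benchmark(rev(units), refs = list(mature = ref), min_cells = 10)
  t2 <- rep2$table[match(tab$protocol, rep2$table$protocol), ]
  expect_equal(t2$rank, tab$rank)
  expect_equal(t2$combined, tab$combined, tolerance = 1e-12)
})

test_that("identical units tie on the combined score with deterministic ranks", {
  tis <- small_tissue()
  ref <- build_reference(split_batches(tis), group = "mature",
                         min_cells = 10)
  o <- simulate_organoid(tis$truth, organoid_sim_config(n_cells = 700,
                                                        seed = 4))
  u <- list(protocol = "same", matrix = o$matrix, annotation = o$annotation)
  rep <- benchmark(list(u, u), refs = list(mature = ref), min_cells = 10)
  expect_equal(rep$table$combined[1], rep$table$combined[2])
  expect_setequal(rep$table$rank, 1:2)
})
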