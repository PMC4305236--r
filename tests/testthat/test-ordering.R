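two_scaf_maps <- function(a_pos, b_pos, w = 1) {
  mk <- rbind(
    data.frame(scaffold = "a", pos = seq_along(a_pos) * 10L, map = "m",
               lg = "1", map_pos = a_pos, stringsAsFactors = FALSE),
    data.frame(scaffold = "b", pos = seq_along(b_pos) * 10L, map = "m",
               lg = "1", map_pos = b_pos, stringsAsFactors = FALSE))
  map_collection(mk, weights = c(m = w))
}

test_that("orientation score signs follow colinearity", {
  # LMS(a||b) = 4 vs LMS(a||-b) = 3 -> o = +1
  expect_equal(orientation_score("a", "b", two_scaf_maps(c(1, 2), c(3, 4))),
               1)
  # reversed second scaffold -> negative score
  expect_equal(orientation_score("a", "b", two_scaf_maps(c(1, 2), c(4, 3))),
               -1)
  # single markers: orientation undetermined
  expect_equal(orientation_score("a", "b", two_scaf_maps(1, 3)), 0)
  # no shared map
  mk <- rbind(
    data.frame(scaffold = "a", pos = 1L, map = "m1", lg = "1", map_pos = 1),
    data.frame(scaffold = "b", pos = 1L, map = "m2", lg = "1", map_pos = 1))
  expect_equal(orientation_score("a", "b", map_collection(mk)), 0)
  # weights scale the score
  expect_equal(orientation_score("a", "b",
                                 two_scaf_maps(c(1, 2), c(3, 4), w = 3)), 3)
})

test_that("eigenvector orientation recovers pairwise agreement", {
  M <- matrix(c(0, 1, 1, 0), 2L)
  expect_equal(orient_by_eigenvector(M), c(1L, 1L))
  M2 <- matrix(c(0, -1, -1, 0), 2L)
  expect_equal(orient_by_eigenvector(M2), c(1L, -1L))
  expect_equal(orient_by_eigenvector(matrix(0, 3L, 3L)), rep(0L, 3L))
})

test_that("eigenvector orientation recovers planted signs", {
  set.seed(31)
  for (rep in 1:20) {
    s <- sample(c(-1L, 1L), 5L, replace = TRUE)
    M <- outer(s, s)
    diag(M) <- 0
    got <- orient_by_eigenvector(M)
    expect_true(all(got == s) || all(got == -s))
    # secondary oracle: exhaustive sign search maximizing sum M[a,b] s_a s_b
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 5L)))
    obj <- apply(signs, 1L, function(v) sum(M * outer(v, v)))
    best <- signs[which.max(obj), ]
    expect_equal(abs(sum(got * best)), 5) # equal up to global flip
  }
})

test_that("pairwise distance is the weighted closest-marker gap", {
  expect_equal(pairwise_distance("a", "b",
                                 two_scaf_maps(c(1, 2), c(2.5, 9))), 0.5)
  expect_equal(pairwise_distance("a", "a",
                                 two_scaf_maps(c(1, 2), c(2.5, 9))), 0)
  # two maps, w = (2, 1), per-map minima (0.5, 1.0) -> 2*0.5 + 1*1 = 2
  mk <- rbind(
    data.frame(scaffold = c("a", "b"), pos = 1L, map = "m1", lg = "1",
               map_pos = c(1, 1.5), stringsAsFactors = FALSE),
    data.frame(scaffold = c("a", "b"), pos = 1L, map = "m2", lg = "1",
               map_pos = c(4, 5), stringsAsFactors = FALSE))
  mc <- map_collection(mk, weights = c(m1 = 2, m2 = 1))
  expect_equal(pairwise_distance("a", "b", mc), 2)
})

test_that("missing-map pairs get the span penalty, not zero", {
  mk <- rbind(
    data.frame(scaffold = c("a", "b"), pos = 1L, map = "m1", lg = "1",
               map_pos = c(1, 2), stringsAsFactors = FALSE),
    data.frame(scaffold = "a", pos = 2L, map = "m2", lg = "1",
               map_pos = 10, stringsAsFactors = FALSE),
    data.frame(scaffold = "c", pos = 1L, map = "m2", lg = "1",
               map_pos = 50, stringsAsFactors = FALSE))
  mc <- map_collection(mk)
  # b has no m2 markers: m2 contributes its span (50 - 10 = 40)
  expect_equal(pairwise_distance("a", "b", mc), 1 + 40)
  expect_equal(pairwise_distance("a", "b", mc, penalty = c(m2 = 7)), 1 + 7)
})

test_that("TSP heuristic solves lines and tiny instances near-optimally", {
  expect_equal(initial_order(matrix(0, 1L, 1L)), 1L)
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3L)
  ord <- initial_order(D)
  expect_true(all(ord == 1:3) || all(ord == 3:1))
  set.seed(32)
  worse <- 0L
  for (rep in 1:100) {
    n <- sample(4:7, 1L)
    D <- matrix(stats::runif(n * n), n)
    D <- (D + t(D)) / 2
    diag(D) <- 0
    got <- path_cost(D, initial_order(D))
    opt <- oracle_tsp_cost(D)
    expect_gte(got, opt - 1e-9)
    if (got > opt * 1.05 + 1e-9) worse <- worse + 1L
  }
  expect_equal(worse, 0L) # within 5% of the exhaustive optimum throughout
})

test_that("flip pass corrects a planted inversion and nothing else", {
  mc <- collinear_maps(3L, 3L)
  good <- scaffold_configuration("chr", paste0("s", 1:3), 1L)
  expect_equal(flip_pass(good, mc)$orientation, good$orientation)
  planted <- scaffold_configuration("chr", paste0("s", 1:3), c(1L, -1L, 1L))
  fixed <- flip_pass(planted, mc)
  expect_equal(fixed$orientation, c(1L, 1L, 1L))
  expect_gt(score_configuration(fixed, mc)$total,
            score_configuration(planted, mc)$total)
  # single-marker scaffolds (orientation 0) are never flipped
  mk <- data.frame(scaffold = c("s1", "s1", "x"), pos = c(1L, 5L, 1L),
                   map = "m1", lg = "1", map_pos = c(1, 2, 1.5),
                   stringsAsFactors = FALSE)
  cfg <- scaffold_configuration("chr", c("s1", "x"), c(1L, 0L))
  out <- flip_pass(cfg, map_collection(mk))
  expect_equal(out$orientation, c(1L, 0L))
})

test_that("GA refinement never loses the elite and is deterministic", {
  set.seed(33)
  for (rep in 1:8) {
    mc <- random_tiny_instance(n_scaf = 5L, n_maps = 2L)
    scafs <- paste0("s", 1:5)
    init <- scaffold_configuration("chr", sample(scafs),
                                   sample(c(-1L, 1L), 5L, TRUE))
    L0 <- score_configuration(init, mc)$total
    out <- ga_refine(init, mc, npop = 30L, ngen = 40L, seed = rep)
    expect_gte(score_configuration(out, mc)$total, L0)
    out2 <- ga_refine(init, mc, npop = 30L, ngen = 40L, seed = rep)
    expect_identical(out$scaffolds, out2$scaffolds)
    expect_identical(out$orientation, out2$orientation)
  }
  expect_error(ga_refine(scaffold_configuration("c", "a"), mc,
                         mutpb = 1.5), "probabilities")
})

test_that("GA keeps an already-optimal configuration at optimal L", {
  set.seed(34)
  for (rep in 1:5) {
    mc <- random_tiny_instance(n_scaf = 4L, n_maps = 2L)
    best <- best_configuration_bruteforce(paste0("s", 1:4), mc)
    L_best <- score_configuration(best, mc)$total
    out <- ga_refine(best, mc, npop = 30L, ngen = 30L, seed = rep)
    expect_equal(score_configuration(out, mc)$total, L_best)
  }
})

test_that("order_chromosome recovers a collinear layout exactly", {
  mc <- collinear_maps(5L, 3L)
  cfg <- order_chromosome(paste0("s", 5:1), mc, chrom = "1", seed = 9L,
                          npop = 40L, ngen = 60L)
  expect_equal(score_configuration(cfg, mc)$total, 15)
  # canonical polarity: the map realized increasing -> s1..s5 forward
  expect_equal(cfg$scaffolds, paste0("s", 1:5))
  expect_equal(cfg$orientation, rep(1L, 5L))
})

test_that("identical seeds give identical end-to-end configurations", {
  set.seed(35)
  mc <- random_tiny_instance(n_scaf = 6L, n_maps = 2L)
  a <- order_chromosome(paste0("s", 1:6), mc, seed = 4L, npop = 30L,
                        ngen = 40L)
  b <- order_chromosome(paste0("s", 1:6), mc, seed = 4L, npop = 30L,
                        ngen = 40L)
  expect_identical(a$scaffolds, b$scaffolds)
  expect_identical(a$orientation, b$orientation)
})
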