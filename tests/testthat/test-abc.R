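chainObserved <- function(nodes = c("A", "B", "C"), perturb = nodes[1]) {
  gt <- chainDGRN(nodes)
  simulateObserved(gt, perturbedNodes = perturb)$log2fc
}

test_that("candidate counts are orientations times conditions", {
  obs <- chainObserved()
  cand <- simulateCandidates(chainUGRN(), obs)
  expect_equal(nrow(cand$table), 4 * 3)
  expect_equal(cand$diagnostics$nTotal, 12)

  single <- undirectedGRN(edges = data.frame(from = "A", to = "B", sign = "+"))
  cand <- simulateCandidates(single, c(A = 1, B = 0.5))
  expect_equal(nrow(cand$table), 2 * 2)

  tri <- triangleUGRN()
  cand <- simulateCandidates(tri, c(A = 1, B = 0.5, C = 0.5),
                             acyclicOnly = TRUE)
  expect_equal(nrow(cand$table), 6 * 3)
  expect_equal(cand$diagnostics$nFilteredCyclic, 2 * 3)
})

test_that("each orientation appears in exactly |conditions| candidates (uniform prior)", {
  cand <- simulateCandidates(chainUGRN(), chainObserved())
  tally <- table(cand$table$orientation)
  expect_equal(unname(as.vector(tally)), rep(3, 4))
})

test_that("misaligned observed vectors are rejected", {
  expect_error(simulateCandidates(chainUGRN(), c(A = 1, B = 1)),
               class = "steadyABC_alignment_error")
  expect_error(simulateCandidates(chainUGRN(), c(1, 2, 3)),
               class = "steadyABC_alignment_error")
})

test_that("rejection applies the ceiling and tie rules", {
  fake <- function(distances) {
    g <- undirectedGRN(edges = data.frame(from = "A", to = "B", sign = "+"))
    structure(list(network = g,
                   table = data.frame(orientation = seq_along(distances) - 1,
                                      condition = 1L,
                                      distance = distances,
                                      converged = TRUE)),
              class = "steadyABC_candidates")
  }
  expect_equal(nrow(rejectCandidates(fake(c(1, 2, 3)), topFraction = 34)), 2)
  expect_equal(nrow(rejectCandidates(fake(c(1, 1, 3)), topFraction = 20)), 2)
  expect_equal(nrow(rejectCandidates(fake(c(1, 2, 3)),
                                     distanceThreshold = 2)), 2)
  # fraction mode always keeps at least one candidate
  expect_equal(nrow(rejectCandidates(fake(c(5, 6, 7)), topFraction = 0.001)), 1)
  expect_error(rejectCandidates(fake(1:3)), class = "steadyABC_usage_error")
  expect_error(rejectCandidates(fake(1:3), topFraction = 10,
                                distanceThreshold = 1),
               class = "steadyABC_usage_error")
  expect_error(rejectCandidates(fake(1:3), topFraction = 101),
               class = "steadyABC_usage_error")
})

test_that("link posteriors are acceptance proportions and sum to one with the reverse", {
  g <- chainUGRN(c("A", "B"))
  accepted <- data.frame(orientation = c(1L, 1L, 1L, 0L), condition = 1L,
                         distance = 0, converged = TRUE)
  p <- linkPosteriors(accepted, g)
  expect_equal(p$posterior, 0.75)
  acceptedAll <- data.frame(orientation = rep(1L, 4), condition = 1L,
                            distance = 0, converged = TRUE)
  expect_equal(linkPosteriors(acceptedAll, g)$posterior, 1)
})

test_that("a direction-symmetric observed vector gives posterior one half", {
  single <- undirectedGRN(edges = data.frame(from = "A", to = "B", sign = "+"))
  res <- runABC(single, c(A = 1, B = 1), topFraction = 50)
  expect_equal(linkPosteriors(res)$posterior, 0.5)
  resZero <- runABC(single, c(A = 0, B = 0), topFraction = 50)
  expect_equal(linkPosteriors(resZero)$posterior, 0.5)
})

test_that("zero-noise chain data recover the true link directions", {
  obs <- chainObserved()
  res <- runABC(chainUGRN(), obs)
  p <- linkPosteriors(res)
  expect_true(all(p$posterior > 0.5))
  # acceptance bookkeeping invariants
  expect_equal(res@acceptanceFraction,
               100 * nrow(acceptedCandidates(res)) / res@totalCandidates)
  expect_true(all(p$posterior >= 0 & p$posterior <= 1))
})

test_that("halving the acceptance fraction never flips a posterior across 0.5", {
  for (nodes in list(c("A", "B", "C"), c("A", "B", "C", "D"))) {
    obs <- chainObserved(nodes)
    g <- chainUGRN(nodes)
    prev <- NULL
    for (f in c(20, 10, 5, 2.5, 1.25)) {
      p <- linkPosteriors(runABC(g, obs, topFraction = f))$posterior
      if (!is.null(prev)) {
        crossed <- (prev > 0.5 & p < 0.5) | (prev < 0.5 & p > 0.5)
        expect_false(any(crossed))
      }
      prev <- p
    }
    # and at the sharpest cut every true direction is recovered
    expect_true(all(prev > 0.5))
  }
})

test_that("repeated runs are bit-identical (no RNG in the exhaustive path)", {
  obs <- chainObserved()
  r1 <- runABC(chainUGRN(), obs, topFraction = 25)
  r2 <- runABC(chainUGRN(), obs, topFraction = 25)
  expect_identical(acceptedCandidates(r1), acceptedCandidates(r2))
  expect_identical(linkPosteriors(r1), linkPosteriors(r2))
  expect_identical(r1@threshold, r2@threshold)
})

test_that("runABC agrees candidate-for-candidate with the naive loop oracle", {
  fixtures <- list(
    list(grn = chainUGRN(), obs = chainObserved(), top = 25),
    list(grn = chainUGRN(c("A", "B", "C"), c("+", "-")),
         obs = local({
           gt <- chainDGRN(c("A", "B", "C"), c("+", "-"))
           simulateObserved(gt, perturbedNodes = "A")$log2fc
         }), top = 25),
    list(grn = triangleUGRN(),
         obs = local({
           gt <- directedGRN(links = data.frame(from = c("A", "A", "B"),
                                                to = c("B", "C", "C"),
                                                sign = "+"))
           simulateObserved(gt, perturbedNodes = "A")$log2fc
         }), top = 10))
  for (fx in fixtures) {
    res <- runABC(fx$grn, fx$obs, topFraction = fx$top)
    oracle <- naiveABC(fx$grn, fx$obs, topFraction = fx$top)
    tab <- res@accepted
    expect_equal(sort(simulateCandidates(fx$grn, fx$obs)$table$distance),
                 oracle$distances, tolerance = 1e-6)
    expect_equal(nrow(tab), oracle$nAccepted)
    expect_equal(sort(tab$orientation + (tab$condition - 1) / 1000),
                 oracle$accepted, tolerance = 1e-9)
    expect_equal(res@threshold, oracle$threshold, tolerance = 1e-6)
    expect_equal(linkPosteriors(res)$posterior, unname(oracle$posterior),
                 tolerance = 1e-9)
  }
})

test_that("ABC results serialize with provenance and majority directions", {
  obs <- chainObserved()
  res <- runABC(chainUGRN(), obs, topFraction = 25)
  prefix <- file.path(tempdir(), "abc-out")
  paths <- writeABCResult(res, prefix, dot = TRUE)
  expect_true(all(file.exists(paths)))
  j <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(j$totalCandidates, 12)
  expect_equal(j$config$topFraction, 25)
  tsv <- read.delim(paste0(prefix, ".tsv"))
  expect_true(all(tsv$posterior >= 0.5))
  dot <- readLines(paste0(prefix, ".dot"))
  expect_match(dot[1], "digraph")
})
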