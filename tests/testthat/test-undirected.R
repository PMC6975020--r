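test_that("expression tables validate their input", {
  m <- matrix(1:6, 2, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  se <- expressionTable(m, conditions = c("a", "a", "b"))
  expect_s4_class(se, "SummarizedExperiment")
  expect_error(expressionTable(matrix(1:4, 2)), class = "steadyABC_data_error")
  m2 <- m; m2[1, 1] <- -1
  expect_error(expressionTable(m2), class = "steadyABC_data_error")
  expect_error(expressionTable(m[, 1, drop = FALSE]),
               class = "steadyABC_data_error")
})

test_that("Pearson correlation has unit diagonal and detects linear dependence", {
  set.seed(42)
  a <- runif(20)
  m <- rbind(A = a, B = 2 * a, C = -a + 5, D = runif(20))
  r <- pearsonCorrelationMatrix(m)
  expect_equal(unname(diag(r)), rep(1, 4))
  expect_equal(r["A", "B"], 1)
  expect_equal(r["A", "C"], -1)
  expect_true(abs(r["A", "D"]) < 1)
})

test_that("constant genes are excluded with a warning", {
  m <- rbind(A = c(1, 2, 3, 4), FLAT = c(2, 2, 2, 2), B = c(4, 3, 2, 1))
  expect_warning(r <- pearsonCorrelationMatrix(m), "FLAT")
  expect_equal(rownames(r), c("A", "B"))
})

test_that("partial correlation equals correlation for two genes", {
  set.seed(3)
  a <- runif(30); b <- a + rnorm(30, sd = 0.5)
  m <- rbind(A = a, B = b)
  r <- pearsonCorrelationMatrix(m)
  pc <- partialCorrelationMatrix(m)
  expect_equal(pc["A", "B"], r["A", "B"], tolerance = 1e-12)
})

test_that("partial correlation suppresses the indirect link of a noisy chain", {
  set.seed(1)
  n <- 200
  x <- rnorm(n)
  y <- x + rnorm(n, sd = 1e-3)
  z <- y + rnorm(n, sd = 1e-3)
  m <- rbind(X = x, Y = y, Z = z)
  r <- pearsonCorrelationMatrix(m)
  pc <- partialCorrelationMatrix(m)
  expect_gt(r["X", "Z"], 0.99)
  expect_lt(abs(pc["X", "Z"]), abs(r["X", "Z"]))
  expect_lt(abs(pc["X", "Z"]), 0.2)
})

test_that("independent genes have small partial correlations", {
  set.seed(1)
  m <- matrix(rnorm(5 * 500), nrow = 5,
              dimnames = list(sprintf("G%d", 1:5), NULL))
  pc <- partialCorrelationMatrix(m)
  off <- pc[upper.tri(pc)]
  expect_true(all(abs(off) < 0.2))
})

test_that("singular correlation matrices trigger logged shrinkage", {
  # 4 genes, 3 samples: rank-deficient correlation matrix
  set.seed(9)
  m <- matrix(rnorm(12), nrow = 4,
              dimnames = list(sprintf("G%d", 1:4), NULL))
  expect_message(pc <- partialCorrelationMatrix(m), "lambda")
  expect_gt(attr(pc, "shrinkage"), 0)
  expect_true(all(is.finite(pc)))
})

test_that("thresholding requires both correlation passes and carries signs", {
  genes <- c("A", "B", "C")
  eye <- diag(3); dimnames(eye) <- list(genes, genes)
  expect_equal(edgeCount(thresholdLinks(eye, eye)), 0)

  co <- eye; pc <- eye
  co["A", "B"] <- co["B", "A"] <- 0.995
  pc["A", "B"] <- pc["B", "A"] <- 0.995
  g <- thresholdLinks(co, pc)
  expect_equal(edgeTable(g),
               data.frame(from = "A", to = "B", sign = "+"))

  co["A", "B"] <- co["B", "A"] <- -0.999
  pc["A", "B"] <- pc["B", "A"] <- -0.999
  expect_equal(edgeTable(thresholdLinks(co, pc))$sign, "-")

  # both must pass: high correlation alone is not enough
  co["A", "C"] <- co["C", "A"] <- 0.999
  pc["A", "C"] <- pc["C", "A"] <- 0.5
  expect_equal(nrow(edgeTable(thresholdLinks(co, pc))), 1)
})

test_that("lowering the threshold never removes an edge", {
  set.seed(11)
  n <- 30
  x <- rnorm(n); m <- rbind(A = x, B = x + rnorm(n, sd = 0.05),
                            C = x + rnorm(n, sd = 0.3), D = rnorm(n))
  co <- pearsonCorrelationMatrix(m)
  pc <- partialCorrelationMatrix(m)
  prev <- character()
  for (thr in c(0.999, 0.99, 0.9, 0.7, 0.5)) {
    g <- thresholdLinks(co, pc, rThreshold = thr)
    cur <- with(edgeTable(g), paste(from, to))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("threshold output is independent of gene ordering", {
  set.seed(5)
  x <- rnorm(40)
  m <- rbind(A = x, B = x + rnorm(40, sd = 0.01), C = rnorm(40))
  co <- pearsonCorrelationMatrix(m); pc <- partialCorrelationMatrix(m)
  g1 <- thresholdLinks(co, pc, 0.9)
  perm <- c("C", "A", "B")
  g2 <- thresholdLinks(co[perm, perm], pc[perm, perm], 0.9)
  k1 <- with(edgeTable(g1), sort(paste(pmin(from, to), pmax(from, to))))
  k2 <- with(edgeTable(g2), sort(paste(pmin(from, to), pmax(from, to))))
  expect_equal(k1, k2)
})

test_that("standalone components are sorted and singletons dropped", {
  g <- undirectedGRN(
    nodes = c("A", "B", "C", "D", "E", "F", "LONER"),
    edges = data.frame(from = c("A", "B", "D"), to = c("B", "C", "E"),
                       sign = "+"))
  comps <- networkComponents(g)
  expect_length(comps, 2)
  expect_equal(nodeNames(comps[[1]]), c("A", "B", "C"))
  expect_equal(nodeNames(comps[[2]]), c("D", "E"))
  expect_length(networkComponents(undirectedGRN(nodes = c("A", "B"))), 0)
  one <- chainUGRN(sprintf("N%d", 1:5))
  expect_equal(nodeNames(networkComponents(one)[[1]]), nodeNames(one))
})

test_that("log2 fold changes compare condition means with explicit pseudocounts", {
  m <- matrix(c(2, 2, 8, 8,
                4, 4, 4, 4,
                0, 0, 1, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("up", "flat", "zero"),
                              sprintf("s%d", 1:4)))
  se <- expressionTable(m, conditions = c("a", "a", "b", "b"))
  expect_error(log2FoldChange(se, "a", "b"), class = "steadyABC_data_error")
  fc <- log2FoldChange(se, "a", "b", pseudocount = 1)
  expect_equal(unname(fc["zero"]), 1)  # log2((1+1)/(0+1))
  fcSub <- log2FoldChange(se[c("up", "flat"), ], "a", "b")
  expect_equal(unname(fcSub), c(2, 0))
  expect_error(log2FoldChange(se, "a", "nope"), class = "steadyABC_usage_error")
})

test_that("differential-expression prefilter keeps the pipeline shape", {
  m <- matrix(runif(12) + 0.1, nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:4)))
  se <- expressionTable(m)
  expect_equal(rownames(filterDifferential(se, genes = c("g1", "g3"))),
               c("g1", "g3"))
  pv <- c(g1 = 0.01, g2 = 0.5, g3 = 0.04)
  expect_equal(rownames(filterDifferential(se, pValues = pv)), c("g1", "g3"))
})

test_that("a Gaussian chain keeps direct links and prunes the indirect one", {
  set.seed(2)
  n <- 100
  x <- rnorm(n); y <- x + rnorm(n, sd = 0.02); z <- y + rnorm(n, sd = 0.02)
  m <- rbind(X = x, Y = y, Z = z)
  # adjacent partial correlations in a near-deterministic Gaussian chain
  # tend to 1/sqrt(2), so the demonstration threshold sits below that
  g <- thresholdLinks(pearsonCorrelationMatrix(m),
                      partialCorrelationMatrix(m), rThreshold = 0.6)
  keys <- with(edgeTable(g), paste(pmin(from, to), pmax(from, to)))
  expect_true("X Y" %in% keys)
  expect_true("Y Z" %in% keys)
  expect_false("X Z" %in% keys)
  # correlation alone would have added the indirect link
  expect_gt(abs(pearsonCorrelationMatrix(m)["X", "Z"]), 0.9)
})
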