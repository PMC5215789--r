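## helper: z-score rows of a raw matrix, quietly
zrows <- function(m) suppressWarnings(zscoreRows(m))

test_that("a planted shifted block is recovered across seeds", {
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  rowJ <- colJ <- numeric(10)
  for (s in 1:10) {
    set.seed(100 + s)
    m <- namedMatrix(100, 60)
    rows <- sprintf("g%03d", 1:20); cols <- sprintf("s%03d", 1:15)
    m[rows, cols] <- m[rows, cols] + 2
    bics <- discoverBiclusters(zrows(m))
    expect_gt(length(bics), 0)
    j <- vapply(bics, function(b) jacc(biclusterRows(b), rows), numeric(1))
    best <- bics[[which.max(j)]]
    rowJ[s] <- max(j)
    colJ[s] <- jacc(biclusterCols(best), cols)
  }
  expect_gte(mean(rowJ), 0.8)
  expect_gte(mean(colJ), 0.8)
})

test_that("two disjoint planted blocks come out without cross-contamination", {
  set.seed(31)
  m <- namedMatrix(100, 60)
  r1 <- sprintf("g%03d", 1:15);  c1 <- sprintf("s%03d", 1:12)
  r2 <- sprintf("g%03d", 40:55); c2 <- sprintf("s%03d", 30:45)
  m[r1, c1] <- m[r1, c1] + 2.5
  m[r2, c2] <- m[r2, c2] - 2.5   # repressed block, opposite sign
  bics <- discoverBiclusters(zrows(m))
  expect_gte(length(bics), 2)
  hits1 <- vapply(bics, function(b) length(intersect(biclusterRows(b), r1)),
                  numeric(1))
  hits2 <- vapply(bics, function(b) length(intersect(biclusterRows(b), r2)),
                  numeric(1))
  b1 <- bics[[which.max(hits1)]]; b2 <- bics[[which.max(hits2)]]
  expect_length(intersect(biclusterRows(b1), r2), 0)
  expect_length(intersect(biclusterRows(b2), r1), 0)
})

test_that("pure noise yields few biclusters and degenerate input none", {
  set.seed(32)
  bics <- discoverBiclusters(zrows(namedMatrix(120, 50)))
  expect_lte(length(bics), 3)
  expect_identical(discoverBiclusters(namedMatrix(1, 30)), list())
  expect_identical(discoverBiclusters(namedMatrix(30, 1)), list())
})

test_that("discovery is invariant to row/column permutation up to relabeling", {
  set.seed(33)
  m <- namedMatrix(80, 40)
  m[1:15, 1:12] <- m[1:15, 1:12] + 2.5
  z <- zrows(m)
  b1 <- discoverBiclusters(z)
  zp <- z[sample(nrow(z)), sample(ncol(z))]
  b2 <- discoverBiclusters(zp)
  key <- function(b) paste(paste(sort(biclusterRows(b)), collapse = ","),
                           paste(sort(biclusterCols(b)), collapse = ","))
  expect_setequal(vapply(b1, key, character(1)),
                  vapply(b2, key, character(1)))
})

test_that("a pluggable backend replaces the reference search", {
  stub <- function(z, minMrnas, overlapFactor)
    list(new("Bicluster", rows = rownames(z)[1:2], cols = colnames(z)[1:2],
             score = 1))
  out <- discoverBiclusters(namedMatrix(5, 5), backend = stub)
  expect_identical(biclusterRows(out[[1]]), c("g001", "g002"))
})

test_that("permutation test: exact degenerate case and reproducibility", {
  set.seed(34)
  m <- namedMatrix(30, 20)
  ## module of identical profiles: observed average is exactly 1 and no
  ## random module can exceed it
  prof <- rnorm(8)
  m[1:4, 1:8] <- matrix(prof, 4, 8, byrow = TRUE)
  b <- new("Bicluster", rows = rownames(m)[1:4], cols = colnames(m)[1:8],
           score = 0)
  res <- permutationTest(b, m, nPerm = 300, seed = 1)
  expect_equal(res$observed_avg, 1)
  expect_equal(res$p_value, 0)
  ## reproducible under the same seed, different under another
  res2 <- permutationTest(b, m, nPerm = 300, seed = 1)
  expect_identical(res$random_avgs, res2$random_avgs)
  res3 <- permutationTest(b, m, nPerm = 300, seed = 2)
  expect_false(identical(res$random_avgs, res3$random_avgs))
  ## single-gene module is an error
  b1 <- new("Bicluster", rows = rownames(m)[1], cols = colnames(m)[1:4],
            score = 0)
  expect_error(permutationTest(b1, m), "two genes")
})

test_that("permutation p approximates the exhaustive module enumeration", {
  ## 5 x 4 toy: enumerate every possible 2-gene x 3-sample module exactly
  set.seed(35)
  m <- namedMatrix(5, 4)
  b <- new("Bicluster", rows = rownames(m)[1:2], cols = colnames(m)[1:3],
           score = 0)
  obs <- cor(m[1, 1:3], m[2, 1:3])
  gsets <- utils::combn(5, 2, simplify = FALSE)
  ssets <- utils::combn(4, 3, simplify = FALSE)
  allAvg <- unlist(lapply(gsets, function(g) vapply(ssets, function(s)
    cor(m[g[1], s], m[g[2], s]), numeric(1))))
  pEnum <- mean(allAvg > obs)
  res <- permutationTest(b, m, nPerm = 4000, seed = 3)
  expect_equal(res$observed_avg, obs, tolerance = 1e-12)
  expect_lt(abs(res$p_value - pEnum), 0.05)
  ## smoothed variant stays within (0, 1]
  resS <- permutationTest(b, m, nPerm = 50, seed = 3, smooth = TRUE)
  expect_gt(resS$p_value, 0)
})

test_that("adding a perfectly correlated gene never lowers the observed average", {
  set.seed(36)
  m <- namedMatrix(20, 12)
  m[2, ] <- m[1, ] * 0.5 + 1          # perfect linear copy of gene 1
  b0 <- new("Bicluster", rows = rownames(m)[c(1, 3, 4)],
            cols = colnames(m)[1:8], score = 0)
  b1 <- new("Bicluster", rows = rownames(m)[c(1, 2, 3, 4)],
            cols = colnames(m)[1:8], score = 0)
  o0 <- permutationTest(b0, m, nPerm = 1, seed = 1)$observed_avg
  o1 <- permutationTest(b1, m, nPerm = 1, seed = 1)$observed_avg
  expect_gte(o1, o0)
})

test_that("significance filter applies the chosen correction", {
  p <- c(0.001, 0.02, 0.5)
  keep <- selectSignificant(p, level = 0.05, correction = "bonferroni")
  expect_equal(attr(keep, "p_adjusted"), c(0.003, 0.06, 1))
  expect_identical(as.logical(keep), c(TRUE, FALSE, FALSE))
  keepBH <- selectSignificant(p, level = 0.05, correction = "BH")
  expect_equal(attr(keepBH, "p_adjusted"), p.adjust(p, "BH"))
  ## all zero p-values are kept; a single 0.04 is kept at level 0.05
  expect_true(all(selectSignificant(c(0, 0))))
  expect_true(selectSignificant(0.04)[1])
})
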