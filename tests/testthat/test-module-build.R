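test_that("PPI expansion follows the strict average-PCC acceptance rule", {
  set.seed(41)
  n <- 24
  m <- namedMatrix(12, n)
  ## a coherent 5-gene module
  f <- rnorm(n)
  for (g in 1:5) m[g, ] <- 0.9 * f + sqrt(1 - 0.81) * rnorm(n)
  mod <- toyModule(rownames(m)[1:5], colnames(m))

  ## no PPI neighbours: unchanged, trace of length one
  empty <- PPINetwork(data.frame(a = "gX", b = "gY"))
  out0 <- expandWithPPI(mod, empty, m)
  expect_length(out0@mrnaAdded, 0)
  expect_length(out0@avgPccTrace, 1)

  ## an exact copy of a module gene must be accepted (average rises), an
  ## anti-correlated candidate must be rejected at its first trial
  m["g006", ] <- m["g001", ]
  m["g007", ] <- -f + 0.1 * rnorm(n)
  ppi <- PPINetwork(data.frame(a = c("g001", "g002"), b = c("g006", "g007")))
  out <- expandWithPPI(mod, ppi, m)
  expect_identical(out@mrnaAdded, "g006")
  expect_true(all(diff(out@avgPccTrace) > 0))
  ## the recorded trace equals a direct recomputation of the averages
  avgOf <- function(genes) {
    cm <- cor(t(m[genes, ]))
    mean(cm[upper.tri(cm)])
  }
  expect_equal(out@avgPccTrace,
               c(avgOf(rownames(m)[1:5]), avgOf(c(rownames(m)[1:5], "g006"))),
               tolerance = 1e-12)
})

test_that("network BIC equals the stats::lm + stats::BIC oracle", {
  set.seed(42)
  n <- 50
  children <- namedMatrix(4, n)
  parents <- namedMatrix(2, n, rowPrefix = "p")
  ## intercept-only baseline
  base <- gaussianBnBic(children, NULL)
  oracle0 <- -0.5 * sum(vapply(seq_len(4), function(i)
    BIC(lm(children[i, ] ~ 1)), numeric(1)))
  expect_equal(base, oracle0, tolerance = 1e-8)
  ## with parents
  sc <- gaussianBnBic(children, parents)
  oracle <- -0.5 * sum(vapply(seq_len(4), function(i)
    BIC(lm(children[i, ] ~ t(parents))), numeric(1)))
  expect_equal(sc, oracle, tolerance = 1e-8)

  ## a parent that is the child plus tiny noise raises the score; a pure
  ## noise parent lowers it (penalty dominates at n = 50)
  strong <- children[1, , drop = FALSE] + 0.05 * rnorm(n)
  rownames(strong) <- "pStrong"
  expect_gt(gaussianBnBic(children, strong), base)
  noise <- namedMatrix(1, n, rowPrefix = "pn")
  expect_lt(gaussianBnBic(children, noise), base)

  ## collinear parents: NA with a warning
  coll <- rbind(parents, parents[1, , drop = FALSE] * 2)
  expect_warning(bad <- gaussianBnBic(children, coll), "singular")
  expect_true(is.na(bad))
  expect_error(gaussianBnBic(children[, 1:3], parents), "samples")
})

test_that("greedy inclusion equals exhaustive best-subset BIC on 3-candidate toys", {
  set.seed(43)
  for (rep in 1:25) {
    n <- 60
    u1 <- rnorm(n); u2 <- rnorm(n)
    pool <- namedMatrix(3, n, rowPrefix = "c")
    pool["c001", ] <- u1 + 0.3 * rnorm(n)
    pool["c002", ] <- u2 + 0.6 * rnorm(n)
    ## c003 stays independent noise
    nStrong <- sample(0:2, 1)
    children <- namedMatrix(4, n)
    if (nStrong >= 1) children <- children + outer(rep(0.8, 4), u1)
    if (nStrong >= 2) children <- children + outer(rep(0.6, 4), u2)
    cand <- c("c001", "c002", "c003")
    sc <- vapply(cand, function(id)
      mean(abs(cor(pool[id, ], t(children)))), numeric(1))
    cand <- cand[order(-sc, cand)]
    fit <- miRTriOmics:::.greedy_bic(
      children, pool, matrix(0, 0, n, dimnames = list(NULL, colnames(pool))),
      cand)
    expect_identical(sort(fit$accepted), bestSubsetBic(children, pool, cand))
    ## traces are strictly increasing
    expect_true(all(diff(fit$trace) > 0) || length(fit$trace) == 1)
  }
})

test_that("protein stage screens by top-beta percent and recovers a planted regulator", {
  set.seed(44)
  n <- 80; nMod <- 12
  mrna <- namedMatrix(40, n)
  f <- rnorm(n)
  for (g in seq_len(nMod)) mrna[g, ] <- 0.8 * f + 0.6 * rnorm(n)
  ## 1 planted regulator (linear combination of module mRNAs + noise) among
  ## 30 noise proteins
  prot <- namedMatrix(31, n, rowPrefix = "P")
  prot["P001", ] <- colMeans(mrna[1:nMod, ]) + 0.3 * rnorm(n)
  mod <- toyModule(rownames(mrna)[1:nMod], colnames(mrna))
  out <- addProteins(mod, prot, mrna, betaPct = 3)
  expect_true("P001" %in% out@proteinIds)
  expect_lte(length(setdiff(out@proteinIds, "P001")), 3)  # >90% of 30 excluded
  expect_true(all(diff(out@bicTraceProteins) > 0))
  ## deterministic given identical inputs
  out2 <- addProteins(mod, prot, mrna, betaPct = 3)
  expect_identical(out@proteinIds, out2@proteinIds)
  ## an empty candidate set (no protein with a defined correlation) leaves
  ## the module unchanged
  flat <- matrix(1, 3, n, dimnames = list(paste0("F", 1:3), colnames(mrna)))
  none <- suppressWarnings(addProteins(mod, flat, mrna, betaPct = 3))
  expect_length(none@proteinIds, 0)
  expect_length(none@bicTraceProteins, 1)
})

test_that("miRNA stage recovers a planted repressor and keeps its sign", {
  set.seed(45)
  n <- 80; nMod <- 12
  u <- rnorm(n); f <- rnorm(n)
  mrna <- namedMatrix(40, n)
  for (g in seq_len(nMod)) mrna[g, ] <- 0.6 * f - 0.55 * u + 0.5 * rnorm(n)
  prot <- namedMatrix(10, n, rowPrefix = "P")
  prot["P001", ] <- 0.8 * f + 0.5 * rnorm(n)
  mirna <- namedMatrix(30, n, rowPrefix = "mir")
  mirna["mir001", ] <- u + 0.3 * rnorm(n)   # repressor: negative coupling
  mod <- toyModule(rownames(mrna)[1:nMod], colnames(mrna),
                   proteins = "P001")
  out <- addMirnas(mod, mirna, mrna, prot, gammaPct = 5)
  expect_true("mir001" %in% out@mirnaIds)
  expect_true(all(diff(out@bicTraceMirnas) > 0))
  ## the repressive (negative) correlation is preserved in the data
  expect_lt(cor(mirna["mir001", ], mrna[1, ]), 0)
  ## no candidates (no miRNA with a defined correlation) -> unchanged
  flat <- matrix(1, 3, n, dimnames = list(paste0("F", 1:3), colnames(mrna)))
  none <- suppressWarnings(addMirnas(mod, flat, mrna, prot, gammaPct = 3))
  expect_length(none@mirnaIds, 0)
})

test_that("module serialisation round-trips through JSON and TSV", {
  mod <- toyModule(c("gA", "gB"), c("s1", "s2", "s3"),
                   proteins = "P1", mirnas = c("mirX"))
  mod@mrnaAdded <- "gC"
  mod@avgPccTrace <- c(0.5, 0.6)
  mod@bicTraceProteins <- c(-10, -5)
  mod@bicTraceMirnas <- c(-5, -1)
  js <- tempfile(fileext = ".json")
  writeModulesJson(list(mod), js)
  back <- jsonlite::read_json(js, simplifyVector = FALSE)[[1]]
  expect_identical(unlist(back$mrna_core), c("gA", "gB"))
  expect_identical(unlist(back$mirnas), "mirX")
  tsv <- tempfile(fileext = ".tsv")
  writeModulesTsv(list(mod), tsv)
  flat <- read.delim(tsv)
  expect_setequal(flat$member_id[flat$member_type == "mrna_added"], "gC")
  expect_equal(sum(flat$member_type == "sample"), 3)
})
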