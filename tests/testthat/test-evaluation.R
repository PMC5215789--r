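mkRanking <- function(scores) rankMirnas(scores, alphaPct = 5)

test_that("top-k catalogue fraction counts within the ranked universe", {
  sc <- setNames(20:1, sprintf("mir%02d", 1:20))
  r <- mkRanking(sc)
  top <- rankingTable(r)$mirna[1:2]   # floor(20 * 10%) = 2
  expect_equal(topkKnownFraction(r, top, topPct = 10), 1)
  bottom <- rankingTable(r)$mirna[19:20]
  expect_equal(topkKnownFraction(r, bottom, topPct = 10), 0)
  ## counting oracle on a mixed catalogue, including ids outside the ranking
  known <- c(rankingTable(r)$mirna[c(1, 3, 8, 15, 20)], "mirZZ")
  k <- floor(20 * 25 / 100)
  oracle <- length(intersect(known, rankingTable(r)$mirna[1:k])) /
    length(intersect(known, rankingTable(r)$mirna))
  expect_equal(topkKnownFraction(r, known, topPct = 25), oracle)
  ## non-decreasing in the percentage
  fr <- vapply(c(5, 10, 25, 50, 100), function(p)
    topkKnownFraction(r, known, topPct = p), numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_error(topkKnownFraction(r, "mirZZ"), "no miRNA")
})

test_that("ROC/AUC equals the Mann-Whitney identity and handles ties", {
  ## perfect separation
  sc <- setNames(c(9, 8, 7, 2, 1), sprintf("m%d", 1:5))
  known <- c("m1", "m2", "m3")
  roc <- rocAuc(mkRanking(sc), known)
  expect_equal(roc$auc, 1)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(utils::tail(roc$points$tpr, 1), 1)
  expect_true(all(diff(roc$points$fpr) >= 0) &&
                all(diff(roc$points$tpr) >= 0))

  ## 4-item toy against the rank-sum (Mann-Whitney) oracle, with a tie
  sc2 <- setNames(c(4, 3, 3, 1), sprintf("m%d", 1:4))
  known2 <- c("m1", "m3")
  roc2 <- rocAuc(mkRanking(sc2), known2)
  pos <- sc2[known2]; neg <- sc2[setdiff(names(sc2), known2)]
  u <- sum(vapply(pos, function(p)
    sum(p > neg) + 0.5 * sum(p == neg), numeric(1)))
  expect_equal(roc2$auc, u / (length(pos) * length(neg)))

  ## invariant under strictly monotone transforms of the scores
  roc3 <- rocAuc(mkRanking(exp(sc2 / 2)), known2)
  expect_equal(roc3$auc, roc2$auc)
  expect_error(rocAuc(mkRanking(sc2), names(sc2)), "classes")
})

test_that("permuted labels give a chance-level mean AUC", {
  set.seed(51)
  sc <- setNames(rnorm(40), sprintf("m%02d", 1:40))
  r <- mkRanking(sc)
  aucs <- vapply(seq_len(500), function(i)
    rocAuc(r, sample(names(sc), 15))$auc, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("survival stratification is a deterministic sort-and-slice", {
  clin <- data.frame(sample = sprintf("s%02d", 1:10),
                     time = seq(100, 1000, by = 100),
                     event = rep(c(TRUE, FALSE), 5))
  expr <- setNames(c(5, 3, 9, 1, 7, 2, 8, 4, 6, 0), clin$sample)
  gr <- survivalStratify(expr, clin, xPct = 50)
  expect_length(gr$top, 5); expect_length(gr$bottom, 5)
  expect_length(intersect(gr$top, gr$bottom), 0)
  ord <- names(sort(expr, decreasing = TRUE))
  expect_setequal(gr$top, ord[1:5])
  expect_setequal(gr$bottom, rev(ord)[1:5])
  ## all-equal expression: groups still deterministic via the id tie-break
  tie <- setNames(rep(1, 10), clin$sample)
  gTie <- survivalStratify(tie, clin, xPct = 30)
  expect_identical(gTie$top, sprintf("s%02d", 1:3))
  expect_identical(gTie$bottom, sprintf("s%02d", 1:3))
  expect_error(survivalStratify(expr, clin, xPct = 60), "overlap")
})

test_that("log-rank comparison matches a hand-computed 6-subject oracle", {
  ## identical groups: statistic 0, p = 1
  clin <- data.frame(sample = sprintf("s%d", 1:8),
                     time = rep(c(50, 120, 200, 310), 2),
                     event = rep(c(TRUE, TRUE, FALSE, TRUE), 2))
  same <- kmLogrank(list(top = sprintf("s%d", 1:4),
                         bottom = sprintf("s%d", 5:8)), clin)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  ## 6-subject table, hand-computed observed/expected per event time
  clin6 <- data.frame(sample = sprintf("p%d", 1:6),
                      time = c(10, 20, 30, 25, 35, 45),
                      event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  groups <- list(top = c("p1", "p2", "p3"), bottom = c("p4", "p5", "p6"))
  res <- kmLogrank(groups, clin6, mirnaId = "mirT")
  ## oracle: loop over distinct event times, hypergeometric expectations
  df <- clin6; df$g <- rep(c(1, 0), each = 3)
  times <- sort(unique(df$time[df$event]))
  O <- E <- V <- 0
  for (tt in times) {
    at <- df$time >= tt
    d <- sum(df$event & df$time == tt)
    d1 <- sum(df$event & df$time == tt & df$g == 1)
    n <- sum(at); n1 <- sum(at & df$g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oracle <- (O - E)^2 / V
  expect_equal(res$statistic, oracle, tolerance = 1e-8)
  expect_equal(res$p_value, pchisq(oracle, 1, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_identical(res$mirna_id, "mirT")

  ## no events at all: statistic undefined, reported NA with warning
  clin0 <- within(clin6, event <- FALSE)
  expect_warning(nores <- kmLogrank(groups, clin0), "no events")
  expect_true(is.na(nores$statistic))

  ## Kaplan-Meier curve starts at 1 and never increases
  s <- summary(res$fit)
  expect_true(all(s$surv <= 1))
  expect_true(all(diff(s$surv[s$strata == s$strata[1]]) <= 0))
})

test_that("log-rank power at hazard ratio 2 exceeds 80 percent", {
  set.seed(52)
  rej <- vapply(seq_len(200), function(i) {
    t1 <- rexp(100, rate = 1)
    t2 <- rexp(100, rate = 2)
    cens <- runif(200, 0, 4)
    tm <- pmin(c(t1, t2), cens)
    ev <- c(t1, t2) <= cens
    clin <- data.frame(sample = sprintf("x%03d", 1:200), time = tm,
                       event = ev)
    r <- kmLogrank(list(top = clin$sample[1:100],
                        bottom = clin$sample[101:200]), clin)
    r$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})
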