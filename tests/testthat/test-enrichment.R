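test_that("ranked lists are decreasing and reject duplicates", {
  s <- c(a = 1, b = 3, c = -2)
  expect_identical(names(rankedList(s)), c("b", "a", "c"))
  expect_error(rankedList(c(a = 1, a = 2)), "uniquely named")
})

test_that("enrichment score has the textbook limits", {
  r <- rankedList(c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1, g6 = 0.5))
  # all members at the top, weight 0: running sum peaks at exactly +1
  es0 <- enrichmentScore(r, c("g1", "g2"), weightExponent = 0)
  expect_equal(es0$es, 1)
  expect_equal(unname(which.max(es0$runningSum)), 2)
  # set = entire list is degenerate
  expect_error(enrichmentScore(r, names(r)), "entire")
  # empty intersection yields a missing result
  expect_message(em <- enrichmentScore(r, "absent"), "does not intersect")
  expect_true(is.na(em$es))
  # positive-scale invariance at weight 1 is exact
  es1 <- enrichmentScore(r, c("g2", "g5"))
  es2 <- enrichmentScore(rankedList(7.3 * c(g1 = 5, g2 = 4, g3 = 3,
                                            g4 = 2, g5 = 1, g6 = 0.5)),
                         c("g2", "g5"))
  expect_equal(es1$es, es2$es)   # equal up to floating-point rounding
})

test_that("ES equals an independent running-sum enumeration", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    r <- rankedList(stats::setNames(round(rnorm(n), 3) +
                                    seq(n, 1) * 1e-6,
                                    paste0("g", 1:n)))
    set <- sample(names(r), sample(1:(n - 1), 1))
    w <- sample(c(0, 1, 2), 1)
    expect_equal(enrichmentScore(r, set, w)$es,
                 unname(bruteES(r, set, w)), tolerance = 1e-12)
  }
})

test_that("the fast hit-boundary ES agrees with the full running sum", {
  set.seed(31)
  r <- rankedList(stats::setNames(rnorm(200), paste0("g", 1:200)))
  wAll <- abs(r)
  for (i in 1:25) {
    pos <- sample(200, sample(2:40, 1))
    expect_equal(DemethylSig:::.esAtPositions(wAll, 200, pos),
                 enrichmentScore(r, names(r)[pos])$es)
  }
})

test_that("NES normalizes against the same-sign null and p is its tail rank", {
  nullES <- c(0.2, 0.3, 0.4, -0.1, -0.5)
  r <- rankedList(c(a = 1, b = 0.5, c = 0.2))
  out <- permutationNes(0.3, r, 2, nullES = nullES)
  expect_equal(out$nes, 0.3 / mean(c(0.2, 0.3, 0.4)))
  expect_equal(out$p, 2 / 3)
  # es equal to the null mean gives NES exactly 1
  out2 <- permutationNes(mean(c(0.2, 0.3, 0.4)), r, 2, nullES = nullES)
  expect_equal(out2$nes, 1)
  # no same-sign null values: flagged floor p
  out3 <- permutationNes(0.5, r, 2, nullES = c(-0.2, -0.4))
  expect_true(out3$flagged)
  expect_equal(out3$p, 1 / 3)
})

test_that("preranked GSEA is seed-deterministic and flags planted sets", {
  set.seed(8)
  scores <- stats::setNames(rnorm(300), sprintf("g%03d", 1:300))
  scores[1:25] <- scores[1:25] + 3          # planted block at the top
  r <- rankedList(scores)
  sets <- list(planted = sprintf("g%03d", 1:25),
               random = sprintf("g%03d", seq(10, 250, by = 10)))
  a <- gseaPreranked(r, sets, nPerm = 200, seed = 5)
  b <- gseaPreranked(r, sets, nPerm = 200, seed = 5)
  expect_identical(a, b)
  expect_true(a$significant[a$set_id == "planted"])
  expect_gt(a$nes[a$set_id == "planted"], 1)
})

test_that("the NES matrix places zeros exactly where significance fails", {
  res <- data.frame(
    list_id = rep(c("L1", "L2", "L3"), each = 3),
    set_id = rep(c("sigL1only", "always", "never"), 3),
    nes = c(2.1, 1.8, 1.2,  0.4, 2.2, 1.1,  0.3, 1.9, 1.0),
    significant = c(TRUE, TRUE, FALSE,  FALSE, TRUE, FALSE,
                    FALSE, TRUE, FALSE))
  m <- assembleNesMatrix(res)
  expect_false("never" %in% rownames(m))     # significant nowhere
  expect_equal(m["sigL1only", ], c(L1 = 2.1, L2 = 0, L3 = 0))
  expect_equal(m["always", ], c(L1 = 1.8, L2 = 2.2, L3 = 1.9))
  # all significant: matrix equals raw NES
  resAll <- transform(res, significant = TRUE)
  mAll <- assembleNesMatrix(resAll)
  expect_equal(mAll["never", "L2"], 1.1)
})

test_that("ES matches fgsea's statistic on a shared instance", {
  skip_if_not_installed("fgsea")
  set.seed(12)
  r <- rankedList(stats::setNames(rnorm(100) + rep(c(1, 0), c(10, 90)),
                                  paste0("g", 1:100)))
  set <- paste0("g", c(1:8, 40, 70))
  ref <- suppressWarnings(
    fgsea::calcGseaStat(unname(r), selectedStats = match(set, names(r)),
                        gseaParam = 1))
  expect_equal(enrichmentScore(r, set)$es, ref, tolerance = 1e-12)
})
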