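test_that("degenerate profiles (all-0, all-saturation) are removed exactly", {
  v <- matrix(c(0, 0, 0, 0,
                1000, 1000, 1000, 1000,
                0, 1000, 3, 0,
                5, 5, 5, 5), 4, 4, byrow = TRUE,
              dimnames = list(c("zero", "sat", "mix", "flat"),
                              paste0("c", 1:4)))
  m <- ExpressionMatrix(v)
  suppressMessages(f <- filterDegenerate(m, saturationValue = 1000))
  expect_setequal(f$removedIds, c("zero", "sat"))
  expect_equal(f$removedZeroIds, "zero")
  expect_equal(f$removedSaturatedIds, "sat")
  expect_setequal(entityIds(f$kept), c("mix", "flat"))

  # constant-but-not-degenerate rows survive; saturation rule can be disabled
  suppressMessages(f2 <- filterDegenerate(m, saturationValue = NULL))
  expect_equal(f2$removedIds, "zero")

  allbad <- ExpressionMatrix(matrix(0:0, 1, 3, dimnames = list("z", paste0("c", 1:3))))
  suppressMessages(f3 <- filterDegenerate(allbad))
  expect_null(f3$kept)
  expect_equal(f3$removedIds, "z")
})

test_that("common conditions intersect by normalized label in first-matrix order", {
  a <- ExpressionMatrix(matrix(1:8, 2, 4,
         dimnames = list(c("a1", "a2"), c("D", "B", "C", "A"))))
  b <- ExpressionMatrix(matrix(1:8, 2, 4,
         dimnames = list(c("b1", "b2"), c("b", "c", "d", "e"))))
  expect_equal(commonConditions(a, b, minCommon = 2), c("d", "b", "c"))
  expect_error(commonConditions(a, b, minCommon = 5), "need >= 5")
  dis <- ExpressionMatrix(matrix(1:4, 2, 2,
           dimnames = list(c("x1", "x2"), c("q", "r"))))
  expect_error(commonConditions(a, dis, minCommon = 1), "0 condition")
})

test_that("spearmanRho equals the average-rank-then-Pearson oracle", {
  expect_equal(spearmanRho(c(1, 2, 3), c(10, 20, 30)), 1)
  expect_equal(spearmanRho(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(spearmanRho(c(1, 2, 2, 4), c(1, 3, 2, 4)),
               0.9486833, tolerance = 1e-6)
  expect_equal(spearmanRho(c(1, 2, 2, 4), c(1, 3, 2, 4)),
               oracleSpearman(c(1, 2, 2, 4), c(1, 3, 2, 4)))
  expect_true(is.na(spearmanRho(c(2, 2, 2), c(1, 5, 3))))

  set.seed(11)
  for (i in 1:100) {
    n <- sample(4:15, 1)
    x <- sample(0:9, n, replace = TRUE)   # heavy ties
    y <- sample(0:9, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearmanRho(x, y), oracleSpearman(x, y), tolerance = 1e-12)
    expect_equal(spearmanRho(x, y), spearmanRho(y, x))
    # invariance under strictly increasing transforms
    expect_equal(spearmanRho(exp(x / 3), y^3 + 2 * y), spearmanRho(x, y),
                 tolerance = 1e-12)
  }
})

test_that("network construction matches a brute-force double loop", {
  set.seed(3)
  conds <- paste0("t", 1:8)
  lnc <- randomExprMatrix(6, conds, "l")
  genes <- randomExprMatrix(15, conds, "g")
  cutoff <- 0.4
  suppressMessages(net <- buildCoexpressionNetwork(lnc, genes,
                                                   cutoff = cutoff,
                                                   minCommon = 5))
  brute <- list()
  for (i in entityIds(lnc)) for (j in entityIds(genes)) {
    r <- oracleSpearman(expressionValues(lnc)[i, ],
                        expressionValues(genes)[j, ])
    if (!is.na(r) && r >= cutoff)
      brute[[length(brute) + 1L]] <- data.frame(lncrna_id = i, gene_id = j,
                                                rho = r)
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(brute$lncrna_id, brute$gene_id), ]
  expect_equal(net$lncrna_id, brute$lncrna_id)
  expect_equal(net$gene_id, brute$gene_id)
  expect_equal(net$rho, brute$rho, tolerance = 1e-12)
  expect_true(all(net$p_value > 0 & net$p_value <= 1))
})

test_that("the rho cutoff is inclusive and edge count is monotone in it", {
  conds <- paste0("t", 1:5)
  # ranks (3,1,2,4,5) against (1,2,3,4,5): rho = 1 - 6*6/120 = 0.7 exactly
  lnc <- ExpressionMatrix(matrix(c(10, 20, 30, 40, 50), 1, 5,
           dimnames = list("L", conds)))
  g <- matrix(c(30, 10, 20, 40, 50,
                10, 20, 30, 40, 50), 2, 5, byrow = TRUE,
              dimnames = list(c("gBorder", "gPerfect"), conds))
  genes <- ExpressionMatrix(g)
  suppressMessages(net <- buildCoexpressionNetwork(lnc, genes, cutoff = 0.7,
                                                   minCommon = 5))
  expect_setequal(net$gene_id, c("gBorder", "gPerfect"))
  expect_equal(net$rho[net$gene_id == "gBorder"], 0.7)
  expect_equal(net$rho[net$gene_id == "gPerfect"], 1)

  set.seed(5)
  lnc2 <- randomExprMatrix(5, paste0("t", 1:8), "l")
  gen2 <- randomExprMatrix(20, paste0("t", 1:8), "g")
  counts <- vapply(c(-1, -0.5, 0, 0.3, 0.7, 0.9, 1), function(cut)
    nrow(suppressMessages(buildCoexpressionNetwork(lnc2, gen2, cutoff = cut,
                                                   minCommon = 5))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("constant profiles over the shared conditions are skipped, not fatal", {
  conds <- paste0("t", 1:6)
  lv <- matrix(c(rep(4, 6), 1:6), 2, 6, byrow = TRUE,
               dimnames = list(c("const", "ok"), conds))
  lnc <- ExpressionMatrix(lv)
  genes <- ExpressionMatrix(matrix(c(1:6), 1, 6, dimnames = list("g", conds)))
  expect_message(net <- buildCoexpressionNetwork(lnc, genes, cutoff = 0.5,
                                                 minCommon = 5),
                 "skipped 1 pair")
  expect_equal(net$lncrna_id, "ok")
})
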