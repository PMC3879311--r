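test_that("hypergeometric tail matches exact values and enumeration", {
  expect_equal(hypergeomTail(10, 5, 4, 0), 1)
  expect_equal(hypergeomTail(10, 5, 4, 4), 5 / 210)
  expect_equal(hypergeomTail(6, 3, 3, 2), 0.5)
  # literal enumeration of all C(M,n) draws for every valid tuple, M <= 10
  worst <- 0
  for (M in 1:10) for (x in 0:M) for (n in 0:M) for (y in 0:min(n, x)) {
    worst <- max(worst, abs(hypergeomTail(M, x, n, y) -
                              oracleHypergeomEnum(M, x, n, y)))
  }
  expect_lt(worst, 1e-12)
  expect_error(hypergeomTail(10, 11, 4, 0), "x <= M")
  expect_error(hypergeomTail(10, 5, 4, 5), "min\\(n, x\\)")
  expect_error(hypergeomTail(10.5, 5, 4, 1), "integers")
})

test_that("hypergeometric tail is non-increasing in the overlap", {
  for (M in c(10, 17, 25)) for (x in c(3, 7)) for (n in c(5, 9)) {
    ys <- 0:min(n, x)
    p <- hypergeomTail(M, x, n, ys)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("Bonferroni is min(1, p*m)", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_equal(bonferroni(0.37, 1), 0.37)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(rep(0.07, 5)), rep(0.07, 5))
  expect_identical(bhFdr(numeric(0)), numeric(0))

  set.seed(19)
  for (i in 1:100) {
    p <- runif(sample(1:30, 1))
    expect_equal(bhFdr(p), oracleBH(p), tolerance = 1e-14)
    # permutation equivariance
    perm <- sample(length(p))
    expect_equal(bhFdr(p[perm]), bhFdr(p)[perm])
    # q >= p at the last rank bound: q_i >= p_i * m/m
    expect_true(all(bhFdr(p) >= p - 1e-15))
    # family padding equals explicit padding with p = 1
    m <- length(p) + sample(0:5, 1)
    expect_equal(bhFdr(p, m = m),
                 oracleBH(c(p, rep(1, m - length(p))))[seq_along(p)])
  }
})

# one lncRNA with a 3-gene co-expressed set against one disease: the worked
# reference case with p = 1/3
.tinyNetwork <- function() {
  data.frame(lncrna_id = "L1", gene_id = c("g1", "g2", "g3"),
             rho = 0.9, p_value = 0.01, stringsAsFactors = FALSE)
}

test_that("enrichment reproduces the exact reference p-value", {
  gd <- suppressMessages(GeneDiseaseMap(
    data.frame(gene = c("g1", "g2", "g5", "g6"), disease = "D1")))
  res <- suppressMessages(enrichDiseases(.tinyNetwork(), gd,
                                         universe = paste0("g", 1:10),
                                         fdrCutoff = 1))
  expect_equal(nrow(res), 1L)
  expect_equal(res$n, 3L)
  expect_equal(res$x, 4L)
  expect_equal(res$y, 2L)
  expect_equal(res$p_raw, 1 / 3)
  expect_equal(res$p_raw, oracleHypergeomSum(10, 4, 3, 2))
})

test_that("zero-overlap diseases are absent and results are ordered by FDR", {
  gd <- suppressMessages(GeneDiseaseMap(data.frame(
    gene = c("g1", "g2", "g3", "g7", "g8", "g4"),
    disease = c("Dhit", "Dhit", "Dhit", "Dmiss", "Dmiss", "Dweak"))))
  res <- suppressMessages(enrichDiseases(.tinyNetwork(), gd,
                                         universe = paste0("g", 1:10),
                                         fdrCutoff = 1))
  expect_false("Dmiss" %in% res$disease_id)
  expect_equal(res$disease_id[1L], "Dhit")  # strongest enrichment first
  expect_true(!is.unsorted(res$q_fdr))
  expect_true(all(res$p_raw <= res$p_bonferroni))
  expect_true(all(res$q_fdr <= 1))
  # family = all 3 diseases with x >= 1, although Dmiss is never reported
  expect_equal(attr(res, "family_size"), 3L)
  expect_equal(res$p_bonferroni, pmin(1, res$p_raw * 3))
})

test_that("disease gene sets are clipped to the universe; outsiders dropped", {
  gd <- suppressMessages(GeneDiseaseMap(data.frame(
    gene = c("g1", "g2", "gOUT", "zOUT1", "zOUT2"),
    disease = c("D1", "D1", "D1", "Dout", "Dout"))))
  expect_message(
    res <- enrichDiseases(.tinyNetwork(), gd, universe = paste0("g", 1:10),
                          fdrCutoff = 1),
    "dropped 1 disease")
  expect_equal(res$x, 2L)  # gOUT not counted
  expect_false("Dout" %in% res$disease_id)
  # explicit universe-size override changes M
  res2 <- suppressMessages(enrichDiseases(.tinyNetwork(), gd,
                                          universe = paste0("g", 1:10),
                                          universeSize = 20, fdrCutoff = 1))
  expect_equal(res2$p_raw, oracleHypergeomSum(20, 2, 3, res2$y))
})

test_that("per-lncRNA and global families give the documented corrections", {
  net <- rbind(.tinyNetwork(),
               data.frame(lncrna_id = "L2", gene_id = c("g5", "g6"),
                          rho = 0.8, p_value = 0.01))
  gd <- suppressMessages(GeneDiseaseMap(data.frame(
    gene = c("g1", "g2", "g5", "g6"),
    disease = c("D1", "D1", "D2", "D2"))))
  per <- suppressMessages(enrichDiseases(net, gd, paste0("g", 1:10),
                                         fdrCutoff = 1,
                                         family = "per_lncrna"))
  glob <- suppressMessages(enrichDiseases(net, gd, paste0("g", 1:10),
                                          fdrCutoff = 1, family = "global"))
  expect_equal(attr(per, "family_size"), 2L)    # 2 diseases per lncRNA
  expect_equal(attr(glob, "family_size"), 4L)   # 2 lncRNAs x 2 diseases
  key <- function(d) d[order(d$lncrna_id, d$disease_id), ]
  expect_equal(key(glob)$p_raw, key(per)$p_raw)
  expect_true(all(key(glob)$p_bonferroni >= key(per)$p_bonferroni))
  # FDR cutoff is honoured
  strict <- suppressMessages(enrichDiseases(net, gd, paste0("g", 1:10),
                                            fdrCutoff = 0.05))
  expect_true(all(strict$q_fdr <= 0.05))
})
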