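test_that("line-level cis BLUP equals Z times the haplotype BLUP", {
  pan <- tinyPanel(n = 80, nr = 12, seed = 91)
  se <- simulateExpression(pan, simScenario(nGenes = 8, seed = 92))
  Y <- SummarizedExperiment::assay(se, 1)
  Ht <- relValues(buildTransHRM(pan))
  rd <- SummarizedExperiment::rowData(se)
  for (g in rownames(se)) {
    Z <- buildDesignMatrix(pan, rd[g, "range_id"])
    fit <- fitModel3(Y[g, ], Z = Z, Htrans = Ht)
    a <- estimateHare(fit, Z, Y[g, ], Htrans = Ht)
    ucis <- attr(a, "ucis")
    expect_lt(max(abs(ucis - as.vector(Z %*% as.vector(a)))), 1e-8)
    # and the projection identity against the kernel-level BLUP
    if (fit@sigma2Cis > 0) {
      cN <- sum(Z^2) / nrow(Z)
      V <- fit@sigma2Cis * tcrossprod(Z) / cN + fit@sigma2Trans * Ht +
        fit@sigma2E * diag(nrow(Z))
      uKernel <- fit@sigma2Cis * (tcrossprod(Z) / cN) %*%
        solve(V, Y[g, ] - fit@mu)
      expect_lt(max(abs(ucis - as.vector(uKernel))), 1e-6)
    }
  }
})

test_that("BLUP approaches fixed-effect group means as shrinkage vanishes", {
  # balanced design: 4 haplotypes x 10 carriers
  h <- rep(1:4, each = 10)
  Z <- outer(h, 1:4, "==") * 1
  colnames(Z) <- as.character(1:4)
  set.seed(93)
  y <- c(-2, 0, 1, 3)[h] + rnorm(40, sd = 0.3)
  f1 <- fitModel1(y, Z)
  fBig <- new("VarCompFit", model = 2L, mu = mean(y), sigma2Cis = 1e6,
              sigma2Trans = NA_real_, sigma2E = 1e2, loglik = 0,
              converged = TRUE, nUsed = 40L, effects = numeric(),
              flags = character())
  aBig <- estimateHare(fBig, Z, y)
  expect_lt(max(abs(as.vector(aBig) - unname(f1@effects))), 1e-3)
  # full shrinkage: zero cis variance gives all-zero effects
  f0 <- fBig; f0@sigma2Cis <- 0
  expect_true(all(estimateHare(f0, Z, y) == 0))
})

test_that("HareMatrix mean imputation follows the stated rule", {
  eff <- list(g1 = c(A = 1, B = -1))
  hm <- buildHareMatrix(eff, universe = c("A", "B", "C"),
                        mu = c(g1 = 10), rangeIds = c(g1 = "r1"), model = 1L)
  expect_equal(hareEffects(hm)["g1", "C"], 0)
  expect_equal(provenance(hm)["g1", "C"], "imputed")
  expect_equal(provenance(hm)["g1", "A"], "estimated")
  # universe equal to the observed set: nothing imputed
  hm2 <- buildHareMatrix(eff, universe = c("A", "B"), mu = c(g1 = 0),
                         rangeIds = c(g1 = "r1"))
  expect_true(all(provenance(hm2) == "estimated"))
  # a single observed haplotype propagates its value everywhere
  hm3 <- buildHareMatrix(list(g1 = c(A = 2.5)), universe = c("A", "B", "C"),
                         mu = c(g1 = 0), rangeIds = c(g1 = "r1"))
  expect_true(all(hareEffects(hm3) == 2.5))
  # adding an unobserved haplotype never changes estimated cells
  expect_equal(hareEffects(hm)["g1", c("A", "B")],
               hareEffects(hm2)["g1", c("A", "B")])
  expect_message(buildHareMatrix(list(g1 = c(A = 1), g2 = numeric())),
                 "excluding")
})

test_that("imputation is deterministic and respects haplotype sharing", {
  pan <- tinyPanel(n = 40, nr = 10, seed = 94)
  se <- simulateExpression(pan, simScenario(nGenes = 6, seed = 95))
  hm <- hareFromExpression(se, pan, model = 2)
  imp1 <- imputeExpression(hm, pan)
  imp2 <- imputeExpression(hm, pan)
  expect_identical(imp1, imp2)
  # lines sharing a haplotype at a gene get identical values there
  calls <- haplotypeCalls(pan)
  rd <- SummarizedExperiment::rowData(se)
  g <- rownames(se)[1]
  h <- calls[, rd[g, "range_id"]]
  shared <- which(h == h[1])
  expect_true(all(imp1[shared, g] == imp1[shared[1], g]))
  # permuting target line order permutes rows identically
  perm <- rev(seq_len(40))
  imp3 <- imputeExpression(hm, pan[perm, ])
  expect_equal(imp3, imp1[perm, ], ignore_attr = TRUE)
  expect_identical(rownames(imp3), rownames(imp1)[perm])
  # a duplicate of a training line receives that line's fitted cis vector
  calls2 <- rbind(haplotypeCalls(pan), clone = haplotypeCalls(pan)[1, ])
  imp4 <- imputeExpression(hm, HaplotypePanel(calls2, refRanges(pan)))
  expect_equal(unname(imp4["clone", ]), unname(imp1[1, ]))
  # unknown haplotype IDs are refused with coordinates
  calls3 <- haplotypeCalls(pan)
  calls3[2, rd[g, "range_id"]] <- 99L
  expect_error(imputeExpression(hm, HaplotypePanel(calls3, refRanges(pan))),
               "outside the HARE universe")
})

test_that("model-1 imputation on noise-free cis-only data is a round trip", {
  pan <- tinyPanel(n = 50, nr = 10, seed = 96)
  se <- simulateExpression(pan, simScenario(nGenes = 6, cisShare = 1,
                                            heritability = 1, seed = 97))
  hm <- hareFromExpression(se, pan, model = 1)
  imp <- imputeExpression(hm, pan)
  Y <- t(SummarizedExperiment::assay(se, 1))
  expect_lt(max(abs(imp - Y[rownames(imp), colnames(imp)])), 1e-10)
})

test_that("tissue integration takes element-wise mean and max", {
  A <- matrix(1, 2, 2, dimnames = list(c("l1", "l2"), c("g1", "g2")))
  B <- A * 3
  expect_identical(integrateTissues(list(A), "mean"), A)
  expect_identical(integrateTissues(list(A), "max"), A)
  expect_equal(integrateTissues(list(A, B), "mean"), (A + B) / 2)
  expect_equal(integrateTissues(list(A, B), "max"), B)
  # mean never exceeds max
  set.seed(98)
  ms <- replicate(3, matrix(rnorm(12), 3, 4,
                            dimnames = list(paste0("l", 1:3),
                                            paste0("g", 1:4))),
                  simplify = FALSE)
  expect_true(all(integrateTissues(ms, "mean") <=
                    integrateTissues(ms, "max") + 1e-12))
  Bbad <- B; rownames(Bbad) <- c("x", "y")
  expect_error(integrateTissues(list(A, Bbad)), "identical dimnames")
})

test_that("cross-tissue correlation enumerates pairs and handles edge cases", {
  set.seed(99)
  ms <- lapply(1:7, function(i)
    matrix(rnorm(50), 10, 5, dimnames = list(paste0("l", 1:10),
                                             paste0("g", 1:5))))
  names(ms) <- paste0("t", 1:7)
  ct <- crossTissueCorrelation(ms)
  expect_equal(nrow(ct$pairs), 21L)
  expect_equal(ncol(ct$perGene), 21L)
  # identical tissues correlate perfectly
  ct2 <- crossTissueCorrelation(list(a = ms[[1]], b = ms[[1]]))
  expect_true(all(abs(ct2$perGene - 1) < 1e-12))
  # zero-variance genes are reported missing
  mz <- ms[[1]]; mz[, "g1"] <- 5
  r <- hareVsMeasuredCorrelation(mz, ms[[2]])
  expect_true(is.na(r$perGene[["g1"]]))
})

test_that("HARE captures all expression when cis explains everything and none when it cannot", {
  pan <- tinyPanel(n = 60, nf = 8, nr = 12, seed = 101)
  seAll <- simulateExpression(pan, simScenario(nGenes = 8, cisShare = 1,
                                               heritability = 1, seed = 102))
  hmAll <- hareFromExpression(seAll, pan, model = 2)
  rAll <- hareVsMeasuredCorrelation(imputeExpression(hmAll, pan),
                                    t(SummarizedExperiment::assay(seAll, 1)))
  expect_true(all(rAll$perGene > 0.999, na.rm = TRUE))
  # no cis signal: once the trans kernel soaks up the polygenic part,
  # per-haplotype effects shrink toward zero and capture little
  pan2 <- tinyPanel(n = 200, nf = 8, nr = 12, seed = 104)
  seNone <- simulateExpression(pan2, simScenario(nGenes = 8, cisShare = 0,
                                                 seed = 103))
  hmNone <- hareFromExpression(seNone, pan2, model = 3)
  rNone <- hareVsMeasuredCorrelation(imputeExpression(hmNone, pan2),
                                     t(SummarizedExperiment::assay(seNone, 1)))
  med <- median(rNone$perGene, na.rm = TRUE)
  expect_true(is.na(med) || abs(med) < 0.25)
})
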