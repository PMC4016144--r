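test_that("venn partition assigns every gene to exactly one region", {
  vp <- vennPartition(ms = c("1", "2", "3"), rna = c("2", "3", "4"),
                      arr = c("3", "5"))
  sz <- regionSizes(vp)
  expect_equal(sz[["MS:RNA:ARR"]], 1L)
  expect_equal(sz[["MS:RNA"]], 1L)
  expect_equal(sz[["MS"]], 1L)
  expect_equal(sz[["RNA"]], 1L)
  expect_equal(sz[["ARR"]], 1L)
  expect_equal(sum(sz), 5L)
  expect_equal(as.character(regionOf(vp)[["3"]]), "MS:RNA:ARR")

  same <- vennPartition(letters[1:4], letters[1:4], letters[1:4])
  expect_equal(regionSizes(same)[["MS:RNA:ARR"]], 4L)
  expect_equal(sum(regionSizes(same)), 4L)
})

test_that("venn region sizes match brute-force membership on random sets", {
  set.seed(19)
  ids <- sprintf("id%05d", 1:10000)
  for (rep in 1:10) {
    ms <- sample(ids, sample(1000:5000, 1))
    rna <- sample(ids, sample(1000:5000, 1))
    arr <- sample(ids, sample(1000:5000, 1))
    vp <- vennPartition(ms, rna, arr)
    expect_equal(unname(regionSizes(vp)), unname(bfVennSizes(ms, rna, arr)))
    expect_equal(sum(regionSizes(vp)), length(unique(c(ms, rna, arr))))
  }
})

test_that("region summaries use interpolated quartiles on log-scale values", {
  arr <- setNames(c(1, 2, 3, 4, 5), paste0("G", 1:5))
  se <- makeUnified(prot = arr, arr = arr, rna = arr)
  vp <- vennPartition(names(arr), names(arr), names(arr))
  rs <- regionSummaries(vp, se)
  aRow <- rs[rs$technology == "array", ]
  expect_equal(c(aRow$min, aRow$q1, aRow$median, aRow$q3, aRow$max),
               c(1, 2, 3, 4, 5))
  # counts are log2-transformed with the pseudo-floor
  pRow <- rs[rs$technology == "proteomics", ]
  expect_equal(pRow$median, log2(3))

  one <- setNames(7, "G1")
  se1 <- makeUnified(one, one, one)
  rs1 <- regionSummaries(vennPartition("G1", "G1", "G1"), se1)
  expect_true(all(rs1$min == rs1$max))

  set.seed(3)
  v <- rlnorm(200, 5, 1)
  names(v) <- sprintf("G%03d", seq_along(v))
  seR <- makeUnified(v, v, v)
  rsR <- regionSummaries(vennPartition(names(v), names(v), names(v)), seR)
  aR <- rsR[rsR$technology == "array", ]
  expect_equal(unlist(aR[c("min", "q1", "median", "q3", "max")]),
               bfFiveNum(v), ignore_attr = TRUE)
})

test_that("category labels follow keyword rules with fixed precedence", {
  gi <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    description = c("vitellogenin 2 precursor", "histone-like protein",
                    "histone H3", "", "Vitellogenin receptor"),
    go_cc = c("", "GO:0005840;GO:0005737", "", "", ""))
  lab <- annotateCategories(gi)
  expect_equal(as.character(lab[["g1"]]), "vitellogenin")
  expect_equal(as.character(lab[["g2"]]), "ribosomal")  # precedence
  expect_equal(as.character(lab[["g3"]]), "histone")
  expect_equal(as.character(lab[["g4"]]), "none")
  expect_equal(as.character(lab[["g5"]]), "vitellogenin")  # case-insensitive
})

test_that("spearmanRho matches closed forms and is rank-invariant", {
  expect_equal(spearmanRho(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6,
               tolerance = 1e-12)
  # midranks under ties, checked against the hand-computed value
  expect_equal(spearmanRho(c(1, 2, 2, 3), c(1, 2, 3, 4)), 0.9486833,
               tolerance = 1e-6)

  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    x <- sample(seq_len(1000), n)   # tie-free
    y <- sample(seq_len(1000), n)
    d <- rank(x) - rank(y)
    closed <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))
    expect_equal(spearmanRho(x, y), closed, tolerance = 1e-12)
    # symmetry and the base-R cross-check
    expect_equal(spearmanRho(x, y), spearmanRho(y, x), tolerance = 1e-12)
    expect_equal(spearmanRho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(spearmanRho(exp(x / 100), y), spearmanRho(x, y),
                 tolerance = 1e-12)
  }

  expect_warning(r0 <- spearmanRho(c(1, 1, 1), c(1, 2, 3)), "undefined")
  expect_true(is.na(r0))
  expect_error(spearmanRho(1:2, 2:1), "at least 3")
})

test_that("exclusion rules collapse when nothing is excludable", {
  set.seed(29)
  v1 <- rlnorm(40, 3, 1); v2 <- v1 * rlnorm(40, 0, 0.3); v3 <- v1 * rlnorm(40, 0, 0.3)
  names(v1) <- names(v2) <- names(v3) <- sprintf("G%03d", 1:40)
  se <- makeUnified(v1, v2, v3)
  cc <- concordanceWithExclusions(se)
  for (p in unique(cc$pair)) {
    r <- cc[cc$pair == p, ]
    expect_equal(r$rho[1], r$rho[2], tolerance = 1e-12)
    expect_equal(r$rho[2], r$rho[3], tolerance = 1e-12)
    expect_true(all(diff(r$n) <= 0))
  }
})

test_that("excluding injected discordant categories raises rho", {
  set.seed(37)
  n <- 300
  ids <- sprintf("G%04d", 1:n)
  mrna <- rlnorm(n, 3, 1)
  protein <- exp(0.8 * log(mrna) + rnorm(n, 0, 0.6))
  # inject vitellogenin-style discordance: huge protein, near-zero mRNA
  vit <- 1:15
  protein[vit] <- protein[vit] * 100
  mrna[vit] <- mrna[vit] * 0.01
  names(mrna) <- names(protein) <- ids
  gi <- data.frame(gene_id = ids,
                   biotype = "protein_coding",
                   description = ifelse(seq_len(n) %in% vit,
                                        "vitellogenin precursor", "protein"),
                   go_cc = "")
  se <- makeUnified(prot = protein, arr = mrna, rna = mrna, geneInfo = gi)
  cc <- concordanceWithExclusions(se, annotateCategories(gi))
  r <- cc[cc$pair == "rnaseq_vs_proteomics", ]
  rhoAll <- r$rho[r$rule_set == "all"]
  rhoClean <- r$rho[r$rule_set == "drop_multi_and_categories"]
  expect_gt(rhoClean, rhoAll)
  expect_equal(r$n[r$rule_set == "all"] - r$n[r$rule_set == "drop_multi_and_categories"],
               length(vit))

  # multi-gene exclusion removes the flagged rows
  seM <- makeUnified(prot = protein, arr = mrna, rna = mrna,
                     multi = ids[1:10], geneInfo = gi)
  ccM <- concordanceWithExclusions(seM, annotateCategories(gi))
  rM <- ccM[ccM$pair == "rnaseq_vs_proteomics", ]
  expect_equal(rM$n[rM$rule_set == "all"] - rM$n[rM$rule_set == "drop_multi"],
               10L)

  # low-n flagging
  few <- setNames(c(5, 1, 8), c("a", "b", "c"))
  seF <- makeUnified(few, few, few)
  ccF <- concordanceWithExclusions(seF)
  expect_true(all(ccF$low_n))
})
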