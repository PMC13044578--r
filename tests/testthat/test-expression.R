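test_that("low-expression filter is strict on both thresholds", {
  m <- matrix(0, 4, 20, dimnames = list(paste0("g", 1:4), NULL))
  m[1, 1:3] <- 100   # 3/20 = 0.15 > 0.10: kept
  m[2, 1:2] <- 100   # 2/20 = 0.10 exactly: removed
  m[3, 1:3] <- 10    # count not > 10: removed
  kept <- filterLowExpression(m)
  expect_equal(kept, "g1")
  expect_error(filterLowExpression(m[, 0]), "zero samples")
})

test_that("DEG calls are strict on both fold change and adjusted p", {
  res <- data.frame(
    gene_id = paste0("g", 1:4),
    comparison = "c1",
    log2_fc = c(0.6, 0.5, -0.8, 2.0),
    p_adj = c(0.01, 0.001, 0.04, 0.05))
  out <- callDegs(res)
  expect_equal(out$significant, c(TRUE, FALSE, TRUE, FALSE))
  res$p_adj[2] <- NA
  expect_warning(out2 <- callDegs(res), "skipped")
  expect_equal(nrow(out2), 3L)
})

test_that("Welch protein calls match the closed-form statistic", {
  ints <- rbind(g1 = c(10, 10, 10, 40, 40, 40),
                g2 = c(5, 6, 7, 5, 6, 7),
                g3 = c(10, 11, 9, 20, 22, 18))
  colnames(ints) <- paste0("s", 1:6)
  design <- data.frame(sample = paste0("s", 1:6),
                       arm = rep(c("control", "treatment"), each = 3),
                       time_point = "TP1")
  out <- callDifferentialProteins(ints, design)
  # constant arms with different means: |FC| = 2, p = 0 by convention
  expect_equal(out$fc[1], 2)
  expect_true(out$significant[1])
  # identical arms: FC = 0, p = 1
  expect_equal(out$fc[2], 0)
  expect_equal(out$p_value[2], 1)
  expect_false(out$significant[2])
  # FC exactly on the threshold fails the strict rule whatever the p-value:
  # doubling gives fc = 1 exactly, tested against a cutoff of 1
  out1 <- callDifferentialProteins(ints, design, fcCutoff = 1)
  expect_equal(out1$fc[3], 1)
  expect_false(out1$significant[3])

  # random data: p equals the Welch formula computed by hand
  set.seed(12)
  x <- matrix(rlnorm(40, 8, 0.4), 4, 10,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:10)))
  dsn <- data.frame(sample = paste0("s", 1:10),
                    arm = rep(c("control", "treatment"), each = 5),
                    time_point = "TP1")
  got <- callDifferentialProteins(x, dsn)
  for (i in 1:4) {
    c0 <- x[i, 1:5]; t0 <- x[i, 6:10]
    tstat <- (mean(t0) - mean(c0)) /
      sqrt(var(t0) / 5 + var(c0) / 5)
    df <- (var(t0) / 5 + var(c0) / 5)^2 /
      ((var(t0) / 5)^2 / 4 + (var(c0) / 5)^2 / 4)
    expect_equal(got$p_value[i], 2 * pt(-abs(tstat), df),
                 tolerance = 1e-12)
  }
  expect_error(
    callDifferentialProteins(x, dsn[c(1, 6:10), ]), "2 replicates")
})

test_that("cell-type significance is strict FC > 2", {
  fcs <- data.frame(gene_id = paste0("g", 1:3), granularity = "cell",
                    cell_type = "calicoblast", fc = c(2.5, 2.0, 0))
  out <- callCellTypeExpression(fcs)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  fcs$fc[1] <- -1
  expect_error(callCellTypeExpression(fcs), "negative")
  fcs$fc[1] <- 3; fcs$granularity <- "supercell"
  expect_error(callCellTypeExpression(fcs), "granularity")
})

test_that("RBH mapping requires reciprocity and strict coverage", {
  ab <- rbind(mkHit("a1", "b1", 300), mkHit("a1", "b2", 100),
              mkHit("a2", "b2", 200), mkHit("a3", "b3", 150))
  ba <- rbind(mkHit("b1", "a1", 290), mkHit("b2", "a1", 180),
              mkHit("b3", "a3", 140))
  got <- mapIdsRBH(ab, ba)
  want <- oracleRBH(ab, ba)
  expect_equal(got[order(got$id_a), ], want[order(want$id_a), ],
               ignore_attr = TRUE)
  # a2 -> b2 is best A->B but b2's best is a1: excluded
  expect_false("a2" %in% got$id_a)
  expect_true(all(c("a1", "a3") %in% got$id_a))
})

test_that("coverage exactly 60% on both sides is excluded", {
  ab <- mkHit("a1", "b1", 300, qfrac = 0.6, sfrac = 0.6)
  ba <- mkHit("b1", "a1", 300, qfrac = 0.6, sfrac = 0.6)
  expect_equal(nrow(mapIdsRBH(ab, ba)), 0L)
  # one side just over suffices in "either" mode
  ab2 <- mkHit("a1", "b1", 300, qfrac = 0.61, sfrac = 0.3)
  expect_equal(nrow(mapIdsRBH(ab2, ba)), 1L)
  # but not in "both" mode
  ba2 <- mkHit("b1", "a1", 300, qfrac = 0.61, sfrac = 0.3)
  expect_equal(nrow(mapIdsRBH(ab2, ba2, coverageMode = "both")), 0L)
})

test_that("tied best hits drop the query with a warning", {
  ab <- rbind(mkHit("a1", "b1", 300), mkHit("a1", "b2", 300))
  ba <- mkHit("b1", "a1", 300)
  expect_warning(out <- mapIdsRBH(ab, ba), "tied")
  expect_equal(nrow(out), 0L)
})

test_that("RBH mapping is symmetric under table swap", {
  set.seed(23)
  for (i in 1:10) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    ab <- do.call(rbind, lapply(seq_len(na * 2), function(j)
      mkHit(paste0("a", sample(na, 1)), paste0("b", sample(nb, 1)),
            sample(50:500, 1), qfrac = runif(1, 0.3, 1),
            sfrac = runif(1, 0.3, 1))))
    ba <- do.call(rbind, lapply(seq_len(nb * 2), function(j)
      mkHit(paste0("b", sample(nb, 1)), paste0("a", sample(na, 1)),
            sample(50:500, 1), qfrac = runif(1, 0.3, 1),
            sfrac = runif(1, 0.3, 1))))
    f <- suppressWarnings(mapIdsRBH(ab, ba))
    r <- suppressWarnings(mapIdsRBH(ba, ab))
    expect_equal(f[order(f$id_a), "id_b"],
                 r[order(r$id_b), "id_a"])
  }
})

test_that("proportion bias uses any-unit denominators per group", {
  sig <- data.frame(gene_id = c("g1", "g2", "g2"),
                    unit = c("c1", "c1", "c2"))
  grp <- c(g1 = "dark", g2 = "dark")
  out <- proportionBias(sig, grp)
  d <- out$rows[out$rows$group == "dark", ]
  expect_equal(d$proportion[d$unit == "c1"], 1.0)
  expect_equal(d$proportion[d$unit == "c2"], 0.5)
  # no light gene significant anywhere: proportions undefined
  l <- out$rows[out$rows$group == "light", ]
  expect_true(all(is.na(l$proportion)))
  expect_true(all(is.na(out$delta$delta)))
  expect_error(proportionBias(sig, c(g1 = "dark")), "without group")
})

test_that("a gene in k units counts once in the denominator", {
  sig <- data.frame(gene_id = c("d1", "d1", "d1", "l1"),
                    unit = c("u1", "u2", "u3", "u1"))
  grp <- c(d1 = "dark", l1 = "light")
  out <- proportionBias(sig, grp, test = TRUE)
  d <- out$rows[out$rows$group == "dark", ]
  expect_equal(unique(d$denominator), 1L)
  # proportions may sum past 1 across units
  expect_equal(sum(d$proportion), 3)
  expect_true(all(d$proportion >= 0 & d$proportion <= 1))
  expect_true("p_value" %in% names(out$delta))
})
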