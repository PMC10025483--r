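make_sheet <- function() {
  data.frame(library_id = paste0(rep(c("C1", "D", "C2", "R"), each = 3),
                                 "_", 1:3),
             condition = rep(CONDITIONS, each = 3),
             replicate = rep(1:3, 4), stringsAsFactors = FALSE)
}

test_that("size factors follow the median-of-ratios construction", {
  # identical libraries -> unit factors
  m <- matrix(c(5, 9, 30, 5, 9, 30), ncol = 2,
              dimnames = list(paste0("s", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  # hand computation: each row of library b is 2x library a
  m2 <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
               dimnames = list(paste0("s", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))

  # scaling one library by c scales the factor ratio by c
  set.seed(41)
  m3 <- matrix(rpois(300, 50) + 1, ncol = 3,
               dimnames = list(paste0("s", 1:100), c("a", "b", "c")))
  f <- size_factors(m3)
  m4 <- m3; m4[, "b"] <- m3[, "b"] * 4
  f4 <- size_factors(m4)
  expect_equal(f4[["b"]] / f4[["a"]], 4 * f[["b"]] / f[["a"]],
               tolerance = 1e-10)

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "positive counts")
})

test_that("rows with identical counts in all libraries are unchanged", {
  # constant rows make all size factors exactly 1, so the fold change
  # must be exactly 0 with p = 1
  set.seed(42)
  vals <- sample(20:500, 50)
  m <- matrix(rep(vals, 12), nrow = 50,
              dimnames = list(paste0("s", 1:50), make_sheet()$library_id))
  res <- nb_wald(m, make_sheet(), c("drought", "control_1"))
  expect_equal(res$log2fc, rep(0, 50))
  expect_true(all(res$p > 0.99))
  expect_true(all(res$call == "unchanged"))
})

test_that("BH adjustment is monotone in p-rank and bounded by 1", {
  set.seed(43)
  m <- matrix(rnbinom(500 * 12, mu = 80, size = 8), nrow = 500,
              dimnames = list(paste0("s", 1:500), make_sheet()$library_id))
  res <- nb_wald(m, make_sheet(), c("drought", "control_1"))
  ord <- order(res$p)
  expect_true(all(diff(res$padj[ord]) >= -1e-12))
  expect_true(all(res$padj <= 1))
  expect_true(all(res$padj >= res$p - 1e-12))
})

test_that("classification respects inclusive thresholds", {
  expect_equal(classify(1.07, 0.03), "up")
  expect_equal(classify(-0.40, 0.2), "unchanged")   # not significant
  expect_equal(classify(-2.00, 0.0001), "down")
  expect_equal(classify(0.59, 0.001), "unchanged")  # below the 0.6 floor
  expect_equal(classify(0.6, 0.05), "up")           # both boundaries inclusive
  expect_equal(classify(-0.6, 0.05), "down")
  # monotone: increasing |log2fc| at fixed padj never un-calls
  set.seed(44)
  for (i in 1:200) {
    lfc <- runif(1, -5, 5); p <- runif(1)
    c1 <- classify(lfc, p)
    c2 <- classify(lfc * 1.5, p)
    if (c1 %in% c("up", "down")) expect_equal(c2, c1)
  }
})

test_that("NB Wald type-I error is near nominal on a null simulation", {
  set.seed(45)
  n <- 2000
  mu <- runif(n, 50, 1000)
  m <- matrix(rnbinom(n * 12, mu = rep(mu, 12), size = 1 / 0.1), nrow = n,
              dimnames = list(paste0("s", 1:n), make_sheet()$library_id))
  res <- nb_wald(m, make_sheet(), c("drought", "control_1"))
  expect_gte(mean(res$p <= 0.05), 0.03)
  expect_lte(mean(res$p <= 0.05), 0.07)
})

test_that("a planted log2 fold change of 2 is recovered", {
  # effects are planted in a minority of rows over a null background, as
  # in real libraries, so median-of-ratios normalization stays anchored
  set.seed(46)
  sheet <- make_sheet()
  n_null <- 1500; n_fx <- 300  # half planted up, half down, as in real data
  up <- n_null + seq_len(n_fx / 2)
  dn <- n_null + n_fx / 2 + seq_len(n_fx / 2)
  mu <- matrix(runif(n_null + n_fx, 50, 1000), n_null + n_fx, 12)
  mu[c(up, dn), ] <- 500
  mu[up, sheet$condition == "drought"] <- 500 * 4
  mu[dn, sheet$condition == "drought"] <- 500 / 4
  dimnames(mu) <- list(paste0("s", seq_len(nrow(mu))), sheet$library_id)
  m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.1), nrow = nrow(mu),
              dimnames = dimnames(mu))
  res <- nb_wald(m, sheet, c("drought", "control_1"))
  expect_lt(abs(mean(res$log2fc[up]) - 2), 0.2)
  expect_lt(abs(mean(res$log2fc[dn]) + 2), 0.2)
})

test_that("restoration counts equal a brute-force set computation", {
  set.seed(47)
  for (i in 1:20) {
    nm <- paste0("m", 1:40)
    d <- setNames(sample(c("up", "down", "unchanged"), 40, TRUE), nm)
    r <- setNames(sample(c("up", "down", "unchanged"), 40, TRUE), nm)
    s <- restoration_summary(d, r)
    up_d <- nm[d == "up"]; down_d <- nm[d == "down"]
    expect_equal(s$n_restored_up, length(intersect(up_d, nm[r == "unchanged"])))
    expect_equal(s$n_restored_down,
                 length(intersect(down_d, nm[r == "unchanged"])))
    expect_equal(s$n_common_up, length(intersect(up_d, nm[r == "up"])))
    # restored + changed-in-both partitions the drought-changed set
    changed_both <- sum(d != "unchanged" & r != "unchanged")
    expect_equal(s$n_restored_up + s$n_restored_down + changed_both,
                 s$n_up_drought + s$n_down_drought)
  }
  expect_error(restoration_summary(setNames("up", "a"), setNames("up", "b")),
               "universe")
})

test_that("pri-miRNA cross-tab equals the nested-loop oracle", {
  # hand-built 9-pair set covering each cell once
  nm <- paste0("p", 1:9)
  lev <- c("up", "down", "const")
  pri <- setNames(rep(lev, each = 3), nm)
  mir <- setNames(rep(lev, 3), nm)
  tab <- primirna_crosstab(pri, mir)
  expect_equal(unname(tab), matrix(1L, 3, 3), ignore_attr = TRUE)
  expect_equal(sum(tab), 9L)

  set.seed(48)
  for (i in 1:10) {
    nm <- paste0("g", 1:30)
    pri <- setNames(sample(lev, 30, TRUE), nm)
    mir <- setNames(sample(c("up", "down", "unchanged"), 25, TRUE),
                    sample(nm, 25))
    tab <- primirna_crosstab(pri, mir)
    common <- intersect(names(pri), names(mir))
    for (a in lev) for (b in lev) {
      mm <- mir[common]; mm[mm == "unchanged"] <- "const"
      expect_equal(tab[a, b], sum(pri[common] == a & mm == b))
    }
    expect_equal(sum(tab), length(common))
  }
})

test_that("the printed fold-change table reproduces the published counts", {
  calls <- classify_table2(load_table2_fixture())
  s <- restoration_summary(
    setNames(calls$call_drought, calls$mirna_name),
    setNames(calls$call_rehydration, calls$mirna_name))
  expect_equal(s$n_up_drought, 11)
  expect_equal(s$n_down_drought, 38)
  expect_equal(s$n_up_rehyd, 9)
  expect_equal(s$n_down_rehyd, 16)
  expect_equal(s$n_common_up, 5)
  expect_equal(s$n_common_down, 11)
  expect_equal(s$n_restored_up, 6)
  expect_equal(s$n_restored_down, 27)
})

test_that("fold-change estimates agree with an established NB engine", {
  skip_if_not_installed("DESeq2")
  set.seed(49)
  sheet <- make_sheet()
  n <- 300
  mu <- matrix(runif(n, 30, 600), n, 12)
  mu[1:30, sheet$condition == "drought"] <- mu[1:30, 1] * 4
  mu[31:60, sheet$condition == "drought"] <- mu[31:60, 1] / 4
  dimnames(mu) <- list(paste0("s", 1:n), sheet$library_id)
  m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.1), nrow = n,
              dimnames = dimnames(mu))
  ours <- nb_wald(m, sheet, c("drought", "control_1"))

  keep <- sheet$condition %in% c("control_1", "drought")
  cd <- data.frame(condition = factor(sheet$condition[keep],
                                      levels = c("control_1", "drought")))
  dds <- DESeq2::DESeqDataSetFromMatrix(m[, keep], cd, ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  ref <- as.data.frame(DESeq2::results(dds))

  expect_gt(cor(ours$log2fc, ref$log2FoldChange), 0.95)
  # every strongly planted effect agrees in direction and call
  expect_true(all(sign(ours$log2fc[1:60]) == sign(ref$log2FoldChange[1:60])))
  expect_true(all(ours$call[1:30] == "up"))
  expect_true(all(ours$call[31:60] == "down"))
})
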