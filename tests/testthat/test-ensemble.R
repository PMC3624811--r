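test_that("confidence scores measure per-predictor explained variance", {
  set.seed(14)
  n <- 24
  # orthonormal columns scaled to unit sample variance
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3))) * sqrt(n - 1)
  colnames(Q) <- c("T1", "T2", "T3")

  # single predictor explaining the response exactly -> S = 1
  Y1 <- matrix(Q[, 1], dimnames = list(NULL, list("g1")))
  dr1 <- make_design(Q[, 1:2], Y1)
  fits1 <- list(g1 = structure(list(selected = "T1",
                                    betas = c(T1 = 1),
                                    method = "bbsr"),
                               class = "grn_regfit"))
  S1 <- confidence_scores(fits1, dr1)
  expect_equal(unname(S1["T1", "g1"]), 1)
  expect_equal(unname(S1["T2", "g1"]), 0)

  # two orthonormal predictors with equal shares and matching residual:
  # removing either doubles the residual variance -> S = 0.5 for both
  y <- Q[, 1] + Q[, 2] + Q[, 3]
  Y2 <- matrix(y, dimnames = list(NULL, list("g1")))
  dr2 <- make_design(Q[, 1:2], Y2)
  fits2 <- list(g1 = structure(list(selected = c("T1", "T2"),
                                    betas = c(T1 = 1, T2 = 1),
                                    method = "bbsr"),
                               class = "grn_regfit"))
  S2 <- confidence_scores(fits2, dr2)
  expect_equal(unname(S2["T1", "g1"]), 0.5, tolerance = 1e-10)
  expect_equal(unname(S2["T2", "g1"]), 0.5, tolerance = 1e-10)

  # an uninformative selected predictor scores 0
  fits3 <- list(g1 = structure(list(selected = c("T1", "T2"),
                                    betas = c(T1 = 1, T2 = 0),
                                    method = "bbsr"),
                               class = "grn_regfit"))
  Y3 <- matrix(Q[, 1] + Q[, 3], dimnames = list(NULL, list("g1")))
  S3 <- confidence_scores(fits3, make_design(Q[, 1:2], Y3))
  expect_equal(unname(S3["T2", "g1"]), 0, tolerance = 1e-10)
})

test_that("rank combination averages ranks across bootstraps", {
  tfs <- c("A", "B")
  genes <- c("A", "g1", "g2")
  m1 <- matrix(c(0, 0.9, 0.5,
                 0, 0.0, 0.0), 2, 3, byrow = TRUE,
               dimnames = list(tfs, genes))
  m2 <- matrix(c(0, 0.2, 0.0,
                 0, 0.8, 0.0), 2, 3, byrow = TRUE,
               dimnames = list(tfs, genes))

  # identical matrices: final order equals the single-matrix order
  rc <- rank_combine(list(m1, m1))
  expect_identical(rc$network$tf[1], "A")
  expect_identical(rc$network$gene[1], "g1")
  expect_identical(rc$network[, 1:2], rank_combine(list(m1))$network[, 1:2])

  # edge ranked 1st and 3rd -> mean rank 2
  rc2 <- rank_combine(list(m1, m2))
  expect_equal(rc2$mean_rank["A", "g1"], (1 + 2) / 2)
  expect_equal(rc2$mean_rank["B", "g1"], (1 + mean(3:5)) / 2)

  # permutation invariance over the bootstrap list
  rc3 <- rank_combine(list(m2, m1))
  expect_equal(rc2$network, rc3$network)

  # self pairs never appear
  expect_false(any(rc2$network$tf == rc2$network$gene))

  expect_error(rank_combine(list(m1, m1[, c(2, 1, 3)])), "mismatched")
})

test_that("bootstrap ensembles are seeded, reproducible, and support-consistent", {
  sim <- standard_sim(seed = 4)
  f1 <- grn_infer(sim$dataset, half_life = 0.75, n_boot = 4, seed = 77)
  f2 <- grn_infer(sim$dataset, half_life = 0.75, n_boot = 4, seed = 77)
  expect_equal(f1$network, f2$network)
  expect_equal(f1$s_matrices, f2$s_matrices)

  f3 <- grn_infer(sim$dataset, half_life = 0.75, n_boot = 4, seed = 78)
  expect_false(isTRUE(all.equal(f1$network, f3$network)))

  # no-resample mode: every replicate equals the full-data run
  f4 <- grn_infer(sim$dataset, half_life = 0.75, n_boot = 2, seed = 5,
                  resample = FALSE)
  expect_equal(f4$s_matrices[[1]], f4$s_matrices[[2]])
  expect_equal(f4$s_matrices[[1]], f4$full_scores)

  # confidence respects model support
  pos <- f1$s_matrices[[1]] > 0
  expect_true(all(f1$selection_count[pos] >= 1))
})

test_that("fitted model objects expose the usual accessors", {
  sim <- standard_sim(seed = 8)
  fit <- grn_infer(sim$dataset, priors = sim$gold, half_life = 0.75,
                   n_boot = 3, seed = 12)
  expect_s3_class(fit, "grn_fit")
  expect_output(print(fit), "Regulatory network fit")
  expect_output(print(summary(fit)), "Top edges")

  B <- coef(fit)
  expect_equal(dim(B), c(10, 20))
  yhat <- fitted(fit)
  expect_equal(dim(yhat), dim(fit$design$response))
  expect_equal(residuals(fit) + yhat, fit$design$response)
  expect_equal(predict(fit), yhat)
  pred <- predict(fit, sim$dataset)
  expect_equal(dim(pred), dim(yhat))

  net <- fit$network
  expect_identical(names(net),
                   c("tf", "gene", "combined_score", "mean_rank", "sign"))
  expect_equal(nrow(net), 10 * 20 - 10)
  expect_false(is.unsorted(net$mean_rank))
  expect_true(all(net$sign %in% c(-1, 0, 1)))

  dir <- withr::local_tempdir()
  f <- file.path(dir, "net.tsv")
  write_network(fit, f)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(net))
  expect_equal(back$combined_score, net$combined_score)

  pdf(NULL)
  on.exit(dev.off(), add = TRUE)
  expect_silent(plot(fit))
  pr <- plot(fit, gold = sim$gold)
  expect_s3_class(pr, "grn_pr")
})
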