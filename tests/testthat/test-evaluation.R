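gold2 <- function() {
  matrix(c(1, 0, 0, 1), 2, 2,
         dimnames = list(c("A", "B"), c("g1", "g2")))
}

ranked <- function(tf, gene) {
  data.frame(tf = tf, gene = gene,
             combined_score = rev(seq_along(tf)),
             stringsAsFactors = FALSE)
}

test_that("AUPR walks the list with step-wise summation", {
  g <- gold2()
  # all gold first -> perfect score
  r <- ranked(c("A", "B", "A", "B"), c("g1", "g2", "g2", "g1"))
  expect_equal(aupr(r, g)$aupr, 1)

  # gold hits at positions 3 and 4 of a 4-pair universe:
  # aupr = 0.5 * (1/3) + 0.5 * (2/4)
  r5 <- ranked(c("A", "B", "B", "A"), c("g2", "g1", "g2", "g1"))
  pr5 <- aupr(r5, g)
  expect_equal(pr5$n_eval, 4)
  expect_equal(pr5$n_gold, 2)
  expect_equal(pr5$aupr, 0.5 * (1 / 3) + 0.5 * (2 / 4))

  # a first hit at position 2 has precision 1/2
  r <- ranked(c("B", "A", "A", "B"), c("g1", "g1", "g2", "g2"))
  expect_equal(aupr(r, g)$precision[2], 0.5)
})

test_that("AUPR matches an independent step-sum on random rankings", {
  # independent oracle: direct cumulative computation over a permutation
  oracle <- function(hits, n_gold) {
    tp <- cumsum(hits)
    sum(diff(c(0, tp / n_gold)) * (tp / seq_along(tp)))
  }
  set.seed(8)
  tfs <- paste0("T", 1:3)
  genes <- paste0("g", 1:4)
  for (rep in 1:25) {
    gold <- matrix(rbinom(12, 1, 0.4), 3, 4,
                   dimnames = list(tfs, genes))
    if (sum(gold) == 0) next
    u_tf <- rownames(gold)[rowSums(gold) > 0]
    u_g <- colnames(gold)[colSums(gold) > 0]
    pairs <- expand.grid(tf = u_tf, gene = u_g,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$tf != pairs$gene, ]
    ord <- sample(nrow(pairs))
    r <- data.frame(tf = pairs$tf[ord], gene = pairs$gene[ord],
                    combined_score = rev(seq_len(nrow(pairs))))
    expected <- oracle(gold[cbind(r$tf, r$gene)] == 1, sum(
      gold[cbind(pairs$tf, pairs$gene)]))
    expect_equal(aupr(r, gold)$aupr, expected)
  }
})

test_that("evaluation restricts to gold-active TFs and genes", {
  gold <- matrix(0, 3, 3, dimnames = list(paste0("T", 1:3),
                                          paste0("g", 1:3)))
  gold["T1", "g1"] <- 1
  gold["T2", "g2"] <- 1
  # T3 and g3 have no gold edges: pairs involving them are not evaluated
  r <- ranked(c("T3", "T1", "T2"), c("g1", "g1", "g2"))
  pr <- aupr(r, gold)
  expect_equal(pr$n_eval, 4)  # {T1,T2} x {g1,g2}
  expect_equal(pr$n_gold, 2)

  expect_error(aupr(r, gold * 0), "universe|gold")
})

test_that("unranked universe pairs are appended so recall reaches 1", {
  gold <- gold2()
  r <- ranked("A", "g1")  # ranking covers one of four pairs
  pr <- aupr(r, gold, seed = 3)
  expect_equal(length(pr$recall), 4)
  expect_equal(pr$recall[length(pr$recall)], 1)
})

test_that("leave-out evaluation removes prior pairs from the universe", {
  gold <- gold2()
  pki0 <- gold * 0
  r <- ranked(c("A", "B", "B", "A"), c("g1", "g2", "g1", "g2"))
  expect_equal(leave_out_aupr(r, gold, pki0)$aupr, aupr(r, gold)$aupr)

  pki <- gold * 0
  pki["A", "g1"] <- 1
  lo <- leave_out_aupr(r, gold, pki)
  expect_equal(lo$n_gold, 1)
  expect_equal(lo$n_eval, 3)

  expect_error(leave_out_aupr(r, gold, gold), "empty")
})

test_that("prior corruption hits the published ratios", {
  set.seed(1)
  gold <- matrix(0, 10, 120, dimnames = list(
    sprintf("T%02d", 1:10), sprintf("g%03d", 1:120)))
  gold[sample(length(gold), 100)] <- 1
  diag_pairs <- intersect(rownames(gold), colnames(gold))
  gold[cbind(diag_pairs, diag_pairs)] <- 0
  n_gold <- sum(gold)

  pri <- corrupt_priors(gold, tpi_fraction = 0.5, fpi_ratio = 10,
                        seed = 42)
  tpi <- attr(pri, "tpi")
  fpi <- attr(pri, "fpi")
  expect_equal(nrow(tpi), round(0.5 * n_gold))
  expect_equal(nrow(fpi), 10 * nrow(tpi))
  expect_equal(attr(pri, "erroneous_fraction"), 10 / 11)
  # FPIs never overlap the gold standard
  expect_true(all(gold[cbind(fpi$tf, fpi$gene)] == 0))
  # TPIs are gold edges
  expect_true(all(gold[cbind(tpi$tf, tpi$gene)] == 1))

  # ratio 1:0 -> TPIs only
  p0 <- corrupt_priors(gold, 0.5, 0, seed = 7)
  expect_equal(sum(p0), round(0.5 * n_gold))
  expect_true(all(gold[p0 == 1] == 1))

  # determinism
  expect_identical(corrupt_priors(gold, 0.5, 2, seed = 9),
                   corrupt_priors(gold, 0.5, 2, seed = 9))

  # impossible request
  small <- matrix(1, 2, 3, dimnames = list(c("A", "B"),
                                           c("g1", "g2", "g3")))
  expect_error(corrupt_priors(small, 1, 10, seed = 1), "not enough")
})

test_that("the naive ranking is perfect priors-first, random otherwise", {
  gold <- gold2()
  expect_equal(aupr(naive_prior_ranking(gold, gold, seed = 2),
                    gold)$aupr, 1)

  # empty priors: expected AUPR near prevalence over many seeds (a
  # large universe keeps the small-sample upward bias of random-ranking
  # AUPR negligible)
  set.seed(77)
  gold_big <- matrix(0, 10, 30, dimnames = list(
    paste0("T", 1:10), paste0("g", 1:30)))
  gold_big[sample(length(gold_big), 28)] <- 1
  prev_universe <- pr_universe_size <- {
    u_tf <- rownames(gold_big)[rowSums(gold_big) > 0]
    u_g <- colnames(gold_big)[colSums(gold_big) > 0]
    pairs <- expand.grid(tf = u_tf, gene = u_g,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$tf != pairs$gene, ]
    sum(gold_big[cbind(pairs$tf, pairs$gene)]) / nrow(pairs)
  }
  empty <- gold_big * 0
  as <- vapply(1:200, function(s)
    aupr(naive_prior_ranking(empty, gold_big, seed = s), gold_big,
         seed = s)$aupr, numeric(1))
  se <- sd(as) / sqrt(length(as))
  expect_lt(abs(mean(as) - prev_universe), 3 * se + 0.02)
  expect_true(all(as >= 0 & as <= 1))
})

test_that("prior subsampling is exact and reproducible", {
  gold <- matrix(0, 10, 10, dimnames = list(
    paste0("T", 1:10), paste0("x", 1:10)))
  set.seed(3)
  gold[sample(100, 40)] <- 1
  n_gold <- sum(gold)

  sets <- subsample_priors(gold, fractions = c(0.2, 1), reps = 2,
                           seed = 11)
  expect_equal(sum(sets[["0.2"]][[1]]), round(0.2 * n_gold))
  expect_equal(sum(sets[["1"]][[1]]), n_gold)
  expect_true(all(gold[sets[["0.2"]][[2]] == 1] == 1))

  sets2 <- subsample_priors(gold, fractions = c(0.2, 1), reps = 2,
                            seed = 11)
  expect_identical(sets, sets2)
  expect_false(identical(sets[["0.2"]][[1]], sets[["0.2"]][[2]]))
})

test_that("more true priors never hurt overall performance", {
  fracs <- c(0, 0.4, 0.8)
  med <- sapply(fracs, function(f) {
    median(sapply(1:3, function(s) {
      sim <- standard_sim(seed = s)
      pki <- if (f == 0) NULL else
        subsample_priors(sim$gold, fractions = f, reps = 1,
                         seed = s)[[as.character(f)]][[1]]
      fit <- grn_infer(sim$dataset, priors = pki, weight = 1.26,
                       half_life = 0.75, n_boot = 10, seed = s + 60)
      aupr(fit, sim$gold)$aupr
    }))
  })
  expect_true(all(diff(med) > -0.02))
})
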