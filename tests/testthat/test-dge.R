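# Brute-force oracle for the conditional pmf: iterative product, no
# log-gamma, independent of the package's log-space path.
ac_pmf_bruteforce <- function(y, x, N1, N2) {
  r <- N2 / N1
  p <- (1 / (1 + r))^(x + 1)
  if (y > 0) for (i in seq_len(y)) p <- p * (x + i) / i * r / (1 + r)
  p
}

ac_two_sided_bruteforce <- function(x, y, N1, N2) {
  S <- sum(vapply(0:y, ac_pmf_bruteforce, numeric(1), x = x, N1 = N1, N2 = N2))
  p <- if (S <= 0.5) 2 * S else 2 * (1 - S + ac_pmf_bruteforce(y, x, N1, N2))
  min(p, 1)
}

test_that("conditional pmf matches exact-rational anchor values", {
  # frozen from an arbitrary-precision rational evaluation of the formula
  anchors <- list(
    list(x = 0, y = 0, N1 = 1, N2 = 1, p = 0.5),
    list(x = 1, y = 1, N1 = 1, N2 = 1, p = 0.25),
    list(x = 5, y = 12, N1 = 1e6, N2 = 2e6, p = 6.54225801671527024e-02),
    list(x = 3, y = 7, N1 = 2, N2 = 1, p = 1.08384561973953828e-02),
    list(x = 20, y = 35, N1 = 1, N2 = 1, p = 7.00880034512914307e-03),
    list(x = 50, y = 50, N1 = 1e6, N2 = 5e5, p = 1.46938960089859741e-04)
  )
  for (a in anchors)
    expect_equal(ac_pmf(a$y, a$x, a$N1, a$N2), a$p, tolerance = 1e-13)
})

test_that("pmf agrees with the brute-force oracle and dnbinom over x,y <= 50", {
  for (ratio in c(0.5, 1, 2)) {
    N1 <- 1e6; N2 <- ratio * 1e6
    xy <- expand.grid(x = 0:50, y = 0:50)
    mine <- ac_pmf(xy$y, xy$x, N1, N2)
    oracle <- mapply(ac_pmf_bruteforce, xy$y, xy$x, N1, N2)
    expect_equal(mine, oracle, tolerance = 1e-12)
    # independent distribution identity: NB(size = x + 1, prob = N1/(N1+N2))
    nb <- dnbinom(xy$y, size = xy$x + 1, prob = N1 / (N1 + N2))
    expect_equal(mine, nb, tolerance = 1e-12)
  }
})

test_that("pmf normalizes to 1 over y and is symmetric at equal depth", {
  for (x in c(0, 1, 10, 100)) {
    ymax <- 20 * (x + 10)  # tail beyond this is negligible
    expect_equal(sum(ac_pmf(0:ymax, x, 1e6, 1e6)), 1, tolerance = 1e-9)
  }
  xy <- expand.grid(x = 0:30, y = 0:30)
  expect_equal(ac_pmf(xy$y, xy$x, 1e7, 1e7), ac_pmf(xy$x, xy$y, 1e7, 1e7))
})

test_that("pmf is stable for large counts and deep libraries", {
  p <- ac_pmf(1e6, 1e6, 1e9, 1e9)
  expect_true(is.finite(p) && p > 0 && p <= 1)
  p2 <- ac_two_sided_p(1e6, 999000, 1e9, 1e9)
  expect_true(is.finite(p2) && p2 > 0 && p2 <= 1)
})

test_that("two-sided p matches direct tail summation and boundary cases", {
  expect_equal(ac_two_sided_p(0, 0, 1e6, 1e6), 1.0)
  # frozen from an exact-rational summation of the pmf
  expect_equal(ac_two_sided_p(10, 40, 1e6, 1e6), 2.3861331676755526e-05,
               tolerance = 1e-12)
  cases <- data.frame(x = c(10, 5, 100, 0, 7), y = c(40, 12, 80, 3, 7),
                      ratio = c(1, 2, 1, 1, 0.5))
  for (i in seq_len(nrow(cases))) {
    N1 <- 1e6; N2 <- cases$ratio[i] * 1e6
    expect_equal(ac_two_sided_p(cases$x[i], cases$y[i], N1, N2),
                 ac_two_sided_bruteforce(cases$x[i], cases$y[i], N1, N2),
                 tolerance = 1e-10)
  }
  expect_true(all(ac_two_sided_p(0:50, 50:0, 1e6, 1e6) <= 1))
})

test_that("invalid AC inputs are rejected", {
  expect_error(ac_pmf(-1, 0, 1e6, 1e6), "non-negative")
  expect_error(ac_pmf(1.5, 0, 1e6, 1e6), "integral")
  expect_error(ac_two_sided_p(1, 1, 0, 1e6), "positive")
})

test_that("FDR adjustment follows the step-up rule and BY dominates BH", {
  expect_equal(adjust_fdr(0.03, method = "BH"), 0.03)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  # order preservation
  p <- c(0.04, 0.01, 0.03, 0.02)
  expect_equal(adjust_fdr(p, "BH"), p.adjust(p, "BH"))
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    bh <- adjust_fdr(p, "BH"); by <- adjust_fdr(p, "BY")
    expect_true(all(by >= bh - 1e-15))
    expect_true(all(bh >= p - 1e-15))
  }
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("DEG calling applies both inclusive gates and assigns direction", {
  tbl <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    log2_ratio = c(1.5, 0.5, 3.0, -2.0, 1.0),
                    p_adjusted = c(0.0005, 0.0005, 0.005, 0.001, 0.001))
  out <- call_degs(tbl)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(out$direction, c("up", "none", "none", "down", "up"))
})

test_that("stage summaries add up and handle empty comparisons", {
  mk <- function(up, down) data.frame(
    significant = rep(c(TRUE, TRUE, FALSE), c(up, down, 3)),
    direction = rep(c("up", "down", "none"), c(up, down, 3)))
  s <- summarize_stage_counts(list(a = mk(5, 2), b = mk(0, 0)))
  expect_equal(s$total, s$up + s$down)
  expect_equal(s$up, c(5, 0))
  expect_equal(s$down, c(2, 0))
})

test_that("planted DE genes are recovered with high sensitivity and low FDP", {
  cfg <- synthetic_config(n_genes = 20000,
                          library_sizes = c(FCP = 1e7, AP = 1e7),
                          de_fraction = 0.05, effect_sizes = c(-2, 2),
                          dispersion = 0, seed = 11)
  sim <- simulate_de_experiment(cfg)
  res <- dge_test(sim$counts, sim$profiles, "FCP", "AP")
  planted <- sim$truth$log2fc != 0
  sens <- mean(res$significant[planted])
  fdp <- sum(res$significant & !planted) / max(1, sum(res$significant))
  expect_gte(sens, 0.9)
  expect_lte(fdp, 0.01)
  # direction matches the planted sign for recovered genes
  hit <- res$significant & planted
  expect_true(all(sign(sim$truth$log2fc[hit]) ==
                    ifelse(res$direction[hit] == "up", 1, -1)))
})

test_that("dge_test rejects undeclared libraries", {
  cfg <- synthetic_config(n_genes = 50, seed = 2)
  sim <- simulate_de_experiment(cfg)
  expect_error(dge_test(sim$counts, sim$profiles, "FCP", "SGP"),
               "not declared")
})
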