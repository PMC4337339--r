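test_that("config validation names the offending field", {
  expect_error(synthetic_config(n_genes = 5), "n_genes")
  expect_error(synthetic_config(de_fraction = 1.5), "de_fraction")
  expect_error(synthetic_config(library_sizes = c(FCP = 1e3, AP = 1e7)),
               "library_sizes")
  expect_error(synthetic_config(dispersion = -1), "dispersion")
})

test_that("two-library simulation is deterministic and honours the null", {
  cfg <- synthetic_config(n_genes = 200, seed = 4, de_fraction = 0)
  a <- simulate_de_experiment(cfg)
  b <- simulate_de_experiment(cfg)
  expect_identical(a, b)
  expect_true(all(a$truth$log2fc == 0))
  expect_true(all(a$truth$gene_id %in% a$counts$gene_id))
  cfg2 <- synthetic_config(n_genes = 200, seed = 5, de_fraction = 0.2)
  expect_false(identical(simulate_de_experiment(cfg2)$counts, a$counts))
})

test_that("overdispersion inflates count variance beyond Poisson", {
  base <- synthetic_config(n_genes = 4000, library_sizes = c(FCP = 1e6, AP = 1e6),
                           de_fraction = 0, seed = 8)
  over <- base; over$dispersion <- 0.5
  x_p <- simulate_de_experiment(base)$counts
  x_o <- simulate_de_experiment(over)$counts
  # pooled index of dispersion across the two library draws per gene
  iod <- function(ct) {
    m <- (ct$FCP + ct$AP) / 2
    keep <- m > 50
    mean(((ct$FCP - ct$AP)^2 / 2)[keep] / m[keep])
  }
  expect_lt(iod(x_p), 2)
  expect_gt(iod(x_o), 5)
})

test_that("null AC p-values are calibrated and uniform for randomized tails", {
  cfg <- synthetic_config(n_genes = 20000,
                          library_sizes = c(FCP = 1e7, AP = 1e7),
                          de_fraction = 0, dispersion = 0, seed = 17)
  sim <- simulate_de_experiment(cfg)
  x <- sim$counts$FCP; y <- sim$counts$AP
  p <- ac_two_sided_p(x, y, 1e7, 1e7)
  frac <- mean(p <= 0.05)
  se <- sqrt(0.05 * 0.95 / length(p))
  expect_lt(abs(frac - 0.05), 3 * se)
  # uniformity via randomized p-values, the standard device for discrete
  # statistics (the raw doubling rule has an atom at p = 1)
  set.seed(18)
  S_below <- ifelse(y > 0, pbeta(0.5, x + 1, pmax(y, 1)), 0)
  Sr <- S_below + runif(length(x)) * ac_pmf(y, x, 1e7, 1e7)
  p_rand <- 2 * pmin(Sr, 1 - Sr)
  ks <- suppressWarnings(ks.test(p_rand, "punif"))
  expect_gt(ks$p.value, 0.01)
  # raw p-values are flat away from the discrete atom
  dec <- table(cut(p[p < 0.9], seq(0, 0.9, 0.1))) / sum(p < 0.9)
  expect_true(all(abs(dec - 1 / 9) < 0.01))
})

test_that("biofilm scenario plants the reported truth", {
  scen <- simulate_biofilm_scenario(seed = 1)
  scen2 <- simulate_biofilm_scenario(seed = 1)
  expect_identical(scen, scen2)

  expect_equal(unname(truth_lfc(scen$truth, "Flo11", "FCP_vs_AP")), log2(6.8))
  expect_equal(unname(truth_lfc(scen$truth, "Flo11", "FCP_vs_SGP")), log2(5.0))
  expect_equal(unname(truth_lfc(scen$truth, "Flo11", "FCP_vs_BMP")), log2(18.4))
  expect_equal(unname(truth_lfc(scen$truth, "Fbp1", "FCP_vs_AP")), log2(239))
  expect_equal(unname(truth_lfc(scen$truth, "Pck1", "FCP_vs_AP")), log2(555))
  expect_equal(unname(truth_lfc(scen$truth, "Bsc1", "FCP_vs_AP")), -log2(42))
  expect_equal(unname(truth_lfc(scen$truth, "Mig1", "FCP_vs_AP")), -log2(26))
  expect_error(truth_lfc(scen$truth, "NoSuchGene", "FCP_vs_AP"), "unknown gene")

  # annotation universe holds exactly 2143 genes; planted categories match
  # the enrichment contingencies at the attachment comparison
  expect_length(scen$annotation$universe, 2143)
  expect_length(scen$annotation$categories$ko00020, 32)
  expect_length(scen$annotation$categories$ko00010, 55)
  lfc_ap <- truth_lfc(scen$truth, scen$annotation$universe, "FCP_vs_AP")
  expect_equal(sum(lfc_ap[scen$annotation$categories$ko00020] != 0), 26)
  expect_equal(sum(lfc_ap[scen$annotation$categories$ko00010] != 0), 37)
  expect_equal(sum(lfc_ap != 0), 648)
  expect_true(all(unlist(scen$truth$enriched_categories) %in%
                    names(scen$annotation$categories)))

  # planted per-comparison up/down totals follow the reported summaries
  tl <- scen$truth$log2fc
  expect_equal(c(sum(tl$FCP_vs_AP > 0), sum(tl$FCP_vs_AP < 0)), c(522, 1576))
  expect_equal(c(sum(tl$FCP_vs_SGP > 0), sum(tl$FCP_vs_SGP < 0)), c(511, 1045))
  expect_equal(c(sum(tl$FCP_vs_BMP > 0), sum(tl$FCP_vs_BMP < 0)), c(472, 455))
})

test_that("FASTQ simulation is byte-identical under a seed and label-exact", {
  a <- simulate_fastq(300, contamination = c(adapter = 0.1, n_rich = 0.1,
                                             lowqual = 0.1), seed = 3)
  b <- simulate_fastq(300, contamination = c(adapter = 0.1, n_rich = 0.1,
                                             lowqual = 0.1), seed = 3)
  expect_identical(a, b)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_fastq(a$reads, p1); write_fastq(b$reads, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_error(simulate_fastq(100, contamination = c(adapter = 0.6,
                                                     n_rich = 0.6)),
               "sum to <= 1")
  expect_error(simulate_fastq(100, read_length = 10), "read_length")
  # zero contamination: the QC stage passes every read
  clean <- simulate_fastq(200, seed = 6)
  res <- filter_fastq(clean$reads,
                      qc_thresholds(adapter_sequences = clean$adapter))
  expect_equal(res$report$clean_reads, 200)
})

test_that("qPCR simulation recovers planted fold changes", {
  truth <- structure(list(log2fc = data.frame(
    gene_id = c("flat", "eight"), FCP_vs_AP = c(0, 3),
    stringsAsFactors = FALSE)), class = "synthetic_truth")
  ct0 <- simulate_qpcr(truth, c("flat", "eight"), noise_sd = 0, seed = 1)
  fc <- qpcr_fold_changes(ct0)
  expect_equal(fc$fold_change[fc$gene_id == "flat"], 1)
  expect_equal(fc$fold_change[fc$gene_id == "eight"], 8)
  expect_error(simulate_qpcr(truth, "missing_gene", seed = 1), "unknown gene")
  expect_error(simulate_qpcr(truth, "flat", noise_sd = -1), "noise_sd")

  # six planted genes at realistic noise: concordance with the truth
  scen <- simulate_biofilm_scenario(seed = 1)
  panel <- c("Flo11", "Fbp1", "Pck1", "Hsp12", "Mig1", "Gut1")
  ct <- simulate_qpcr(scen$truth, panel, noise_sd = 0.1, seed = 2)
  rec <- qpcr_fold_changes(ct)
  planted <- truth_lfc(scen$truth, panel, "FCP_vs_AP")
  r <- cor(planted[rec$gene_id], rec$log2_fold_change)
  expect_gte(r, 0.95)
})
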