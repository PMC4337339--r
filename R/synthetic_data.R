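# Synthetic staged-biofilm data generator. Every input the pipeline
# consumes -- count libraries with planted truth, annotation maps,
# contaminated FASTQ reads, qPCR Ct tables -- is produced here under a
# single seed, so downstream stages are testable without external data.

#' Configuration for a two-library synthetic DGE experiment
#'
#' @param n_genes Number of genes (>= 10).
#' @param library_sizes Named numeric vector mapping stage label to total
#'   uniquely mapped reads N (each >= 1e4); exactly two entries.
#' @param gene_length_law List with \code{meanlog}, \code{sdlog},
#'   \code{min} for log-normal transcript lengths in nt (min 100).
#' @param baseline_expression_law List with \code{sdlog}: log-normal
#'   relative-abundance dispersion (long-tailed so a realistic RPKM
#'   dynamic range arises).
#' @param de_fraction Fraction of genes planted as differentially
#'   expressed, in [0, 1].
#' @param effect_sizes Numeric set of planted log2 fold changes sampled
#'   uniformly for DE genes.
#' @param dispersion Overdispersion of the gamma-mixed Poisson count law;
#'   0 (default) gives pure Poisson.
#' @param seed Integer seed; identical seed and config give bit-identical
#'   outputs.
#' @return An object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_genes = 6000,
                             library_sizes = c(FCP = 1e7, AP = 1e7),
                             gene_length_law = list(meanlog = log(1300),
                                                    sdlog = 0.45, min = 100),
                             baseline_expression_law = list(sdlog = 1.2),
                             de_fraction = 0.1,
                             effect_sizes = c(-2, 2),
                             dispersion = 0,
                             seed = 1) {
  if (n_genes < 10)
    stop("n_genes must be >= 10", call. = FALSE)
  if (length(library_sizes) != 2 || is.null(names(library_sizes)))
    stop("library_sizes must be a named vector of two stage totals",
         call. = FALSE)
  if (any(library_sizes < 1e4))
    stop("library_sizes entries must be >= 1e4", call. = FALSE)
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must lie in [0, 1]", call. = FALSE)
  if (dispersion < 0)
    stop("dispersion must be >= 0", call. = FALSE)
  if (gene_length_law$min < 100)
    stop("gene_length_law$min must be >= 100", call. = FALSE)
  structure(list(n_genes = n_genes, library_sizes = library_sizes,
                 gene_length_law = gene_length_law,
                 baseline_expression_law = baseline_expression_law,
                 de_fraction = de_fraction, effect_sizes = effect_sizes,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Draw counts with expected value mu, optionally gamma-mixed for
# overdispersion (variance mu + dispersion * mu^2).
draw_counts <- function(mu, dispersion) {
  if (dispersion > 0) {
    shape <- 1 / dispersion
    mu <- mu * rgamma(length(mu), shape = shape, rate = shape)
  }
  rpois(length(mu), mu)
}

#' Simulate a two-library tag-count experiment with planted fold changes
#'
#' Gene lengths and baseline relative abundances are drawn from the
#' configured laws; expected tag counts are length-weighted abundance
#' fractions times the library total, and counts are Poisson (or
#' gamma-Poisson when \code{dispersion > 0}) around them. A planted DE
#' gene's expected count in the second library is multiplied by
#' \code{2^log2fc}; library totals are supplied constants and are not
#' re-normalized, so planted effects are exact in expectation.
#'
#' @param config A [synthetic_config()].
#' @return List with \code{counts} (count table), \code{profiles}
#'   (library profiles) and \code{truth} (data.frame \code{gene_id},
#'   \code{log2fc} over all genes; zero for non-DE genes).
#' @export
simulate_de_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_genes
  stages <- names(config$library_sizes)
  gene_id <- sprintf("g%05d", seq_len(n))

  len <- pmax(config$gene_length_law$min,
              round(rlnorm(n, config$gene_length_law$meanlog,
                           config$gene_length_law$sdlog)))
  ab <- rlnorm(n, 0, config$baseline_expression_law$sdlog)
  frac <- ab * len
  frac <- frac / sum(frac)

  lfc <- numeric(n)
  n_de <- round(config$de_fraction * n)
  if (n_de > 0) {
    idx <- sample.int(n, n_de)
    lfc[idx] <- sample(config$effect_sizes, n_de, replace = TRUE)
  }

  N1 <- unname(config$library_sizes[1])
  N2 <- unname(config$library_sizes[2])
  x <- draw_counts(N1 * frac, config$dispersion)
  y <- draw_counts(N2 * frac * 2^lfc, config$dispersion)

  counts <- data.frame(gene_id = gene_id, length_nt = len,
                       stringsAsFactors = FALSE)
  counts[[stages[1]]] <- x
  counts[[stages[2]]] <- y
  profiles <- library_profiles(stages, stages, c(N1, N2))
  truth <- data.frame(gene_id = gene_id, log2fc = lfc,
                      stringsAsFactors = FALSE)
  list(counts = counts, profiles = profiles, truth = truth)
}

# Sentinel genes planted with the fold changes reported for staged yeast
# biofilm development (test stage vs free cells; negative = down).
biofilm_sentinels <- function() {
  data.frame(
    gene_id  = c("Flo11", "Fbp1", "Pck1", "Hsp12", "Gut1",
                 "Bsc1", "Mig1", "Tec1", "Kss1"),
    baseline = c(500, 300, 300, 400, 600, 3000, 2000, 800, 1200),
    AP  = log2(c(6.8, 239, 555, 181, 6.6, 1 / 42, 1 / 26, 2, 1 / 3)),
    SGP = log2(c(5.0, 1, 1, 49, 1.4, 1 / 4, 1, 1, 1)),
    BMP = log2(c(18.4, 1, 1, 13, 2.3, 1 / 3, 1, 1, 1)),
    stringsAsFactors = FALSE
  )
}

#' Simulate the four-stage biofilm scenario with planted truth
#'
#' Builds one library per stage (FCP, AP, SGP, BMP; free cells are the
#' reference) around a shared baseline, plants nine sentinel genes with
#' the fold changes reported for staged biofilm development (e.g. Flo11
#' up 6.8/5.0/18.4-fold, Fbp1 239-fold and Pck1 555-fold up at
#' attachment, Bsc1 42/4/3-fold down, Mig1 26-fold down at attachment),
#' and plants generic DE genes so each comparison against free cells
#' reaches the reported up/down totals (522/1576 at AP, 511/1045 at SGP,
#' 472/455 at BMP). The annotation universe holds exactly 2143 genes; a
#' 32-gene TCA-cycle-like category with 26 of its genes planted DE at AP
#' and a 55-gene glycolysis/gluconeogenesis-like category with 37 planted
#' DE at AP reproduce the enrichment contingencies, with the attachment
#' comparison carrying 648 annotated DE genes in total.
#'
#' @param seed Integer seed.
#' @param n_genes Total genes (default 6000, yeast-genome scale).
#' @param library_size Total uniquely mapped reads per stage library.
#' @param dispersion Overdispersion knob passed to the count draws.
#' @return List with \code{counts}, \code{profiles}, \code{annotation}
#'   (an [annotation_set()]) and \code{truth} (class
#'   \code{synthetic_truth}: \code{log2fc} data.frame with one column per
#'   comparison, \code{enriched_categories} list keyed by comparison).
#' @export
simulate_biofilm_scenario <- function(seed = 1, n_genes = 6000,
                                      library_size = 1e7, dispersion = 0) {
  set.seed(seed)
  sent <- biofilm_sentinels()
  stages <- c("FCP", "AP", "SGP", "BMP")
  comparisons <- c("FCP_vs_AP", "FCP_vs_SGP", "FCP_vs_BMP")

  n_other <- n_genes - nrow(sent)
  other_id <- sprintf("g%05d", seq_len(n_other))
  gene_id <- c(sent$gene_id, other_id)

  len <- pmax(100, round(rlnorm(n_genes, log(1300), 0.45)))
  ab <- rlnorm(n_genes, 0, 1.2)
  frac <- ab * len
  frac <- frac / sum(frac)
  # pin sentinel expected FCP counts to solid baselines, then renormalize
  # the remainder so abundances still sum to one
  sent_frac <- sent$baseline / library_size
  frac[seq_len(nrow(sent))] <- 0
  frac <- frac / sum(frac) * (1 - sum(sent_frac))
  frac[seq_len(nrow(sent))] <- sent_frac

  # annotation universe: 2143 genes, including the two gluconeogenesis
  # sentinels; categories mirror the enrichment contingencies at AP
  universe <- c("Fbp1", "Pck1", other_id[seq_len(2141)])
  tca_genes <- other_id[1:32]
  gly_genes <- c("Fbp1", "Pck1", other_id[33:85])
  cats <- list(ko00020 = tca_genes, ko00010 = gly_genes)
  desc <- c(ko00020 = "Citrate cycle (TCA cycle)",
            ko00010 = "Glycolysis / Gluconeogenesis")
  pool <- other_id[seq_len(2141)]
  for (i in seq_len(28)) {
    id <- sprintf("bg%02d", i)
    cats[[id]] <- sample(pool, sample(10:120, 1))
    desc[id] <- sprintf("background category %02d", i)
  }
  annotation <- annotation_set(cats, universe = universe,
                               descriptions = desc)

  # planted log2fc, one column per comparison vs free cells
  lfc <- matrix(0, n_genes, 3, dimnames = list(gene_id, comparisons))
  lfc[sent$gene_id, ] <- as.matrix(sent[, c("AP", "SGP", "BMP")])

  cat_de_ap <- c(tca_genes[1:26], "Fbp1", "Pck1", setdiff(gly_genes, c("Fbp1", "Pck1"))[1:35])
  rand_lfc <- function(k, sign) sign * runif(k, 1.5, 3.5)
  lfc[cat_de_ap[!cat_de_ap %in% sent$gene_id], "FCP_vs_AP"] <-
    rand_lfc(sum(!cat_de_ap %in% sent$gene_id), +1)

  # generic DE to reach the reported per-comparison up/down totals
  targets <- list(FCP_vs_AP = c(up = 522, down = 1576),
                  FCP_vs_SGP = c(up = 511, down = 1045),
                  FCP_vs_BMP = c(up = 472, down = 455))
  for (cmp in comparisons) {
    planted <- lfc[, cmp] != 0
    need_up <- targets[[cmp]]["up"] - sum(lfc[planted, cmp] > 0)
    need_down <- targets[[cmp]]["down"] - sum(lfc[planted, cmp] < 0)
    free <- gene_id[!planted]
    if (cmp == "FCP_vs_AP") {
      # keep the annotated-DEG draw at 648 (63 category DEGs + 585 more)
      # and the category contingencies at exactly 26/32 and 37/55
      free_univ <- setdiff(intersect(free, universe),
                           c(tca_genes, gly_genes))
      free_out <- setdiff(free, universe)
      extra_annot <- sample(free_univ, 585)
      extra_out <- sample(free_out, need_up + need_down - 585)
      chosen <- sample(c(extra_annot, extra_out))
    } else {
      chosen <- sample(free, need_up + need_down)
    }
    ups <- chosen[seq_len(need_up)]
    downs <- setdiff(chosen, ups)
    lfc[ups, cmp] <- rand_lfc(length(ups), +1)
    lfc[downs, cmp] <- rand_lfc(length(downs), -1)
  }

  counts <- data.frame(gene_id = gene_id, length_nt = len,
                       stringsAsFactors = FALSE)
  counts$FCP <- draw_counts(library_size * frac, dispersion)
  for (cmp in comparisons) {
    stage <- sub("FCP_vs_", "", cmp)
    counts[[stage]] <- draw_counts(library_size * frac * 2^lfc[, cmp],
                                   dispersion)
  }
  profiles <- library_profiles(stages, stages, rep(library_size, 4))

  truth <- structure(list(
    log2fc = data.frame(gene_id = gene_id, lfc,
                        stringsAsFactors = FALSE, row.names = NULL),
    enriched_categories = list(FCP_vs_AP = c("ko00020", "ko00010"),
                               FCP_vs_SGP = character(),
                               FCP_vs_BMP = character())
  ), class = "synthetic_truth")

  list(counts = counts, profiles = profiles, annotation = annotation,
       truth = truth)
}

#' Look up planted log2 fold changes in a synthetic truth table
#'
#' @param truth A \code{synthetic_truth} object.
#' @param genes Gene ids (must exist in the truth table).
#' @param comparison Comparison name, e.g. "FCP_vs_AP".
#' @return Named numeric vector of planted log2 fold changes.
#' @export
truth_lfc <- function(truth, genes, comparison) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!comparison %in% names(truth$log2fc))
    stop("unknown comparison '", comparison, "'", call. = FALSE)
  m <- match(genes, truth$log2fc$gene_id)
  if (anyNA(m))
    stop("unknown gene id: ", paste(genes[is.na(m)], collapse = ", "),
         call. = FALSE)
  setNames(truth$log2fc[[comparison]][m], genes)
}

# default Illumina adapter used by the FASTQ simulator
default_adapter <- function() "AGATCGGAAGAGC"

#' Simulate a FASTQ file with planted contamination classes
#'
#' Generates \code{n_reads} reads of fixed length; a
#' \code{round(n_reads * fraction)} subset of each contamination class is
#' planted: \code{adapter} reads contain the adapter sequence as an exact
#' substring, \code{n_rich} reads carry more than 5\% unknown bases, and
#' \code{lowqual} reads carry more than 30\% bases at Phred <= 10. Clean
#' reads satisfy all QC thresholds by construction (adapter-free by
#' rejection sampling, no N bases, all qualities at Phred >= 30). Read
#' order is shuffled; the returned labels align with the read order.
#'
#' @param n_reads Number of reads.
#' @param read_length Read length in nt (>= 20), default 90.
#' @param contamination Named fractions \code{adapter}, \code{n_rich},
#'   \code{lowqual}; must sum to at most 1.
#' @param seed Integer seed.
#' @param adapter Adapter sequence planted in adapter reads (and screened
#'   out of all others).
#' @param phred_offset 33 (default) or 64.
#' @return List with \code{reads} (data.frame id/seq/qual),
#'   \code{labels} (per-read class: clean/adapter/n_rich/lowqual) and
#'   \code{adapter}.
#' @export
simulate_fastq <- function(n_reads, read_length = 90,
                           contamination = c(adapter = 0, n_rich = 0,
                                             lowqual = 0),
                           seed = 1, adapter = default_adapter(),
                           phred_offset = 33) {
  if (read_length < 20) stop("read_length must be >= 20", call. = FALSE)
  frac <- c(adapter = 0, n_rich = 0, lowqual = 0)
  frac[names(contamination)] <- contamination
  if (sum(frac) > 1)
    stop("contamination fractions must sum to <= 1", call. = FALSE)
  set.seed(seed)

  n_ad <- round(n_reads * frac[["adapter"]])
  n_nr <- round(n_reads * frac[["n_rich"]])
  n_lq <- round(n_reads * frac[["lowqual"]])
  n_cl <- n_reads - n_ad - n_nr - n_lq

  rand_bases <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * read_length, replace = TRUE),
                nrow = k)
    apply(m, 1, paste, collapse = "")
  }
  # adapter-free random reads (rejection sampling keeps determinism)
  clean_bases <- function(k) {
    s <- rand_bases(k)
    repeat {
      hit <- grepl(adapter, s, fixed = TRUE)
      if (!any(hit)) return(s)
      s[hit] <- rand_bases(sum(hit))
    }
  }
  qual_string <- function(k, phreds) {
    m <- matrix(intToUtf8(phred_offset +
                            sample(phreds, k * read_length, replace = TRUE),
                          multiple = TRUE), nrow = k)
    apply(m, 1, paste, collapse = "")
  }
  hi_q <- 30:40
  lo_q <- 2:10

  seqs <- character(0); quals <- character(0); labels <- character(0)
  if (n_cl > 0) {
    seqs <- c(seqs, clean_bases(n_cl))
    quals <- c(quals, qual_string(n_cl, hi_q))
    labels <- c(labels, rep("clean", n_cl))
  }
  if (n_ad > 0) {
    s <- clean_bases(n_ad)
    start <- sample.int(read_length - nchar(adapter) + 1, n_ad, replace = TRUE)
    s <- vapply(seq_len(n_ad), function(i) {
      paste0(substr(s[i], 1, start[i] - 1), adapter,
             substr(s[i], start[i] + nchar(adapter), read_length))
    }, character(1))
    seqs <- c(seqs, s)
    quals <- c(quals, qual_string(n_ad, hi_q))
    labels <- c(labels, rep("adapter", n_ad))
  }
  if (n_nr > 0) {
    s <- clean_bases(n_nr)
    n_N <- max(ceiling(0.06 * read_length), floor(0.05 * read_length) + 1)
    s <- vapply(seq_len(n_nr), function(i) {
      pos <- sample.int(read_length, n_N)
      v <- strsplit(s[i], "", fixed = TRUE)[[1]]
      v[pos] <- "N"
      paste(v, collapse = "")
    }, character(1))
    seqs <- c(seqs, s)
    quals <- c(quals, qual_string(n_nr, hi_q))
    labels <- c(labels, rep("n_rich", n_nr))
  }
  if (n_lq > 0) {
    s <- clean_bases(n_lq)
    n_low <- floor(0.30 * read_length) + 1
    q <- vapply(seq_len(n_lq), function(i) {
      pos <- sample.int(read_length, n_low)
      v <- phred_offset + sample(hi_q, read_length, replace = TRUE)
      v[pos] <- phred_offset + sample(lo_q, n_low, replace = TRUE)
      intToUtf8(v)
    }, character(1))
    seqs <- c(seqs, s)
    quals <- c(quals, q)
    labels <- c(labels, rep("lowqual", n_lq))
  }

  ord <- sample.int(n_reads)
  reads <- data.frame(
    id = sprintf("read_%06d", seq_len(n_reads)),
    seq = seqs[ord], qual = quals[ord],
    stringsAsFactors = FALSE
  )
  list(reads = reads, labels = labels[ord], adapter = adapter)
}

#' Simulate a qPCR Ct table consistent with planted fold changes
#'
#' For each requested gene the target Ct in the test condition is the
#' control Ct minus the planted log2 fold change plus Gaussian noise; the
#' reference gene (18S) Ct is constant across conditions up to the same
#' noise. Three technical replicates are emitted per measurement. At
#' \code{noise_sd = 0} the 2^-ddCt method recovers the planted fold
#' change exactly.
#'
#' @param truth A \code{synthetic_truth} object (from
#'   [simulate_biofilm_scenario()]).
#' @param genes Gene ids present in the truth table.
#' @param noise_sd Ct noise standard deviation in cycles (>= 0).
#' @param seed Integer seed.
#' @param comparison Comparison whose planted fold changes are emulated.
#' @param reference_gene Reference gene id (default "18S").
#' @param n_replicates Technical replicates per measurement.
#' @return A Ct table data.frame (columns \code{sample_id},
#'   \code{condition}, \code{gene_id}, \code{replicate}, \code{ct}).
#' @export
simulate_qpcr <- function(truth, genes, noise_sd = 0.1, seed = 1,
                          comparison = "FCP_vs_AP",
                          reference_gene = "18S", n_replicates = 3) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  lfc <- truth_lfc(truth, genes, comparison)  # errors on unknown gene
  set.seed(seed)
  rows <- list()
  emit <- function(condition, gene, mean_ct) {
    data.frame(sample_id = paste0(condition, "_pool"),
               condition = condition, gene_id = gene,
               replicate = seq_len(n_replicates),
               ct = mean_ct + rnorm(n_replicates, 0, noise_sd),
               stringsAsFactors = FALSE)
  }
  # reference gene: constant across conditions up to noise
  rows[[length(rows) + 1]] <- emit("control", reference_gene, 15)
  rows[[length(rows) + 1]] <- emit("test", reference_gene, 15)
  base_ct <- 24 + runif(length(genes), -2, 2)
  for (i in seq_along(genes)) {
    rows[[length(rows) + 1]] <- emit("control", genes[i], base_ct[i])
    rows[[length(rows) + 1]] <- emit("test", genes[i], base_ct[i] - lfc[i])
  }
  do.call(rbind, rows)
}
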