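#' Audic-Claverie conditional probability mass function
#'
#' Probability of observing \code{y} tags for a gene in a library of total
#' depth \code{N2}, conditional on \code{x} tags in a library of depth
#' \code{N1}, under the null hypothesis that the gene is expressed at the
#' same (unknown) rate in both libraries. The unknown Poisson rate is
#' marginalized out, which yields
#' \deqn{p(y \mid x) = \left(\frac{N_2}{N_1}\right)^y
#'   \frac{(x+y)!}{x!\,y!}
#'   \left(1 + \frac{N_2}{N_1}\right)^{-(x+y+1)},}
#' the negative-binomial law with size \eqn{x+1} and success probability
#' \eqn{N_1/(N_1+N_2)}. Evaluation is in log space via \code{lgamma} so
#' counts up to 1e6 and depths up to 1e9 do not overflow.
#'
#' @param y Tag count in library 2 (non-negative integer, vectorized).
#' @param x Tag count in library 1 (non-negative integer, vectorized).
#' @param N1,N2 Total clean-tag counts of libraries 1 and 2 (positive).
#' @return Probabilities in (0, 1], recycled to the common length.
#' @examples
#' ac_pmf(0, 0, 1e6, 1e6)  # 0.5
#' ac_pmf(1, 1, 1e6, 1e6)  # 0.25
#' @seealso [ac_two_sided_p()] for the two-sided test built on this law.
#' @export
ac_pmf <- function(y, x, N1, N2) {
  check_ac_inputs(x, y, N1, N2)
  r <- N2 / N1
  exp(lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) +
        y * log(r) - (x + y + 1) * log1p(r))
}

#' Two-sided Audic-Claverie p-value for a two-library tag comparison
#'
#' Computes the lower-tail mass \eqn{S = \sum_{i=0}^{y} p(i \mid x)} of the
#' conditional law and doubles the smaller tail: \code{2 * S} when
#' \eqn{S \le 0.5}, otherwise \code{2 * (1 - S + p(y | x))} (the observed
#' point is kept in both branches so they agree at \eqn{S \approx 0.5});
#' the result is capped at 1. The cumulative sum is evaluated through the
#' regularized incomplete beta identity for the negative-binomial CDF,
#' which is stable for counts far into either tail.
#'
#' @inheritParams ac_pmf
#' @return Two-sided p-values in (0, 1], recycled to the common length.
#' @examples
#' ac_two_sided_p(0, 0, 1e6, 1e6)   # 1
#' ac_two_sided_p(10, 40, 1e6, 1e6) # ~2.4e-5
#' @export
ac_two_sided_p <- function(x, y, N1, N2) {
  check_ac_inputs(x, y, N1, N2)
  pr <- N1 / (N1 + N2)
  S <- pbeta(pr, x + 1, y + 1)  # == P(Y <= y), Y ~ NB(size = x + 1, prob = pr)
  pmf <- ac_pmf(y, x, N1, N2)
  p <- ifelse(S <= 0.5, 2 * S, 2 * (1 - S + pmf))
  pmin(p, 1)
}

check_ac_inputs <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0))
    stop("tag counts x and y must be non-negative", call. = FALSE)
  if (any(x != floor(x)) || any(y != floor(y)))
    stop("tag counts x and y must be integral", call. = FALSE)
  if (any(N1 <= 0) || any(N2 <= 0))
    stop("library sizes N1 and N2 must be positive", call. = FALSE)
  invisible(TRUE)
}

#' Adjust p-values for multiple testing by the FDR step-up procedure
#'
#' Thin wrapper around [stats::p.adjust()] restricted to the two
#' false-discovery-rate variants used here: Benjamini-Hochberg ("BH") and
#' the dependency-robust Benjamini-Yekutieli ("BY", the default), which
#' multiplies the BH adjustment by the harmonic-sum factor
#' \eqn{\sum_{i=1}^m 1/i}. Input order is preserved.
#'
#' @param p Numeric vector of raw p-values in [0, 1].
#' @param method "BY" (default) or "BH".
#' @return Adjusted p-values, same length and order as \code{p}.
#' @export
adjust_fdr <- function(p, method = c("BY", "BH")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = method)
}

#' Differential expression test between two tag libraries
#'
#' Runs the Audic-Claverie two-sided test gene by gene for one comparison,
#' attaches the library-size-normalized log2 ratio (with pseudocount, see
#' [log2_ratio()]), FDR-adjusts the p-values, and calls differentially
#' expressed genes (DEGs) at the joint criterion
#' \code{p_adjusted <= fdr_cutoff} and \code{|log2_ratio| >= lfc_cutoff}.
#'
#' @param counts Count table as returned by [read_count_table()]: columns
#'   \code{gene_id}, \code{length_nt}, then one count column per library.
#' @param profiles Library profiles ([library_profiles()]): columns
#'   \code{library_id}, \code{stage}, \code{total_reads}.
#' @param lib_a,lib_b Library ids of the reference (a) and test (b)
#'   libraries; the log2 ratio is b over a.
#' @param pseudocount Pseudocount added to both counts before the ratio.
#' @param fdr_method "BY" (default) or "BH"; see [adjust_fdr()].
#' @param fdr_cutoff,lfc_cutoff DEG thresholds, both inclusive.
#' @return A data.frame with columns \code{gene_id}, \code{x}, \code{y},
#'   \code{log2_ratio}, \code{p_raw}, \code{p_adjusted},
#'   \code{significant}, \code{direction} ("up", "down" or "none").
#' @export
dge_test <- function(counts, profiles, lib_a, lib_b, pseudocount = 1,
                     fdr_method = c("BY", "BH"),
                     fdr_cutoff = 0.001, lfc_cutoff = 1) {
  fdr_method <- match.arg(fdr_method)
  for (lib in c(lib_a, lib_b)) {
    if (!lib %in% profiles$library_id)
      stop("library '", lib, "' is not declared in the profiles", call. = FALSE)
    if (!lib %in% names(counts))
      stop("library '", lib, "' has no count column", call. = FALSE)
  }
  Na <- profiles$total_reads[match(lib_a, profiles$library_id)]
  Nb <- profiles$total_reads[match(lib_b, profiles$library_id)]
  x <- counts[[lib_a]]
  y <- counts[[lib_b]]
  res <- data.frame(
    gene_id    = counts$gene_id,
    x          = x,
    y          = y,
    log2_ratio = log2_ratio(y, x, Nb, Na, pseudocount = pseudocount),
    p_raw      = ac_two_sided_p(x, y, Na, Nb),
    stringsAsFactors = FALSE
  )
  res$p_adjusted <- adjust_fdr(res$p_raw, method = fdr_method)
  call_degs(res, fdr_cutoff = fdr_cutoff, lfc_cutoff = lfc_cutoff)
}

#' Call differentially expressed genes at the joint FDR / fold-change gate
#'
#' Both criteria are inclusive: a gene is significant iff
#' \code{p_adjusted <= fdr_cutoff} and \code{|log2_ratio| >= lfc_cutoff}.
#' Direction follows the sign of the log2 ratio for significant genes and
#' is "none" otherwise.
#'
#' @param results Data.frame with columns \code{log2_ratio} and
#'   \code{p_adjusted} (e.g. from [dge_test()]).
#' @param fdr_cutoff,lfc_cutoff Inclusive thresholds (defaults 0.001 and 1).
#' @return \code{results} with \code{significant} and \code{direction}
#'   columns replaced/added.
#' @export
call_degs <- function(results, fdr_cutoff = 0.001, lfc_cutoff = 1) {
  stopifnot(all(c("log2_ratio", "p_adjusted") %in% names(results)))
  sig <- results$p_adjusted <= fdr_cutoff & abs(results$log2_ratio) >= lfc_cutoff
  results$significant <- sig
  results$direction <- ifelse(!sig, "none",
                              ifelse(results$log2_ratio > 0, "up", "down"))
  results
}

#' Summarize up/down DEG counts across stage comparisons
#'
#' @param deg_tables Named list of DEG tables (one per comparison), each
#'   with \code{significant} and \code{direction} columns.
#' @return A data.frame with columns \code{comparison}, \code{up},
#'   \code{down}, \code{total} (total = up + down).
#' @export
summarize_stage_counts <- function(deg_tables) {
  stopifnot(is.list(deg_tables))
  nm <- names(deg_tables)
  if (is.null(nm)) nm <- paste0("comparison_", seq_along(deg_tables))
  rows <- lapply(seq_along(deg_tables), function(i) {
    tbl <- deg_tables[[i]]
    up <- sum(tbl$significant & tbl$direction == "up")
    down <- sum(tbl$significant & tbl$direction == "down")
    data.frame(comparison = nm[i], up = up, down = down, total = up + down,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
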