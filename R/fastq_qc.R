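#' Quality-control thresholds for read filtering
#'
#' The three filter rules, applied in fixed order with first failure
#' winning: (1) adapter — the read contains any configured adapter
#' sequence as an exact substring; (2) unknown bases — the fraction of
#' 'N' bases strictly exceeds \code{max_unknown_fraction}; (3)
#' low-quality bases — the fraction of bases with Phred score less than
#' or equal to \code{lowqual_phred_cutoff} strictly exceeds
#' \code{max_lowqual_fraction}.
#'
#' @param max_unknown_fraction Strict upper bound on the N fraction
#'   (default 0.05, i.e. reads with > 5\% N are removed).
#' @param max_lowqual_fraction Strict upper bound on the low-quality base
#'   fraction (default 0.30).
#' @param lowqual_phred_cutoff Inclusive Phred threshold defining a
#'   low-quality base (default 10).
#' @param adapter_sequences Character vector of adapter sequences; empty
#'   disables the adapter rule.
#' @param phred_offset Quality encoding offset, 33 (default) or 64.
#' @return An object of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(max_unknown_fraction = 0.05,
                          max_lowqual_fraction = 0.30,
                          lowqual_phred_cutoff = 10,
                          adapter_sequences = character(),
                          phred_offset = 33) {
  if (max_unknown_fraction < 0 || max_unknown_fraction > 1 ||
      max_lowqual_fraction < 0 || max_lowqual_fraction > 1)
    stop("QC fractions must lie in [0, 1]", call. = FALSE)
  if (lowqual_phred_cutoff < 0)
    stop("lowqual_phred_cutoff must be >= 0", call. = FALSE)
  if (!phred_offset %in% c(33, 64))
    stop("phred_offset must be 33 or 64", call. = FALSE)
  structure(list(max_unknown_fraction = max_unknown_fraction,
                 max_lowqual_fraction = max_lowqual_fraction,
                 lowqual_phred_cutoff = lowqual_phred_cutoff,
                 adapter_sequences = toupper(adapter_sequences),
                 phred_offset = phred_offset),
            class = "qc_thresholds")
}

# Vectorized verdicts for a reads data.frame; returns a character vector in
# {"pass", "adapter", "unknown", "lowqual"}.
classify_reads <- function(reads, thresholds) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  n <- nrow(reads)
  if (n == 0) return(character())
  len_s <- nchar(reads$seq)
  len_q <- nchar(reads$qual)
  bad <- which(len_s != len_q)
  if (length(bad))
    stop("malformed record '", reads$id[bad[1]],
         "': bases and qualities differ in length", call. = FALSE)
  seqs <- toupper(reads$seq)

  verdict <- rep("pass", n)

  # rule 1: adapter substring
  if (length(thresholds$adapter_sequences)) {
    hit <- rep(FALSE, n)
    for (ad in thresholds$adapter_sequences)
      hit <- hit | grepl(ad, seqs, fixed = TRUE)
    verdict[hit] <- "adapter"
  }

  # rule 2: unknown-base fraction (strict >)
  open <- verdict == "pass"
  n_count <- nchar(seqs) - nchar(gsub("N", "", seqs, fixed = TRUE))
  verdict[open & n_count / len_s > thresholds$max_unknown_fraction] <- "unknown"

  # rule 3: low-quality fraction (strict >), Phred <= cutoff inclusive
  open <- verdict == "pass"
  if (any(open)) {
    cutoff_char <- thresholds$phred_offset + thresholds$lowqual_phred_cutoff
    lowq_frac <- vapply(which(open), function(i) {
      codes <- as.integer(charToRaw(reads$qual[i]))
      if (any(codes < thresholds$phred_offset))
        stop("malformed record '", reads$id[i],
             "': quality character below the configured Phred offset",
             call. = FALSE)
      mean(codes <= cutoff_char)
    }, numeric(1))
    fail <- which(open)[lowq_frac > thresholds$max_lowqual_fraction]
    verdict[fail] <- "lowqual"
  }
  verdict
}

#' Classify a single read against the QC rules
#'
#' Rules are checked in fixed order adapter -> unknown -> lowqual; the
#' first failing rule is reported.
#'
#' @param id Read identifier (used in error messages).
#' @param bases Base string.
#' @param qualities Quality string, same length as \code{bases}.
#' @param thresholds A [qc_thresholds()] object.
#' @return "pass", "adapter", "unknown" or "lowqual".
#' @export
classify_read <- function(id, bases, qualities, thresholds = qc_thresholds()) {
  classify_reads(data.frame(id = id, seq = bases, qual = qualities,
                            stringsAsFactors = FALSE), thresholds)
}

#' Filter a FASTQ file by the QC rules
#'
#' Reads the input, classifies every record, writes passing records (in
#' input order, byte-identical) to \code{output} if given, and returns
#' the clean reads plus a removal report. Each read is removed for
#' exactly one (first-matching) reason, so
#' \code{input_reads = clean_reads + removed_adapter + removed_unknown +
#' removed_lowqual}.
#'
#' @param input FASTQ path or a reads data.frame (from [read_fastq()]).
#' @param thresholds A [qc_thresholds()] object.
#' @param output Optional path for the clean FASTQ.
#' @return List with \code{clean} (data.frame of passing reads) and
#'   \code{report} (data.frame with columns \code{input_reads},
#'   \code{removed_adapter}, \code{removed_unknown},
#'   \code{removed_lowqual}, \code{clean_reads}).
#' @export
filter_fastq <- function(input, thresholds = qc_thresholds(), output = NULL) {
  reads <- if (is.character(input)) read_fastq(input) else input
  verdict <- classify_reads(reads, thresholds)
  clean <- reads[verdict == "pass", , drop = FALSE]
  rownames(clean) <- NULL
  report <- data.frame(
    input_reads     = nrow(reads),
    removed_adapter = sum(verdict == "adapter"),
    removed_unknown = sum(verdict == "unknown"),
    removed_lowqual = sum(verdict == "lowqual"),
    clean_reads     = sum(verdict == "pass")
  )
  if (!is.null(output)) write_fastq(clean, output)
  list(clean = clean, report = report)
}
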