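# Shared readers and writers. All tables are plain TSV with a single
# header line; pipeline artifacts additionally carry one leading comment
# line ("# biofilmDGE <version> config=<hash>") which readers skip.

#' Read a FASTQ file into a data.frame of records
#'
#' Plain 4-line-record FASTQ. Each record is validated: the id line must
#' start with "@", the separator line with "+", and bases and qualities
#' must have equal length. Violations, including a truncated final
#' record, raise an error naming the 1-based record index.
#'
#' @param path FASTQ file path.
#' @return Data.frame with character columns \code{id}, \code{seq},
#'   \code{qual} (ids without the leading "@").
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("truncated FASTQ record at index ", length(lines) %/% 4 + 1,
         " in ", path, call. = FALSE)
  n <- length(lines) %/% 4
  if (n == 0)
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  idx <- seq_len(n)
  hdr <- lines[(idx - 1) * 4 + 1]
  seqs <- lines[(idx - 1) * 4 + 2]
  sep <- lines[(idx - 1) * 4 + 3]
  quals <- lines[(idx - 1) * 4 + 4]
  bad <- which(!startsWith(hdr, "@") | !startsWith(sep, "+"))
  if (length(bad))
    stop("malformed FASTQ record at index ", bad[1], " in ", path,
         call. = FALSE)
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("malformed FASTQ record at index ", bad[1],
         ": bases and qualities differ in length", call. = FALSE)
  data.frame(id = sub("^@", "", hdr), seq = seqs, qual = quals,
             stringsAsFactors = FALSE)
}

#' Write FASTQ records
#'
#' @param reads Data.frame with columns \code{id}, \code{seq}, \code{qual}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (nrow(reads) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  out <- rbind(paste0("@", reads$id), reads$seq, "+", reads$qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read a per-gene count table
#'
#' TSV with columns \code{gene_id}, \code{length_nt}, then one integer
#' count column per library.
#'
#' @param path TSV path.
#' @return Data.frame count table.
#' @export
read_count_table <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  need <- c("gene_id", "length_nt")
  if (!all(need %in% names(tbl)))
    stop("count table ", path, " must have columns gene_id and length_nt",
         call. = FALSE)
  libs <- setdiff(names(tbl), need)
  if (length(libs) == 0)
    stop("count table ", path, " has no library count columns", call. = FALSE)
  for (lib in libs) {
    if (any(tbl[[lib]] < 0) || any(tbl[[lib]] != floor(tbl[[lib]])))
      stop("count column '", lib, "' must hold non-negative integers",
           call. = FALSE)
  }
  if (any(tbl$length_nt < 1))
    stop("length_nt must be >= 1", call. = FALSE)
  tbl
}

#' Construct library profiles
#'
#' @param library_id Character vector of library ids.
#' @param stage Stage labels, each one of FCP, AP, SGP, BMP.
#' @param total_reads Total uniquely aligned reads per library (positive).
#' @return Data.frame of profiles.
#' @export
library_profiles <- function(library_id, stage, total_reads) {
  stage <- as.character(stage)
  bad <- setdiff(stage, c("FCP", "AP", "SGP", "BMP"))
  if (length(bad))
    stop("unknown stage label: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(total_reads <= 0))
    stop("total_reads must be positive", call. = FALSE)
  data.frame(library_id = as.character(library_id), stage = stage,
             total_reads = total_reads, stringsAsFactors = FALSE)
}

#' Read library profiles from TSV
#' @param path TSV with columns library_id, stage, total_reads.
#' @return Data.frame of profiles.
#' @export
read_library_profiles <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  library_profiles(tbl$library_id, tbl$stage, tbl$total_reads)
}

#' Read a GMT-like annotation file
#'
#' Tab-separated lines: category id, description, then one gene id per
#' remaining field. The universe defaults to the union of all categories.
#'
#' @param path GMT file path.
#' @param universe Optional explicit universe of annotated gene ids.
#' @return An [annotation_set()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields", call. = FALSE)
  ids <- vapply(fields, `[[`, character(1), 1)
  desc <- vapply(fields, `[[`, character(1), 2)
  cats <- lapply(fields, function(f) f[-(1:2)])
  names(cats) <- ids
  annotation_set(cats, universe = universe,
                 descriptions = setNames(desc, ids))
}

#' Write an annotation set as GMT
#' @param annotation An [annotation_set()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_set"))
  ids <- names(annotation$categories)
  lines <- vapply(ids, function(id) {
    paste(c(id, annotation$descriptions[[id]], annotation$categories[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' TSV with columns \code{sample_id}, \code{condition} (control/test),
#' \code{gene_id}, \code{replicate}, \code{ct}.
#'
#' @param path TSV path.
#' @return Data.frame of Ct measurements.
#' @export
read_ct_table <- function(path) {
  tbl <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "condition", "gene_id", "replicate", "ct")
  if (!all(need %in% names(tbl)))
    stop("Ct table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(tbl$ct <= 0 | tbl$ct >= 45))
    stop("Ct values must lie in (0, 45)", call. = FALSE)
  bad <- setdiff(unique(tbl$condition), c("control", "test"))
  if (length(bad))
    stop("condition must be 'control' or 'test', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  tbl
}

# Fixed-format TSV writer for pipeline artifacts: floats at 6 significant
# digits, p/q-value columns in scientific notation, optional comment header.
write_result_tsv <- function(tbl, path, header = NULL) {
  fmt <- tbl
  for (nm in names(fmt)) {
    if (is.numeric(fmt[[nm]]) && !all(fmt[[nm]] == floor(fmt[[nm]]), na.rm = TRUE)) {
      if (grepl("^(p|q)_", nm)) {
        fmt[[nm]] <- sprintf("%.6e", fmt[[nm]])
      } else {
        fmt[[nm]] <- formatC(signif(fmt[[nm]], 6), format = "g", digits = 6)
      }
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(fmt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline result TSV (skipping the comment header)
#' @param path TSV path.
#' @return Data.frame.
#' @export
read_result_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
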