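#' Sample-by-taxon sequence count matrix with metadata
#'
#' The central container of the package: an integer matrix of sequence
#' counts with samples in rows and operational taxa in columns, carrying
#' per-sample metadata (sampler code, site, sampling method, initiation time
#' in minutes since the start of the deployment, optional grab replicate
#' index) and per-taxon metadata (barcode locus, rank, label).
#'
#' @param counts numeric matrix of non-negative integers; rownames are
#'   sample names, colnames taxon labels.
#' @param sample_meta optional data frame keyed by sample name, with any of
#'   the columns `sampler`, `site`, `method`, `time_min`, `replicate`.
#'   When omitted it is parsed from the sample names (see
#'   [parse_sample_names()]).
#' @param taxon_meta optional data frame keyed by taxon label, with columns
#'   such as `locus` and `rank`.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, sample_meta = NULL, taxon_meta = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 && is.null(rownames(counts))) {
    stop("counts must have sample names as rownames")
  }
  if (ncol(counts) > 0 && is.null(colnames(counts))) {
    stop("counts must have taxon labels as colnames")
  }
  if (nrow(counts) == 0) rownames(counts) <- character(0)
  if (ncol(counts) == 0) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts))) stop("duplicate sample names")
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon labels")
  if (any(counts < 0)) stop("negative counts")
  if (any(abs(counts - round(counts)) > 1e-8)) stop("counts must be integers")
  storage.mode(counts) <- "integer"

  if (is.null(sample_meta)) {
    sample_meta <- parse_sample_names(rownames(counts))
  } else {
    sample_meta <- as.data.frame(sample_meta)
    if (!is.null(sample_meta[["sample"]])) {
      rownames(sample_meta) <- sample_meta[["sample"]]
      sample_meta[["sample"]] <- NULL
    }
    missing <- setdiff(rownames(counts), rownames(sample_meta))
    if (length(missing)) stop("sample_meta lacks sample(s): ", paste(missing, collapse = ", "))
    sample_meta <- sample_meta[rownames(counts), , drop = FALSE]
  }
  if (is.null(taxon_meta)) {
    taxon_meta <- data.frame(row.names = colnames(counts))
  } else {
    taxon_meta <- as.data.frame(taxon_meta)
    if (!is.null(taxon_meta[["taxon"]])) {
      rownames(taxon_meta) <- taxon_meta[["taxon"]]
      taxon_meta[["taxon"]] <- NULL
    }
    missing <- setdiff(colnames(counts), rownames(taxon_meta))
    if (length(missing)) stop("taxon_meta lacks taxon(a): ", paste(missing, collapse = ", "))
    taxon_meta <- taxon_meta[colnames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, sample_meta = sample_meta,
                 taxon_meta = taxon_meta),
            class = "count_matrix")
}

#' Parse sample names of the form `<sampler>_<minutes>[(<replicate>)]`
#'
#' Sample names combine the sampler code with the initiation time of the
#' sample in minutes since the start of the deployment; grab replicates carry
#' the replicate number in parentheses, e.g. `"B_1425(2)"`.
#'
#' @param x character vector of sample names.
#' @return data frame with columns `sampler`, `time_min`, `replicate`
#'   (`NA` when absent), rownames `x`.
#' @export
parse_sample_names <- function(x) {
  m <- regmatches(x, regexec("^([A-Za-z]+)_([0-9]+)(\\(([0-9]+)\\))?$", x))
  bad <- vapply(m, length, integer(1)) == 0L
  out <- data.frame(
    sampler = vapply(m, function(g) if (length(g)) g[2] else NA_character_, character(1)),
    time_min = vapply(m, function(g) if (length(g)) as.integer(g[3]) else NA_integer_, integer(1)),
    replicate = vapply(m, function(g) {
      if (length(g) && nzchar(g[5])) as.integer(g[5]) else NA_integer_
    }, integer(1)),
    row.names = x, stringsAsFactors = FALSE
  )
  if (any(bad)) {
    warning("sample name(s) not in <sampler>_<minutes>[(rep)] form: ",
            paste(x[bad], collapse = ", "))
  }
  out
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("<count_matrix>", nrow(x$counts), "samples x", ncol(x$counts), "taxa;",
      "total counts", format(sum(as.numeric(x$counts)), big.mark = ","), "\n")
  if (!is.null(x$taxon_meta$locus)) {
    cat("  loci:", paste(sprintf("%s (%d)", names(table(x$taxon_meta$locus)),
                                 table(x$taxon_meta$locus)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  count_matrix(x$counts[i, j, drop = FALSE],
               x$sample_meta[i, , drop = FALSE],
               x$taxon_meta[j, , drop = FALSE])
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

as_count_matrix <- function(x) {
  if (inherits(x, "count_matrix")) x else count_matrix(x)
}

#' Read a sample-by-taxon count table from TSV
#'
#' Expects a tab-separated file whose first column holds sample names and
#' whose header row holds taxon labels. Per-sample metadata is taken from a
#' sidecar TSV when given (columns `sample`, `sampler`, `site`, `method`,
#' `time_min`, `replicate`), otherwise parsed from sample names; a sidecar
#' overrides name parsing. Per-taxon loci can likewise be supplied as a
#' sidecar (columns `taxon`, `locus`, ...).
#'
#' @param path count table TSV.
#' @param meta_path optional sample metadata TSV.
#' @param taxon_meta_path optional taxon metadata TSV.
#' @return a [count_matrix()].
#' @export
read_count_table <- function(path, meta_path = NULL, taxon_meta_path = NULL) {
  header <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  if (anyDuplicated(header[-1])) {
    stop("duplicate taxon column(s) in header: ",
         paste(unique(header[-1][duplicated(header[-1])]), collapse = ", "))
  }
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(raw)
  if (!is.numeric(mat)) stop("non-numeric cells in count table")
  meta <- if (!is.null(meta_path)) {
    utils::read.table(meta_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else NULL
  tmeta <- if (!is.null(taxon_meta_path)) {
    utils::read.table(taxon_meta_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else NULL
  count_matrix(mat, meta, tmeta)
}

#' Write a count matrix (and its metadata) to TSV
#'
#' @param x a [count_matrix()].
#' @param path output path for the count table.
#' @param meta_path optional output path for the sample metadata.
#' @return `x`, invisibly.
#' @export
write_count_table <- function(x, path, meta_path = NULL) {
  x <- as_count_matrix(x)
  df <- data.frame(sample = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    md <- data.frame(sample = rownames(x$sample_meta), x$sample_meta,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(md, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}
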