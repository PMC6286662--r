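#' Drop taxa below a run-wide minimum sequence count
#'
#' Retains operational taxa (or OTUs) with at least `min_total` sequence
#' counts summed over the whole sequencing run. A minimum of 10 is a
#' conservative guard against diversity inflation from sample cross-talk and
#' PCR artifacts, stricter than simply discarding singletons.
#'
#' @param x a [count_matrix()] or bare counts matrix.
#' @param min_total minimum run-wide total (default 10).
#' @return the filtered `count_matrix`; attribute `"removed"` is a data frame
#'   of dropped taxa and their totals.
#' @export
filter_min_run_count <- function(x, min_total = 10) {
  x <- as_count_matrix(x)
  totals <- colSums(x$counts)
  keep <- totals >= min_total
  removed <- data.frame(taxon = colnames(x$counts)[!keep],
                        total = unname(totals[!keep]),
                        stringsAsFactors = FALSE)
  if (!any(keep)) warning("all taxa fall below the run-wide minimum count; empty matrix returned")
  out <- x[, keep]
  attr(out, "removed") <- removed
  out
}

locus_length_rules <- function() {
  list(
    coi = c(312, 379),   # observed range; no COI OTU excluded on length
    `16s` = c(350, Inf), # minimum length 350 nt
    `12s` = c(76, 170)   # > 75 nt and <= 170 nt
  )
}

#' Length-filter OTU representative sequences per locus
#'
#' Applies the per-locus amplicon length windows: COI 312--379 nt, 16S at
#' least 350 nt, 12S longer than 75 nt and at most 170 nt.
#'
#' @param otu_lengths named numeric vector of representative sequence lengths
#'   (names are OTU ids).
#' @param locus one of `"coi"`, `"16s"`, `"12s"`, or a vector of the same
#'   length as `otu_lengths`.
#' @return named logical keep-vector over `otu_lengths`.
#' @export
filter_length <- function(otu_lengths, locus) {
  rules <- locus_length_rules()
  locus <- tolower(locus)
  bad <- setdiff(unique(locus), names(rules))
  if (length(bad)) stop("unknown locus: ", paste(bad, collapse = ", "))
  if (length(locus) == 1L) locus <- rep(locus, length(otu_lengths))
  keep <- vapply(seq_along(otu_lengths), function(i) {
    r <- rules[[locus[i]]]
    otu_lengths[i] >= r[1] && otu_lengths[i] <= r[2]
  }, logical(1))
  names(keep) <- names(otu_lengths)
  keep
}

#' Censor probable sequencer cross-talk
#'
#' A taxon is retained only when its run-wide total is at least `min_total`
#' and it has two or more reads in at least one sample, i.e. it is not
#' exclusively represented by singletons. Index misassignment between
#' multiplexed samples produces exactly such scattered singleton detections.
#' The rule is applied per locus when `locus` is given (the study applied it
#' to all 12S taxa).
#'
#' @param x a [count_matrix()] or bare counts matrix.
#' @param min_total minimum run-wide total (default 10).
#' @param min_max minimum of the per-sample maximum count (default 2).
#' @param locus optional locus tag; only taxa of this locus are tested,
#'   others pass through.
#' @return the censored `count_matrix`; attribute `"removed"` reports the
#'   censored taxa with their totals and per-sample maxima.
#' @export
censor_crosstalk <- function(x, min_total = 10, min_max = 2, locus = NULL) {
  x <- as_count_matrix(x)
  totals <- colSums(x$counts)
  maxima <- apply(x$counts, 2, max)
  fails <- totals < min_total | maxima < min_max
  if (!is.null(locus)) {
    if (is.null(x$taxon_meta$locus)) stop("taxon_meta lacks a locus column")
    fails <- fails & x$taxon_meta$locus %in% locus
  }
  removed <- data.frame(taxon = colnames(x$counts)[fails],
                        total = unname(totals[fails]),
                        max_per_sample = unname(maxima[fails]),
                        stringsAsFactors = FALSE)
  out <- x[, !fails]
  attr(out, "removed") <- removed
  out
}

#' Collapse taxa to a target rank
#'
#' Sums counts within the ancestor of each taxon at `target_rank`, per locus.
#' Taxa with no ancestor at the target rank receive operational labels:
#' a genus lacking a family is reported as `"<genus> incertae sedis"`, and a
#' species-level label lacking a genus has `" sp. "` rewritten to
#' `" genus "` (an operational genus); with `on_missing = "error"` such taxa
#' abort with a listing instead.
#'
#' @param x a [count_matrix()] whose `taxon_meta` carries a `taxon_id`
#'   column, or a bare matrix plus `taxon_ids`.
#' @param target_rank rank label to collapse to (e.g. `"genus"`, `"family"`).
#' @param db a [taxonomy_db()].
#' @param taxon_ids optional integer vector of taxon ids, one per column.
#' @param on_missing `"label"` (default) or `"error"`.
#' @return a `count_matrix` of collapsed counts; per-sample totals are
#'   conserved exactly.
#' @export
collapse_rank <- function(x, target_rank, db, taxon_ids = NULL,
                          on_missing = c("label", "error")) {
  on_missing <- match.arg(on_missing)
  x <- as_count_matrix(x)
  if (is.null(taxon_ids)) taxon_ids <- x$taxon_meta$taxon_id
  if (is.null(taxon_ids)) stop("collapse_rank needs taxon ids (taxon_meta$taxon_id or taxon_ids)")
  target <- rank_level(target_rank)
  if (is.na(target)) stop("unknown rank label: ", target_rank)

  labels <- character(ncol(x$counts))
  offenders <- character(0)
  for (j in seq_len(ncol(x$counts))) {
    anc <- ancestor_at_rank(db, taxon_ids[j], target_rank)
    if (!is.na(anc) && rank_level(db$rank[[as.character(anc)]]) == target) {
      labels[j] <- taxon_name(db, anc)
    } else {
      lbl <- colnames(x$counts)[j]
      offenders <- c(offenders, lbl)
      labels[j] <- operational_label(db, taxon_ids[j], lbl, target_rank)
    }
  }
  if (on_missing == "error" && length(offenders)) {
    stop("taxa with no ancestor at rank ", target_rank, ": ",
         paste(offenders, collapse = ", "))
  }

  locus <- if (!is.null(x$taxon_meta$locus)) x$taxon_meta$locus else rep("", ncol(x$counts))
  group <- paste(locus, labels, sep = "\r")
  groups <- unique(group)
  newc <- vapply(groups, function(g) {
    rowSums(x$counts[, group == g, drop = FALSE])
  }, numeric(nrow(x$counts)))
  newc <- matrix(newc, nrow = nrow(x$counts),
                 dimnames = list(rownames(x$counts), NULL))
  parts <- strsplit(groups, "\r", fixed = TRUE)
  new_labels <- vapply(parts, `[`, character(1), 2)
  new_locus <- vapply(parts, `[`, character(1), 1)
  ## keep labels unique across loci by suffixing when needed
  lab <- if (anyDuplicated(new_labels)) paste0(new_labels, ifelse(nzchar(new_locus), paste0(" [", new_locus, "]"), "")) else new_labels
  colnames(newc) <- lab
  tm <- data.frame(row.names = lab, label = new_labels, rank = target_rank,
                   stringsAsFactors = FALSE)
  if (any(nzchar(new_locus))) tm$locus <- new_locus
  count_matrix(newc, x$sample_meta, tm)
}

operational_label <- function(db, taxon_id, label, target_rank) {
  if (target_rank == "genus" && grepl(" sp\\.? ", label)) {
    return(sub(" sp\\.? ", " genus ", label))
  }
  ## nearest named ancestor below the target (typically the orphan genus)
  own <- tryCatch(taxon_name(db, taxon_id), error = function(e) label)
  paste(own, "incertae sedis")
}

#' Keep the n most abundant taxa by library-normalized abundance
#'
#' Ranks taxa by their summed counts-per-million abundance and keeps the top
#' `n`. Ties at the boundary are broken deterministically by lexicographic
#' label order.
#'
#' @param x a [count_matrix()] or bare counts matrix.
#' @param n number of taxa to keep (default 150).
#' @return the restricted `count_matrix`.
#' @export
top_n_by_abundance <- function(x, n = 150) {
  stopifnot(n >= 1)
  x <- as_count_matrix(x)
  if (n >= ncol(x$counts)) {
    if (n > ncol(x$counts)) warning("n exceeds the number of taxa; returning all")
    return(x)
  }
  score <- colSums(to_cpm(x, quiet = TRUE))
  ord <- order(-score, colnames(x$counts))
  x[, sort(ord[seq_len(n)])]
}

#' Normalize counts to counts per million
#'
#' Each cell is divided by its sample total and scaled to one million, so
#' rows sum to 1e6. Samples with zero total counts cannot be normalized and
#' are dropped with a warning.
#'
#' @param x a [count_matrix()] or bare counts matrix.
#' @param quiet suppress the zero-total warning.
#' @return numeric matrix of cpm values (samples x taxa).
#' @export
to_cpm <- function(x, quiet = FALSE) {
  x <- as_count_matrix(x)
  totals <- rowSums(x$counts)
  zero <- totals == 0
  if (any(zero) && !quiet) {
    warning("dropping zero-total sample(s): ",
            paste(rownames(x$counts)[zero], collapse = ", "))
  }
  m <- x$counts[!zero, , drop = FALSE]
  sweep(m, 1, rowSums(m), "/") * 1e6
}
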