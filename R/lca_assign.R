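#' Assignment parameters for the LCA classifier
#'
#' Bundles the tunable constants of the modified lowest-common-ancestor
#' assignment: a bit-score floor on HSPs, the LCA score window (fraction of
#' the best bit score), and the mean-identity thresholds below which species
#' and genus assignments are demoted.
#'
#' @param min_bitscore floor on HSP bit scores; weaker alignments are dropped.
#' @param lca_window fraction in (0, 1]; HSPs scoring within this fraction of
#'   the best retained bit score vote in the LCA (0.05 = "5\% window").
#' @param species_min_identity minimum mean percent identity for a
#'   species-level assignment to stand (default 95).
#' @param genus_min_identity minimum mean percent identity for a genus-level
#'   assignment to stand (default 90).
#' @param allowed_taxa optional integer vector of taxon ids used by
#'   [constrained_reassign()].
#' @param constraint_clade optional taxon id of the clade (e.g. the ray-finned
#'   fishes) inside which `allowed_taxa` applies.
#' @return an object of class `assignment_params`.
#' @seealso [locus_preset()] for the per-locus defaults.
#' @export
assignment_params <- function(min_bitscore = 250, lca_window = 0.05,
                              species_min_identity = 95,
                              genus_min_identity = 90,
                              allowed_taxa = NULL,
                              constraint_clade = NULL) {
  stopifnot(lca_window > 0, lca_window <= 1,
            genus_min_identity >= 0,
            species_min_identity >= genus_min_identity,
            species_min_identity <= 100,
            min_bitscore >= 0)
  structure(list(min_bitscore = min_bitscore, lca_window = lca_window,
                 species_min_identity = species_min_identity,
                 genus_min_identity = genus_min_identity,
                 allowed_taxa = allowed_taxa,
                 constraint_clade = constraint_clade),
            class = "assignment_params")
}

#' Per-locus assignment presets
#'
#' The metazoan COI and eukaryotic 16S barcodes use a bit-score floor of 250
#' with a 5\% LCA window; the shorter vertebrate 12S barcode uses a floor of
#' 200 with a 2\% window and is normally followed by a watershed-constrained
#' re-assignment within the ray-finned fishes (see
#' [constrained_reassign()]).
#'
#' @param locus one of `"coi"`, `"euk16s"`, `"12s"`.
#' @param ... overrides passed on to [assignment_params()].
#' @return an `assignment_params` object.
#' @export
locus_preset <- function(locus = c("coi", "euk16s", "12s"), ...) {
  locus <- match.arg(tolower(locus), c("coi", "euk16s", "12s"))
  defaults <- switch(locus,
    coi = list(min_bitscore = 250, lca_window = 0.05),
    euk16s = list(min_bitscore = 250, lca_window = 0.05),
    `12s` = list(min_bitscore = 200, lca_window = 0.02)
  )
  do.call(assignment_params, utils::modifyList(defaults, list(...)))
}

unassigned_row <- function(query_id, notes = "") {
  data.frame(query_id = query_id, taxon_id = NA_integer_,
             taxon_name = NA_character_, rank = NA_character_,
             mean_identity = NA_real_, n_contributing = 0L,
             demoted = FALSE, notes = notes, stringsAsFactors = FALSE)
}

validate_hits <- function(hits) {
  need <- c("query_id", "subject_acc", "taxon_id", "bit_score", "pct_identity")
  missing <- setdiff(need, colnames(hits))
  if (length(missing)) stop("hit table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(hits$bit_score < 0, na.rm = TRUE)) stop("negative bit scores in hit table")
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100, na.rm = TRUE)) {
    stop("percent identity outside [0, 100]")
  }
  hits
}

#' Assign one OTU by the windowed LCA of its alignment hits
#'
#' The classifier (i) drops HSPs below the bit-score floor, (ii) keeps only
#' the best-scoring HSP per subject accession, (iii) retains HSPs scoring
#' within `lca_window` of the best retained score (closed interval), and
#' (iv) assigns the lowest common ancestor of the retained taxa. The mean
#' percent identity of the retained HSPs is then used to demote assignments
#' the evidence cannot support: species-level results with mean identity
#' below `species_min_identity` fall back to the nearest genus-or-above
#' ancestor, and genus-level results below `genus_min_identity` fall back to
#' the family ancestor. Demotion never reports a rank above family; when the
#' walk would pass family, the OTU is returned unassigned.
#'
#' @param hits data frame of HSPs for a single query: columns `query_id`,
#'   `subject_acc`, `taxon_id`, `bit_score`, `pct_identity` (and optionally
#'   `aln_length`).
#' @param params an [assignment_params()] object.
#' @param db a [taxonomy_db()].
#' @return one-row data frame: `query_id`, `taxon_id`, `taxon_name`, `rank`,
#'   `mean_identity`, `n_contributing`, `demoted`, `notes`. An OTU with no
#'   surviving HSP comes back unassigned (`taxon_id` `NA`), not as an error.
#' @export
assign_otu <- function(hits, params = assignment_params(), db) {
  if (is.null(hits) || nrow(hits) == 0L) return(unassigned_row(NA_character_, "no hits"))
  validate_hits(hits)
  qid <- unique(hits$query_id)
  if (length(qid) != 1L) stop("assign_otu expects hits for a single query_id")

  h <- hits[hits$bit_score >= params$min_bitscore, , drop = FALSE]
  if (nrow(h) == 0L) return(unassigned_row(qid, "no HSP above bit-score floor"))

  ## best HSP per subject accession, so one reference cannot vote twice
  h <- h[order(h$subject_acc, -h$bit_score), , drop = FALSE]
  h <- h[!duplicated(h$subject_acc), , drop = FALSE]

  cutoff <- (1 - params$lca_window) * max(h$bit_score)
  h <- h[h$bit_score >= cutoff, , drop = FALSE]

  taxa <- resolve_taxid(db, h$taxon_id)
  lca <- lowest_common_ancestor(taxa, db)
  mean_id <- mean(h$pct_identity)
  res <- list(id = lca, demoted = FALSE, notes = "")

  lvl <- rank_level(db$rank[[as.character(lca)]])
  species_lvl <- rank_level("species")
  genus_lvl <- rank_level("genus")
  family_lvl <- rank_level("family")

  if (!is.na(lvl) && lvl <= species_lvl && mean_id < params$species_min_identity) {
    g <- ancestor_at_rank(db, res$id, "genus")
    if (is.na(g) || rank_level(db$rank[[as.character(g)]]) > family_lvl) {
      return(unassigned_row(qid, "species-level identity rule failed; no supportable ancestor at or below family"))
    }
    res$id <- g
    res$demoted <- TRUE
    res$notes <- "demoted from species by identity rule"
    lvl <- rank_level(db$rank[[as.character(res$id)]])
  }
  if (!is.na(lvl) && lvl < family_lvl && lvl >= genus_lvl &&
      mean_id < params$genus_min_identity) {
    f <- ancestor_at_rank(db, res$id, "family")
    if (is.na(f) || rank_level(db$rank[[as.character(f)]]) > family_lvl) {
      return(unassigned_row(qid, "genus-level identity rule failed; no family ancestor"))
    }
    res$id <- f
    res$demoted <- TRUE
    res$notes <- paste0(res$notes, if (nzchar(res$notes)) "; ",
                        "demoted to family by identity rule")
  }

  data.frame(query_id = qid, taxon_id = res$id,
             taxon_name = taxon_name(db, res$id),
             rank = taxon_rank(db, res$id),
             mean_identity = mean_id, n_contributing = nrow(h),
             demoted = res$demoted, notes = res$notes,
             stringsAsFactors = FALSE)
}

#' Assign every OTU in a hit table
#'
#' @param hits data frame of HSPs for any number of queries.
#' @param params an [assignment_params()] object.
#' @param db a [taxonomy_db()].
#' @return data frame with one row per query, as [assign_otu()].
#' @export
assign_all <- function(hits, params = assignment_params(), db) {
  validate_hits(hits)
  out <- lapply(split(hits, hits$query_id), assign_otu, params = params, db = db)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Re-assign an OTU after restricting hits to an expected-taxon list
#'
#' Used for loci too conserved to discriminate all reference species: when an
#' OTU's initial assignment falls inside `constraint_clade`, alignment hits
#' whose taxa are not on the expected list (membership judged over the full
#' lineage, so genus-level entries admit their species) are removed and the
#' LCA is recomputed. Assignments outside the clade are returned unchanged;
#' an OTU whose hits are all disallowed comes back unassigned with a note.
#'
#' @param hits data frame of HSPs for one query.
#' @param allowed_taxa integer vector of permitted taxon ids.
#' @param constraint_clade taxon id of the clade within which the list applies.
#' @param params an [assignment_params()] object.
#' @param db a [taxonomy_db()].
#' @return one-row assignment data frame.
#' @export
constrained_reassign <- function(hits, allowed_taxa, constraint_clade,
                                 params = assignment_params(), db) {
  if (!is.null(constraint_clade) && (is.null(allowed_taxa) || length(allowed_taxa) == 0L)) {
    stop("constraint_clade is set but allowed_taxa is empty")
  }
  initial <- assign_otu(hits, params, db)
  if (is.na(initial$taxon_id)) return(initial)
  if (!(constraint_clade %in% lineage(db, initial$taxon_id))) return(initial)

  allowed <- resolve_taxid(db, allowed_taxa)
  keep <- vapply(hits$taxon_id, function(tid) {
    any(lineage(db, tid) %in% allowed)
  }, logical(1))
  if (!any(keep)) {
    out <- unassigned_row(initial$query_id,
                          "all hits to taxa outside the expected-taxon list")
    return(out)
  }
  res <- assign_otu(hits[keep, , drop = FALSE], params, db)
  if (!identical(res$taxon_id, initial$taxon_id)) {
    res$notes <- paste0(res$notes, if (nzchar(res$notes)) "; ",
                        "re-assigned under expected-taxon constraint")
  }
  res
}

#' Apply ordered post-hoc adjustments to taxonomic assignments
#'
#' Post-hoc curation of an assignment table: remove taxa known to be
#' artifactual (e.g. feed-derived reads), rename a taxon to an operational
#' label, or merge one taxon into another it cannot be distinguished from.
#' Rules are applied in order; a rule that matches nothing is an error so
#' that stale configuration is caught.
#'
#' @param assignments data frame as produced by [assign_all()], or a
#'   [count_matrix()] (columns are pooled for `merge_into`).
#' @param adjustments data frame with columns `match` (taxon name),
#'   `action` (`"remove"`, `"rename"` or `"merge_into"`) and `target`
#'   (new label for rename/merge; ignored for remove).
#' @param ... unused.
#' @return object of the same class with the adjustments applied; an
#'   attribute `"adjustment_log"` records each action.
#' @export
apply_taxon_adjustments <- function(assignments, adjustments, ...) {
  UseMethod("apply_taxon_adjustments")
}

check_adjustments <- function(adjustments) {
  stopifnot(is.data.frame(adjustments),
            all(c("match", "action") %in% colnames(adjustments)))
  if (!"target" %in% colnames(adjustments)) adjustments$target <- NA_character_
  bad <- setdiff(adjustments$action, c("remove", "rename", "merge_into"))
  if (length(bad)) stop("unknown adjustment action(s): ", paste(bad, collapse = ", "))
  adjustments
}

#' @export
apply_taxon_adjustments.data.frame <- function(assignments, adjustments, ...) {
  adjustments <- check_adjustments(adjustments)
  log <- character(0)
  unmatched <- character(0)
  out <- assignments
  for (i in seq_len(nrow(adjustments))) {
    rule <- adjustments[i, ]
    hit <- out$taxon_name %in% rule$match
    if (!any(hit)) { unmatched <- c(unmatched, rule$match); next }
    if (rule$action == "remove") {
      out <- out[!hit, , drop = FALSE]
      log <- c(log, sprintf("removed %d assignment(s) of %s", sum(hit), rule$match))
    } else {
      out$taxon_name[hit] <- rule$target
      if (rule$action == "merge_into" && "taxon_id" %in% colnames(out)) {
        tgt <- out$taxon_id[out$taxon_name == rule$target & !hit]
        out$taxon_id[hit] <- if (length(tgt)) tgt[1] else NA_integer_
      }
      log <- c(log, sprintf("%s %s -> %s", rule$action, rule$match, rule$target))
    }
  }
  if (length(unmatched)) {
    stop("adjustment rule(s) matched no taxon: ", paste(unmatched, collapse = ", "))
  }
  rownames(out) <- NULL
  attr(out, "adjustment_log") <- log
  out
}

#' Read a BLAST-style tabular hit file
#'
#' Reads the 12-column tabular dialect (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bit score), plus an optional 13th subject-taxon-id
#' column. When the taxon column is absent a sidecar accession-to-taxid map
#' must be supplied.
#'
#' @param path path to the tab-separated hit file (no header).
#' @param taxid_map optional data frame with columns `subject_acc`,
#'   `taxon_id` used when the file has no taxon column.
#' @return data frame with columns `query_id`, `subject_acc`, `taxon_id`,
#'   `bit_score`, `pct_identity`, `aln_length`.
#' @export
read_hit_table <- function(path, taxid_map = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(raw) < 12) stop("hit table must have at least 12 tab-separated columns")
  hits <- data.frame(
    query_id = as.character(raw[[1]]),
    subject_acc = as.character(raw[[2]]),
    pct_identity = as.numeric(raw[[3]]),
    aln_length = as.integer(raw[[4]]),
    bit_score = as.numeric(raw[[12]]),
    stringsAsFactors = FALSE
  )
  if (ncol(raw) >= 13) {
    hits$taxon_id <- as.integer(raw[[13]])
  } else {
    if (is.null(taxid_map)) {
      stop("hit table has no taxon-id column; supply taxid_map (subject_acc -> taxon_id)")
    }
    idx <- match(hits$subject_acc, taxid_map$subject_acc)
    if (anyNA(idx)) {
      stop("accession(s) missing from taxid_map: ",
           paste(unique(hits$subject_acc[is.na(idx)]), collapse = ", "))
    }
    hits$taxon_id <- as.integer(taxid_map$taxon_id[idx])
  }
  validate_hits(hits)
}
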