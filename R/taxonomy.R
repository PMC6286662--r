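## Ordered rank ladder, leafward to rootward. Unlisted labels ("no rank",
## "subfamily", ...) are treated as unranked and skipped when walking up.
RANK_LADDER <- c(
  "subspecies", "varietas", "forma", "species", "genus", "family", "order",
  "class", "phylum", "kingdom", "superkingdom", "root"
)

#' Position of a rank label on the rank ladder
#'
#' Higher values are more rootward. Unknown labels (including "no rank")
#' return `NA`.
#'
#' @param rank character vector of rank labels.
#' @return integer vector of ladder positions.
#' @keywords internal
rank_level <- function(rank) match(rank, RANK_LADDER)

#' Construct a validated taxonomy database
#'
#' A rooted taxonomy in the style of the NCBI taxonomy dumps: every node has
#' a parent, a rank label and a name, the root is its own parent, and merged
#' (retired) identifiers can be remapped onto current ones.
#'
#' @param nodes data frame with columns `id`, `parent`, `rank` (integer ids,
#'   character ranks).
#' @param names optional data frame with columns `id`, `name` (scientific
#'   names); missing names default to `"taxon <id>"`.
#' @param merged optional data frame with columns `old`, `new` mapping retired
#'   ids to current ones.
#' @return an object of class `taxonomy_db`.
#' @examples
#' db <- taxonomy_db(data.frame(id = c(1, 2, 3), parent = c(1, 1, 2),
#'                              rank = c("root", "genus", "species")))
#' lineage(db, 3)
#' @export
taxonomy_db <- function(nodes, names = NULL, merged = NULL) {
  stopifnot(is.data.frame(nodes), all(c("id", "parent", "rank") %in% colnames(nodes)))
  id <- as.integer(nodes$id)
  parent <- as.integer(nodes$parent)
  if (anyDuplicated(id)) stop("duplicate taxon ids in nodes table")
  if (!all(parent %in% id)) {
    bad <- setdiff(parent, id)
    stop("unknown parent id(s): ", paste(bad, collapse = ", "))
  }
  root <- id[parent == id]
  if (length(root) != 1L) {
    stop("taxonomy must have exactly one root (parent == id); found ", length(root))
  }
  key <- as.character(id)
  parent_of <- stats::setNames(parent, key)
  rank_of <- stats::setNames(as.character(nodes$rank), key)

  nm <- stats::setNames(paste("taxon", key), key)
  if (!is.null(names)) {
    stopifnot(all(c("id", "name") %in% colnames(names)))
    nk <- as.character(as.integer(names$id))
    nm[nk[nk %in% key]] <- as.character(names$name)[nk %in% key]
  }
  merged_map <- integer(0)
  if (!is.null(merged) && nrow(merged) > 0) {
    stopifnot(all(c("old", "new") %in% colnames(merged)))
    merged_map <- stats::setNames(as.integer(merged$new), as.character(as.integer(merged$old)))
  }
  db <- structure(
    list(parent = parent_of, rank = rank_of, name = nm,
         merged = merged_map, root = root),
    class = "taxonomy_db"
  )
  ## cycle check: every parent chain must reach the root
  for (i in key) {
    cur <- i
    for (step in seq_len(length(id) + 1L)) {
      p <- parent_of[[cur]]
      if (p == as.integer(cur)) break
      cur <- as.character(p)
      if (step > length(id)) stop("cycle detected in parent chain starting at id ", i)
    }
    if (parent_of[[cur]] != as.integer(cur)) {
      stop("parent chain of id ", i, " does not terminate at the root")
    }
  }
  db
}

#' @export
print.taxonomy_db <- function(x, ...) {
  cat("<taxonomy_db>", length(x$parent), "nodes, root id", x$root,
      "|", length(x$merged), "merged ids\n")
  invisible(x)
}

parse_dmp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  if (grepl("|", lines[[1]], fixed = TRUE)) {
    ## NCBI taxdump dialect: fields separated by "\t|\t", trailing "\t|"
    lapply(strsplit(sub("\t?\\|$", "", lines), "\t\\|\t?"), trimws)
  } else {
    strsplit(lines, "\t")
  }
}

#' Load a taxonomy from NCBI-style dump files
#'
#' Accepts both the pipe-delimited NCBI taxdump dialect (`nodes.dmp`,
#' `names.dmp`, `merged.dmp`) and a plain-TSV toy dialect with the same
#' column order (nodes: id, parent, rank; names: id, name\[, ..., class\];
#' merged: old, new). For `names.dmp`, only rows of name class
#' `"scientific name"` are used when a class column is present.
#'
#' @param nodes_source path to the nodes file.
#' @param names_source optional path to the names file.
#' @param merged_source optional path to the merged file.
#' @return a [taxonomy_db()].
#' @export
load_taxonomy <- function(nodes_source, names_source = NULL, merged_source = NULL) {
  nf <- parse_dmp(nodes_source)
  nodes <- data.frame(
    id = vapply(nf, function(r) as.integer(r[[1]]), integer(1)),
    parent = vapply(nf, function(r) as.integer(r[[2]]), integer(1)),
    rank = vapply(nf, function(r) if (length(r) >= 3) r[[3]] else "no rank", character(1)),
    stringsAsFactors = FALSE
  )
  names_df <- NULL
  if (!is.null(names_source)) {
    rows <- parse_dmp(names_source)
    keep <- vapply(rows, function(r) {
      length(r) < 4 || grepl("scientific", r[[4]], fixed = TRUE)
    }, logical(1))
    rows <- rows[keep]
    names_df <- data.frame(
      id = vapply(rows, function(r) as.integer(r[[1]]), integer(1)),
      name = vapply(rows, function(r) r[[2]], character(1)),
      stringsAsFactors = FALSE
    )
  }
  merged_df <- NULL
  if (!is.null(merged_source)) {
    rows <- parse_dmp(merged_source)
    if (length(rows) > 0) {
      merged_df <- data.frame(
        old = vapply(rows, function(r) as.integer(r[[1]]), integer(1)),
        new = vapply(rows, function(r) as.integer(r[[2]]), integer(1)),
        stringsAsFactors = FALSE
      )
    }
  }
  taxonomy_db(nodes, names_df, merged_df)
}

#' Resolve taxon ids through the merged-id map
#'
#' @param db a [taxonomy_db()].
#' @param ids integer vector of taxon ids (possibly retired).
#' @param partial if `TRUE`, unresolvable ids come back as `NA` instead of
#'   raising an error.
#' @return integer vector of current ids.
#' @export
resolve_taxid <- function(db, ids, partial = FALSE) {
  ids <- as.integer(ids)
  out <- ids
  for (i in seq_along(out)) {
    seen <- integer(0)
    while (!is.na(out[i]) && !(as.character(out[i]) %in% names(db$parent))) {
      k <- as.character(out[i])
      if (k %in% names(db$merged) && !(out[i] %in% seen)) {
        seen <- c(seen, out[i])
        out[i] <- db$merged[[k]]
      } else {
        if (partial) {
          out[i] <- NA_integer_
        } else {
          stop("taxon id ", ids[i], " not resolvable in taxonomy")
        }
      }
    }
  }
  out
}

#' Root-to-node lineage of a taxon
#'
#' @param db a [taxonomy_db()].
#' @param id a single taxon id.
#' @return integer vector of ids ordered root first, the node itself last.
#' @export
lineage <- function(db, id) {
  id <- resolve_taxid(db, id)
  path <- integer(0)
  cur <- id
  repeat {
    path <- c(cur, path)
    p <- db$parent[[as.character(cur)]]
    if (p == cur) break
    cur <- p
  }
  path
}

#' Name and rank lookups
#'
#' @param db a [taxonomy_db()].
#' @param ids integer vector of taxon ids.
#' @return character vector.
#' @export
taxon_name <- function(db, ids) {
  ids <- resolve_taxid(db, ids)
  unname(db$name[as.character(ids)])
}

#' @rdname taxon_name
#' @export
taxon_rank <- function(db, ids) {
  ids <- resolve_taxid(db, ids)
  unname(db$rank[as.character(ids)])
}

#' Look up a taxon id by its scientific name
#'
#' @param db a [taxonomy_db()].
#' @param names character vector of scientific names.
#' @return integer vector of ids (`NA` where not found).
#' @export
taxon_id_by_name <- function(db, names) {
  idx <- match(names, db$name)
  as.integer(names(db$name)[idx])
}

#' Lowest common ancestor of a set of taxa
#'
#' Returns the deepest node that is ancestral to (or equal to) every input
#' taxon, by intersecting root-to-node paths.
#'
#' @param taxon_ids integer vector (treated as a set) of taxon ids.
#' @param db a [taxonomy_db()].
#' @return a single taxon id.
#' @examples
#' db <- taxonomy_db(data.frame(id = 1:3, parent = c(1, 1, 1),
#'                              rank = c("root", "species", "species")))
#' lowest_common_ancestor(c(2, 3), db)  # 1
#' @export
lowest_common_ancestor <- function(taxon_ids, db) {
  taxon_ids <- unique(resolve_taxid(db, taxon_ids))
  if (length(taxon_ids) == 0L) stop("empty taxon set has no common ancestor")
  if (length(taxon_ids) == 1L) return(taxon_ids)
  paths <- lapply(taxon_ids, function(id) lineage(db, id))
  depth <- min(vapply(paths, length, integer(1)))
  lca <- db$root
  for (d in seq_len(depth)) {
    at_d <- vapply(paths, `[[`, integer(1), d)
    if (all(at_d == at_d[1])) lca <- at_d[1] else break
  }
  lca
}

#' Nearest ancestor at or above a target rank
#'
#' Walks rootward from `id` (inclusive) to the nearest node whose rank sits
#' at or above `target_rank` on the rank ladder; unranked nodes are skipped.
#' Returns `NA` when no such node exists below the root.
#'
#' @param db a [taxonomy_db()].
#' @param id a single taxon id.
#' @param target_rank rank label, e.g. `"genus"`.
#' @return taxon id or `NA`.
#' @export
ancestor_at_rank <- function(db, id, target_rank) {
  target <- rank_level(target_rank)
  if (is.na(target)) stop("unknown rank label: ", target_rank)
  path <- rev(lineage(db, id))     # leaf first
  for (node in path) {
    if (node == db$root) break
    lvl <- rank_level(db$rank[[as.character(node)]])
    if (!is.na(lvl) && lvl >= target) return(node)
  }
  NA_integer_
}
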