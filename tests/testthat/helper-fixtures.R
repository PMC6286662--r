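# Shared fixtures: the 10-node toy taxonomy used across the LCA tests,
# brute-force oracles, and small count matrices.

# root(1) -> Chordata(2) -> Actinopterygii(3) ->
#   Salmonidae(4) -> Salmo(5) -> S. salar(6); Coregonus(7) -> C. artedi(8)
#   Cyprinidae(9) -> Chrosomus(10)
toy_fish_db <- function() {
  nodes <- data.frame(
    id     = 1:10,
    parent = c(1, 1, 2, 3, 4, 5, 4, 7, 3, 9),
    rank   = c("root", "phylum", "class", "family", "genus", "species",
               "genus", "species", "family", "genus")
  )
  nm <- data.frame(id = 1:10, name = c(
    "root", "Chordata", "Actinopterygii", "Salmonidae", "Salmo",
    "Salmo salar", "Coregonus", "Coregonus artedi", "Cyprinidae", "Chrosomus"
  ))
  taxonomy_db(nodes, nm)
}

# Brute-force LCA: intersect the full root paths and take the deepest
# shared node. Independent of the package's prefix-walk implementation.
lca_oracle <- function(ids, db) {
  paths <- lapply(ids, function(i) lineage(db, i))
  common <- Reduce(intersect, paths)
  common[length(common)]
}

# Random rooted taxonomy with n internal/leaf nodes; each node's parent is
# drawn among earlier nodes, guaranteeing acyclicity.
random_taxonomy <- function(n, seed) {
  set.seed(seed)
  parent <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  ranks <- sample(c("species", "genus", "family", "order", "no rank"),
                  n, replace = TRUE)
  ranks[1] <- "root"
  taxonomy_db(data.frame(id = seq_len(n), parent = parent, rank = ranks))
}

# Exhaustive rarefaction oracle: enumerate every subset of n reads from the
# expanded read vector; richness mean and sd over all C(N, n) subsets.
rarefaction_oracle <- function(counts, n) {
  reads <- rep(seq_along(counts), counts)
  subsets <- utils::combn(length(reads), n)
  rich <- apply(subsets, 2, function(ix) length(unique(reads[ix])))
  list(mean = mean(rich), sd = sqrt(mean((rich - mean(rich))^2)))
}

# Small count matrix with the study's metadata layout.
small_count_matrix <- function() {
  counts <- rbind(
    "A_0"      = c(10L, 5L, 0L, 3L),
    "A_180"    = c(8L, 7L, 1L, 2L),
    "B_0(1)"   = c(4L, 3L, 0L, 1L),
    "B_0(2)"   = c(5L, 2L, 1L, 0L),
    "B_0(3)"   = c(6L, 4L, 0L, 2L)
  )
  colnames(counts) <- c("Salmo", "Coregonus", "RareEuk_01", "BactFam_001")
  meta <- data.frame(
    sample = rownames(counts),
    sampler = c("A", "A", "B", "B", "B"),
    site = "downstream",
    method = c("composite", "composite", "grab", "grab", "grab"),
    time_min = c(0L, 180L, 0L, 0L, 0L),
    replicate = c(NA, NA, 1L, 2L, 3L)
  )
  tmeta <- data.frame(
    taxon = colnames(counts),
    label = colnames(counts),
    locus = c("12S", "12S", "COI", "16S-bact")
  )
  count_matrix(counts, meta, tmeta)
}
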