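mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query_id = "OTU1", subject_acc = r[[1]], taxon_id = r[[2]],
               bit_score = r[[3]], pct_identity = r[[4]], stringsAsFactors = FALSE)
  }))
}

test_that("windowed LCA follows the worked examples", {
  db <- toy_fish_db()
  p <- assignment_params(min_bitscore = 250, lca_window = 0.05)

  # both salmonid species within the 5% window -> family, mean identity 98.5
  a <- assign_otu(mk_hits(list("a1", 6, 300, 99), list("a2", 8, 295, 98)), p, db)
  expect_equal(a$taxon_id, 4)
  expect_equal(a$rank, "family")
  expect_equal(a$mean_identity, 98.5)
  expect_equal(a$n_contributing, 2L)

  # second hit falls below the 285 cutoff -> species retained
  b <- assign_otu(mk_hits(list("b1", 6, 300, 99), list("b2", 8, 280, 98)), p, db)
  expect_equal(b$taxon_id, 6)
  expect_equal(b$rank, "species")
  expect_equal(b$mean_identity, 99)
  expect_false(b$demoted)

  # identity 93 < 95 -> species demoted to genus; 93 >= 90 so genus stands
  d <- assign_otu(mk_hits(list("d1", 6, 300, 93)), p, db)
  expect_equal(d$taxon_id, 5)
  expect_equal(d$rank, "genus")
  expect_true(d$demoted)

  # everything below the floor -> unassigned, not an error
  u <- assign_otu(mk_hits(list("u1", 6, 240, 99), list("u2", 8, 200, 98)), p, db)
  expect_true(is.na(u$taxon_id))
  expect_equal(u$n_contributing, 0L)
})

test_that("window boundary is closed and per-subject best HSP is used", {
  db <- toy_fish_db()
  p <- assignment_params(min_bitscore = 250, lca_window = 0.05)
  # bit 285 == (1 - 0.05) * 300 exactly: retained -> LCA at family
  a <- assign_otu(mk_hits(list("a1", 6, 300, 99), list("a2", 8, 285, 98)), p, db)
  expect_equal(a$taxon_id, 4)
  # duplicate accession: only its best HSP votes, so n_contributing stays 2
  b <- assign_otu(mk_hits(list("a1", 6, 300, 99), list("a1", 6, 290, 97),
                          list("a2", 8, 295, 98)), p, db)
  expect_equal(b$n_contributing, 2L)
  expect_equal(b$mean_identity, (99 + 98) / 2)
})

test_that("identity rules demote genus to family and give up above family", {
  db <- toy_fish_db()
  p <- assignment_params(min_bitscore = 250, lca_window = 0.05)
  # genus-level LCA with mean identity below 90 -> family
  a <- assign_otu(mk_hits(list("a1", 6, 300, 89), list("a2", 8, 298, 88)), p, db)
  # LCA of {6,8} is already family 4: no identity rule at family level
  expect_equal(a$taxon_id, 4)
  b <- assign_otu(mk_hits(list("b1", 6, 300, 89)), p, db)
  # species at 89 -> genus, then genus at 89 < 90 -> family
  expect_equal(b$taxon_id, 4)
  expect_equal(b$rank, "family")
  expect_true(b$demoted)
})

test_that("shrinking the window never yields a shallower raw LCA", {
  # identity thresholds disabled to isolate the windowing monotonicity
  db <- toy_fish_db()
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(2:6, 1)
    hits <- data.frame(
      query_id = "OTU1", subject_acc = sprintf("s%d", seq_len(n)),
      taxon_id = sample(c(6, 8, 10), n, replace = TRUE),
      bit_score = runif(n, 250, 330), pct_identity = runif(n, 90, 100),
      stringsAsFactors = FALSE)
    depths <- vapply(c(0.20, 0.10, 0.05, 0.02), function(w) {
      p <- assignment_params(min_bitscore = 250, lca_window = w,
                             species_min_identity = 0, genus_min_identity = 0)
      length(lineage(db, assign_otu(hits, p, db)$taxon_id))
    }, numeric(1))
    expect_true(all(diff(depths) >= 0))  # smaller window -> deeper or equal
  }
})

test_that("raising the bit-score floor never increases n_contributing", {
  db <- toy_fish_db()
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    hits <- data.frame(
      query_id = "OTU1", subject_acc = sprintf("s%d", seq_len(n)),
      taxon_id = sample(c(6, 8, 10), n, replace = TRUE),
      bit_score = runif(n, 150, 350), pct_identity = runif(n, 90, 100),
      stringsAsFactors = FALSE)
    ns <- vapply(c(0, 150, 250, 300), function(fl) {
      p <- assignment_params(min_bitscore = fl, lca_window = 0.05)
      assign_otu(hits, p, db)$n_contributing
    }, integer(1))
    expect_true(all(diff(ns) <= 0))
  }
})

test_that("constrained re-assignment drops disallowed taxa within the clade", {
  db <- toy_fish_db()
  p <- assignment_params(min_bitscore = 250, lca_window = 0.02)
  allowed <- c(6)  # Salmo salar on the expected-fish list; Coregonus not
  # equal scores to an allowed and a disallowed fish: disallowed hit dropped
  a <- constrained_reassign(
    mk_hits(list("a1", 6, 300, 99), list("a2", 8, 300, 99)),
    allowed_taxa = allowed, constraint_clade = 3, params = p, db = db)
  expect_equal(a$taxon_id, 6)
  expect_match(a$notes, "re-assigned")

  # all hits disallowed -> unassigned with a note
  b <- constrained_reassign(
    mk_hits(list("b1", 8, 300, 99)),
    allowed_taxa = allowed, constraint_clade = 3, params = p, db = db)
  expect_true(is.na(b$taxon_id))
  expect_match(b$notes, "expected-taxon list")

  # initial assignment outside the clade is returned unchanged
  db2 <- taxonomy_db(
    data.frame(id = c(1, 2, 3, 20, 21),
               parent = c(1, 1, 2, 1, 20),
               rank = c("root", "class", "species", "class", "species")))
  cc <- constrained_reassign(
    mk_hits(list("c1", 21, 300, 99)),
    allowed_taxa = 3, constraint_clade = 2, params = p, db = db2)
  expect_equal(cc$taxon_id, 21)

  # allowed list covering everything is the identity
  full <- constrained_reassign(
    mk_hits(list("f1", 6, 300, 99), list("f2", 8, 300, 99)),
    allowed_taxa = 1:10, constraint_clade = 3, params = p, db = db)
  plain <- assign_otu(mk_hits(list("f1", 6, 300, 99), list("f2", 8, 300, 99)), p, db)
  expect_equal(full$taxon_id, plain$taxon_id)

  expect_error(
    constrained_reassign(mk_hits(list("e", 6, 300, 99)),
                         allowed_taxa = NULL, constraint_clade = 3,
                         params = p, db = db),
    "empty")
})

test_that("post-hoc adjustments remove, merge and rename in order", {
  asg <- data.frame(
    query_id = c("O1", "O2", "O3", "O4"),
    taxon_id = c(11L, 12L, 13L, 13L),
    taxon_name = c("Gallus gallus", "Margariscus margarita", "Chrosomus", "Chrosomus"),
    stringsAsFactors = FALSE)
  adj <- data.frame(
    match = c("Gallus gallus", "Margariscus margarita"),
    action = c("remove", "merge_into"),
    target = c(NA, "Chrosomus"), stringsAsFactors = FALSE)
  out <- apply_taxon_adjustments(asg, adj)
  expect_false("Gallus gallus" %in% out$taxon_name)
  expect_equal(sum(out$taxon_name == "Chrosomus"), 3)
  expect_equal(unique(out$taxon_id[out$taxon_name == "Chrosomus"]), 13L)
  expect_length(attr(out, "adjustment_log"), 2)

  # empty rule set is the identity
  empty <- apply_taxon_adjustments(asg, adj[0, ])
  expect_equal(empty$taxon_name, asg$taxon_name)

  # a rule that matches nothing is an error naming the rule
  bad <- data.frame(match = "Nessiteras", action = "remove", target = NA)
  expect_error(apply_taxon_adjustments(asg, bad), "Nessiteras")
})

test_that("hit tables read from BLAST tabular with and without taxid column", {
  f <- withr::local_tempfile()
  line <- function(q, s, pid, len, bits, tax = NULL) {
    paste(c(q, s, pid, len, 0, 0, 1, len, 1, len, "1e-50", bits, tax), collapse = "\t")
  }
  writeLines(c(line("O1", "ACC1", 99.1, 150, 300, 6),
               line("O1", "ACC2", 98.0, 150, 290, 8)), f)
  h <- read_hit_table(f)
  expect_equal(nrow(h), 2)
  expect_equal(h$taxon_id, c(6L, 8L))
  expect_equal(h$bit_score, c(300, 290))

  f2 <- withr::local_tempfile()
  writeLines(c(line("O1", "ACC1", 99.1, 150, 300)), f2)
  expect_error(read_hit_table(f2), "taxid_map")
  h2 <- read_hit_table(f2, taxid_map = data.frame(subject_acc = "ACC1", taxon_id = 6))
  expect_equal(h2$taxon_id, 6L)
})

test_that("constructed toy hit tables are classified to their known truth", {
  toy <- generate_toy_taxonomy_and_hits(n_species = 24, seed = 11)
  res <- assign_all(toy$hits, assignment_params(250, 0.05), toy$db)
  res <- res[match(toy$truth$query_id, res$query_id), ]
  expect_equal(res$taxon_id, toy$truth$true_taxon)
  expect_equal(res$rank, toy$truth$true_rank)
  expect_equal(res$demoted, toy$truth$demoted)
})
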