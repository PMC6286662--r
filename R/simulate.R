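#' Define a synthetic stream sampling scenario
#'
#' A scenario bundles everything needed to simulate sequence-count tables
#' with the statistical structure the composite-versus-grab comparison
#' assumes: a taxon table with per-mL particle fluxes, clumping and
#' between-site retention; the composite and grab sampling schedules; the
#' storage model (psychrophilic bacterial bloom, eukaryotic eDNA decay); the
#' per-sample library size and the sequencer cross-talk rate.
#'
#' The particle model is compound Poisson: clusters of eDNA-bearing
#' particles arrive as a Poisson process and cluster sizes are geometric
#' with mean `1 + 1/clumping`, so `clumping = Inf` recovers a pure Poisson
#' count (the bacterial regime) and small `clumping` gives strongly
#' overdispersed counts (the clumped eukaryotic regime). Compound-Poisson
#' counts are additive across aliquots, which is exactly what makes
#' compositing informative. On top of the within-sample clumping, each
#' taxon's flux fluctuates over time as a lognormal AR(1) "patch" process
#' with marginal log-sd `patch_sd` and correlation time
#' `patch_corr_min` minutes: consecutive grab replicates see the same
#' momentary flux, while a 3-h composite averages over many patches.
#'
#' @param taxa data frame with columns `label`, `locus`, `flux`
#'   (expected particles per mL at the upstream site), `clumping`
#'   (dispersion parameter; `Inf` = Poisson), `retention` (fraction of flux
#'   surviving to the downstream site), `patch_sd` (lognormal sd of the
#'   temporal flux process; 0 = constant), `patch_group` (taxa sharing a
#'   group share one flux process, e.g. two barcodes of one genus),
#'   `bloom` (logical: grows in storage), `decays` (logical: decays in
#'   storage), `decay_scale` (optional per-taxon multiplier on the storage
#'   decay rate; shorter amplicons decay slower).
#' @param schedule list: `n_bottles`, `aliquots_per_bottle`,
#'   `aliquot_vol_ml`, `aliquot_interval_min`, `grab_replicates`,
#'   `grab_vol_ml`, `grab_interval_min` (named vector for
#'   `downstream`/`upstream`).
#' @param storage list: `decay_per_h` (exponential decay rate of eukaryotic
#'   counts per hour stored), `bloom_rate_per_h` and `bloom_max` (logistic
#'   growth rate and asymptotic fold-change of the bloom taxon).
#' @param library_size sequence reads drawn per sample.
#' @param crosstalk_rate per-read probability of misassignment to a random
#'   other sample.
#' @param patch_corr_min correlation time of the patch process, minutes.
#' @param seed integer seed.
#' @return an object of class `stream_scenario`.
#' @seealso [default_study_scenario()], [simulate_counts()]
#' @export
stream_scenario <- function(taxa, schedule, storage, library_size = 20000,
                            crosstalk_rate = 2e-4, patch_corr_min = 45,
                            seed = 1) {
  stopifnot(is.data.frame(taxa),
            all(c("label", "locus", "flux", "clumping", "retention") %in% colnames(taxa)))
  if (any(taxa$flux < 0)) stop("fluxes must be non-negative")
  if (any(taxa$retention <= 0 | taxa$retention > 1)) stop("retention must be in (0, 1]")
  if (any(taxa$clumping <= 0)) stop("clumping must be positive (Inf = Poisson)")
  if (library_size < 1) stop("library_size must be at least 1")
  if (crosstalk_rate < 0 || crosstalk_rate >= 1) stop("crosstalk_rate must be in [0, 1)")
  if (is.null(taxa$patch_sd)) taxa$patch_sd <- 0
  if (is.null(taxa$patch_group)) taxa$patch_group <- taxa$label
  if (is.null(taxa$bloom)) taxa$bloom <- FALSE
  if (is.null(taxa$decays)) taxa$decays <- FALSE
  if (is.null(taxa$decay_scale)) taxa$decay_scale <- 1
  need <- c("n_bottles", "aliquots_per_bottle", "aliquot_vol_ml",
            "aliquot_interval_min", "grab_replicates", "grab_vol_ml",
            "grab_interval_min")
  missing <- setdiff(need, names(schedule))
  if (length(missing)) stop("schedule lacks: ", paste(missing, collapse = ", "))
  if (schedule$aliquot_vol_ml <= 0 || schedule$grab_vol_ml <= 0) stop("volumes must be positive")
  structure(list(taxa = taxa, schedule = schedule, storage = storage,
                 library_size = library_size, crosstalk_rate = crosstalk_rate,
                 patch_corr_min = patch_corr_min, seed = seed),
            class = "stream_scenario")
}

#' @export
print.stream_scenario <- function(x, ...) {
  s <- x$schedule
  cat("<stream_scenario>", nrow(x$taxa), "taxa;",
      s$n_bottles, "composite bottles of",
      s$aliquots_per_bottle, "x", s$aliquot_vol_ml, "mL per site;",
      "library", x$library_size, "reads; seed", x$seed, "\n")
  invisible(x)
}

#' Scenario mirroring the stream deployment of the study design
#'
#' Two sites 100 m apart on a small stream below a fish-rearing facility.
#' Each site has a composite sampler (22 bottles, each compositing twelve
#' 45-mL volumes at 15-min intervals, i.e. 540 mL per 3-h bottle) and a grab
#' sampler (triplicate 500-mL bottles; every 6 h downstream, every 12 h
#' upstream). Two dominant fish genera are fed in from upstream effluent at
#' a roughly 4:1 flux ratio, with the numerator genus retained far less over
#' the 100 m reach (differential settling); a tail of ~30 rare eukaryotes is
#' strongly clumped; 150 bacterial families follow a geometric
#' rank-abundance curve with near-Poisson dispersion; one psychrophilic
#' bacterial family blooms with time held in cold storage while eukaryotic
#' eDNA decays.
#'
#' @param seed integer seed.
#' @return a [stream_scenario()].
#' @export
default_study_scenario <- function(seed = 1) {
  ## Fluxes are calibrated so that post-storage read shares echo the
  ## study's per-locus sequencing yields (bacterial reads dominating, with
  ## roughly 0.6% 12S and 1.5% COI), and the two fish genera enter at a
  ## ~3.85:1 flux ratio with strongly differential retention over the reach.
  fish <- data.frame(
    label = c("Salmo", "Coregonus", "Salmo", "Coregonus"),
    locus = c("12S", "12S", "COI", "COI"),
    flux = c(47.6, 12.4, 118, 30.7),
    clumping = 0.2,
    retention = c(0.392, 0.9, 0.392, 0.9),
    patch_sd = 0.9,
    ## both genera enter premixed through the rearing-facility effluent, so
    ## they share one flux process and their ratio is stable in time
    patch_group = "fish_effluent",
    bloom = FALSE, decays = TRUE,
    decay_scale = c(0.3, 0.3, 1, 1),   # the short 12S locus decays slower
    stringsAsFactors = FALSE
  )
  ## The rare-eukaryote tail decays steeply: most taxa are either common
  ## enough that a 500-mL bottle nearly always captures them, or too rare
  ## for either method to see, which is what keeps per-taxon detection
  ## rates comparable between methods even though profiles are clumped.
  n_rare <- 30
  rare <- data.frame(
    label = sprintf("RareEuk_%02d", seq_len(n_rare)),
    locus = rep(c("COI", "16S-euk"), c(25, 5)),
    flux = c(40 * 0.62^(0:24), c(4, 2, 1, 0.5, 0.25)),
    clumping = 0.05,
    retention = 0.8,
    patch_sd = 0.8,
    patch_group = sprintf("RareEuk_%02d", seq_len(n_rare)),
    bloom = FALSE, decays = TRUE,
    decay_scale = 1,
    stringsAsFactors = FALSE
  )
  n_fam <- 150
  w <- 0.96^(seq_len(n_fam) - 1)
  fam_labels <- sprintf("BactFam_%03d", seq_len(n_fam))
  fam_labels[8] <- "Flavobacteriaceae"
  bact <- data.frame(
    label = fam_labels,
    locus = "16S-bact",
    flux = 5000 * w / sum(w),
    clumping = Inf,
    retention = 1.0,
    patch_sd = 0.05,
    patch_group = fam_labels,
    bloom = fam_labels == "Flavobacteriaceae",
    decays = FALSE,
    decay_scale = 1,
    stringsAsFactors = FALSE
  )
  taxa <- rbind(fish, rare, bact)
  stream_scenario(
    taxa = taxa,
    schedule = list(
      n_bottles = 22, aliquots_per_bottle = 12, aliquot_vol_ml = 45,
      aliquot_interval_min = 15, grab_replicates = 3, grab_vol_ml = 500,
      grab_interval_min = c(downstream = 360, upstream = 720)
    ),
    storage = list(decay_per_h = 0.035, bloom_rate_per_h = 0.15, bloom_max = 30),
    library_size = 20000,
    crosstalk_rate = 2e-4,
    patch_corr_min = 30,
    seed = seed
  )
}

## geometric-cluster compound Poisson draw; m is the mean cluster size
## (m = 1 gives pure Poisson). Vectorized over lam/m.
rcompound_pois <- function(lam, m) {
  nclus <- stats::rpois(length(lam), lam / m)
  out <- nclus
  idx <- which(nclus > 0 & m > 1)
  if (length(idx)) {
    out[idx] <- nclus[idx] +
      stats::rnbinom(length(idx), size = nclus[idx], prob = 1 / m[idx])
  }
  out
}

bloom_factor <- function(hours, rate, bmax) {
  bmax / (1 + (bmax - 1) * exp(-rate * hours))
}

#' Simulate a sequence-count table from a stream scenario
#'
#' Draws per-taxon particle counts for every aliquot and grab bottle from
#' the scenario's compound-Poisson patch model, sums composite aliquots into
#' bottles, applies downstream retention, then applies the storage model at
#' recovery time (bottles initiated earlier are stored longer): exponential
#' binomial thinning of decaying taxa and logistic bloom growth for the
#' bloom taxon. Sequence reads are then drawn multinomially per sample at
#' the fixed library size from the post-storage particle composition — which
#' decouples total input DNA from the number of reads recovered — and
#' finally each read is misassigned to a random other sample with the
#' cross-talk probability.
#'
#' Sampler codes: A = downstream composite, B = downstream grab,
#' C = upstream composite, D = upstream grab.
#'
#' @param scenario a [stream_scenario()].
#' @return a [count_matrix()] of reads (samples x taxa). The attribute
#'   `"truth"` records the generating quantities: the taxon table,
#'   per-sample true particle counts before and after storage, and the
#'   expected numerator fraction of the two fish genera at each site.
#' @export
simulate_counts <- function(scenario) {
  stopifnot(inherits(scenario, "stream_scenario"))
  set.seed(scenario$seed)
  tx <- scenario$taxa
  sc <- scenario$schedule
  st <- scenario$storage
  n_taxa <- nrow(tx)
  m <- ifelse(is.finite(tx$clumping), 1 + 1 / tx$clumping, 1)

  interval <- sc$aliquot_interval_min
  t_end <- sc$n_bottles * sc$aliquots_per_bottle * interval
  grid <- seq(0, t_end - interval, by = interval)
  rho <- exp(-interval / scenario$patch_corr_min)

  sites <- c("downstream", "upstream")
  groups <- unique(tx$patch_group)
  ## lognormal AR(1) patch process per (site, group); E[G] = 1
  patch <- list()
  for (s in sites) {
    gmat <- matrix(1, nrow = length(grid), ncol = length(groups),
                   dimnames = list(NULL, groups))
    for (g in groups) {
      sdg <- tx$patch_sd[match(g, tx$patch_group)]
      if (sdg > 0) {
        mu <- -sdg^2 / 2
        z <- numeric(length(grid))
        z[1] <- stats::rnorm(1, mu, sdg)
        innov <- stats::rnorm(length(grid) - 1, 0, sdg * sqrt(1 - rho^2))
        for (i in seq_along(innov)) z[i + 1] <- mu + rho * (z[i] - mu) + innov[i]
        gmat[, g] <- exp(z)
      }
    }
    patch[[s]] <- gmat
  }

  site_flux <- function(s) tx$flux * if (s == "downstream") tx$retention else 1

  samples <- list()   # each: list(name, site, method, sampler, time, counts)
  codes <- c(downstream.composite = "A", downstream.grab = "B",
             upstream.composite = "C", upstream.grab = "D")

  for (s in sites) {
    fx <- site_flux(s)
    gmat <- patch[[s]][, tx$patch_group, drop = FALSE]
    ## composite bottles
    for (b in seq_len(sc$n_bottles)) {
      idx <- (b - 1) * sc$aliquots_per_bottle + seq_len(sc$aliquots_per_bottle)
      lam <- gmat[idx, , drop = FALSE] *
        matrix(fx * sc$aliquot_vol_ml, nrow = length(idx), ncol = n_taxa, byrow = TRUE)
      draws <- rcompound_pois(as.vector(t(lam)), rep(m, length(idx)))
      counts <- colSums(matrix(draws, nrow = length(idx), byrow = TRUE))
      samples[[length(samples) + 1L]] <- list(
        site = s, method = "composite", sampler = codes[[paste(s, "composite", sep = ".")]],
        time = grid[idx[1]], replicate = NA_integer_, particles = counts)
    }
    ## grab events
    g_int <- sc$grab_interval_min[[s]]
    events <- seq(0, t_end - interval, by = g_int)
    for (et in events) {
      ti <- which(grid == et)
      for (r in seq_len(sc$grab_replicates)) {
        lam <- gmat[ti, ] * fx * sc$grab_vol_ml
        counts <- rcompound_pois(lam, m)
        samples[[length(samples) + 1L]] <- list(
          site = s, method = "grab", sampler = codes[[paste(s, "grab", sep = ".")]],
          time = et, replicate = r, particles = counts)
      }
    }
  }

  n_samp <- length(samples)
  particles <- matrix(unlist(lapply(samples, `[[`, "particles")),
                      nrow = n_samp, ncol = n_taxa, byrow = TRUE)
  time_min <- vapply(samples, `[[`, numeric(1), "time")
  pre_storage <- particles

  ## storage at recovery: earlier-initiated bottles store longer
  hours <- (t_end - time_min) / 60
  for (j in which(tx$decays)) {
    decay_p <- exp(-st$decay_per_h * tx$decay_scale[j] * hours)
    particles[, j] <- stats::rbinom(n_samp, particles[, j], decay_p)
  }
  for (j in which(tx$bloom)) {
    f <- bloom_factor(hours, st$bloom_rate_per_h, st$bloom_max)
    growth <- stats::rpois(n_samp, particles[, j] * (f - 1))
    particles[, j] <- particles[, j] + growth
  }

  ## sequencing: multinomial reads from post-storage composition
  reads <- matrix(0L, n_samp, n_taxa)
  for (i in seq_len(n_samp)) {
    tot <- sum(particles[i, ])
    if (tot > 0) {
      reads[i, ] <- stats::rmultinom(1, scenario$library_size, particles[i, ] / tot)
    }
  }

  ## sequencer cross-talk: each read jumps to a random other sample
  if (scenario$crosstalk_rate > 0 && n_samp > 1) {
    for (j in seq_len(n_taxa)) {
      moved <- stats::rbinom(n_samp, reads[, j], scenario$crosstalk_rate)
      if (sum(moved) > 0) {
        reads[, j] <- reads[, j] - moved
        dest <- stats::rmultinom(1, sum(moved), rep(1 / n_samp, n_samp))
        reads[, j] <- reads[, j] + dest[, 1]
      }
    }
  }

  sampler <- vapply(samples, `[[`, character(1), "sampler")
  repl <- vapply(samples, function(x) x$replicate, integer(1))
  names_out <- ifelse(is.na(repl),
                      sprintf("%s_%d", sampler, as.integer(time_min)),
                      sprintf("%s_%d(%d)", sampler, as.integer(time_min), repl))
  taxon_cols <- ifelse(duplicated(tx$label) | duplicated(tx$label, fromLast = TRUE),
                       paste(tx$label, tx$locus, sep = "_"), tx$label)
  dimnames(reads) <- list(names_out, taxon_cols)
  dimnames(particles) <- dimnames(pre_storage) <- list(names_out, taxon_cols)
  sample_meta <- data.frame(
    sampler = sampler,
    site = vapply(samples, `[[`, character(1), "site"),
    method = vapply(samples, `[[`, character(1), "method"),
    time_min = as.integer(time_min), replicate = repl,
    row.names = names_out, stringsAsFactors = FALSE
  )
  taxon_meta <- data.frame(label = tx$label, locus = tx$locus,
                           row.names = taxon_cols, stringsAsFactors = FALSE)
  out <- count_matrix(reads, sample_meta, taxon_meta)

  frac <- function(s) {
    fx <- site_flux(s)
    sum(fx[tx$label == "Salmo"]) /
      sum(fx[tx$label %in% c("Salmo", "Coregonus")])
  }
  attr(out, "truth") <- list(
    taxa = tx, storage = st, schedule = sc, seed = scenario$seed,
    particles_pre_storage = pre_storage, particles_post_storage = particles,
    expected_fraction = if (any(tx$label == "Salmo"))
      c(downstream = frac("downstream"), upstream = frac("upstream")) else NULL
  )
  out
}

#' Generate a toy taxonomy and matching alignment hit tables
#'
#' Builds a rank-complete random taxonomy (root, class, orders, families,
#' genera with two species each) and, for each species, an OTU hit table
#' constructed so the correct LCA outcome is known: the true taxon gets the
#' best bit score; decoy hits to a congeneric species fall inside or outside
#' the LCA window depending on the case; a far decoy from another family
#' always falls outside. Three cases cycle across OTUs: a clean
#' species-level assignment, a congener inside the window (LCA lands on the
#' genus), and a species-level case with low identity that the classifier
#' must demote to genus.
#'
#' @param n_species number of species (at least 2).
#' @param seed integer seed.
#' @param lca_window,min_bitscore parameters the tables are constructed for.
#' @return list with `db` (a [taxonomy_db()]), `hits` (data frame of HSPs
#'   for all OTUs) and `truth` (data frame: `query_id`, `true_taxon`,
#'   `true_rank`, `demoted`).
#' @export
generate_toy_taxonomy_and_hits <- function(n_species = 20, seed = 1,
                                           lca_window = 0.05,
                                           min_bitscore = 250) {
  stopifnot(n_species >= 2)
  set.seed(seed)
  n_gen <- ceiling(n_species / 2)
  n_fam <- ceiling(n_gen / 2)
  n_ord <- ceiling(n_fam / 2)

  ids <- list(root = 1L, class = 2L)
  nodes <- data.frame(id = c(1L, 2L), parent = c(1L, 1L),
                      rank = c("root", "class"), stringsAsFactors = FALSE)
  nm <- c("cellular organisms", "ToyClass")
  nxt <- 3L
  ord_ids <- integer(n_ord); fam_ids <- integer(n_fam); gen_ids <- integer(n_gen)
  sp_ids <- integer(n_species)
  for (i in seq_len(n_ord)) {
    ord_ids[i] <- nxt
    nodes <- rbind(nodes, data.frame(id = nxt, parent = 2L, rank = "order"))
    nm <- c(nm, sprintf("Order%02d", i)); nxt <- nxt + 1L
  }
  for (i in seq_len(n_fam)) {
    fam_ids[i] <- nxt
    nodes <- rbind(nodes, data.frame(id = nxt, parent = ord_ids[(i - 1) %% n_ord + 1],
                                     rank = "family"))
    nm <- c(nm, sprintf("Family%02d", i)); nxt <- nxt + 1L
  }
  for (i in seq_len(n_gen)) {
    gen_ids[i] <- nxt
    nodes <- rbind(nodes, data.frame(id = nxt, parent = fam_ids[(i - 1) %% n_fam + 1],
                                     rank = "genus"))
    nm <- c(nm, sprintf("Genus%02d", i)); nxt <- nxt + 1L
  }
  for (i in seq_len(n_species)) {
    sp_ids[i] <- nxt
    nodes <- rbind(nodes, data.frame(id = nxt, parent = gen_ids[(i - 1) %% n_gen + 1],
                                     rank = "species"))
    nm <- c(nm, sprintf("Genus%02d species%02d", (i - 1) %% n_gen + 1, i)); nxt <- nxt + 1L
  }
  db <- taxonomy_db(nodes, data.frame(id = nodes$id, name = nm))

  cases <- rep(c("species", "genus", "demoted"), length.out = n_species)
  hits <- list(); truth <- list()
  for (i in seq_len(n_species)) {
    qid <- sprintf("OTU%03d", i)
    sp <- sp_ids[i]
    gen <- gen_ids[(i - 1) %% n_gen + 1]
    siblings <- sp_ids[sp_ids != sp &
                         nodes$parent[match(sp_ids, nodes$id)] == gen]
    best <- stats::runif(1, 280, 330)
    id_true <- if (cases[i] == "demoted") 93 else stats::runif(1, 97, 100)
    h <- data.frame(query_id = qid, subject_acc = sprintf("ACC%03da", i),
                    taxon_id = sp, bit_score = best, pct_identity = id_true,
                    stringsAsFactors = FALSE)
    if (length(siblings)) {
      inside <- cases[i] == "genus"
      sib_bit <- if (inside) best * (1 - lca_window / 2) else best * (1 - 2 * lca_window)
      h <- rbind(h, data.frame(query_id = qid, subject_acc = sprintf("ACC%03db", i),
                               taxon_id = siblings[1], bit_score = sib_bit,
                               pct_identity = if (cases[i] == "demoted") 93 else
                                 stats::runif(1, 96, 100)))
    }
    far <- sp_ids[nodes$parent[match(sp_ids, nodes$id)] != gen]
    if (length(far)) {
      h <- rbind(h, data.frame(query_id = qid, subject_acc = sprintf("ACC%03dc", i),
                               taxon_id = far[1], bit_score = best * (1 - 3 * lca_window),
                               pct_identity = stats::runif(1, 85, 95)))
    }
    case_i <- if (cases[i] == "genus" && !length(siblings)) "species" else cases[i]
    truth[[i]] <- data.frame(
      query_id = qid,
      true_taxon = switch(case_i, species = sp, genus = gen, demoted = gen),
      true_rank = switch(case_i, species = "species", genus = "genus", demoted = "genus"),
      demoted = case_i == "demoted", stringsAsFactors = FALSE)
    hits[[i]] <- h
  }
  list(db = db, hits = do.call(rbind, hits), truth = do.call(rbind, truth))
}
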