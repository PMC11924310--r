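# Run code with a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate a logistic growth series with multiplicative noise
#'
#' Daily sampling of a logistic trajectory
#' \deqn{N(t) = K / (1 + \frac{K - N_0}{N_0} e^{-\mu t})}
#' with multiplicative lognormal observation noise of coefficient of
#' variation `noise_cv` (abundances are positive, so noise is
#' multiplicative by construction). One record per day including day 0.
#'
#' @param mu True maximum specific growth rate, per day.
#' @param n0 Initial abundance (> 0).
#' @param capacity Carrying capacity K (>= n0).
#' @param days Number of days (>= 3); sampling at 0, 1, ..., days.
#' @param noise_cv Coefficient of variation of the lognormal noise
#'   (>= 0; 0 = noiseless).
#' @param seed Integer seed; same seed and parameters give an identical
#'   series.
#' @inheritParams growth_series
#'
#' @return A [growth_series()].
#' @export
simulate_growth_series <- function(mu, n0, capacity, days = 6L,
                                   noise_cv = 0, seed = 1L,
                                   strain_id = "sim", condition = list(),
                                   replicate = 1L) {
  if (n0 <= 0 || capacity <= 0) stop("n0 and capacity must be positive")
  if (capacity < n0) stop("capacity must be at least n0")
  if (days < 3L) stop("need at least 3 days of sampling")
  if (noise_cv < 0) stop("noise_cv must be nonnegative")
  t <- 0:days
  n <- capacity / (1 + ((capacity - n0) / n0) * exp(-mu * t))
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    n <- with_seed(seed, n * stats::rlnorm(length(n), -sdlog^2 / 2, sdlog))
  }
  growth_series(t, n, strain_id = strain_id, condition = condition,
                replicate = replicate)
}

#' Simulate a thermal-gradient growth-rate experiment
#'
#' Draws per-replicate growth rates at each temperature from the
#' exponential-times-quadratic curve [tpc_value()] plus additive
#' Gaussian noise (rates may be negative, so noise is additive).
#'
#' @param truth Named list/vector with true `a`, `b`, `z`, `w`.
#' @param temperatures Tested temperatures, degrees C; at least 5
#'   distinct values (the curve has 4 parameters).
#' @param replicates Replicates per temperature (>= 1).
#' @param noise_sd Standard deviation of the additive rate noise,
#'   per day.
#' @param seed Integer seed.
#'
#' @return Data frame `temperature`, `replicate`, `rate`.
#' @export
simulate_tpc_experiment <- function(truth, temperatures, replicates = 4L,
                                    noise_sd = 0, seed = 1L) {
  if (length(unique(temperatures)) < 5L)
    stop("need at least 5 distinct temperatures (4-parameter model)")
  if (replicates < 1L) stop("need at least 1 replicate")
  p <- as.list(truth)
  d <- expand.grid(temperature = temperatures,
                   replicate = seq_len(replicates))
  d <- d[order(d$temperature, d$replicate), ]
  rownames(d) <- NULL
  d$rate <- tpc_value(d$temperature, p$a, p$b, p$z, p$w)
  if (noise_sd > 0)
    d$rate <- with_seed(seed,
                        d$rate + stats::rnorm(nrow(d), 0, noise_sd))
  d
}

#' Simulate a 15N nitrate-uptake assay
#'
#' For each substrate level the true cell-normalized uptake
#' \eqn{V = V_{max} S / (K_s + S)} is converted to the delta-15N the
#' analyzer would report by inverting the mixing model of
#' [absolute_uptake()]; multiplicative lognormal noise is applied to the
#' delta-15N. Source-pool enrichment defaults to the tracer mixing rule
#' of [source_atom_percent()].
#'
#' @param truth_vmax True V_max, umol N / h / cell.
#' @param truth_ks True K_s, umol/L.
#' @param substrate_levels Nitrate additions, umol/L (all > 0).
#' @param cells Cell density, cells/L.
#' @param pn0 Particulate nitrogen, umol N/L.
#' @param source_atom_pct Optional atom percent 15N of the source pool
#'   per level (same length as `substrate_levels`); computed from the
#'   label-mixing rule when NULL.
#' @param duration Incubation duration, h (> 0).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   delta-15N noise.
#' @param replicates Replicates per level.
#' @param seed Integer seed.
#' @param atom_pct_baseline Baseline atom percent 15N.
#' @param strain_id Strain identifier for the output table.
#'
#' @return Data frame of isotope samples: `strain_id`, `substrate`,
#'   `replicate`, `delta15n_particulate`, `atom_pct_source`,
#'   `atom_pct_baseline`, `pon`, `duration`, `cells`.
#' @export
simulate_uptake_assay <- function(truth_vmax, truth_ks, substrate_levels,
                                  cells = 5e7, pn0 = 10,
                                  source_atom_pct = NULL,
                                  duration = 2 / 3, noise_cv = 0,
                                  replicates = 1L, seed = 1L,
                                  atom_pct_baseline = 0.3663,
                                  strain_id = "sim") {
  if (any(substrate_levels <= 0)) stop("substrate levels must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (is.null(source_atom_pct)) {
    source_atom_pct <- source_atom_percent(substrate_levels)
  } else if (length(source_atom_pct) != length(substrate_levels)) {
    stop("source_atom_pct must have one value per substrate level")
  }
  d <- expand.grid(level = seq_along(substrate_levels),
                   replicate = seq_len(replicates))
  s <- substrate_levels[d$level]
  a_src <- source_atom_pct[d$level]
  v_cell <- truth_vmax * s / (truth_ks + s)
  frac <- v_cell * cells * duration / pn0
  if (any(frac >= 1))
    stop("uptake over the incubation exceeds the particulate N pool; ",
         "reduce cells, duration or V_max")
  a_pn <- atom_pct_baseline + frac * (a_src - atom_pct_baseline)
  delta <- atom_percent_to_delta(a_pn)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    delta <- with_seed(seed,
                       delta * stats::rlnorm(length(delta), -sdlog^2 / 2, sdlog))
  }
  data.frame(strain_id = strain_id, substrate = s, replicate = d$replicate,
             delta15n_particulate = delta, atom_pct_source = a_src,
             atom_pct_baseline = atom_pct_baseline, pon = pn0,
             duration = duration, cells = cells)
}

#' Default photoperiod reaction-norm shapes
#'
#' Convenience truth curves for simulation: the arctic shape is
#' saturating in photoperiod (no decline under continuous light); the
#' temperate shape peaks near 17 h and declines towards 24 h.
#'
#' @param photoperiod Photoperiod, h. Vectorized.
#' @return Growth rate, per day.
#' @export
#' @rdname photoperiod_curves
photoperiod_curve_arctic <- function(photoperiod) {
  0.55 * photoperiod / (photoperiod + 3)
}

#' @export
#' @rdname photoperiod_curves
photoperiod_curve_temperate <- function(photoperiod) {
  0.60 * exp(-((photoperiod - 17) / 8)^2)
}

#' Simulate a photoperiod growth-rate table
#'
#' Draws per-replicate maximum growth rates from origin-specific truth
#' curves with multiplicative lognormal noise (rates are positive).
#'
#' @param curve_arctic,curve_temperate Functions photoperiod (h) ->
#'   rate (per day).
#' @param photoperiods Tested photoperiods, h.
#' @param strains_per_origin Number of strains per origin.
#' @param replicates Replicates per strain and photoperiod.
#' @param noise_cv Coefficient of variation of the lognormal noise.
#' @param seed Integer seed.
#'
#' @return Data frame `strain_id`, `origin`, `photoperiod`, `replicate`,
#'   `mu_max` (not yet normalized; see [normalize_rates()]).
#' @export
simulate_photoperiod_table <- function(curve_arctic = photoperiod_curve_arctic,
                                       curve_temperate = photoperiod_curve_temperate,
                                       photoperiods = c(1, 4, 8, 16, 24),
                                       strains_per_origin = 4L,
                                       replicates = 3L, noise_cv = 0.05,
                                       seed = 1L) {
  grid <- expand.grid(origin = c("arctic", "temperate"),
                      strain = seq_len(strains_per_origin),
                      photoperiod = photoperiods,
                      replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  mu <- ifelse(grid$origin == "arctic",
               curve_arctic(grid$photoperiod),
               curve_temperate(grid$photoperiod))
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    mu <- with_seed(seed,
                    mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog))
  }
  data.frame(strain_id = paste0(ifelse(grid$origin == "arctic", "A", "T"),
                                grid$strain),
             origin = grid$origin, photoperiod = grid$photoperiod,
             replicate = grid$replicate, mu_max = mu,
             stringsAsFactors = FALSE)
}

#' Default species tree and habitat labels for the substitution screen
#'
#' A 10-taxon tree in which arctic and temperate taxa interleave across
#' clades, so that a residue fixed in all arctic tips necessarily arose
#' on several independent branches; each habitat includes culture and
#' metatranscriptome sources, and the focal species pair (one arctic,
#' one temperate) is flagged.
#'
#' @return `default_caas_tree()`: a `phylo`; `default_caas_labels()`:
#'   a data frame `taxon`, `habitat`, `source`, `is_focal`.
#' @export
#' @rdname caas_defaults
default_caas_tree <- function() {
  ape::read.tree(text = paste0(
    "(((Tgravida_A1:1,ArcticMeta1:1):1,(Trotula_T1:1,TempMeta1:1):1):1,",
    "((Dconfervacea:1,ArcticMeta2:1):1,(Chaetoceros_sp:1,TempMeta2:1):1):1,",
    "(Sbioculatus:1,Ldanicus:1):1);"))
}

#' @export
#' @rdname caas_defaults
default_caas_labels <- function() {
  data.frame(
    taxon = c("Tgravida_A1", "ArcticMeta1", "Dconfervacea", "ArcticMeta2",
              "Sbioculatus", "Trotula_T1", "TempMeta1", "Chaetoceros_sp",
              "TempMeta2", "Ldanicus"),
    habitat = rep(c("arctic", "temperate"), each = 5L),
    source = c("culture", "metatranscriptome", "culture", "metatranscriptome",
               "culture", "culture", "metatranscriptome", "culture",
               "metatranscriptome", "culture"),
    is_focal = c(TRUE, FALSE, FALSE, FALSE, FALSE,
                 TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# preorder parent-before-child edge ordering of a phylo tree
preorder_edges <- function(tree) {
  po <- stats::reorder(tree, "postorder")$edge
  po[rev(seq_len(nrow(po))), , drop = FALSE]
}

#' Simulate habitat-labeled homolog clusters with planted convergent sites
#'
#' Background columns evolve neutrally on the species tree (per-branch
#' substitution probability `sub_prob`, uniform 20-residue kernel).
#' Planted columns receive one residue fixed in every arctic tip and a
#' disjoint residue set in the temperate tips; with an interleaved tree
#' (the default) the arctic residue arises on at least two independent
#' branches. Planted columns and their +/- `window` flanks are kept
#' substitution- and gap-free so the conserved-context check is
#' exercised against unambiguous truth; a small fraction of the
#' remaining columns is made heavily gapped to exercise trimming.
#'
#' @param tree Species tree (`phylo`) over the taxa; default
#'   [default_caas_tree()].
#' @param labels Habitat labels (`taxon`, `habitat`, `source`,
#'   `is_focal`); default [default_caas_labels()]. If `source` is
#'   absent, sources are drawn from `source_mix` forcing at least one
#'   metatranscriptome member per habitat.
#' @param n_clusters Number of clusters.
#' @param length Alignment length (columns).
#' @param n_planted Planted convergent sites per cluster.
#' @param source_mix Length-2 numeric c(culture, metatranscriptome)
#'   fractions, used only when `labels$source` is missing.
#' @param sub_prob Per-branch, per-column neutral substitution
#'   probability.
#' @param window Protected flank half-width around planted sites
#'   (matches the default of [check_conserved_context()]).
#' @param gap_col_frac Fraction of free columns made heavily gapped.
#' @param seed Integer seed; same seed gives byte-identical datasets.
#'
#' @return List of class `caas_simulation`: `clusters` (list of
#'   [homolog_cluster()]), `truth` (data frame `cluster_id`, `column`
#'   (1-based original coordinates), `arctic_residue`), `tree`,
#'   `labels`, `seed`.
#' @export
simulate_caas_dataset <- function(tree = default_caas_tree(),
                                  labels = default_caas_labels(),
                                  n_clusters = 10L, length = 300L,
                                  n_planted = 5L,
                                  source_mix = c(0.5, 0.5),
                                  sub_prob = 0.02, window = 5L,
                                  gap_col_frac = 0.03, seed = 1L) {
  if (!all(tree$tip.label %in% labels$taxon))
    stop("tree tips missing from labels: ",
         paste(setdiff(tree$tip.label, labels$taxon), collapse = ", "))
  labels <- labels[match(tree$tip.label, labels$taxon), , drop = FALSE]
  for (h in c("arctic", "temperate"))
    if (sum(labels$habitat == h) < 2L)
      stop("habitat '", h, "' has fewer than 2 taxa; screen untestable")
  if (n_planted > length) stop("cannot plant more sites than columns")
  if (n_planted > 0 && length < 2L * window + 1L)
    stop("alignment too short for the protected windows")

  with_seed(seed, {
    if (!"source" %in% names(labels)) {
      labels$source <- sample(c("culture", "metatranscriptome"),
                              nrow(labels), replace = TRUE,
                              prob = source_mix)
      for (h in c("arctic", "temperate")) {
        sel <- which(labels$habitat == h)
        if (!any(labels$source[sel] == "metatranscriptome"))
          labels$source[sample(sel, 1L)] <- "metatranscriptome"
      }
    }
    if (!"is_focal" %in% names(labels)) labels$is_focal <- FALSE

    n_tip <- base::length(tree$tip.label)
    edges <- preorder_edges(tree)
    root <- n_tip + 1L
    clusters <- vector("list", n_clusters)
    truth <- list()

    for (c_i in seq_len(n_clusters)) {
      cid <- sprintf("cluster%03d", c_i)
      L <- length
      rootseq <- sample(AA20, L, replace = TRUE)

      planted <- integer(0)
      if (n_planted > 0L) {
        avail <- seq(window + 1L, L - window)
        for (k in seq_len(n_planted)) {
          if (!base::length(avail))
            stop("could not place ", n_planted,
                 " non-overlapping protected windows in ", L, " columns")
          p <- if (base::length(avail) == 1L) avail else sample(avail, 1L)
          planted <- c(planted, p)
          avail <- avail[abs(avail - p) > 2L * window]
        }
        planted <- sort(planted)
      }
      protected <- unique(unlist(lapply(planted, function(p)
        (p - window):(p + window))))
      free <- setdiff(seq_len(L), protected)

      # neutral evolution, free columns only
      seqmat <- matrix(NA_character_, n_tip + tree$Nnode, L)
      seqmat[root, ] <- rootseq
      for (e in seq_len(nrow(edges))) {
        par <- edges[e, 1L]; ch <- edges[e, 2L]
        s <- seqmat[par, ]
        if (base::length(free)) {
          hit <- free[stats::runif(base::length(free)) < sub_prob]
          if (base::length(hit))
            s[hit] <- sample(AA20, base::length(hit), replace = TRUE)
        }
        seqmat[ch, ] <- s
      }
      tips <- seqmat[seq_len(n_tip), , drop = FALSE]
      rownames(tips) <- tree$tip.label

      arc <- labels$habitat == "arctic"
      for (p in planted) {
        r_a <- sample(AA20, 1L)
        pool <- setdiff(AA20, r_a)
        k_t <- sample(1:3, 1L)
        tset <- sample(pool, k_t)
        tips[arc, p] <- r_a
        tips[!arc, p] <- sample(tset, sum(!arc), replace = TRUE)
        truth[[base::length(truth) + 1L]] <-
          data.frame(cluster_id = cid, column = p, arctic_residue = r_a,
                     stringsAsFactors = FALSE)
      }

      # heavily gapped decoy columns outside the protected windows
      n_gap <- round(gap_col_frac * base::length(free))
      if (n_gap > 0L) {
        gap_cols <- sample(free, n_gap)
        for (g in gap_cols) {
          n_gapped <- sample(ceiling(0.6 * n_tip):n_tip, 1L)
          tips[sample(n_tip, n_gapped), g] <- "-"
        }
      }

      seqs <- apply(tips, 1L, paste, collapse = "")
      clusters[[c_i]] <- homolog_cluster(cid, seqs, labels, tree = tree)
    }

    truth <- if (base::length(truth)) do.call(rbind, truth)
             else data.frame(cluster_id = character(), column = integer(),
                             arctic_residue = character(),
                             stringsAsFactors = FALSE)
    structure(list(clusters = clusters, truth = truth, tree = tree,
                   labels = labels, seed = seed),
              class = "caas_simulation")
  })
}

#' Write a simulated substitution-screen dataset to disk
#'
#' One aligned FASTA per cluster (header convention
#' `taxon|source|habitat[|focal]`), the species tree as newick, and the
#' planted truth as TSV. Output is deterministic: the same simulation
#' yields byte-identical files.
#'
#' @param sim A `caas_simulation` from [simulate_caas_dataset()].
#' @param dir Output directory (created if needed).
#'
#' @return Invisibly, the paths written.
#' @export
write_caas_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "caas_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (cl in sim$clusters) {
    p <- file.path(dir, paste0(cl$cluster_id, ".fasta"))
    write_fasta(cl$seqs, p, labels = cl$labels)
    paths <- c(paths, p)
  }
  tp <- file.path(dir, "species_tree.nwk")
  ape::write.tree(sim$tree, file = tp)
  tt <- file.path(dir, "truth.tsv")
  write_tsv(sim$truth, tt)
  invisible(c(paths, tp, tt))
}
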