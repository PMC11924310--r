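test_that("cluster construction enforces labeling and equal lengths", {
  expect_error(
    homolog_cluster("c", c(a = "MKL", b = "MK"),
                    data.frame(taxon = c("a", "b"),
                               habitat = c("arctic", "temperate"),
                               source = "culture")),
    "equal length")
  expect_error(
    homolog_cluster("c", c(a = "MKL", b = "MKL"),
                    data.frame(taxon = "a", habitat = "arctic",
                               source = "culture")),
    "unlabeled")
})

test_that("single-linkage clustering matches a graph-components oracle", {
  base <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 2), collapse = "")  # 40 aa
  mutate_at <- function(s, pos, to = "W") {
    v <- strsplit(s, "")[[1]]; v[pos] <- to; paste(v, collapse = "")
  }
  A <- base
  B <- mutate_at(A, 1:8, "G")            # 80% identical to A
  C <- mutate_at(B, 9:16, "P")           # 80% to B, 60% to A
  D <- mutate_at(A, 1:20, "H")           # 50% to A
  seqs <- c(A = A, B = B, C = C, D = D)
  got <- cluster_homologs(seqs, 0.75)
  # oracle: brute-force pairwise identity (equal length, gapless) + igraph
  skip_if_not_installed("igraph")
  n <- length(seqs)
  edges <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (plain_identity(seqs[[i]], seqs[[j]]) >= 0.75)
      edges <- c(edges, i, j)
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  want <- unname(split(names(seqs), comp))
  norm <- function(x) sort(vapply(x, function(s) paste(sort(s), collapse = ","),
                                  character(1)))
  expect_equal(norm(got), norm(want))
  # A-B and B-C link at 80% but A-C only 60%: transitivity joins all three
  expect_true(any(vapply(got, function(cl)
    all(c("A", "B", "C") %in% cl), logical(1))))
  # trivial cases
  expect_length(cluster_homologs(c(x = A, y = A), 0.75), 1L)
  expect_length(cluster_homologs(c(x = A, y = D), 0.75), 2L)
  expect_length(cluster_homologs(character(0)), 0L)
})

test_that("trimming removes exactly the columns the gap-score rule names", {
  habs <- rep(c("arctic", "temperate"), each = 3)
  # gapless alignment: untouched, identity map
  m0 <- matrix("A", 6, 10)
  cl0 <- make_cluster(m0, habs)
  tr0 <- trim_alignment(cl0)
  expect_equal(nchar(tr0$seqs[[1]]), 10L)
  expect_equal(tr0$column_map, 1:10)
  # one fully gapped column among gapless ones: exactly it is removed
  m1 <- m0; m1[, 4] <- "-"
  tr1 <- trim_alignment(make_cluster(m1, habs))
  expect_equal(tr1$column_map, c(1:3, 5:10))
  # random gap pattern: compare against an independent recomputation
  set.seed(5)
  m2 <- matrix(sample(c("A", "K", "S"), 6 * 40, TRUE), 6, 40)
  for (j in sample(40, 12)) m2[sample(6, sample(0:6, 1)), j] <- "-"
  cl2 <- make_cluster(m2, habs)
  tr2 <- trim_alignment(cl2, gap_fraction_max = 0.2)
  gf <- colMeans(m2 == "-")
  u <- sort(unique(gf))
  keep <- if (length(u) == 1L) gf <= 0.2 else gf <= u[which.max(diff(u))]
  expect_equal(tr2$column_map, which(keep))
  # an alignment that is nothing but gaps cannot be trimmed
  expect_error(trim_alignment(make_cluster(matrix("-", 6, 4), habs)),
               "all columns")
})

test_that("the scanner reports exactly the disjoint-with-singleton columns", {
  habs <- c(rep("arctic", 3), rep("temperate", 6))
  m <- matrix("G", 9, 6)
  m[, 2] <- c("S", "S", "S", "A", "E", "H", "K", "Q", "R")  # arctic-specific
  m[, 3] <- c("A", "I", "A", "V", "V", "V", "V", "V", "V")  # temperate-specific
  m[, 4] <- c("L", "L", "L", "V", "V", "V", "V", "V", "V")  # both
  m[, 5] <- c("A", "C", "D", "E", "F", "G", "H", "I", "K")  # no singleton side
  m[1, 6] <- "-"                                            # gapped: skipped
  cl <- make_cluster(m, habs)
  recs <- scan_caas(cl)
  expect_equal(recs$column, c(2L, 3L, 4L))
  expect_equal(recs$specificity, c("arctic", "temperate", "both"))
  expect_equal(recs$arctic_residues, c("S", "A,I", "L"))
  expect_equal(recs$temperate_residues, c("A,E,H,K,Q,R", "V", "V"))
  # gap-tolerant mode also scans column 6 (all non-gap members are G: no record)
  recs_g <- scan_caas(cl, allow_gaps = TRUE)
  expect_equal(recs_g$column, c(2L, 3L, 4L))
})

test_that("scanning is invariant to member order and every record is disjoint", {
  sim <- simulate_caas_dataset(n_clusters = 3, length = 150, n_planted = 4,
                               seed = 31)
  for (cl in sim$clusters) {
    recs <- scan_caas(cl)
    perm <- sample(length(cl$seqs))
    cl2 <- homolog_cluster(cl$cluster_id, cl$seqs[perm],
                           cl$labels[perm, ], tree = cl$tree)
    recs2 <- scan_caas(cl2)
    expect_equal(recs$column, recs2$column)
    expect_equal(recs$specificity, recs2$specificity)
    # independent recomputation of the residue sets
    for (i in seq_len(nrow(recs))) {
      sets <- column_sets(cl, recs$column[i])
      expect_length(intersect(sets$arctic, sets$temperate), 0L)
      expect_equal(sort(strsplit(recs$arctic_residues[i], ",")[[1]]),
                   sort(sets$arctic))
    }
  }
})

test_that("conserved-context check separates planted sites from gap-flanked decoys", {
  habs <- rep(c("arctic", "temperate"), each = 3)
  m <- matrix("A", 6, 30)
  m[, 15] <- c("S", "S", "S", "V", "V", "V")  # candidate in a clean block
  m[, 24] <- c("L", "L", "L", "I", "I", "I")  # decoy...
  m[2, 26] <- "-"                             # ...next to a gap column
  cl <- make_cluster(m, habs)
  expect_true(as.logical(check_conserved_context(cl, 15)))
  expect_false(as.logical(check_conserved_context(cl, 24)))
  # window running off the alignment edge fails with the edge flag
  res <- check_conserved_context(cl, 3)
  expect_false(as.logical(res))
  expect_true(attr(res, "edge"))
  # high flank diversity fails even when gapless
  set.seed(8)
  m2 <- matrix(sample(c("A", "C", "D", "E", "F", "G"), 6 * 30, TRUE), 6, 30)
  m2[, 15] <- c("S", "S", "S", "V", "V", "V")
  expect_false(as.logical(check_conserved_context(make_cluster(m2, habs), 15)))
})

test_that("the additional-species filter demands non-focal support on both sides", {
  habs <- c("arctic", "arctic", "temperate", "temperate")
  m <- matrix("A", 4, 3)
  m[, 2] <- c("S", "S", "V", "V")
  # focal pair = first arctic + first temperate; both sides have others
  cl <- make_cluster(m, habs, focal = c(TRUE, FALSE, TRUE, FALSE))
  expect_true(filter_additional_species(cl, 2))
  # arctic side is focal-only at this site
  m2 <- m; m2[2, 2] <- "-"
  cl2 <- make_cluster(m2, habs, focal = c(TRUE, FALSE, TRUE, FALSE))
  expect_false(filter_additional_species(cl2, 2))
  # permuting members does not change the verdict
  perm <- c(3, 1, 4, 2)
  clp <- homolog_cluster("c1", cl$seqs[perm], cl$labels[perm, ])
  expect_true(filter_additional_species(clp, 2))
  # unflagged focal pair is a configuration error
  cl3 <- make_cluster(m, habs, focal = rep(FALSE, 4))
  expect_error(filter_additional_species(cl3, 2), "focal")
})

test_that("expression evidence requires metatranscriptomes from both habitats", {
  habs <- c("arctic", "arctic", "temperate", "temperate")
  m <- matrix("A", 4, 2)
  both <- make_cluster(m, habs,
                       sources = c("culture", "metatranscriptome",
                                   "culture", "metatranscriptome"))
  expect_true(filter_expression_evidence(both))
  none <- make_cluster(m, habs, sources = rep("culture", 4))
  expect_false(filter_expression_evidence(none))
  onesided <- make_cluster(m, habs,
                           sources = c("culture", "metatranscriptome",
                                       "culture", "culture"))
  expect_false(filter_expression_evidence(onesided))
})

test_that("origin counting matches exhaustive gains-only parsimony", {
  t1 <- ape::read.tree(text = "((A1,A2),(T1,T2));")
  st <- c(A1 = "S", A2 = "S", T1 = "V", T2 = "V")
  expect_equal(count_origins_fitch(t1, st, "S"), 1L)
  t2 <- ape::read.tree(text = "((A1,T1),(A2,T2));")
  expect_equal(count_origins_fitch(t2, st, "S"), 2L)
  allS <- c(A1 = "S", A2 = "S", T1 = "S", T2 = "S")
  expect_equal(count_origins_fitch(t1, allS, "S"), 1L)
  expect_equal(count_origins_fitch(t1, st, "W"), 0L)
  expect_error(count_origins_fitch(t1, st[-1], "S"), "missing")
  # random trees with <= 6 tips against the exhaustive oracle
  set.seed(17)
  for (i in 1:25) {
    ntip <- sample(3:6, 1)
    tr <- ape::rtree(ntip)
    states <- setNames(sample(c("S", "V", "L"), ntip, TRUE), tr$tip.label)
    expect_equal(count_origins_fitch(tr, states, "S"),
                 exhaustive_origins(tr, states, "S"),
                 info = paste("case", i))
  }
})

test_that("origin-specificity classification follows the singleton rule", {
  expect_equal(classify_origin_specificity("V", c("E", "G", "S", "T")),
               "arctic")
  expect_equal(classify_origin_specificity(c("D", "F", "T"), "S"),
               "temperate")
  expect_equal(classify_origin_specificity("L", "V"), "both")
  expect_error(classify_origin_specificity(c("A", "B"), c("C", "D")),
               "singleton")
  expect_error(classify_origin_specificity(c("A", "V"), "V"), "overlap")
  expect_error(classify_origin_specificity(character(0), "V"), "nonempty")
})

test_that("candidate summaries collapse positions to IDs correctly", {
  empty <- summarize_candidates(
    data.frame(cluster_id = character(), specificity = character()))
  expect_equal(empty$n_candidates, 0L)
  expect_equal(sum(empty$by_specificity), 0L)
  # one ID with three arctic positions counts once; mixed ID counts as both
  recs <- data.frame(
    cluster_id = c("g1", "g1", "g1", "g2", "g3", "g3"),
    specificity = c("arctic", "arctic", "arctic", "temperate",
                    "arctic", "temperate"))
  ann <- data.frame(cluster_id = c("g1", "zz"),
                    annotation = c("ABC transporter", "ghost"),
                    functional_group = c("Q", "X"))
  expect_warning(sm <- summarize_candidates(recs, ann), "unknown IDs")
  expect_equal(sm$n_candidates, 3L)
  expect_equal(unname(sm$by_specificity),
               c(1L, 1L, 1L))
  expect_equal(sm$n_annotated, 1L)
  expect_equal(count_ids_in_groups(sm, "Q"), 1L)
})

test_that("zero-noise planted datasets are recovered perfectly end to end", {
  sim <- simulate_caas_dataset(n_clusters = 4, length = 200, n_planted = 5,
                               sub_prob = 0, gap_col_frac = 0, seed = 9)
  recs <- caas_screen(sim$clusters, trim = FALSE)
  expect_equal(nrow(recs), nrow(sim$truth))
  expect_setequal(paste(recs$cluster_id, recs$column_orig),
                  paste(sim$truth$cluster_id, sim$truth$column))
  expect_true(all(recs$independence))
  # planted arctic residues are read back exactly
  key <- paste(sim$truth$cluster_id, sim$truth$column)
  got <- recs$arctic_residues[match(key, paste(recs$cluster_id,
                                               recs$column_orig))]
  expect_equal(got, sim$truth$arctic_residue)
})

test_that("the packaged example candidate table loads and classifies", {
  fx <- read_caas_candidates(example_candidate_table())
  expect_equal(nrow(fx$records), 28L)  # 26 IDs, one with three positions
  expect_equal(length(unique(fx$records$cluster_id)), 26L)
  expect_equal(fx$records$specificity[fx$records$cluster_id == "12554"],
               "both")
})
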