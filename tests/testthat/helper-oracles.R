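# Independent oracles used across test files. Each recomputes the checked
# quantity by brute force, without touching the implementation path.

# maximum slope of ln(abundance) by finite differences
fd_max_slope <- function(times, abundances) {
  y <- log(abundances)
  max(diff(y) / diff(times))
}

# analytic argmax of the exponential-times-quadratic curve: solve
# b(1 - u^2) = 4u/w for u = (T - z)/(w/2), pick the root in (-1, 1)
analytic_topt <- function(a, b, z, w) {
  if (b == 0) return(z)
  roots <- (-4 / w + c(-1, 1) * sqrt(16 / w^2 + 4 * b^2)) / (2 * b)
  u <- roots[roots > -1 & roots < 1]
  stopifnot(length(u) == 1L)
  z + u * w / 2
}

# exhaustive gains-only parsimony: minimum number of independent origins
# of state 1 over all internal-node labelings, losses (1 -> 0) forbidden,
# a root in state 1 counting as one origin
exhaustive_origins <- function(tree, tip_states, target) {
  x <- as.integer(tip_states[tree$tip.label] == target)
  if (!any(x)) return(0L)
  n <- length(tree$tip.label)
  m <- tree$Nnode
  best <- Inf
  for (code in 0:(2^m - 1)) {
    states <- c(x, as.integer(intToBits(code))[seq_len(m)])
    ok <- TRUE
    gains <- states[n + 1L]  # root origin
    for (e in seq_len(nrow(tree$edge))) {
      s <- states[tree$edge[e, 1L]]; t <- states[tree$edge[e, 2L]]
      if (s == 1L && t == 0L) { ok <- FALSE; break }
      if (s == 0L && t == 1L) gains <- gains + 1L
    }
    if (ok) best <- min(best, gains)
  }
  as.integer(best)
}

# percent identity of two equal-length gapless sequences
plain_identity <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  mean(va == vb)
}

# residue sets of one alignment column per habitat, recomputed directly
column_sets <- function(cluster, j) {
  chars <- vapply(cluster$seqs, function(s) substr(s, j, j), character(1))
  hab <- cluster$labels$habitat[match(names(cluster$seqs),
                                      cluster$labels$taxon)]
  list(arctic = unique(chars[hab == "arctic" & chars != "-"]),
       temperate = unique(chars[hab == "temperate" & chars != "-"]))
}

# build a small labeled cluster from explicit column strings: `cols` is a
# character matrix (members x columns)
make_cluster <- function(cols, habitats,
                         sources = NULL, focal = NULL, id = "c1",
                         tree = NULL) {
  n <- nrow(cols)
  taxa <- paste0("tax", seq_len(n))
  if (is.null(sources))
    sources <- ifelse(seq_len(n) %% 2 == 0, "metatranscriptome", "culture")
  if (is.null(focal)) {
    focal <- rep(FALSE, n)
    focal[match(c("arctic", "temperate"), habitats)] <- TRUE
  }
  seqs <- apply(cols, 1L, paste, collapse = "")
  names(seqs) <- taxa
  homolog_cluster(id, seqs,
                  data.frame(taxon = taxa, habitat = habitats,
                             source = sources, is_focal = focal,
                             stringsAsFactors = FALSE),
                  tree = tree)
}
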