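#' Construct a homolog cluster
#'
#' An aligned, habitat-labeled protein family: the unit on which the
#' convergent-substitution scan operates.
#'
#' @param cluster_id Identifier.
#' @param seqs Named character vector of aligned amino-acid sequences of
#'   equal length; gap character `-`. Names are taxa.
#' @param labels Data frame with columns `taxon`, `habitat`
#'   (`"arctic"`/`"temperate"`), `source`
#'   (`"culture"`/`"metatranscriptome"`), `is_focal` (logical; marks the
#'   focal species pair whose contrast defines the screen). Every
#'   sequence must map to exactly one label row.
#' @param tree Optional `phylo` species tree over the member taxa.
#' @param column_map Integer vector mapping current column index to the
#'   column index in the original (untrimmed) alignment; defaults to the
#'   identity.
#'
#' @return Object of class `homolog_cluster`.
#' @export
homolog_cluster <- function(cluster_id, seqs, labels, tree = NULL,
                            column_map = NULL) {
  if (!length(seqs)) stop("cluster has no sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique taxon names")
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("aligned sequences must have equal length; got lengths ",
         paste(sort(unique(nchar(seqs))), collapse = ", "))
  need <- c("taxon", "habitat", "source")
  miss <- setdiff(need, names(labels))
  if (length(miss)) stop("labels missing columns: ", paste(miss, collapse = ", "))
  if (!"is_focal" %in% names(labels)) labels$is_focal <- FALSE
  unl <- setdiff(names(seqs), labels$taxon)
  if (length(unl))
    stop("unlabeled members: ", paste(unl, collapse = ", "))
  labels <- labels[match(names(seqs), labels$taxon), , drop = FALSE]
  rownames(labels) <- NULL
  if (is.null(column_map)) column_map <- seq_len(len)
  structure(
    list(cluster_id = cluster_id, seqs = seqs, labels = labels,
         tree = tree, column_map = as.integer(column_map)),
    class = "homolog_cluster")
}

#' @export
print.homolog_cluster <- function(x, ...) {
  cat(sprintf("<homolog_cluster> %s: %d members x %d columns (%d arctic, %d temperate)\n",
              x$cluster_id, length(x$seqs), nchar(x$seqs[[1]]),
              sum(x$labels$habitat == "arctic"),
              sum(x$labels$habitat == "temperate")))
  invisible(x)
}

# member x column character matrix of the alignment
aln_matrix <- function(cluster) {
  m <- do.call(rbind, strsplit(unname(cluster$seqs), ""))
  rownames(m) <- names(cluster$seqs)
  m
}

#' Single-linkage homolog clustering at a percent-identity threshold
#'
#' Computes pairwise global alignments (simple +1/-1 residue scoring)
#' and links two sequences when identities divided by the pairwise
#' alignment length reach the threshold; clusters are the transitive
#' closure (single linkage, union-find).
#'
#' @param seqs Named character vector of unaligned protein sequences
#'   (gap characters, if present, are stripped).
#' @param identity_threshold Fraction in (0, 1]; default 0.75.
#'
#' @return List of character vectors of member names, one per cluster,
#'   ordered by first appearance.
#' @export
cluster_homologs <- function(seqs, identity_threshold = 0.75) {
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]")
  if (!length(seqs)) return(list())
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- gsub("-", "", seqs)
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  aa <- Biostrings::AAStringSet(seqs)
  letters_used <- unique(unlist(strsplit(toupper(seqs), "")))
  mat <- matrix(-1L, length(letters_used), length(letters_used),
                dimnames = list(letters_used, letters_used))
  diag(mat) <- 1L
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        aln <- Biostrings::pairwiseAlignment(
          aa[i], aa[j], type = "global", substitutionMatrix = mat,
          gapOpening = 2, gapExtension = 1)
        pid <- Biostrings::nmatch(aln) /
          nchar(as.character(Biostrings::alignedPattern(aln)))
        if (pid >= identity_threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(lapply(split(names(seqs), match(roots, unique(roots))), identity))
}

#' Trim high-gap alignment columns (simplified gappyout)
#'
#' Removes columns whose gap fraction exceeds a data-driven cutoff: the
#' steepest-jump breakpoint in the sorted distinct column gap fractions
#' (columns strictly above the breakpoint's lower edge are dropped).
#' When the gap fractions show no jump to break at (all equal), the
#' fixed fallback cutoff `gap_fraction_max` applies. The returned
#' cluster's `column_map` composes with any existing map so positions
#' remain reportable in original coordinates.
#'
#' @param cluster A [homolog_cluster()].
#' @param gap_fraction_max Fallback cutoff: columns with gap fraction
#'   above this are removed when no breakpoint exists. Default 0.2.
#'
#' @return A trimmed [homolog_cluster()].
#' @export
trim_alignment <- function(cluster, gap_fraction_max = 0.2) {
  m <- aln_matrix(cluster)
  gf <- colMeans(m == "-")
  u <- sort(unique(gf))
  if (length(u) == 1L) {
    keep <- gf <= gap_fraction_max
  } else {
    jumps <- diff(u)
    cutoff <- u[which.max(jumps)]
    keep <- gf <= cutoff
  }
  if (!any(keep)) stop("all columns removed by trimming")
  idx <- which(keep)
  seqs <- apply(m[, idx, drop = FALSE], 1L, paste, collapse = "")
  homolog_cluster(cluster$cluster_id, seqs, cluster$labels,
                  tree = cluster$tree,
                  column_map = cluster$column_map[idx])
}

#' Scan a cluster for convergent amino-acid substitutions
#'
#' For each alignment column that is gap-free in every member (default;
#' with `allow_gaps = TRUE`, gapped members simply contribute no
#' residue), the arctic and temperate residue sets are compared. A
#' candidate is reported when the sets are disjoint and at least one of
#' them is a singleton — i.e. one habitat has converged on a single
#' residue that never occurs in the other habitat. Specificity is
#' `"arctic"` or `"temperate"` when only that side is a singleton, and
#' `"both"` when both are.
#'
#' @param cluster A [homolog_cluster()]; every member must be labeled.
#' @param allow_gaps Scan columns with gaps, treating gapped members as
#'   missing (default FALSE: such columns are skipped).
#'
#' @return Data frame of candidate records: `cluster_id`, `column`
#'   (1-based, current alignment coordinates), `column_orig` (1-based,
#'   original pre-trimming coordinates), `arctic_residues`,
#'   `temperate_residues` (comma-separated, sorted), `specificity`.
#' @export
scan_caas <- function(cluster, allow_gaps = FALSE) {
  m <- aln_matrix(cluster)
  hab <- cluster$labels$habitat
  for (h in c("arctic", "temperate"))
    if (sum(hab == h) < 2L)
      stop("habitat '", h, "' has fewer than 2 members; scan undefined")
  arc <- hab == "arctic"; tem <- hab == "temperate"
  recs <- list()
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (!allow_gaps && any(col == "-")) next
    a <- unique(col[arc & col != "-"])
    t <- unique(col[tem & col != "-"])
    if (!length(a) || !length(t)) next
    if (length(intersect(a, t))) next
    a1 <- length(a) == 1L; t1 <- length(t) == 1L
    if (!a1 && !t1) next
    spec <- if (a1 && t1) "both" else if (a1) "arctic" else "temperate"
    recs[[length(recs) + 1L]] <- data.frame(
      cluster_id = cluster$cluster_id, column = j,
      column_orig = cluster$column_map[j],
      arctic_residues = paste(sort(a), collapse = ","),
      temperate_residues = paste(sort(t), collapse = ","),
      specificity = spec, stringsAsFactors = FALSE)
  }
  if (!length(recs))
    return(data.frame(cluster_id = character(), column = integer(),
                      column_orig = integer(), arctic_residues = character(),
                      temperate_residues = character(),
                      specificity = character(), stringsAsFactors = FALSE))
  do.call(rbind, recs)
}

#' Check that a candidate site sits in an otherwise gapless conserved region
#'
#' Passes when every column within +/- `window` of the site is gap-free
#' in all members and the mean per-column residue diversity (distinct
#' residues / members) over the flanking columns (focal site excluded)
#' does not exceed `max_other_variability`. A window extending past the
#' alignment edge fails with attribute `edge = TRUE` rather than
#' erroring.
#'
#' @param cluster A [homolog_cluster()].
#' @param column 1-based column index of the candidate site.
#' @param window Flank half-width in columns (default 5).
#' @param max_other_variability Maximum mean flank diversity (default
#'   0.3).
#'
#' @return Logical; attribute `edge` is TRUE when the window ran off the
#'   alignment edge.
#' @export
check_conserved_context <- function(cluster, column, window = 5L,
                                    max_other_variability = 0.3) {
  m <- aln_matrix(cluster)
  if (column < 1L || column > ncol(m)) stop("column out of range")
  lo <- column - window; hi <- column + window
  if (lo < 1L || hi > ncol(m)) {
    out <- FALSE; attr(out, "edge") <- TRUE
    return(out)
  }
  block <- m[, lo:hi, drop = FALSE]
  if (any(block == "-")) {
    out <- FALSE; attr(out, "edge") <- FALSE
    return(out)
  }
  flanks <- setdiff(lo:hi, column)
  div <- vapply(flanks, function(j) length(unique(m[, j])) / nrow(m),
                numeric(1))
  out <- mean(div) <= max_other_variability
  attr(out, "edge") <- FALSE
  out
}

#' Additional-species support filter
#'
#' A candidate substitution must be carried beyond the focal species
#' pair: at the candidate column, each habitat side must include at
#' least one non-focal species contributing a residue.
#'
#' @param cluster A [homolog_cluster()] whose labels flag the focal pair
#'   via `is_focal`.
#' @param column 1-based candidate column.
#'
#' @return Logical.
#' @export
filter_additional_species <- function(cluster, column) {
  lab <- cluster$labels
  if (!any(lab$is_focal))
    stop("no focal species flagged in labels (is_focal)")
  m <- aln_matrix(cluster)
  col <- m[, column]
  present <- col != "-"
  for (h in c("arctic", "temperate")) {
    if (!any(present & lab$habitat == h & !lab$is_focal))
      return(FALSE)
  }
  TRUE
}

#' Metatranscriptome expression-evidence filter
#'
#' A candidate gene variant must be expressed in its native habitat:
#' the cluster must contain at least one metatranscriptome-sourced
#' member from each habitat.
#'
#' @param cluster A [homolog_cluster()].
#'
#' @return Logical.
#' @export
filter_expression_evidence <- function(cluster) {
  lab <- cluster$labels
  meta <- lab$source == "metatranscriptome"
  any(meta & lab$habitat == "arctic") && any(meta & lab$habitat == "temperate")
}

#' Minimum independent origins of a residue on a species tree
#'
#' Counts how many times the target residue must have arisen
#' independently, by gains-only (irreversible) parsimony on the binary
#' recoding target-vs-other: losses are forbidden, a gain on an edge
#' costs 1, and a root already in the target state counts as one origin.
#' The phylogenetic-independence filter requires at least 2 origins.
#'
#' @param tree A rooted `phylo` tree (polytomies allowed).
#' @param tip_states Named character vector: residue per tip; must cover
#'   all tree tips.
#' @param target_residue The residue whose origins are counted.
#'
#' @return Integer: minimum number of independent origins (0 when the
#'   residue is absent from all tips).
#' @export
count_origins_fitch <- function(tree, tip_states, target_residue) {
  stopifnot(inherits(tree, "phylo"))
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss))
    stop("tips missing a state: ", paste(miss, collapse = ", "))
  x <- as.integer(tip_states[tree$tip.label] == target_residue)
  if (!any(x)) return(0L)
  n <- length(tree$tip.label)
  n_nodes <- n + tree$Nnode
  # cost[v, s+1]: minimal number of gains in the subtree of v given v has
  # state s; transitions 1 -> 0 are forbidden (Inf)
  cost <- matrix(0, n_nodes, 2L)
  cost[seq_len(n), 1L] <- ifelse(x == 1L, Inf, 0)
  cost[seq_len(n), 2L] <- ifelse(x == 1L, 0, Inf)
  tr <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    # parent state 0: child may stay 0 (free) or gain (cost 1)
    from0 <- min(cost[ch, 1L], cost[ch, 2L] + 1)
    # parent state 1: loss forbidden, child must be 1
    from1 <- cost[ch, 2L]
    cost[par, 1L] <- cost[par, 1L] + from0
    cost[par, 2L] <- cost[par, 2L] + from1
  }
  root <- n + 1L
  as.integer(min(cost[root, 1L], cost[root, 2L] + 1))
}

#' Classify a candidate's origin specificity
#'
#' A candidate is arctic-specific when the arctic side converged on a
#' single residue while the temperate side is variable; temperate
#' -specific in the mirror case; and specific to both origins when each
#' side carries exactly one (different) residue.
#'
#' @param arctic_set,temperate_set Character vectors of residues; must
#'   be nonempty, disjoint, with at least one singleton.
#'
#' @return `"arctic"`, `"temperate"`, or `"both"`.
#' @export
classify_origin_specificity <- function(arctic_set, temperate_set) {
  if (!length(arctic_set) || !length(temperate_set))
    stop("residue sets must be nonempty")
  if (length(intersect(arctic_set, temperate_set)))
    stop("residue sets overlap: not a convergent substitution")
  a1 <- length(arctic_set) == 1L; t1 <- length(temperate_set) == 1L
  if (a1 && t1) return("both")
  if (a1) return("arctic")
  if (t1) return("temperate")
  stop("neither residue set is a singleton")
}

#' Apply candidate filters to scan records
#'
#' Adds the four filter flags to each record: `additional_species`
#' (non-focal support on both sides), `expression` (metatranscriptome
#' members from both habitats in the cluster), `conserved_context`
#' (gapless conserved flank, [check_conserved_context()]), and
#' `independence` (every convergent singleton residue arose on >= 2
#' independent branches, [count_origins_fitch()]; `NA` without a tree).
#'
#' @param cluster A [homolog_cluster()].
#' @param records Scan records for this cluster from [scan_caas()].
#' @param window,max_other_variability Passed to
#'   [check_conserved_context()].
#'
#' @return `records` with logical columns `additional_species`,
#'   `expression`, `conserved_context`, `independence` appended.
#' @export
apply_caas_filters <- function(cluster, records, window = 5L,
                               max_other_variability = 0.3) {
  if (!nrow(records)) {
    records$additional_species <- logical(0)
    records$expression <- logical(0)
    records$conserved_context <- logical(0)
    records$independence <- logical(0)
    return(records)
  }
  m <- aln_matrix(cluster)
  expr <- filter_expression_evidence(cluster)
  records$additional_species <- vapply(records$column, function(j)
    filter_additional_species(cluster, j), logical(1))
  records$expression <- expr
  records$conserved_context <- vapply(records$column, function(j)
    as.logical(check_conserved_context(cluster, j, window,
                                       max_other_variability)), logical(1))
  records$independence <- NA
  if (!is.null(cluster$tree)) {
    tr <- cluster$tree
    keep <- intersect(tr$tip.label, names(cluster$seqs))
    tr <- ape::keep.tip(tr, keep)
    records$independence <- vapply(seq_len(nrow(records)), function(i) {
      j <- records$column[i]
      states <- m[, j]; names(states) <- rownames(m)
      states <- states[states != "-"]
      targets <- character()
      if (records$specificity[i] %in% c("arctic", "both"))
        targets <- c(targets, records$arctic_residues[i])
      if (records$specificity[i] %in% c("temperate", "both"))
        targets <- c(targets, records$temperate_residues[i])
      tr2 <- ape::keep.tip(tr, intersect(tr$tip.label, names(states)))
      all(vapply(targets, function(res)
        count_origins_fitch(tr2, states, res) >= 2L, logical(1)))
    }, logical(1))
  }
  records
}

#' Run the full convergent-substitution screen over clusters
#'
#' Per cluster: trim high-gap columns, scan for candidate columns,
#' compute filter flags, and keep records passing the additional-species,
#' expression and conserved-context filters (phylogenetic independence is
#' reported as a flag and only enforced when `require_independence` is
#' TRUE).
#'
#' @param clusters List of [homolog_cluster()]s.
#' @param trim Trim alignments before scanning (default TRUE).
#' @param gap_fraction_max Passed to [trim_alignment()].
#' @param window,max_other_variability Passed to
#'   [check_conserved_context()].
#' @param require_independence Enforce >= 2 independent origins as a
#'   hard filter (default FALSE: reported only).
#' @param allow_gaps Passed to [scan_caas()].
#'
#' @return Data frame of records passing the filters, with flag columns;
#'   positions in both trimmed (`column`) and original (`column_orig`)
#'   1-based coordinates.
#' @export
caas_screen <- function(clusters, trim = TRUE, gap_fraction_max = 0.2,
                        window = 5L, max_other_variability = 0.3,
                        require_independence = FALSE, allow_gaps = FALSE) {
  out <- lapply(clusters, function(cl) {
    if (trim) cl <- trim_alignment(cl, gap_fraction_max)
    recs <- scan_caas(cl, allow_gaps = allow_gaps)
    recs <- apply_caas_filters(cl, recs, window = window,
                               max_other_variability = max_other_variability)
    keep <- recs$additional_species & recs$expression & recs$conserved_context
    if (require_independence)
      keep <- keep & (!is.na(recs$independence) & recs$independence)
    recs[keep, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize candidate records at the gene (alignment-ID) level
#'
#' Collapses per-position records to distinct alignment IDs, assigns an
#' ID-level specificity (arctic/temperate when all its positions agree,
#' both when it has a both-specificity position or positions of both
#' kinds), joins functional annotations, and tallies counts by
#' specificity and by functional-group letter (an ID annotated with
#' several letters counts under each).
#'
#' @param records Data frame of (post-filter) records with at least
#'   `cluster_id` and `specificity`.
#' @param annotations Optional data frame `cluster_id`, `annotation`,
#'   `functional_group` (comma-separated one-letter functional category
#'   codes). IDs without a usable annotation are counted as function
#'   unknown.
#'
#' @return List of class `candidate_summary`: `n_candidates`,
#'   `n_annotated`, `by_specificity` (named integer vector),
#'   `by_letter` (named integer vector of IDs per functional letter),
#'   `id_table` (per-ID data frame with `cluster_id`, `specificity`,
#'   `annotation`, `letters`, `annotated`).
#' @export
summarize_candidates <- function(records, annotations = NULL) {
  if (!nrow(records)) {
    return(structure(
      list(n_candidates = 0L, n_annotated = 0L,
           by_specificity = c(arctic = 0L, temperate = 0L, both = 0L),
           by_letter = integer(0),
           id_table = data.frame(cluster_id = character(),
                                 specificity = character(),
                                 annotation = character(),
                                 letters = character(),
                                 annotated = logical())),
      class = "candidate_summary"))
  }
  ids <- unique(records$cluster_id)
  if (!is.null(annotations)) {
    unknown <- setdiff(annotations$cluster_id, ids)
    if (length(unknown))
      warning("annotations reference unknown IDs: ",
              paste(unknown, collapse = ", "))
  }
  id_rows <- lapply(ids, function(id) {
    sp <- unique(records$specificity[records$cluster_id == id])
    spec <- if ("both" %in% sp || length(sp) > 1L) "both" else sp
    ann <- ""; letters <- ""
    if (!is.null(annotations)) {
      arows <- annotations[annotations$cluster_id == id, , drop = FALSE]
      anns <- arows$annotation[!is.na(arows$annotation) &
                               arows$annotation != "" &
                               arows$annotation != "—"]
      if (length(anns)) ann <- anns[1L]
      lets <- unlist(strsplit(arows$functional_group[
        !is.na(arows$functional_group)], ","))
      lets <- unique(trimws(lets)); lets <- lets[lets != ""]
      letters <- paste(sort(lets), collapse = ",")
    }
    data.frame(cluster_id = id, specificity = spec, annotation = ann,
               letters = letters, annotated = nzchar(ann),
               stringsAsFactors = FALSE)
  })
  id_table <- do.call(rbind, id_rows)
  by_spec <- c(arctic = sum(id_table$specificity == "arctic"),
               temperate = sum(id_table$specificity == "temperate"),
               both = sum(id_table$specificity == "both"))
  all_letters <- sort(unique(unlist(strsplit(id_table$letters, ","))))
  all_letters <- all_letters[all_letters != ""]
  by_letter <- vapply(all_letters, function(L)
    sum(vapply(strsplit(id_table$letters, ","), function(x) L %in% x,
               logical(1))), integer(1))
  structure(
    list(n_candidates = length(ids), n_annotated = sum(id_table$annotated),
         by_specificity = by_spec, by_letter = by_letter,
         id_table = id_table),
    class = "candidate_summary")
}

#' @export
print.candidate_summary <- function(x, ...) {
  cat(sprintf("<candidate_summary> %d candidate IDs (%d annotated)\n",
              x$n_candidates, x$n_annotated))
  cat(sprintf("  specificity: arctic %d, temperate %d, both %d\n",
              x$by_specificity[["arctic"]], x$by_specificity[["temperate"]],
              x$by_specificity[["both"]]))
  if (length(x$by_letter))
    cat("  functional letters:",
        paste(sprintf("%s=%d", names(x$by_letter), x$by_letter),
              collapse = " "), "\n")
  invisible(x)
}

#' Count candidate IDs annotated with any of a set of functional letters
#'
#' @param summary A `candidate_summary` from [summarize_candidates()].
#' @param letters Character vector of one-letter functional category
#'   codes (e.g. `c("J", "K", "L")` for central-dogma processes).
#'
#' @return Integer: number of distinct IDs carrying at least one of the
#'   letters.
#' @export
count_ids_in_groups <- function(summary, letters) {
  stopifnot(inherits(summary, "candidate_summary"))
  sum(vapply(strsplit(summary$id_table$letters, ","),
             function(x) any(letters %in% x), logical(1)))
}

#' Path to the packaged example candidate table
#'
#' A curated candidate table for the Arctic (*T. gravida*) versus
#' temperate (*T. rotula*) diatom contrast: 26 alignment IDs with
#' per-position arctic/temperate residue sets and functional
#' annotations. Load with [read_caas_candidates()].
#'
#' @return Path to the TSV inside the installed package.
#' @export
example_candidate_table <- function() {
  system.file("extdata", "caas_candidates_tgravida_trotula.tsv",
              package = "polartrait", mustWork = TRUE)
}

#' Read a candidate-substitution table
#'
#' Reads a TSV with columns `alignment_id`, `position`, `arctic_aa`,
#' `temperate_aa`, `annotation`, `functional_group` (residues
#' comma-separated; annotation empty or "-" when unknown; the
#' functional-group field holds comma-separated one-letter codes).
#' Specificity is derived from the residue sets with
#' [classify_origin_specificity()].
#'
#' @param path Path to the TSV file.
#'
#' @return List with `records` (cluster_id, column, arctic_residues,
#'   temperate_residues, specificity) and `annotations` (cluster_id,
#'   annotation, functional_group).
#' @export
read_caas_candidates <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", comment.char = "#")
  need <- c("alignment_id", "position", "arctic_aa", "temperate_aa")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  split_res <- function(x) trimws(strsplit(x, ",")[[1]])
  spec <- vapply(seq_len(nrow(d)), function(i)
    classify_origin_specificity(split_res(d$arctic_aa[i]),
                                split_res(d$temperate_aa[i])), character(1))
  records <- data.frame(
    cluster_id = d$alignment_id, column = as.integer(d$position),
    arctic_residues = gsub(" ", "", d$arctic_aa),
    temperate_residues = gsub(" ", "", d$temperate_aa),
    specificity = spec, stringsAsFactors = FALSE)
  annotations <- data.frame(
    cluster_id = d$alignment_id,
    annotation = if ("annotation" %in% names(d)) d$annotation else "",
    functional_group = if ("functional_group" %in% names(d))
      d$functional_group else "",
    stringsAsFactors = FALSE)
  list(records = records, annotations = annotations)
}
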