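#' Read an (aligned) amino-acid FASTA with habitat labels in the headers
#'
#' Headers follow the convention `taxon|source|habitat[|focal]`;
#' wrapped lines are concatenated and gap characters preserved.
#' Headers without the pipe-delimited fields yield a label row with
#' `NA` source/habitat.
#'
#' @param path Path to a FASTA file.
#'
#' @return List with `seqs` (named character vector, names = taxon) and
#'   `labels` (data frame `taxon`, `source`, `habitat`, `is_focal`).
#'   An empty file yields empty components with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) {
    warning("empty FASTA: ", path)
    return(list(seqs = character(0),
                labels = data.frame(taxon = character(),
                                    source = character(),
                                    habitat = character(),
                                    is_focal = logical())))
  }
  headers <- names(set)
  parts <- strsplit(headers, "|", fixed = TRUE)
  taxa <- vapply(parts, `[`, character(1), 1L)
  dup <- taxa[duplicated(taxa)]
  if (length(dup))
    stop("duplicate sequence IDs: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- taxa
  labels <- data.frame(
    taxon = taxa,
    source = vapply(parts, function(p)
      if (length(p) >= 2L) p[2L] else NA_character_, character(1)),
    habitat = vapply(parts, function(p)
      if (length(p) >= 3L) p[3L] else NA_character_, character(1)),
    is_focal = vapply(parts, function(p)
      length(p) >= 4L && p[4L] == "focal", logical(1)),
    stringsAsFactors = FALSE)
  list(seqs = seqs, labels = labels)
}

#' Write sequences as FASTA with labeled headers
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param labels Optional data frame (`taxon`, `source`, `habitat`,
#'   `is_focal`); when supplied, headers are
#'   `taxon|source|habitat[|focal]`.
#' @param width Line-wrap width (default 60).
#'
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, labels = NULL, width = 60L) {
  headers <- names(seqs)
  if (!is.null(labels)) {
    i <- match(names(seqs), labels$taxon)
    headers <- paste(labels$taxon[i], labels$source[i], labels$habitat[i],
                     sep = "|")
    foc <- !is.na(labels$is_focal[i]) & labels$is_focal[i]
    headers[foc] <- paste0(headers[foc], "|focal")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(seqs)) {
    writeLines(paste0(">", headers[k]), con)
    s <- seqs[[k]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a species tree from newick
#'
#' Optionally checks the tips against an expected taxon set and applies
#' midpoint rooting (branch lengths required for midpoint rooting; the
#' parsimony machinery itself ignores them).
#'
#' @param path Path to a newick file.
#' @param expected_tips Optional character vector; an error names any
#'   mismatch.
#' @param midpoint Midpoint-root the tree (default FALSE).
#'
#' @return A `phylo`.
#' @export
read_newick <- function(path, expected_tips = NULL, midpoint = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in ", path)
  if (!is.null(expected_tips)) {
    miss <- setdiff(expected_tips, tree$tip.label)
    extra <- setdiff(tree$tip.label, expected_tips)
    if (length(miss) || length(extra))
      stop("tip/label mismatch; missing from tree: ",
           paste(miss, collapse = ", "), "; not expected: ",
           paste(extra, collapse = ", "))
  }
  if (midpoint) tree <- phangorn::midpoint(tree)
  tree
}

#' Write / read tab-separated tables
#'
#' UTF-8, tab-separated, `.` decimal, header row; the package's own
#' outputs are all re-readable with [read_tsv()].
#'
#' @param x Data frame.
#' @param path File path.
#'
#' @return `write_tsv()`: invisibly, `path`; `read_tsv()`: a data
#'   frame.
#' @export
#' @rdname tsv
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @param ... Passed to [utils::read.delim()].
#' @export
#' @rdname tsv
read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#", ...)
}

#' Read homolog clusters from a directory of aligned FASTA files
#'
#' Each `*.fasta`/`*.fa` file becomes one [homolog_cluster()] named
#' after the file; headers must carry the `taxon|source|habitat[|focal]`
#' convention.
#'
#' @param dir Directory of FASTA files.
#' @param tree Optional `phylo` attached to every cluster.
#'
#' @return List of [homolog_cluster()]s.
#' @export
read_cluster_dir <- function(dir, tree = NULL) {
  files <- list.files(dir, pattern = "\\.(fasta|fa)$", full.names = TRUE)
  if (!length(files)) stop("no FASTA files in ", dir)
  lapply(files, function(f) {
    fa <- read_fasta(f)
    homolog_cluster(sub("\\.(fasta|fa)$", "", basename(f)),
                    fa$seqs, fa$labels, tree = tree)
  })
}
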