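## Distance-based phylogeny of class I-IV SET domains: p-distances from
## pairwise global alignments, neighbor-joining, coordinate-resampling
## bootstrap, and a clade-purity statistic for the family labels.

#' Pairwise p-distance matrix of SET-domain sequences
#'
#' `d(i, j) = 1 - identity` of the global alignment of sequences i and j
#' (identity over aligned columns excluding terminal gaps).
#'
#' @param seqs Named character vector of amino-acid sequences (>= 3).
#' @param ... Alignment parameters passed to [global_align()].
#' @return Symmetric numeric matrix with zero diagonal, labels from
#'   `names(seqs)`.
#' @export
pdistance_matrix <- function(seqs, ...) {
  n <- length(seqs)
  stopifnot(n >= 3, !is.null(names(seqs)), !anyDuplicated(names(seqs)))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    al <- align_many(seqs[[i]], unname(seqs[(i + 1):n]), ...)
    d[i, (i + 1):n] <- d[(i + 1):n, i] <- 1 - al$identity
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei neighbor joining (exact on additive distances).
#' Negative branch-length estimates are clamped to zero with a warning and
#' counted in the tree's `clamped` attribute.
#'
#' @param d Symmetric non-negative matrix with zero diagonal and unique
#'   labels (>= 3 taxa).
#' @return An unrooted `phylo` tree (leaves = matrix labels).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be 0")
  tree <- ape::nj(d)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    warning(sum(neg), " negative branch length(s) clamped to 0")
    tree$edge.length[neg] <- 0
  }
  attr(tree, "clamped") <- sum(neg)
  tree
}

## Project every sequence onto the coordinates of the longest one
## ("anchor"): a character matrix with one row per sequence and one column
## per anchor residue (NA where a sequence has no residue aligned there).
anchor_profile <- function(seqs, ...) {
  stopifnot(length(seqs) >= 3, !is.null(names(seqs)))
  anchor_i <- which.max(nchar(seqs))
  anchor <- seqs[[anchor_i]]
  L <- nchar(anchor)
  M <- matrix(NA_character_, nrow = length(seqs), ncol = L,
              dimnames = list(names(seqs), NULL))
  M[anchor_i, ] <- strsplit(anchor, "", fixed = TRUE)[[1]]
  others <- setdiff(seq_along(seqs), anchor_i)
  if (length(others)) {
    al <- align_many(anchor, unname(seqs[others]), ...)
    for (k in seq_along(others)) {
      ca <- strsplit(al$aligned_query[k], "", fixed = TRUE)[[1]]
      cb <- strsplit(al$aligned_subject[k], "", fixed = TRUE)[[1]]
      pos <- cumsum(ca != "-")
      keep <- ca != "-" & cb != "-"
      M[others[k], pos[keep]] <- cb[keep]
    }
  }
  M
}

profile_pdist <- function(M) {
  n <- nrow(M)
  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(M[i, ]) & !is.na(M[j, ])
      d[i, j] <- d[j, i] <-
        if (any(ok)) mean(M[i, ok] != M[j, ok]) else 1
    }
  }
  d
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Because no multiple alignment is built, resampling works on a
#' reference-anchored column set: every sequence is aligned once to the
#' longest sequence, giving a pseudo-alignment in the anchor's coordinates;
#' bootstrap replicates resample those columns with replacement. Support of
#' an internal edge is the percentage of replicate NJ trees containing its
#' bipartition.
#'
#' @param seqs Named character vector of amino-acid sequences (>= 4 for
#'   informative supports).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed RNG seed (supports are reproducible given the seed).
#' @param ... Alignment parameters passed to [global_align()].
#' @return A `phylo` tree built from the full anchor-projected distances,
#'   with `node.label` holding supports in percent (root label empty) and a
#'   `support` vector attribute.
#' @export
bootstrap_support <- function(seqs, n_reps = 100, seed = 1, ...) {
  stopifnot(n_reps >= 1)
  M <- anchor_profile(seqs, ...)
  main <- nj_tree(profile_pdist(M))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(M), replace = TRUE)
    reps[[r]] <- suppressWarnings(nj_tree(profile_pdist(M[, cols,
                                                          drop = FALSE])))
  }
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / n_reps, 1)
  support[1] <- NA  # root of the unrooted representation carries no split
  main$node.label <- ifelse(is.na(support), "", as.character(support))
  attr(main, "support") <- support
  main
}

## leaf index sets below each edge's child node
edge_tip_sets <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(k)
    tree$tip.label[below[[tree$edge[k, 2]]]])
}

#' Clade purity of family labels on a tree
#'
#' For each family, the purity is the best Jaccard overlap between the
#' family's leaf set and the leaf set on one side of any edge of the tree
#' (the full leaf set counts as a side, so a single-family tree has purity
#' 1). A family that forms a clade scores 1.
#'
#' @param tree A `phylo` tree.
#' @param labels Named character vector tip label -> family; every leaf must
#'   be labeled.
#' @return List with `per_family` (named numeric in `[0, 1]`) and `mean`.
#' @export
class_purity <- function(tree, labels) {
  tips <- tree$tip.label
  if (!all(tips %in% names(labels)))
    stop("unlabeled leaves: ",
         paste(setdiff(tips, names(labels)), collapse = ", "))
  labels <- labels[tips]
  sides <- edge_tip_sets(tree)
  sides <- c(sides, lapply(sides, function(s) setdiff(tips, s)),
             list(tips))
  sides <- sides[vapply(sides, length, 0L) > 0]
  fams <- unique(labels)
  per <- vapply(fams, function(f) {
    fset <- tips[labels == f]
    max(vapply(sides, function(s)
      length(intersect(s, fset)) / length(union(s, fset)), 0))
  }, 0)
  list(per_family = per, mean = mean(per))
}

#' Write a tree in Newick format
#'
#' Bootstrap supports, when present, are written as internal node labels.
#'
#' @param tree A `phylo` tree.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
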