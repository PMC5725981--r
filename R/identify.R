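## Candidate identification and redundancy removal.

#' Filter proteins to SET-domain candidates
#'
#' Keeps proteins carrying at least one SET domain hit with
#' `score >= min_score`. The 200-3500 aa range reported for SET proteins is
#' treated as a sanity window: out-of-range candidates are kept with a
#' warning unless `strict = TRUE`.
#'
#' @param proteins data.frame with columns `protein_id`, `species`,
#'   `sequence` (and optionally `locus_id`, `source`).
#' @param hits Hit data.frame; every `protein_id` must appear in `proteins`.
#' @param min_score Minimum SET hit score (default 0: trust precomputed hit
#'   tables).
#' @param min_len,max_len Sanity length window in residues.
#' @param strict Drop (rather than warn about) out-of-window candidates.
#' @return The candidate subset of `proteins`, input order preserved.
#' @export
find_set_candidates <- function(proteins, hits, min_score = 0,
                                min_len = 200, max_len = 3500,
                                strict = FALSE) {
  unknown <- setdiff(unique(hits$protein_id), proteins$protein_id)
  if (length(unknown))
    stop("hits reference unknown protein(s): ",
         paste(unknown, collapse = ", "))
  set_ids <- unique(hits$protein_id[hits$domain == "SET" &
                                      hits$score >= min_score])
  out <- proteins[proteins$protein_id %in% set_ids, , drop = FALSE]
  if (nrow(out)) {
    len <- nchar(out$sequence)
    off <- len < min_len | len > max_len
    if (any(off)) {
      if (strict) {
        out <- out[!off, , drop = FALSE]
      } else {
        warning("candidate length outside [", min_len, ", ", max_len,
                "] aa: ", paste(out$protein_id[off], collapse = ", "))
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Extract each protein's SET-domain subsequence
#'
#' Uses the best-scoring SET hit (after merging interrupted hits) to cut the
#' SET region out of the full-length sequence.
#'
#' @inheritParams find_set_candidates
#' @return Named character vector (names = protein ids); proteins without a
#'   SET hit are absent.
#' @export
set_domain_sequences <- function(proteins, hits) {
  hits <- merge_interrupted_set(hits)
  hits <- hits[hits$domain == "SET", , drop = FALSE]
  if (!nrow(hits)) return(stats::setNames(character(0), character(0)))
  hits <- hits[order(-hits$score), , drop = FALSE]
  hits <- hits[!duplicated(hits$protein_id), , drop = FALSE]
  i <- match(hits$protein_id, proteins$protein_id)
  ok <- !is.na(i)
  stats::setNames(
    substr(proteins$sequence[i[ok]], hits$start[ok], hits$end[ok]),
    hits$protein_id[ok])
}

#' Remove redundant candidates
#'
#' Two-step redundancy removal: (1) within each locus (nonempty `locus_id`,
#' per species) only the longest sequence is kept (ties to the
#' lexicographically smallest id); (2) among survivors of the same species,
#' proteins whose SET-domain subsequences are identical strings are collapsed
#' to the longest protein (ties again to the smallest id). Deterministic and
#' idempotent.
#'
#' @inheritParams find_set_candidates
#' @return The non-redundant subset, input order preserved.
#' @export
deduplicate <- function(candidates, hits) {
  if (!nrow(candidates)) return(candidates)
  stopifnot("species" %in% names(candidates))
  x <- candidates
  x$._len <- nchar(x$sequence)
  if (!"locus_id" %in% names(x)) x$locus_id <- ""
  x$locus_id[is.na(x$locus_id)] <- ""
  ## (1) longest per locus
  pick <- rep(TRUE, nrow(x))
  grp <- ifelse(nzchar(x$locus_id),
                paste(x$species, x$locus_id, sep = "\r"), NA)
  for (g in unique(grp[!is.na(grp)])) {
    idx <- which(!is.na(grp) & grp == g)
    if (length(idx) < 2) next
    best <- idx[order(-x$._len[idx], x$protein_id[idx])][1]
    pick[setdiff(idx, best)] <- FALSE
  }
  x <- x[pick, , drop = FALSE]
  ## (2) identical SET substrings within a species
  setseq <- set_domain_sequences(x, hits)
  key <- paste(x$species, setseq[x$protein_id], sep = "\r")
  key[!x$protein_id %in% names(setseq)] <- NA
  pick <- rep(TRUE, nrow(x))
  for (g in unique(key[!is.na(key)])) {
    idx <- which(!is.na(key) & key == g)
    if (length(idx) < 2) next
    best <- idx[order(-x$._len[idx], x$protein_id[idx])][1]
    pick[setdiff(idx, best)] <- FALSE
  }
  x <- x[pick, , drop = FALSE]
  x$._len <- NULL
  rownames(x) <- NULL
  x
}
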