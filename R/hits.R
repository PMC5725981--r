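## Domain-hit tables (CD-search / PFAM style) and architecture extraction.

#' Read a per-protein domain-hit table
#'
#' Tab-separated with columns `protein_id`, `domain`, `start`, `end`,
#' `score`; coordinates are 1-based inclusive residue indices. Domain names
#' are canonicalized through the synonym map.
#'
#' @param path TSV file path.
#' @param synonyms Alias lookup from [read_synonyms()].
#' @return data.frame of validated hits.
#' @export
read_domain_hits <- function(path, synonyms = read_synonyms()) {
  hits <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_hits(hits, synonyms)
}

validate_hits <- function(hits, synonyms = read_synonyms()) {
  need <- c("protein_id", "domain", "start", "end", "score")
  if (!all(need %in% names(hits)))
    stop("hit table must have columns: ", paste(need, collapse = ", "))
  if (nrow(hits)) {
    if (any(hits$start < 1) || any(hits$end < hits$start))
      stop("hit coordinates must satisfy 1 <= start <= end")
    hits$domain <- as.character(normalize_domain_name(hits$domain, synonyms))
  }
  if (!"interrupted" %in% names(hits))
    hits$interrupted <- rep(FALSE, nrow(hits))
  hits
}

#' Merge interrupted SET-domain hits
#'
#' Some Class V Orphan proteins carry a SET domain split into two hits. Two
#' SET hits on the same protein separated by a gap of at least `min_gap`
#' residues, whose union spans at most `max_span` residues and whose piece
#' lengths sum to at most `max_total` (about one SET domain -- this keeps
#' genuine tandem SET-SET architectures intact), are merged into a single
#' hit flagged `interrupted` (score = the larger of the two).
#'
#' @param hits Hit data.frame (see [read_domain_hits()]).
#' @param min_gap Minimum residue gap between the two parts (default 10).
#' @param max_span Maximum span of the merged hit (default 400).
#' @param max_total Maximum summed length of the merged pieces (default 200;
#'   a single SET domain is ~130-150 aa).
#' @return Hit data.frame with qualifying SET pairs merged.
#' @export
merge_interrupted_set <- function(hits, min_gap = 10, max_span = 400,
                                  max_total = 200) {
  if (!nrow(hits)) return(hits)
  out <- split(hits, hits$protein_id)
  out <- lapply(out, function(h) {
    is_set <- h$domain == "SET"
    if (sum(is_set) < 2) return(h)
    s <- h[is_set, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    merged <- s[1, , drop = FALSE]
    for (i in seq_len(nrow(s))[-1]) {
      last <- nrow(merged)
      gap <- s$start[i] - merged$end[last] - 1L
      span <- s$end[i] - merged$start[last] + 1L
      total <- (merged$end[last] - merged$start[last] + 1L) +
        (s$end[i] - s$start[i] + 1L)
      if (gap >= min_gap && span <= max_span && total <= max_total) {
        merged$end[last] <- s$end[i]
        merged$score[last] <- max(merged$score[last], s$score[i])
        merged$interrupted[last] <- TRUE
      } else {
        merged <- rbind(merged, s[i, , drop = FALSE])
      }
    }
    rbind(h[!is_set, , drop = FALSE], merged)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$protein_id, unique(hits$protein_id)), out$start), ,
      drop = FALSE]
}

#' Build the N-to-C domain architecture of one protein
#'
#' Sorts hits by start coordinate and resolves conflicts: two hits with more
#' than 50% reciprocal overlap keep only the better one (higher score, then
#' longer, then smaller start).
#'
#' @param hits Hit data.frame for a single protein (any `protein_id` column
#'   must be constant).
#' @return Character vector of canonical domain names, N->C (empty if no
#'   hits).
#' @export
#' @examples
#' h <- data.frame(protein_id = "p", domain = c("SET", "AWS"),
#'                 start = c(500, 430), end = c(640, 490), score = c(90, 40))
#' build_architecture(h)  # AWS SET
build_architecture <- function(hits) {
  if (!nrow(hits)) return(character(0))
  if ("protein_id" %in% names(hits) && length(unique(hits$protein_id)) > 1)
    stop("build_architecture expects hits of a single protein")
  len <- hits$end - hits$start + 1L
  ord <- order(-hits$score, -len, hits$start)
  keep <- integer(0)
  for (i in ord) {
    clash <- FALSE
    for (j in keep) {
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j]) + 1L
      if (ov > 0 && ov / len[i] > 0.5 && ov / len[j] > 0.5) {
        clash <- TRUE
        break
      }
    }
    if (!clash) keep <- c(keep, i)
  }
  keep <- keep[order(hits$start[keep], hits$end[keep])]
  hits$domain[keep]
}

#' @rdname build_architecture
#' @param arch Character vector of domain names.
#' @export
architecture_string <- function(arch) paste(arch, collapse = "-")
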