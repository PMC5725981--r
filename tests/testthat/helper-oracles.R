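# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: the ORF oracle enumerates every start/stop pair,
# the alignment oracle enumerates every global alignment recursively, and
# the purity oracle rescans every bipartition with ape.

# all ATG-initiated ORFs in all six frames; returns the longest peptide
# (ties: any longest -- tests compare lengths and membership)
oracle_longest_orf <- function(seq) {
  rc <- function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  gc <- Biostrings::GENETIC_CODE
  best <- ""
  for (s in c(seq, rc(seq))) {
    for (off in 1:3) {
      n <- nchar(s)
      starts <- seq(off, n - 2, by = 3)
      if (!length(starts)) next
      cod <- substring(s, starts, starts + 2)
      for (i in seq_along(cod)) {
        if (cod[i] != "ATG") next
        pep <- character(0)
        for (j in i:length(cod)) {
          aa <- gc[cod[j]]
          if (is.na(aa)) aa <- "X"
          if (aa == "*") break
          pep <- c(pep, aa)
        }
        pep <- paste(pep, collapse = "")
        if (nchar(pep) > nchar(best)) best <- pep
      }
    }
  }
  best
}

# exhaustive global alignment score, linear gap penalty `gap`, substitution
# matrix `sm` (plain recursion; strings must be short)
oracle_global_score <- function(a, b, sm, gap) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb))
      best <- max(best, sm[ca[i], cb[j]] + Recall(i + 1, j + 1))
    if (i <= length(ca)) best <- max(best, -gap + Recall(i + 1, j))
    if (j <= length(cb)) best <- max(best, -gap + Recall(i, j + 1))
    best
  }
  rec(1, 1)
}

# correct 4-taxon split by the four-point condition: the pairing with the
# smallest sum of opposite distances is the cherry pairing
oracle_quartet_split <- function(d) {
  l <- rownames(d)
  sums <- c(d[l[1], l[2]] + d[l[3], l[4]],
            d[l[1], l[3]] + d[l[2], l[4]],
            d[l[1], l[4]] + d[l[2], l[3]])
  splits <- list(list(c(l[1], l[2]), c(l[3], l[4])),
                 list(c(l[1], l[3]), c(l[2], l[4])),
                 list(c(l[1], l[4]), c(l[2], l[3])))
  splits[[which.min(sums)]]
}

# does an unrooted tree contain the bipartition {side, rest}?
tree_has_split <- function(tree, side) {
  pp <- ape::prop.part(ape::unroot(tree))
  tips <- attr(pp, "labels")
  for (p in pp) {
    s <- tips[p]
    if (setequal(s, side) || setequal(setdiff(tips, s), side)) return(TRUE)
  }
  FALSE
}

# clade purity recomputed from ape's bipartition list
oracle_purity <- function(tree, labels) {
  tips <- tree$tip.label
  pp <- ape::prop.part(tree)
  sides <- lapply(pp, function(p) attr(pp, "labels")[p])
  sides <- c(sides, lapply(sides, function(s) setdiff(tips, s)),
             lapply(seq_along(tips), function(i) tips[i]),
             lapply(seq_along(tips), function(i) setdiff(tips, tips[i])),
             list(tips))
  sides <- sides[vapply(sides, length, 0L) > 0]
  fams <- unique(labels[tips])
  sapply(fams, function(f) {
    fset <- tips[labels[tips] == f]
    max(vapply(sides, function(s)
      length(intersect(s, fset)) / length(union(s, fset)), 0))
  })
}

random_transcript <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_hits <- function(protein_id, domains, starts, ends,
                      scores = rep(100, length(domains))) {
  data.frame(protein_id = protein_id, domain = domains, start = starts,
             end = ends, score = scores, stringsAsFactors = FALSE)
}

# one shared noise-free full-table pipeline run for the acceptance checks
acc_cache <- new.env(parent = emptyenv())
noise_free_run <- function() {
  if (is.null(acc_cache$res)) {
    b <- generate_proteome(generator_config(seed = 1, mutation_rate = 0))
    run <- run_pipeline(pipeline_config(
      proteins = b$proteins, transcripts = b$transcripts, hits = b$hits,
      references = b$references, seed = 1))
    acc_cache$res <- list(bundle = b, run = run)
  }
  acc_cache$res
}

small_gencfg <- function(seed, ...) {
  args <- list(seed = seed, families = c("Ash", "Su(var)"),
               decoys_per_species = 2, isoform_rate = 0.15,
               transcript_fraction = 0.1, mutation_rate = 0)
  args <- utils::modifyList(args, list(...))
  do.call(generator_config, args)
}
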