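## End-to-end orchestration: transdecode -> identify -> dedupe -> classify
## -> name -> summarise -> filter -> phylogeny, with a run manifest.

#' Pipeline configuration
#'
#' Inputs may be in-memory tables (as produced by [generate_proteome()]) or
#' file paths (FASTA / hit TSV / reference FASTA), mixed freely.
#'
#' @param proteins Protein table or protein FASTA path (may be `NULL` when
#'   only transcripts are supplied).
#' @param transcripts Transcript table or nucleotide FASTA path (optional).
#' @param hits Hit table or TSV path.
#' @param references Reference set table or FASTA path (needed when any
#'   protein requires the homology fallback).
#' @param catalog A `set_catalog` or catalog file path.
#' @param out_dir Output directory for artifacts (`NULL` = in-memory only).
#' @param seed Seed for the bootstrap stage (recorded in the manifest).
#' @param min_aa Transdecoding minimum ORF length (aa).
#' @param min_score,strict Candidate filter settings
#'   (see [find_set_candidates()]).
#' @param threshold,min_coverage Homology fallback settings.
#' @param n_boot Bootstrap replicates for the tree (0 = plain NJ tree).
#' @param include_family_orphans Passed to [phylogeny_input_filter()].
#' @return A `setfam_runcfg` list.
#' @export
pipeline_config <- function(proteins = NULL, transcripts = NULL, hits,
                            references = NULL, catalog = default_catalog(),
                            out_dir = NULL, seed = 1, min_aa = 100,
                            min_score = 0, strict = FALSE, threshold = 0.3,
                            min_coverage = 0.8, n_boot = 0,
                            include_family_orphans = FALSE) {
  cfg <- list(proteins = proteins, transcripts = transcripts, hits = hits,
              references = references, catalog = catalog,
              out_dir = out_dir, seed = seed, min_aa = min_aa,
              min_score = min_score, strict = strict,
              threshold = threshold, min_coverage = min_coverage,
              n_boot = n_boot,
              include_family_orphans = include_family_orphans)
  for (nm in c("proteins", "transcripts", "hits", "references", "catalog"))
    if (is.character(cfg[[nm]]) && !file.exists(cfg[[nm]]))
      stop("input file does not exist: ", cfg[[nm]])
  structure(cfg, class = "setfam_runcfg")
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes transdecode, candidate identification, redundancy removal,
#' catalog classification with homology fallback, naming, comparative
#' summaries, the phylogeny inclusion filter and the NJ tree (with optional
#' bootstrap). Writes TSV/FASTA/Newick/JSON artifacts when `out_dir` is set
#' and returns all results plus a manifest of per-stage counts. Idempotent
#' for fixed inputs and seed.
#'
#' @param cfg A [pipeline_config()].
#' @return List with `classified`, `names`, `counts`, `presence`, `tree`,
#'   `distances` and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "setfam_runcfg"))
  catalog <- if (is.character(cfg$catalog)) read_catalog(cfg$catalog)
             else cfg$catalog
  proteins <- resolve_input(cfg$proteins, read_protein_fasta)
  transcripts <- resolve_input(cfg$transcripts, read_transcript_fasta)
  hits <- resolve_input(cfg$hits, read_domain_hits)
  references <- resolve_input(cfg$references, read_reference_set)
  if (is.data.frame(hits)) hits <- validate_hits(hits)

  decoded <- if (!is.null(transcripts) && nrow(transcripts))
    stage("transdecode", transdecode(transcripts, cfg$min_aa)) else NULL
  all_prot <- rbind(proteins, decoded)
  if (is.null(all_prot))
    all_prot <- data.frame(protein_id = character(0),
                           species = character(0),
                           locus_id = character(0),
                           sequence = character(0), source = character(0),
                           stringsAsFactors = FALSE)
  candidates <- stage("identify",
                      find_set_candidates(all_prot, hits, cfg$min_score,
                                          strict = cfg$strict))
  nr <- stage("deduplicate", deduplicate(candidates, hits))
  classified <- stage("classify",
                      classify_all(nr, hits, catalog, references,
                                   cfg$threshold, cfg$min_coverage))
  ref_names <- NULL
  if (!is.null(references) && nrow(references) && nrow(classified)) {
    ## proteins classified by exact architecture never consulted a
    ## reference; name them after their family's canonical homolog
    fam_ref <- references$name[match(classified$family, references$family)]
    need <- (is.na(classified$nearest_ref) |
               !nzchar(classified$nearest_ref)) & !is.na(fam_ref)
    ref_names <- stats::setNames(fam_ref[need],
                                 classified$protein_id[need])
  }
  nms <- stage("name", name_proteins(classified, ref_names))
  counts <- stage("summarise", count_by_class_species(classified))
  fams <- intersect(c("E(z)", "Ash", "Trx", "Su(var)"),
                    unique(classified$family))
  presence <- stats::setNames(
    lapply(fams, function(f) presence_matrix(classified, f, catalog)),
    fams)
  phylo_in <- stage("filter", phylogeny_input_filter(
    classified, cfg$include_family_orphans))
  tree <- NULL
  distances <- NULL
  if (nrow(phylo_in) >= 3) {
    seqs <- stats::setNames(phylo_in$set_sequence, phylo_in$protein_id)
    seqs <- seqs[!is.na(seqs)]
    if (length(seqs) >= 3) {
      ## anchor-projected distances (the same column set the bootstrap
      ## resamples), so supports and tree come from one distance definition
      if (cfg$n_boot > 0) {
        tree <- stage("tree", suppressWarnings(
          bootstrap_support(seqs, n_reps = cfg$n_boot, seed = cfg$seed)))
        distances <- profile_pdist(anchor_profile(seqs))
      } else {
        distances <- stage("tree", profile_pdist(anchor_profile(seqs)))
        tree <- suppressWarnings(nj_tree(distances))
      }
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("setfam")),
    seed = cfg$seed,
    counts = list(
      input_proteins = if (is.null(proteins)) 0L else nrow(proteins),
      input_transcripts = if (is.null(transcripts)) 0L
                          else nrow(transcripts),
      transdecoded = if (is.null(decoded)) 0L else nrow(decoded),
      identified = nrow(candidates),
      deduplicated = nrow(nr),
      classified = nrow(classified),
      phylogeny_input = nrow(phylo_in)),
    families = as.list(colSums(counts)))
  res <- list(classified = classified, names = nms, counts = counts,
              presence = presence, tree = tree, distances = distances,
              manifest = manifest)
  if (!is.null(cfg$out_dir)) write_run(res, cfg$out_dir)
  res
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(as.data.frame(res$classified),
            file.path(out_dir, "classified.tsv"))
  write_tsv(res$names, file.path(out_dir, "names.tsv"))
  write_tsv(res$counts, file.path(out_dir, "counts.tsv"))
  for (f in names(res$presence)) {
    m <- res$presence[[f]]
    write_tsv(ifelse(m, "+", "-"),
              file.path(out_dir, paste0(
                "presence_", gsub("[^A-Za-z]", "", f), ".tsv")))
  }
  if (!is.null(res$tree))
    write_newick(res$tree, file.path(out_dir, "set_domains.nwk"))
  if (!is.null(res$distances))
    write_phylip_dist(res$distances, file.path(out_dir, "distances.phy"))
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
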