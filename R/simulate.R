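## Ground-truth-labelled synthetic proteomes/transcriptomes emulating the
## study inputs: proteins with implanted domain architectures drawn from the
## catalog, decoys without SET, redundant isoforms, transcript-only entries,
## and species-structured presence/absence mirroring the tables.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

random_aa <- function(n) paste(sample(aa_alphabet(), n, replace = TRUE),
                               collapse = "")

mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(aa_alphabet(), ch[i]), 1)
  paste(ch, collapse = "")
}

seq_identity_naive <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- min(length(ca), length(cb))
  mean(ca[seq_len(n)] == cb[seq_len(n)])
}

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Generator configuration
#'
#' Bundles the knobs of the synthetic proteome generator. Defaults emulate
#' the study conditions: presence matrices transcribed from the family
#' classification tables (all four families, one protein per presence cell),
#' a handful of SET-free decoys per species, a 10% isoform and transcript
#' load, and a 5% per-site substitution rate on the implanted domain blocks.
#'
#' @param seed RNG seed (mandatory; the generator is fully reproducible).
#' @param families Families to generate.
#' @param presence Named list of logical presence matrices (default: the
#'   transcribed tables via [catalog_presence()]).
#' @param proteins_per_cell Proteins emitted per TRUE presence cell.
#' @param decoys_per_species SET-free decoy proteins per species.
#' @param isoform_rate Fraction of proteins duplicated as a truncated
#'   isoform of the same locus.
#' @param transcript_fraction Fraction of proteins emitted only as
#'   nucleotide transcripts (their protein is the longest ORF).
#' @param mutation_rate Per-site substitution probability applied to each
#'   implanted domain block.
#' @param extra_rate Probability that a protein of an entry with recorded
#'   extra domains carries one of them.
#' @param catalog A `set_catalog`.
#' @return A `setfam_gencfg` list.
#' @export
generator_config <- function(seed,
                             families = c("E(z)", "Ash", "Trx", "Su(var)"),
                             presence = NULL,
                             proteins_per_cell = 1,
                             decoys_per_species = 5,
                             isoform_rate = 0.1,
                             transcript_fraction = 0.1,
                             mutation_rate = 0.05,
                             extra_rate = 0.25,
                             catalog = default_catalog()) {
  if (missing(seed)) stop("generator seed is mandatory")
  rates <- c(isoform_rate, transcript_fraction, mutation_rate, extra_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  stopifnot(proteins_per_cell >= 1, decoys_per_species >= 0)
  if (is.null(presence))
    presence <- stats::setNames(
      lapply(families, catalog_presence, catalog = catalog), families)
  structure(list(seed = seed, families = families, presence = presence,
                 proteins_per_cell = proteins_per_cell,
                 decoys_per_species = decoys_per_species,
                 isoform_rate = isoform_rate,
                 transcript_fraction = transcript_fraction,
                 mutation_rate = mutation_rate, extra_rate = extra_rate,
                 catalog = catalog),
            class = "setfam_gencfg")
}

## One fixed random block per domain name; the SET block additionally gets
## one divergent variant per family so that SET-domain homology carries the
## family signal the fallback classifier needs (bare-SET Orphans are
## unclassifiable otherwise).
make_blocks <- function(catalog, families) {
  doms <- unique(c(unlist(lapply(catalog, `[[`, "backbone")),
                   unlist(lapply(catalog, `[[`, "extras"))))
  blocks <- lapply(stats::setNames(doms, doms), function(d)
    if (d == "SET") random_aa(140) else random_aa(sample(60:150, 1)))
  set_variants <- stats::setNames(
    lapply(families, function(f) mutate_seq(blocks$SET, 0.35)), families)
  list(blocks = blocks, set_variants = set_variants)
}

reference_names <- function() {
  list(At = c("E(z)" = "CLF", Ash = "SDG8", Trx = "ATX1",
              "Su(var)" = "KYP"),
       Os = c("E(z)" = "SDG711", Ash = "SDG724", Trx = "SDG723",
              "Su(var)" = "SDG728"))
}

make_references <- function(set_variants, families) {
  nm <- reference_names()
  rows <- list()
  for (sp in names(nm)) {
    for (f in intersect(families, names(nm[[sp]]))) {
      seqv <- if (sp == "At") set_variants[[f]] else
        mutate_seq(set_variants[[f]], 0.05)
      rows[[length(rows) + 1]] <- data.frame(
        name = unname(nm[[sp]][f]), family = f, species = sp,
        sequence = seqv, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## Distinct loci never carry byte-identical SET domains in real proteomes;
## a 3-residue tag encoding the locus counter (base 20, positions 5-7 of the
## SET block) keeps synthetic paralogs distinct even at mutation rate 0 so
## the redundancy filter only collapses true duplicates.
tag_set_block <- function(block, i) {
  alpha <- aa_alphabet()
  digits <- c(i %% 20, (i %/% 20) %% 20, (i %/% 400) %% 20) + 1
  ch <- strsplit(block, "", fixed = TRUE)[[1]]
  ch[5:7] <- alpha[digits]
  paste(ch, collapse = "")
}

assemble_protein <- function(domains, family, blocks, cfg, locus_i = 0L) {
  pieces <- character(0)
  hits <- list()
  linker <- random_aa(sample(20:80, 1))
  substr(linker, 1, 1) <- "M"
  seqs <- linker
  pos <- nchar(linker)
  for (d in domains) {
    block <- if (d == "SET") blocks$set_variants[[family]] else
      blocks$blocks[[d]]
    block <- mutate_seq(block, cfg$mutation_rate)
    if (d == "SET") block <- tag_set_block(block, locus_i)
    hits[[length(hits) + 1]] <- data.frame(
      domain = d, start = pos + 1L, end = pos + nchar(block),
      score = round(stats::runif(1, 80, 200), 1),
      stringsAsFactors = FALSE)
    seqs <- paste0(seqs, block)
    pos <- pos + nchar(block)
    gap <- random_aa(sample(10:40, 1))
    seqs <- paste0(seqs, gap)
    pos <- pos + nchar(gap)
  }
  tail_pad <- random_aa(sample(20:60, 1))
  seqs <- paste0(seqs, tail_pad)
  if (nchar(seqs) < 200) seqs <- paste0(seqs, random_aa(200 - nchar(seqs)))
  list(sequence = seqs, hits = do.call(rbind, hits))
}

reverse_translate <- function(protein, codons) {
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(aas, function(a) sample(codons[[a]], 1), ""), collapse = "")
}

make_transcript <- function(protein, codons, max_try = 25) {
  utr_alpha <- c("C", "G", "T")  # no A, so UTRs cannot spawn an ATG
  for (k in seq_len(max_try)) {
    utr5 <- paste(sample(utr_alpha, sample(6:30, 1), replace = TRUE),
                  collapse = "")
    utr3 <- paste(sample(utr_alpha, sample(6:30, 1), replace = TRUE),
                  collapse = "")
    cds <- reverse_translate(protein, codons)
    tx <- paste0(utr5, cds, sample(c("TAA", "TAG", "TGA"), 1), utr3)
    orf <- extract_longest_orf(tx, min_aa = min(100, nchar(protein)))
    if (!is.null(orf) && identical(orf$peptide, protein)) return(tx)
  }
  stop("could not realise a transcript whose longest ORF is the protein")
}

#' Generate a synthetic proteome bundle with ground truth
#'
#' Emits, for every TRUE cell of every family presence matrix,
#' `proteins_per_cell` proteins whose sequences embed random linkers and
#' per-domain sequence blocks (with matching hit coordinates), plus SET-free
#' decoys, truncated same-locus isoforms, and a fraction of proteins
#' realised only as transcripts whose longest ORF encodes them. Fully
#' reproducible from the config seed.
#'
#' @param cfg A [generator_config()].
#' @return List with `proteins`, `transcripts`, `hits`, `references` (the
#'   family SET variants as an At/Os-style reference set) and `truth`
#'   (per-protein table plus `expected_counts` and `expected_presence`).
#' @export
generate_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "setfam_gencfg"))
  with_seed(cfg$seed, {
    catalog <- cfg$catalog
    panel_codes <- unique(unlist(lapply(cfg$presence, colnames)))
    bl <- make_blocks(catalog, cfg$families)
    refs <- make_references(bl$set_variants, cfg$families)
    codons <- codon_table()
    proteins <- list(); hits <- list(); truth <- list()
    n_loc <- 0L
    for (f in cfg$families) {
      pm <- cfg$presence[[f]]
      for (id in rownames(pm)) {
        entry <- catalog_entry(catalog, id)
        for (sp in colnames(pm)[pm[id, ]]) {
          for (k in seq_len(cfg$proteins_per_cell)) {
            n_loc <- n_loc + 1L
            pid <- sprintf("%s_%s_%04d", sp,
                           gsub("[^A-Za-z0-9]", "", id), n_loc)
            locus <- paste0("LOC", n_loc)
            domains <- entry$backbone
            if (length(entry$extras) && stats::runif(1) < cfg$extra_rate) {
              ex <- sample(entry$extras, 1)
              domains <- if (stats::runif(1) < 0.5) c(ex, domains)
                         else c(domains, ex)
            }
            asm <- assemble_protein(domains, f, bl, cfg, locus_i = n_loc)
            proteins[[pid]] <- data.frame(
              protein_id = pid, species = sp, locus_id = locus,
              sequence = asm$sequence, source = "proteome",
              stringsAsFactors = FALSE)
            h <- asm$hits
            h$protein_id <- pid
            hits[[pid]] <- h[, c("protein_id", "domain", "start", "end",
                                 "score")]
            truth[[pid]] <- data.frame(
              protein_id = pid, species = sp, locus = locus, label = id,
              family = f,
              architecture = architecture_string(entry$backbone),
              role = "primary", via_transcript = FALSE,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    proteins <- do.call(rbind, proteins)
    hits_df <- do.call(rbind, hits)
    truth_df <- do.call(rbind, truth)
    rownames(proteins) <- rownames(hits_df) <- rownames(truth_df) <- NULL
    if (is.null(proteins) || !nrow(proteins)) {
      if (cfg$transcript_fraction > 0)
        stop("transcript_fraction > 0 but no proteins to emit")
      proteins <- transdecode(data.frame(transcript_id = character(0),
                                         species = character(0),
                                         sequence = character(0)))
    }
    ## truncated isoforms sharing the locus
    n0 <- nrow(proteins)
    for (i in seq_len(n0)) {
      if (stats::runif(1) >= cfg$isoform_rate) next
      pid <- proteins$protein_id[i]
      h <- hits_df[hits_df$protein_id == pid, , drop = FALSE]
      cut_at <- max(max(h$end) + 5L, 200L)
      if (cut_at >= nchar(proteins$sequence[i])) next
      iso_id <- paste0(pid, "_iso")
      proteins <- rbind(proteins, data.frame(
        protein_id = iso_id, species = proteins$species[i],
        locus_id = proteins$locus_id[i],
        sequence = substr(proteins$sequence[i], 1, cut_at),
        source = "proteome", stringsAsFactors = FALSE))
      h$protein_id <- iso_id
      hits_df <- rbind(hits_df, h)
      truth_df <- rbind(truth_df, within(
        truth_df[truth_df$protein_id == pid, , drop = FALSE], {
          protein_id <- iso_id; role <- "isoform"
        }))
    }
    ## SET-free decoys
    non_set <- setdiff(names(bl$blocks), "SET")
    for (sp in panel_codes) {
      for (j in seq_len(cfg$decoys_per_species)) {
        pid <- sprintf("%s_decoy_%03d", sp, j)
        dseq <- random_aa(sample(200:600, 1))
        proteins <- rbind(proteins, data.frame(
          protein_id = pid, species = sp, locus_id = paste0("LOCD", pid),
          sequence = dseq, source = "proteome", stringsAsFactors = FALSE))
        d <- sample(non_set, 1)
        blen <- min(nchar(bl$blocks[[d]]), nchar(dseq) - 10L)
        st <- sample.int(nchar(dseq) - blen, 1)
        hits_df <- rbind(hits_df, data.frame(
          protein_id = pid, domain = d, start = st, end = st + blen - 1L,
          score = round(stats::runif(1, 40, 120), 1),
          stringsAsFactors = FALSE))
        truth_df <- rbind(truth_df, data.frame(
          protein_id = pid, species = sp, locus = paste0("LOCD", pid),
          label = NA_character_, family = NA_character_,
          architecture = d, role = "decoy", via_transcript = FALSE,
          stringsAsFactors = FALSE))
      }
    }
    ## realise a fraction of primaries only as transcripts
    transcripts <- data.frame(transcript_id = character(0),
                              species = character(0),
                              sequence = character(0),
                              stringsAsFactors = FALSE)
    prim <- which(proteins$protein_id %in%
                    truth_df$protein_id[truth_df$role == "primary"])
    n_tx <- floor(cfg$transcript_fraction * length(prim))
    if (n_tx > 0) {
      tx_rows <- sort(sample(prim, n_tx))
      for (i in tx_rows) {
        pid <- proteins$protein_id[i]
        tx <- make_transcript(proteins$sequence[i], codons)
        transcripts <- rbind(transcripts, data.frame(
          transcript_id = pid, species = proteins$species[i],
          sequence = tx, stringsAsFactors = FALSE))
        new_id <- paste0(pid, ".p1")
        hits_df$protein_id[hits_df$protein_id == pid] <- new_id
        truth_df$protein_id[truth_df$protein_id == pid] <- new_id
        truth_df$via_transcript[truth_df$protein_id == new_id] <- TRUE
      }
      proteins <- proteins[-tx_rows, , drop = FALSE]
    }
    rownames(proteins) <- rownames(hits_df) <- rownames(truth_df) <- NULL
    ## expectations: primaries only, per family x species
    prim_truth <- truth_df[truth_df$role == "primary", , drop = FALSE]
    counts <- count_by_class_species(
      structure(data.frame(species = prim_truth$species,
                           family = prim_truth$family,
                           stringsAsFactors = FALSE),
                class = c("set_classification", "data.frame")))
    list(proteins = proteins, transcripts = transcripts, hits = hits_df,
         references = refs,
         truth = list(table = truth_df, expected_counts = counts,
                      expected_presence = cfg$presence),
         config = cfg)
  })
}

#' Simulated SET-domain families for phylogeny tests
#'
#' Draws one random ancestor per family (rejection-sampled to pairwise
#' identity below `max_ancestor_identity`), then descendants by per-site
#' point substitution.
#'
#' @param seed RNG seed.
#' @param families Family names (>= 2 for a meaningful tree).
#' @param n_per_family Descendants per family.
#' @param mutation_rate Per-site substitution probability per descendant.
#' @param seq_length Ancestor length in residues.
#' @param max_ancestor_identity Rejection bound on ancestor similarity.
#' @return data.frame with `id`, `family`, `sequence`.
#' @export
generate_family_sequences <- function(seed,
                                      families = c("E(z)", "Ash", "Trx",
                                                   "Su(var)"),
                                      n_per_family = 10,
                                      mutation_rate = 0.05,
                                      seq_length = 140,
                                      max_ancestor_identity = 0.4) {
  stopifnot(length(families) >= 1, n_per_family >= 1)
  with_seed(seed, {
    anc <- list()
    for (f in families) {
      repeat {
        cand <- random_aa(seq_length)
        ok <- all(vapply(anc, function(a)
          seq_identity_naive(a, cand) < max_ancestor_identity, NA))
        if (isTRUE(ok) || !length(anc)) {
          anc[[f]] <- cand
          break
        }
      }
    }
    rows <- list()
    for (f in families) {
      for (i in seq_len(n_per_family)) {
        rows[[length(rows) + 1]] <- data.frame(
          id = sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", f), i),
          family = f, sequence = mutate_seq(anc[[f]], mutation_rate),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
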