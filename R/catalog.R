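## Rule catalog: machine-readable transcription of the family classification
## tables (Ash, Trx, Su(var)), the seven E(z) architecture variants and the
## Class V (Orphan/SETD/TPR) rules, plus domain-name canonicalization.

#' Read a domain-name synonym map
#'
#' The map resolves PFAM/CDD-style aliases (e.g. `"Post-SET"`, `"zf-C2H2"`)
#' to a single canonical spelling, case-insensitively.
#'
#' @param path TSV with columns `canonical` and `aliases` (comma-separated).
#' @return Named character vector mapping lower-cased alias -> canonical name.
#' @export
read_synonyms <- function(path = system.file("extdata", "domain_synonyms.tsv",
                                             package = "setfam")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("canonical", "aliases") %in% names(tab)))
  lut <- character(0)
  for (i in seq_len(nrow(tab))) {
    canon <- tab$canonical[i]
    als <- c(canon, strsplit(tab$aliases[i], ",", fixed = TRUE)[[1]])
    als <- trimws(als[nzchar(trimws(als))])
    lut[tolower(als)] <- canon
  }
  lut
}

#' Canonicalize a domain name
#'
#' Case-insensitive lookup against the synonym map. Unknown names pass
#' through unchanged and are flagged as "extra" (the tables list many one-off
#' extra domains, so unknown names must never error).
#'
#' @param raw Character vector of raw domain names (nonempty strings).
#' @param synonyms Alias lookup from [read_synonyms()].
#' @return Character vector of canonical names, with a logical attribute
#'   `"extra"` marking names absent from the synonym map.
#' @export
#' @examples
#' normalize_domain_name(c("Post-SET", "SET", "FRILLYDOMAIN"))
normalize_domain_name <- function(raw, synonyms = read_synonyms()) {
  if (!length(raw)) return(structure(character(0), extra = logical(0)))
  stopifnot(is.character(raw), all(nzchar(raw)))
  hit <- synonyms[tolower(raw)]
  extra <- is.na(hit)
  out <- ifelse(extra, raw, hit)
  structure(unname(out), extra = unname(extra))
}

## "II-2C would belong to Class II, subclass 2 and subdivision of subclass C"
parse_label_id <- function(id) {
  fam_map <- c(I = "E(z)", II = "Ash", III = "Trx", IV = "Su(var)",
               V = "ClassV")
  parts <- strsplit(id, "-", fixed = TRUE)[[1]]
  cls <- parts[1]
  if (!cls %in% names(fam_map)) stop("bad class code in label id: ", id)
  lab <- list(id = id, family = unname(fam_map[cls]), class_code = cls,
              subclass = "", subdivision = "", classv_kind = "",
              family_orphan = FALSE)
  rest <- if (length(parts) > 1) parts[2] else ""
  if (cls == "V") {
    if (!rest %in% c("Orphan", "SETD", "TPR"))
      stop("Class V label must be V-Orphan, V-SETD or V-TPR: ", id)
    lab$classv_kind <- rest
  } else if (rest == "Orphan") {
    if (cls == "I") stop("E(z) has no Orphan subclass: ", id)
    lab$family_orphan <- TRUE
  } else if (nzchar(rest)) {
    num <- sub("^([0-9]+).*$", "\\1", rest)
    lab$subclass <- paste0(cls, "-", num)
    if (grepl("^[0-9]+[A-Z]$", rest)) lab$subdivision <- id
  }
  lab
}

#' Load the architecture rule catalog
#'
#' Parses the human-editable catalog file (one record per line: label id,
#' hyphen-joined backbone, `extras=`, 16-character `presence=` string and
#' optional `orphan`/`ambig` flags; a `species` line declares the presence
#' column order). Domain names are canonicalized through the synonym map.
#'
#' Rows flagged `orphan` (the per-family "SET"-only rows) are matched by
#' SET-domain homology rather than by exact architecture and are exempt from
#' the backbone-uniqueness check. A row flagged `ambig` declares that its
#' backbone duplicates an earlier row; undeclared duplicates are an error.
#'
#' @param path Catalog file; defaults to the bundled transcription.
#' @param synonyms Alias lookup from [read_synonyms()].
#' @param panel Species panel from [set_species()].
#' @return An object of class `set_catalog`: a list of entries, each with
#'   `id`, `family`, `class_code`, `subclass`, `subdivision`, `classv_kind`,
#'   `family_orphan`, `orphan`, `ambig`, `backbone` (character vector, N->C),
#'   `extras` and `presence` (named logical, length 16).
#' @export
read_catalog <- function(path = system.file("extdata", "set_catalog.txt",
                                            package = "setfam"),
                         synonyms = read_synonyms(),
                         panel = set_species()) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  species <- table_species_order()
  entries <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "species") {
      species <- tok[-1]
      check_species_codes(species, panel)
      if (length(species) != nrow(panel))
        stop("species line must list all ", nrow(panel), " codes")
      next
    }
    if (length(tok) < 2) stop("malformed catalog line: ", ln)
    id <- tok[1]
    backbone_raw <- strsplit(tok[2], "-", fixed = TRUE)[[1]]
    backbone <- as.character(normalize_domain_name(backbone_raw, synonyms))
    kv <- tok[-(1:2)]
    extras <- character(0)
    presence_str <- NULL
    orphan <- FALSE
    ambig <- FALSE
    for (t in kv) {
      if (startsWith(t, "extras=")) {
        v <- sub("^extras=", "", t)
        if (v != "-") extras <- strsplit(v, ",", fixed = TRUE)[[1]]
      } else if (startsWith(t, "presence=")) {
        presence_str <- sub("^presence=", "", t)
      } else if (t == "orphan") orphan <- TRUE
      else if (t == "ambig") ambig <- TRUE
      else stop("unknown token '", t, "' in catalog line: ", ln)
    }
    if (is.null(presence_str) || nchar(presence_str) != length(species) ||
        grepl("[^+-]", presence_str))
      stop("entry ", id, ": presence must be ", length(species),
           " characters of +/-")
    presence <- stats::setNames(
      strsplit(presence_str, "")[[1]] == "+", species)
    lab <- parse_label_id(id)
    if (lab$classv_kind != "TPR" && !("SET" %in% backbone))
      stop("entry ", id, ": backbone must contain SET")
    entry <- c(lab, list(
      orphan = orphan, ambig = ambig, backbone = backbone,
      extras = as.character(normalize_domain_name(extras, synonyms))))
    entry$presence <- presence
    entries[[length(entries) + 1L]] <- entry
  }
  if (!length(entries)) {
    warning("empty catalog file: ", path)
  }
  ids <- vapply(entries, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate catalog ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ## backbone uniqueness among exact-matchable rows, unless declared ambig
  key <- vapply(entries, function(e)
    if (e$orphan) NA_character_ else paste(e$backbone, collapse = "-"),
    "")
  seen <- character(0)
  for (i in seq_along(entries)) {
    if (is.na(key[i])) next
    if (key[i] %in% names(seen) && !entries[[i]]$ambig)
      stop("duplicate backbone '", key[i], "' in entries ",
           seen[key[i]], " and ", entries[[i]]$id,
           " (flag the later one 'ambig' if intended)")
    if (!key[i] %in% names(seen)) seen[key[i]] <- entries[[i]]$id
  }
  structure(entries, class = "set_catalog", species = species, path = path)
}

.catalog_cache <- new.env(parent = emptyenv())

#' The bundled rule catalog
#'
#' Cached accessor for the catalog shipped with the package (the transcribed
#' family tables plus E(z) variants and Class V rules).
#' @return A `set_catalog` object; see [read_catalog()].
#' @export
default_catalog <- function() {
  if (is.null(.catalog_cache$cat)) .catalog_cache$cat <- read_catalog()
  .catalog_cache$cat
}

#' @export
print.set_catalog <- function(x, ...) {
  ids <- vapply(x, `[[`, "", "id")
  fam <- vapply(x, `[[`, "", "family")
  cat("SET-domain architecture catalog:", length(x), "entries\n")
  print(table(family = fam))
  cat("ids:", paste(ids, collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.set_catalog <- function(x, ...) {
  data.frame(
    id = vapply(x, `[[`, "", "id"),
    family = vapply(x, `[[`, "", "family"),
    class_code = vapply(x, `[[`, "", "class_code"),
    subclass = vapply(x, `[[`, "", "subclass"),
    subdivision = vapply(x, `[[`, "", "subdivision"),
    backbone = vapply(x, function(e) paste(e$backbone, collapse = "-"), ""),
    extras = vapply(x, function(e) paste(e$extras, collapse = ","), ""),
    orphan = vapply(x, `[[`, NA, "orphan"),
    presence = vapply(x, function(e)
      paste(ifelse(e$presence, "+", "-"), collapse = ""), ""),
    stringsAsFactors = FALSE)
}

catalog_entry <- function(catalog, id) {
  ids <- vapply(catalog, `[[`, "", "id")
  i <- match(id, ids)
  if (is.na(i)) stop("no catalog entry with id ", id)
  catalog[[i]]
}

## Domains that make up any exact-matchable class I-IV backbone; everything
## else on a protein counts as an "extra" and is stripped before matching.
signature_vocabulary <- function(catalog) {
  keep <- vapply(catalog, function(e)
    !e$orphan && e$class_code != "V", NA)
  unique(unlist(lapply(catalog[keep], `[[`, "backbone")))
}
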