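## On-disk formats. A family library is one directory per family containing
##   alignment.fasta   aligned FASTA, headers "seq_id|taxon_id|tier"
##   tree.nwk          rooted Newick whose leaf labels match the row ids
##   labels_<src>.tsv  optional orthology labels (seq_id, group_id)
##   annotations.tsv   optional annotations (seq_id, kind, value, evidence)
##   meta.json         optional {family_id, family_type}

parse_fasta_header <- function(h) {
  parts <- strsplit(h, "|", fixed = TRUE)[[1]]
  list(seq_id = parts[1],
       taxon_id = if (length(parts) >= 2 && nzchar(parts[2])) parts[2] else "unknown",
       curation_tier = if (length(parts) >= 3 && parts[3] == "curated")
         "curated" else "automatic")
}

#' Read a single-record protein query from FASTA
#'
#' Residues are uppercased and gaps/whitespace stripped; the sequence must be
#' non-empty, within the configured maximum length (default 2000 amino acids),
#' and drawn from the 20-letter alphabet plus X.
#'
#' @param fasta_path path to a single-record FASTA file
#' @param max_length maximum accepted length (residues)
#' @return a [sequence_record()]
#' @export
read_query <- function(fasta_path, max_length = 2000) {
  ## read as raw strings: residue validation (with offender listing) is ours
  set <- Biostrings::readBStringSet(fasta_path)
  if (length(set) == 0) stop("no FASTA record in ", fasta_path)
  if (length(set) > 1) stop("expected a single-record FASTA, found ", length(set))
  hdr <- parse_fasta_header(names(set)[1])
  res <- gsub("[-. \t]", "", toupper(as.character(set[[1]])))
  if (nchar(res) == 0) stop("empty query sequence")
  if (nchar(res) > max_length) {
    stop("query length ", nchar(res), " exceeds the maximum of ",
         max_length, " amino acids")
  }
  sequence_record(hdr$seq_id, res, hdr$taxon_id, hdr$curation_tier)
}

#' Assemble a family object
#'
#' Binds an alignment, a rooted tree, orthology labelings and annotations into
#' one validated family. The tree's leaf-label set must equal the alignment's
#' row-identifier set; an unrooted tree is midpoint-rooted with a warning.
#'
#' @param family_id identifier
#' @param alignment a [family_alignment()]
#' @param tree a `phylo`
#' @param seq_meta data.frame (seq_id, taxon_id, curation_tier); defaults
#'   filled for missing rows
#' @param labelings named list of `list(source_name, assignments)` labelings
#' @param annotations data.frame (seq_id, kind, value, evidence)
#' @param family_type "mda" (global homology) or "domain" (local matches)
#' @return object of class `ortho_family`
#' @export
ortho_family <- function(family_id, alignment, tree, seq_meta = NULL,
                         labelings = list(), annotations = NULL,
                         family_type = c("mda", "domain")) {
  family_type <- match.arg(family_type)
  stopifnot(inherits(alignment, "family_alignment"), inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    warning("tree for family '", family_id, "' is unrooted; midpoint rooting")
    tree <- phangorn::midpoint(tree)
  }
  extra_tips <- setdiff(tree$tip.label, alignment$row_ids)
  extra_rows <- setdiff(alignment$row_ids, tree$tip.label)
  if (length(extra_tips) > 0 || length(extra_rows) > 0) {
    stop("tree/alignment identifier mismatch in family '", family_id, "': ",
         if (length(extra_tips)) paste("tree-only:", paste(extra_tips, collapse = ", ")),
         if (length(extra_tips) && length(extra_rows)) "; ",
         if (length(extra_rows)) paste("alignment-only:", paste(extra_rows, collapse = ", ")))
  }
  if (is.null(seq_meta)) {
    seq_meta <- data.frame(seq_id = alignment$row_ids, taxon_id = "unknown",
                           curation_tier = "automatic", stringsAsFactors = FALSE)
  }
  miss <- setdiff(alignment$row_ids, seq_meta$seq_id)
  if (length(miss) > 0) {
    seq_meta <- rbind(seq_meta,
                      data.frame(seq_id = miss, taxon_id = "unknown",
                                 curation_tier = "automatic"))
  }
  seq_meta <- seq_meta[match(alignment$row_ids, seq_meta$seq_id), , drop = FALSE]
  rownames(seq_meta) <- NULL
  if (is.null(annotations)) {
    annotations <- data.frame(seq_id = character(), kind = character(),
                              value = character(), evidence = character(),
                              stringsAsFactors = FALSE)
  }
  bad_ann <- setdiff(annotations$seq_id, alignment$row_ids)
  if (length(bad_ann) > 0) {
    stop("annotations reference unknown sequence(s): ",
         paste(unique(bad_ann), collapse = ", "))
  }
  for (lab in labelings) {
    if (anyDuplicated(names(lab$assignments))) {
      stop("labeling '", lab$source_name, "' assigns a sequence twice")
    }
    bad <- setdiff(names(lab$assignments), alignment$row_ids)
    if (length(bad) > 0) {
      stop("labeling '", lab$source_name, "' references unknown sequence(s): ",
           paste(bad, collapse = ", "))
    }
  }
  names(labelings) <- vapply(labelings, `[[`, "", "source_name")
  labelings <- labelings[order(names(labelings))]  # canonical source order
  structure(list(family_id = family_id, family_type = family_type,
                 alignment = alignment, tree = tree, seq_meta = seq_meta,
                 labelings = labelings, annotations = annotations),
            class = "ortho_family")
}

#' @export
print.ortho_family <- function(x, ...) {
  cat(sprintf("<ortho_family> %s (%s): %d sequences, %d labeling source(s), %d annotation(s)\n",
              x$family_id, x$family_type, length(x$alignment$row_ids),
              length(x$labelings), nrow(x$annotations)))
  invisible(x)
}

#' Read one family from a library directory
#'
#' @param dir_path directory containing `alignment.fasta` and `tree.nwk`
#'   (mandatory), plus optional `labels_*.tsv`, `annotations.tsv`, `meta.json`
#' @param occupancy_min match-column occupancy threshold
#' @return an `ortho_family`
#' @export
read_family <- function(dir_path, occupancy_min = 0.5) {
  afile <- file.path(dir_path, "alignment.fasta")
  tfile <- file.path(dir_path, "tree.nwk")
  for (f in c(afile, tfile)) {
    if (!file.exists(f)) stop("missing mandatory file: ", f)
  }
  set <- Biostrings::readBStringSet(afile)
  heads <- lapply(names(set), parse_fasta_header)
  ids <- vapply(heads, `[[`, "", "seq_id")
  aln <- family_alignment(ids, as.character(set), occupancy_min = occupancy_min)
  seq_meta <- data.frame(
    seq_id = ids,
    taxon_id = vapply(heads, `[[`, "", "taxon_id"),
    curation_tier = vapply(heads, `[[`, "", "curation_tier"),
    stringsAsFactors = FALSE)
  tree <- ape::read.tree(tfile)

  labelings <- list()
  for (lf in sort(list.files(dir_path, pattern = "^labels_.*\\.tsv$"))) {
    src <- sub("^labels_(.*)\\.tsv$", "\\1", lf)
    tab <- utils::read.delim(file.path(dir_path, lf), comment.char = "#",
                             stringsAsFactors = FALSE)
    labelings[[src]] <- list(
      source_name = src,
      assignments = stats::setNames(as.character(tab$group_id),
                                    as.character(tab$seq_id)))
  }
  annotations <- NULL
  annf <- file.path(dir_path, "annotations.tsv")
  if (file.exists(annf)) {
    annotations <- utils::read.delim(annf, comment.char = "#",
                                     stringsAsFactors = FALSE)
  }
  meta <- list(family_id = basename(normalizePath(dir_path, mustWork = FALSE)),
               family_type = "mda")
  mfile <- file.path(dir_path, "meta.json")
  if (file.exists(mfile)) {
    m <- jsonlite::read_json(mfile, simplifyVector = TRUE)
    meta[names(m)] <- m
  }
  ortho_family(meta$family_id, aln, tree, seq_meta = seq_meta,
               labelings = labelings, annotations = annotations,
               family_type = meta$family_type)
}

#' Write a family to a library directory
#'
#' Inverse of [read_family()]; the pair round-trips losslessly on valid
#' families. Branch lengths are written with six decimals so regeneration from
#' the same seed is byte-identical.
#'
#' @param family an `ortho_family`
#' @param dir_path output directory (created if needed)
#' @return `dir_path`, invisibly
#' @export
write_family <- function(family, dir_path) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  aln <- family$alignment
  meta <- family$seq_meta
  headers <- paste(meta$seq_id, meta$taxon_id, meta$curation_tier, sep = "|")
  writeLines(paste0(">", headers, "\n", aln$rows),
             file.path(dir_path, "alignment.fasta"))
  tr <- family$tree
  if (!is.null(tr$edge.length)) tr$edge.length <- round(tr$edge.length, 6)
  ape::write.tree(tr, file.path(dir_path, "tree.nwk"))
  for (lab in family$labelings) {
    tab <- data.frame(seq_id = names(lab$assignments),
                      group_id = unname(lab$assignments))
    utils::write.table(tab,
                       file.path(dir_path, paste0("labels_", lab$source_name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (nrow(family$annotations) > 0) {
    utils::write.table(family$annotations, file.path(dir_path, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(family_id = family$family_id,
                            family_type = family$family_type),
                       file.path(dir_path, "meta.json"), auto_unbox = TRUE)
  invisible(dir_path)
}

#' Read every family under a library directory
#' @param lib_dir directory whose subdirectories are families
#' @param occupancy_min match-column occupancy threshold
#' @return named list of `ortho_family` objects
#' @export
read_library <- function(lib_dir, occupancy_min = 0.5) {
  dirs <- sort(list.dirs(lib_dir, recursive = FALSE))
  fams <- lapply(dirs, read_family, occupancy_min = occupancy_min)
  stats::setNames(fams, vapply(fams, `[[`, "", "family_id"))
}

#' Read a pipeline configuration file (JSON)
#'
#' The file holds a `preset` name plus any individual parameter overrides,
#' mirroring `preset_config(preset, ...)`.
#' @param path JSON config file
#' @return a `preset_config`
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  preset <- if (!is.null(raw$preset)) raw$preset else "high_recall"
  raw$preset <- NULL
  do.call(preset_config, c(list(preset = preset), raw))
}
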