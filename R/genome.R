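# Data model and I/O for multi-protein viral genomes, protein-boundary
# segmentation into fixed-size blocks, and coordinate bookkeeping between
# padded-block space and residue space.
#
# Conventions: protein ordinals are 0-based (they are identifiers carried by
# the FASTA header / TSV file contracts); residue and token positions inside
# the R API are 1-based, the R convention.

#' Construct a genome record
#'
#' A genome record holds the ordered proteins of one genome together with
#' their coordinates in the unpadded concatenation of all protein sequences.
#'
#' @param genome_id Genome identifier.
#' @param protein_id Character vector of protein identifiers, one per protein.
#' @param ordinal Integer vector of 0-based positions of each protein in
#'   genome order; must be consecutive from 0.
#' @param sequence Character vector of amino-acid sequences (20 canonical
#'   residues plus B, J, O, U, X, Z).
#' @return An object of class `genome_record`: a list with `genome_id`, a
#'   `proteins` data frame (`protein_id`, `ordinal`, `sequence`, `length`,
#'   `start`, `end` — 1-based closed coordinates in the concatenated genome)
#'   and `total_length`.
#' @examples
#' g <- genome_record("g1", c("a", "b"), c(0, 1), c("MKV", "ACDEF"))
#' g$total_length
#' @export
genome_record <- function(genome_id, protein_id, ordinal, sequence) {
  vb_assert(length(protein_id) == length(ordinal) &&
              length(ordinal) == length(sequence),
            "protein_id, ordinal and sequence must have equal length")
  vb_assert(length(sequence) >= 1L, "a genome needs at least one protein")
  ordinal <- as.integer(ordinal)
  ord <- order(ordinal)
  protein_id <- protein_id[ord]
  ordinal <- ordinal[ord]
  sequence <- toupper(sequence[ord])
  if (anyDuplicated(ordinal)) {
    stop(sprintf("duplicate (genome_id, ordinal) for genome '%s': ordinal %d",
                 genome_id, ordinal[duplicated(ordinal)][1L]), call. = FALSE)
  }
  expect <- seq.int(0L, length(ordinal) - 1L)
  if (!identical(ordinal, expect)) {
    stop(sprintf("genome '%s': missing ordinal %d (ordinals must be 0..k)",
                 genome_id, setdiff(expect, ordinal)[1L]), call. = FALSE)
  }
  lens <- nchar(sequence)
  vb_assert(all(lens > 0L), "genome '%s': empty protein sequence", genome_id)
  for (p in seq_along(sequence)) {
    chars <- strsplit(sequence[p], "", fixed = TRUE)[[1L]]
    bad <- which(!(chars %in% AA_EXTENDED))
    if (length(bad) > 0L) {
      stop(sprintf(
        "genome '%s', protein '%s': non-alphabet residue '%s' at position %d",
        genome_id, protein_id[p], chars[bad[1L]], bad[1L]), call. = FALSE)
    }
  }
  end <- cumsum(lens)
  start <- end - lens + 1L
  structure(list(
    genome_id = as.character(genome_id),
    proteins = data.frame(
      protein_id = as.character(protein_id),
      ordinal = ordinal,
      sequence = sequence,
      length = as.integer(lens),
      start = as.integer(start),
      end = as.integer(end),
      stringsAsFactors = FALSE
    ),
    total_length = as.integer(sum(lens))
  ), class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("genome_record '%s': %d proteins, %d aa\n",
              x$genome_id, nrow(x$proteins), x$total_length))
  cat(sprintf("  lengths: %s\n", paste(x$proteins$length, collapse = " ")))
  invisible(x)
}

#' Concatenated amino-acid sequence of a genome
#'
#' @param genome A `genome_record`.
#' @return Single string: proteins concatenated in genome order, no padding.
#' @export
genome_sequence <- function(genome) {
  paste(genome$proteins$sequence, collapse = "")
}

# Map 1-based concatenated-genome positions to protein ordinals (0-based).
token_protein <- function(genome, pos) {
  vb_assert(all(pos >= 1L & pos <= genome$total_length),
            "position out of range 1..%d", genome$total_length)
  findInterval(pos, genome$proteins$start) - 1L
}

#' Read multi-protein genomes from an amino-acid FASTA file
#'
#' Headers follow the dialect `>genome_id|ordinal|protein_id` with 0-based
#' ordinals giving each protein's position in genome order. Alternatively a
#' boundary table (TSV with columns `protein_id`, `genome_id`, `ordinal`, or a
#' GFF3 file whose records carry `ID` and `genome_id` attributes) maps plain
#' FASTA identifiers to genomes and order.
#'
#' @param path FASTA file of amino-acid sequences.
#' @param boundary_table Optional path to a TSV or GFF3 boundary table.
#' @return List of [genome_record()] objects, one per genome, proteins sorted
#'   by ordinal. An empty FASTA yields an empty list with a warning.
#' @export
read_genome_fasta <- function(path, boundary_table = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    warning(sprintf("no sequences in '%s'", path))
    return(list())
  }
  headers <- names(seqs)
  sequences <- as.character(seqs)
  if (is.null(boundary_table)) {
    parts <- strsplit(headers, "|", fixed = TRUE)
    ok <- vapply(parts, length, 1L) >= 3L
    vb_assert(all(ok),
              "header '%s' does not follow 'genome_id|ordinal|protein_id'",
              headers[!ok][1L])
    genome_id <- vapply(parts, `[[`, "", 1L)
    ordinal <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
    vb_assert(!anyNA(ordinal), "non-integer ordinal in FASTA header")
    protein_id <- vapply(parts, function(p) paste(p[-(1:2)], collapse = "|"), "")
  } else {
    bt <- read_boundary_table(boundary_table)
    # FASTA ids may carry descriptions after whitespace
    ids <- sub("\\s.*$", "", headers)
    idx <- match(ids, bt$protein_id)
    vb_assert(!anyNA(idx), "protein '%s' absent from boundary table",
              ids[is.na(idx)][1L])
    genome_id <- bt$genome_id[idx]
    ordinal <- bt$ordinal[idx]
    protein_id <- ids
  }
  out <- lapply(split(seq_along(sequences), genome_id), function(i) {
    genome_record(genome_id[i[1L]], protein_id[i], ordinal[i], sequences[i])
  })
  out[order(names(out))]
}

# Boundary table: TSV with header columns protein_id, genome_id, ordinal
# (extra columns ignored), or GFF3 with ID= and genome_id= attributes.
read_boundary_table <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^##gff-version", first)) {
    vb_assert(requireNamespace("rtracklayer", quietly = TRUE),
              "reading GFF3 boundary tables requires the rtracklayer package")
    gff <- as.data.frame(rtracklayer::readGFF(path))
    vb_assert(all(c("ID", "genome_id") %in% names(gff)),
              "GFF3 boundary table needs ID and genome_id attributes")
    gff <- gff[order(gff$genome_id, gff$start), ]
    ordinal <- stats::ave(seq_len(nrow(gff)), gff$genome_id,
                          FUN = function(i) seq_along(i) - 1L)
    data.frame(protein_id = as.character(gff$ID),
               genome_id = as.character(gff$genome_id),
               ordinal = as.integer(ordinal), stringsAsFactors = FALSE)
  } else {
    bt <- utils::read.delim(path, stringsAsFactors = FALSE)
    vb_assert(all(c("protein_id", "genome_id", "ordinal") %in% names(bt)),
              "boundary table needs columns protein_id, genome_id, ordinal")
    bt$ordinal <- as.integer(bt$ordinal)
    bt
  }
}

#' Write genomes to FASTA in the package's header dialect
#'
#' @param genomes List of `genome_record` objects (or a single one).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  recs <- do.call(c, lapply(genomes, function(g) {
    s <- Biostrings::AAStringSet(g$proteins$sequence)
    names(s) <- sprintf("%s|%d|%s", g$genome_id, g$proteins$ordinal,
                        g$proteins$protein_id)
    s
  }))
  Biostrings::writeXStringSet(recs, path, width = 60L)
  invisible(path)
}

#' Segment a genome into fixed-size blocks at protein boundaries
#'
#' Each protein is padded independently up to a multiple of `block_size`, so
#' no block ever spans a protein boundary. The layout records, for every
#' padded position, which protein and residue it carries (or PAD).
#'
#' @param genome A `genome_record`.
#' @param block_size Block length B in residues; default 32.
#' @return Object of class `block_layout`: list with `block_size`,
#'   `n_blocks` (per protein), `first_block` (1-based index of each protein's
#'   first block), `padded_length`, `total_length`, and `position_map`, a data
#'   frame over padded positions with columns `ordinal` (0-based protein
#'   ordinal or NA for PAD), `residue` (1-based residue index within the
#'   protein or NA) and `genome_pos` (1-based position in the unpadded
#'   concatenation or NA).
#' @export
segment_genome <- function(genome, block_size = 32L) {
  vb_assert(is.numeric(block_size) && length(block_size) == 1L &&
              block_size >= 1, "block_size must be a positive integer")
  block_size <- as.integer(block_size)
  lens <- genome$proteins$length
  n_blocks <- as.integer(ceiling(lens / block_size))
  first_block <- c(1L, 1L + cumsum(n_blocks)[-length(n_blocks)])
  padded_length <- as.integer(block_size * sum(n_blocks))
  ordinal <- rep(NA_integer_, padded_length)
  residue <- rep(NA_integer_, padded_length)
  genome_pos <- rep(NA_integer_, padded_length)
  off <- 0L
  for (p in seq_along(lens)) {
    idx <- off + seq_len(lens[p])
    ordinal[idx] <- genome$proteins$ordinal[p]
    residue[idx] <- seq_len(lens[p])
    genome_pos[idx] <- genome$proteins$start[p] + seq_len(lens[p]) - 1L
    off <- off + n_blocks[p] * block_size
  }
  structure(list(
    block_size = block_size,
    n_blocks = n_blocks,
    first_block = as.integer(first_block),
    padded_length = padded_length,
    total_length = genome$total_length,
    position_map = data.frame(ordinal = ordinal, residue = residue,
                              genome_pos = genome_pos)
  ), class = "block_layout")
}

#' @export
print.block_layout <- function(x, ...) {
  cat(sprintf(
    "block_layout: B=%d, %d proteins, %d blocks, padded %d (of %d aa, %d PAD)\n",
    x$block_size, length(x$n_blocks), sum(x$n_blocks), x$padded_length,
    x$total_length, x$padded_length - x$total_length))
  invisible(x)
}

#' Map padded positions back to protein coordinates
#'
#' Inverse of the per-protein padding embedding.
#'
#' @param layout A `block_layout`.
#' @param padded_index Integer vector of 1-based padded positions.
#' @return Data frame with one row per index: `ordinal` (0-based protein
#'   ordinal), `residue` (1-based residue index within the protein); both NA
#'   for PAD positions.
#' @export
token_coordinates <- function(layout, padded_index) {
  vb_assert(all(padded_index >= 1L & padded_index <= layout$padded_length),
            "padded index out of range 1..%d", layout$padded_length)
  layout$position_map[padded_index, c("ordinal", "residue"), drop = FALSE]
}

# 1-based padded positions that carry residues, in genome order.
non_pad_positions <- function(layout) {
  which(!is.na(layout$position_map$ordinal))
}

# padded positions covered by block b (1-based block index)
block_positions <- function(layout, b) {
  ((b - 1L) * layout$block_size + 1L):(b * layout$block_size)
}

#' Read a protein-pair interaction table
#'
#' TSV with header `genome_id  i  j  score  rank  adjacent`; `i`, `j` are
#' 0-based protein ordinals, stored canonically with `i < j`.
#'
#' @param path TSV path.
#' @return Data frame with those columns (`adjacent` logical).
#' @export
read_interaction_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "i", "j", "score", "rank", "adjacent")
  vb_assert(all(need %in% names(tb)),
            "interaction table needs columns: %s", paste(need, collapse = " "))
  tb <- tb[, need]
  tb$i <- as.integer(tb$i); tb$j <- as.integer(tb$j)
  vb_assert(!any(tb$i == tb$j), "self interaction (i == j) is not allowed")
  flip <- tb$i > tb$j
  if (any(flip)) {
    tmp <- tb$i[flip]; tb$i[flip] <- tb$j[flip]; tb$j[flip] <- tmp
  }
  tb$score <- as.numeric(tb$score)
  tb$rank <- as.integer(tb$rank)
  tb$adjacent <- as.logical(tb$adjacent)
  tb
}

#' Write a protein-pair interaction table
#'
#' @param table Data frame with columns `genome_id`, `i`, `j`, `score`,
#'   `rank`, `adjacent`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(table, path) {
  vb_assert(!any(table$i == table$j), "self interaction (i == j) is not allowed")
  flip <- table$i > table$j
  if (any(flip)) {
    tmp <- table$i[flip]; table$i[flip] <- table$j[flip]; table$j[flip] <- tmp
  }
  cols <- c("genome_id", "i", "j", "score", "rank", "adjacent")
  write_tsv_deterministic(table[, cols], path)
}
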