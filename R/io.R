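# Flat-binary + JSON-manifest containers for attention stacks, embedding
# matrices, and BSR masks. Arrays are stored as little-endian float64 (or
# int32 for indices) in column-major order; the manifest records shapes so
# any consumer can reconstruct them.

write_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Write an attention stack container
#'
#' Writes `manifest.json` (shape, dtype, layout) and `attention.bin` (all
#' matrices concatenated, layer-major then head, each column-major float64)
#' into `dir`.
#'
#' @param stack An [attention_stack()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_attention_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(list(kind = "attention_stack",
                      n_layers = stack$n_layers, n_heads = stack$n_heads,
                      L = stack$L, dtype = "float64",
                      order = "layer-major, head, column-major matrix",
                      file = "attention.bin"),
                 file.path(dir, "manifest.json"))
  con <- file(file.path(dir, "attention.bin"), "wb")
  on.exit(close(con))
  for (l in seq_len(stack$n_layers)) {
    for (h in seq_len(stack$n_heads)) {
      writeBin(as.vector(stack$matrices[[l]][[h]]), con, size = 8L,
               endian = "little")
    }
  }
  invisible(dir)
}

#' Read an attention stack container
#'
#' @param dir Directory written by [write_attention_stack()].
#' @return An [attention_stack()].
#' @export
read_attention_stack <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  vb_assert(identical(man$kind, "attention_stack"),
            "'%s' is not an attention stack container", dir)
  L <- man$L
  con <- file(file.path(dir, man$file), "rb")
  on.exit(close(con))
  mats <- lapply(seq_len(man$n_layers), function(l) {
    lapply(seq_len(man$n_heads), function(h) {
      matrix(readBin(con, "double", n = L * L, size = 8L, endian = "little"),
             L, L)
    })
  })
  attention_stack(mats)
}

#' Write an embedding container
#'
#' @param embeddings Numeric matrix, one row per item.
#' @param dir Output directory.
#' @param item_ids Optional item identifiers (default rownames or indices).
#' @return `dir`, invisibly.
#' @export
write_embeddings <- function(embeddings, dir, item_ids = NULL) {
  embeddings <- as.matrix(embeddings)
  if (is.null(item_ids)) {
    item_ids <- rownames(embeddings)
    if (is.null(item_ids)) item_ids <- as.character(seq_len(nrow(embeddings)))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_manifest(list(kind = "embeddings", n_items = nrow(embeddings),
                      n_dims = ncol(embeddings), dtype = "float64",
                      order = "column-major", file = "embeddings.bin",
                      item_ids = item_ids),
                 file.path(dir, "manifest.json"))
  con <- file(file.path(dir, "embeddings.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(embeddings), con, size = 8L, endian = "little")
  invisible(dir)
}

#' Read an embedding container
#'
#' @param dir Directory written by [write_embeddings()].
#' @return Numeric matrix with item ids as rownames.
#' @export
read_embeddings <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  vb_assert(identical(man$kind, "embeddings"),
            "'%s' is not an embeddings container", dir)
  con <- file(file.path(dir, man$file), "rb")
  on.exit(close(con))
  m <- matrix(readBin(con, "double", n = man$n_items * man$n_dims, size = 8L,
                      endian = "little"), man$n_items, man$n_dims)
  rownames(m) <- man$item_ids
  m
}

#' Serialize a BSR mask to JSON manifest + flat binary arrays
#'
#' Writes `<prefix>.json` (block size, counts, origin tags) and
#' `<prefix>.bin` (row pointers then column indices, int32 little-endian).
#'
#' @param mask A `bsr_layout`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_bsr_mask <- function(mask, prefix) {
  write_manifest(list(kind = "bsr_mask", block_size = mask$block_size,
                      n_block_rows = mask$n_block_rows,
                      n_stored = length(mask$col_ind),
                      dtype = "int32", file = paste0(basename(prefix), ".bin"),
                      origin = mask$origin),
                 paste0(prefix, ".json"))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.integer(mask$row_ptr), con, size = 4L, endian = "little")
  writeBin(as.integer(mask$col_ind), con, size = 4L, endian = "little")
  invisible(prefix)
}

#' Read a BSR mask serialized by [write_bsr_mask()]
#'
#' @param prefix Path prefix used when writing.
#' @return A `bsr_layout`.
#' @export
read_bsr_mask <- function(prefix) {
  man <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  vb_assert(identical(man$kind, "bsr_mask"), "'%s' is not a BSR mask", prefix)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  row_ptr <- readBin(con, "integer", n = man$n_block_rows + 1L, size = 4L,
                     endian = "little")
  col_ind <- readBin(con, "integer", n = man$n_stored, size = 4L,
                     endian = "little")
  structure(list(block_size = man$block_size,
                 n_block_rows = man$n_block_rows,
                 row_ptr = row_ptr, col_ind = col_ind,
                 origin = man$origin),
            class = "bsr_layout")
}
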