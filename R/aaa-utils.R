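# Internal helpers shared across modules.

# Amino-acid alphabet: 20 canonical residues plus the IUPAC ambiguity /
# rare-residue codes seen in real proteomes. PAD is a layout concept only and
# never appears in sequences.
AA_CANONICAL <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)
AA_EXTENDED <- c(AA_CANONICAL, "B", "J", "O", "U", "X", "Z")

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the random number generator seeded to `seed` and restores
#' the caller's RNG state afterwards, so seeded generators never perturb
#' global randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# stopifnot-style check with a formatted message
vb_assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# Deterministic TSV writer: fixed column order, no quoting, "." decimal,
# 15 significant digits for doubles so outputs are byte-stable across runs.
write_tsv_deterministic <- function(df, path) {
  fmt <- vapply(df, function(col) {
    if (is.double(col)) {
      out <- formatC(col, digits = 15, format = "g")
      out[is.na(col)] <- "NA"  # formatC pads NA with spaces
      out
    } else {
      as.character(col)
    }
  }, FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L, dimnames = list(NULL, names(df)))
  con <- file(path, open = "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    writeLines(apply(fmt, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}
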