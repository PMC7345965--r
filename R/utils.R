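# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so package functions never perturb user code.
withSeed <- function(seed, expr) {
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
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit polynomial string hash (exact in double arithmetic:
# intermediate values stay below 2^53). Used to derive per-stream seeds from
# analyte names so panel composition never perturbs existing columns.
stringHash <- function(x) {
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 131 + code) %% 2147483647
  as.integer(h)
}

# Fold a root seed and a stream label into a reproducible 31-bit seed.
deriveSeed <- function(root, label) {
  as.integer((as.numeric(root) %% 2147483647 + stringHash(label)) %% 2147483647)
}

# Write a data.frame as CSV preceded by '#'-prefixed header comment lines
# documenting units and column semantics. Readable with read.csv(comment.char="#").
writeCommentedCSV <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (line in comments) writeLines(paste0("# ", line), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

readCommentedCSV <- function(path, ...) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE,
                  stringsAsFactors = FALSE, ...)
}
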