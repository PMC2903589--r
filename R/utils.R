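# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without clobbering the caller's
# RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

stop_pdacsig <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "pdacsig_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

check_expression_matrix <- function(mat, what = "expression matrix") {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop_pdacsig(sprintf("%s must be a numeric matrix", what), "invalid_input")
  }
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    stop_pdacsig(sprintf("%s must have unique gene IDs as rownames", what),
                 "invalid_input")
  }
  if (is.null(colnames(mat)) || anyDuplicated(colnames(mat))) {
    stop_pdacsig(sprintf("%s must have unique sample IDs as colnames", what),
                 "invalid_input")
  }
  invisible(mat)
}
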