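# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_chemoconn <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "chemoconn_error")))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == as.integer(x)
}

# Centered moving average with partial windows at the edges, so length is
# preserved and a constant series passes through unchanged.
moving_average <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n == 0L) return(x)
  lo <- (window - 1L) %/% 2L          # points taken before t
  hi <- window - 1L - lo              # points taken after t
  cs <- cumsum(c(0, x))
  from <- pmax(seq_len(n) - lo, 1L)
  to <- pmin(seq_len(n) + hi, n)
  (cs[to + 1L] - cs[from]) / (to - from + 1L)
}

# Minimal flat YAML emitter for the cohort manifest (write-only; nothing in
# the pipeline parses it back).
write_flat_yaml <- function(x, path) {
  fmt <- function(v) {
    if (length(v) > 1L) paste0("[", paste(fmt_scalar(v), collapse = ", "), "]")
    else fmt_scalar(v)
  }
  fmt_scalar <- function(v) {
    ifelse(is.character(v), paste0('"', v, '"'), format(v, scientific = FALSE))
  }
  lines <- vapply(names(x), function(k) paste0(k, ": ", fmt(x[[k]])),
                  character(1))
  writeLines(lines, path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}
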