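# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# 32-bit FNV-1a hash of a character scalar, returned as 8 hex digits.
# Used to stamp pipeline outputs with their generating configuration.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits; keeps h a safe double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619, done in doubles,
    # split into 16-bit halves to stay inside the 2^53 exact-integer range
    h_hi <- h %/% 65536
    h_lo <- h %% 65536
    h <- (((h_hi * 16777619) %% 65536) * 65536 + h_lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stop_if_not_matrix_like <- function(x, name) {
  if (!is.matrix(x)) {
    stop(sprintf("`%s` must be a matrix", name), call. = FALSE)
  }
}

# Coerce a samples/variable table argument to a plain numeric matrix with
# column names preserved.
as_numeric_matrix <- function(x, name = deparse(substitute(x))) {
  if (is.data.frame(x)) {
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix or data frame", name),
         call. = FALSE)
  }
  if (anyNA(x)) {
    stop(sprintf("`%s` contains missing values", name), call. = FALSE)
  }
  x
}
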