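#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix sparseMatrix rowSums colSums crossprod tcrossprod t
#' @importFrom methods as
#' @importFrom stats cov qchisq rpois runif setNames
#' @importFrom utils adist write.table read.delim
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used in printed summary tables.
#' `base::round()` rounds half to even, which disagrees on values such as
#' 0.5 or 26.5.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge guards against decimal values that are stored just below x.5
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# FNV-1a over a character scalar; cheap content fingerprint for provenance.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\x1f")))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256); h itself can exceed 2^31
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # 32-bit modular multiply without exceeding 2^53: split h into 16-bit
    # halves so each partial product stays exact in double precision
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Fingerprint of a vocabulary: sensitive to term order, ids, and hierarchy
# placement (two vocabularies agreeing on all three are column-compatible).
vocab_digest <- function(vocab) {
  fnv1a(c(length(vocab$terms$term_id), vocab$terms$term_id,
          vapply(vocab$terms$tree_paths, paste, "", collapse = ";")))
}

squish <- function(x) gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x))

# Lower-case, strip punctuation, collapse whitespace: the normal form used
# for bibliographic field comparison.
normalize_field <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9 ]+", " ", x)
  squish(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
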