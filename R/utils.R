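#' @keywords internal
"_PACKAGE"

# Fisher z with |r| = 1 guarded: atanh diverges, so perfect correlations are
# capped just inside the open interval and flagged by the caller.
.Z_CAP <- 1 - 1e-15

#' Fisher z-transform of a correlation
#'
#' `atanh(r)`, with `|r| = 1` capped at `1 - 1e-15` so the transform stays
#' finite. Values at the cap should be treated as degenerate by callers.
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @return numeric vector of z values.
#' @export
fisher_z <- function(r) {
  stopifnot(is.numeric(r), all(is.na(r) | abs(r) <= 1))
  atanh(pmin(pmax(r, -.Z_CAP), .Z_CAP))
}

#' Inverse Fisher z-transform
#' @param z numeric vector.
#' @return correlations `tanh(z)`.
#' @export
fisher_z_inv <- function(z) tanh(z)

# Deterministic substream derivation: fold a label into a Lehmer iteration so
# named stages get independent, reproducible child seeds below 2^31.
seed_stream <- function(seed, stream, n = 1L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  lab <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  base <- (abs(as.numeric(seed)) %% 2147483647) + 1
  out <- numeric(n)
  x <- (base * 48271 + lab * 8191) %% 2147483647
  for (i in seq_len(n)) {
    x <- (x * 48271) %% 2147483647
    out[i] <- x
  }
  as.integer(out %% 2147483000)
}

# run expr with a local RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% 2147483000))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
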