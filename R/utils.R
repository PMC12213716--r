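#' @keywords internal
"_PACKAGE"

# Deterministic seed derivation: every stochastic stage hashes the global seed
# together with a stage label (and optional indices) into a 32-bit seed, so
# stages are independently reproducible from the one pipeline seed.
#' Derive a stage seed from a global seed
#'
#' Hashes a global integer seed together with string/numeric qualifiers into a
#' deterministic 32-bit seed. Used so that every stochastic stage of the
#' pipeline (phantom geometry, noise draws, weight init, data shuffling) gets
#' its own reproducible stream from a single top-level seed.
#'
#' @param seed Integer global seed.
#' @param ... Stage qualifiers (strings or numbers).
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), unlist(lapply(list(...), function(p) {
    if (is.character(p)) {
      cp <- utf8ToInt(p)
      sum(cp * seq_along(cp))
    } else {
      as.numeric(p)
    }
  })))
  x <- 104729
  for (p in parts) {
    # keep intermediates < 2^53 so double arithmetic stays exact
    x <- (x * 69069 + (abs(p) %% 2147483647) * 40503 + 12345) %% 2147483647
  }
  as.integer(x)
}

# Evaluate expr with a local RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Separable Gaussian blur with edge replication; fwhm in pixels.
blur_gaussian <- function(img, fwhm_px) {
  if (fwhm_px < 0) stopf("blur FWHM must be non-negative, got %g", fwhm_px)
  if (fwhm_px == 0) return(img)
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], h), v, rep(v[n], h))
    as.numeric(stats::filter(vp, k, sides = 2))[(h + 1):(h + n)]
  }
  out <- apply(img, 2, pad_conv)
  t(apply(out, 1, pad_conv))
}
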