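# internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's random-number state afterwards, so seeded generators
#' do not disturb an enclosing simulation. A `NULL` seed leaves the RNG alone.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive reproducible sub-seeds from a master seed
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of `n` seeds, each below 2^31.
#' @export
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# FNV-1a 32-bit hash of a character scalar; used for config provenance
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; keep h a double to stay within 2^32
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # 32-bit modular multiply by the FNV prime 16777619, split into 16-bit
    # halves so doubles never exceed 2^53
    h0 <- h %% 65536
    h1 <- h %/% 65536
    h <- (h0 * 16777619 + (h1 * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stopf("'%s' must be a single integer >= %d", name, min)
  invisible(as.integer(x))
}

assertProb <- function(x, name, maxExclusive = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x >= maxExclusive)
    stopf("'%s' must be a probability in [0, %s)", name, format(maxExclusive))
  invisible(as.numeric(x))
}

# genotype string helpers (biallelic dialect: alleles coded 0/1, "." missing)

#' Split genotype strings into an allele matrix
#'
#' @param gt Character vector of genotype strings (`"0/1"`, `"1|0"`,
#'   `"./."`).
#' @return 2 x n integer matrix of allele codes, NA for missing.
#' @export
gtAlleles <- function(gt) {
  # returns a 2 x n integer matrix with NA for missing
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) {
    p <- suppressWarnings(as.integer(p))
    if (length(p) != 2L) p <- c(NA_integer_, NA_integer_)
    p
  }, integer(2))
}

#' Heterozygous / missing tests for genotype strings
#'
#' @param gt Character vector of genotype strings.
#' @return Logical vector.
#' @export
isHetGt <- function(gt) {
  al <- gtAlleles(gt)
  !is.na(al[1, ]) & !is.na(al[2, ]) & al[1, ] != al[2, ]
}

#' @rdname isHetGt
#' @export
isMissingGt <- function(gt) {
  al <- gtAlleles(gt)
  is.na(al[1, ]) | is.na(al[2, ])
}
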