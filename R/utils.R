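#' @import methods
#' @importFrom stats rnbinom rpois rlnorm runif aggregate lowess approx
#'   p.adjust pt var cor setNames dnbinom
#' @importFrom utils read.delim write.table packageVersion
NULL

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) .stopf(fmt, ...)
  invisible(TRUE)
}

# locale-independent character sort, used everywhere ordering must be stable
.csort <- function(x) {
  if (!length(x)) return(character(0))
  sort(x, method = "radix")
}

.corder <- function(...) order(..., method = "radix")

#' Stable string hash
#'
#' Deterministic polynomial hash of character vectors, used to derive
#' per-feature random-number substreams so that adding features to a
#' simulation does not reshuffle the draws of existing ones.
#'
#' @param x character vector.
#' @return numeric vector of non-negative integers below 2^31.
#' @keywords internal
stableHash <- function(x) {
  vapply(as.character(x), function(s) {
    h <- 5381
    for (k in utf8ToInt(s)) h <- (h * 33 + k) %% 2147483629
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# evaluate expr under a substream seeded from (seed, id), restoring the
# caller's RNG state afterwards
withSubSeed <- function(seed, id, expr) {
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
  sub <- (as.double(seed) %% 2147483629) * 48271 + stableHash(id)[1L]
  set.seed(as.integer(sub %% 2147483629))
  expr
}

.DNA_BASES <- c("A", "C", "G", "T")

# uppercase, RNA->DNA, validate alphabet
.toDNA <- function(x, what = "sequence") {
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) .stopf("%s contains characters outside {A,C,G,U/T}", what)
  x
}

.revcompDNA <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.compBase <- function(b) chartr("ACGT", "TGCA", b)

# all (overlapping) 0-based start positions of fixed pattern in subject
.findAllFixed <- function(pattern, subject) {
  if (nchar(subject) < nchar(pattern)) return(integer(0))
  m <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m) - 1L
}

.randomDNA <- function(n) {
  paste(sample(.DNA_BASES, n, replace = TRUE), collapse = "")
}
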