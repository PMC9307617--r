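#' @importFrom rlang .data %||%
#' @importFrom stats median rbinom runif setNames cor
#' @importFrom utils head read.delim write.table
NULL

# Seed the RNG for the caller's frame and restore the previous state when the
# caller exits, so seeded package functions do not disturb the session RNG.
local_rng <- function(seed, envir = parent.frame()) {
  if (is.null(seed) || is.na(seed)) stop("a seed is required", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = envir)
  set.seed(as.integer(seed))
  invisible(seed)
}

# Random DNA strings: n sequences of the given width.
random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  mat <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
                nrow = n)
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}
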