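#' @keywords internal
"_PACKAGE"

#' @importFrom stats fisher.test p.adjust phyper rbinom rnbinom runif sd setNames
#' @importFrom utils read.delim write.table head
NULL

# Internal: run `expr` under a local RNG state seeded with `seed`.
# Leaves the caller's RNG untouched; seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Internal: trim whitespace and drop empties; optionally force uppercase.
clean_symbols <- function(x, uppercase = FALSE) {
  x <- trimws(as.character(x))
  x <- x[nzchar(x)]
  if (uppercase) x <- toupper(x)
  x
}

#' @export
`[.ewce_result` <- function(x, ...) { y <- NextMethod(); class(y) <- "data.frame"; y }
#' @export
`[.localization_test` <- function(x, ...) { y <- NextMethod(); class(y) <- "data.frame"; y }
#' @export
`[.enrichment_result` <- function(x, ...) { y <- NextMethod(); class(y) <- "data.frame"; y }

# Internal: empirical permutation p-value, ties inclusive.
# tail "greater": P(random >= observed); "less": P(random <= observed).
# pseudocount adds the observed draw to the pool: (r + 1) / (n + 1).
empirical_p <- function(random, observed, tail = c("greater", "less"),
                        pseudocount = FALSE) {
  tail <- match.arg(tail)
  r <- if (tail == "greater") sum(random >= observed) else sum(random <= observed)
  n <- length(random)
  if (pseudocount) (r + 1) / (n + 1) else r / n
}
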