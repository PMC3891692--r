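#' @keywords internal
"_PACKAGE"

## Modulus for derived RNG seeds: a prime below 2^31 so derived seeds stay
## valid 32-bit integers.
.SEED_MOD <- 2147483629

#' Derive a reproducible child seed from a master seed and a string label
#'
#' Each simulated sample gets its own RNG stream keyed by
#' `(master seed, sample id)`, so adding or reordering replicates does not
#' reshuffle the fragments of the others.
#'
#' @param master Integer master seed.
#' @param label Character label (e.g. a sample id).
#' @return An integer seed in `[1, 2^31)`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- master %% .SEED_MOD
  for (code in utf8ToInt(paste(label, collapse = ":"))) {
    h <- (h * 131 + code) %% .SEED_MOD
  }
  as.integer(h + 1)
}

## Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Count sorted integer positions falling in [start, end) (0-based half-open).
## `pos` must be sorted non-decreasing.
count_in_interval <- function(pos, start, end) {
  findInterval(end - 1L, pos) - findInterval(start - 1L, pos)
}

## Truncated-normal draw by rejection, all arguments scalar except n.
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

## data.frame -> tab-separated file, no quoting; the package's standard
## table dialect.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
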