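# Shortest decimal representation that round-trips to the same double.
# Writers use this so identical objects always produce byte-identical files.
fmtNum <- function(x) {
  s <- sprintf("%.15g", x)
  bad <- is.finite(x) & (as.numeric(s) != x)
  if (any(bad)) s[bad] <- sprintf("%.17g", x[bad])
  nf <- !is.finite(x)
  if (any(nf)) s[nf] <- as.character(x[nf])   # Inf/NaN in R spelling
  s
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Integer chromosome code per bin (1..C in table order).
chromCode <- function(bins) {
  r <- rle(bins@chrom)
  rep.int(seq_along(r$values), r$lengths)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
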