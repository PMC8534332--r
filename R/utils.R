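# internal helpers

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == as.integer(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

# coerce an image array (possibly multi-channel, values in [0,1] or [0,255])
# to a binary 0/1 integer matrix; any value > 0 maps to 1
binarize <- function(img) {
  if (is.array(img) && length(dim(img)) == 3L) {
    img <- apply(img, c(1L, 2L), max)
  }
  if (!is.matrix(img)) stopf("expected a 2-D image, got dimensions [%s]",
                             paste(dim(img), collapse = ", "))
  m <- matrix(as.integer(img > 0), nrow = nrow(img), ncol = ncol(img))
  m
}

# largest run length of TRUE values (0 when none)
max_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}
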