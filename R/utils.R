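#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Reflected (mirror) 1-based indices for out-of-range access.
#' @noRd
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  j <- (idx - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  as.integer(ifelse(j < n, j, period - 1L - j)) + 1L
}

#' @noRd
as_mask <- function(x) {
  m <- as.logical(x)
  dim(m) <- dim(x)
  m
}

#' @noRd
mask_volume_ml <- function(mask, spacing) {
  sum(mask) * prod(spacing) / 1000
}

#' @noRd
check_same_dim <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s have different grids: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

# Linear-interpolation percentile summary used in cohort reports.
#' @noRd
median_iqr <- function(x) {
  q <- quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  c(median = q[1], p25 = q[2], p75 = q[3])
}

#' @noRd
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2)
  unname(tools::md5sum(f))
}
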