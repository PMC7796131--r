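#' Activity levels
#'
#' Canonical ordered set of activity labels used throughout the package.
#' `merged = TRUE` returns the three-class set where running and sprinting
#' share one label.
#'
#' @param merged Logical; return the run/sprint-merged level set.
#' @return Character vector of levels.
#' @export
activity_levels <- function(merged = FALSE) {
  if (merged) c("stand", "walk", "run_sprint") else c("stand", "walk", "run", "sprint")
}

as_activity <- function(x, merged = FALSE) {
  lv <- activity_levels(merged)
  x <- as.character(x)
  bad <- setdiff(unique(x), lv)
  if (length(bad) > 0) {
    abort(paste0("unknown activity label(s): ", paste(bad, collapse = ", ")))
  }
  factor(x, levels = lv)
}

## Counter-based sub-seed derivation: one study seed fans out to independent,
## reproducible per-channel seeds. Arithmetic stays exact in doubles
## (< 2^53) and the result stays below 2^31 - 1.
sub_seed <- function(seed, counter) {
  s <- (as.double(seed) %% 2147483647) * 69069 + as.double(counter) * 2654435761
  as.integer(s %% 2147483629) + 1L
}

## floor() with a relative tolerance so that e.g. (150 - 0.5) / 0.2 counts
## as 747.5 even when binary rounding lands at 747.49999999999989.
floor_tol <- function(x, tol = 1e-9) floor(x + tol)

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number"))
  }
}

## Column-wise sample SDs of a matrix (n - 1 denominator), without forming
## large temporaries per column.
col_sds <- function(m) {
  n <- nrow(m)
  if (n < 2L) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  v <- (colSums(m^2) - n * mu^2) / (n - 1)
  sqrt(pmax(v, 0))
}
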