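#' @noRd
.assert <- function(cond, msg, class = "lyoglass_error") {
  if (!isTRUE(cond)) abort(msg, class = class)
  invisible(TRUE)
}

# Coerce a two-column-ish data frame to a tibble with the given column
# names, tolerating extra columns and positional input.
#' @noRd
.as_xy <- function(data, x, y, caller) {
  .assert(is.data.frame(data), sprintf("`%s` expects a data frame.", caller))
  nms <- names(data)
  if (all(c(x, y) %in% nms)) {
    out <- as_tibble(data)[, unique(c(x, y, setdiff(nms, c(x, y))))]
  } else {
    .assert(ncol(data) >= 2,
            sprintf("`%s` needs columns `%s` and `%s` (or two unnamed columns).",
                    caller, x, y))
    out <- as_tibble(data[, 1:2], .name_repair = "minimal")
    names(out) <- c(x, y)
  }
  .assert(is.numeric(out[[x]]) && is.numeric(out[[y]]),
          sprintf("`%s` and `%s` must be numeric.", x, y))
  out
}

# Grid uniformity check used by every spectrum type.
#' @noRd
.check_uniform <- function(x, rel_tol = 1e-6, what = "axis") {
  d <- diff(x)
  .assert(length(d) >= 1 && all(d > 0),
          sprintf("%s must be strictly increasing.", what))
  .assert(max(d) - min(d) <= rel_tol * stats::median(d),
          sprintf("%s must be uniformly sampled.", what),
          class = "lyoglass_nonuniform")
  stats::median(d)
}

# Run `code` under a fixed seed without touching the caller's RNG state.
# A NULL seed leaves the global stream alone (still advances it).
#' @noRd
.with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' @noRd
.trapz <- function(x, y) pracma::trapz(x, y)

# Tukey (tapered cosine) window: flat centre, half-cosine ramps covering
# `fraction` of the total length.
#' @noRd
.tukey_window <- function(n, fraction) {
  if (fraction <= 0) return(rep(1, n))
  w <- rep(1, n)
  m <- floor(fraction * (n - 1) / 2)
  if (m < 1) return(w)
  i <- seq_len(m)
  ramp <- 0.5 * (1 + cos(pi * ((i - 1) / m - 1)))
  w[i] <- ramp
  w[n - i + 1] <- ramp
  w
}
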