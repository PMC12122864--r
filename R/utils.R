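## Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring RNG state afterwards.
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed %% 2147483647L), code)
}

# Derive a per-stage seed from a top-level one; keeps results independent
# across stages while reproducible from a single integer.
derive_seed <- function(seed, stage) {
  (as.double(seed) * 7919 + stage) %% 2147483647
}

stop_arg <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

is_pos_num <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x > 0
}

# Centered running mean. Windows shrink symmetrically at the edges so the
# filter stays unbiased for linear trends everywhere (an asymmetric edge
# window would lag a drifting signal by up to half a window).
runmean_ <- function(v, w) {
  n <- length(v)
  if (w <= 1 || n <= 1) return(v)
  half <- floor(w / 2)
  i <- seq_len(n)
  h <- pmin(half, i - 1L, n - i)
  cs <- cumsum(c(0, v))
  lo <- i - 1L - h
  hi <- i + h
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

# Freedman-Diaconis histogram mode with ties broken toward the smaller value.
hist_mode_ <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0) stop_arg("cannot take the mode of an empty sample")
  if (length(unique(v)) == 1) return(v[1])
  h <- hist_fd_(v)
  h$mids[which.max(h$counts)]
}

# hist(breaks = "FD") falls over when IQR = 0; fall back to Sturges there.
hist_fd_ <- function(v, min_bins = 1) {
  nb <- tryCatch(grDevices::nclass.FD(v), error = function(e) grDevices::nclass.Sturges(v))
  if (!is.finite(nb) || nb < 1) nb <- grDevices::nclass.Sturges(v)
  nb <- max(nb, min_bins)
  graphics_free_hist_(v, nb)
}

# hist() without plotting, with an explicit suggested bin count.
graphics_free_hist_ <- function(v, nbins) {
  graphics::hist(v, breaks = nbins, plot = FALSE)
}

# Format numerics so a CSV round trip is value-exact for doubles.
format_full_ <- function(x) {
  if (is.double(x)) format(x, digits = 17, trim = TRUE, scientific = NA) else as.character(x)
}
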