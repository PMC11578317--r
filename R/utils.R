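# Internal helpers shared across modules.

# Stop with a classed error so callers/tests can distinguish failure modes.
ppg_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "ppgglucose_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

# Validate a single positive finite scalar, naming the offending field.
check_positive_scalar <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    ppg_stop(sprintf("field '%s' must be a positive finite number", field),
             "ppg_validation_error")
  invisible(x)
}

check_scalar <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ppg_stop(sprintf("field '%s' must be a finite number", field),
             "ppg_validation_error")
  invisible(x)
}

# Interior local minima / maxima. Plateau-tolerant: a point qualifies when
# one side strictly changes and the other is flat or changing the same way,
# so sample-exact ties (e.g. an extremum falling mid-sample) are not missed.
local_minima <- function(x) {
  d <- diff(x)
  dl <- d[-length(d)]; dr <- d[-1]
  which((dl < 0 & dr >= 0) | (dl <= 0 & dr > 0)) + 1L
}

local_maxima <- function(x) {
  d <- diff(x)
  dl <- d[-length(d)]; dr <- d[-1]
  which((dl > 0 & dr <= 0) | (dl >= 0 & dr < 0)) + 1L
}

# Centered moving average with odd window, edges padded by replication.
moving_average <- function(x, width) {
  width <- max(3L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  half <- (width - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2L))[
    (half + 1L):(half + length(x))]
}

# Adjacent-valley prominence of local maxima: drop from the peak to the
# higher of the lowest points separating it from its neighbouring peaks
# (or the vector ends).
peak_prominences <- function(x, peaks) {
  anchors <- sort(unique(c(1L, peaks, length(x))))
  vapply(peaks, function(i) {
    k <- match(i, anchors)
    left <- min(x[anchors[k - 1L]:i])
    right <- min(x[i:anchors[k + 1L]])
    x[i] - max(left, right)
  }, 0.0)
}

# Deterministic integer sub-seeds derived from one parent seed.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}

# Canonical JSON writer: bare numbers, full precision, stable key order.
write_json_canonical <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

# md5 of an object's canonical JSON form (used to stamp artifacts).
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  cat(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null"),
      file = tf)
  unname(tools::md5sum(tf))
}
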