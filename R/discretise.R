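#' Discretise a single column of continuous measurements
#'
#' Maps real-valued observations to integer states `0..k-1`. Missing values
#' are preserved and all statistics (means, medians, quantiles) are
#' computed over the non-missing values only. Methods:
#' \describe{
#'   \item{ceil, floor, round}{nearest-integer maps; the distinct produced
#'     integers are then re-indexed in ascending order to the dense range
#'     `0..k-1` (CPTs need dense state indices). `round` rounds half to
#'     even, as base R does.}
#'   \item{arithmetic_mean, harmonic_mean, median, fixed_threshold}{binary:
#'     state 1 iff the value is strictly greater than the statistic (or the
#'     supplied `threshold`); ties at the cut go to state 0.}
#'   \item{z_score}{binary: state 1 iff the z-transformed value is strictly
#'     positive (equivalently, value > arithmetic mean).}
#'   \item{bracket_medians}{`buckets` equal-probability classes cut at the
#'     `i/k` empirical quantiles (type-1, inverted CDF); ties at a cut go
#'     to the lower bracket.}
#'   \item{pearson_tukey}{three classes cut at the 0.185 and 0.815
#'     empirical quantiles, the classical 0.185/0.63/0.185 three-point
#'     mass split.}
#'   \item{none}{asserts the column already holds nonnegative integer
#'     states and passes it through.}
#' }
#' Every method is monotone: `x <= y` implies `state(x) <= state(y)`.
#'
#' @param values numeric vector, `NA` for missing; at least one value must
#'   be non-missing.
#' @param method one of the method names above.
#' @param threshold cut point for `fixed_threshold`.
#' @param buckets class count (>= 2) for `bracket_medians`.
#' @return list with `states` (integer vector, `NA` preserved) and
#'   `nstates` (the state count `k`).
#' @examples
#' discretise_column(c(1, 2, 3, 4), "median")           # 0 0 1 1
#' discretise_column(1:9, "bracket_medians", buckets = 3)
#' @export
discretise_column <- function(values, method, threshold = NULL,
                              buckets = NULL) {
  method <- match.arg(method, DISC_METHODS)
  obs <- values[!is.na(values)]
  if (!length(obs)) stop("all values are missing")
  states <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  binary_cut <- function(cut) {
    states[ok] <<- as.integer(values[ok] > cut)
    2L
  }
  quantile_cut <- function(ps) {
    cuts <- quantile_type1(obs, ps)
    st <- integer(sum(ok))
    for (cut in cuts) st <- st + as.integer(values[ok] > cut)
    states[ok] <<- st
    length(ps) + 1L
  }
  k <- switch(method,
    ceil = , floor = , round = {
      f <- switch(method, ceil = ceiling, floor = floor, round = round)
      ints <- f(values[ok])
      lev <- sort(unique(ints))
      states[ok] <- match(ints, lev) - 1L
      length(lev)
    },
    arithmetic_mean = binary_cut(mean(obs)),
    harmonic_mean = {
      if (any(obs <= 0)) {
        stop("harmonic mean requires strictly positive values")
      }
      binary_cut(length(obs) / sum(1 / obs))
    },
    median = binary_cut(stats::median(obs)),
    z_score = {
      s <- stats::sd(obs)
      if (is.na(s) || s == 0) stop("z_score: standard deviation is zero")
      binary_cut(mean(obs))  # z > 0  <=>  value > mean
    },
    fixed_threshold = {
      if (is.null(threshold)) stop("fixed_threshold requires a threshold")
      binary_cut(threshold)
    },
    bracket_medians = {
      if (is.null(buckets) || buckets < 2) {
        stop("bracket_medians requires buckets >= 2")
      }
      quantile_cut(seq_len(buckets - 1L) / buckets)
    },
    pearson_tukey = quantile_cut(c(0.185, 0.815)),
    none = {
      if (any(obs < 0 | obs != floor(obs))) {
        stop("method 'none' requires nonnegative integer states")
      }
      states[ok] <- as.integer(values[ok])
      max(2L, max(states, na.rm = TRUE) + 1L)
    })
  list(states = states, nstates = as.integer(k))
}

# type-1 (inverted CDF) empirical quantile: smallest order statistic whose
# CDF reaches p
quantile_type1 <- function(x, ps) {
  unname(stats::quantile(x, probs = ps, type = 1, names = FALSE))
}

#' Discretise an observation matrix
#'
#' Applies [discretise_column()] to every variable (row) according to the
#' specification; variables without an explicit entry use the spec's
#' default.
#'
#' @param raw numeric matrix, variables x samples, `NA` missing.
#' @param spec a `cbn_disc_spec` from [read_discretisation_spec()], or a
#'   single method name applied to every variable, optionally with
#'   `threshold`/`buckets` via `...`.
#' @param ... parameters for a single-method `spec`.
#' @return integer matrix of the same shape with attribute `nstates`, a
#'   named integer vector of per-variable state counts.
#' @export
discretise_matrix <- function(raw, spec, ...) {
  stopifnot(is.matrix(raw), !is.null(rownames(raw)))
  if (is.character(spec) && length(spec) == 1L) {
    spec <- structure(list(default = check_disc_entry(
      c(list(method = spec), list(...)), "the default entry"),
      variables = list()), class = "cbn_disc_spec")
  }
  stopifnot(inherits(spec, "cbn_disc_spec"))
  out <- matrix(NA_integer_, nrow = nrow(raw), ncol = ncol(raw),
                dimnames = dimnames(raw))
  ns <- stats::setNames(integer(nrow(raw)), rownames(raw))
  for (v in rownames(raw)) {
    e <- spec$variables[[v]]
    if (is.null(e)) e <- spec$default
    if (is.null(e)) {
      stop("no discretisation method for variable ", v, " and no default")
    }
    d <- discretise_column(raw[v, ], e$method, threshold = e$threshold,
                           buckets = e$buckets)
    out[v, ] <- d$states
    ns[[v]] <- d$nstates
  }
  attr(out, "nstates") <- ns
  out
}
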