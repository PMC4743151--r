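#' Factors over joint discrete states
#'
#' A factor is a nonnegative table over the joint states of an ordered list
#' of variables — the workhorse object of variable elimination. CPTs are
#' factors, evidence reduces factors, and inference alternates products and
#' marginalisations. Values are stored in column-major order: the first
#' scope variable varies fastest.
#'
#' @param scope character vector of variable names (may be empty for a
#'   scalar factor).
#' @param card integer vector of state counts, parallel to `scope`.
#' @param values numeric vector of length `prod(card)`, all `>= 0`.
#' @return an object of class `cbn_factor`.
#' @export
cbn_factor <- function(scope, card, values) {
  scope <- as.character(scope)
  card <- as.integer(card)
  if (length(scope) != length(card)) stop("scope and card lengths differ")
  if (anyDuplicated(scope)) stop("duplicate variable in scope")
  if (length(values) != prod(card)) {
    stop("values length ", length(values), " != prod(card) ", prod(card))
  }
  if (any(values < 0)) stop("factor values must be nonnegative")
  structure(list(scope = scope, card = stats::setNames(card, scope),
                 values = as.numeric(values)),
            class = "cbn_factor")
}

#' @export
print.cbn_factor <- function(x, ...) {
  cat("Factor over {", paste(x$scope, collapse = ", "), "}: ",
      length(x$values), " cells, mass ", format(sum(x$values)), "\n", sep = "")
  invisible(x)
}

# factor holding a node's CPT; scope = (child, parents)
cpt_factor <- function(net, node) {
  cpt <- net$cpts[[node]]
  vars <- names(dimnames(cpt))
  cbn_factor(vars, unname(nstates(net, vars)), as.vector(cpt))
}

# state index (0-based) of variable `pos` for every cell of a factor with
# cardinalities `card`; column-major
cell_states <- function(card, pos) {
  n <- prod(card)
  stride <- if (pos == 1L) 1L else prod(card[seq_len(pos - 1L)])
  (seq_len(n) - 1L) %/% stride %% card[pos]
}

#' Factor product
#'
#' Pointwise product over the union scope: the result's scope is `f`'s
#' scope followed by `g`'s new variables, and each cell is the product of
#' the two matching cells.
#'
#' @param f,g factors; shared variables must agree in cardinality.
#' @return a `cbn_factor` over the union scope.
#' @export
factor_product <- function(f, g) {
  stopifnot(inherits(f, "cbn_factor"), inherits(g, "cbn_factor"))
  shared <- intersect(f$scope, g$scope)
  if (any(f$card[shared] != g$card[shared])) {
    stop("cardinality mismatch on shared variable(s): ",
         paste(shared[f$card[shared] != g$card[shared]], collapse = ", "))
  }
  scope <- c(f$scope, setdiff(g$scope, f$scope))
  card <- c(f$card, g$card[setdiff(g$scope, f$scope)])
  n <- prod(card)
  if (n == 0) stop("empty factor")
  idx_f <- rep(1, n); idx_g <- rep(1, n)
  for (j in seq_along(scope)) {
    s <- cell_states(card, j)
    pf <- match(scope[j], f$scope)
    if (!is.na(pf)) {
      stride <- if (pf == 1L) 1 else prod(f$card[seq_len(pf - 1L)])
      idx_f <- idx_f + s * stride
    }
    pg <- match(scope[j], g$scope)
    if (!is.na(pg)) {
      stride <- if (pg == 1L) 1 else prod(g$card[seq_len(pg - 1L)])
      idx_g <- idx_g + s * stride
    }
  }
  cbn_factor(scope, card, f$values[idx_f] * g$values[idx_g])
}

#' Marginalise a variable out of a factor
#'
#' Removes `v` from the scope by summing over its states; total mass is
#' conserved.
#'
#' @param f a factor.
#' @param v a variable in `f`'s scope.
#' @return a `cbn_factor` over the remaining scope (a scalar factor if `v`
#'   was the only variable).
#' @export
factor_marginalize <- function(f, v) {
  stopifnot(inherits(f, "cbn_factor"))
  pos <- match(v, f$scope)
  if (is.na(pos)) stop("variable ", v, " not in factor scope")
  if (length(f$scope) == 1L) {
    return(cbn_factor(character(0), integer(0), sum(f$values)))
  }
  a <- array(f$values, dim = f$card)
  keep <- seq_along(f$scope)[-pos]
  vals <- apply(a, keep, sum)
  cbn_factor(f$scope[keep], f$card[keep], as.vector(vals))
}

#' Reduce a factor by evidence
#'
#' Zeroes every cell inconsistent with the evidence; the scope is retained
#' and no renormalisation is performed. Evidence on variables outside the
#' scope is ignored.
#'
#' @param f a factor.
#' @param evidence named list or named integer vector of 0-based states.
#' @return the reduced `cbn_factor`.
#' @export
factor_reduce <- function(f, evidence) {
  stopifnot(inherits(f, "cbn_factor"))
  evidence <- unlist(evidence)
  vals <- f$values
  for (v in intersect(names(evidence), f$scope)) {
    pos <- match(v, f$scope)
    s <- as.integer(evidence[[v]])
    if (s < 0L || s >= f$card[pos]) {
      stop("evidence state ", s, " out of range for ", v)
    }
    vals[cell_states(f$card, pos) != s] <- 0
  }
  cbn_factor(f$scope, unname(f$card), vals)
}
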