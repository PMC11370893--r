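#' Exact test for a 2x2 contingency table
#'
#' Computes the two-sided Fisher exact p-value and the conditional
#' maximum-likelihood estimate (CMLE) of the odds ratio for a 2x2 table with
#' cells
#' \preformatted{   a  b
#'    c  d}
#' where rows are the exposure (e.g. disease-enriched vs disease-depleted)
#' and columns the property (e.g. bacteremia yes vs no).
#'
#' Conditional on both margins, the first cell follows a noncentral
#' hypergeometric distribution with noncentrality equal to the odds ratio
#' \eqn{\psi}. The CMLE solves \eqn{E_\psi[A] = a} and is found by a
#' monotone root search on \eqn{\log\psi} (relative tolerance about 1e-8).
#' The two-sided p-value sums the central hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed that of
#' the observed table (within relative tolerance 1e-7). Boundary tables, where
#' `a` sits at an end of its conditional support, return an odds ratio of 0 or
#' `Inf` with `boundary = TRUE`.
#'
#' @param a,b,c,d Non-negative integer cell counts; at least one margin must
#'   be positive.
#' @return An object of class `fisher2x2`: a list with elements `cells`
#'   (named integer vector), `odds_ratio` (CMLE, in \[0, Inf\]), `p_value`
#'   (two-sided exact, in (0, 1\]), and `boundary` (logical). [tidy()] and
#'   [glance()] methods return one-row tibbles.
#' @examples
#' fisher_exact_2x2(105, 58, 16, 82) # odds ratio rounds to 9.2
#' fisher_exact_2x2(2, 0, 0, 2)      # p = 1/3, odds ratio Inf (boundary)
#' @seealso [fisher_p_enumeration()] for an independent brute-force p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  # `c` is a cell count here, so base::c must be called explicitly
  cells <- base::c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("all four cells are zero", call. = FALSE)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)

  # two-sided p: mass of tables no more probable than the observed one
  support <- lo:hi
  dens <- stats::dhyper(support, c1, c2, r1)
  p_obs <- stats::dhyper(a, c1, c2, r1)
  p_value <- min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))

  if (lo == hi) {
    # degenerate support: odds ratio not identifiable from the margins
    or <- NA_real_
    boundary <- TRUE
  } else if (a == lo) {
    or <- 0
    boundary <- TRUE
  } else if (a == hi) {
    or <- Inf
    boundary <- TRUE
  } else {
    or <- exp(.cmle_log_psi(a, r1, r2, c1))
    boundary <- FALSE
  }

  structure(
    list(cells = cells, odds_ratio = or, p_value = p_value,
         boundary = boundary),
    class = "fisher2x2"
  )
}

# conditional mean of the first cell under noncentral hypergeometric(e^t),
# computed with log-space weights for stability
.nchg_mean <- function(t, support, lw0) {
  lw <- lw0 + support * t
  w <- exp(lw - max(lw))
  sum(support * w) / sum(w)
}

# root of E_psi[A] - a on the log-psi scale; E is strictly increasing in t
.cmle_log_psi <- function(a, r1, r2, c1) {
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  lw0 <- lchoose(r1, support) + lchoose(r2, c1 - support)
  f <- function(t) .nchg_mean(t, support, lw0) - a
  lim <- 50
  while (f(-lim) > 0 || f(lim) < 0) lim <- lim * 2 # a is interior, so bounded
  stats::uniroot(f, c(-lim, lim), tol = 1e-10)$root
}

#' Brute-force two-sided exact p-value for a 2x2 table
#'
#' Reference implementation used as an independent oracle in the test suite:
#' enumerates the full conditional support of the first cell with explicit
#' log-factorial arithmetic (no distribution functions) and sums the
#' probabilities of all tables no more probable than the observed one.
#'
#' @inheritParams fisher_exact_2x2
#' @param max_n Guard on the table total (enumeration is for small tables).
#' @return The two-sided exact p-value.
#' @examples
#' fisher_p_enumeration(2, 0, 0, 2) # 1/3
#' @export
fisher_p_enumeration <- function(a, b, c, d, max_n = 1000) {
  n <- a + b + c + d
  if (n == 0) stop("all four cells are zero", call. = FALSE)
  if (n > max_n) stop("table total exceeds enumeration cap", call. = FALSE)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  lf <- lgamma(seq_len(n + 1)) # lf[k+1] = log(k!)
  lp <- function(x) {
    lf[r1 + 1] + lf[r2 + 1] + lf[c1 + 1] + lf[c2 + 1] - lf[n + 1] -
      lf[x + 1] - lf[r1 - x + 1] - lf[c1 - x + 1] - lf[r2 - c1 + x + 1]
  }
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- exp(lp(support))
  p_obs <- exp(lp(a))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]) / sum(probs))
}

#' @export
print.fisher2x2 <- function(x, ...) {
  cat("Fisher exact test (2x2)\n")
  cat(sprintf("  cells: a=%d b=%d c=%d d=%d\n",
              x$cells["a"], x$cells["b"], x$cells["c"], x$cells["d"]))
  cat(sprintf("  conditional-MLE odds ratio: %s%s\n",
              format(x$odds_ratio, digits = 4),
              if (x$boundary) " (boundary)" else ""))
  cat(sprintf("  two-sided p-value: %s\n", format(x$p_value, digits = 3)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fisher_exact_2x2
#' @param x A `fisher2x2` object.
#' @param ... Unused.
#' @method tidy fisher2x2
#' @export
tidy.fisher2x2 <- function(x, ...) {
  tibble(
    estimate = x$odds_ratio,
    p.value = x$p_value,
    a = unname(x$cells["a"]), b = unname(x$cells["b"]),
    c = unname(x$cells["c"]), d = unname(x$cells["d"]),
    boundary = x$boundary,
    method = "Fisher exact (conditional MLE)"
  )
}

#' @rdname fisher_exact_2x2
#' @method glance fisher2x2
#' @export
glance.fisher2x2 <- function(x, ...) {
  tibble(
    estimate = x$odds_ratio,
    p.value = x$p_value,
    n = sum(x$cells),
    boundary = x$boundary
  )
}
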