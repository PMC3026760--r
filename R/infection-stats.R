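#' Proportions of worms with at least k infection symptoms
#'
#' Scores cohorts on the four morphological infection symptoms of intestinal
#' cells (gut-granule loss, nuclear degeneration, cytoplasm liquefaction,
#' cell fusion) and returns, per condition, the proportion of animals showing
#' at least k symptoms for k = 1..4. These proportions are non-increasing in
#' k by construction. Also emits the 2x2 table (>=1 symptom vs none, by
#' condition) ready for [fisherExactTwoSided()] when exactly two conditions
#' are present.
#'
#' @param records data.frame with a `condition` column and four logical (or
#'   0/1) symptom columns.
#' @param symptomCols names of the symptom columns; defaults to every column
#'   except `condition`.
#' @return list with `proportions` (condition x k matrix) and `table2x2`
#'   (matrix, or NULL unless exactly 2 conditions).
#' @export
symptomProportions <- function(records, symptomCols = NULL) {
  if (!"condition" %in% names(records)) stop("records need a condition column")
  if (nrow(records) == 0L) stop("no records")
  if (is.null(symptomCols)) symptomCols <- setdiff(names(records), "condition")
  if (length(symptomCols) == 0L) stop("no symptom columns")
  conds <- unique(records$condition)
  flags <- as.matrix(records[, symptomCols, drop = FALSE]) != 0
  nsym <- rowSums(flags)
  ks <- seq_len(length(symptomCols))
  prop <- t(vapply(conds, function(cc) {
    s <- nsym[records$condition == cc]
    if (length(s) == 0L) stop("condition '", cc, "' has no records")
    vapply(ks, function(k) mean(s >= k), 0)
  }, numeric(length(ks))))
  dimnames(prop) <- list(conds, paste0("k", ks))
  tab <- NULL
  if (length(conds) == 2L) {
    a <- sum(nsym >= 1L & records$condition == conds[1L])
    b <- sum(nsym == 0L & records$condition == conds[1L])
    c <- sum(nsym >= 1L & records$condition == conds[2L])
    d <- sum(nsym == 0L & records$condition == conds[2L])
    tab <- matrix(c(a, c, b, d), 2L,
                  dimnames = list(conds, c("symptomatic", "asymptomatic")))
  }
  list(proportions = prop, table2x2 = tab)
}

## hypergeometric pmf over the support of a 2x2 table with fixed margins;
## exact choose() arithmetic for small tables, log-gamma otherwise
.hyperPmf <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c; N <- m + n
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  if (N <= 170L) {
    p <- choose(m, x) * choose(n, k - x) / choose(N, k)
  } else {
    lp <- lgamma(m + 1) - lgamma(x + 1) - lgamma(m - x + 1) +
      lgamma(n + 1) - lgamma(k - x + 1) - lgamma(n - k + x + 1) -
      (lgamma(N + 1) - lgamma(k + 1) - lgamma(N - k + 1))
    p <- exp(lp)
  }
  list(x = x, p = p)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test with the standard two-sided rule: the p-value is
#' the sum of the hypergeometric probabilities, over all tables with the
#' observed margins, of every table whose probability does not exceed that of
#' the observed table (within a relative tolerance of 1e-7 to absorb
#' floating-point ties). Probabilities use exact binomial-coefficient
#' arithmetic for totals up to 170 and log-gamma accumulation above.
#'
#' @param tab 2x2 matrix `rbind(c(a, b), c(c, d))` (rows = conditions,
#'   columns = symptomatic/asymptomatic), or a length-4 vector `c(a, b, c,
#'   d)`.
#' @return p-value in (0, 1].
#' @examples
#' fisherExactTwoSided(rbind(c(5, 5), c(5, 5)))    # 1
#' fisherExactTwoSided(rbind(c(10, 0), c(0, 10)))  # 2/184756
#' @export
fisherExactTwoSided <- function(tab) {
  if (is.matrix(tab)) tab <- c(t(tab))
  if (length(tab) != 4L) stop("expected a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers")
  if (sum(tab) < 1L) stop("table total must be >= 1")
  a <- tab[1L]; b <- tab[2L]; c <- tab[3L]; d <- tab[4L]
  h <- .hyperPmf(a, b, c, d)
  pObs <- h$p[match(a, h$x)]
  min(1, sum(h$p[h$p <= pObs * (1 + 1e-7)]))
}
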