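#' Regression of eyespot ring complexity on gene-network complexity
#'
#' Ordinary least squares of the maximum number of colored rings in a
#' species' eyespots (`n_rings`) on the number of eyespot-associated genes
#' with focal expression (`n_genes`), with the overall F-test on
#' (1, n - 2) degrees of freedom. Deliberately plain regression — the
#' question is whether species expressing more genes build more elaborate
#' eyespots.
#'
#' @param records data frame with columns `n_genes` and `n_rings`
#'   (optionally `species`); at least 3 rows with variance in `n_genes`.
#' @return a `complexity_fit`: list with `slope`, `intercept`,
#'   `F_statistic`, `df` (length 2), `p_value`, `r_squared`, `n`, and the
#'   underlying `lm` fit.
#' @examples
#' rec <- data.frame(n_genes = c(2, 3, 3, 4, 5, 5, 6),
#'                   n_rings = c(2, 1, 3, 2, 3, 2, 3))
#' complexity_regression(rec)
#' @export
complexity_regression <- function(records) {
  need <- c("n_genes", "n_rings")
  if (!all(need %in% names(records)))
    stopf("records need columns: %s", paste(need, collapse = ", "))
  if (any(records$n_genes < 0 | records$n_rings < 0)) stopf("counts must be >= 0")
  n <- nrow(records)
  if (n < 3L) stopf("need at least 3 records")
  if (stats::var(records$n_genes) == 0)
    stopf("no variance in the predictor (n_genes)")
  fit <- stats::lm(n_rings ~ n_genes, data = records)
  # collinear records make the F-test degenerate; reported as R^2 = 1 with
  # an unbounded F rather than a warning storm
  an <- suppressWarnings(stats::anova(fit))
  Fval <- an[["F value"]][1L]
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    F_statistic = Fval,
    df = c(1L, n - 2L),
    p_value = an[["Pr(>F)"]][1L],
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n = n,
    lm_fit = fit
  ), class = "complexity_fit")
}

#' @export
print.complexity_fit <- function(x, ...) {
  cat("Network complexity vs eyespot ring complexity (OLS)\n")
  cat(sprintf("  slope = %.4g rings per gene, R^2 = %.3f\n",
              x$slope, x$r_squared))
  if (is.finite(x$F_statistic)) {
    cat(sprintf("  F(%d,%d) = %.3g, p = %.3g\n",
                x$df[1L], x$df[2L], x$F_statistic, x$p_value))
  } else {
    cat(sprintf("  perfect fit (R^2 = 1); F(%d,%d) unbounded\n",
                x$df[1L], x$df[2L]))
  }
  invisible(x)
}

#' Read complexity records from delimited text
#'
#' Expected columns: `species`, `n_genes`, `n_rings`.
#' @param file path to tab- or comma-separated text with a header.
#' @export
read_complexity_records <- function(file) {
  if (!file.exists(file)) stopf("complexity file not found: %s", file)
  first <- readLines(file, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(file, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  if (!all(c("n_genes", "n_rings") %in% names(d)))
    stopf("complexity file needs columns n_genes, n_rings")
  d
}
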