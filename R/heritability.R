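# Broad-sense heritability from strain replicates.

#' Broad-sense heritability from strain replicates
#'
#' For a fully inbred RI panel the genetic variance is estimated as the
#' variance of strain means (`V_A`), the environmental variance as
#' `V_E = V_T - V_A` with `V_T` the total variance among all subjects, and
#' broad-sense heritability as
#' `H2 = 0.5 V_A / (0.5 V_A + V_E) = V_A / (V_A + 2 V_E)`.
#' The factor 2 reflects that an inbred panel carries twice the additive
#' variance of a randomly mating population.
#'
#' Both variances use the unbiased (n - 1) estimator.  A negative `V_E`
#' (a sampling artifact when `V_A > V_T`) is clamped to 0 before the
#' formula; the raw value is reported so the clamp is auditable.  Strain
#' means are unweighted under unbalanced replication.
#'
#' @param replicate_values Replicate data for one trait: either a named
#'   list (strain -> numeric vector of replicate values) or a data frame
#'   with columns `strain` and `value`.
#' @return A list of class `variance_components` with `va`, `vt`, `ve`
#'   (raw, possibly negative), `h2` (in `[0, 1]`), `n_strains` and
#'   `n_subjects`.
#' @examples
#' broad_sense_h2(list(a = c(1, 1), b = c(3, 3)))  # V_E = 0 -> H2 = 1
#' @export
broad_sense_h2 <- function(replicate_values) {
  if (is.data.frame(replicate_values)) {
    stopifnot(all(c("strain", "value") %in% names(replicate_values)))
    replicate_values <- split(replicate_values$value,
                              replicate_values$strain)
  }
  vals <- lapply(replicate_values, function(v) v[!is.na(v)])
  vals <- vals[lengths(vals) > 0L]
  if (length(vals) < 2L)
    stop("heritability needs replicate values for at least 2 strains")
  if (!any(lengths(vals) >= 2L))
    stop("heritability needs at least one strain with >= 2 replicates")
  means <- vapply(vals, mean, numeric(1L))
  all_values <- unlist(vals, use.names = FALSE)
  va <- stats::var(means)
  vt <- stats::var(all_values)
  ve <- vt - va
  h2 <- if (va <= 0) 0 else va / (va + 2 * max(ve, 0))
  h2 <- min(max(h2, 0), 1)
  structure(list(va = va, vt = vt, ve = ve, h2 = h2,
                 n_strains = length(vals),
                 n_subjects = length(all_values)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("V_A = %.4g  V_T = %.4g  V_E = %.4g  H2 = %.3f (%d strains, %d subjects)\n",
              x$va, x$vt, x$ve, x$h2, x$n_strains, x$n_subjects))
  invisible(x)
}

#' Heritability of every probe in a replicate-level expression matrix
#'
#' @param expr An [expr_matrix()] with replicate-level data.
#' @return Data frame with one row per probe: `probe`, `va`, `ve`, `vt`,
#'   `h2`.
#' @export
h2_scan <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (is.null(expr$replicates))
    stop("expression matrix has no replicate-level values")
  vals <- expr$replicates$values
  strain <- expr$replicates$strain
  out <- lapply(seq_len(nrow(vals)), function(i) {
    vc <- broad_sense_h2(split(vals[i, ], strain))
    data.frame(probe = rownames(vals)[i], va = vc$va, ve = vc$ve,
               vt = vc$vt, h2 = vc$h2)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
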