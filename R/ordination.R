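#' Correspondence analysis of a nonnegative table
#'
#' Classical CA: with `P` the table divided by its grand total, row and
#' column masses `r` and `c`, the standardized residuals
#' `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` are decomposed by SVD.
#' Principal inertias are the squared singular values, principal
#' coordinates the mass-scaled singular vectors, and the total inertia
#' equals the Pearson chi-square statistic of the table divided by its
#' grand total.  All-zero rows and columns are dropped with a warning.
#' Axis signs are not identifiable and may differ between platforms.
#'
#' @param m nonnegative numeric matrix (e.g. samples x genes mean FPKM).
#' @param n_axes number of axes to retain (default: all informative).
#' @return A list of class `ca_result`: `principal_inertias`,
#'   `explained_fraction`, `total_inertia`, `row_coords`, `col_coords`.
#' @export
correspondence_analysis <- function(m, n_axes = NULL) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("correspondence analysis requires nonnegative input")
  gt <- sum(m)
  if (gt <= 0) stop("zero grand total")
  zr <- rowSums(m) == 0; zc <- colSums(m) == 0
  if (any(zr) || any(zc)) {
    warning(sprintf("dropping %d all-zero row(s) and %d all-zero column(s)",
                    sum(zr), sum(zc)))
    m <- m[!zr, !zc, drop = FALSE]
  }
  P <- m / gt
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  maxdim <- min(nrow(m), ncol(m)) - 1L
  d <- sv$d[seq_len(maxdim)]
  d[d < 1e-12] <- 0
  inertia <- d^2
  total <- sum(inertia)
  keep <- if (is.null(n_axes)) seq_len(maxdim) else
    seq_len(min(n_axes, maxdim))
  rowc <- diag(1 / sqrt(r)) %*% sv$u[, keep, drop = FALSE] %*%
    diag(d[keep], nrow = length(keep))
  colc <- diag(1 / sqrt(cc)) %*% sv$v[, keep, drop = FALSE] %*%
    diag(d[keep], nrow = length(keep))
  dimnames(rowc) <- list(rownames(m), paste0("Dim", keep))
  dimnames(colc) <- list(colnames(m), paste0("Dim", keep))
  structure(list(
    principal_inertias = inertia,
    explained_fraction = if (total > 0) inertia / total else inertia * 0,
    total_inertia = total,
    row_coords = rowc, col_coords = colc), class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  k <- min(5L, length(x$principal_inertias))
  cat(sprintf("<ca_result> total inertia %.6g; leading axes: %s\n",
              x$total_inertia,
              paste(sprintf("%.1f%%", 100 * x$explained_fraction[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Relative expression by the double-delta Ct method
#'
#' `ddCt = (Ct_target_test - Ct_hk_test) - (Ct_target_ctrl -
#' Ct_hk_ctrl)`; the relative expression of the target in the test
#' condition versus the control, normalized to the housekeeping gene, is
#' `2^(-ddCt)`.
#'
#' @param ct_target_test,ct_hk_test Ct of target and housekeeping gene in
#'   the test condition.
#' @param ct_target_ctrl,ct_hk_ctrl same in the control condition.
#' @return Fold ratio `2^(-ddCt)`.
#' @export
ddct_relative_expression <- function(ct_target_test, ct_hk_test,
                                     ct_target_ctrl, ct_hk_ctrl) {
  stopifnot(is.finite(ct_target_test), is.finite(ct_hk_test),
            is.finite(ct_target_ctrl), is.finite(ct_hk_ctrl))
  ddct <- (ct_target_test - ct_hk_test) - (ct_target_ctrl - ct_hk_ctrl)
  2^(-ddct)
}
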