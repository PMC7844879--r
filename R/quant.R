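#' Build the uncommitted segment-to-CRL mapping matrix Y
#'
#' `y[s, c] = 1` iff some candidate locus of read segment `s` is a member
#' of CRL `c`. A segment hitting several loci of *one* CRL contributes a
#' single 1 — within its CRL it counts as uniquely mapped. Each segment of
#' a chimeric read is its own row (a chimeric read counts as 2 reads, one
#' per arm, during quantification; a singleton counts as 1).
#'
#' @param alignments Alignment tibble carrying `segment_id` and `locus_id`.
#' @param crls CRL tibble from [build_crls()].
#' @return A list of class `mapping_matrices`: `Y` (sparse binary
#'   dgCMatrix, segments x CRLs, dimnames set), `segments`, `crls`
#'   (the ordered id vectors).
#' @export
build_y <- function(alignments, crls) {
  locus2crl <- tibble(
    crl_id = rep(crls$crl_id, lengths(crls$member_loci)),
    locus_id = unlist(crls$member_loci)
  )
  hits <- alignments |>
    distinct(.data$segment_id, .data$locus_id) |>
    left_join(locus2crl, by = "locus_id")
  if (anyNA(hits$crl_id)) {
    abort(paste0("segment candidate locus not in any CRL (pipeline bug): ",
                 paste(head(unique(hits$locus_id[is.na(hits$crl_id)])),
                       collapse = ", ")))
  }
  hits <- distinct(hits, .data$segment_id, .data$crl_id)
  segs <- sort(unique(hits$segment_id))
  cids <- crls$crl_id
  Y <- Matrix::sparseMatrix(
    i = match(hits$segment_id, segs),
    j = match(hits$crl_id, cids),
    x = 1,
    dims = c(length(segs), length(cids)),
    dimnames = list(segs, cids)
  )
  structure(list(Y = Y, segments = segs, crls = cids),
            class = "mapping_matrices")
}

#' EM quantification of CRL abundances
#'
#' Estimates the abundance `rho[c] = Pr[segment from CRL c]` maximising the
#' observed-data likelihood `L(rho) = prod_s sum_c y[s,c] rho[c]` by
#' expectation-maximization:
#'
#' * E-step: `post[s,c] = rho[c] / sum_{c'} y[s,c'] rho[c']` on the support
#'   of row `s` — the expected committed assignment `E[z_{s,c}]`;
#' * M-step: `rho[c] = sum_s post[s,c] / N` — the maximum-likelihood
#'   estimate given the expected assignments.
#'
#' Iteration stops when the L1 change `sum_c |rho[c]^(t+1) - rho[c]^(t)|`
#' drops to `epsilon` or below. `rho` starts uniform at `1/K`. The
#' log-likelihood is non-decreasing across iterations; the trace is kept so
#' tests can assert it. Convergence to the simplex boundary is allowed (no
#' smoothing).
#'
#' @param m A `mapping_matrices` object from [build_y()], or a plain
#'   binary matrix (rows = segments, columns = CRLs).
#' @param epsilon Convergence tolerance on the L1 abundance change
#'   (default 1e-5).
#' @param max_iter Iteration safeguard (default 1000).
#' @return An object of class `crl_quant`: list with `rho` (named vector
#'   summing to 1), `posterior` (sparse matrix, rows sum to 1), `tpm`
#'   (`rho * 1e6`; CRLs have similar lengths, so length normalization is
#'   omitted), `n_iterations`, `converged`, `epsilon`, `loglik` (final),
#'   `loglik_trace`, `n_segments`.
#' @export
em_quantify <- function(m, epsilon = 1e-5, max_iter = 1000L) {
  Y <- if (inherits(m, "mapping_matrices")) m$Y else m
  Y <- methods::as(methods::as(methods::as(
    Matrix::Matrix(Y, sparse = TRUE), "dMatrix"), "generalMatrix"),
    "CsparseMatrix")
  Y@x[] <- 1
  N <- nrow(Y)
  K <- ncol(Y)
  if (N == 0L) abort("no read segments to quantify")
  if (any(Matrix::rowSums(Y) == 0)) abort("segment mapping to no CRL")
  rho <- rep(1 / K, K)
  loglik_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  post <- NULL
  repeat {
    it <- it + 1L
    denom <- as.numeric(Y %*% rho)            # sum_c y[s,c] rho[c]
    loglik_trace <- c(loglik_trace, sum(log(denom)))
    # E-step on the sparse support
    post <- Y
    ij <- Matrix::summary(post)
    post@x <- rho[ij$j] / denom[ij$i]
    # M-step
    rho_new <- as.numeric(Matrix::colSums(post)) / N
    delta <- sum(abs(rho_new - rho))
    rho <- rho_new
    if (delta <= epsilon) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
  }
  if (!converged) {
    warn(sprintf("EM did not converge in %d iterations (last delta > %g)",
                 max_iter, epsilon))
  }
  denom <- as.numeric(Y %*% rho)
  post <- Y
  ij <- Matrix::summary(post)
  post@x <- rho[ij$j] / denom[ij$i]
  names(rho) <- colnames(Y)
  structure(
    list(
      rho = rho,
      posterior = post,
      tpm = rho * 1e6,
      n_iterations = it,
      converged = converged,
      epsilon = epsilon,
      loglik = sum(log(denom)),
      loglik_trace = loglik_trace,
      n_segments = N
    ),
    class = "crl_quant"
  )
}

#' @export
print.crl_quant <- function(x, ...) {
  cat(sprintf(
    "<crl_quant> %d read segments, %d CRLs; %s after %d EM iteration(s), logLik %.4f\n",
    x$n_segments, length(x$rho),
    if (x$converged) "converged" else "NOT converged", x$n_iterations,
    x$loglik
  ))
  invisible(x)
}

#' Tidy the EM fit: one row per CRL
#'
#' @param x A `crl_quant` object.
#' @param ... Unused.
#' @return Tibble `crl_id`, `rho`, `tpm`, `n_segments` (posterior mass).
#' @method tidy crl_quant
#' @export
tidy.crl_quant <- function(x, ...) {
  tibble(
    crl_id = names(x$rho),
    rho = unname(x$rho),
    tpm = unname(x$tpm),
    n_segments = unname(as.numeric(Matrix::colSums(x$posterior)))
  )
}

#' One-row EM fit summary
#'
#' @param x A `crl_quant` object.
#' @param ... Unused.
#' @method glance crl_quant
#' @export
glance.crl_quant <- function(x, ...) {
  tibble(
    n_segments = x$n_segments,
    n_crls = length(x$rho),
    n_iterations = x$n_iterations,
    converged = x$converged,
    epsilon = x$epsilon,
    logLik = x$loglik
  )
}

#' @method autoplot crl_quant
#' @export
autoplot.crl_quant <- function(object, top_n = 25L, ...) {
  d <- tidy(object) |>
    arrange(dplyr::desc(.data$tpm)) |>
    head(top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$crl_id, .data$tpm), y = .data$tpm
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "TPM",
                  title = "CRL abundance (EM estimate)") +
    ggplot2::theme_minimal()
}

#' Interaction score of two arms
#'
#' The probability that a chimeric read `..s..s'..` reflects an interaction
#' between CRLs `c` and `c'` is the product of the two arms' posterior
#' assignment probabilities, `Pr[(s,s') in c<->c'] = Pr(z[s,c]=1)
#' Pr(z[s',c']=1)`. Summed over all CRL combinations of a read this is 1.
#'
#' @param posterior1,posterior2 Posterior entries of the two arms.
#' @return Numeric vector of products.
#' @export
score_pairs <- function(posterior1, posterior2) {
  posterior1 * posterior2
}

#' CRL abundance in transcripts per million
#'
#' `tpm[c] = rho[c] * 1e6`; length normalization is omitted because CRLs
#' (merged short interaction loci) have similar lengths.
#'
#' @param rho Abundance vector summing to 1 (or a `crl_quant` object).
#' @return Numeric vector summing to 1e6.
#' @export
crl_tpm <- function(rho) {
  if (inherits(rho, "crl_quant")) rho <- rho$rho
  rho * 1e6
}
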