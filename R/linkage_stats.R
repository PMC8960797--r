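# Association statistics on binary vectors: the phi coefficient (Pearson r
# on dichotomous variables), its chi-square significance (chi2 = n * phi^2,
# df = 1, no continuity correction), BH false-discovery-rate adjustment,
# and assembly of genome-genome and trait-trait similarity matrices.

#' Phi coefficient between two binary vectors
#'
#' Computed from the 2x2 contingency table as
#' (n11*n00 - n10*n01) / sqrt(n1. * n0. * n.1 * n.0). When either vector is
#' constant (a zero margin) phi is undefined; 0 is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param x,y binary vectors of equal length >= 2.
#' @return numeric in \[-1, 1\], possibly with a `degenerate` attribute.
#' @export
phi_coef <- function(x, y) {
  if (length(x) != length(y)) ta_stop("phi: vectors of unequal length")
  if (length(x) < 2L) ta_stop("phi: need length >= 2")
  check_binary(x, "phi input x"); check_binary(y, "phi input y")
  n <- length(x)
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  den <- sqrt(as.numeric(n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
  if (den == 0) return(structure(0, degenerate = TRUE))
  (n11 * n00 - n10 * n01) / den
}

#' Phi and chi-square significance for one binary pair
#'
#' The chi-square statistic uses the identity chi2 = n * phi^2 with 1
#' degree of freedom and no continuity correction; the p-value is the upper
#' tail. Degenerate margins yield phi = 0, p = 1 and `degenerate = TRUE`.
#'
#' @inheritParams phi_coef
#' @return list with `phi`, `chi2`, `p`, `degenerate`.
#' @export
pair_significance <- function(x, y) {
  phi <- phi_coef(x, y)
  degen <- isTRUE(attr(phi, "degenerate"))
  phi <- as.numeric(phi)
  n <- length(x)
  chi2 <- n * phi^2
  p <- if (degen) 1 else pchisq(chi2, df = 1, lower.tail = FALSE)
  list(phi = phi, chi2 = chi2, p = p, degenerate = degen)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) ta_stop("p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

# all pairwise phi coefficients between the columns of a binary matrix,
# in closed form from the cross-product
phi_matrix <- function(M) {
  n <- nrow(M)
  s <- colSums(M)
  n11 <- crossprod(M)                       # co-presence counts
  num <- n * n11 - outer(s, s)
  den <- sqrt(outer(s * (n - s), s * (n - s)))
  P <- num / den
  P[!is.finite(P)] <- 0                      # degenerate (constant) columns
  diag(P) <- 1
  P
}

#' Build a similarity matrix from a trait matrix
#'
#' For `kind = "trait"` the matrix of pairwise phi coefficients between
#' trait columns is thresholded: negative phi is set to 0 (clustering must
#' be driven by positive association only), and among the remaining
#' positive pairs only those significant after BH correction of the
#' chi-square p-values (df = 1) at level `alpha` are retained; the rest are
#' zeroed. For `kind = "genome"` phi is computed between genome rows and no
#' thresholding is applied — negative genome similarities pass through and
#' their count is recorded. Constant rows/columns are dropped with a
#' warning before correlation. The FDR family is, by default, the positive
#' pairs only; `fdr_family = "all"` corrects over every pair instead.
#'
#' @param tm a [trait_matrix()] or a plain binary matrix (genomes x traits).
#' @param kind "trait" or "genome".
#' @param alpha FDR level for trait-pair retention.
#' @param fdr_family "positive" (default) or "all".
#' @return object of class `similarity_matrix`: list with `S` (the parsed
#'   similarity matrix), `phi_raw` (pre-threshold phi), `pairs` (long table
#'   with phi, chi2, p, p_adj, retained), `kind`, `dropped`, `n_negative`.
#' @export
build_similarity <- function(tm, kind = c("trait", "genome"), alpha = 0.05,
                             fdr_family = c("positive", "all")) {
  kind <- match.arg(kind)
  fdr_family <- match.arg(fdr_family)
  M <- if (inherits(tm, "trait_matrix")) tm$values else as.matrix(tm)
  if (kind == "genome") M <- t(M)            # items = genomes -> columns
  if (ncol(M) < 2L) ta_stop("need >= 2 %ss to build a similarity matrix", kind)
  keep <- apply(M, 2L, var) > 0
  if (!all(keep)) {
    ta_warn("dropping %d constant %s(s) before correlation: %s",
            sum(!keep), kind, paste(colnames(M)[!keep], collapse = ", "))
    M <- M[, keep, drop = FALSE]
    if (ncol(M) < 2L) ta_stop("fewer than 2 non-constant %ss remain", kind)
  }
  n <- nrow(M)
  P <- phi_matrix(M)
  ut <- which(upper.tri(P), arr.ind = TRUE)
  pairs <- data.frame(a = colnames(P)[ut[, 1L]], b = colnames(P)[ut[, 2L]],
                      phi = P[ut], stringsAsFactors = FALSE)
  pairs$chi2 <- n * pairs$phi^2
  pairs$p <- pchisq(pairs$chi2, df = 1, lower.tail = FALSE)
  S <- P
  n_negative <- sum(pairs$phi < 0)
  if (kind == "trait") {
    fam <- if (fdr_family == "positive") which(pairs$phi >= 0) else seq_len(nrow(pairs))
    pairs$p_adj <- NA_real_
    pairs$p_adj[fam] <- bh_adjust(pairs$p[fam])
    pairs$retained <- !is.na(pairs$p_adj) & pairs$p_adj < alpha & pairs$phi > 0
    S[S < 0] <- 0
    drop_idx <- ut[!pairs$retained, , drop = FALSE]
    S[drop_idx] <- 0
    S[drop_idx[, c(2L, 1L), drop = FALSE]] <- 0
  } else {
    pairs$p_adj <- bh_adjust(pairs$p)
    pairs$retained <- TRUE                   # genomes: no thresholding
  }
  diag(S) <- NA_real_                        # preference unset until clustering
  structure(list(S = S, phi_raw = P, pairs = pairs, kind = kind,
                 alpha = alpha, fdr_family = fdr_family,
                 dropped = names(keep)[!keep],
                 n_negative = n_negative),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix (%s): %d items, %d pairs retained of %d",
              x$kind, nrow(x$S), sum(x$pairs$retained), nrow(x$pairs)), "\n")
  if (x$n_negative > 0) {
    cat(sprintf("  %d negative raw correlations%s\n", x$n_negative,
                if (x$kind == "trait") " (zeroed)" else " (passed through)"))
  }
  invisible(x)
}
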