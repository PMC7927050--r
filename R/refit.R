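#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0`. Small, dependency-free
#' implementation of the classical active-set algorithm, adequate for
#' signature-refitting problems (96 x tens).
#'
#' @param A Numeric matrix (m x n).
#' @param b Numeric vector of length m.
#' @param tol Dual-feasibility tolerance.
#' @return List with `x` (coefficients) and `resid_norm`.
#' @export
nnls_fit <- function(A, b, tol = 1e-10) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  max_iter <- 30L * n
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      z_p <- tryCatch(qr.coef(qr(Ap), b), error = function(e) NULL)
      if (is.null(z_p)) z_p <- drop(MASS_ginv(Ap) %*% b)
      z_p[is.na(z_p)] <- 0
      z <- numeric(n); z[passive] <- z_p
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  structure(list(x = x, resid_norm = sqrt(sum((b - A %*% x)^2))),
            names = c("x", "resid_norm"))
}

# minimal pseudo-inverse fallback for rank-deficient passive sets
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Refit known mutational signatures to a sample catalog vector
#'
#' Normalises the count vector to proportions and solves a non-negative
#' least-squares fit against the catalog profiles, then prunes greedily:
#' while the smallest-weight active signature either (a) carries weight below
#' `prune_threshold` or (b) can be dropped at a cost of less than
#' `min_cosine_drop` in reconstruction cosine similarity, it is removed and
#' the remainder refitted. Final weights are renormalised to sum to 1.
#' Refitting (rather than de-novo extraction) is the appropriate tool at
#' cohort sizes of a dozen samples, and matches a per-sample
#' contribution-of-known-signatures readout.
#'
#' @param catalog_vector A `catalog_vector` from [build_catalog()], or a
#'   named count vector over the catalog categories.
#' @param catalog A `signature_catalog` of the same scheme.
#' @param prune_threshold Weights below this are always pruned (default 0.05).
#' @param min_cosine_drop Maximum tolerated cosine loss when pruning a
#'   signature (default 0.01).
#' @return A `refit_result`: list with `weights` (named, non-negative,
#'   summing to 1 when any mutation present), `cosine` (reconstruction
#'   cosine similarity), `n_mutations`, and `pruned` (signatures removed).
#' @export
refit_signatures <- function(catalog_vector, catalog,
                             prune_threshold = 0.05,
                             min_cosine_drop = 0.01) {
  counts <- if (inherits(catalog_vector, "catalog_vector")) {
    if (catalog_vector$scheme != catalog$scheme)
      stopf("catalog vector scheme (%s) does not match catalog (%s)",
            catalog_vector$scheme, catalog$scheme)
    catalog_vector$counts
  } else {
    catalog_vector
  }
  cats <- catalog$categories
  if (!all(cats %in% names(counts)))
    stopf("count vector does not cover the catalog categories")
  v <- as.numeric(counts[cats])
  n_mut <- sum(v)
  sigs <- colnames(catalog$signatures)
  if (n_mut == 0) {
    return(structure(list(weights = setNames(numeric(0), character(0)),
                          cosine = NA_real_, n_mutations = 0L,
                          pruned = character(0)),
                     class = "refit_result"))
  }
  if (qr(catalog$signatures)$rank < length(sigs))
    warnf("signature catalog is rank deficient; fit may not be unique")
  vn <- v / sum(v)
  active <- sigs
  fit_active <- function(act) {
    S <- catalog$signatures[, act, drop = FALSE]
    f <- nnls_fit(S, vn)
    list(w = setNames(f$x, act), recon = drop(S %*% f$x))
  }
  cur <- fit_active(active)
  cur_cos <- cosine_sim(vn, cur$recon)
  pruned <- character(0)
  while (sum(cur$w > 0) > 1L) {
    pos <- cur$w[cur$w > 0]
    smallest <- names(pos)[which.min(pos)]
    trial_active <- setdiff(names(pos), smallest)
    trial <- fit_active(trial_active)
    trial_cos <- cosine_sim(vn, trial$recon)
    if (pos[[smallest]] < prune_threshold ||
        (cur_cos - trial_cos) < min_cosine_drop) {
      pruned <- c(pruned, smallest)
      active <- trial_active
      cur <- trial
      cur_cos <- trial_cos
    } else break
  }
  w <- cur$w[cur$w > 0]
  w <- w / sum(w)
  structure(list(weights = w, cosine = cur_cos,
                 n_mutations = as.integer(n_mut),
                 pruned = sort(pruned)),
            class = "refit_result")
}

#' Annotate a refit result with aetiology flags
#'
#' A flag group (e.g. clock-like, MMR deficiency) is raised when the summed
#' weight of its member signatures exceeds `floor`; a small floor guards
#' against over-interpreting trace weights that are likely refit overfitting.
#'
#' @param refit A `refit_result`.
#' @param flag_map Named list mapping flag group to signature names
#'   (default [default_flag_map()]).
#' @param floor Minimum summed weight for a flag to be reported
#'   (default 0.05).
#' @return data.frame with `flag`, `weight`, `flagged`.
#' @export
flag_aetiology <- function(refit, flag_map = default_flag_map(),
                           floor = 0.05) {
  w <- refit$weights
  rows <- lapply(names(flag_map), function(g) {
    members <- intersect(flag_map[[g]], names(w))
    wt <- sum(w[members])
    data.frame(flag = g, weight = wt, flagged = wt > floor,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
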