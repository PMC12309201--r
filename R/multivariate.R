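#' Principal component analysis with a deterministic sign convention
#'
#' Thin wrapper over singular-value decomposition (as in `prcomp`) of the
#' column-centred matrix, with each component's sign fixed so that its
#' largest-magnitude loading element is positive.
#'
#' @param x Samples-by-features numeric matrix (typically already
#'   Pareto-scaled; centring is applied here).
#' @param n_components Number of components to keep (truncated to the rank
#'   with a warning if too large).
#' @return Object of class `pca_metab`: `scores` (tibble with `sample_id`
#'   and `PC*` columns), `loadings` (matrix), `var_explained` (fractions).
#' @export
pca_metab <- function(x, n_components = 2) {
  x <- as.matrix(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  pos <- sum(sv$d > max(sv$d) * 1e-12)
  if (n_components > pos) {
    rlang::warn(sprintf("n_components truncated to rank %d", pos))
    n_components <- pos
  }
  idx <- seq_len(n_components)
  load <- sv$v[, idx, drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, `*`)
  scores <- sweep(sv$u[, idx, drop = FALSE] %*% diag(sv$d[idx],
                                                     n_components),
                  2, flip, `*`)
  colnames(load) <- colnames(scores) <- paste0("PC", idx)
  rownames(load) <- colnames(x)
  var_expl <- sv$d^2 / sum(sv$d^2)
  st <- tibble::as_tibble(scores)
  st <- tibble::add_column(st, sample_id = rownames(x) %||%
                             as.character(seq_len(nrow(x))), .before = 1)
  structure(list(scores = st, loadings = load,
                 var_explained = var_expl[idx],
                 all_var_explained = var_expl),
            class = "pca_metab")
}

# NIPALS PLS1 regression: X (n x p) and y (n) are centred internally.
# Returns weights W, scores TT, loadings P, y-loadings q, coefficients B
# for each number of components up to ncomp.
nipals_pls <- function(X, y, ncomp) {
  X <- as.matrix(X)
  xmean <- colMeans(X)
  ymean <- mean(y)
  E <- sweep(X, 2, xmean)
  f <- y - ymean
  n <- nrow(E); p <- ncol(E)
  ncomp <- min(ncomp, n - 1, p)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  TT <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  ssy <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      ncomp <- a - 1L
      break
    }
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    pvec <- crossprod(E, t) / tt
    qa <- sum(f * t) / tt
    W[, a] <- w
    P[, a] <- pvec
    TT[, a] <- t
    q[a] <- qa
    ssy[a] <- qa^2 * tt
    E <- E - t %*% t(pvec)
    f <- f - qa * t
  }
  if (ncomp == 0) rlang::abort("no predictive variation: constant response")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  TT <- TT[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  R <- W %*% solve(crossprod(P, W))
  B <- R %*% q
  list(W = W, P = P, scores = TT, q = q, coef = drop(B),
       ssy = ssy[seq_len(ncomp)], xmean = xmean, ymean = ymean,
       ncomp = ncomp)
}

predict_nipals <- function(fit, newX) {
  drop(sweep(as.matrix(newX), 2, fit$xmean) %*% fit$coef) + fit$ymean
}

#' Fit an OPLS-DA model for a two-class contrast
#'
#' Orthogonal-signal-correction PLS: class labels are coded -1/+1 and
#' centred; `n_ortho` components orthogonal to the class-predictive
#' variation are extracted and removed from X, after which a single
#' predictive PLS component is fitted on the deflated matrix. With
#' `n_ortho = 0` the model coincides with one-component PLS-DA.
#'
#' The matrix is centred internally; scaling is the caller's choice (the
#' pipeline feeds already Pareto-scaled data and the model does not
#' rescale).
#'
#' @param X Samples-by-features matrix.
#' @param y Two-class factor or vector.
#' @param n_ortho Number of orthogonal components (default 1).
#' @return Object of class `opls_model`: predictive scores/loadings/
#'   weights (`t_p`, `p_p`, `w_p`, `q`), orthogonal blocks (`T_o`, `W_o`,
#'   `P_o`), explained-variation fractions, per-feature `vip`, class
#'   levels and coding.
#' @export
oplsda_fit <- function(X, y, n_ortho = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2) rlang::abort("y must have exactly two classes")
  if (min(table(y)) < 2) rlang::abort("each class needs at least 2 samples")
  yy <- ifelse(y == levels(y)[2], 1, -1)
  yy <- yy - mean(yy)
  xmean <- colMeans(X)
  E <- sweep(X, 2, xmean)
  n <- nrow(E); p <- ncol(E)
  ssx_total <- sum(E^2)

  T_o <- matrix(0, n, n_ortho)
  W_o <- matrix(0, p, n_ortho)
  P_o <- matrix(0, p, n_ortho)
  k <- 0L
  while (k < n_ortho) {
    w <- crossprod(E, yy)
    w <- w / sqrt(sum(w^2))
    t <- E %*% w
    pvec <- crossprod(E, t) / sum(t^2)
    w_o <- pvec - drop(crossprod(w, pvec)) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo < 1e-10) break
    w_o <- w_o / nwo
    t_o <- E %*% w_o
    p_o <- crossprod(E, t_o) / sum(t_o^2)
    E <- E - t_o %*% t(p_o)
    k <- k + 1L
    T_o[, k] <- t_o
    W_o[, k] <- w_o
    P_o[, k] <- p_o
  }
  T_o <- T_o[, seq_len(k), drop = FALSE]
  W_o <- W_o[, seq_len(k), drop = FALSE]
  P_o <- P_o[, seq_len(k), drop = FALSE]

  # predictive component on the deflated matrix
  w_p <- crossprod(E, yy)
  w_p <- w_p / sqrt(sum(w_p^2))
  t_p <- E %*% w_p
  p_p <- crossprod(E, t_p) / sum(t_p^2)
  q <- sum(yy * t_p) / sum(t_p^2)

  ssy_total <- sum(yy^2)
  r2y <- (q^2 * sum(t_p^2)) / ssy_total
  r2x_pred <- sum((t_p %*% t(p_p))^2) / ssx_total
  r2x_ortho <- if (k > 0) {
    vapply(seq_len(k), function(a) {
      sum((T_o[, a] %*% t(P_o[, a]))^2) / ssx_total
    }, numeric(1))
  } else numeric(0)

  vip <- sqrt(p) * abs(drop(w_p))
  names(vip) <- colnames(X) %||% paste0("V", seq_len(p))

  structure(list(
    t_p = drop(t_p), p_p = drop(p_p), w_p = drop(w_p), q = q,
    T_o = T_o, W_o = W_o, P_o = P_o,
    n_ortho = k, r2y = r2y, r2x_pred = r2x_pred, r2x_ortho = r2x_ortho,
    vip = vip, levels = levels(y), y_coded = yy, xmean = xmean,
    feature_ids = colnames(X) %||% paste0("V", seq_len(p)),
    sample_ids = rownames(X) %||% as.character(seq_len(n))
  ), class = "opls_model")
}

#' Variable influence on projection scores of an OPLS model
#'
#' Standard VIP over the predictive component(s):
#' \eqn{VIP_j = \sqrt{p \sum_a w_{ja}^2 SSY_a / \sum_a SSY_a}} with `p`
#' the feature count. With one predictive component this reduces to
#' \eqn{\sqrt{p}\,|w_j|}; the mean squared VIP equals 1 by construction,
#' so VIP > 1 marks above-average contributors to the class separation.
#'
#' @param model A fitted [oplsda_fit()] model.
#' @return Named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "opls_model"))
  model$vip
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA model: %d features, %d samples, %d orthogonal component(s)\n",
    length(x$w_p), length(x$t_p), x$n_ortho
  ))
  cat(sprintf("  R2Y = %.3f, R2X(pred) = %.3f\n", x$r2y, x$r2x_pred))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-feature summary of an OPLS-DA model
#'
#' @param x A fitted `opls_model`.
#' @param ... Unused.
#' @return Tibble with `feature_id`, `weight`, `loading`, `vip`.
#' @export
tidy.opls_model <- function(x, ...) {
  tibble::tibble(feature_id = x$feature_ids, weight = x$w_p,
                 loading = x$p_p, vip = unname(x$vip))
}

#' One-row summary of an OPLS-DA model fit
#'
#' @param x A fitted `opls_model`.
#' @param ... Unused.
#' @return Tibble with `r2y`, `r2x_pred`, `n_ortho`, `n_features`,
#'   `n_samples`.
#' @export
glance.opls_model <- function(x, ...) {
  tibble::tibble(r2y = x$r2y, r2x_pred = x$r2x_pred, n_ortho = x$n_ortho,
                 n_features = length(x$w_p), n_samples = length(x$t_p))
}
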