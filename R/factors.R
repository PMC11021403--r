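# Transdiagnostic dimension extraction: heterogeneous correlations over
# ordinal/continuous items, CNG factor-count selection, ML factor
# extraction with oblimin (direct quartimin) rotation, regression factor
# scores, and bootstrap loading CIs.

# Bivariate standard-normal CDF, Owen's single-integral form
#   Phi2(h, k, rho) = Phi(h) Phi(k) + (1/2pi) Int_0^asin(rho)
#                       exp(-(h^2 + k^2 - 2 h k sin t) / (2 cos^2 t)) dt
# evaluated with fixed Gauss-Legendre quadrature; vectorised over (h, k).
pbvnorm <- local({
  gl <- NULL
  function(h, k, rho) {
    if (is.null(gl)) gl <<- gauss_legendre(48)
    rho <- max(-1 + 1e-12, min(1 - 1e-12, rho))
    up <- asin(rho)
    tt <- up / 2 * (gl$nodes + 1)
    wt <- up / 2 * gl$weights
    s <- sin(tt); c2 <- cos(tt)^2
    acc <- 0
    for (q in seq_along(tt))
      acc <- acc + wt[q] * exp(-(h^2 + k^2 - 2 * h * k * s[q]) / (2 * c2[q]))
    stats::pnorm(h) * stats::pnorm(k) + acc / (2 * pi)
  }
})

# cell probabilities of a bivariate normal over threshold grids
# a, b include -Inf / Inf bounds
.bvn_cells <- function(a, b, rho) {
  ra <- length(a) - 1; rb <- length(b) - 1
  Fg <- matrix(0, length(a), length(b))
  fin_a <- is.finite(a); fin_b <- is.finite(b)
  Fg[!fin_a & a < 0, ] <- 0
  Fg[, !fin_b & b < 0] <- 0
  Fg[!fin_a & a > 0, ] <- matrix(stats::pnorm(b), nrow = sum(!fin_a & a > 0),
                                 ncol = length(b), byrow = TRUE)
  Fg[, !fin_b & b > 0] <- matrix(stats::pnorm(a), ncol = sum(!fin_b & b > 0),
                                 nrow = length(a))
  ia <- which(fin_a); ib <- which(fin_b)
  if (length(ia) && length(ib)) {
    hh <- rep(a[ia], times = length(ib))
    kk <- rep(b[ib], each = length(ia))
    Fg[cbind(rep(ia, times = length(ib)), rep(ib, each = length(ia)))] <-
      pbvnorm(hh, kk, rho)
  }
  P <- Fg[-1, -1, drop = FALSE] - Fg[-1, -(rb + 1), drop = FALSE] -
    Fg[-(ra + 1), -1, drop = FALSE] + Fg[-(ra + 1), -(rb + 1), drop = FALSE]
  pmax(P, 1e-12)
}

.thresholds_from_margin <- function(counts) {
  p <- cumsum(counts) / sum(counts)
  stats::qnorm(p[-length(p)])
}

#' Two-step maximum-likelihood polychoric correlation
#'
#' Latent bivariate-normal correlation between two ordinal variables:
#' thresholds are set from the marginal cumulative proportions (normal
#' quantiles), then rho maximises the multinomial likelihood of the
#' contingency table with bivariate-normal cell probabilities.
#'
#' @param x,y ordinal vectors (integer-coded; pairwise-complete cases used).
#' @return correlation estimate in (-0.999, 0.999).
#' @export
polychoric_ml <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 20) stop("need n >= 20 pairwise-complete observations")
  tab <- table(factor(x), factor(y))
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("polychoric undefined: a variable has a single observed category")
  a <- c(-Inf, .thresholds_from_margin(rowSums(tab)), Inf)
  b <- c(-Inf, .thresholds_from_margin(colSums(tab)), Inf)
  nll <- function(rho) -sum(tab * log(.bvn_cells(a, b, rho)))
  opt <- stats::optimize(nll, c(-0.999, 0.999), tol = 1e-5)
  opt$minimum
}

#' Two-step maximum-likelihood polyserial correlation
#'
#' Latent correlation between a continuous and an ordinal variable: the
#' continuous margin is standardized, ordinal thresholds come from the
#' margins, and rho maximises the conditional-normal likelihood of the
#' ordinal responses given the continuous values.
#'
#' @param x continuous vector.
#' @param y ordinal vector.
#' @return correlation estimate in (-0.999, 0.999).
#' @export
polyserial_ml <- function(x, y) {
  ok <- is.finite(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 20) stop("need n >= 20 pairwise-complete observations")
  yf <- factor(y)
  if (nlevels(yf) < 2)
    stop("polyserial undefined: ordinal variable has a single category")
  z <- (x - mean(x)) / stats::sd(x)
  tau <- c(-Inf, .thresholds_from_margin(table(yf)), Inf)
  yi <- as.integer(yf)
  nll <- function(rho) {
    sr <- sqrt(1 - rho^2)
    p <- stats::pnorm((tau[yi + 1] - rho * z) / sr) -
      stats::pnorm((tau[yi] - rho * z) / sr)
    -sum(log(pmax(p, 1e-12)))
  }
  stats::optimize(nll, c(-0.999, 0.999), tol = 1e-5)$minimum
}

#' Heterogeneous correlation matrix
#'
#' Pearson correlations between continuous pairs, polyserial for mixed
#' pairs, polychoric for ordinal pairs, on pairwise-complete observations.
#' If the result is not positive semi-definite it is smoothed by clipping
#' eigenvalues at 1e-6 and rescaling to unit diagonal (`smoothing_applied`
#' set).
#'
#' @param table data.frame or matrix, participants x variables.
#' @param var_types character vector (`"continuous"` / `"ordinal"`), one
#'   per variable.
#' @return object of class `HetCorMatrix`: `matrix`, `pair_type`,
#'   `smoothing_applied`.
#' @export
hetcor_matrix <- function(table, var_types) {
  X <- as.data.frame(table)
  p <- ncol(X)
  if (length(var_types) != p)
    stop("var_types must declare one type per variable")
  if (!all(var_types %in% c("continuous", "ordinal")))
    stop("var_types entries must be 'continuous' or 'ordinal'")
  R <- diag(1, p)
  ptype <- matrix("", p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    ok <- !is.na(X[[i]]) & !is.na(X[[j]])
    if (!any(ok))
      stop("all-missing pair: ", names(X)[i], " x ", names(X)[j])
    ti <- var_types[i]; tj <- var_types[j]
    r <- if (ti == "continuous" && tj == "continuous") {
      ptype[i, j] <- "pearson"
      stats::cor(X[[i]][ok], X[[j]][ok])
    } else if (ti == "ordinal" && tj == "ordinal") {
      ptype[i, j] <- "polychoric"
      polychoric_ml(X[[i]][ok], X[[j]][ok])
    } else {
      ptype[i, j] <- "polyserial"
      if (ti == "continuous") polyserial_ml(X[[i]][ok], X[[j]][ok])
      else polyserial_ml(X[[j]][ok], X[[i]][ok])
    }
    R[i, j] <- R[j, i] <- r
  }
  dimnames(R) <- list(names(X), names(X))
  smoothed <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 0) {
    smoothed <- TRUE
    v <- pmax(ev$values, 1e-6)
    R <- ev$vectors %*% diag(v, p) %*% t(ev$vectors)
    D <- 1 / sqrt(diag(R))
    R <- R * tcrossprod(D)
    dimnames(R) <- list(names(X), names(X))
  }
  structure(list(matrix = R, pair_type = ptype,
                 smoothing_applied = smoothed),
            class = "HetCorMatrix")
}

#' Cattell-Nelson-Gorsuch factor count
#'
#' For each admissible split t, straight lines are fitted to the eigenvalue
#' triplets (t-2..t) and (t+1..t+3); the CNG index is the change in scree
#' slope (slope after minus slope before), and the selected factor count is
#' the t maximising it (ties broken to the smallest t).
#'
#' @param eigenvalues decreasing numeric vector (length >= 6).
#' @return integer factor count.
#' @export
cng_factor_count <- function(eigenvalues) {
  e <- as.numeric(eigenvalues)
  p <- length(e)
  if (p < 6) stop("CNG needs at least 6 eigenvalues")
  slope3 <- function(ix) {
    x <- seq_along(ix)
    sum((x - mean(x)) * (e[ix] - mean(e[ix]))) / sum((x - mean(x))^2)
  }
  ts <- 3:(p - 3)
  cng <- vapply(ts, function(t)
    slope3((t + 1):(t + 3)) - slope3((t - 2):t), 0)
  ts[which.max(cng)]
}

# Tucker congruence coefficient between two loading columns
tucker_congruence <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# direct quartimin (oblimin, gamma = 0) rotation by gradient projection
.quartimin_vgQ <- function(L) {
  m <- ncol(L)
  L2 <- L^2
  Nm <- matrix(1, m, m) - diag(m)
  list(f = sum(L2 * (L2 %*% Nm)) / 4, G = L * (L2 %*% Nm))
}

.gpf_oblq <- function(A, Tmat = diag(ncol(A)), maxit = 1000, eps = 1e-6) {
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  V <- .quartimin_vgQ(L)
  f <- V$f
  G <- -t(t(L) %*% V$G %*% Ti)
  for (it in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(A))
    s <- sqrt(sum(Gp^2))
    if (s < eps) break
    al <- 2 * al
    for (half in 1:30) {
      X <- Tmat - al * Gp
      X <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(A))
      Ti2 <- tryCatch(solve(X), error = function(e) NULL)
      if (!is.null(Ti2)) {
        L2 <- A %*% t(Ti2)
        V2 <- .quartimin_vgQ(L2)
        if (V2$f < f - 0.5 * s^2 * al) break
      }
      al <- al / 2
    }
    if (is.null(Ti2)) break
    Tmat <- X; f <- V2$f; L <- L2; Ti <- Ti2
    G <- -t(t(L) %*% V2$G %*% Ti2)
  }
  list(loadings = L, Phi = t(Tmat) %*% Tmat, Tmat = Tmat, f = f,
       converged = s < eps, iterations = it)
}

# random orthonormal matrix
.rand_orth <- function(m) qr.Q(qr(matrix(stats::rnorm(m * m), m, m)))

#' Maximum-likelihood EFA with oblimin rotation
#'
#' Extracts `n_factors` by maximum likelihood from a (smoothed)
#' heterogeneous correlation matrix via [stats::factanal()], then applies a
#' direct-quartimin (oblimin, gamma = 0) oblique rotation by gradient
#' projection with multiple random starts. Columns are ordered by explained
#' variance and signed so that the majority of salient loadings
#' (|loading| >= 0.3) are positive.
#'
#' @param corr `HetCorMatrix` (or plain correlation matrix).
#' @param n_factors number of factors (>= 1, < items / 2).
#' @param n_obs number of observations behind the correlations.
#' @param n_starts random rotation starts, default 8.
#' @param labels optional factor labels (e.g. `c("AD", "IIO", "CIT")`).
#' @return object of class `FactorSolution`: `eigenvalues`, `n_factors`,
#'   `loadings` (pattern matrix), `factor_corr`, `uniquenesses`,
#'   `communalities`, `corr` (the input matrix), `rotation_f`.
#' @export
fit_ml_efa <- function(corr, n_factors, n_obs = NULL, n_starts = 8,
                       labels = NULL) {
  R <- if (inherits(corr, "HetCorMatrix")) corr$matrix else as.matrix(corr)
  p <- ncol(R)
  if (n_factors < 1) stop("n_factors must be >= 1")
  if (n_factors >= p / 2) stop("n_factors must be below items / 2")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  fa_args <- list(factors = n_factors, covmat = stats::cov2cor(R),
                  rotation = "none", control = list(lower = 0.005))
  if (!is.null(n_obs)) fa_args$n.obs <- n_obs
  fa <- do.call(stats::factanal, fa_args)
  A <- unclass(fa$loadings)
  if (n_factors == 1) {
    L <- A; Phi <- matrix(1, 1, 1); best <- list(f = 0, converged = TRUE)
  } else {
    best <- NULL
    for (s in seq_len(n_starts)) {
      Tm <- if (s == 1) diag(n_factors) else .rand_orth(n_factors)
      cand <- .gpf_oblq(A, Tm)
      if (is.null(best) || cand$f < best$f) best <- cand
    }
    if (!best$converged)
      stop("oblimin rotation failed to converge after ", best$iterations,
           " iterations (criterion ", signif(best$f, 6), ")")
    L <- best$loadings; Phi <- best$Phi
  }
  ## order columns by explained variance (structure-weighted SS loadings)
  ssl <- colSums(L^2)
  ord <- order(ssl, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  Phi <- Phi[ord, ord, drop = FALSE]
  ## sign convention: majority of salient loadings positive
  for (j in seq_len(ncol(L))) {
    sal <- L[abs(L[, j]) >= 0.3, j]
    flip <- if (length(sal)) sum(sign(sal)) < 0 else sum(L[, j]) < 0
    if (flip) {
      L[, j] <- -L[, j]
      Phi[j, ] <- -Phi[j, ]; Phi[, j] <- -Phi[, j]
    }
  }
  labs <- labels %||% paste0("F", seq_len(n_factors))
  colnames(L) <- labs
  dimnames(Phi) <- list(labs, labs)
  rownames(L) <- rownames(R)
  comm <- rowSums((L %*% Phi) * L)
  structure(list(eigenvalues = ev, n_factors = n_factors, loadings = L,
                 factor_corr = Phi, uniquenesses = fa$uniquenesses,
                 communalities = comm, corr = R,
                 rotation_f = best$f, n_obs = n_obs),
            class = "FactorSolution")
}

#' Regression-method (Thurstone) factor scores
#'
#' Scores computed as `Z R^{-1} (L Phi)` from the heterogeneous correlation
#' matrix, pattern loadings and factor correlations, then standardized to
#' mean 0 / SD 1. Items are standardized by their observed means and SDs.
#' Participants with missing items are scored on the available items with
#' the weight sum rescaled (a warning is issued).
#'
#' @param solution `FactorSolution` fitted on the same variables.
#' @param table participants x items data (columns matching the solution).
#' @return participants x factors matrix of standardized scores.
#' @export
factor_scores <- function(solution, table) {
  stopifnot(inherits(solution, "FactorSolution"))
  X <- as.matrix(as.data.frame(table)[, rownames(solution$loadings),
                                      drop = FALSE])
  Z <- scale(X)
  W <- solve(solution$corr, solution$loadings %*% solution$factor_corr)
  nmiss <- rowSums(is.na(Z))
  if (any(nmiss > 0)) {
    warning(sum(nmiss > 0),
            " participant(s) scored on available items only (reweighted)")
    p <- ncol(Z)
    Zf <- ifelse(is.na(Z), 0, Z)
    S <- Zf %*% W
    S <- S * (p / (p - nmiss))
  } else {
    S <- Z %*% W
  }
  scale(S)[, , drop = FALSE]
}

#' Bootstrap confidence intervals for oblimin loadings
#'
#' Participants are resampled with replacement; each replicate refits the
#' heterogeneous correlation matrix and the ML-EFA, is aligned to the
#' reference solution by Tucker-congruence column matching plus sign
#' flipping, and contributes to percentile 2.5/97.5 intervals per loading.
#' Non-converging replicates are dropped and counted; more than 10%
#' dropped is an error.
#'
#' @param table participants x items data.
#' @param n_factors factors to extract.
#' @param n_boot bootstrap replicates (>= 100; the study default is 1000).
#' @param seed integer seed.
#' @param var_types per-variable types, default all ordinal.
#' @param reference optional `FactorSolution` to align to (fitted on the
#'   full sample if omitted).
#' @param indices_fn optional function `(b, n) -> integer indices` replacing
#'   the default with-replacement resampler (testing hook for degenerate
#'   resampling schemes).
#' @return list: `lower`, `upper` (items x factors), `n_dropped`,
#'   `reference`.
#' @export
bootstrap_loading_cis <- function(table, n_factors, n_boot = 1000, seed = 1,
                                  var_types = NULL, reference = NULL,
                                  indices_fn = NULL) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  X <- as.data.frame(table)
  vt <- var_types %||% rep("ordinal", ncol(X))
  if (is.null(reference)) {
    hc <- hetcor_matrix(X, vt)
    reference <- fit_ml_efa(hc, n_factors, n_obs = nrow(X))
  }
  ref <- reference$loadings
  m <- ncol(ref)
  boots <- array(NA_real_, c(nrow(ref), m, n_boot))
  dropped <- 0
  set.seed(seed)
  for (bidx in seq_len(n_boot)) {
    ix <- if (is.null(indices_fn)) sample.int(nrow(X), replace = TRUE)
          else indices_fn(bidx, nrow(X))
    L <- tryCatch({
      hc <- hetcor_matrix(X[ix, , drop = FALSE], vt)
      fit_ml_efa(hc, n_factors, n_obs = nrow(X))$loadings
    }, error = function(e) NULL)
    if (is.null(L)) { dropped <- dropped + 1; next }
    ## align columns to the reference by greedy |congruence| matching
    cg <- outer(seq_len(m), seq_len(m), Vectorize(function(i, j)
      tucker_congruence(ref[, i], L[, j])))
    perm <- integer(m); sgn <- numeric(m)
    avail <- rep(TRUE, m)
    for (i in order(-apply(abs(cg), 1, max))) {
      j <- which.max(abs(cg[i, ]) * avail)
      perm[i] <- j; sgn[i] <- sign(cg[i, j]); avail[j] <- FALSE
    }
    boots[, , bidx] <- sweep(L[, perm, drop = FALSE], 2, sgn, `*`)
  }
  if (dropped > 0.1 * n_boot)
    stop("more than 10% of bootstrap replicates failed (", dropped, "/",
         n_boot, ")")
  lower <- apply(boots, c(1, 2), stats::quantile, 0.025, na.rm = TRUE)
  upper <- apply(boots, c(1, 2), stats::quantile, 0.975, na.rm = TRUE)
  dimnames(lower) <- dimnames(upper) <- dimnames(ref)
  list(lower = lower, upper = upper, n_dropped = dropped,
       reference = reference)
}
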