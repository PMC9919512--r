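# Eight alternative algorithms that map a preprocessed RGB trace to a
# one-dimensional blood-volume-pulse signal: fixed channel combinations
# (GRD, AGRD), chrominance projections with running-std tuning (CHROM,
# POS), and data-driven decompositions (PCA, ICA, Laplacian eigenmaps,
# stochastic proximity embedding) followed by pulse-component selection.

#' Extraction method parameters
#'
#' @param L_seconds running-standard-deviation window of the CHROM and POS
#'   projections, seconds (default 1.6).
#' @param le_k neighbor count of the Laplacian-eigenmap mutual k-NN graph.
#' @param le_metric distance in RGB space: `"mahalanobis"` (covariance
#'   estimated from the whole preprocessed trace) or `"euclidean"`.
#' @param spe_lambda0,spe_lambdaF initial and final learning rate of the
#'   stochastic proximity embedding; the rate decreases linearly across
#'   cycles.
#' @param spe_cycles,spe_steps_per_cycle refinement schedule;
#'   `spe_steps_per_cycle = NULL` means ten pair updates per sample.
#' @param spe_epsilon small constant guarding the division by the map
#'   distance.
#' @param seed RNG seed for the stochastic methods (ICA initialization,
#'   SPE pair sampling); identical seeds give identical output.
#' @return list of class `method_params`.
#' @export
method_params <- function(L_seconds = 1.6, le_k = 9L,
                          le_metric = c("mahalanobis", "euclidean"),
                          spe_lambda0 = 1.0, spe_lambdaF = 0.01,
                          spe_cycles = 20L, spe_steps_per_cycle = NULL,
                          spe_epsilon = 1e-10, seed = 1L) {
  le_metric <- match.arg(le_metric)
  stopifnot(L_seconds > 0, le_k >= 1L, spe_lambda0 >= spe_lambdaF,
            spe_lambdaF > 0, spe_epsilon > 0)
  structure(list(L_seconds = L_seconds, le_k = as.integer(le_k),
                 le_metric = le_metric, spe_lambda0 = spe_lambda0,
                 spe_lambdaF = spe_lambdaF, spe_cycles = as.integer(spe_cycles),
                 spe_steps_per_cycle = spe_steps_per_cycle,
                 spe_epsilon = spe_epsilon, seed = as.integer(seed)),
            class = "method_params")
}

#' Running standard deviation over trailing windows
#'
#' `sigma(t, L) = sqrt( sum(x^2)/(L-1) - (sum x)^2 / (L (L-1)) )` over the
#' trailing `L`-sample window ending at `t`.  The first `L - 1` samples
#' reuse the first full window's value.
#'
#' @param x numeric vector.
#' @param L window length in samples, `2 <= L <= length(x)`.
#' @return vector of running standard deviations, same length as `x`.
#' @export
running_std <- function(x, L) {
  n <- length(x)
  if (L < 2L || L > n) stop("running_std: need 2 <= L <= length(x)")
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  t <- L:n
  s <- cs[t + 1L] - cs[t + 1L - L]
  s2 <- cs2[t + 1L] - cs2[t + 1L - L]
  v <- s2 / (L - 1) - s^2 / (L * (L - 1))
  v[v < 0] <- 0
  out <- numeric(n)
  out[t] <- sqrt(v)
  out[seq_len(L - 1L)] <- out[L]
  out
}

# sigma1/sigma2 ratio; windows with a degenerate sigma2 carry no
# chrominance information and are flagged so the projection output can
# be zeroed there.
std_ratio <- function(s1, s2, floor = 1e-12) {
  bad <- s2 <= floor
  if (any(bad))
    warning(sprintf("running-std ratio clamped in %d degenerate window(s)",
                    sum(bad)))
  r <- numeric(length(s1))
  r[!bad] <- s1[!bad] / s2[!bad]
  list(ratio = r, bad = bad)
}

#' Green-red difference (GRD)
#'
#' The green channel carries the strongest pulse; the red channel is
#' treated as an artifact reference: `iPPG0 = g - r`.
#'
#' @param trace a preprocessed [rgb_trace].
#' @return an [ippg_signal] (not yet polarity-oriented).
#' @export
grd <- function(trace) {
  ippg_signal(trace$g - trace$r, trace$fs, "GRD")
}

#' Adaptive green-red difference (AGRD)
#'
#' `iPPG0 = ||c0(t)|| (g/g0 - r/r0)`, with `||c0||` the Euclidean norm of
#' the raw channels.  The normalization by the raw channels acts as an
#' adaptive band-pass against residual motion artifacts; without
#' preprocessing, `g = g0` and `r = r0` give an identically zero signal.
#'
#' @param trace_raw the raw [rgb_trace] (`stage = "raw"`).
#' @param trace_pre the preprocessed trace, aligned sample-for-sample.
#' @param floor raw-channel magnitude floor; smaller values are an error.
#' @return an [ippg_signal].
#' @export
agrd <- function(trace_raw, trace_pre, floor = 1e-6) {
  n <- length(trace_pre)
  if (length(trace_raw) != n)
    stop("agrd: raw and preprocessed traces must align")
  bad <- which(abs(trace_raw$g) < floor | abs(trace_raw$r) < floor)
  if (length(bad))
    stop("agrd: raw channel magnitude below floor at sample ", bad[1L])
  nrm <- sqrt(trace_raw$r^2 + trace_raw$g^2 + trace_raw$b^2)
  v <- nrm * (trace_pre$g / trace_raw$g - trace_pre$r / trace_raw$r)
  ippg_signal(v, trace_pre$fs, "AGRD")
}

#' Chrominance-based extraction (CHROM)
#'
#' Projects onto the chrominance combinations `x1 = 0.77 r - 0.51 g` and
#' `x2 = 0.77 r + 0.51 g` and removes the residual distortion by tuning
#' with running standard deviations:
#' `iPPG0 = x1 - (sigma1/sigma2) x2` over trailing windows of
#' `L_seconds`.
#'
#' @param trace a preprocessed [rgb_trace].
#' @param params a [method_params].
#' @return an [ippg_signal].
#' @export
chrom <- function(trace, params = method_params()) {
  L <- ceiling(params$L_seconds * trace$fs)
  if (length(trace) < L) stop("chrom: trace shorter than the L window")
  x1 <- 0.77 * trace$r - 0.51 * trace$g
  x2 <- 0.77 * trace$r + 0.51 * trace$g
  rt <- std_ratio(running_std(x1, L), running_std(x2, L))
  v <- x1 - rt$ratio * x2
  v[rt$bad] <- 0
  ippg_signal(v, trace$fs, "CHROM")
}

#' Plane-orthogonal-to-skin extraction (POS)
#'
#' Simplified and improved variant of CHROM operating in a plane
#' orthogonal to the skin tone: `x1 = g - b`, `x2 = g + b - 2r`,
#' `iPPG0 = x1 + (sigma1/sigma2) x2`.  Both combinations are
#' intensity-null, so adding the same series to all channels leaves the
#' output unchanged.
#'
#' @inheritParams chrom
#' @return an [ippg_signal].
#' @export
pos <- function(trace, params = method_params()) {
  L <- ceiling(params$L_seconds * trace$fs)
  if (length(trace) < L) stop("pos: trace shorter than the L window")
  x1 <- trace$g - trace$b
  x2 <- trace$g + trace$b - 2 * trace$r
  rt <- std_ratio(running_std(x1, L), running_std(x2, L))
  v <- x1 + rt$ratio * x2
  v[rt$bad] <- 0
  ippg_signal(v, trace$fs, "POS")
}

# Standardize the channels of a trace into a T x 3 matrix; zero-variance
# columns are dropped.  Errors when fewer than two informative channels
# remain.
standardized_channels <- function(trace, min_cols = 2L) {
  X <- cbind(r = trace$r, g = trace$g, b = trace$b)
  sds <- apply(X, 2L, stats::sd)
  keep <- sds > 0
  if (sum(keep) < min_cols)
    stop("trace has fewer than ", min_cols, " channels with variance")
  X <- scale(X[, keep, drop = FALSE])
  attr(X, "kept") <- keep
  X
}

# Pick the component (column) with maximal in-band spectral prominence;
# ties broken by lower index.
select_component <- function(components, fs, band) {
  scores <- apply(components, 2L, function(x)
    inband_prominence(x, fs, band)$score)
  sel <- which.max(scores)         # which.max takes the first on ties
  list(index = sel, score = scores[sel])
}

#' Orient the polarity of a pulse signal
#'
#' Decomposition outputs are sign-ambiguous.  In reflection the green
#' channel is pulse-down (more blood absorbs more light), so the signal
#' is flipped when its correlation with the negated preprocessed green
#' channel is negative, leaving systolic peaks pointing up.
#'
#' @param sig an [ippg_signal].
#' @param trace the preprocessed [rgb_trace] the signal came from.
#' @return the oriented [ippg_signal] (`polarity_oriented = TRUE`).
#' @export
orient_polarity <- function(sig, trace) {
  stopifnot(inherits(sig, "ippg_signal"))
  if (stats::sd(sig$values) == 0 || stats::sd(trace$g) == 0) {
    warning("orient_polarity: zero-variance input; left unchanged")
    sig$polarity_oriented <- TRUE
    return(sig)
  }
  if (stats::cor(sig$values, -trace$g) < 0) sig$values <- -sig$values
  sig$polarity_oriented <- TRUE
  sig
}

#' Principal-component extraction (PCA)
#'
#' Projects the standardized channel matrix onto its principal components
#' and keeps the component with the most prominent spectral peak in the
#' pulse band.
#'
#' @param trace a preprocessed [rgb_trace], length >= 30.
#' @param params a [method_params].
#' @param band pulse band in Hz used for component selection.
#' @return list: `signal` (oriented [ippg_signal]) and `model`
#'   (components, basis, selected index, selection score).
#' @export
pca_extract <- function(trace, params = method_params(),
                        band = c(0.65, 4)) {
  if (length(trace) < 30L) stop("pca_extract: need at least 30 samples")
  X <- standardized_channels(trace)
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  sel <- select_component(pc$x, trace$fs, band)
  sig <- orient_polarity(
    ippg_signal(pc$x[, sel$index], trace$fs, "PCA"), trace)
  list(signal = sig,
       model = list(components = pc$x, basis = pc$rotation,
                    selected_index = sel$index,
                    selection_score = sel$score))
}

# Deflationary fixed-point ICA with the cubic nonlinearity on whitened
# data.  Rows of the returned `S` are the estimated sources.
fastica_cubic <- function(X, seed, tol = 1e-6, max_iter = 500L) {
  n <- nrow(X)
  p <- ncol(X)
  Xc <- scale(X, scale = FALSE)
  cv <- stats::cov(Xc)
  ei <- eigen(cv, symmetric = TRUE)
  K <- ei$vectors %*% diag(1 / sqrt(pmax(ei$values, 1e-12)), p) # whitener
  Z <- Xc %*% K                         # n x p, identity covariance
  W <- matrix(0, p, p)
  conv <- logical(p)
  for (comp in seq_len(p)) {
    converged <- FALSE
    for (attempt in 0:3) {
      w <- with_seed(seed + 101L * comp + attempt, stats::rnorm(p))
      w <- w / sqrt(sum(w^2))
      for (it in seq_len(max_iter)) {
        wx <- Z %*% w
        w_new <- colMeans(Z * as.vector(wx)^3) - 3 * w
        if (comp > 1L) {                 # Gram-Schmidt against previous
          prev <- W[seq_len(comp - 1L), , drop = FALSE]
          w_new <- w_new - as.vector(crossprod(prev %*% w_new, prev))
        }
        nw <- sqrt(sum(w_new^2))
        if (nw < 1e-12) break
        w_new <- w_new / nw
        delta <- abs(abs(sum(w_new * w)) - 1)
        w <- w_new
        if (delta < tol) { converged <- TRUE; break }
      }
      if (converged) break
    }
    # near-Gaussian residual directions have no stable cubic fixed
    # point; keep the last (deterministic) iterate and flag it
    if (!converged)
      warning("fastica_cubic: component ", comp,
              " did not converge after 4 seeded initializations; ",
              "keeping the last iterate")
    conv[comp] <- converged
    W[comp, ] <- w
  }
  if (!any(conv))
    stop("fastica_cubic: no component converged")
  list(S = Z %*% t(W), W = W, K = K, converged = conv)
}

#' Independent-component extraction (ICA)
#'
#' Blind source separation of the standardized channels by deflationary
#' fixed-point iteration (cubic nonlinearity), followed by selection of
#' the component with the most prominent pulse-band peak.  Deterministic
#' for a fixed `params$seed`.  A component that fails to converge is
#' retried with three alternative seeded initializations; if it still
#' cycles (the usual fate of near-Gaussian residual directions, which
#' have no stable cubic fixed point) its last iterate is kept with a
#' warning, and an error is raised only when no component converges.
#'
#' @inheritParams pca_extract
#' @return list: `signal` and `model` (components, separation matrix `W`,
#'   whitener `K`, selected index, selection score).
#' @export
ica_extract <- function(trace, params = method_params(),
                        band = c(0.65, 4)) {
  if (length(trace) < 30L) stop("ica_extract: need at least 30 samples")
  X <- standardized_channels(trace)
  fit <- fastica_cubic(X, seed = params$seed)
  sel <- select_component(fit$S, trace$fs, band)
  sig <- orient_polarity(
    ippg_signal(fit$S[, sel$index], trace$fs, "ICA"), trace)
  list(signal = sig,
       model = list(components = fit$S, W = fit$W, K = fit$K,
                    converged = fit$converged,
                    selected_index = sel$index,
                    selection_score = sel$score))
}

#' Laplacian-eigenmap extraction (LE)
#'
#' Embeds the per-frame RGB samples into one dimension while preserving
#' local neighborhoods: a mutual k-nearest-neighbor graph (binary
#' weights) is built under the configured metric, and the embedding is
#' the generalized eigenvector of the graph Laplacian with the
#' second-smallest eigenvalue.  Temporal order of the samples is kept, so
#' the embedding coordinate indexed by frame is the pulse signal.  A
#' disconnected graph triggers increments of `k` until connected.
#'
#' @inheritParams pca_extract
#' @return list: `signal` and `model` (embedding, final `k`, degrees).
#' @export
le_extract <- function(trace, params = method_params(),
                       band = c(0.65, 4)) {
  n <- length(trace)
  if (n <= params$le_k) stop("le_extract: need more samples than le_k")
  X <- standardized_channels(trace)
  if (params$le_metric == "mahalanobis") {
    # regularized whitening: floor the covariance spectrum so that
    # numerically empty directions of near-rank-deficient traces do not
    # explode into noise
    cv <- stats::cov(X)
    ei <- eigen(cv, symmetric = TRUE)
    lam <- pmax(ei$values, max(ei$values) * 1e-6)
    X <- X %*% ei$vectors %*% diag(1 / sqrt(lam), ncol(X))
  }
  D <- as.matrix(stats::dist(X))
  k <- params$le_k
  repeat {
    if (k >= n) stop("le_extract: graph never became connected")
    # k nearest neighbors of each point (self excluded)
    NNidx <- apply(D, 1L, function(row) order(row)[2:(k + 1L)])
    A <- matrix(FALSE, n, n)
    A[cbind(rep(seq_len(n), each = k), as.vector(NNidx))] <- TRUE
    W <- A & t(A)                       # mutual neighbors, binary weights
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected")
    if (igraph::components(g)$no == 1L) break
    k <- min(n - 1L, k + max(1L, k %/% 2L))
  }
  if (k != params$le_k)
    message("le_extract: k increased to ", k, " for connectivity")
  Wn <- W * 1
  deg <- rowSums(Wn)
  dis <- 1 / sqrt(deg)
  M <- -Wn * tcrossprod(dis)            # D^-1/2 (D - W) D^-1/2 off-diag
  diag(M) <- 1
  ei <- eigen((M + t(M)) / 2, symmetric = TRUE)
  y <- dis * ei$vectors[, n - 1L]       # second-smallest eigenvalue
  sig <- orient_polarity(ippg_signal(y, trace$fs, "LE"), trace)
  list(signal = sig, model = list(embedding = y, k = k, degrees = deg,
                                  eigenvalues = rev(ei$values)[1:3]))
}

#' Stochastic-proximity-embedding extraction (SPE)
#'
#' Self-organizing one-dimensional embedding of the RGB samples:
#' random point pairs are drawn and their map coordinates nudged so the
#' map distance approaches the RGB-space proximity,
#' `x_a <- x_a + lambda/2 * (r_ab - d_ab)/(d_ab + eps) * (x_a - x_b)` and
#' symmetrically for `x_b`, with the learning rate decreasing linearly
#' from `spe_lambda0` to `spe_lambdaF` across cycles.  Deterministic for
#' a fixed seed; temporal sample order is kept.
#'
#' @inheritParams pca_extract
#' @return list: `signal` and `model` (embedding, schedule).
#' @export
spe_extract <- function(trace, params = method_params(),
                        band = c(0.65, 4)) {
  n <- length(trace)
  if (n < 30L) stop("spe_extract: need at least 30 samples")
  X <- standardized_channels(trace)
  xr <- X[, 1L]
  xg <- if (ncol(X) >= 2L) X[, 2L] else numeric(n)
  xb <- if (ncol(X) >= 3L) X[, 3L] else numeric(n)
  steps <- params$spe_steps_per_cycle
  if (is.null(steps)) steps <- 10L * n
  eps <- params$spe_epsilon
  lam_sched <- seq(params$spe_lambda0, params$spe_lambdaF,
                   length.out = params$spe_cycles)
  y <- with_seed(params$seed, {
    y <- stats::rnorm(n, sd = 0.5)
    for (cyc in seq_len(params$spe_cycles)) {
      lam <- lam_sched[cyc]
      ia <- sample.int(n, steps, replace = TRUE)
      ib <- sample.int(n, steps, replace = TRUE)
      for (s in seq_len(steps)) {
        a <- ia[s]; b <- ib[s]
        if (a == b) next
        d <- abs(y[a] - y[b])
        r <- sqrt((xr[a] - xr[b])^2 + (xg[a] - xg[b])^2 +
                  (xb[a] - xb[b])^2)
        f <- lam * 0.5 * (r - d) / (d + eps)
        dya <- f * (y[a] - y[b])
        y[a] <- y[a] + dya
        y[b] <- y[b] - dya
      }
    }
    y
  })
  sig <- orient_polarity(ippg_signal(y, trace$fs, "SPE"), trace)
  list(signal = sig,
       model = list(embedding = y, lambda_schedule = lam_sched,
                    steps_per_cycle = steps))
}

#' Extract a pulse signal by name
#'
#' Dispatcher over the eight extraction methods.  All outputs are
#' polarity-oriented (systolic peaks up).  For decomposition methods the
#' fitted model is attached as attribute `"model"`.
#'
#' @param trace_pre preprocessed [rgb_trace].
#' @param method one of `r paste(IPPG_METHODS, collapse = ", ")`.
#' @param trace_raw raw trace, required by `"AGRD"`.
#' @param params a [method_params].
#' @param band pulse band for component selection, Hz.
#' @return an oriented [ippg_signal].
#' @export
extract_ippg <- function(trace_pre, method, trace_raw = NULL,
                         params = method_params(), band = c(0.65, 4)) {
  method <- toupper(method)
  if (!method %in% IPPG_METHODS)
    stop("unknown method '", method, "'; valid methods: ",
         paste(IPPG_METHODS, collapse = ", "))
  out <- switch(method,
    GRD = orient_polarity(grd(trace_pre), trace_pre),
    AGRD = {
      if (is.null(trace_raw)) stop("AGRD requires the raw trace")
      orient_polarity(agrd(trace_raw, trace_pre), trace_pre)
    },
    CHROM = orient_polarity(chrom(trace_pre, params), trace_pre),
    POS = orient_polarity(pos(trace_pre, params), trace_pre),
    PCA = pca_extract(trace_pre, params, band),
    ICA = ica_extract(trace_pre, params, band),
    LE = le_extract(trace_pre, params, band),
    SPE = spe_extract(trace_pre, params, band))
  if (is.list(out) && !inherits(out, "ippg_signal")) {
    sig <- out$signal
    attr(sig, "model") <- out$model
    sig
  } else out
}
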