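#' Partial volume estimate (PVE) map for the three tissue classes
#'
#' Bundles per-class PVE volumes for OM (other matter, the CSF-like class),
#' GM and WM, plus the brain mask they live in. Inside the mask the per-voxel
#' class sum is 1 (within 1e-6); outside it is 0. The class order OM < GM < WM
#' is fixed throughout the package (files, labels, tie-breaks).
#'
#' @param om,gm,wm per-class `agetpl_volume`s with values in \[0,1\].
#' @param mask binary `agetpl_volume`.
#' @param normalize if TRUE, renormalize the per-voxel sum to 1 inside the
#'   mask and zero the classes outside.
#' @return an `agetpl_pve` object.
#' @export
pve_map <- function(om, gm, wm, mask, normalize = FALSE) {
  stopifnot_same_grid(om, gm); stopifnot_same_grid(om, wm)
  stopifnot_same_grid(om, mask)
  if (normalize) {
    m <- mask$data > 0
    s <- om$data + gm$data + wm$data
    s[!m | s <= 0] <- 1
    om$data <- om$data / s * m
    gm$data <- gm$data / s * m
    wm$data <- wm$data / s * m
  }
  structure(list(om = om, gm = gm, wm = wm, mask = mask,
                 classes = PVE_CLASSES), class = "agetpl_pve")
}

PVE_CLASSES <- c("om", "gm", "wm")

#' @export
print.agetpl_pve <- function(x, ...) {
  cat(sprintf("<agetpl_pve> classes om/gm/wm, %d voxels in mask\n",
              sum(x$mask$data > 0)))
  invisible(x)
}

pve_matrix <- function(pve, where = NULL) {
  if (is.null(where)) where <- pve$mask$data > 0
  cbind(om = pve$om$data[where], gm = pve$gm$data[where], wm = pve$wm$data[where])
}

#' Segmentation configuration
#'
#' Mirrors the prior-usage modes of a FAST-style classifier: `a_priori` uses
#' the spatial priors only to initialize (flat priors thereafter, "FAST -A");
#' `a_posteriori` multiplies the priors into every posterior update
#' ("FAST -p").
#'
#' @param prior_usage `"a_priori"` or `"a_posteriori"`; ignored without priors.
#' @param mrf_beta Potts smoothing weight for the optional ICM regularization;
#'   default 0 (off). EM log-likelihood monotonicity is only guaranteed at 0.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood change for convergence.
#' @param pure_threshold PVE treated as "pure" tissue (\eqn{\ge} threshold).
#' @return a `seg_config` list.
#' @export
seg_config <- function(prior_usage = c("a_posteriori", "a_priori"),
                       mrf_beta = 0, max_iter = 200L, tol = 1e-6,
                       pure_threshold = 0.999) {
  prior_usage <- match.arg(prior_usage)
  if (mrf_beta < 0) stop("mrf_beta must be >= 0")
  structure(list(prior_usage = prior_usage, mrf_beta = mrf_beta,
                 max_iter = as.integer(max_iter), tol = tol,
                 pure_threshold = pure_threshold), class = "seg_config")
}

log_dnorm <- function(y, mu, sigma) {
  -0.5 * log(2 * pi) - log(sigma) - 0.5 * ((y - mu) / sigma)^2
}

#' Gaussian-mixture EM tissue classification
#'
#' Three-class (OM/GM/WM) Gaussian mixture fitted by expectation maximization
#' on the in-mask intensities; the PVE is the final posterior probability
#' (soft assignment). Without priors, class means are initialized at the
#' 25th/50th/75th intensity percentiles (OM/GM/WM, consistent with T1
#' contrast). With priors, the `a_priori` mode seeds the responsibilities with
#' the prior maps and then proceeds with flat spatial priors (global mixing
#' weights only); the `a_posteriori` mode keeps the prior maps in every
#' E-step. Classes are reported in increasing-mean order (OM < GM < WM).
#'
#' @param volume an `agetpl_volume` of intensities.
#' @param mask binary `agetpl_volume`; segmentation is restricted to it.
#' @param priors an `agetpl_pve` of spatial priors on the same grid (e.g.
#'   warped template priors), or NULL for prior-free segmentation.
#' @param config a [seg_config()].
#' @return a `seg_result` list: `pve` (an `agetpl_pve`), `class_means`,
#'   `class_sds`, `mixing`, `loglik_trace`, `n_iter`, `converged`.
#' @export
segment_em <- function(volume, mask, priors = NULL, config = seg_config()) {
  stopifnot_same_grid(volume, mask)
  idx <- which(mask$data > 0)
  if (length(idx) == 0L) stop("mask is empty")
  y <- volume$data[idx]
  K <- 3L
  if (length(unique(round(y, 8))) < K)
    stop("fewer distinct intensities than classes")
  sd_floor <- max(1e-3, 1e-4 * diff(range(y)))

  P <- NULL
  if (!is.null(priors)) {
    if (!same_grid(priors$om, volume))
      priors <- resample_pve(priors, grid_of(volume))
    P <- pve_matrix(priors, idx)
    s <- rowSums(P)
    bad <- s <= 0
    if (any(bad)) {
      message(sprintf("segment_em: %d in-mask voxels have zero prior mass; using flat priors there", sum(bad)))
      P[bad, ] <- 1 / K
      s[bad] <- 1
    }
    P <- P / s
  }

  # initialization: percentile-seeded 1D k-means centers (deterministic,
  # ordering-consistent with T1 contrast: OM < GM < WM)
  if (is.null(P)) {
    mu <- kmeans1d(y, K)
    sg <- rep(max(sd(y) / 3, sd_floor), K)
    w <- rep(1 / K, K)
    R <- NULL
  } else {
    R <- P
    nk <- pmax(colSums(R), 1e-12)
    mu <- colSums(R * y) / nk
    sg <- pmax(sqrt(colSums(R * (outer(y, mu, "-")^2)) / nk), sd_floor)
    w <- colMeans(R)
  }
  use_spatial <- !is.null(P) && config$prior_usage == "a_posteriori"

  loglik <- numeric(0)
  for (it in seq_len(config$max_iter)) {
    lp <- vapply(1:K, function(k) log_dnorm(y, mu[k], sg[k]), numeric(length(y)))
    lpri <- if (use_spatial) log(pmax(P, 1e-300)) else
      matrix(log(pmax(w, 1e-300)), length(y), K, byrow = TRUE)
    lj <- lp + lpri
    m <- apply(lj, 1, max)
    R <- exp(lj - m)
    rs <- rowSums(R)
    ll <- sum(m + log(rs))
    R <- R / rs
    if (use_spatial) {
      # a zero spatial prior annihilates the posterior exactly
      R[P == 0] <- 0
      R <- R / pmax(rowSums(R), 1e-300)
    }
    if (config$mrf_beta > 0)
      R <- mrf_icm_step(R, idx, dim(volume$data), config$mrf_beta)
    nk <- pmax(colSums(R), 1e-12)
    mu <- colSums(R * y) / nk
    sg <- pmax(sqrt(colSums(R * (outer(y, mu, "-")^2)) / nk), sd_floor)
    w <- nk / length(y)
    loglik <- c(loglik, ll)
    if (it > 1 && abs(ll - loglik[it - 1]) <= config$tol * abs(loglik[it - 1]))
      break
  }
  converged <- it < config$max_iter ||
    (it > 1 && abs(loglik[it] - loglik[it - 1]) <= config$tol * abs(loglik[it - 1]))

  # Prior-free runs fix class identity by intensity order (OM < GM < WM on
  # T1); with priors the class identity comes from the prior maps themselves.
  if (is.null(priors)) {
    ord <- order(mu)
    R <- R[, ord, drop = FALSE]
    mu <- mu[ord]; sg <- sg[ord]; w <- w[ord]
  }

  mk <- function(k) {
    a <- array(0, dim(volume$data))
    a[idx] <- R[, k]
    as_volume(a, volume$affine)
  }
  pve <- pve_map(mk(1), mk(2), mk(3), mask)
  structure(list(pve = pve,
                 class_means = stats::setNames(mu, PVE_CLASSES),
                 class_sds = stats::setNames(sg, PVE_CLASSES),
                 mixing = stats::setNames(w, PVE_CLASSES),
                 loglik_trace = loglik, n_iter = it, converged = converged),
            class = "seg_result")
}

#' @export
print.seg_result <- function(x, ...) {
  cat(sprintf("<seg_result> %d EM iterations (%s), means om/gm/wm = %.1f/%.1f/%.1f\n",
              x$n_iter, if (x$converged) "converged" else "max_iter",
              x$class_means[1], x$class_means[2], x$class_means[3]))
  invisible(x)
}

# one ICM-style Potts smoothing pass: multiply responsibilities by
# exp(beta * mean 6-neighborhood responsibility) and renormalize.
mrf_icm_step <- function(R, idx, dims, beta) {
  full <- matrix(0, prod(dims), ncol(R))
  full[idx, ] <- R
  for (k in seq_len(ncol(R))) {
    a <- array(full[, k], dims)
    nb <- gauss_smooth(a, 0.8)   # compact smooth surrogate of the 6-neighborhood mean
    full[, k] <- full[, k] * exp(beta * as.numeric(nb))
  }
  Rn <- full[idx, , drop = FALSE]
  Rn / pmax(rowSums(Rn), 1e-300)
}

#' Hard classification of a PVE map
#'
#' Per-voxel argmax class; ties broken toward the lowest class in the fixed
#' order OM < GM < WM. Voxels outside the mask get the background label 0.
#'
#' @param pve an `agetpl_pve`.
#' @return an `agetpl_volume` of integer labels (0 background, 1 OM, 2 GM,
#'   3 WM).
#' @export
classify_hard <- function(pve) {
  d <- dim(pve$mask$data)
  m <- pve$mask$data > 0
  out <- array(0L, d)
  if (any(m)) {
    p <- pve_matrix(pve, m)
    out[m] <- max.col(p, ties.method = "first")
  }
  as_volume(out, pve$mask$affine)
}
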