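# Independent oracles and small constructors shared across test files.

# exhaustive grid-search maximum-likelihood oracle for small Gaussian
# mixtures: equal weights, common known sigma, one mean grid per class
grid_search_mixture <- function(y, grids, sigma) {
  all_mu <- sort(unique(unlist(grids)))
  D <- vapply(all_mu, function(m) dnorm(y, m, sigma), numeric(length(y)))
  best <- list(loglik = -Inf, mu = NULL)
  combos <- do.call(expand.grid, grids)
  combos <- combos[apply(combos, 1, function(m) all(diff(as.numeric(m)) > 0)), ,
                   drop = FALSE]
  for (i in seq_len(nrow(combos))) {
    mu <- as.numeric(combos[i, ])
    dens <- rowMeans(D[, match(mu, all_mu), drop = FALSE])
    ll <- sum(log(dens))
    if (ll > best$loglik) best <- list(loglik = ll, mu = mu)
  }
  best
}

as_vol1d <- function(y) {
  d <- c(length(y), 1L, 1L)
  as_volume(array(y, d), centered_affine(d, 1))
}

mask_like <- function(vol) {
  as_volume(array(1, dim(vol$data)), vol$affine)
}
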