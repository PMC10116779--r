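# Independent oracles used to cross-check the index and raking code paths.

# Erreygers index computed from the concentration-curve definition:
# order categories most-deprived-first, build the weighted concentration
# curve through the grouped cumulative points, and integrate it by
# trapezoids: C = 1 - sum (p_k - p_{k-1}) (L_k + L_{k-1}), then rescale by
# 4*mu/(b-a). No covariance is computed anywhere on this path.
cci_curve_oracle <- function(y, levels, w = rep(1, length(y)), bounds = c(0, 1)) {
  f <- if (is.factor(levels)) levels else factor(levels, levels = sort(unique(levels)))
  cat_order <- rev(levels(f)) # most deprived first
  w_cat <- vapply(cat_order, function(l) sum(w[f == l]), numeric(1))
  yw_cat <- vapply(cat_order, function(l) sum((w * y)[f == l]), numeric(1))
  keep <- w_cat > 0
  p <- cumsum(w_cat[keep]) / sum(w_cat)
  L <- cumsum(yw_cat[keep]) / sum(yw_cat)
  p0 <- c(0, head(p, -1)); L0 <- c(0, head(L, -1))
  C <- 1 - sum((p - p0) * (L + L0))
  mu <- sum(w * y) / sum(w)
  4 * mu * C / (bounds[2] - bounds[1])
}

# Brute-force 2-margin iterative proportional fitting on a contingency
# table of cell weights; plain loop, no shared code with rake().
ipf_oracle <- function(cells, row_targets, col_targets, iters = 1000) {
  for (i in seq_len(iters)) {
    cells <- cells * (row_targets / (rowSums(cells) / sum(cells)))
    cells <- cells * rep(col_targets / (colSums(cells) / sum(cells)),
                         each = nrow(cells))
  }
  cells
}

# Shapley values by explicit averaging over all m! elimination orderings.
shapley_permutation_oracle <- function(di, m) {
  perms <- permutations_of(seq_len(m))
  phi <- numeric(m)
  for (ord in perms) {
    mask <- 0L
    for (k in ord) {
      before <- di[mask + 1]
      mask <- mask + bitwShiftL(1L, k - 1L)
      phi[k] <- phi[k] + (di[mask + 1] - before)
    }
  }
  phi / length(perms)
}

permutations_of <- function(x) {
  if (length(x) == 1) return(list(x))
  unlist(lapply(seq_along(x), function(i) {
    lapply(permutations_of(x[-i]), function(p) c(x[i], p))
  }), recursive = FALSE)
}
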