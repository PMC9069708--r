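# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# model admittance of the three-element patch circuit (uS; R MOhm, C pF)
rc_admittance <- function(f, rs, rm, cm) {
  w <- 2 * pi * f
  1 / (rs + rm / (1 + 1i * w * rm * cm * 1e-6))
}

# brute-force least-squares solve of (rs, rm, cm) from an admittance pair
# by iterated grid refinement around a starting center
rc_grid_solve <- function(y1, y2, f1, f2, center, rel_range = 0.5,
                          stages = 6, points = 11) {
  ctr <- center
  r <- rel_range
  for (s in seq_len(stages)) {
    grid <- expand.grid(
      rs = ctr[1] * seq(1 - r, 1 + r, length.out = points),
      rm = ctr[2] * seq(1 - r, 1 + r, length.out = points),
      cm = ctr[3] * seq(1 - r, 1 + r, length.out = points))
    d1 <- rc_admittance(f1, grid$rs, grid$rm, grid$cm) - y1
    d2 <- rc_admittance(f2, grid$rs, grid$rm, grid$cm) - y2
    rss <- Mod(d1)^2 + Mod(d2)^2
    best <- which.min(rss)
    ctr <- as.numeric(grid[best, ])
    r <- r / 5
  }
  ctr
}

# exhaustive hypergeometric upper tail: enumerate every subset of the
# universe of size |hits| and count those overlapping the category by at
# least the observed amount (only viable for small universes)
hyper_enum_p <- function(hits, category, universe) {
  obs <- length(intersect(hits, category))
  draws <- utils::combn(universe, length(hits), simplify = FALSE)
  mean(vapply(draws,
              function(d) length(intersect(d, category)) >= obs,
              logical(1)))
}

# literal step-down Sidak definition, element by element
holm_sidak_literal <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (k in seq_len(m)) {
    j <- ord[k]
    running <- max(running, 1 - (1 - p[j])^(m - k + 1))
    adj[j] <- min(1, running)
  }
  adj
}

# tiny DEG-table stub for the set-logic tests
deg_stub <- function(genes, status, log2fc = NULL) {
  if (is.null(log2fc)) {
    log2fc <- ifelse(status == "down", -2, ifelse(status == "up", 2, 0))
  }
  tibble::tibble(gene_symbol = genes, log2fc = log2fc,
                 status = factor(status,
                                 levels = c("up", "down", "ns",
                                            "not_expressed")))
}
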