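# Shared fixtures: small balanced trials built in code, and a
# from-definition sums-of-squares oracle independent of the lm-based
# engine.

# balanced g x 2 x r single-trait table; `values` (optional) must be in
# the row order of expand.grid(block, treatment, accession)
make_mini_trial <- function(g = 2, r = 2, trait = "ssc", values = NULL,
                            seed = NULL, classes = NULL) {
  ids <- sprintf("A%02d", seq_len(g))
  grid <- expand.grid(block = seq_len(r), treatment = c("LN", "HN"),
                      accession = ids, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  if (is.null(values)) {
    if (!is.null(seed)) set.seed(seed)
    values <- rnorm(nrow(grid), 5, 1)
  }
  cls <- if (is.null(classes)) rep("local", g) else classes
  df <- data.frame(accession = grid$accession,
                   class = cls[match(grid$accession, ids)],
                   treatment = grid$treatment, block = grid$block,
                   trait = trait, value = values,
                   stringsAsFactors = FALSE)
  trial_table(df)
}

# data matrix whose sample correlation equals a target matrix exactly:
# whiten an arbitrary draw, then colour it with the Cholesky factor
exact_corr_data <- function(C, n = 60, seed = 2) {
  set.seed(seed)
  p <- ncol(C)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X, center = TRUE, scale = FALSE)
  W <- solve(t(chol(cov(X))))
  Z <- X %*% t(W)         # identity sample covariance
  M <- Z %*% chol(C)
  colnames(M) <- paste0("t", seq_len(p))
  M
}

# from-definition ANOVA sums of squares for the balanced additive-block
# bifactorial layout: explicit sums over marginal and cell means
ss_oracle <- function(df) {
  y <- df$value
  gm <- mean(y)
  gi <- tapply(y, df$accession, mean)
  nj <- tapply(y, df$treatment, mean)
  bk <- tapply(y, df$block, mean)
  cell <- tapply(y, list(df$accession, df$treatment), mean)
  g <- length(gi); d <- length(nj); r <- length(bk)
  dev <- sweep(sweep(cell, 1, gi), 2, nj) + gm
  ss <- c(block = g * d * sum((bk - gm)^2),
          G = d * r * sum((gi - gm)^2),
          N = g * r * sum((nj - gm)^2),
          GxN = r * sum(dev^2))
  ss["residual"] <- sum((y - gm)^2) - sum(ss)
  ss
}
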