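# Independent oracles and small fixture builders. Oracles deliberately use
# naive element-wise formulations so they share no code path with the
# package implementations they check.

# per-sample dot product, element by element
oracle_scores <- function(meth, weights) {
  vapply(rownames(meth), function(s) {
    tot <- 0
    for (cg in names(weights)) tot <- tot + weights[[cg]] * meth[s, cg]
    tot
  }, numeric(1))
}

# per-column residuals via explicitly solved normal equations
oracle_residuals <- function(Y, X) {
  D <- cbind(1, as.matrix(X))
  DtD <- t(D) %*% D
  out <- Y
  for (j in seq_len(ncol(Y))) {
    beta <- solve(DtD, t(D) %*% Y[, j])
    out[, j] <- Y[, j] - drop(D %*% beta)
  }
  out
}

# O(n^2) pairwise Mann-Whitney AUC with half-credit ties
oracle_auc <- function(score, label) {
  pos <- score[label]; neg <- score[!label]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# full OLS report from hand-rolled (X'X)^-1 X'y algebra
oracle_ols <- function(y, X) {
  D <- cbind(1, as.matrix(X))
  n <- nrow(D); p <- ncol(D) - 1L
  XtXinv <- solve(t(D) %*% D)
  beta <- drop(XtXinv %*% t(D) %*% y)
  res <- y - drop(D %*% beta)
  rss <- sum(res^2); tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p - 1)
  se <- sqrt(diag(XtXinv) * sigma2)
  r2 <- 1 - rss / tss
  list(beta = beta, se = se,
       p = 2 * pt(abs(beta / se), n - p - 1, lower.tail = FALSE),
       r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1))
}

rand_meth <- function(n, cpgs, beta_scale = TRUE) {
  m <- matrix(if (beta_scale) runif(n * length(cpgs)) else
    rnorm(n * length(cpgs)), nrow = n,
    dimnames = list(sprintf("s%04d", seq_len(n)), cpgs))
  m
}

write_coef_file <- function(df) {
  f <- tempfile(fileext = ".tsv")  # session tempdir, removed at exit
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

# minimal nested two-set family on disk
tiny_family_file <- function() {
  write_coef_file(data.frame(
    cpg = c("cg1", "cg1", "cg2"),
    weight = c(2, 2.1, -1),
    set = c("a", "b", "b")))
}

# small parents-only simulation config used across tests
fast_config <- function(...) {
  sim_config(cohorts = "parents", background_cpgs = 0, ...)
}
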