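# Naive dense-matrix REML evaluation and BLUP solve, used as an
# independent oracle in the test suite.  Builds the full n x n marginal
# covariance V = Zs (A (x) Gs) Zs' + Zd (I (x) Gd) Zd' + R and evaluates
#   l_R = -1/2 [ (n-p) log 2pi + log|V| + log|X'V^-1 X| + y'Py ]
# directly; only suitable for small instances.

reml_loglik_dense <- function(records, components,
                              mode = c("heterogeneous", "homogeneous"),
                              sire_relationship = NULL, trait = "yield") {
  mode <- match.arg(mode)
  comp <- normalize_components(components, mode)
  dd <- dense_design(records, mode, trait)
  V <- dense_V(dd, comp, sire_relationship)
  X <- dd$X
  y <- dd$y
  n <- length(y)
  p <- ncol(X)
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  XtViX <- XtVi %*% X
  beta <- solve(XtViX, XtVi %*% y)
  r <- y - X %*% beta
  yPy <- drop(t(r) %*% Vi %*% r)
  ldV <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  ldX <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
  -0.5 * ((n - p) * log(2 * pi) + ldV + ldX + yPy)
}

# Dense BLUP of the sire effects: u_s = (A (x) Gs) Zs' V^-1 (y - X beta)
blup_dense <- function(records, components,
                       mode = c("heterogeneous", "homogeneous"),
                       sire_relationship = NULL, trait = "yield") {
  mode <- match.arg(mode)
  comp <- normalize_components(components, mode)
  dd <- dense_design(records, mode, trait)
  V <- dense_V(dd, comp, sire_relationship)
  Vi <- solve(V)
  XtVi <- t(dd$X) %*% Vi
  beta <- solve(XtVi %*% dd$X, XtVi %*% dd$y)
  resid <- dd$y - dd$X %*% beta
  q <- length(dd$sire_levels)
  Aq <- if (is.null(sire_relationship)) diag(q)
        else sire_relationship[dd$sire_levels, dd$sire_levels]
  Gbig <- kronecker(Aq, comp$Gs)
  u <- Gbig %*% t(dd$Zs) %*% Vi %*% resid
  list(beta = drop(beta),
       u = matrix(u, ncol = 2, byrow = TRUE,
                  dimnames = list(dd$sire_levels, c("gp", "es"))))
}

dense_design <- function(records, mode, trait) {
  prep <- prep_reml_data(records, mode, trait = trait)
  n <- length(prep$y)
  q <- length(prep$sire_levels)
  sire_rec <- rep(prep$d_sire, diff(prep$d_start)) + 1L
  Zs <- matrix(0, n, 2 * q)
  for (i in seq_len(n)) {
    j <- sire_rec[i]
    Zs[i, 2 * j - 1] <- 1
    Zs[i, 2 * j] <- prep$records$env[i]
  }
  nd <- length(prep$d_sire)
  qd <- ncol(prep$Wd)
  Zd <- matrix(0, n, qd * nd)
  for (i in seq_len(nd)) {
    rows <- (prep$d_start[i] + 1L):prep$d_start[i + 1L]
    Zd[rows, (qd * (i - 1) + 1):(qd * i)] <- prep$Wd[rows, , drop = FALSE]
  }
  list(y = prep$y, X = prep$X, Zs = Zs, Zd = Zd,
       rclass = prep$rclass, sire_levels = prep$sire_levels, nd = nd, qd = qd)
}

dense_V <- function(dd, comp, sire_relationship) {
  q <- length(dd$sire_levels)
  Aq <- if (is.null(sire_relationship)) diag(q)
        else sire_relationship[dd$sire_levels, dd$sire_levels]
  Gs_big <- kronecker(Aq, comp$Gs)
  Gd_big <- kronecker(diag(dd$nd), comp$Gd)
  R <- diag(comp$sigma2_e[dd$rclass], length(dd$y))
  dd$Zs %*% Gs_big %*% t(dd$Zs) + dd$Zd %*% Gd_big %*% t(dd$Zd) + R
}
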