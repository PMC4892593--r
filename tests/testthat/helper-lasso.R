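# x on the sample-by-gene orientation, standardized the way the penalised
# fit standardizes (population SD), for checking optimality conditions.
std_design <- function(gm) {
  x <- t(gm$values)
  sdn <- apply(x, 2, function(c) sqrt(mean((c - mean(c))^2)))
  list(x = x, xs = scale(x, TRUE, sdn), sdn = sdn,
       y = as.integer(gm$labels == "case"))
}

# Penalised objective in standardized coordinates.
l1_objective <- function(a, b, xs, y, lam)
  mean(log1p(exp(-(2 * y - 1) * (a + xs %*% b)))) + lam * sum(abs(b))

# Generic convex solver for the same objective: split beta into positive and
# negative parts, smooth bound-constrained problem, L-BFGS-B.
l1_oracle_optim <- function(xs, y, lam) {
  p <- ncol(xs); n <- nrow(xs)
  f <- function(th) {
    a <- th[1]; b <- th[2:(p + 1)] - th[(p + 2):(2 * p + 1)]
    mean(log1p(exp(-(2 * y - 1) * (a + xs %*% b)))) +
      lam * sum(th[-1])
  }
  gr <- function(th) {
    a <- th[1]; b <- th[2:(p + 1)] - th[(p + 2):(2 * p + 1)]
    pr <- stats::plogis(a + xs %*% b)
    gb <- as.vector(crossprod(xs, pr - y)) / n
    c(mean(pr - y), gb + lam, -gb + lam)
  }
  stats::optim(rep(0, 2 * p + 1), f, gr, method = "L-BFGS-B",
               lower = c(-Inf, rep(0, 2 * p)),
               control = list(maxit = 2000, factr = 1e4))$value
}
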