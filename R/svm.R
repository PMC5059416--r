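# Linear L2-regularized squared-hinge SVM, solved in the primal by Newton
# iteration with Armijo backtracking. The feature dimension is small (tens)
# while n can reach hundreds of thousands, so each Newton step costs O(n d)
# for the active-set gradient plus an O(d^3) solve.
#
# minimize_w  0.5 ||w||^2 + sum_i C_i * max(0, 1 - y_i x_i' w)^2
#
# X must already contain the bias column; C is a per-row cost vector.
svm_l2_primal <- function(X, y, C, w0 = NULL, max_iter = 100L, tol = 1e-8) {
  d <- ncol(X)
  w <- if (is.null(w0)) numeric(d) else w0
  yC <- y * C
  obj <- function(w, m) 0.5 * sum(w^2) + sum(C[m > 0] * m[m > 0]^2)
  m <- 1 - y * drop(X %*% w)
  f <- obj(w, m)
  for (iter in seq_len(max_iter)) {
    act <- which(m > 0)
    g <- w - 2 * drop(crossprod(X[act, , drop = FALSE], yC[act] * m[act]))
    if (sqrt(sum(g^2)) < tol * max(1, sqrt(sum(w^2)))) break
    Xa <- X[act, , drop = FALSE] * sqrt(C[act])
    H <- diag(d) + 2 * crossprod(Xa)
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    t_ls <- 1
    repeat {
      w_new <- w - t_ls * step
      m_new <- 1 - y * drop(X %*% w_new)
      f_new <- obj(w_new, m_new)
      if (f_new <= f - 1e-4 * t_ls * sum(g * step) || t_ls < 1e-8) break
      t_ls <- t_ls / 2
    }
    if (f - f_new < tol * max(1, abs(f))) {
      w <- w_new; m <- m_new; f <- f_new
      break
    }
    w <- w_new; m <- m_new; f <- f_new
  }
  w
}
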