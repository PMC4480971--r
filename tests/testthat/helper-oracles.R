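# Independent NIPALS oracle: predictions built in score space
# (t = X w, deflate, yhat = ybar + sum_a t_a q_a), not via composite
# regression coefficients, so it exercises a different algebraic route
# than the implementation under test.
nipals_oracle_predict <- function(X, y, Xnew, ncomp = 2) {
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  Xs <- scale(X, ctr, scl); ybar <- mean(y); yd <- y - ybar
  Xn <- scale(Xnew, ctr, scl)
  pred <- rep(ybar, nrow(Xn))
  for (a in seq_len(ncomp)) {
    w <- drop(t(Xs) %*% yd); w <- w / sqrt(sum(w^2))
    t_a <- drop(Xs %*% w); tt <- sum(t_a^2)
    p_a <- drop(t(Xs) %*% t_a) / tt
    q_a <- sum(yd * t_a) / tt
    t_new <- drop(Xn %*% w)
    pred <- pred + t_new * q_a
    Xs <- Xs - outer(t_a, p_a); yd <- yd - t_a * q_a
    Xn <- Xn - outer(t_new, p_a)
  }
  pred
}
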