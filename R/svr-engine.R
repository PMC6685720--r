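# Internal nu-SVR engine.
#
# Model fitting is delegated to libsvm. The hot loops (leave-one-out
# refits inside permutation tests) call e1071's registered native routine
# `svmtrain` directly with preassembled arguments, bypassing the R-level
# preprocessing of `e1071::svm()` (~20x faster, identical coefficients;
# verified against the public interface in the test suite). If the symbol
# cannot be resolved, the slow path through `e1071::svm()` is used.

.svr_engine <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  assign("svmtrain_sym", resolve_svmtrain(), envir = .svr_engine)
  invisible()
}

resolve_svmtrain <- function() {
  tryCatch({
    loadNamespace("e1071")   # ensures the shared library is loaded
    getNativeSymbolInfo("svmtrain", PACKAGE = "e1071")
  }, error = function(e) NULL)
}

# Fit a linear nu-SVR on pre-transposed training data.
# xt: p x m matrix (t of the m x p training matrix); y: length-m response.
# Returns index (1-based rows of the training set that are support
# vectors), coefs (their dual coefficients), rho (so that
# prediction = x . w - rho), and n_sv.
nusvr_fit_raw <- function(xt, y, nu, cost) {
  m <- length(y)
  sym <- get0("svmtrain_sym", envir = .svr_engine, ifnotfound = NULL)
  if (is.null(sym)) {
    sym <- resolve_svmtrain()
    assign("svmtrain_sym", sym, envir = .svr_engine)
  }
  if (is.null(sym)) {
    fit <- e1071::svm(t(xt), y, type = "nu-regression", kernel = "linear",
                      nu = nu, cost = cost, scale = FALSE, fitted = FALSE)
    return(list(index = fit$index, coefs = as.numeric(fit$coefs),
                rho = fit$rho, n_sv = fit$tot.nSV))
  }
  err <- paste(rep(" ", 255), collapse = "")
  cret <- .C(sym,
             as.double(xt), as.integer(m), as.integer(nrow(xt)),
             as.double(y),
             as.integer(0L), as.integer(0L),     # sparse ia/ja (unused)
             as.integer(4L),                     # type: nu-regression
             as.integer(0L),                     # kernel: linear
             as.integer(3L), as.double(0), as.double(0),  # degree/gamma/coef0
             as.double(cost), as.double(nu),
             as.integer(0L), as.double(0), as.integer(0L),  # class weights
             as.double(40), as.double(0.001), as.double(0.1),
             as.integer(1L),                     # shrinking
             as.integer(0L), as.integer(0L), as.integer(0L),
             nclasses = integer(1), nr = integer(1), index = integer(m),
             labels = integer(2), nSV = integer(2), rho = double(1),
             coefs = double(m), sigma = double(1), probA = double(1),
             probB = double(1), cresults = double(0), ctotal1 = double(1),
             ctotal2 = double(1), error = err)
  if (cret$error != err) stop(trimws(cret$error))
  nsv <- cret$nr
  list(index = cret$index[seq_len(nsv)],
       coefs = cret$coefs[seq_len(nsv)],
       rho = cret$rho[1], n_sv = nsv)
}

# Primal weight vector of a linear fit: w = sum_i coef_i * x_i over SVs.
nusvr_weights_from_fit <- function(fit, xt) {
  drop(xt[, fit$index, drop = FALSE] %*% fit$coefs)
}

# Precomputed leave-one-out context.
#
# A linear kernel only sees dot products, so when p > n the rows are
# projected onto an exact rank-n orthogonal basis (thin SVD: Z = U D,
# X = Z V' with V orthonormal). ZZ' equals XX', hence every fold's dual
# solution, predictions and support vectors are identical, but each fit
# runs in n dimensions instead of p. Primal weights are mapped back via
# w_x = V w_z.
loo_context <- function(X) {
  n <- nrow(X)
  if (ncol(X) > n) {
    sv <- svd(X, nu = n, nv = n)
    Z <- sv$u * rep(sv$d, each = n)
    V <- sv$v
  } else {
    Z <- X
    V <- NULL
  }
  fold_zts <- lapply(seq_len(n), function(i) t(Z[-i, , drop = FALSE]))
  list(Z = Z, V = V, fold_zts = fold_zts, n = n, p = ncol(X))
}

# Leave-one-out predictions over a precomputed context.
# Returns out-of-fold predictions and (optionally) per-fold primal
# weights in the original p-dimensional feature space.
loo_core <- function(ctx, y, nu, cost, want_weights = TRUE) {
  n <- ctx$n
  pred <- numeric(n)
  n_sv <- integer(n)
  Wz <- if (want_weights) matrix(0, n, ncol(ctx$Z)) else NULL
  for (i in seq_len(n)) {
    fit <- nusvr_fit_raw(ctx$fold_zts[[i]], y[-i], nu, cost)
    w <- nusvr_weights_from_fit(fit, ctx$fold_zts[[i]])
    pred[i] <- sum(w * ctx$Z[i, ]) - fit$rho
    n_sv[i] <- fit$n_sv
    if (want_weights) Wz[i, ] <- w
  }
  W <- if (!want_weights) NULL
       else if (is.null(ctx$V)) Wz
       else Wz %*% t(ctx$V)
  list(predicted = pred, weights = W, n_sv = n_sv)
}
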