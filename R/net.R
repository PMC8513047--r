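# Two-layer feedforward pattern-recognition network trained by
# Levenberg-Marquardt with Bayesian regularization (the MacKay evidence
# framework). The objective is F = beta * E_D + alpha * E_W with E_D the sum
# of squared output errors against one-hot targets and E_W the sum of
# squared weights; after every accepted LM step the hyperparameters are
# re-estimated from the effective number of parameters
#   gamma = N_w - 2 * alpha * tr(H^-1),  alpha = gamma / (2 E_W),
#   beta  = (N_t - gamma) / (2 E_D),
# with H = 2 * beta * J'J + 2 * alpha * I (Gauss-Newton curvature). No
# validation subset is held out: regularization replaces early stopping.

#' Control parameters for [grain_net()]
#'
#' @param mu0 Initial Levenberg-Marquardt damping (default 0.005).
#' @param mu_factor Multiplicative damping update (default 10).
#' @param mu_max Damping overflow bound; training stops above it.
#' @param max_epochs Maximum accepted LM steps (default 300).
#' @param grad_tol Infinity-norm gradient stopping tolerance (default 1e-7).
#' @param mse_tol Training-MSE floor; fits saturated below it stop early
#'   (default 1e-10).
#' @param lr,momentum Learning rate and momentum for the gradient-descent
#'   baseline (`algorithm = "gdm"`).
#' @return A list of control parameters.
#' @export
grain_net_control <- function(mu0 = 0.005, mu_factor = 10, mu_max = 1e10,
                              max_epochs = 300, grad_tol = 1e-7,
                              mse_tol = 1e-10, lr = 0.01, momentum = 0.9) {
  list(mu0 = mu0, mu_factor = mu_factor, mu_max = mu_max,
       max_epochs = max_epochs, grad_tol = grad_tol, mse_tol = mse_tol,
       lr = lr, momentum = momentum)
}

#' Fit a grain classification network
#'
#' Trains a 9-input (or general p-input), one-hidden-layer, K-output
#' feedforward network with tanh hidden units and logistic output units.
#' Inputs are standardized by the training-set center and scale; targets are
#' one-hot class indicators. The default trainer is Levenberg-Marquardt with
#' Bayesian regularization (`"br"`); `"gdm"` is a plain full-batch
#' gradient-descent-with-momentum baseline.
#'
#' @param formula Model formula, e.g. `class_id ~ .`; the response is the
#'   class label, all other referenced columns are numeric features.
#' @param data Data frame holding features and labels.
#' @param n_hidden Hidden-layer size (default 10).
#' @param algorithm `"br"` (Bayesian regularization, default) or `"gdm"`.
#' @param seed Integer seed controlling weight initialization (training is
#'   deterministic given the seed).
#' @param control See [grain_net_control()].
#' @return Object of class `grain_net` with weight matrices `W1`
#'   (n_hidden x p), `b1`, `W2` (K x n_hidden), `b2`, standardization
#'   constants `input_center`/`input_scale`, hyperparameters `alpha`,
#'   `beta`, `gamma`, the class-id map `classes`, and a per-epoch `trace`.
#' @examples
#' tab <- sample_feature_table(read_class_specs()[1:3], 30, seed = 1, sd_scale = 0.1)
#' fit <- grain_net(class_id ~ ., tab, n_hidden = 3, seed = 1)
#' mean(predict(fit, tab) == tab$class_id)
#' @export
grain_net <- function(formula, data, n_hidden = 10,
                      algorithm = c("br", "gdm"), seed = NULL,
                      control = grain_net_control()) {
  algorithm <- match.arg(algorithm)
  stopifnot(n_hidden >= 1)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- mf[[1]]
  X <- as.matrix(mf[, -1, drop = FALSE])
  if (!is.numeric(X)) stop("all features must be numeric")
  if (any(!is.finite(X))) stop("non-finite feature values")
  classes <- sort(unique(as.vector(y)))
  if (length(classes) < 2) stop("need at least 2 classes to train")
  Tmat <- outer(as.vector(y), classes, `==`) * 1

  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  p <- ncol(X); K <- length(classes); N <- nrow(X); h <- n_hidden
  Nw <- h * (p + 1) + K * (h + 1)
  if (Nw >= N)
    warning("over-parameterized network: ", Nw, " weights for ", N, " rows")

  w0 <- with_seed(seed, init_weights(p, h, K))
  fit <- if (algorithm == "br") {
    br_lm_train(Xs, Tmat, w0, p, h, K, control)
  } else {
    gdm_train(Xs, Tmat, w0, p, h, K, control)
  }
  wl <- unpack_weights(fit$w, p, h, K)
  structure(list(W1 = wl$W1, b1 = wl$b1, W2 = wl$W2, b2 = wl$b2,
                 input_center = ctr, input_scale = scl,
                 feature_names = colnames(X), classes = classes,
                 n_hidden = h, algorithm = algorithm,
                 alpha = fit$alpha, beta = fit$beta, gamma = fit$gamma,
                 n_weights = Nw, trace = fit$trace,
                 stop_reason = fit$stop_reason, seed = seed,
                 call = match.call()),
            class = "grain_net")
}

# scaled-uniform (Nguyen-Widrow-style) initialization
init_weights <- function(p, h, K) {
  mag <- 0.7 * h^(1 / p)
  W1 <- matrix(runif(h * p, -1, 1), h, p)
  W1 <- W1 / sqrt(rowSums(W1^2)) * mag
  b1 <- runif(h, -mag, mag)
  W2 <- matrix(runif(K * h, -0.5, 0.5), K, h)
  b2 <- rep(0, K)
  pack_weights(W1, b1, W2, b2)
}

pack_weights <- function(W1, b1, W2, b2) c(as.vector(W1), b1, as.vector(W2), b2)

unpack_weights <- function(w, p, h, K) {
  i <- 0
  W1 <- matrix(w[i + seq_len(h * p)], h, p); i <- i + h * p
  b1 <- w[i + seq_len(h)]; i <- i + h
  W2 <- matrix(w[i + seq_len(K * h)], K, h); i <- i + K * h
  b2 <- w[i + seq_len(K)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

net_forward <- function(Xs, w, p, h, K) {
  wl <- unpack_weights(w, p, h, K)
  Z <- tanh(sweep(Xs %*% t(wl$W1), 2, wl$b1, "+"))
  Y <- stats::plogis(sweep(Z %*% t(wl$W2), 2, wl$b2, "+"))
  list(Z = Z, Y = Y, wl = wl)
}

# Jacobian of the stacked residual vector e = vec(Y - T) (rows ordered
# class-major: all samples of output 1, then output 2, ...) w.r.t. the
# packed weight vector.
net_jacobian <- function(Xs, fw, p, h, K) {
  N <- nrow(Xs)
  Z <- fw$Z; Y <- fw$Y; W2 <- fw$wl$W2
  Zp <- 1 - Z^2
  J <- matrix(0, N * K, h * (p + 1) + K * (h + 1))
  ib1 <- h * p
  iW2 <- h * (p + 1)
  ib2 <- iW2 + K * h
  for (k in seq_len(K)) {
    rows <- (k - 1) * N + seq_len(N)
    Yp <- Y[, k] * (1 - Y[, k])
    Q <- Zp * matrix(W2[k, ], N, h, byrow = TRUE) * Yp   # N x h
    for (j in seq_len(h)) {
      J[rows, (0:(p - 1)) * h + j] <- Q[, j] * Xs        # dW1[j, ]
      J[rows, ib1 + j] <- Q[, j]                         # db1[j]
      J[rows, iW2 + (j - 1) * K + k] <- Yp * Z[, j]      # dW2[k, j]
    }
    J[rows, ib2 + k] <- Yp
  }
  J
}

br_lm_train <- function(Xs, Tmat, w, p, h, K, control) {
  N <- nrow(Xs); Nt <- length(Tmat); Nw <- length(w)
  alpha <- 0; beta <- 1
  mu <- control$mu0
  trace <- list()
  stop_reason <- "max_epochs"

  fw <- net_forward(Xs, w, p, h, K)
  e <- as.vector(fw$Y - Tmat)
  ED <- sum(e^2); EW <- sum(w^2)
  for (epoch in seq_len(control$max_epochs)) {
    if (ED / Nt < control$mse_tol) { stop_reason <- "mse_floor"; break }
    J <- net_jacobian(Xs, fw, p, h, K)
    g <- 2 * beta * crossprod(J, e) + 2 * alpha * w
    if (max(abs(g)) < control$grad_tol) { stop_reason <- "gradient"; break }
    H <- 2 * beta * crossprod(J)
    diag(H) <- diag(H) + 2 * alpha
    F_old <- beta * ED + alpha * EW

    accepted <- FALSE
    while (mu <= control$mu_max) {
      step <- tryCatch(solve(H + diag(mu, Nw), -g), error = function(e) NULL)
      if (!is.null(step)) {
        w_new <- w + as.vector(step)
        fw_new <- net_forward(Xs, w_new, p, h, K)
        e_new <- as.vector(fw_new$Y - Tmat)
        ED_new <- sum(e_new^2); EW_new <- sum(w_new^2)
        F_new <- beta * ED_new + alpha * EW_new
        if (is.finite(F_new) && F_new < F_old) {
          w <- w_new; fw <- fw_new; e <- e_new
          ED <- ED_new; EW <- EW_new
          mu <- max(mu / control$mu_factor, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * control$mu_factor
    }
    if (!accepted) { stop_reason <- "mu_overflow"; break }

    # evidence-framework re-estimation at the accepted point
    J <- net_jacobian(Xs, fw, p, h, K)
    H <- 2 * beta * crossprod(J)
    diag(H) <- diag(H) + 2 * alpha
    trH_inv <- sum(diag(tryCatch(solve(H), error = function(e) diag(1e6, Nw))))
    gamma <- Nw - 2 * alpha * trH_inv
    gamma <- min(max(gamma, 0), Nw)
    alpha <- gamma / max(2 * EW, 1e-12)
    beta <- max(Nt - gamma, 1e-3) / max(2 * ED, 1e-12)

    trace[[length(trace) + 1L]] <- data.frame(
      epoch = epoch, F_old = F_old, F_new = F_new, mse = ED / Nt,
      EW = EW, alpha = alpha, beta = beta, gamma = gamma, mu = mu)
  }
  list(w = w, alpha = alpha, beta = beta, gamma = gamma,
       trace = do.call(rbind, trace), stop_reason = stop_reason)
}

# full-batch gradient descent with momentum on the plain MSE objective
gdm_train <- function(Xs, Tmat, w, p, h, K, control) {
  Nt <- length(Tmat)
  velocity <- numeric(length(w))
  trace <- list()
  stop_reason <- "max_epochs"
  for (epoch in seq_len(control$max_epochs)) {
    fw <- net_forward(Xs, w, p, h, K)
    E <- fw$Y - Tmat
    dY <- 2 * E * fw$Y * (1 - fw$Y)
    gW2 <- t(dY) %*% fw$Z
    gb2 <- colSums(dY)
    dZ <- (dY %*% fw$wl$W2) * (1 - fw$Z^2)
    gW1 <- t(dZ) %*% Xs
    gb1 <- colSums(dZ)
    g <- pack_weights(gW1, gb1, gW2, gb2)
    if (max(abs(g)) < control$grad_tol) { stop_reason <- "gradient"; break }
    velocity <- control$momentum * velocity - control$lr * g / nrow(Xs)
    w <- w + velocity
    if (epoch %% 25 == 0)
      trace[[length(trace) + 1L]] <- data.frame(
        epoch = epoch, F_old = NA, F_new = NA, mse = sum(E^2) / Nt,
        EW = sum(w^2), alpha = NA, beta = NA, gamma = NA, mu = NA)
  }
  list(w = w, alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
       trace = do.call(rbind, trace), stop_reason = stop_reason)
}

#' Predict classes or class scores for new grains
#'
#' @param object A fitted `grain_net`.
#' @param newdata Data frame containing exactly the training feature
#'   columns (the label and bookkeeping columns `class_id`, `grain_id`,
#'   `image_id`, `abbreviation` are tolerated; any other unknown column is
#'   an error, so silent schema drift cannot pass unnoticed).
#' @param type `"class"` for hard labels (argmax with lowest-class-id
#'   tie-break) or `"scores"` for the N x K matrix of output activations in
#'   \[0,1\].
#' @param ... Unused.
#' @return Integer-like vector of class labels, or a score matrix with one
#'   column per class.
#' @export
predict.grain_net <- function(object, newdata, type = c("class", "scores"), ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols))
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
  allowed <- c(object$feature_names, "class_id", "grain_id", "image_id",
               "abbreviation")
  extra <- setdiff(names(newdata), allowed)
  if (length(extra))
    stop("unknown columns in newdata: ", paste(extra, collapse = ", "))
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  Xs <- sweep(sweep(X, 2, object$input_center), 2, object$input_scale, "/")
  Z <- tanh(sweep(Xs %*% t(object$W1), 2, object$b1, "+"))
  Y <- stats::plogis(sweep(Z %*% t(object$W2), 2, object$b2, "+"))
  colnames(Y) <- as.character(object$classes)
  if (type == "scores") return(Y)
  object$classes[apply(Y, 1, which.max)]  # which.max: first (lowest id) wins ties
}

#' @export
print.grain_net <- function(x, ...) {
  cat(sprintf("grain_net: %d-%d-%d feedforward network (%s)\n",
              length(x$input_center), x$n_hidden, length(x$classes),
              if (x$algorithm == "br") "Bayesian regularization"
              else "gradient descent with momentum"))
  cat(sprintf("  %d weights; stop: %s\n", x$n_weights, x$stop_reason))
  if (x$algorithm == "br")
    cat(sprintf("  alpha %.4g  beta %.4g  gamma %.1f (effective parameters)\n",
                x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' @export
summary.grain_net <- function(object, ...) {
  out <- list(model = object,
              final_mse = if (!is.null(object$trace) && nrow(object$trace))
                object$trace$mse[nrow(object$trace)] else NA_real_,
              epochs = if (!is.null(object$trace)) nrow(object$trace) else 0L)
  class(out) <- "summary.grain_net"
  out
}

#' @export
print.summary.grain_net <- function(x, ...) {
  print(x$model)
  cat(sprintf("  epochs %d, final training MSE %.5f\n", x$epochs, x$final_mse))
  invisible(x)
}

#' @export
coef.grain_net <- function(object, ...) {
  list(W1 = object$W1, b1 = object$b1, W2 = object$W2, b2 = object$b2)
}
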