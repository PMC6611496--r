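#' Configuration for the neural-network ensemble
#'
#' A small feed-forward network — one hidden layer of tanh units and a
#' linear output — trained by Levenberg-Marquardt with validation-based
#' early stopping, replicated into a median ensemble. Defaults follow the
#' study design: 5 hidden neurons, 10 ensemble members, per-member random
#' 70:15:15 train/validation/test split, patience of 20 epochs, and
#' Nguyen-Widrow initialization for every member.
#'
#' @param hidden_neurons hidden-layer width (>= 1).
#' @param ensemble_size number of independently trained members (>= 1).
#' @param train_val_test_split three fractions summing to 1.
#' @param patience_epochs epochs without strict validation improvement
#'   before stopping.
#' @param max_epochs hard epoch cap.
#' @param seed master seed; each member derives its own seed stream.
#' @return list of class `mlnn_config`.
#' @export
mlnn_config <- function(hidden_neurons = 5, ensemble_size = 10,
                        train_val_test_split = c(0.70, 0.15, 0.15),
                        patience_epochs = 20, max_epochs = 1000,
                        seed = 1L) {
  stopifnot(hidden_neurons >= 1, ensemble_size >= 1,
            length(train_val_test_split) == 3,
            abs(sum(train_val_test_split) - 1) < 1e-9,
            patience_epochs >= 1, max_epochs >= 1)
  structure(
    list(hidden_neurons = as.integer(hidden_neurons),
         ensemble_size = as.integer(ensemble_size),
         train_val_test_split = train_val_test_split,
         patience_epochs = as.integer(patience_epochs),
         max_epochs = as.integer(max_epochs),
         seed = as.integer(seed)),
    class = "mlnn_config"
  )
}

#' Deterministic sub-seed for a named random stream
#'
#' All pipeline randomness flows from one master seed through named
#' substreams (split, svm, per-member init/split, synthetic); this maps
#' (seed, tag) to a reproducible integer below 2^31.
#'
#' @param seed master integer seed.
#' @param tag stream name.
#' @return derived integer seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Nguyen-Widrow initialization of the hidden layer
#'
#' Each hidden unit's input-weight row is drawn in a random direction and
#' scaled to the magnitude beta = 0.7 * H^(1/n); biases are spread
#' uniformly over [-beta, beta] with alternating sign so the units' active
#' regions tile the input range. The output layer gets small uniform
#' weights.
#'
#' @param n_inputs,n_hidden layer dimensions (>= 1).
#' @param seed integer seed.
#' @return list with `W1` (n_hidden x n_inputs), `b1`, `w2`, `b2`.
#' @export
nguyen_widrow_init <- function(n_inputs, n_hidden, seed) {
  stopifnot(n_inputs >= 1, n_hidden >= 1)
  set.seed(seed)
  beta <- 0.7 * n_hidden^(1 / n_inputs)
  W1 <- matrix(stats::runif(n_hidden * n_inputs, -1, 1), n_hidden, n_inputs)
  norms <- sqrt(rowSums(W1^2))
  norms[norms == 0] <- 1
  W1 <- W1 / norms * beta
  spread <- if (n_hidden == 1) 0 else seq(-1, 1, length.out = n_hidden)
  b1 <- beta * spread * (-1)^(seq_len(n_hidden) + 1)
  list(
    W1 = W1, b1 = b1,
    w2 = stats::runif(n_hidden, -0.5, 0.5),
    b2 = stats::runif(1, -0.5, 0.5)
  )
}

mlnn_forward <- function(w, X) {
  # X: n x p matrix; returns list(a = hidden activations n x H, y = outputs)
  z <- X %*% t(w$W1) + matrix(w$b1, nrow(X), length(w$b1), byrow = TRUE)
  a <- tanh(z)
  list(a = a, y = as.numeric(a %*% w$w2 + w$b2))
}

flatten_weights <- function(w) c(as.numeric(w$W1), w$b1, w$w2, w$b2)

unflatten_weights <- function(theta, n_inputs, n_hidden) {
  i <- n_hidden * n_inputs
  list(
    W1 = matrix(theta[seq_len(i)], n_hidden, n_inputs),
    b1 = theta[i + seq_len(n_hidden)],
    w2 = theta[i + n_hidden + seq_len(n_hidden)],
    b2 = theta[i + 2 * n_hidden + 1]
  )
}

# Jacobian of model outputs wrt parameters, n x p_theta
mlnn_jacobian <- function(w, X, a) {
  n <- nrow(X); H <- length(w$b1)
  d <- (1 - a^2) * matrix(w$w2, n, H, byrow = TRUE)  # n x H: df/dz
  JW1 <- matrix(0, n, H * ncol(X))
  for (j in seq_len(ncol(X))) {
    JW1[, (j - 1) * H + seq_len(H)] <- d * X[, j]
  }
  cbind(JW1, d, a, rep(1, n))
}

#' Levenberg-Marquardt training with validation-based early stopping
#'
#' Damped Gauss-Newton on the sum-of-squares loss. Each epoch performs one
#' accepted parameter update: the step solving (J'J + mu I) delta = J'r is
#' taken if it reduces the training SSE (then mu is decreased); otherwise
#' mu is increased and the step retried. Training stops when the validation
#' MSE has not strictly improved for `patience` consecutive epochs, when
#' `max_epochs` is reached, or when mu exceeds its cap (a converged local
#' minimum if the gradient has vanished; otherwise best-so-far weights are
#' returned with a warning). The weights at the minimum of the validation
#' error are returned.
#'
#' @param weights initial weights, as from [nguyen_widrow_init()].
#' @param X_train,y_train,X_val,y_val training and validation partitions
#'   (matrices / numeric vectors).
#' @param patience early-stopping patience in epochs.
#' @param max_epochs epoch cap.
#' @param mu_init,mu_dec,mu_inc,mu_max damping schedule.
#' @return list with `weights` (validation-optimal), `train_mse`,
#'   `val_mse`, `epoch` (stopping epoch), `best_epoch`, and the per-epoch
#'   `val_trajectory`.
#' @export
train_mlnn_lm <- function(weights, X_train, y_train, X_val, y_val,
                          patience = 20, max_epochs = 1000,
                          mu_init = 1e-3, mu_dec = 0.1, mu_inc = 10,
                          mu_max = 1e10) {
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  n_inputs <- ncol(X_train); n_hidden <- length(weights$b1)
  theta <- flatten_weights(weights)
  p <- length(theta)

  sse <- function(th) {
    w <- unflatten_weights(th, n_inputs, n_hidden)
    sum((y_train - mlnn_forward(w, X_train)$y)^2)
  }
  val_mse_of <- function(th) {
    w <- unflatten_weights(th, n_inputs, n_hidden)
    mean((y_val - mlnn_forward(w, X_val)$y)^2)
  }

  mu <- mu_init
  current_sse <- sse(theta)
  best_val <- val_mse_of(theta)
  best_theta <- theta
  best_epoch <- 0L
  stall <- 0L
  val_traj <- numeric(0)
  epoch <- 0L
  mu_blown <- FALSE

  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    w <- unflatten_weights(theta, n_inputs, n_hidden)
    fw <- mlnn_forward(w, X_train)
    r <- y_train - fw$y
    J <- mlnn_jacobian(w, X_train, fw$a)
    JtJ <- crossprod(J)
    Jtr <- crossprod(J, r)

    accepted <- FALSE
    while (!accepted) {
      delta <- tryCatch(
        solve(JtJ + diag(mu, p), Jtr),
        error = function(e) NULL
      )
      if (!is.null(delta)) {
        cand <- theta + as.numeric(delta)
        cand_sse <- sse(cand)
        if (is.finite(cand_sse) && cand_sse < current_sse) {
          theta <- cand
          current_sse <- cand_sse
          mu <- max(mu * mu_dec, 1e-20)
          accepted <- TRUE
        }
      }
      if (!accepted) {
        mu <- mu * mu_inc
        if (mu > mu_max) break
      }
    }
    if (!accepted) {
      # no descent direction at any damping: converged if the gradient has
      # vanished, otherwise a genuine failure worth reporting
      mu_blown <- max(abs(Jtr)) > 1e-6
      break
    }

    vm <- val_mse_of(theta)
    val_traj <- c(val_traj, vm)
    if (vm < best_val) {
      best_val <- vm
      best_theta <- theta
      best_epoch <- epoch
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  if (mu_blown) {
    warning("Levenberg-Marquardt damping exceeded its cap; ",
            "returning best weights found")
  }

  w_best <- unflatten_weights(best_theta, n_inputs, n_hidden)
  list(
    weights = w_best,
    train_mse = mean((y_train - mlnn_forward(w_best, X_train)$y)^2),
    val_mse = best_val,
    epoch = epoch,
    best_epoch = best_epoch,
    val_trajectory = val_traj
  )
}

#' Fit the median ensemble of small neural networks
#'
#' Each member draws an independent train/validation/test partition of the
#' table and an independent Nguyen-Widrow initialization from its own seed
#' stream, then trains by [train_mlnn_lm()]. The ensemble prediction is the
#' elementwise median of the member predictions. A member whose training
#' fails is recorded; the ensemble is valid while at least half the members
#' trained.
#'
#' @param table normalized data.frame with predictor and target columns.
#' @param config an [mlnn_config()].
#' @param predictors,target column names.
#' @return object of class `mlnn_em` with `members` (weights), `report`
#'   (per-member train/val/test MSE and stopping epoch plus ensemble
#'   summary), `predictors`, `target`, `config`.
#' @export
fit_mlnn_em <- function(table, config = mlnn_config(),
                        predictors = predictor_vars, target = "iol_ideal_d") {
  X <- as.matrix(table[, predictors, drop = FALSE])
  y <- table[[target]]
  n <- nrow(X)
  fr <- config$train_val_test_split

  members <- vector("list", config$ensemble_size)
  rows <- list()
  failures <- 0L
  for (i in seq_len(config$ensemble_size)) {
    seed_split <- derive_seed(config$seed, paste0("member-", i, "-split"))
    seed_init <- derive_seed(config$seed, paste0("member-", i, "-init"))
    set.seed(seed_split)
    idx <- sample.int(n)
    n_tr <- round(fr[1] * n)
    n_va <- round(fr[2] * n)
    tr <- idx[seq_len(n_tr)]
    va <- idx[n_tr + seq_len(n_va)]
    te <- idx[(n_tr + n_va + 1):n]

    res <- tryCatch({
      w0 <- nguyen_widrow_init(ncol(X), config$hidden_neurons, seed_init)
      fit <- train_mlnn_lm(w0, X[tr, , drop = FALSE], y[tr],
                           X[va, , drop = FALSE], y[va],
                           patience = config$patience_epochs,
                           max_epochs = config$max_epochs)
      test_mse <- mean((y[te] -
                          mlnn_forward(fit$weights, X[te, , drop = FALSE])$y)^2)
      list(fit = fit, test_mse = test_mse)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      members[[i]] <- NULL
      rows[[i]] <- data.frame(member = i, train_mse = NA, val_mse = NA,
                              test_mse = NA, epoch = NA)
    } else {
      members[[i]] <- res$fit$weights
      rows[[i]] <- data.frame(member = i, train_mse = res$fit$train_mse,
                              val_mse = res$fit$val_mse,
                              test_mse = res$test_mse,
                              epoch = res$fit$epoch)
    }
  }
  if (failures > config$ensemble_size / 2) {
    stop("more than half of the ensemble members failed to train",
         call. = FALSE)
  }
  per_member <- do.call(rbind, rows)
  summarize <- function(x) c(mean = mean(x, na.rm = TRUE),
                             median = stats::median(x, na.rm = TRUE),
                             std = stats::sd(x, na.rm = TRUE),
                             min = min(x, na.rm = TRUE),
                             max = max(x, na.rm = TRUE))
  summary_tab <- rbind(
    train_mse = summarize(per_member$train_mse),
    val_mse = summarize(per_member$val_mse),
    test_mse = summarize(per_member$test_mse),
    epoch = summarize(per_member$epoch)
  )
  structure(
    list(members = Filter(Negate(is.null), members),
         report = list(per_member = per_member, summary = summary_tab),
         predictors = predictors, target = target, config = config),
    class = "mlnn_em"
  )
}

#' @export
predict.mlnn_em <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$predictors, drop = FALSE])
  preds <- vapply(object$members, function(w) mlnn_forward(w, X)$y,
                  numeric(nrow(X)))
  if (nrow(X) == 1) preds <- matrix(preds, nrow = 1)
  apply(preds, 1, stats::median)
}

#' Select the hidden-layer width from precomputed scores
#'
#' Argmin of the per-size score (ties broken toward the smaller network).
#'
#' @param scores named numeric vector; names are hidden-layer sizes.
#' @return the selected size (integer).
#' @export
topology_select <- function(scores) {
  sizes <- as.integer(names(scores))
  o <- order(scores, sizes)
  sizes[o[1]]
}

#' Hidden-layer topology search
#'
#' Trains a full ensemble for every candidate hidden-layer size and scores
#' each by median(test MSE) + 1 * SD(test MSE) over the members; the size
#' with the smallest score wins, ties going to the smaller network.
#'
#' @param table normalized training table.
#' @param h_range candidate hidden-layer sizes.
#' @param config base [mlnn_config()]; `hidden_neurons` is overridden.
#' @param predictors,target column names.
#' @return list with `selected`, `scores` (named vector), and `details`
#'   (per-size test-MSE median and SD).
#' @export
topology_search <- function(table, h_range = 1:350, config = mlnn_config(),
                            predictors = predictor_vars,
                            target = "iol_ideal_d") {
  stopifnot(length(h_range) >= 1)
  scores <- numeric(0)
  details <- list()
  for (h in h_range) {
    cfg <- config
    cfg$hidden_neurons <- as.integer(h)
    cfg$seed <- derive_seed(config$seed, paste0("topology-", h))
    em <- fit_mlnn_em(table, cfg, predictors, target)
    tm <- em$report$per_member$test_mse
    sc <- stats::median(tm, na.rm = TRUE) + stats::sd(tm, na.rm = TRUE)
    if (is.na(sc)) sc <- stats::median(tm, na.rm = TRUE)  # single member
    scores[as.character(h)] <- sc
    details[[as.character(h)]] <- c(median = stats::median(tm, na.rm = TRUE),
                                    sd = stats::sd(tm, na.rm = TRUE))
  }
  list(selected = topology_select(scores), scores = scores,
       details = do.call(rbind, details))
}

#' Denormalized IOL power prediction
#'
#' Runs a fitted model on normalized predictors and maps the output back to
#' diopters with the selection-set normalizer. Inputs outside the trained
#' [-1, 1] range are refused, mirroring the out-of-range clearing policy.
#'
#' @param model a fitted `svm_rm` or `mlnn_em` (anything with a `predict`
#'   method returning normalized target values).
#' @param newdata_norm data.frame of normalized predictors.
#' @param normalizer the selection-set [fit_normalizer()] object.
#' @param target target variable name in the normalizer.
#' @param tol tolerance on the range check.
#' @return predicted IOL power in D.
#' @export
predict_iol <- function(model, newdata_norm, normalizer,
                        target = "iol_ideal_d", tol = 1e-8) {
  preds_cols <- intersect(model$predictors, names(newdata_norm))
  vals <- as.matrix(as.data.frame(newdata_norm)[, preds_cols, drop = FALSE])
  if (any(vals < -1 - tol) || any(vals > 1 + tol)) {
    stop("normalized predictors outside the trained [-1, 1] range",
         call. = FALSE)
  }
  y_norm <- stats::predict(model, newdata_norm)
  denormalize(y_norm, normalizer, variable = target)
}
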