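#' @name fbm
#' @title Feature-based health grading model
#' @description
#' A small feedforward classifier grading individual nuclei as
#' healthy/intermediate (HI) or sick (S) from five features -- scattering
#' bandwidth, nucleus count, dry-mass density, surface area and sphericity
#' -- with embryo-level grades obtained by max-voting the per-nucleus
#' predictions. The network is fully connected with hidden layers of size
#' (10, 2), rectified-linear hidden activations and a softmax output,
#' trained full-batch by a quasi-Newton (L-BFGS) minimizer of the
#' cross-entropy loss with an L2 penalty on the weights.
NULL

fbm_feature_order <- c(
  "bw3dB", "nuc_count", "dmd_pg_per_um3", "surface_um2", "sphericity"
)

fbm_classes <- c("HI", "S")

# internal: parameter pack/unpack ----------------------------------------
fbm_shapes <- function(sizes = c(5L, 10L, 2L, 2L)) {
  lapply(seq_len(length(sizes) - 1L), function(i) c(sizes[i], sizes[i + 1L]))
}

fbm_unpack <- function(par, shapes) {
  out <- list(W = list(), b = list())
  pos <- 0L
  for (i in seq_along(shapes)) {
    nw <- prod(shapes[[i]])
    out$W[[i]] <- matrix(par[pos + seq_len(nw)], shapes[[i]][1], shapes[[i]][2])
    pos <- pos + nw
    out$b[[i]] <- par[pos + seq_len(shapes[[i]][2])]
    pos <- pos + shapes[[i]][2]
  }
  out
}

fbm_pack <- function(wb) {
  unlist(c(
    lapply(seq_along(wb$W), function(i) c(as.vector(wb$W[[i]]), wb$b[[i]]))
  ))
}

# internal: forward pass; returns softmax probabilities and (optionally)
# intermediate activations
fbm_forward <- function(wb, X, keep = FALSE) {
  A <- X
  Zs <- As <- list()
  L <- length(wb$W)
  for (i in seq_len(L)) {
    Z <- sweep(A %*% wb$W[[i]], 2, wb$b[[i]], "+")
    if (i < L) {
      A <- pmax(Z, 0)
    } else {
      # softmax with max subtraction for stability
      Zm <- Z - apply(Z, 1, max)
      E <- exp(Zm)
      A <- E / rowSums(E)
    }
    if (keep) {
      Zs[[i]] <- Z
      As[[i]] <- A
    }
  }
  if (keep) list(prob = A, Z = Zs, A = As) else A
}

# internal: loss and analytic gradient of CE + lambda * ||W||^2
fbm_loss_grad <- function(par, shapes, X, Y, lambda) {
  wb <- fbm_unpack(par, shapes)
  fw <- fbm_forward(wb, X, keep = TRUE)
  n <- nrow(X)
  p <- pmax(fw$prob, 1e-300)
  loss <- -sum(Y * log(p)) / n +
    lambda * sum(vapply(wb$W, function(w) sum(w^2), numeric(1)))
  L <- length(wb$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- (fw$prob - Y) / n
  for (i in rev(seq_len(L))) {
    A_prev <- if (i == 1L) X else fw$A[[i - 1L]]
    gW[[i]] <- crossprod(A_prev, delta) + 2 * lambda * wb$W[[i]]
    gb[[i]] <- colSums(delta)
    if (i > 1L) {
      delta <- (delta %*% t(wb$W[[i]])) * (fw$Z[[i - 1L]] > 0)
    }
  }
  list(loss = loss, grad = fbm_pack(list(W = gW, b = gb)))
}

#' Train the feature-based grading model
#'
#' Trains the (10, 2) hidden-layer network on per-nucleus feature rows.
#' Features are z-scored with the training-split statistics (applied
#' identically at prediction time). Weights start from Glorot-uniform
#' initialization with zero biases. Optimization runs full-batch L-BFGS in
#' short segments; after each segment the validation loss is evaluated and
#' the parameters achieving the minimum validation loss are retained. Early
#' stopping triggers after `patience` evaluations without improvement, or
#' when the gradient norm or the loss decrease falls below `tol`.
#'
#' @param features data frame containing the five feature columns
#'   `bw3dB`, `nuc_count`, `dmd_pg_per_um3`, `surface_um2`, `sphericity`.
#' @param labels vector of class labels (`"HI"`/`"S"`, or 0/1 with 1 = S).
#' @param validation optional integer row indices for the validation split;
#'   if omitted, a stratified random fraction `val_fraction` is held out.
#' @param val_fraction validation fraction when `validation` is not given.
#' @param lambda L2 regularization weight (default 1e-6).
#' @param patience validation evaluations without improvement before
#'   stopping (default 20).
#' @param tol gradient / loss-change tolerance (default 1e-9).
#' @param max_evals maximum validation evaluations (optimizer segments).
#' @param seed RNG seed for initialization and the validation split;
#'   identical data + seed reproduces identical weights.
#' @return an `fbm_model` object.
#' @export
train_fbm <- function(features, labels, validation = NULL,
                      val_fraction = 0.15, lambda = 1e-6, patience = 20L,
                      tol = 1e-9, max_evals = 400L, seed = 1L) {
  X_all <- as.matrix(features[, fbm_feature_order])
  if (anyNA(X_all) || !all(is.finite(X_all))) {
    stop("features contain missing or non-finite values")
  }
  y <- if (is.numeric(labels)) {
    fbm_classes[labels + 1L]
  } else {
    as.character(labels)
  }
  if (!all(y %in% fbm_classes)) stop("labels must be 'HI'/'S' (or 0/1)")
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  with_seed(seed, {
    n <- nrow(X_all)
    if (is.null(validation)) {
      validation <- unlist(lapply(fbm_classes, function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1L, round(val_fraction * length(idx))))
      }))
    }
    tr <- setdiff(seq_len(n), validation)
    mu <- colMeans(X_all[tr, , drop = FALSE])
    sg <- apply(X_all[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    Xs <- sweep(sweep(X_all, 2, mu), 2, sg, "/")
    Ymat <- cbind(HI = y == "HI", S = y == "S") * 1

    sizes <- c(ncol(Xs), 10L, 2L, 2L)
    shapes <- fbm_shapes(sizes)
    par0 <- unlist(lapply(shapes, function(s) {
      lim <- sqrt(6 / (s[1] + s[2]))
      c(runif(prod(s), -lim, lim), rep(0, s[2])) # weights then zero biases
    }))

    Xtr <- Xs[tr, , drop = FALSE]
    Ytr <- Ymat[tr, , drop = FALSE]
    Xv <- Xs[validation, , drop = FALSE]
    Yv <- Ymat[validation, , drop = FALSE]
    fn <- function(p) fbm_loss_grad(p, shapes, Xtr, Ytr, lambda)$loss
    gr <- function(p) fbm_loss_grad(p, shapes, Xtr, Ytr, lambda)$grad
    val_loss <- function(p) fbm_loss_grad(p, shapes, Xv, Yv, lambda)$loss

    par <- par0
    best_par <- par
    best_val <- val_loss(par)
    since_best <- 0L
    prev_train <- fn(par)
    stop_reason <- "max_evals"
    evals <- 0L
    for (ev in seq_len(max_evals)) {
      opt <- optim(par, fn, gr,
        method = "L-BFGS-B",
        control = list(maxit = 5L)
      )
      par <- opt$par
      evals <- ev
      v <- val_loss(par)
      if (v < best_val - 1e-12) {
        best_val <- v
        best_par <- par
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      gnorm <- sqrt(sum(gr(par)^2))
      dloss <- abs(prev_train - opt$value)
      prev_train <- opt$value
      if (since_best >= patience) {
        stop_reason <- "validation_patience"
        break
      }
      if (gnorm < tol) {
        stop_reason <- "gradient_tolerance"
        break
      }
      if (dloss < tol) {
        stop_reason <- "loss_tolerance"
        break
      }
    }
    structure(
      list(
        wb = fbm_unpack(best_par, shapes), sizes = sizes,
        features = fbm_feature_order, classes = fbm_classes,
        center = mu, scale = sg, lambda = lambda,
        seed = seed, evals = evals, stop_reason = stop_reason,
        val_loss = best_val
      ),
      class = "fbm_model"
    )
  })
}

#' @export
print.fbm_model <- function(x, ...) {
  cat(sprintf(
    "<fbm_model> layers %s | lambda %.2g | stopped: %s after %d evaluations (val loss %.4g)\n",
    paste(x$sizes, collapse = "-"), x$lambda, x$stop_reason, x$evals,
    x$val_loss
  ))
  invisible(x)
}

#' Per-item class predictions
#'
#' Forward pass of a trained model over feature rows. The predicted class is
#' the softmax argmax (an exact tie resolves to HI, the first class); the
#' score is the winning probability.
#'
#' @param model an `fbm_model`.
#' @param rows data frame with the model's five feature columns.
#' @return data frame with `class` and `score`, one row per input row.
#' @export
predict_items <- function(model, rows) {
  missing_cols <- setdiff(model$features, names(rows))
  if (length(missing_cols)) {
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(rows[, model$features, drop = FALSE])
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  p <- fbm_forward(model$wb, Xs)
  cls <- model$classes[max.col(p, ties.method = "first")]
  data.frame(
    class = cls, score = p[cbind(seq_len(nrow(p)), max.col(p, "first"))],
    stringsAsFactors = FALSE
  )
}

#' Embryo-level grade by max-voting
#'
#' The embryo's class is the most frequent class among per-item (nucleus or
#' z-slice) predictions. The confidence `cp` is the mean prediction score
#' over the majority-class items. An exact tie resolves conservatively to S
#' (down-grading is the acceptable error mode) and is flagged.
#'
#' @param predictions data frame with `class` and `score` columns (from
#'   [predict_items()]).
#' @return a `grade_result`: list with `class`, `cp`, `majority_fraction`,
#'   `tie`, `votes` (the input).
#' @export
max_vote <- function(predictions) {
  if (nrow(predictions) < 1L) stop("empty prediction list")
  counts <- vapply(fbm_classes, function(cl) {
    sum(predictions$class == cl)
  }, numeric(1))
  tie <- counts["HI"] == counts["S"]
  winner <- if (tie) "S" else fbm_classes[which.max(counts)]
  maj <- predictions$class == winner
  structure(
    list(
      class = winner,
      cp = mean(predictions$score[maj]),
      majority_fraction = mean(maj),
      tie = unname(tie),
      votes = predictions
    ),
    class = "grade_result"
  )
}

#' @export
print.grade_result <- function(x, ...) {
  cat(sprintf(
    "<grade_result> %s (cp %.3f, %.0f%% of %d votes%s)\n",
    x$class, x$cp, 100 * x$majority_fraction, nrow(x$votes),
    if (x$tie) ", TIE" else ""
  ))
  invisible(x)
}

#' Grade from a sparse subset of z-slices
#'
#' Mimics a faster acquisition that records fewer z-sections: per-slice
#' predictions are subsampled to the requested inter-slice spacing by
#' dropping intermediate entries, then max-voted. Configurations known to be
#' unreliable are refused unless forced: spacings above 10 um, or fewer than
#' 7 selected slices (6 slices are specifically avoided since an even split
#' of a small even count is inconclusive).
#'
#' @param predictions data frame with `class`, `score` and `z_um` columns.
#' @param step_um requested inter-slice spacing in micrometres.
#' @param min_slices minimum number of selected slices (default 7).
#' @param max_step_um maximum allowed spacing (default 10 um).
#' @param force bypass the policy checks.
#' @return a `grade_result` (see [max_vote()]) with attribute `selected`
#'   (row indices used).
#' @export
sparse_vote <- function(predictions, step_um, min_slices = 7L,
                        max_step_um = 10, force = FALSE) {
  stopifnot(!is.null(predictions$z_um))
  if (!force && step_um > max_step_um) {
    stop(sprintf(
      "sparse-vote policy: spacing %.3g um exceeds the %.3g um bound (use force = TRUE to override)",
      step_um, max_step_um
    ))
  }
  ord <- order(predictions$z_um)
  z <- predictions$z_um[ord]
  dz <- if (length(z) > 1L) median(diff(z)) else step_um
  stride <- max(1L, as.integer(round(step_um / dz)))
  sel <- ord[seq(1L, length(ord), by = stride)]
  if (!force && length(sel) < min_slices) {
    stop(sprintf(
      "sparse-vote policy: only %d slices selected, minimum is %d (use force = TRUE to override)",
      length(sel), min_slices
    ))
  }
  out <- max_vote(predictions[sel, , drop = FALSE])
  attr(out, "selected") <- sel
  out
}

#' Serialize / restore an FBM model as JSON
#'
#' @param model an `fbm_model`.
#' @param path file path.
#' @return `read_fbm` returns the restored model; `write_fbm` returns the
#'   path invisibly.
#' @export
write_fbm <- function(model, path) {
  obj <- list(
    sizes = model$sizes, features = model$features, classes = model$classes,
    W = lapply(model$wb$W, function(w) unclass(w)),
    b = model$wb$b, center = as.list(model$center),
    scale = as.list(model$scale),
    lambda = model$lambda, seed = model$seed, evals = model$evals,
    stop_reason = model$stop_reason, val_loss = model$val_loss
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fbm
#' @export
read_fbm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      wb = list(W = lapply(obj$W, as.matrix), b = lapply(obj$b, as.numeric)),
      sizes = as.integer(obj$sizes), features = obj$features,
      classes = obj$classes,
      center = unlist(obj$center), scale = unlist(obj$scale),
      lambda = obj$lambda, seed = obj$seed, evals = obj$evals,
      stop_reason = obj$stop_reason, val_loss = obj$val_loss
    ),
    class = "fbm_model"
  )
}
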