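#' Assemble the 8-predictor outcome matrix
#'
#' Builds the candidate-predictor matrix for outcome-group prediction:
#' wall thickness (WT), circumferential and longitudinal curvature (C_cur,
#' L_cur) and end-diastolic volume (V) at begin-ejection from the
#' begin-ejection metrics table, begin-ejection wall stress (StressE) and the
#' three phase-difference stresses from the phase-stress table:
#' StressE_D = BE - EF, StressE_F = BE - EE, StressE_C = BE - BF.
#'
#' @param phase_stress data.frame with columns \code{patient},
#'   \code{stress_2g_bf}, \code{stress_2g_ef}, \code{stress_2g_be},
#'   \code{stress_2g_ee} (kPa).
#' @param geometry data.frame with columns \code{patient}, \code{group},
#'   \code{wt}, \code{ccur}, \code{lcur}, \code{edv}.
#' @return data.frame with columns WT, C_cur, L_cur, V, StressE, StressE_D,
#'   StressE_F, StressE_C and the binary \code{group} (1/2) outcome.
#' @export
build_predictors <- function(phase_stress, geometry) {
  need_s <- c("patient", "stress_2g_bf", "stress_2g_ef", "stress_2g_be",
              "stress_2g_ee")
  need_g <- c("patient", "group", "wt", "ccur", "lcur", "edv")
  stopifnot(all(need_s %in% names(phase_stress)),
            all(need_g %in% names(geometry)))
  if (!setequal(phase_stress$patient, geometry$patient))
    stop("patient sets of the two tables differ")
  m <- merge(geometry[, need_g], phase_stress[, need_s], by = "patient",
             sort = TRUE)
  if (any(!stats::complete.cases(m))) stop("missing patient values")
  out <- data.frame(
    patient = m$patient,
    WT = m$wt, C_cur = m$ccur, L_cur = m$lcur, V = m$edv,
    StressE = m$stress_2g_be,
    StressE_D = m$stress_2g_be - m$stress_2g_ef,
    StressE_F = m$stress_2g_be - m$stress_2g_ee,
    StressE_C = m$stress_2g_be - m$stress_2g_bf,
    group = m$group)
  out
}

#' Column names of the 8 candidate predictors
#' @return character vector in fixed order.
#' @export
predictor_names <- function() {
  c("WT", "C_cur", "L_cur", "V", "StressE", "StressE_D", "StressE_F",
    "StressE_C")
}

# Ridge-penalized logistic IRLS with step-halving (internal). X includes no
# intercept column; the intercept is unpenalized.
logistic_irls <- function(X, y, ridge = 1e-3, max_iter = 60, tol = 1e-9) {
  X1 <- cbind(1, X)
  dimnames(X1) <- NULL
  p <- ncol(X1)
  pen <- c(0, rep.int(ridge, p - 1L))
  penmat <- diag(pen + 1e-12, p)
  nll <- function(b) {                     # penalized neg. log-likelihood
    e <- X1 %*% b
    sum(log1p(exp(-abs(e))) + e * (e > 0) - y * e) + 0.5 * sum(pen * b * b)
  }
  beta <- numeric(p)
  obj <- nll(beta)
  g <- numeric(p)
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(drop(X1 %*% beta))
    g <- drop(crossprod(X1, y - mu)) - pen * beta
    W <- mu * (1 - mu) + 1e-10
    H <- crossprod(X1 * W, X1) + penmat
    step <- solve(H, g)
    s <- 1
    repeat {
      bnew <- beta + s * step
      onew <- nll(bnew)
      if (onew <= obj + 1e-12 || s < 1e-6) break
      s <- s / 2
    }
    beta <- bnew
    if (abs(obj - onew) < tol * (abs(onew) + 1)) {
      return(list(coef = beta, converged = TRUE, iterations = it,
                  grad_norm = sqrt(sum(g^2))))
    }
    obj <- onew
  }
  list(coef = beta, converged = FALSE, iterations = max_iter,
       grad_norm = sqrt(sum(g^2)))
}

#' Ridge-penalized logistic regression
#'
#' Penalized maximum likelihood by iteratively reweighted least squares with
#' a small ridge penalty on the (standardized) slopes; the intercept is
#' unpenalized. The default penalty 1e-3 tames the complete separation that
#' several predictor subsets produce on a 16-patient cohort.
#'
#' @param X numeric predictor matrix (columns are assumed standardized by the
#'   caller for the penalty to be scale-meaningful).
#' @param y binary 0/1 outcome.
#' @param ridge ridge penalty on slopes (default 1e-3).
#' @return list with \code{coef} (intercept first), \code{scores} (fitted
#'   probabilities), \code{converged}, \code{iterations}.
#' @export
fit_logistic <- function(X, y, ridge = 1e-3) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  fit <- logistic_irls(X, y, ridge)
  if (!fit$converged && fit$grad_norm > 1e-4)
    stop("logistic non-convergence: gradient norm ", signif(fit$grad_norm, 3))
  scores <- drop(stats::plogis(cbind(1, X) %*% fit$coef))
  list(coef = fit$coef, scores = scores, converged = fit$converged,
       iterations = fit$iterations)
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Probability that a random positive outranks a random negative, ties
#' counted 1/2, computed from midranks.
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels (both classes present).
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("undefined AUC: single-class input")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Optimal probability cutoff (Youden)
#'
#' Scans all midpoints between adjacent distinct scores (plus the boundaries)
#' for the cutoff maximizing sensitivity + specificity; ties are broken
#' toward higher specificity (higher cutoff).
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 labels (both classes present).
#' @return list with \code{cutoff}, \code{sensitivity}, \code{specificity}.
#' @export
optimal_cutoff <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("undefined cutoff: single-class input")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  best <- NULL
  for (cu in cand) {
    pred <- scores > cu
    sens <- sum(pred & labels == 1) / n1
    spec <- sum(!pred & labels == 0) / n0
    if (is.null(best) || sens + spec > best$sum + 1e-12 ||
        (abs(sens + spec - best$sum) <= 1e-12 && spec > best$specificity))
      best <- list(cutoff = cu, sensitivity = sens, specificity = spec,
                   sum = sens + spec)
  }
  best[c("cutoff", "sensitivity", "specificity")]
}

#' Cross-validation configuration
#'
#' @param folds folds per repeat (default 2).
#' @param repeats repeats per round (default 20).
#' @param rounds rounds for the AUC average and confidence interval
#'   (default 100).
#' @param base_seed base RNG seed; round r uses \code{base_seed + r}.
#' @param stratified stratify folds by outcome group (default TRUE; prevents
#'   single-class folds at n = 16).
#' @param ridge ridge penalty passed to the logistic fit (default 1e-3).
#' @param pooling \code{"pooled"}: one AUC per repeat from the pooled
#'   held-out scores (default); \code{"per-fold"}: AUC per fold, averaged.
#' @return object of class \code{cv_config}.
#' @export
cv_config <- function(folds = 2, repeats = 20, rounds = 100, base_seed = 1,
                      stratified = TRUE, ridge = 1e-3,
                      pooling = c("pooled", "per-fold")) {
  stopifnot(folds >= 2, repeats >= 1, rounds >= 1)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 rounds = as.integer(rounds), base_seed = as.integer(base_seed),
                 stratified = isTRUE(stratified), ridge = ridge,
                 pooling = match.arg(pooling)),
            class = "cv_config")
}

# Fold assignment for one repeat (internal); returns integer vector 1..folds
make_folds <- function(y, folds, stratified) {
  n <- length(y)
  f <- integer(n)
  if (stratified) {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  } else {
    f <- sample(rep_len(seq_len(folds), n))
  }
  f
}

# All fold assignments for one round: list of length repeats (internal)
round_splits <- function(y, cfg, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  reps <- vector("list", cfg$repeats)
  for (k in seq_len(cfg$repeats)) {
    repeat {
      f <- make_folds(y, cfg$folds, cfg$stratified)
      ok <- all(vapply(seq_len(cfg$folds), function(j)
        length(unique(y[f == j])) == 2L, TRUE))
      if (ok) break                       # re-draw single-class folds
    }
    reps[[k]] <- f
  }
  reps
}

# AUC and cutoff for one repeat on standardized Xs (internal)
repeat_metrics <- function(Xs, y, fold, cfg) {
  n <- length(y)
  held <- numeric(n)
  if (cfg$pooling == "per-fold") aucs <- numeric(cfg$folds)
  for (j in seq_len(cfg$folds)) {
    te <- fold == j
    fit <- logistic_irls(Xs[!te, , drop = FALSE], y[!te], cfg$ridge)
    held[te] <- drop(stats::plogis(cbind(1, Xs[te, , drop = FALSE]) %*%
                                     fit$coef))
    if (cfg$pooling == "per-fold") aucs[j] <- auc(held[te], y[te])
  }
  oc <- optimal_cutoff(held, y)
  a <- if (cfg$pooling == "per-fold") mean(aucs) else auc(held, y)
  list(auc = a, cutoff = oc$cutoff, sens = oc$sensitivity,
       spec = oc$specificity)
}

#' Repeated cross-validated prediction performance for one predictor subset
#'
#' For each round, runs \code{repeats} repeats of stratified k-fold
#' cross-validation of the ridge-logistic model on the chosen predictor
#' subset; held-out scores are pooled per repeat into an AUC and a
#' Youden-optimal cutoff, and repeats are averaged into the round AUC. Across
#' rounds the AUC average and a 2.5/97.5-percentile confidence interval are
#' reported. Deterministic given the base seed.
#'
#' @param X predictor data.frame/matrix (columns standardized internally).
#' @param y binary 0/1 outcome (1 = worse-outcome group).
#' @param subset character or integer vector of predictor columns.
#' @param cfg a \code{\link{cv_config}}.
#' @param splits optional precomputed splits (list over rounds of lists over
#'   repeats of fold vectors), used by \code{\link{rank_combinations}} so all
#'   subsets see identical folds.
#' @return one-row data.frame: subset, auc (round-1 value), auc_average,
#'   ci_lo, ci_hi, cutoff, sensitivity, specificity.
#' @export
repeated_cv <- function(X, y, subset, cfg = cv_config(), splits = NULL) {
  if (length(subset) == 0) stop("subset must be non-empty")
  X <- as.matrix(as.data.frame(X)[, subset, drop = FALSE])
  Xs <- scale(X)
  Xs[is.nan(Xs)] <- 0                     # constant columns
  dimnames(Xs) <- NULL; attributes(Xs)$`scaled:center` <- NULL
  attributes(Xs)$`scaled:scale` <- NULL
  y <- as.numeric(y)
  round_auc <- numeric(cfg$rounds)
  cuts <- sens <- spec <- numeric(0)
  for (r in seq_len(cfg$rounds)) {
    sp <- if (is.null(splits)) round_splits(y, cfg, cfg$base_seed + r)
    else splits[[r]]
    rep_auc <- numeric(cfg$repeats)
    for (k in seq_len(cfg$repeats)) {
      m <- repeat_metrics(Xs, y, sp[[k]], cfg)
      rep_auc[k] <- m$auc
      cuts <- c(cuts, m$cutoff); sens <- c(sens, m$sens)
      spec <- c(spec, m$spec)
    }
    round_auc[r] <- mean(rep_auc)
  }
  ci <- stats::quantile(round_auc, c(0.025, 0.975), names = FALSE)
  data.frame(subset = paste(subset, collapse = "+"),
             auc = round_auc[1], auc_average = mean(round_auc),
             ci_lo = ci[1], ci_hi = ci[2],
             cutoff = mean(cuts), sensitivity = mean(sens),
             specificity = mean(spec))
}

#' Rank all predictor-subset combinations
#'
#' Runs \code{\link{repeated_cv}} for every non-empty subset of the given
#' predictors (255 subsets for the 8 candidates), with identical fold splits
#' across subsets, and ranks them by AUC average (descending).
#'
#' @param X predictor data.frame/matrix.
#' @param y binary 0/1 outcome.
#' @param cfg a \code{\link{cv_config}}.
#' @param predictors columns to combine (default \code{colnames(X)} minus
#'   any \code{patient}/\code{group} bookkeeping columns).
#' @return data.frame with one row per subset, ranked; column \code{rank} is
#'   a permutation of 1..(2^k - 1).
#' @export
rank_combinations <- function(X, y, cfg = cv_config(), predictors = NULL) {
  X <- as.data.frame(X)
  if (is.null(predictors))
    predictors <- setdiff(colnames(X), c("patient", "group"))
  k <- length(predictors)
  stopifnot(k >= 1, k <= 16)
  y <- as.numeric(y)
  splits <- lapply(seq_len(cfg$rounds), function(r)
    round_splits(y, cfg, cfg$base_seed + r))
  subsets <- lapply(seq_len(2^k - 1), function(m)
    predictors[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
  rows <- lapply(subsets, function(s)
    repeated_cv(X, y, s, cfg, splits = splits))
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc_average), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
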